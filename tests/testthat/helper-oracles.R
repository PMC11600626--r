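# Shared independent oracles and fixture builders, all generated in code.

# Grid-search oracle for the antimode-placing mixture weight: for each
# candidate weight, evaluate the two-component mixture density on a dense
# grid and record where its interior minimum falls; return the weight whose
# minimum is closest to the target.  Independent of solve_mixture_weight.
grid_weight_oracle <- function(m1, s1, m2, s2, target,
                               w_step = 5e-5, x_step = 1e-3) {
  x <- seq(target - 1, target + 1, by = x_step)
  ws <- seq(w_step, 1 - w_step, by = w_step)
  best_w <- NA_real_
  best_err <- Inf
  d1 <- dnorm(x, m1, s1)
  d2 <- dnorm(x, m2, s2)
  for (w in ws) {
    f <- w * d1 + (1 - w) * d2
    i <- which.min(f)
    if (i == 1L || i == length(x)) next         # minimum not interior
    err <- abs(x[i] - target)
    if (err < best_err) {
      best_err <- err
      best_w <- w
    }
  }
  best_w
}

# Exhaustive window-scan oracle: score every window by direct summation.
exhaustive_window_scores <- function(profile, seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- profile$length
  n <- length(chars)
  if (n < L) return(numeric(0))
  sapply(seq_len(n - L + 1), function(s) {
    total <- 0
    for (k in seq_len(L)) {
      r <- chars[s + k - 1]
      if (r %in% colnames(profile$weights))
        total <- total + profile$weights[k, r]
    }
    unname(total)
  })
}

# Brute-force per-column consensus-score oracle.
consensus_scores_oracle <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  sapply(seq_len(nrow(m)), function(i) {
    total <- 0
    for (j in seq_len(ncol(m))) {
      r <- m[i, j]
      if (r %in% c("-", ".")) next
      total <- total + sum(m[, j] == r)
    }
    total
  })
}

# A small aligned family: n near-identical rows derived from one consensus
# (deterministic substitutions), optionally plus one unrelated row.
make_alignment <- function(consensus, n = 10, outlier = FALSE, seed = 42) {
  set.seed(seed)
  rows <- replicate(n, consensus)
  names(rows) <- sprintf("row%02d", seq_len(n))
  if (outlier) {
    len <- nchar(consensus)
    other <- paste(sample(setdiff(introntd:::AA_RESIDUES, "A"), len,
                          replace = TRUE), collapse = "")
    rows <- c(rows, outlier = other)
  }
  rows
}

# Generate an annotation, write it out and read it back: the usual entry
# point for classifier tests.
read_annotation_from <- function(spec, seed) {
  sim <- generate_annotation(spec, seed = seed)
  path <- tempfile(fileext = ".gff3")
  write_annotation(sim, path)
  read_annotation(path)
}

random_protein <- function(len, seed) {
  set.seed(seed)
  paste(sample(introntd:::AA_RESIDUES, len, replace = TRUE), collapse = "")
}
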