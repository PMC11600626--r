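# Profile models over protein alignments: consensus scoring, alignment
# filtering, position-specific log-odds construction and window scanning.
#
# The profile model is a column-wise log-odds matrix (a PSSM).  It supplies
# the same decision contract as an HMM domain scan — a windowed score
# compared against calibrated thresholds — while remaining transparent and
# dependency-free.

#' Per-sequence consensus scores of an alignment
#'
#' The score of a row is the sum over columns of the count, across all
#' rows, of the residue that row carries in the column.  Gap positions
#' contribute 0.  Ten identical rows of length 30 therefore all score 300;
#' a row sharing no residue with any other scores its own length.
#'
#' @param alignment equal-length aligned sequences: named character vector,
#'   character matrix, or `Biostrings::AAStringSet`.
#' @return named numeric vector of scores, one per row.
#' @export
consensus_scores <- function(alignment) {
  m <- alignment_matrix(alignment)
  scores <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- !is_gap(col)
    if (!any(res)) next
    counts <- table(col[res])
    scores[res] <- scores[res] + as.numeric(counts[col[res]])
  }
  stats::setNames(scores, rownames(m))
}

#' Filter alignment rows by consensus score
#'
#' Removes rows scoring below `threshold` and returns the survivors (a
#' single pass: consensus statistics are recomputed on the survivors by any
#' downstream call, but rows are not re-aligned).  Removed row names are
#' attached as attribute `removed`.
#'
#' @param alignment as in [consensus_scores()].
#' @param threshold minimum consensus score to keep a row; default 250.
#' @return the surviving rows as a character matrix with attribute
#'   `removed`.
#' @export
filter_alignment <- function(alignment, threshold = 250) {
  stopifnot(threshold >= 0)
  m <- alignment_matrix(alignment)
  sc <- consensus_scores(m)
  keep <- sc >= threshold
  if (!any(keep)) stop("all rows fall below the consensus-score threshold")
  removed <- rownames(m)[!keep]
  if (length(removed))
    message("filter_alignment: removed ", length(removed), " row(s): ",
            paste(removed, collapse = ", "))
  out <- m[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Build a position-specific log-odds profile from an alignment
#'
#' Column weights are
#' `log2(((count + pseudocount * background) / (n_rows + pseudocount)) / background)`.
#' Columns with more than 50% gaps are dropped from the model.
#'
#' @param alignment as in [consensus_scores()]; typically the output of
#'   [filter_alignment()].
#' @param pseudocount Laplace-style pseudocount mass; default 1.
#' @param background length-20 residue background frequencies summing to 1;
#'   default uniform 1/20.
#' @param name model name attached to hits.
#' @return object of class `profile_model`: list with `weights`
#'   (length x 20 matrix, columns [AA_RESIDUES]), `counts`, `length`,
#'   `consensus` (modal residue per kept column), `background`,
#'   `pseudocount`, `name`, `kept_columns`.
#' @export
build_profile <- function(alignment, pseudocount = 1,
                          background = rep(1 / 20, 20), name = "profile") {
  m <- alignment_matrix(alignment)
  if (nrow(m) == 0L) stop("empty alignment")
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-6,
            pseudocount >= 0)
  background <- stats::setNames(as.numeric(background), AA_RESIDUES)
  gap_frac <- apply(m, 2, function(col) mean(is_gap(col)))
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0L) stop("all columns exceed the 50% gap limit")
  n <- nrow(m)
  counts <- matrix(0, nrow = length(keep), ncol = 20,
                   dimnames = list(NULL, AA_RESIDUES))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    tab <- table(factor(col[!is_gap(col)], levels = AA_RESIDUES))
    counts[k, ] <- as.numeric(tab)
  }
  weights <- log2(sweep(counts + pseudocount * rep(background, each = nrow(counts)),
                        1, n + pseudocount, "/"))
  weights <- sweep(weights, 2, log2(background), "-")
  consensus <- AA_RESIDUES[apply(counts, 1, which.max)]
  structure(list(weights = weights, counts = counts,
                 length = length(keep), consensus = paste(consensus, collapse = ""),
                 background = background, pseudocount = pseudocount,
                 name = name, kept_columns = keep),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model '%s': %d columns (log2 odds)\n", x$name, x$length))
  invisible(x)
}

#' Score one window of a profile (internal)
#'
#' @keywords internal
#' @noRd
profile_window_scores <- function(profile, chars) {
  L <- profile$length
  n <- length(chars)
  if (n < L) return(numeric(0))
  ridx <- match(chars, AA_RESIDUES)          # NA for X/gap: contributes 0
  w <- profile$weights
  vapply(seq_len(n - L + 1L), function(s) {
    idx <- ridx[s:(s + L - 1L)]
    ok <- !is.na(idx)
    sum(w[cbind(which(ok), idx[ok])])
  }, numeric(1))
}

#' Scan a peptide sequence with a profile model
#'
#' Slides the profile over all windows of the sequence, then reports
#' non-overlapping hits with score above `threshold`, chosen greedily by
#' descending score.  The best-scoring window is always reported (flagged
#' in column `above_threshold`) so that score distributions can be
#' inspected for calibration even when nothing passes.
#'
#' @param profile a [build_profile()] model.
#' @param seq a protein sequence (single character string).
#' @param seq_id identifier used in the output.
#' @param threshold minimum score for a reported hit, log2-odds units.
#' @return data.frame of hits: `seq_id`, `model`, `start`, `end`, `score`,
#'   `above_threshold`; zero rows when the sequence is shorter than the
#'   profile.
#' @export
scan_peptides <- function(profile, seq, seq_id = "seq", threshold = 0) {
  stopifnot(inherits(profile, "profile_model"), is.character(seq),
            length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  scores <- profile_window_scores(profile, chars)
  empty <- data.frame(seq_id = character(0), model = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), above_threshold = logical(0))
  if (length(scores) == 0L) return(empty)
  L <- profile$length
  ord <- order(scores, decreasing = TRUE)
  taken <- rep(FALSE, length(chars))
  picked <- integer(0)
  for (s in ord) {
    if (scores[s] < threshold) break
    span <- s:(s + L - 1L)
    if (any(taken[span])) next
    picked <- c(picked, s)
    taken[span] <- TRUE
  }
  if (length(picked) == 0L) picked <- ord[1L]   # best window, for calibration
  picked <- sort(picked)
  data.frame(seq_id = seq_id, model = profile$name, start = picked,
             end = picked + L - 1L, score = scores[picked],
             above_threshold = scores[picked] >= threshold,
             stringsAsFactors = FALSE)
}
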