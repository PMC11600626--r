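# Pairwise sequence distances over a multiple sequence alignment, using the
# rescaled residue distance: the mean of D over the columns where both
# sequences carry a standard residue.

#' Distance between two aligned rows
#'
#' The aligned set `i` comprises the columns where both rows carry one of
#' the 20 standard residues (gaps and unknown residues such as X are
#' excluded).  The distance is `sum(D[a[i], b[i]]) / |i|`.
#'
#' @param rowA,rowB aligned sequences of equal length (character strings).
#' @param D a [rescale_substitution_matrix()] result.
#' @return mean residue distance.
#' @export
aligned_pair_distance <- function(rowA, rowB, D) {
  stopifnot(is.character(rowA), is.character(rowB),
            nchar(rowA) == nchar(rowB))
  a <- strsplit(toupper(rowA), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(rowB), "", fixed = TRUE)[[1]]
  ia <- match(a, AA_RESIDUES)
  ib <- match(b, AA_RESIDUES)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok))
    stop("no aligned residue pairs: the rows do not overlap")
  sum(unclass(D)[cbind(ia[ok], ib[ok])]) / sum(ok)
}

#' Pairwise distance matrix over an alignment
#'
#' Computes [aligned_pair_distance()] for every unordered pair of rows,
#' recording the number of aligned residue pairs per comparison.  Pairs
#' with no overlap are recorded as `NA` with a warning.
#'
#' @param alignment aligned sequences (named character vector, matrix, or
#'   `AAStringSet`), `>= 2` rows.
#' @param D a [rescale_substitution_matrix()] result.
#' @return object of class `pairwise_distances`: list with `labels`,
#'   `distances` (symmetric matrix, zero diagonal), `n_aligned` (matrix of
#'   pair overlap counts).
#' @export
pairwise_distance_matrix <- function(alignment, D) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least two aligned sequences")
  labels <- rownames(m)
  idx <- matrix(match(m, AA_RESIDUES), nrow = n)   # NA for gap/unknown
  Dm <- unclass(D)
  dist <- matrix(0, n, n, dimnames = list(labels, labels))
  n_aligned <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(n_aligned) <- rowSums(!is.na(idx))
  missing_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      k <- sum(ok)
      n_aligned[i, j] <- n_aligned[j, i] <- k
      if (k == 0L) {
        dist[i, j] <- dist[j, i] <- NA_real_
        missing_pairs <- missing_pairs + 1L
        next
      }
      d <- sum(Dm[cbind(idx[i, ok], idx[j, ok])]) / k
      dist[i, j] <- dist[j, i] <- d
    }
  }
  if (missing_pairs > 0L)
    warning(missing_pairs, " pair(s) share no aligned residues; ",
            "distances recorded as NA")
  structure(list(labels = labels, distances = dist, n_aligned = n_aligned),
            class = "pairwise_distances")
}

#' @export
print.pairwise_distances <- function(x, ...) {
  cat(sprintf("pairwise_distances: %d sequences, mean distance %.3f\n",
              length(x$labels),
              mean(x$distances[upper.tri(x$distances)], na.rm = TRUE)))
  invisible(x)
}

#' Write a labelled symmetric distance matrix as TSV
#'
#' @param x a `pairwise_distances` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(x, path) {
  stopifnot(inherits(x, "pairwise_distances"))
  utils::write.table(
    data.frame(label = x$labels, x$distances, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
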