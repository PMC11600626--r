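# PR-SET class assignment: average-linkage clustering of the pairwise
# distance matrix, cut to k classes, ordered by similarity to a reference
# sequence (class I is the most reference-similar).

#' Assign sequences to distance classes
#'
#' Average-linkage hierarchical clustering on the pairwise distance matrix,
#' cut to `k` clusters.  Classes are labelled with roman numerals I..k in
#' order of increasing mean distance to the `reference` row, so class I is
#' the most reference-similar (the reference is typically the rooting
#' outgroup, e.g. a mammalian orthologue).
#'
#' @param M a `pairwise_distances` object or labelled symmetric matrix.
#' @param k number of classes, `2 <= k <= n`.
#' @param reference label of the reference row used to order classes;
#'   default: the first label.
#' @return object of class `class_assignment`: list with `classes` (named
#'   character vector, labels I..k per sequence), `k`, `reference`,
#'   `linkage` (`"average"`), `class_mean_ref_distance`.
#' @export
assign_classes <- function(M, k = 4, reference = NULL) {
  D <- if (inherits(M, "pairwise_distances")) M$distances else as.matrix(M)
  n <- nrow(D)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  labels <- rownames(D)
  reference <- reference %||% labels[1]
  if (!reference %in% labels) stop("reference label not in matrix: ", reference)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cut <- stats::cutree(hc, k = k)
  ref_d <- vapply(seq_len(k), function(cl) {
    members <- labels[cut == cl]
    mean(D[reference, members])
  }, numeric(1))
  roman <- as.character(utils::as.roman(seq_len(k)))
  relabel <- roman[rank(ref_d, ties.method = "first")]
  classes <- stats::setNames(relabel[cut], labels)
  structure(list(classes = classes, k = k, reference = reference,
                 linkage = "average",
                 class_mean_ref_distance = stats::setNames(
                   sort(ref_d), roman)),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("class_assignment: %d sequences in %d classes (ref: %s)\n",
              length(x$classes), x$k, x$reference))
  print(table(x$classes))
  invisible(x)
}
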