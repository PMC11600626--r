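# Substitution matrices and the rescaled residue distance.
#
# The residue distance is derived from a BLOSUM-style score matrix B as
#   D(x, y) = -B(x, y) + (B(x, x) + B(y, y)) / 2
# which is zero on the diagonal, symmetric, and non-negative whenever
# B(x, y) <= (B(x, x) + B(y, y)) / 2, as holds for BLOSUM62.

#' Read a substitution matrix in the standard text layout
#'
#' Parses the format used to distribute BLOSUM/PAM matrices: `#` comment
#' lines, a header row of residue letters, then one labelled row of integer
#' scores per residue.  A copy of BLOSUM62 ships with the package (see
#' examples).
#'
#' @param path matrix file.
#' @return symmetric integer matrix with residue dimnames (class
#'   `substitution_matrix`).
#' @examples
#' B <- read_substitution_matrix(
#'   system.file("extdata", "BLOSUM62.txt", package = "introntd"))
#' B["A", "R"]
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1]))
  if (any(vapply(vals, length, integer(1)) != length(header)))
    stop("matrix rows do not match header width")
  B <- do.call(rbind, vals)
  dimnames(B) <- list(labels, header)
  if (!isTRUE(all.equal(B, t(B)))) stop("substitution matrix is not symmetric")
  if (max(B[upper.tri(B)]) > max(diag(B)))
    warning("off-diagonal maximum exceeds diagonal maximum; ",
            "rescaled distances may be negative")
  class(B) <- c("substitution_matrix", class(B))
  B
}

#' Load the packaged BLOSUM62 matrix
#'
#' @return the BLOSUM62 `substitution_matrix` (24 x 24, including B/Z/X/*).
#' @export
blosum62 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "introntd"))
}

#' Rescale a substitution matrix into a residue distance matrix
#'
#' Applies `D(x, y) = -B(x, y) + (B(x, x) + B(y, y)) / 2` over the 20
#' standard residues.
#'
#' @param B a symmetric substitution matrix with residue dimnames (e.g.
#'   from [read_substitution_matrix()]); extra columns such as B/Z/X/* are
#'   ignored.
#' @return 20 x 20 numeric distance matrix (class
#'   `rescaled_distance_matrix`): zero diagonal, symmetric.
#' @export
rescale_substitution_matrix <- function(B) {
  B <- unclass(B)
  if (!isTRUE(all.equal(B, t(B)))) stop("substitution matrix must be symmetric")
  if (!all(AA_RESIDUES %in% rownames(B)))
    stop("matrix must cover the 20 standard residues")
  B <- B[AA_RESIDUES, AA_RESIDUES]
  self <- diag(B)
  D <- -B + (outer(self, self, "+")) / 2
  class(D) <- c("rescaled_distance_matrix", class(D))
  D
}
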