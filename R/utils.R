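# Shared constants and small internal helpers.

# The 20 standard amino-acid residues, BLOSUM row order.
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHARS <- c("-", ".")

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Alignment rows (character vector of equal-length strings) -> character matrix
#' @keywords internal
#' @noRd
alignment_matrix <- function(alignment) {
  if (methods::is(alignment, "AAStringSet") || methods::is(alignment, "XStringSet"))
    alignment <- as.character(alignment)
  if (is.matrix(alignment)) {
    if (!is.character(alignment)) stop("alignment matrix must be character")
    return(alignment)
  }
  if (!is.character(alignment) || length(alignment) == 0L)
    stop("alignment must be a named character vector, matrix or AAStringSet")
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("ragged alignment: rows have differing lengths")
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(m) <- if (is.null(names(alignment)))
    sprintf("seq%03d", seq_along(alignment)) else names(alignment)
  m
}

#' @keywords internal
#' @noRd
is_gap <- function(x) x %in% GAP_CHARS

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
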