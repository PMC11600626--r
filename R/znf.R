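# C2H2 zinc-finger detection and array grouping.

#' Detect C2H2 zinc fingers and finger arrays
#'
#' Matches the simplified C2H2 pattern `C-x(2,4)-C-x(11,13)-H-x(3,5)-H`
#' non-overlapping, left to right.  Consecutive fingers whose separating
#' gap is at most `array_gap` residues are grouped into one array;
#' mammalian-like PRDM9 orthologues typically show one long terminal array
#' with an optional isolated proximal finger.
#'
#' @param seq protein sequence (single character string).
#' @param array_gap maximum residue gap between consecutive fingers of one
#'   array; default 15.
#' @return list with `fingers` (data.frame: `start`, `end`, 1-based
#'   inclusive) and `arrays` (data.frame: `first_finger`, `n_fingers`,
#'   `start`, `end`).
#' @export
detect_zn_fingers <- function(seq, array_gap = 15) {
  stopifnot(is.character(seq), length(seq) == 1L, array_gap >= 0)
  pat <- "C.{2,4}C.{11,13}H.{3,5}H"
  m <- gregexpr(pat, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) {
    fingers <- data.frame(start = integer(0), end = integer(0))
  } else {
    fingers <- data.frame(start = as.integer(m),
                          end = as.integer(m) + attr(m, "match.length") - 1L)
  }
  if (nrow(fingers) == 0L) {
    arrays <- data.frame(first_finger = integer(0), n_fingers = integer(0),
                         start = integer(0), end = integer(0))
    return(list(fingers = fingers, arrays = arrays))
  }
  gaps <- fingers$start[-1] - fingers$end[-nrow(fingers)] - 1L
  new_array <- c(TRUE, gaps > array_gap)
  aid <- cumsum(new_array)
  arrays <- do.call(rbind, lapply(split(seq_len(nrow(fingers)), aid),
    function(ix) data.frame(first_finger = ix[1], n_fingers = length(ix),
                            start = fingers$start[ix[1]],
                            end = fingers$end[ix[length(ix)]])))
  rownames(arrays) <- NULL
  list(fingers = fingers, arrays = arrays)
}
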