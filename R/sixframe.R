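# Six-frame translation of genome sequence into stop-free peptide segments
# with coordinate bookkeeping, so profile scans can run directly against
# unannotated assemblies.

#' Six-frame translation into peptide segments
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement under the standard genetic code (ambiguous codons, e.g. those
#' containing N, become `X`).  Each frame's peptide is split at stop codons
#' into segments; every segment records the 1-based nucleotide start of its
#' first codon both in its source strand sequence (`source_start`: the
#' input for `+`, the reverse complement for `-`) and in genomic
#' coordinates (`genomic_start`/`genomic_end`, always on the input
#' sequence, start <= end).
#'
#' @param dna a nucleotide sequence (character string over ACGTN, or a
#'   `Biostrings::DNAString`).
#' @return data.frame of segments: `strand`, `frame` (1-3), `peptide`,
#'   `source_start`, `genomic_start`, `genomic_end`.
#' @export
six_frame_translate <- function(dna) {
  if (methods::is(dna, "DNAString")) dna <- as.character(dna)
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) == 0L) stop("empty input sequence")
  dna <- toupper(dna)
  L <- nchar(dna)
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  translate_frame <- function(src, frame) {
    len <- (length(src) - frame + 1L) %/% 3L * 3L
    if (len < 3L) return(NULL)
    aa <- as.character(Biostrings::translate(
      Biostrings::subseq(src, frame, frame + len - 1L),
      if.fuzzy.codon = "X"))
    aa
  }
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") fwd else rev
    for (frame in 1:3) {
      aa <- translate_frame(src, frame)
      if (is.null(aa)) next
      # split at stops, tracking peptide offsets
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
      off <- 0L
      for (p in pieces) {
        if (nchar(p) > 0L) {
          src_start <- frame + 3L * off
          nt_len <- 3L * nchar(p)
          if (strand == "+") {
            g_start <- src_start
            g_end <- src_start + nt_len - 1L
          } else {
            g_end <- L - src_start + 1L
            g_start <- g_end - nt_len + 1L
          }
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, frame = frame, peptide = p,
            source_start = src_start, genomic_start = g_start,
            genomic_end = g_end, stringsAsFactors = FALSE)
        }
        off <- off + nchar(p) + 1L   # +1 for the stop codon
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(strand = character(0), frame = integer(0),
                      peptide = character(0), source_start = integer(0),
                      genomic_start = integer(0), genomic_end = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan six-frame translation segments with a profile model
#'
#' Runs [scan_peptides()] within every stop-free segment of
#' [six_frame_translate()] output and returns the hits with genomic
#' coordinates attached.
#'
#' @param profile a [build_profile()] model.
#' @param dna nucleotide sequence.
#' @param seq_id identifier for the output.
#' @param threshold hit threshold in log2-odds units.
#' @return data.frame of hits with `strand`, `frame`, segment-relative
#'   `start`/`end` (residues) and `score`; attribute `best_score` carries
#'   the single best window score over all frames.
#' @export
scan_genome <- function(profile, dna, seq_id = "genome", threshold = 0) {
  segs <- six_frame_translate(dna)
  hits <- list()
  best <- -Inf
  for (i in seq_len(nrow(segs))) {
    h <- scan_peptides(profile, segs$peptide[i], seq_id = seq_id,
                       threshold = threshold)
    if (nrow(h) == 0L) next
    best <- max(best, max(h$score))
    h <- h[h$above_threshold, , drop = FALSE]
    if (nrow(h) == 0L) next
    h$strand <- segs$strand[i]
    h$frame <- segs$frame[i]
    hits[[length(hits) + 1L]] <- h
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_id = character(0), model = character(0),
               start = integer(0), end = integer(0), score = numeric(0),
               above_threshold = logical(0), strand = character(0),
               frame = integer(0))
  rownames(out) <- NULL
  attr(out, "best_score") <- best
  out
}
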