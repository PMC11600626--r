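# Intron extraction from GFF3 genome annotation.
#
# Coordinates are GFF3 throughout: 1-based, inclusive.  The intron between
# consecutive exons is [prev_end + 1, next_start - 1], so its size is
# next_start - prev_end - 1.  Introns are reported in genomic orientation;
# strand never alters the coordinates.

#' Read a GFF3 annotation into an annotation set
#'
#' Parses gene/mRNA/exon features and links them through `Parent`
#' attributes.  Both GenBank- and RefSeq-styled NCBI annotations use the
#' same `ID`/`Parent` chain; `dialect` is retained for explicitness, with
#' `"auto"` inspecting nothing beyond that shared chain.  Exons whose parent
#' transcript cannot be resolved are skipped and counted.
#'
#' @param path a GFF3 file.
#' @param dialect one of `"auto"`, `"genbank"`, `"refseq"`.
#' @param transcript_types feature types treated as transcripts.
#' @return an object of class `annotation_set`: list with `genes`
#'   (data.frame: gene_id, seqid, strand), `transcripts` (data.frame:
#'   transcript_id, gene_id, seqid, strand), `exons` (data.frame:
#'   transcript_id, start, end) and `skipped` (named integer counts of
#'   dropped records).
#' @export
read_annotation <- function(path, dialect = c("auto", "genbank", "refseq"),
                            transcript_types = c("mRNA", "transcript")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  parent1 <- vapply(as.list(df$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  df$parent <- parent1
  skipped <- c(no_parent = 0L, bad_coordinates = 0L)

  bad <- df$end < df$start
  if (any(bad)) {
    skipped["bad_coordinates"] <- sum(bad)
    df <- df[!bad, , drop = FALSE]
  }

  genes <- df[df$type == "gene", , drop = FALSE]
  genes_df <- data.frame(gene_id = genes$ID, seqid = genes$seqnames,
                         strand = genes$strand, stringsAsFactors = FALSE)

  tx <- df[df$type %in% transcript_types, , drop = FALSE]
  tx_df <- data.frame(transcript_id = tx$ID, gene_id = tx$parent,
                      seqid = tx$seqnames, strand = tx$strand,
                      stringsAsFactors = FALSE)
  tx_df <- tx_df[!is.na(tx_df$transcript_id), , drop = FALSE]

  ex <- df[df$type == "exon", , drop = FALSE]
  resolvable <- !is.na(ex$parent) & ex$parent %in% tx_df$transcript_id
  skipped["no_parent"] <- sum(!resolvable)
  ex <- ex[resolvable, , drop = FALSE]
  ex_df <- data.frame(transcript_id = ex$parent, start = ex$start,
                      end = ex$end, stringsAsFactors = FALSE)

  structure(list(genes = genes_df, transcripts = tx_df, exons = ex_df,
                 skipped = skipped, dialect = dialect),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  if (any(x$skipped > 0))
    cat("  skipped records:",
        paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract introns from an annotation set
#'
#' Per transcript, exons are sorted by start; each pair of consecutive exons
#' contributes the intron `[end_i + 1, start_{i+1} - 1]`.  Abutting exons
#' (zero-length gap) produce no intron and are counted.  Transcripts with
#' overlapping exons are skipped and counted.
#'
#' @param ann an `annotation_set` from [read_annotation()].
#' @param dedupe collapse introns identical in (seqid, start, end, strand)
#'   across isoforms, recording how many transcripts share each.  Default
#'   `TRUE`: isoform-shared introns are counted once per gene.
#' @return data.frame with columns `seqid`, `start`, `end`, `strand`,
#'   `size`, `n_transcripts`; attributes `n_abutting` and
#'   `n_skipped_transcripts` carry the tallies.
#' @export
extract_introns <- function(ann, dedupe = TRUE) {
  stopifnot(inherits(ann, "annotation_set"))
  tx_meta <- ann$transcripts
  rownames(tx_meta) <- tx_meta$transcript_id
  ex_split <- split(ann$exons[c("start", "end")], ann$exons$transcript_id)
  n_abutting <- 0L
  n_skipped <- 0L
  pieces <- vector("list", length(ex_split))
  for (k in seq_along(ex_split)) {
    tid <- names(ex_split)[k]
    e <- ex_split[[k]]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    if (any(e$start[-1] <= e$end[-nrow(e)])) {   # overlapping exons
      n_skipped <- n_skipped + 1L
      next
    }
    istart <- e$end[-nrow(e)] + 1L
    iend <- e$start[-1] - 1L
    keep <- iend >= istart
    n_abutting <- n_abutting + sum(!keep)
    if (!any(keep)) next
    meta <- tx_meta[tid, ]
    pieces[[k]] <- data.frame(
      seqid = meta$seqid, start = istart[keep], end = iend[keep],
      strand = meta$strand, transcript_id = tid, stringsAsFactors = FALSE)
  }
  introns <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(introns))
    introns <- data.frame(seqid = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          transcript_id = character(0))
  if (dedupe && nrow(introns) > 0) {
    key <- paste(introns$seqid, introns$start, introns$end, introns$strand)
    n_tx <- as.vector(table(key)[unique(key)])
    introns <- introns[!duplicated(key), , drop = FALSE]
    introns$n_transcripts <- n_tx
  } else {
    introns$n_transcripts <- rep(1L, nrow(introns))
  }
  introns$transcript_id <- NULL
  introns$size <- introns$end - introns$start + 1L
  introns <- introns[order(introns$seqid, introns$start), , drop = FALSE]
  rownames(introns) <- NULL
  attr(introns, "n_abutting") <- n_abutting
  attr(introns, "n_skipped_transcripts") <- n_skipped
  introns
}
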