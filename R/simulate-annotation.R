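# Synthetic genome annotation: GFF3 + FASTA pairs whose introns have a
# prescribed size distribution, for no-download testing of the intron
# pipeline.

#' Annotation specification for the synthetic genome generator
#'
#' @param n_genes number of genes to generate.
#' @param transcripts_per_gene integer range `c(lo, hi)`; isoforms of one
#'   gene share exon coordinates.
#' @param exons_per_transcript integer range `c(lo, hi)`.
#' @param exon_size integer range `c(lo, hi)` in bp.
#' @param intron_model a [mixture_spec()] driving intron sizes.
#' @param seqid_count number of synthetic sequences (chromosomes); genes are
#'   distributed round-robin.
#' @param intergenic_gap gap between consecutive genes on a sequence, bp.
#' @param max_seq_length upper bound on any synthetic sequence length; the
#'   generator stops with an error if features would overflow it.
#' @return an object of class `annotation_spec`.
#' @export
annotation_spec <- function(n_genes = 100,
                            transcripts_per_gene = c(1, 1),
                            exons_per_transcript = c(2, 8),
                            exon_size = c(80, 300),
                            intron_model = td_mixture(),
                            seqid_count = 2,
                            intergenic_gap = 500,
                            max_seq_length = Inf) {
  stopifnot(n_genes >= 1, seqid_count >= 1, intergenic_gap >= 1,
            inherits(intron_model, "mixture_spec"))
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 1
  if (!rng_ok(transcripts_per_gene) || !rng_ok(exons_per_transcript) ||
      !rng_ok(exon_size))
    stop("ranges must be c(lo, hi) with 1 <= lo <= hi")
  structure(list(n_genes = n_genes,
                 transcripts_per_gene = transcripts_per_gene,
                 exons_per_transcript = exons_per_transcript,
                 exon_size = exon_size,
                 intron_model = intron_model,
                 seqid_count = seqid_count,
                 intergenic_gap = intergenic_gap,
                 max_seq_length = max_seq_length),
            class = "annotation_spec")
}

#' Generate a synthetic GFF3 annotation and matching genome sequence
#'
#' Genes are laid out left to right on each synthetic sequence, alternating
#' strand.  Exon sizes are uniform in the configured range; intron sizes are
#' drawn from the mixture model, so re-extracting introns from the emitted
#' annotation recovers exactly the sampled size multiset (per gene; isoforms
#' of a gene share exon coordinates).
#'
#' @param spec an [annotation_spec()].
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return a list of class `synthetic_annotation` with elements
#'   `gff` (character vector of GFF3 lines), `sequences` (named character
#'   vector of genome sequences), and `intron_sizes` (integer vector of the
#'   sampled per-gene intron sizes, in generation order).
#' @seealso [write_annotation()], [read_annotation()], [extract_introns()]
#' @export
generate_annotation <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "annotation_spec"))
  with_seed(seed, {
    runif_int <- function(r) if (r[1] == r[2]) r[1] else
      sample(seq(r[1], r[2]), 1L)
    gff <- c("##gff-version 3")
    cursor <- rep(1L, spec$seqid_count)           # next free base per seqid
    seqids <- sprintf("chr%d", seq_len(spec$seqid_count))
    all_sizes <- integer(0)
    for (g in seq_len(spec$n_genes)) {
      si <- ((g - 1L) %% spec$seqid_count) + 1L
      strand <- if (g %% 2L == 0L) "-" else "+"
      n_ex <- runif_int(spec$exons_per_transcript)
      ex_sizes <- vapply(seq_len(n_ex), function(i) runif_int(spec$exon_size),
                         numeric(1))
      n_int <- n_ex - 1L
      in_sizes <- if (n_int > 0L)
        sample_intron_sizes(spec$intron_model, n_int) else integer(0)
      starts <- ends <- integer(n_ex)
      pos <- cursor[si]
      for (i in seq_len(n_ex)) {
        starts[i] <- pos
        ends[i] <- pos + ex_sizes[i] - 1L
        pos <- ends[i] + 1L
        if (i <= n_int) pos <- pos + in_sizes[i]
      }
      gene_end <- ends[n_ex]
      if (gene_end > spec$max_seq_length)
        stop("chromosome overflow: gene ", g, " would end at ", gene_end,
             " > max_seq_length ", spec$max_seq_length)
      gid <- sprintf("gene%05d", g)
      n_tx <- runif_int(spec$transcripts_per_gene)
      gff <- c(gff, sprintf("%s\tintrontd\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            seqids[si], starts[1], gene_end, strand, gid))
      for (t in seq_len(n_tx)) {
        tid <- sprintf("%s.t%d", gid, t)
        gff <- c(gff,
          sprintf("%s\tintrontd\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                  seqids[si], starts[1], gene_end, strand, tid, gid),
          sprintf("%s\tintrontd\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                  seqids[si], starts, ends, strand, tid, seq_len(n_ex), tid))
      }
      all_sizes <- c(all_sizes, as.integer(in_sizes))
      cursor[si] <- gene_end + spec$intergenic_gap + 1L
    }
    seq_len_out <- pmax(cursor - 1L, 1L)
    sequences <- vapply(seq_len_out, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    names(sequences) <- seqids
    structure(list(gff = gff, sequences = sequences,
                   intron_sizes = all_sizes),
              class = "synthetic_annotation")
  })
}

#' Write a synthetic annotation to GFF3 and FASTA files
#'
#' @param x a `synthetic_annotation` from [generate_annotation()].
#' @param gff_path path for the GFF3 file.
#' @param fasta_path optional path for the genome FASTA (60-column wrap);
#'   skipped when `NULL`.
#' @return invisibly, `gff_path`.
#' @export
write_annotation <- function(x, gff_path, fasta_path = NULL) {
  stopifnot(inherits(x, "synthetic_annotation"))
  writeLines(x$gff, gff_path)
  if (!is.null(fasta_path)) {
    dna <- Biostrings::DNAStringSet(x$sequences)
    Biostrings::writeXStringSet(dna, fasta_path, width = 60L)
  }
  invisible(gff_path)
}
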