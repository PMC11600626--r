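# Consensus scoring, profile building, peptide/genome scanning, zinc
# fingers, canonical transcripts and presence calls.

test_that("consensus scores follow the per-column counting definition", {
  ident <- make_alignment(strrep("A", 30), n = 10)
  expect_true(all(consensus_scores(ident) == 300))

  with_outlier <- make_alignment(strrep("A", 30), n = 10, outlier = TRUE)
  sc <- consensus_scores(with_outlier)
  expect_true(all(sc[1:10] == 300))
  expect_equal(unname(sc["outlier"]), 30)       # self-count 1 per column

  expect_equal(unname(consensus_scores(c(a = "AR-", b = "AA-"))[1]),
               2 + 1 + 0)
  expect_equal(unname(consensus_scores(c(a = "---", b = "AAA"))["a"]), 0)
})

test_that("consensus scores equal the brute-force oracle and are row-order invariant", {
  set.seed(8)
  rows <- replicate(12, paste(sample(introntd:::AA_RESIDUES, 25,
                                     replace = TRUE), collapse = ""))
  names(rows) <- sprintf("s%02d", 1:12)
  sc <- consensus_scores(rows)
  expect_equal(unname(sc), consensus_scores_oracle(rows))
  perm <- sample(length(rows))
  expect_equal(consensus_scores(rows[perm]), sc[perm])
})

test_that("the score filter removes exactly the planted outlier at 250", {
  aln <- make_alignment(strrep("A", 30), n = 10, outlier = TRUE)
  kept <- filter_alignment(aln, threshold = 250)
  expect_equal(attr(kept, "removed"), "outlier")
  expect_equal(nrow(kept), 10L)
  expect_equal(nrow(filter_alignment(aln, threshold = 0)), 11L)
  expect_error(filter_alignment(aln, threshold = 1e6), "below")
  expect_error(consensus_scores(c("AAA", "AA")), "ragged")
})

test_that("single-sequence profile weights reach log2(20) in the limit", {
  prof <- build_profile(c(s = "ACD"), pseudocount = 1e-9)
  for (k in 1:3)
    expect_equal(unname(prof$weights[k, substr("ACD", k, k)]), log2(20),
                 tolerance = 1e-6)
})

test_that("majority-gap columns are dropped from the model", {
  aln <- c(a = "A-C", b = "A-C", c = "ADC")
  prof <- build_profile(aln)
  expect_equal(prof$length, 2L)
  expect_equal(prof$kept_columns, c(1L, 3L))
  expect_error(build_profile(c(a = "--", b = "--")), "gap")
})

test_that("a profile scores its own consensus at the exhaustive maximum", {
  aln <- make_alignment(random_protein(40, seed = 14), n = 8)
  prof <- build_profile(aln, name = "m")
  target <- paste0(random_protein(30, seed = 15), prof$consensus,
                   random_protein(25, seed = 16))
  oracle <- exhaustive_window_scores(prof, target)
  hits <- scan_peptides(prof, target, threshold = 0)
  expect_equal(max(hits$score), max(oracle))
  expect_equal(hits$start[which.max(hits$score)], which.max(oracle))
  # non-overlapping greedy selection matches a direct check
  expect_true(all(diff(hits$start) >= prof$length))
})

test_that("planted domains are recovered at substitution rate zero", {
  cons <- random_protein(50, seed = 77)
  arch <- architecture_spec(list(
    list(kind = "linker", length = 119),
    list(kind = "prset", length = 50, consensus = cons)),
    substitution_rate = 0)
  prots <- generate_protein_set(arch, n = 5, seed = 3)
  prof <- build_profile(stats::setNames(cons, "c"), name = "prset")
  for (p in prots) {
    hits <- scan_peptides(prof, p)
    best <- hits[which.max(hits$score), ]
    expect_equal(best$start, 120L)
    expect_equal(best$end, 120L + 50L - 1L)
  }
  planted <- planted_segments(names(prots)[1])
  expect_equal(planted$start[planted$kind == "prset"], 120L)
})

test_that("mutated proteins keep the expected identity to the consensus", {
  cons <- random_protein(200, seed = 5)
  arch <- architecture_spec(list(list(kind = "prset", length = 200,
                                      consensus = cons)),
                            substitution_rate = 0.05)
  prots <- generate_protein_set(arch, n = 50, seed = 9)
  ident <- mean(vapply(prots, function(p) {
    mean(strsplit(p, "")[[1]] == strsplit(cons, "")[[1]])
  }, numeric(1)))
  # binomial sd of the mean identity: sqrt(.05*.95/(50*200)) ~ 0.0022
  expect_lt(abs(ident - 0.95), 4 * sqrt(0.05 * 0.95 / (50 * 200)))
})

test_that("background sequences rarely reach the presence threshold", {
  aln <- make_alignment(random_protein(60, seed = 23), n = 10)
  prof <- build_profile(aln, name = "akrab")
  set.seed(31)
  n_trials <- 200
  best <- vapply(seq_len(n_trials), function(i) {
    h <- scan_peptides(prof, random_protein(400, seed = 1000 + i))
    max(h$score)
  }, numeric(1))
  th <- presence_thresholds()$akrab$protein_present
  expect_gte(mean(best < th), 0.95)
})

test_that("six-frame translation respects the code and round-trips coordinates", {
  segs <- six_frame_translate("ATGAAA")
  fwd1 <- segs[segs$strand == "+" & segs$frame == 1, ]
  expect_equal(fwd1$peptide, "MK")

  dna <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(.3, .2, .2, .3)), collapse = "")
  segs <- six_frame_translate(dna)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  for (i in seq_len(nrow(segs))) {
    src <- if (segs$strand[i] == "+") dna else rc
    pep <- segs$peptide[i]
    for (k in c(1L, nchar(pep))) {            # first and last residue
      codon <- substr(src, segs$source_start[i] + 3 * (k - 1),
                      segs$source_start[i] + 3 * (k - 1) + 2)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
      expect_equal(substr(pep, k, k), aa)
    }
    # genomic coordinates cover exactly the translated span
    expect_equal(segs$genomic_end[i] - segs$genomic_start[i] + 1L,
                 3L * nchar(segs$peptide[i]))
  }
  # reverse frames equal forward frames of the reverse complement
  rc_segs <- six_frame_translate(rc)
  expect_equal(sort(segs$peptide[segs$strand == "-"]),
               sort(rc_segs$peptide[rc_segs$strand == "+"]))
  expect_error(six_frame_translate(""), "empty")
})

test_that("N bases translate to X and still scan", {
  segs <- six_frame_translate("ATGNNNAAA")
  fwd1 <- segs[segs$strand == "+" & segs$frame == 1, ]
  expect_equal(fwd1$peptide, "MXK")
})

test_that("genome scans find a planted single-exon domain on either strand", {
  cons <- random_protein(40, seed = 55)
  prof <- build_profile(make_alignment(cons, n = 6), name = "akrab")
  # reverse-translate the consensus with one codon per residue
  codons <- names(Biostrings::GENETIC_CODE)
  aa_of <- as.character(Biostrings::GENETIC_CODE)
  codon_for <- vapply(strsplit(cons, "")[[1]],
                      function(a) codons[match(a, aa_of)], character(1))
  insert <- paste(codon_for, collapse = "")
  set.seed(66)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  dna <- paste0(flank(90), insert, flank(60))
  hits <- scan_genome(prof, dna, threshold = 50)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$strand == "+"))
  expect_gt(attr(hits, "best_score"), 50)
  # the same domain on the reverse strand is found in a reverse frame
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  rhits <- scan_genome(prof, rc, threshold = 50)
  expect_true(any(rhits$strand == "-"))
})

test_that("zinc fingers and arrays follow the pattern and gap rule", {
  unit <- zn_finger_unit()
  one <- detect_zn_fingers(unit)
  expect_equal(nrow(one$fingers), 1L)
  expect_equal(nrow(one$arrays), 1L)

  tandem <- paste(rep(unit, 12), collapse = strrep("A", 5))
  twelve <- detect_zn_fingers(tandem)
  expect_equal(nrow(twelve$fingers), 12L)
  expect_equal(nrow(twelve$arrays), 1L)
  expect_equal(twelve$arrays$n_fingers, 12L)

  split <- paste0(unit, strrep("A", 60), unit)
  two <- detect_zn_fingers(split)
  expect_equal(nrow(two$fingers), 2L)
  expect_equal(nrow(two$arrays), 2L)
})

test_that("canonical transcript selection uses count, then length, then id", {
  mk <- function(models, lens) {
    data.frame(model = models, start = cumsum(c(1, head(lens, -1))),
               end = cumsum(lens), stringsAsFactors = FALSE)
  }
  archs <- list(t2 = mk(c("prset", "znf"), c(100, 50)),
                t1 = mk(c("akrab", "prset", "znf"), c(60, 100, 50)))
  expect_equal(select_canonical(archs), "t1")

  archs2 <- list(t1 = mk("prset", 100), t2 = mk("znf", 150))
  expect_equal(select_canonical(archs2), "t2")

  archs3 <- list(t2 = mk("prset", 100), t1 = mk("prset", 100))
  expect_equal(select_canonical(archs3), "t1")
})

test_that("presence calls follow the calibrated score regions", {
  expect_equal(call_presence(31, "akrab", "genome")$call, "present")
  expect_equal(call_presence(29.9, "akrab", "genome")$call, "absent")
  expect_equal(call_presence(40, "akrab", "protein")$call, "uncertain")
  expect_equal(call_presence(15, "akrab", "protein")$call, "absent")
  expect_equal(call_presence(55, "akrab", "protein")$call, "present")
  expect_equal(call_presence(179.9, "eprset", "protein")$call, "absent")
  expect_equal(call_presence(180, "eprset", "protein")$call, "present")
  expect_error(call_presence(10, "mystery"))
})

test_that("planted aKRAB presence is fully recovered at low mutation rates", {
  cons <- random_protein(60, seed = 41)
  prof <- build_profile(make_alignment(cons, n = 10), name = "akrab")
  arch_with <- architecture_spec(list(
    list(kind = "akrab", length = 60, consensus = cons),
    list(kind = "linker", length = 100),
    list(kind = "znfinger_array", length = 6)), substitution_rate = 0.05)
  prots <- generate_protein_set(arch_with, n = 30, seed = 12)
  calls <- vapply(prots, function(p) {
    best <- max(scan_peptides(prof, p)$score)
    call_presence(best, "akrab", "protein")$call
  }, character(1))
  expect_true(all(calls == "present"))
})
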