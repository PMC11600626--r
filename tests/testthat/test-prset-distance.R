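# Rescaled BLOSUM distances, pairwise alignment distances, neighbour
# joining and class assignment.

test_that("the rescaled BLOSUM62 distance is a proper residue distance", {
  D <- rescale_substitution_matrix(blosum62())
  expect_equal(dim(unclass(D)), c(20L, 20L))
  expect_true(all(diag(unclass(D)) == 0))
  expect_equal(unclass(D), t(unclass(D)))
  expect_true(all(unclass(D) >= 0))            # all 210 pairs
  # hand application of the formula to the published A/R entries:
  # -B(A,R) + (B(A,A) + B(R,R)) / 2 = 1 + (4 + 5) / 2
  expect_equal(unclass(D)["A", "R"], 5.5)
})

test_that("asymmetric matrices are rejected", {
  B <- unclass(blosum62())
  B["A", "R"] <- 99
  expect_error(rescale_substitution_matrix(B), "symmetric")
})

test_that("aligned pair distance averages D over doubly-resolved columns", {
  D <- rescale_substitution_matrix(blosum62())
  expect_equal(aligned_pair_distance("ARNDC", "ARNDC", D), 0)
  # hand oracle: D(A,A) = 0, D(R,A) = 5.5, gap column excluded
  expect_equal(aligned_pair_distance("AR-", "AA-", D), (0 + 5.5) / 2)
  expect_equal(aligned_pair_distance("AR-", "AA-", D),
               aligned_pair_distance("AA-", "AR-", D))
  # X is excluded like a gap; appending shared gap columns changes nothing
  expect_equal(aligned_pair_distance("ARX--", "AAX--", D), 2.75)
  expect_error(aligned_pair_distance("A-", "-A", D), "overlap")
})

test_that("the pairwise matrix matches a brute-force double loop", {
  D <- rescale_substitution_matrix(blosum62())
  set.seed(19)
  rows <- replicate(10, {
    chars <- sample(c(introntd:::AA_RESIDUES, "-"), 30, replace = TRUE,
                    prob = c(rep(0.045, 20), 0.1))
    paste(chars, collapse = "")
  })
  names(rows) <- sprintf("s%02d", 1:10)
  M <- pairwise_distance_matrix(rows, D)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(M$distances[i, j],
                 aligned_pair_distance(rows[[i]], rows[[j]], D))
  expect_true(all(diag(M$distances) == 0))
  # permuting rows permutes labels consistently
  perm <- sample(10)
  M2 <- pairwise_distance_matrix(rows[perm], D)
  expect_equal(M2$distances[names(rows), names(rows)], M$distances)
  # identical rows give a zero matrix
  Z <- pairwise_distance_matrix(c(a = "ARND", b = "ARND", c = "ARND"), D)
  expect_true(all(Z$distances == 0))
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  M <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(M)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  lens <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(unname(lens["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(lens["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(lens["c"]), (9 + 10 - 5) / 2)
})

test_that("NJ recovers additive six-taxon trees exactly", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    set.seed(seed)
    true_tree <- ape::rtree(6)
    M <- ape::cophenetic.phylo(true_tree)
    est <- neighbor_joining(M)
    expect_equal(phangorn::RF.dist(ape::unroot(true_tree), est), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(M), colnames(M)], M,
                 tolerance = 1e-9)
    # independent cross-check: agrees with ape's NJ topology
    expect_equal(phangorn::RF.dist(ape::nj(M), est), 0)
  }
})

test_that("NJ is deterministic under Q ties", {
  # four equidistant taxa: every Q is tied; the lexicographically smallest
  # pair must be joined first, making repeated runs identical
  M <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(M) <- 0
  t1 <- neighbor_joining(M)
  t2 <- neighbor_joining(M)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  first_join <- ape::prop.part(t1)
  expect_error(neighbor_joining(M[1:2, 1:2]), "three")
  Mna <- M; Mna[1, 2] <- Mna[2, 1] <- NA
  expect_error(neighbor_joining(Mna), "missing")
})

test_that("outgroup rooting splits the pendant branch and keeps the leaf set", {
  set.seed(3)
  true_tree <- ape::rtree(8)
  M <- ape::cophenetic.phylo(true_tree)
  est <- neighbor_joining(M)
  rooted <- root_by_outgroup(est, "t3")
  expect_true(ape::is.rooted(rooted))
  expect_setequal(rooted$tip.label, est$tip.label)
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  expect_true(match("t3", rooted$tip.label) %in% kids)
  # the two root edges carry equal halves of the original pendant branch
  root_lens <- rooted$edge.length[rooted$edge[, 1] == root]
  expect_equal(root_lens[1], root_lens[2])
  # idempotent on topology
  again <- root_by_outgroup(rooted, "t3")
  expect_equal(phangorn::RF.dist(ape::unroot(again), ape::unroot(rooted)), 0)
  expect_error(root_by_outgroup(est, "nope"), "not present")
})

test_that("block-diagonal distances are classified exactly", {
  n_per <- 5
  labs <- paste0("s", 1:(4 * n_per))
  M <- matrix(10, 4 * n_per, 4 * n_per, dimnames = list(labs, labs))
  for (b in 0:3) {
    ix <- b * n_per + seq_len(n_per)
    M[ix, ix] <- 0
  }
  # reference sits in block 1; blocks at graded distances from it
  for (b in 1:3) M[1:n_per, b * n_per + 1:n_per] <-
    M[b * n_per + 1:n_per, 1:n_per] <- 10 + 2 * b
  cls <- assign_classes(M, k = 4, reference = "s1")
  grp <- split(names(cls$classes), cls$classes)
  expect_equal(sort(grp[["I"]]), sort(labs[1:n_per]))
  expect_equal(sort(grp[["IV"]]), sort(labs[3 * n_per + 1:n_per]))
  expect_lt(mean(M["s1", grp[["I"]]]), mean(M["s1", grp[["IV"]]]))
})

test_that("planted noisy clusters are recovered at >= 95% agreement", {
  agreements <- vapply(1:20, function(seed) {
    set.seed(seed)
    n_per <- 6
    truth <- rep(1:4, each = n_per)
    n <- length(truth)
    M <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      base <- if (truth[i] == truth[j]) 1 else 20 + 4 * abs(truth[i] - truth[j])
      M[i, j] <- M[j, i] <- base + runif(1, 0, 0.5)
    }
    dimnames(M) <- list(paste0("q", 1:n), paste0("q", 1:n))
    cls <- assign_classes(M, k = 4, reference = "q1")
    mean(as.integer(as.roman(cls$classes)) == truth)
  }, numeric(1))
  expect_gte(mean(agreements), 0.95)
})

test_that("k = n produces singleton classes", {
  M <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(M) <- 0
  cls <- assign_classes(M, k = 4)
  expect_equal(as.integer(table(cls$classes)), rep(1L, 4))
  expect_error(assign_classes(M, k = 5), "k must")
})
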