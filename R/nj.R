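# Classic Saitou-Nei neighbour joining and outgroup rooting.
#
# NJ is implemented directly (Q-criterion pair selection, the standard
# branch-length formulas, agglomeration down to three clusters resolved by
# the closed-form three-point formulas).  Ties in Q are broken by the
# lexicographically smallest label pair so that the output is deterministic;
# negative branch lengths are clamped to zero with the total deficit
# reported.  On additive distance matrices the generating tree is recovered
# exactly.  ape::nj / ape::bionj serve as independent cross-checks in the
# test suite, never as the implementation.

#' Neighbour-joining tree from a distance matrix
#'
#' @param M a `pairwise_distances` object from
#'   [pairwise_distance_matrix()], or a labelled symmetric numeric matrix.
#' @return an unrooted `ape::phylo` tree; attribute `clamped_deficit`
#'   carries the summed magnitude of negative branch lengths clamped to 0.
#' @export
neighbor_joining <- function(M) {
  D <- if (inherits(M, "pairwise_distances")) M$distances else as.matrix(M)
  if (any(is.na(D))) stop("distance matrix has missing entries")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("neighbour joining needs at least three taxa")

  clamped <- 0
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- clamped + abs(x)
      0
    } else x
  }
  # each active cluster holds a newick fragment; lengths via %.17g round-trip
  frag <- stats::setNames(as.list(labels), labels)
  fmt <- function(sub, len) sprintf("%s:%.17g", sub, len)
  rownames(D) <- colnames(D) <- labels

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- apply(cand, 1L, function(ix)
      paste(sort(rownames(D)[ix]), collapse = "\r"))
    pick <- cand[order(pair_lab)[1L], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_lab <- paste0("(", rownames(D)[i], ",", rownames(D)[j], ")")
    new_frag <- paste0("(", fmt(frag[[rownames(D)[i]]], li), ",",
                       fmt(frag[[rownames(D)[j]]], lj), ")")
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    labs <- c(rownames(D)[keep], new_lab)
    rownames(D2) <- colnames(D2) <- labs
    frag[[new_lab]] <- new_frag
    frag[rownames(D)[c(i, j)]] <- NULL
    D <- D2
  }
  # resolve the final three clusters around a central node
  a <- rownames(D)[1]; b <- rownames(D)[2]; c_ <- rownames(D)[3]
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- paste0("(", fmt(frag[[a]], la), ",", fmt(frag[[b]], lb), ",",
                   fmt(frag[[c_]], lc), ");")
  tree <- ape::read.tree(text = newick)
  if (clamped > 0)
    message("neighbor_joining: clamped negative branch lengths, total deficit ",
            signif(clamped, 4))
  attr(tree, "clamped_deficit") <- clamped
  tree
}

#' Root a tree on an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant branch, so the
#' outgroup becomes one of the root's two children.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup a leaf label present in the tree.
#' @return a rooted `ape::phylo` tree.
#' @export
root_by_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("outgroup leaf not present in tree: ", outgroup)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  # split the pendant branch evenly across the two root edges
  root_node <- length(rooted$tip.label) + 1L
  root_edges <- which(rooted$edge[, 1] == root_node)
  if (length(root_edges) == 2L && !is.null(rooted$edge.length)) {
    tip_idx <- match(outgroup, rooted$tip.label)
    og_edge <- root_edges[rooted$edge[root_edges, 2] == tip_idx]
    if (length(og_edge) == 1L) {
      total <- sum(rooted$edge.length[root_edges])
      rooted$edge.length[root_edges] <- total / 2
    }
  }
  rooted
}
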