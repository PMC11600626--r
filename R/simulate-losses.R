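# Planted domain-loss scenarios on phylogenies: choose branches, mark all
# descendant leaves absent, keep the chosen branches mutually non-nested.

#' @keywords internal
#' @noRd
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Plant independent losses on a tree
#'
#' Selects `k` branches of a rooted tree such that no selected branch is
#' ancestral to another, and labels every leaf descending from a selected
#' branch `absent`; all other leaves are `present`.  This is the generator
#' counterpart of [maximal_absence_clades()]: when no two selected branches
#' are adjacent through absent-only subtrees, the inference recovers exactly
#' `k` events.
#'
#' @param tree an `ape::phylo` tree (rooted).
#' @param k number of loss branches to plant.
#' @param seed integer seed.
#' @return a list of class `loss_scenario` with `tree`, `loss_edges` (row
#'   indices into `tree$edge`), `loss_nodes` (child node of each loss
#'   branch) and `labels` (named character vector, `present`/`absent` per
#'   leaf label).
#' @export
plant_losses <- function(tree, k, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), k >= 0)
  ntip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  tips_below <- lapply(seq_len(n_edge), function(e) node_tips(tree, tree$edge[e, 2]))
  with_seed(seed, {
    chosen <- integer(0)
    if (k > 0) {
      # a random greedy pass can trap itself (an early pick may cover too
      # many tips); retry with fresh shuffles before declaring infeasibility
      for (attempt in seq_len(64L)) {
        chosen <- integer(0)
        covered <- rep(FALSE, ntip)
        for (e in sample.int(n_edge)) {
          tb <- tips_below[[e]]
          if (any(covered[tb])) next          # nested or overlapping: skip
          chosen <- c(chosen, e)
          covered[tb] <- TRUE
          if (length(chosen) == k) break
        }
        if (length(chosen) == k) break
      }
      if (length(chosen) < k)
        stop("tree does not admit ", k, " mutually non-nested loss branches")
    }
    absent <- unique(unlist(tips_below[chosen]))
    labels <- rep("present", ntip)
    labels[absent] <- "absent"
    names(labels) <- tree$tip.label
    structure(list(tree = tree, loss_edges = chosen,
                   loss_nodes = tree$edge[chosen, 2], labels = labels),
              class = "loss_scenario")
  })
}
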