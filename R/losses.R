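# Independent-event inference on a labelled phylogeny: maximal monophyletic
# clades uniform for a target state.
#
# A clade is reported when every labelled leaf below it carries the target
# state and its parent clade contains at least one labelled leaf of the
# other state.  Unknown-state leaves are transparent: they neither break
# uniformity nor found clades of their own (poor assemblies should not
# split an absence clade).  The count of such clades is a lower bound on
# the number of independent losses (or origins): events on sister branches
# merge into one clade.

#' Maximal monophyletic clades uniform for a target state
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param labels named character vector over (a subset of) the leaf labels
#'   with values `"present"`, `"absent"` or `"unknown"`.
#' @param target_state `"absent"` (loss counting) or `"present"` (origin
#'   counting).
#' @return list of clades; each is a list with `mrca` (node id; for a
#'   singleton, the leaf id), `leaves` (labelled target-state leaf names),
#'   `unknown_leaves` (unknown-state leaves inside the clade), `size`.
#' @export
maximal_absence_clades <- function(tree, labels,
                                   target_state = c("absent", "present")) {
  target_state <- match.arg(target_state)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted: maximality is undefined on unrooted trees")
  bad <- setdiff(names(labels), tree$tip.label)
  if (length(bad))
    stop("labelled leaves not in tree: ", paste(bad, collapse = ", "))
  ntip <- length(tree$tip.label)
  state <- rep("unknown", ntip)
  names(state) <- tree$tip.label
  state[names(labels)] <- labels
  if (!any(state %in% c("present", "absent")))
    stop("no informatively labelled leaves")

  nnode <- ntip + tree$Nnode
  n_target <- integer(nnode)    # labelled target-state leaves below node
  n_other <- integer(nnode)     # labelled other-state leaves below node
  n_unknown <- integer(nnode)
  is_target_leaf <- state == target_state
  is_other_leaf <- state %in% c("present", "absent") & !is_target_leaf
  n_target[seq_len(ntip)] <- as.integer(is_target_leaf)
  n_other[seq_len(ntip)] <- as.integer(is_other_leaf)
  n_unknown[seq_len(ntip)] <- as.integer(state == "unknown")
  # postorder accumulation: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1]; ch <- eo[e, 2]
    n_target[p] <- n_target[p] + n_target[ch]
    n_other[p] <- n_other[p] + n_other[ch]
    n_unknown[p] <- n_unknown[p] + n_unknown[ch]
  }
  uniform <- n_target > 0L & n_other == 0L
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  is_clade <- vapply(seq_len(nnode), function(nd) {
    if (!uniform[nd]) return(FALSE)
    if (nd == root) return(TRUE)
    !uniform[parent[nd]]
  }, logical(1))
  lapply(which(is_clade), function(nd) {
    tips <- node_tips(tree, nd)
    leaf_names <- tree$tip.label[tips]
    list(mrca = nd,
         leaves = leaf_names[state[leaf_names] == target_state],
         unknown_leaves = leaf_names[state[leaf_names] == "unknown"],
         size = sum(state[leaf_names] == target_state))
  })
}

#' Count independent loss (or origin) events
#'
#' The number of maximal monophyletic clades uniform for the target state;
#' see [maximal_absence_clades()].  This is a lower bound: events on sister
#' branches are merged.
#'
#' @inheritParams maximal_absence_clades
#' @return integer count of independent events.
#' @examples
#' fx <- teleost_fixtures()
#' count_independent_events(fx$tree, fx$akrab, "absent")
#' @export
count_independent_events <- function(tree, labels,
                                     target_state = c("absent", "present")) {
  length(maximal_absence_clades(tree, labels, target_state))
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree an `ape::phylo` tree.
#' @param leaves character vector of leaf labels (non-empty, all present).
#' @return node id (for a single leaf, the leaf's own tip id).
#' @export
tree_mrca <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) >= 1L)
  bad <- setdiff(leaves, tree$tip.label)
  if (length(bad)) stop("unknown leaves: ", paste(bad, collapse = ", "))
  if (length(unique(leaves)) == 1L)
    return(match(leaves[1], tree$tip.label))
  ape::getMRCA(tree, unique(leaves))
}
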