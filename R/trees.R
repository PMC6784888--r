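# Ancestral gain/loss reconstruction and tree congruence.
#
# Trees are ape "phylo" objects throughout; Newick reading/writing goes
# through ape.

#' Fitch parsimony ancestral reconstruction of binary characters
#'
#' Unit-cost small parsimony (Sankoff dynamic programme, equivalent to
#' Fitch on binary trees and well defined on multifurcations). For each
#' character the parsimony-minimal change count is computed, every node is
#' assigned its MPR (most-parsimonious-reconstruction) state set, and
#' branch events are tabulated: a branch is a definite gain (0 to 1) or
#' loss (1 to 0) only when parent and child states are unambiguous in
#' every optimal labelling; nodes whose MPR set contains both states are
#' reported ambiguous, never resolved silently.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Binary (0/1) matrix or data frame, tips x characters,
#'   with rownames covering every tip label; or a named vector for a
#'   single character.
#' @param ancestor Node whose state is reported as the reference ancestral
#'   state: either an internal node label or number, default the root
#'   (e.g. the ancestral fungal node when the tree spans fungi).
#' @param ancestor_state Optional known state (0 or 1, recycled across
#'   characters) to condition the root on. On a rooted binary tree a
#'   character gained in one clade always admits an equally parsimonious
#'   loss-side rooting, so gains and losses relative to a reference
#'   ancestor are only definite once that ancestor's state is fixed --
#'   which is how lineage gains and losses relative to an ancestral node
#'   are counted. The reported score is then the conditional parsimony
#'   minimum given that root state.
#' @return An `ancestral_report`: list with `summary` (per character:
#'   `score`, `ancestor_state`, `n_gains`, `n_losses`,
#'   `n_ambiguous_nodes`), `branches` (long data frame of per-branch
#'   events: gain/loss/none/ambiguous), and `node_states` (character
#'   matrix nodes x characters with values "0", "1", "ambiguous").
#' @export
fitch_ancestral <- function(tree, states, ancestor = NULL,
                            ancestor_state = NULL) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted")
  if (is.vector(states) && !is.list(states))
    states <- matrix(states, ncol = 1,
                     dimnames = list(names(states), "char1"))
  states <- as.matrix(states)
  if (is.null(rownames(states)) ||
      !all(tree$tip.label %in% rownames(states)))
    stop("every leaf needs a state")
  if (!all(states[tree$tip.label, ] %in% c(0, 1)))
    stop("states must be binary 0/1")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  anc_node <- if (is.null(ancestor)) root else resolve_node(tree, ancestor)
  chars <- colnames(states) %||% paste0("char", seq_len(ncol(states)))
  node_lab <- c(tree$tip.label,
                tree$node.label %||% paste0("node", root:nnode))
  summ <- vector("list", ncol(states))
  brs <- vector("list", ncol(states))
  node_states <- matrix(NA_character_, nnode, ncol(states),
                        dimnames = list(node_lab, chars))
  for (ci in seq_len(ncol(states))) {
    x <- states[tree$tip.label, ci]
    cost <- matrix(Inf, nnode, 2L)
    cost[seq_len(ntip), ] <- 0
    cost[cbind(seq_len(ntip), 2L - x)] <- Inf  # col 1 = state 0, col 2 = state 1
    cost[cbind(seq_len(ntip), x + 1L)] <- 0
    init <- rep(TRUE, nnode)
    for (e in seq_len(nrow(E))) {
      p <- E[e, 1L]; ch <- E[e, 2L]
      if (init[p]) { cost[p, ] <- 0; init[p] <- FALSE }
      cost[p, 1L] <- cost[p, 1L] + min(cost[ch, 1L], cost[ch, 2L] + 1)
      cost[p, 2L] <- cost[p, 2L] + min(cost[ch, 2L], cost[ch, 1L] + 1)
    }
    if (is.null(ancestor_state)) {
      score <- min(cost[root, ])
      root_allowed <- cost[root, ] == score
    } else {
      rs <- as.integer(rep(ancestor_state, length.out = ncol(states))[ci])
      if (!rs %in% 0:1) stop("`ancestor_state` must be 0 or 1")
      score <- cost[root, rs + 1L]
      root_allowed <- c(FALSE, FALSE)
      root_allowed[rs + 1L] <- TRUE
    }
    # MPR sets, preorder
    sets <- matrix(FALSE, nnode, 2L)
    sets[root, ] <- root_allowed
    for (e in rev(seq_len(nrow(E)))) {
      p <- E[e, 1L]; ch <- E[e, 2L]
      if (ch <= ntip) { sets[ch, x[ch] + 1L] <- TRUE; next }
      for (s in 1:2) {
        for (ps in 1:2) {
          if (!sets[p, ps]) next
          tr <- as.integer(s != ps)
          if (cost[ch, s] + tr ==
              min(cost[ch, 1L] + as.integer(ps != 1L),
                  cost[ch, 2L] + as.integer(ps != 2L)))
            sets[ch, s] <- TRUE
        }
      }
    }
    st <- ifelse(sets[, 1L] & sets[, 2L], "ambiguous",
                 ifelse(sets[, 2L], "1", "0"))
    node_states[, ci] <- st
    ev <- vapply(seq_len(nrow(E)), function(e) {
      sp <- st[E[e, 1L]]; sc <- st[E[e, 2L]]
      if (sp == "0" && sc == "1") "gain"
      else if (sp == "1" && sc == "0") "loss"
      else if (sp == "ambiguous" || sc == "ambiguous") "ambiguous"
      else "none"
    }, character(1))
    brs[[ci]] <- data.frame(fun = chars[ci],
                            parent = node_lab[E[, 1L]],
                            child = node_lab[E[, 2L]],
                            event = ev, stringsAsFactors = FALSE)
    summ[[ci]] <- data.frame(
      fun = chars[ci], score = score,
      ancestor_state = st[anc_node],
      n_gains = sum(ev == "gain"), n_losses = sum(ev == "loss"),
      n_ambiguous_nodes = sum(st[root:nnode] == "ambiguous"),
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, summ),
                 branches = do.call(rbind, brs),
                 node_states = node_states,
                 ancestor = node_lab[anc_node]),
            class = "ancestral_report")
}

resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < ntip + 1L || node > ntip + tree$Nnode)
      stop("`ancestor` must be an internal node")
    return(node)
  }
  if (!is.null(tree$node.label) && node %in% tree$node.label)
    return(ntip + match(node, tree$node.label))
  stop(sprintf("unknown ancestor node '%s'", node))
}

#' @export
print.ancestral_report <- function(x, ...) {
  cat(sprintf("<ancestral_report> ancestor = %s\n", x$ancestor))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Leaf sets below every node, as a list indexed by node number.
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical nontrivial bipartitions of an (unrooted) tree, as strings.
# Each internal edge splits the leaves; the side not containing the
# reference leaf is sorted and collapsed, so representations are
# comparable across trees with the same leaf set.
tree_bipartitions <- function(tree, ref = NULL) {
  tu <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tips <- sort(tu$tip.label)
  ref <- ref %||% tips[1L]
  ntip <- length(tips)
  sets <- clade_tip_sets(tu)
  ntu <- length(tu$tip.label)
  internal_children <- tu$edge[tu$edge[, 2L] > ntu, 2L]
  bps <- vapply(internal_children, function(nd) {
    s <- sets[[nd]]
    if (ref %in% s) s <- setdiff(tips, s)
    if (length(s) < 2L || length(s) > ntip - 2L) return(NA_character_)
    paste(sort(s), collapse = "|")
  }, character(1))
  unique(bps[!is.na(bps)])
}

#' Robinson-Foulds distance and focal-taxon congruence
#'
#' Both trees are pruned to their shared leaves; the RF distance is the
#' size of the symmetric difference of their nontrivial bipartitions
#' (unrooted). A library tree is judged *congruent* for a focal taxon when
#' the taxon's sister group -- the leaves of the smallest clade containing
#' it, minus itself, in the pruned tree as rooted -- is identical in both
#' trees; topology changes elsewhere do not make the placement of the
#' focal taxon incongruent.
#'
#' @param tree1,tree2 `phylo` trees sharing >= 4 leaves.
#' @param focal_taxon Leaf label present in both trees.
#' @return List with `rf_distance`, `congruent`, `sister1`, `sister2`,
#'   `n_shared_leaves`.
#' @export
rf_congruence <- function(tree1, tree2, focal_taxon) {
  stopifnot(inherits(tree1, "phylo"), inherits(tree2, "phylo"))
  shared <- intersect(tree1$tip.label, tree2$tip.label)
  if (length(shared) < 4) stop("trees share fewer than 4 leaves")
  if (!focal_taxon %in% shared)
    stop("`focal_taxon` must be present in both trees")
  t1 <- ape::keep.tip(tree1, shared)
  t2 <- ape::keep.tip(tree2, shared)
  ref <- sort(shared)[1L]
  b1 <- tree_bipartitions(t1, ref)
  b2 <- tree_bipartitions(t2, ref)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  s1 <- sister_group(t1, focal_taxon)
  s2 <- sister_group(t2, focal_taxon)
  list(rf_distance = rf, congruent = setequal(s1, s2),
       sister1 = sort(s1), sister2 = sort(s2),
       n_shared_leaves = length(shared))
}

sister_group <- function(tree, tip) {
  ntip <- length(tree$tip.label)
  tn <- match(tip, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2L] == tn, 1L]
  sets <- clade_tip_sets(tree)
  setdiff(sets[[parent]], tip)
}
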