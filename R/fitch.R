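# Fitch parsimony ancestral-state reconstruction for single nucleotide
# columns on a (possibly multifurcating) species tree, with deterministic tie
# resolution. This is the machinery behind compensatory-substitution
# detection.

# Precompute traversal structure for an ape phylo object.
tree_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  children <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    children[[p]] <- c(children[[p]], tree$edge[i, 2L])
  }
  # DFS preorder (parents before children); its reverse is a postorder
  stack <- root
  order_out <- integer(0)
  while (length(stack) > 0L) {
    n <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order_out <- c(order_out, n)
    if (n > ntip) stack <- c(stack, children[[n]])
  }
  post <- rev(order_out[order_out > ntip])
  list(tree = tree, ntip = ntip, nnode = nnode, root = root,
       children = children, post_internal = post,
       pre_all = order_out)
}

# Deterministic branch identifiers: each edge is named by the sorted leaf set
# descending from its child node, joined with "|" (a leaf edge is named by the
# leaf itself). Stable across topologically identical trees regardless of
# node numbering.
clade_ids <- function(tree) {
  ti <- if (inherits(tree, "phylo")) tree_index(tree) else tree
  tree <- ti$tree
  ids <- character(ti$ntip + ti$nnode)
  ids[seq_len(ti$ntip)] <- tree$tip.label
  leafsets <- vector("list", ti$ntip + ti$nnode)
  for (i in seq_len(ti$ntip)) leafsets[[i]] <- tree$tip.label[i]
  for (n in ti$post_internal) {
    leafsets[[n]] <- sort(unique(unlist(leafsets[ti$children[[n]]])))
    ids[n] <- paste(leafsets[[n]], collapse = "|")
  }
  ids
}

#' Fitch parsimony reconstruction of one character column
#'
#' Generalised (multifurcation-tolerant) Fitch: each internal node's state set
#' is the set of states occurring in the maximal number of its children's
#' sets (for a binary node this is the classic intersection-else-union rule).
#' Final states are assigned top-down with deterministic tie resolution:
#' internal-node ties resolve toward the parent state when it is in the set,
#' the root tie resolves toward the majority leaf state, and residual ties
#' resolve alphabetically.
#'
#' @param tree An `ape::phylo` tree or Newick string.
#' @param states Named character vector of single-character leaf states; names
#'   must cover every tip label.
#' @return List with `node_states` (character, tips then internal nodes, ape
#'   numbering), `node_sets` (list of candidate-state sets), `events`
#'   (`data.frame` with `branch`, `parent`, `child`, `from`, `to`),
#'   `n_changes`, and `branch_ids`.
#' @export
fitch_reconstruct <- function(tree, states) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ti <- tree_index(tree)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states))
  if (length(missing) > 0L) {
    stop("leaf without state: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nall <- ti$ntip + ti$nnode
  sets <- vector("list", nall)
  for (i in seq_len(ti$ntip)) sets[[i]] <- unname(states[tips[i]])
  for (n in ti$post_internal) {
    tab <- table(unlist(lapply(ti$children[[n]], function(ch) sets[[ch]])))
    sets[[n]] <- sort(names(tab)[tab == max(tab)])
  }
  node_states <- character(nall)
  node_states[seq_len(ti$ntip)] <- vapply(seq_len(ti$ntip),
                                          function(i) sets[[i]], character(1))
  # root assignment
  rs <- sets[[ti$root]]
  if (length(rs) == 1L) {
    node_states[ti$root] <- rs
  } else {
    tally <- table(factor(unname(states[tips]), levels = rs))
    best <- names(tally)[tally == max(tally)]
    node_states[ti$root] <- sort(best)[1L]
  }
  # top-down assignment (pre_all is a preorder over all nodes)
  for (n in ti$pre_all) {
    if (n <= ti$ntip || n == ti$root) next
    parent <- ti$tree$edge[ti$tree$edge[, 2L] == n, 1L]
    ps <- node_states[parent]
    node_states[n] <- if (ps %in% sets[[n]]) ps else sort(sets[[n]])[1L]
  }
  bids <- clade_ids(ti)
  ev <- list()
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    if (node_states[p] != node_states[ch]) {
      ev[[length(ev) + 1L]] <- data.frame(
        branch = bids[ch], parent = p, child = ch,
        from = node_states[p], to = node_states[ch],
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(), parent = integer(), child = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  list(node_states = node_states, node_sets = sets, events = events,
       n_changes = nrow(events), branch_ids = bids)
}
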