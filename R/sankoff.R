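# Unit-cost Sankoff dynamic programming over nucleotide states: the
# machinery behind parsimony-ambiguity resolution in compensatory-event
# detection. Fitch's first-pass sets do not contain every state occurring in
# some most-parsimonious labeling; these tables do, and they answer whether
# a given edge can carry a substitution in at least one most-parsimonious
# labeling.

BASES4 <- c("A", "C", "G", "T")

# D[v, s]: min changes within subtree(v) given state s at v.
# A[v, s]: min changes outside subtree(v) given state s at v (including the
#          edge from parent(v) to v). A[root, ] = 0.
sankoff_tables <- function(ti, states) {
  nall <- ti$ntip + ti$nnode
  D <- matrix(Inf, nall, 4L, dimnames = list(NULL, BASES4))
  for (i in seq_len(ti$ntip)) {
    D[i, ] <- ifelse(BASES4 == states[[ti$tree$tip.label[i]]], 0, Inf)
  }
  childmin <- function(ch) {
    # per parent state a: min_t(D[ch, t] + (t != a))
    vapply(seq_len(4L), function(a) {
      min(D[ch, ] + (BASES4 != BASES4[a]))
    }, numeric(1))
  }
  for (n in ti$post_internal) {
    acc <- numeric(4L)
    for (ch in ti$children[[n]]) acc <- acc + childmin(ch)
    D[n, ] <- acc
  }
  A <- matrix(0, nall, 4L, dimnames = list(NULL, BASES4))
  parent_of <- integer(nall)
  for (e in seq_len(nrow(ti$tree$edge))) {
    parent_of[ti$tree$edge[e, 2L]] <- ti$tree$edge[e, 1L]
  }
  for (n in ti$pre_all) {
    if (n == ti$root) next
    u <- parent_of[n]
    sib <- setdiff(ti$children[[u]], n)
    sibsum <- numeric(4L)
    for (w in sib) sibsum <- sibsum + childmin(w)
    A[n, ] <- vapply(seq_len(4L), function(b) {
      min(A[u, ] + (BASES4 != BASES4[b]) + sibsum)
    }, numeric(1))
  }
  list(D = D, A = A, min = min(D[ti$root, ]), parent_of = parent_of)
}

# All (from, to) state pairs (from != to) that the edge into `child` can
# carry in some most-parsimonious labeling, with their (equal) cost.
edge_change_options <- function(ti, tb, child) {
  u <- tb$parent_of[child]
  sib <- setdiff(ti$children[[u]], child)
  sibsum <- numeric(4L)
  for (w in sib) {
    sibsum <- sibsum + vapply(seq_len(4L), function(a) {
      min(tb$D[w, ] + (BASES4 != BASES4[a]))
    }, numeric(1))
  }
  out <- list()
  for (a in seq_len(4L)) {
    for (b in seq_len(4L)) {
      if (a == b) next
      cost <- tb$A[u, a] + sibsum[a] + 1 + tb$D[child, b]
      if (is.finite(cost) && cost == tb$min) {
        out[[length(out) + 1L]] <- c(from = BASES4[a], to = BASES4[b])
      }
    }
  }
  out
}

# A most-parsimonious labeling with the edge into `child` forced to carry
# from_state -> to_state. Ties resolve toward the parent state, then
# alphabetically. Returns NULL when the forced labeling is not
# parsimony-optimal.
constrained_labeling <- function(ti, states, child, from_state, to_state) {
  nall <- ti$ntip + ti$nnode
  D <- matrix(Inf, nall, 4L, dimnames = list(NULL, BASES4))
  for (i in seq_len(ti$ntip)) {
    D[i, ] <- ifelse(BASES4 == states[[ti$tree$tip.label[i]]], 0, Inf)
  }
  force <- list()
  force[[as.character(child)]] <- to_state
  parent_of <- integer(nall)
  for (e in seq_len(nrow(ti$tree$edge))) {
    parent_of[ti$tree$edge[e, 2L]] <- ti$tree$edge[e, 1L]
  }
  force[[as.character(parent_of[child])]] <- from_state
  restrict <- function(n, row) {
    key <- as.character(n)
    if (!is.null(force[[key]])) row[BASES4 != force[[key]]] <- Inf
    row
  }
  for (i in seq_len(ti$ntip)) D[i, ] <- restrict(i, D[i, ])
  for (n in ti$post_internal) {
    acc <- numeric(4L)
    for (ch in ti$children[[n]]) {
      acc <- acc + vapply(seq_len(4L), function(a) {
        min(D[ch, ] + (BASES4 != BASES4[a]))
      }, numeric(1))
    }
    D[n, ] <- restrict(n, acc)
  }
  total <- min(D[ti$root, ])
  if (!is.finite(total)) return(NULL)
  ns <- character(nall)
  pick <- function(costs, prefer = NULL) {
    best <- which(costs == min(costs))
    if (!is.null(prefer) && match(prefer, BASES4) %in% best) {
      return(prefer)
    }
    BASES4[best[1L]]
  }
  ns[ti$root] <- pick(D[ti$root, ])
  for (n in ti$pre_all) {
    if (n == ti$root) next
    ps <- ns[parent_of[n]]
    costs <- D[n, ] + (BASES4 != ps)
    ns[n] <- pick(costs, prefer = ps)
  }
  list(node_states = ns, cost = total)
}

# Substitution events implied by a full node-state labeling.
events_from_states <- function(ti, bids, node_states) {
  edge <- ti$tree$edge
  rows <- list()
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    if (node_states[p] != node_states[ch]) {
      rows[[length(rows) + 1L]] <- data.frame(
        branch = bids[ch], parent = p, child = ch,
        from = node_states[p], to = node_states[ch],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(), parent = integer(), child = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)
}
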