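# Independent oracles and small fixture builders shared across the suite.

# Brute-force homology scan: identity of every window on both strands,
# thresholded, merged with the same keep-max policy. Independent of the
# seed-and-extend path.
brute_force_scan <- function(query, genome, min_identity) {
  query <- toupper(query)
  L <- nchar(query)
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (sid in names(genome)) {
    gv <- strsplit(toupper(genome[[sid]]), "")[[1]]
    if (length(gv) < L) next
    for (strand in c("+", "-")) {
      qv <- strsplit(if (strand == "+") query else revcomp(query), "")[[1]]
      for (a in seq_len(length(gv) - L + 1)) {
        win <- gv[a:(a + L - 1)]
        id <- sum(win == qv & win %in% acgt) / L
        if (id >= min_identity) {
          rows[[length(rows) + 1]] <- data.frame(
            seq_id = sid, start = a - 1L, end = a - 1L + L, strand = strand,
            identity = id, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, rows)
  out <- list()
  for (key in unique(paste(h$seq_id, h$strand))) {
    s <- h[paste(h$seq_id, h$strand) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, s$start[-1] >= cummax(s$end[-nrow(s)])))
    for (g in unique(grp)) {
      sub <- s[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <-
        sub[order(-sub$identity, sub$start), ][1, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive minimum-change enumeration over all internal-node labelings of
# one column. Returns the minimum change count and whether a given full
# labeling (tips + internals) achieves it.
exhaustive_min_changes <- function(tree, states) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  tipstate <- states[tree$tip.label]
  grid <- expand.grid(rep(list(bases), nnode), stringsAsFactors = FALSE)
  cost <- function(assign_int) {
    full <- c(tipstate, unlist(assign_int))
    sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
  }
  costs <- apply(grid, 1, function(row) cost(as.list(row)))
  list(min = min(costs),
       optimal_internal = grid[costs == min(costs), , drop = FALSE])
}

# Per-column complementarity oracle by direct base comparison.
brute_force_profile <- function(seq_c, seq_d) {
  cv <- strsplit(seq_c, "")[[1]]
  dv <- strsplit(seq_d, "")[[1]]
  L <- length(cv)
  comp <- vapply(seq_len(L), function(i) {
    p <- paste0(cv[i], dv[L + 1 - i])
    p %in% c("AT", "TA", "CG", "GC")
  }, logical(1))
  list(complementary = comp, score = mean(comp))
}

# Minimal two-exon transcript model on a 1 kb toy sequence.
toy_model <- function(seq_id = "chrT", strand = "+") {
  transcript_model(
    "toy_tx", "toy_gene",
    genomic_interval(seq_id, 100L, 300L, strand),
    list(genomic_interval(seq_id, 100L, 150L, strand),
         genomic_interval(seq_id, 200L, 300L, strand)),
    "noncoding"
  )
}

read1 <- function(seq_id, start, end, ..., strand = ".") {
  spliced_read(seq_id, start, end, name = "r", strand = strand, ...)
}
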