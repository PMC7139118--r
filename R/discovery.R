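# CNE homology discovery: seed-and-extend scanning of both genome strands,
# synteny-based cluster assignment between the flanking paralog genes, and the
# cross-species presence/absence matrix.

# 1-based window-start positions in gv (character vector genome) anchored by an
# exact seed match of length s against qv (character vector query pattern).
seed_anchor_positions <- function(gv, qv, s) {
  G <- length(gv)
  L <- length(qv)
  nwin <- G - L + 1L
  if (nwin < 1L) return(integer())
  anchors <- logical(nwin)
  nseed <- G - s + 1L
  for (off in 0:(L - s)) {
    m <- rep(TRUE, nseed)
    for (k in seq_len(s)) {
      m <- m & (gv[k:(G - s + k)] == qv[off + k])
    }
    pos <- which(m) - off
    pos <- pos[pos >= 1L & pos <= nwin]
    anchors[pos] <- TRUE
  }
  which(anchors)
}

# Keep the maximal-identity hit (tie-break leftmost) within each group of
# mutually overlapping same-strand hits.
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- list()
  for (key in unique(paste(hits$seq_id, hits$strand))) {
    h <- hits[paste(hits$seq_id, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- integer(nrow(h))
    g <- 1L
    grp[1L] <- g
    cur_end <- h$end[1L]
    for (i in seq_len(nrow(h))[-1L]) {
      if (h$start[i] < cur_end) {
        grp[i] <- g
        cur_end <- max(cur_end, h$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        cur_end <- h$end[i]
      }
    }
    for (gg in unique(grp)) {
      sub <- h[grp == gg, , drop = FALSE]
      best <- sub[order(-sub$identity, sub$start), , drop = FALSE][1L, ,
                                                                   drop = FALSE]
      out[[length(out) + 1L]] <- best
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a genome for homologs of a query element
#'
#' Both strands are scanned. Candidate windows are anchored by an exact seed
#' match of length `seed_len` at any query offset, extended (ungapped) to the
#' full query length, and scored as `identity = matches / query length`.
#' Overlapping hits on the same strand are merged keeping the maximal-identity
#' hit (tie-break leftmost); hits below `min_identity` are discarded. `N`
#' bases never count as matches.
#'
#' @param query Query sequence (alphabet `A/C/G/T/N`).
#' @param genome Named character vector `seq_id -> sequence`.
#' @param min_identity Minimum identity fraction to report a hit.
#' @param seed_len Exact-match seed length. The default (7, the short-query
#'   word-size convention) keeps the scan sensitive for a 32-nt element at
#'   up to ~25% divergence, where an above-threshold window frequently
#'   contains no exact 12-mer.
#' @return `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `identity`, `matched_seq` (reported 5'->3' on the hit strand, i.e.
#'   directly comparable to the query) and `cluster` (always `"unassigned"`;
#'   see [assign_synteny()]).
#' @export
scan_homologs <- function(query, genome, min_identity = 0.75, seed_len = 7L) {
  query <- toupper(query)
  if (grepl("[^ACGTN]", query)) {
    stop("query contains characters outside A/C/G/T/N", call. = FALSE)
  }
  L <- nchar(query)
  if (L < seed_len) stop("query shorter than seed_len", call. = FALSE)
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (sid in names(genome)) {
    g <- toupper(genome[[sid]])
    if (nchar(g) < L) next
    gv <- seq_chars(g)
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") query else revcomp(query)
      qv <- seq_chars(qs)
      for (a in seed_anchor_positions(gv, qv, seed_len)) {
        win <- gv[a:(a + L - 1L)]
        matches <- sum(win == qv & win %in% acgt)
        id <- matches / L
        if (id >= min_identity) {
          wseq <- paste(win, collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = sid, start = a - 1L, end = a - 1L + L, strand = strand,
            identity = id,
            matched_seq = if (strand == "+") wseq else revcomp(wseq),
            cluster = "unassigned", stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), matched_seq = character(),
                      cluster = character(), stringsAsFactors = FALSE))
  }
  merge_overlapping_hits(do.call(rbind, rows))
}

#' Assign a hit to a paralog cluster by flanking-gene synteny
#'
#' A hit is labelled `C` when it lies strictly between the spans of the
#' C-cluster's two flanking genes on the same sequence ("strictly between"
#' meaning no overlap with either gene span), `D` analogously, otherwise
#' `"unassigned"`.
#'
#' @param hit A single hit: a list or one-row `data.frame` with `seq_id`,
#'   `start`, `end`.
#' @param annotation List of [transcript_model()] objects for the species.
#' @param patterns Cluster-coded gene-name substrings, in flanking order,
#'   e.g. `list(C = c("c11", "c12"), D = c("d11", "d12"))` matched
#'   case-insensitively against gene ids.
#' @return `"C"`, `"D"` (or another cluster name from `patterns`) or
#'   `"unassigned"`. Hits nesting between both pairs raise an error
#'   (malformed annotation).
#' @export
assign_synteny <- function(hit, annotation,
                           patterns = list(C = c("c11", "c12"),
                                           D = c("d11", "d12"))) {
  spans <- gene_spans(annotation)
  find_span <- function(pat, seq_id) {
    m <- spans[grepl(pat, tolower(spans$gene_id), fixed = TRUE) &
                 spans$seq_id == seq_id, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    if (nrow(m) > 1L) {
      stop("annotation malformed: multiple genes match pattern '", pat,
           "' on ", seq_id, call. = FALSE)
    }
    m
  }
  labels <- character()
  for (cl in names(patterns)) {
    g1 <- find_span(patterns[[cl]][1L], hit$seq_id)
    g2 <- find_span(patterns[[cl]][2L], hit$seq_id)
    if (is.null(g1) || is.null(g2)) next
    left <- if (g1$start <= g2$start) g1 else g2
    right <- if (g1$start <= g2$start) g2 else g1
    if (hit$start >= left$end && hit$end <= right$start) {
      labels <- c(labels, cl)
    }
  }
  if (length(labels) > 1L) {
    stop("hit lies between the flanking genes of multiple clusters (",
         paste(labels, collapse = ", "), "); annotation malformed",
         call. = FALSE)
  }
  if (length(labels) == 0L) "unassigned" else labels
}

#' Build a cross-species presence/absence matrix
#'
#' @param hits_by_species Named list (species -> hit `data.frame` with a
#'   `cluster` column, as produced by [scan_homologs()] +
#'   [assign_synteny()]).
#' @param species Character vector fixing the row order (typically tree leaf
#'   order). Every species carrying hits must be listed.
#' @param clusters Column labels.
#' @param no_assembly Species without a genome assembly; their rows are marked
#'   `"no_assembly"`.
#' @return Character matrix (`species` x `clusters`) with cells `"present"`,
#'   `"absent"` or `"no_assembly"`.
#' @export
build_presence_matrix <- function(hits_by_species, species,
                                  clusters = c("C", "D"),
                                  no_assembly = character()) {
  unknown <- setdiff(names(hits_by_species), species)
  if (length(unknown) > 0L) {
    stop("species with hits but not in species list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- matrix("absent", nrow = length(species), ncol = length(clusters),
              dimnames = list(species, clusters))
  m[rownames(m) %in% no_assembly, ] <- "no_assembly"
  for (sp in names(hits_by_species)) {
    if (sp %in% no_assembly) next
    h <- hits_by_species[[sp]]
    if (is.null(h) || nrow(h) == 0L) next
    for (cl in intersect(unique(h$cluster), clusters)) {
      m[sp, cl] <- "present"
    }
  }
  m
}
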