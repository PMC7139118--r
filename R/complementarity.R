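# Orientation-aware complementarity between paralogous CNE copies, and
# detection of compensatory substitution events on a species tree.
#
# Convention: the two copies are written 5'->3' in their host-transcript
# orientation. Two 5'->3' RNAs hybridise antiparallel, so column i of the
# C-side sequence pairs with column L-1-i (0-based) of the D-side sequence;
# a column is complementary when the two bases Watson-Crick pair (A:T, C:G).

#' Construct an oriented paralog pair
#'
#' The two paralog CNE sequences of one species, each written 5'->3' in its
#' host-transcript orientation, with the provenance of each orientation
#' (`"annotated"` from an overlapping transcript, `"inferred"` from a flank
#' rule; see [infer_orientation()]).
#'
#' @param species Species label.
#' @param seq_c,seq_d Equal-length sequences over `A/C/G/T`.
#' @param provenance_c,provenance_d `"annotated"` or `"inferred"`.
#' @return An object of class `oriented_pair`.
#' @export
oriented_pair <- function(species, seq_c, seq_d,
                          provenance_c = "annotated",
                          provenance_d = "annotated") {
  seq_c <- toupper(seq_c)
  seq_d <- toupper(seq_d)
  if (nchar(seq_c) != nchar(seq_d)) {
    stop("oriented pair sequences must have equal length (fixed-width ",
         "element), got ", nchar(seq_c), " and ", nchar(seq_d),
         call. = FALSE)
  }
  if (grepl("[^ACGT]", seq_c) || grepl("[^ACGT]", seq_d)) {
    stop("oriented pair sequences must be over A/C/G/T", call. = FALSE)
  }
  if (!provenance_c %in% c("annotated", "inferred") ||
      !provenance_d %in% c("annotated", "inferred")) {
    stop("provenance must be 'annotated' or 'inferred'", call. = FALSE)
  }
  structure(list(species = species, seq_c = seq_c, seq_d = seq_d,
                 provenance_c = provenance_c, provenance_d = provenance_d),
            class = "oriented_pair")
}

#' Per-column complementarity profile of an oriented pair
#'
#' Column `i` (1-based) of `seq_c` is complementary iff it Watson-Crick pairs
#' with column `L + 1 - i` of `seq_d`; equivalently the score is the match
#' fraction between `seq_c` and `revcomp(seq_d)`.
#'
#' @param pair An [oriented_pair()].
#' @param allow_wobble Also accept G:T (G:U at the RNA level) wobble pairs.
#'   Off by default: complementarity is treated as a discrete strict
#'   Watson-Crick state.
#' @return List with `complementary` (logical vector over `seq_c` columns)
#'   and `score` (fraction of complementary columns).
#' @export
complementarity_profile <- function(pair, allow_wobble = FALSE) {
  stopifnot(inherits(pair, "oriented_pair"))
  cv <- seq_chars(pair$seq_c)
  dv <- rev(seq_chars(pair$seq_d))
  comp <- wc_pair(cv, dv, allow_wobble = allow_wobble)
  list(complementary = comp, score = mean(comp))
}

#' Infer the transcriptional orientation of a CNE hit
#'
#' When an annotated transcript overlaps the hit, its strand is used
#' (`provenance = "annotated"`). Otherwise the strand is dictated by a flank
#' rule (`provenance = "inferred"`): by default, antisense to the cluster's
#' first flanking gene (the `gene11`-patterned gene of the hit's assigned
#' cluster).
#'
#' @param hit A hit (list or one-row `data.frame`) with `seq_id`, `start`,
#'   `end` and a `cluster` label (see [assign_synteny()]).
#' @param transcripts List of [transcript_model()] objects.
#' @param patterns Cluster gene-name patterns, as in [assign_synteny()].
#' @param flank_rule Only `"antisense_gene11"` is implemented.
#' @return List with `strand` and `provenance`.
#' @export
infer_orientation <- function(hit, transcripts,
                              patterns = list(C = c("c11", "c12"),
                                              D = c("d11", "d12")),
                              flank_rule = "antisense_gene11") {
  flank_rule <- match.arg(flank_rule, "antisense_gene11")
  hiv <- genomic_interval(hit$seq_id, hit$start, hit$end)
  over <- Filter(function(m) iv_overlaps(m$interval, hiv), transcripts)
  if (length(over) > 0L) {
    strands <- unique(vapply(over, function(m) m$interval$strand,
                             character(1)))
    if (length(strands) > 1L) {
      stop("transcripts on both strands overlap the hit: ",
           paste(vapply(over, function(m) m$transcript_id, character(1)),
                 collapse = ", "), call. = FALSE)
    }
    return(list(strand = strands, provenance = "annotated"))
  }
  cl <- hit$cluster
  if (is.null(cl) || !cl %in% names(patterns)) {
    stop("hit has no cluster label; cannot apply the flank rule",
         call. = FALSE)
  }
  spans <- gene_spans(transcripts)
  g1 <- spans[grepl(patterns[[cl]][1L], tolower(spans$gene_id),
                    fixed = TRUE) & spans$seq_id == hit$seq_id, ,
              drop = FALSE]
  if (nrow(g1) != 1L) {
    stop("flank rule needs exactly one '", patterns[[cl]][1L],
         "' gene on ", hit$seq_id, call. = FALSE)
  }
  list(strand = if (g1$strand == "+") "-" else "+", provenance = "inferred")
}

# Classify a compensatory call from the complementarity state before (parent
# states) and after (child states). Returns NA for the noncomp -> noncomp
# case, which involves no complementarity relationship and is not reported.
classify_call <- function(before, after) {
  if (before && after) "retention"
  else if (before && !after) "loss"
  else if (!before && after) "gain"
  else NA_character_
}

#' Detect compensatory substitution events on a species tree
#'
#' For every column of each side, ancestral states are reconstructed by Fitch
#' parsimony ([fitch_reconstruct()]); a substitution event is any branch whose
#' child state differs from its parent state. A compensatory call is any
#' branch carrying events on both sides at an antiparallel-paired column pair
#' (`d_col = L + 1 - c_col`, 1-based), classified by the complementarity state
#' before versus after the branch: `gain` (non-complementary to
#' complementary), `retention` (complementary before and after a double
#' change) or `loss` (complementary to non-complementary).
#'
#' Parsimony reconstructions are frequently non-unique, and the Fitch
#' first-pass assignment need not be the most-parsimonious labeling that
#' best exhibits co-substitution. Ambiguity is therefore resolved in favour
#' of the compensatory pattern, never at the expense of parsimony: when one
#' side's event cannot be paired under the initial labeling, but an
#' equally-parsimonious labeling of the other side (unit-cost Sankoff
#' feasibility) places its event on the same branch, that labeling is
#' adopted; when a paired double change has an undefinable complementarity
#' class (non-complementary before and after), an equally-parsimonious
#' choice of edge states with a definable class is preferred. Both
#' adjustments are deterministic and flagged per call (`relabelled`). A
#' special case of this rule resolves the inherent polarisation ambiguity of
#' events adjacent to the root.
#'
#' @param pairs Named list (species -> [oriented_pair()]); must cover every
#'   tree leaf, all sequences equal length.
#' @param tree `ape::phylo` or Newick string. Multifurcating trees are
#'   accepted (generalised Fitch) and flagged in the output.
#' @param allow_wobble Passed to the complementarity predicate.
#' @return List with `calls` (`data.frame`: `branch`, `c_col`, `d_col`,
#'   `class`, `c_from`, `c_to`, `d_from`, `d_to`, `relabelled`),
#'   `events` (`data.frame`: `branch`, `side`, `column`, `from`, `to`) and
#'   `multifurcating` flag.
#' @export
detect_compensatory_events <- function(pairs, tree, allow_wobble = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(pairs))
  if (length(missing) > 0L) {
    stop("leaf without an oriented pair: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- vapply(tips, function(sp) nchar(pairs[[sp]]$seq_c), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all pairs must have equal length", call. = FALSE)
  }
  L <- lens[[1L]]
  ti <- tree_index(tree)
  multifurcating <- any(lengths(ti$children[ti$post_internal]) > 2L)
  bids <- clade_ids(ti)

  cmat <- vapply(tips, function(sp) seq_chars(pairs[[sp]]$seq_c),
                 character(L))
  dmat <- vapply(tips, function(sp) seq_chars(pairs[[sp]]$seq_d),
                 character(L))
  if (L == 1L) {
    cmat <- matrix(cmat, nrow = 1L, dimnames = list(NULL, tips))
    dmat <- matrix(dmat, nrow = 1L, dimnames = list(NULL, tips))
  }
  leaf_states <- function(side, col) {
    stats::setNames(if (side == "C") cmat[col, ] else dmat[col, ], tips)
  }
  lab <- list(C = vector("list", L), D = vector("list", L))
  tabs <- list(C = vector("list", L), D = vector("list", L))
  relabelled <- list(C = logical(L), D = logical(L))
  for (i in seq_len(L)) {
    for (side in c("C", "D")) {
      st <- leaf_states(side, i)
      lab[[side]][[i]] <- fitch_reconstruct(tree, st)$node_states
      tabs[[side]][[i]] <- sankoff_tables(ti, st)
    }
  }
  side_events <- function(side, col) {
    events_from_states(ti, bids, lab[[side]][[col]])
  }
  classify_pair <- function(cx, dy) {
    classify_call(wc_pair(cx[["from"]], dy[["from"]], allow_wobble),
                  wc_pair(cx[["to"]], dy[["to"]], allow_wobble))
  }
  # Adopt an equally-parsimonious labeling of `side`/`col` that places an
  # event with states `opt` on the edge into `child`. Returns TRUE on
  # success.
  adopt <- function(side, col, child, opt) {
    st <- leaf_states(side, col)
    cl <- constrained_labeling(ti, st, child, opt[["from"]], opt[["to"]])
    if (is.null(cl) || cl$cost != tabs[[side]][[col]]$min) return(FALSE)
    lab[[side]][[col]] <<- cl$node_states
    relabelled[[side]][col] <<- TRUE
    TRUE
  }

  for (i in seq_len(L)) {
    j <- L + 1L - i
    for (pass in 1:2) {
      ex <- side_events("C", i)
      ey <- side_events("D", j)
      paired <- intersect(ex$branch, ey$branch)
      changed <- FALSE
      # co-locate: move the counterpart side onto an unpaired event's branch
      # when an equally-parsimonious labeling allows it
      co_locate <- function(have, have_side, want_side, want_col) {
        for (k in seq_len(nrow(have))) {
          b <- have$branch[k]
          if (b %in% paired) next
          opts <- edge_change_options(ti, tabs[[want_side]][[want_col]],
                                      have$child[k])
          if (length(opts) == 0L) next
          # prefer an option giving a definable class
          defin <- vapply(opts, function(o) {
            cx <- if (have_side == "C") have[k, ] else o
            dy <- if (have_side == "C") o else have[k, ]
            !is.na(classify_pair(cx, dy))
          }, logical(1))
          opt <- if (any(defin)) opts[[which(defin)[1L]]] else opts[[1L]]
          old_lab <- lab[[want_side]][[want_col]]
          old_flag <- relabelled[[want_side]][want_col]
          if (!adopt(want_side, want_col, have$child[k], opt)) next
          new_other <- side_events(want_side, want_col)
          new_paired <- intersect(
            if (have_side == "C") ex$branch else new_other$branch,
            if (have_side == "C") new_other$branch else ey$branch
          )
          if (length(new_paired) > length(paired) && b %in% new_paired) {
            return(TRUE)
          }
          lab[[want_side]][[want_col]] <<- old_lab
          relabelled[[want_side]][want_col] <<- old_flag
        }
        FALSE
      }
      if (co_locate(ex, "C", "D", j)) changed <- TRUE
      ex <- side_events("C", i)
      ey <- side_events("D", j)
      paired <- intersect(ex$branch, ey$branch)
      if (co_locate(ey, "D", "C", i)) changed <- TRUE
      ex <- side_events("C", i)
      ey <- side_events("D", j)
      paired <- intersect(ex$branch, ey$branch)
      # class repair: prefer equally-parsimonious edge states giving a
      # definable complementarity transition
      for (b in paired) {
        cx <- ex[ex$branch == b, ][1L, ]
        dy <- ey[ey$branch == b, ][1L, ]
        if (!is.na(classify_pair(cx, dy))) next
        fixed <- FALSE
        for (side_fix in c("D", "C")) {
          col_fix <- if (side_fix == "D") j else i
          anchor <- if (side_fix == "D") cx else dy
          child <- if (side_fix == "D") dy$child else cx$child
          opts <- edge_change_options(ti, tabs[[side_fix]][[col_fix]], child)
          defin <- vapply(opts, function(o) {
            a <- if (side_fix == "D") anchor else o
            d <- if (side_fix == "D") o else anchor
            !is.na(classify_pair(a, d))
          }, logical(1))
          if (!any(defin)) next
          if (adopt(side_fix, col_fix, child, opts[[which(defin)[1L]]])) {
            fixed <- TRUE
            changed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (!changed) break
    }
  }

  ev_rows <- list()
  for (i in seq_len(L)) {
    for (side in c("C", "D")) {
      e <- side_events(side, i)
      if (nrow(e) > 0L) {
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          branch = e$branch, side = side, column = i, from = e$from,
          to = e$to, stringsAsFactors = FALSE
        )
      }
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(branch = character(), side = character(), column = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)

  call_rows <- list()
  for (i in seq_len(L)) {
    j <- L + 1L - i
    ex <- side_events("C", i)
    ey <- side_events("D", j)
    for (b in intersect(ex$branch, ey$branch)) {
      cx <- ex[ex$branch == b, ][1L, ]
      dy <- ey[ey$branch == b, ][1L, ]
      cls <- classify_pair(cx, dy)
      if (is.na(cls)) next
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        branch = b, c_col = i, d_col = j, class = cls,
        c_from = cx$from, c_to = cx$to, d_from = dy$from, d_to = dy$to,
        relabelled = relabelled$C[i] || relabelled$D[j],
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(branch = character(), c_col = integer(), d_col = integer(),
               class = character(), c_from = character(),
               c_to = character(), d_from = character(), d_to = character(),
               relabelled = logical(), stringsAsFactors = FALSE)
  list(calls = calls, events = events, multifurcating = multifurcating)
}
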