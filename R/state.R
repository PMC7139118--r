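# Enhancer-state calling per cell type: CTSS tag clustering, divergent
# enhancer-RNA pair detection at nucleosome-scale spacing, chromatin-signal
# feature extraction, and a deterministic decision ladder over
# closed / poised_enhancer / active_enhancer / promoter_ambiguous.

#' Cluster CTSS tags per strand
#'
#' Single-linkage clustering per strand: consecutive CTSS at most `max_gap`
#' bp apart join one cluster. The dominant position of a cluster is the
#' position with the highest tag count (tie-break leftmost).
#'
#' @param ctss CTSS `data.frame` (`seq_id`, `pos`, `count`, `strand`), as
#'   read by [read_ctss_bed()].
#' @param max_gap Maximum gap (bp) joining consecutive tags.
#' @return `data.frame` of clusters: `seq_id`, `start`, `end` (half-open),
#'   `strand`, `dominant` (position), `total` (tags). Zero rows for empty
#'   input.
#' @export
cluster_ctss <- function(ctss, max_gap = 20L) {
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      dominant = integer(), total = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(ctss) || nrow(ctss) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(ctss$seq_id, ctss$strand))) {
    sub <- ctss[paste(ctss$seq_id, ctss$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    # aggregate duplicate positions
    agg <- stats::aggregate(count ~ pos, data = sub, FUN = sum)
    agg <- agg[order(agg$pos), , drop = FALSE]
    brk <- c(0L, which(diff(agg$pos) > max_gap), nrow(agg))
    for (k in seq_len(length(brk) - 1L)) {
      idx <- (brk[k] + 1L):brk[k + 1L]
      counts <- agg$count[idx]
      pos <- agg$pos[idx]
      out[[length(out) + 1L]] <- data.frame(
        seq_id = sub$seq_id[1L], start = min(pos), end = max(pos) + 1L,
        strand = sub$strand[1L], dominant = pos[which.max(counts)],
        total = sum(counts), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find divergent (bidirectional) TSS cluster pairs around an element
#'
#' All (minus, plus) cluster pairs whose dominant positions lie within
#' `window` bp of the element and on opposite sides of (or overlapping) it
#' with divergent geometry (minus dominant strictly left of plus dominant).
#' Spacing is the distance between the dominant positions; a pair is
#' `nucleosome_scale` when the spacing falls inside `spacing_band`.
#'
#' @param clusters Output of [cluster_ctss()].
#' @param element `genomic_interval` of the element.
#' @param window Maximum distance (bp) of a dominant position from the
#'   element.
#' @param spacing_band `c(lo, hi)` inclusive band encoding nucleosome-scale
#'   spacing (147 bp core plus linker by default).
#' @return `data.frame` sorted by total tags descending: dominant positions,
#'   totals, `spacing`, `divergent`, `nucleosome_scale`. Zero rows when no
#'   pair qualifies.
#' @export
find_bidirectional_pairs <- function(clusters, element, window = 300L,
                                     spacing_band = c(100L, 250L)) {
  empty <- data.frame(minus_dominant = integer(), plus_dominant = integer(),
                      minus_total = integer(), plus_total = integer(),
                      total = integer(), spacing = integer(),
                      divergent = logical(), nucleosome_scale = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L) return(empty)
  cl <- clusters[clusters$seq_id == element$seq_id, , drop = FALSE]
  near <- cl$dominant >= element$start - window &
    cl$dominant < element$end + window
  cl <- cl[near, , drop = FALSE]
  minus <- cl[cl$strand == "-", , drop = FALSE]
  plus <- cl[cl$strand == "+", , drop = FALSE]
  if (nrow(minus) == 0L || nrow(plus) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(minus))) {
    for (j in seq_len(nrow(plus))) {
      m <- minus$dominant[i]
      p <- plus$dominant[j]
      divergent <- m < p
      opposite <- m < element$end && p >= element$start
      if (!divergent || !opposite) next
      spacing <- p - m
      rows[[length(rows) + 1L]] <- data.frame(
        minus_dominant = m, plus_dominant = p,
        minus_total = minus$total[i], plus_total = plus$total[j],
        total = minus$total[i] + plus$total[j], spacing = spacing,
        divergent = TRUE,
        nucleosome_scale = spacing >= spacing_band[1L] &&
          spacing <= spacing_band[2L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(-res$total, res$minus_dominant), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract chromatin-signal evidence around an element
#'
#' Per mark: the mean over the element core, the means over the two flanks of
#' width `flank`, and the ratio of the element-region mean to the local
#' background (the mean over element +/- `10 * flank`, excluding the element
#' +/- `flank` region). H3K4me1 bimodality requires both flank means to reach
#' `bimodal_ratio` times the core mean (and to be positive). DHS openness is
#' the core mean over the local background. Uncovered track positions are
#' treated as 0 and counted in `n_uncovered`.
#'
#' @param tracks Named list of [signal_track()]s; recognised names are
#'   `dhs`, `h3k4me1`, `h3k27ac`, `h3k27me3`, `p300` (others are summarised
#'   too).
#' @param element `genomic_interval`.
#' @param flank Flank width (bp).
#' @param bimodal_ratio Flank/core ratio declaring bimodality.
#' @return Named list of evidence: per mark `<mark>_core`, `<mark>_flank`,
#'   `<mark>_level` (region/background ratio); plus `dhs_openness`,
#'   `h3k4me1_bimodal` and `n_uncovered`.
#' @export
signal_features <- function(tracks, element, flank = 500L,
                            bimodal_ratio = 1.5) {
  stopifnot(is.list(tracks), length(tracks) > 0L)
  ev <- list()
  n_uncovered <- 0L
  ratio0 <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else 0
  }
  for (mark in names(tracks)) {
    tr <- tracks[[mark]]
    core_v <- track_values(tr, element$start, element$end)
    left_v <- track_values(tr, max(0L, element$start - flank), element$start)
    right_v <- track_values(tr, element$end, element$end + flank)
    bg_lo <- max(0L, element$start - 10L * flank)
    bg_hi <- element$end + 10L * flank
    bg_v <- track_values(tr, bg_lo, bg_hi)
    # background excludes element +/- flank
    excl_lo <- max(0L, element$start - flank) - bg_lo + 1L
    excl_hi <- element$end + flank - bg_lo
    keep <- setdiff(seq_along(bg_v), excl_lo:excl_hi)
    bg <- if (length(keep) > 0L) mean(bg_v[keep]) else 0
    n_uncovered <- n_uncovered + attr(core_v, "n_uncovered") +
      attr(left_v, "n_uncovered") + attr(right_v, "n_uncovered")
    core <- mean(core_v)
    fl <- c(mean(left_v), mean(right_v))
    region <- mean(track_values(tr, max(0L, element$start - flank),
                                element$end + flank))
    ev[[paste0(mark, "_core")]] <- core
    ev[[paste0(mark, "_flank")]] <- mean(fl)
    ev[[paste0(mark, "_level")]] <- ratio0(region, bg)
    if (mark == "dhs") {
      ev$dhs_openness <- ratio0(core, bg)
    }
    if (mark == "h3k4me1") {
      ev$h3k4me1_bimodal <- all(fl > 0) && all(fl >= bimodal_ratio * core)
    }
  }
  if (is.null(ev$dhs_openness)) ev$dhs_openness <- 0
  if (is.null(ev$h3k4me1_bimodal)) ev$h3k4me1_bimodal <- FALSE
  ev$n_uncovered <- n_uncovered
  if (n_uncovered > 0L) {
    warning(n_uncovered, " uncovered track positions treated as 0",
            call. = FALSE)
  }
  ev
}

#' Call the regulatory state of an element in one cell type
#'
#' Deterministic, strictly ordered decision ladder:
#' \enumerate{
#'   \item element overlaps an annotated promoter -> `promoter_ambiguous`
#'     (chromatin analysis cannot distinguish an enhancer from an overlapping
#'     promoter);
#'   \item DHS openness below `open_threshold` -> `closed`;
#'   \item open and (H3K27ac high or at least one divergent CTSS pair) ->
#'     `active_enhancer` (bidirectional CAGE is the decisive active
#'     hallmark, so active outranks poised);
#'   \item open and H3K4me1 bimodal and H3K27me3 high -> `poised_enhancer`;
#'   \item otherwise `closed`, with a low-confidence note in the evidence.
#' }
#'
#' @param evidence Evidence list from [signal_features()].
#' @param pairs Divergent pairs from [find_bidirectional_pairs()] (may have
#'   zero rows).
#' @param overlaps_promoter Declared by the caller from annotation.
#' @param cell_type Cell-type label.
#' @param element `genomic_interval` (recorded in the call).
#' @param thresholds List with `open_threshold` (DHS openness ratio),
#'   `mark_high` (mark level over local background declaring a mark high).
#' @return An object of class `state_call`: list with `element`, `cell_type`,
#'   `state` and the `evidence` behind it.
#' @export
call_state <- function(evidence, pairs, overlaps_promoter = FALSE,
                       cell_type = "cell_type", element = NULL,
                       thresholds = list(open_threshold = 2.0,
                                         mark_high = 2.0)) {
  required <- c("dhs_openness", "h3k4me1_bimodal", "h3k27ac_level",
                "h3k27me3_level")
  miss <- setdiff(required, names(evidence))
  if (length(miss) > 0L) {
    stop("missing required evidence: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_div <- if (is.null(pairs)) 0L else sum(pairs$divergent)
  evidence$n_divergent_pairs <- n_div
  evidence$erna <- n_div > 0L
  state <- if (isTRUE(overlaps_promoter)) {
    "promoter_ambiguous"
  } else if (evidence$dhs_openness < thresholds$open_threshold) {
    "closed"
  } else if (evidence$h3k27ac_level >= thresholds$mark_high || n_div >= 1L) {
    "active_enhancer"
  } else if (isTRUE(evidence$h3k4me1_bimodal) &&
             evidence$h3k27me3_level >= thresholds$mark_high) {
    "poised_enhancer"
  } else {
    evidence$low_confidence <- TRUE
    "closed"
  }
  structure(list(element = element, cell_type = cell_type, state = state,
                 evidence = evidence),
            class = "state_call")
}

#' @export
print.state_call <- function(x, ...) {
  cat(sprintf("state_call [%s]: %s (DHS openness %.2f, eRNA %s)\n",
              x$cell_type, x$state, x$evidence$dhs_openness,
              if (isTRUE(x$evidence$erna)) "yes" else "no"))
  invisible(x)
}

#' Partition samples into expressing and non-expressing groups
#'
#' @param mat Expression matrix (features x samples, TPM).
#' @param feature Feature id (e.g. the lncRNA host).
#' @param threshold Expressing means TPM at or above this value.
#' @return List with `expressing`, `non_expressing` (sample id vectors) and
#'   `sizes`.
#' @export
group_cell_types <- function(mat, feature, threshold = 1) {
  if (!feature %in% rownames(mat)) {
    stop("feature '", feature, "' absent from matrix", call. = FALSE)
  }
  v <- mat[feature, ]
  expressing <- colnames(mat)[v >= threshold]
  non_expressing <- setdiff(colnames(mat), expressing)
  list(expressing = expressing, non_expressing = non_expressing,
       sizes = c(expressing = length(expressing),
                 non_expressing = length(non_expressing)))
}
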