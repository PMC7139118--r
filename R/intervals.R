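# Genomic intervals and transcript models: the coordinate currency of the
# package. All coordinates are 0-based, half-open (BED-style), regardless of
# the on-disk dialect; GFF3 (1-based inclusive) is converted at the boundary.

#' Construct a genomic interval
#'
#' A located, optionally stranded span on a named sequence, in 0-based
#' half-open coordinates.
#'
#' @param seq_id Non-empty sequence name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` (unstranded).
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr12", 100, 132, "-")
#' @export
genomic_interval <- function(seq_id, start, end, strand = ".") {
  if (!is.character(seq_id) || length(seq_id) != 1L || is.na(seq_id) ||
      !nzchar(seq_id)) {
    stop("seq_id must be a single non-empty string", call. = FALSE)
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("interval requires 0 <= start < end (0-based half-open), got [",
         start, ", ", end, ")", call. = FALSE)
  }
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  structure(
    list(seq_id = seq_id, start = start, end = end, strand = strand),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

#' Width of a genomic interval
#' @param x A `genomic_interval`.
#' @return Integer width (`end - start`).
#' @export
iv_width <- function(x) x$end - x$start

#' Do two intervals overlap?
#'
#' Overlap requires a shared `seq_id` and at least one shared base; strand is
#' ignored (signal windows and unstranded reads routinely cross strands).
#'
#' @param a,b `genomic_interval` objects.
#' @return Logical.
#' @export
iv_overlaps <- function(a, b) {
  a$seq_id == b$seq_id && a$start < b$end && b$start < a$end
}

# Width of the intersection of [s1,e1) and [s2,e2); 0 when disjoint.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Construct a transcript model
#'
#' A transcript with its exon structure. Introns are defined implicitly as the
#' gaps between consecutive exons (see [introns()]).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param interval `genomic_interval` spanning the transcript (stranded).
#' @param exons List of `genomic_interval`s on the same `seq_id` and strand,
#'   non-overlapping; they are sorted by start internally.
#' @param biotype `"coding"` or `"noncoding"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, interval, exons,
                             biotype = c("noncoding", "coding")) {
  biotype <- match.arg(biotype)
  stopifnot(inherits(interval, "genomic_interval"))
  if (!interval$strand %in% c("+", "-")) {
    stop("transcript '", transcript_id, "' must be stranded (+/-)",
         call. = FALSE)
  }
  if (length(exons) == 0L) {
    stop("transcript '", transcript_id, "' has no exons", call. = FALSE)
  }
  for (ex in exons) {
    stopifnot(inherits(ex, "genomic_interval"))
    if (ex$seq_id != interval$seq_id) {
      stop("exon seq_id mismatch in transcript '", transcript_id, "'",
           call. = FALSE)
    }
    if (ex$strand != interval$strand) {
      stop("strand mixing within transcript '", transcript_id, "': exon on '",
           ex$strand, "', transcript on '", interval$strand, "'",
           call. = FALSE)
    }
    if (ex$start < interval$start || ex$end > interval$end) {
      stop("exon [", ex$start, ",", ex$end, ") outside transcript span in '",
           transcript_id, "'", call. = FALSE)
    }
  }
  exons <- exons[order(vapply(exons, function(e) e$start, integer(1)))]
  ends <- vapply(exons, function(e) e$end, integer(1))
  starts <- vapply(exons, function(e) e$start, integer(1))
  if (length(exons) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    stop("overlapping exons in transcript '", transcript_id, "'",
         call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         interval = interval, exons = exons, biotype = biotype),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s, %s): %s:%d-%d(%s), %d exon(s)\n",
              x$transcript_id, x$gene_id, x$biotype, x$interval$seq_id,
              x$interval$start, x$interval$end, x$interval$strand,
              length(x$exons)))
  invisible(x)
}

#' Introns of a transcript model
#'
#' The gaps between consecutive exons, as unstranded-free intervals carrying
#' the transcript strand.
#'
#' @param model A `transcript_model`.
#' @return List of `genomic_interval` (possibly empty for single-exon models).
#' @export
introns <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  n <- length(model$exons)
  if (n < 2L) return(list())
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    out[[i]] <- genomic_interval(model$interval$seq_id,
                                 model$exons[[i]]$end,
                                 model$exons[[i + 1L]]$start,
                                 model$interval$strand)
  }
  out
}

# Gene spans (union of transcript intervals per gene_id) from a list of
# transcript models. Used by synteny assignment and orientation inference.
gene_spans <- function(models) {
  if (length(models) == 0L) {
    return(data.frame(gene_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    gene_id = vapply(models, function(m) m$gene_id, character(1)),
    seq_id = vapply(models, function(m) m$interval$seq_id, character(1)),
    start = vapply(models, function(m) m$interval$start, integer(1)),
    end = vapply(models, function(m) m$interval$end, integer(1)),
    strand = vapply(models, function(m) m$interval$strand, character(1)),
    stringsAsFactors = FALSE
  )
  parts <- split(df, df$gene_id)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(gene_id = p$gene_id[1L], seq_id = p$seq_id[1L],
               start = min(p$start), end = max(p$end),
               strand = p$strand[1L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
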