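# Intron-retention quantification: classify spliced reads against one
# transcript model into exon / intron / junction / unassigned, tally per
# library, and summarise retention and subcellular enrichment.

#' Classify a read against a transcript model
#'
#' A read is `exon` if every aligned base falls in the model's exons,
#' `intron` if every base falls in its introns, `junction` if bases fall in
#' both exon and intron of the same model, and `unassigned` if any base falls
#' outside the transcript span (or on another sequence). Classification
#' ignores read strand (unstranded library default); `stranded = TRUE`
#' additionally requires the read strand to match the transcript.
#'
#' @param read A [spliced_read()].
#' @param model A [transcript_model()].
#' @param stranded Require strand match (default `FALSE`).
#' @return One of `"exon"`, `"intron"`, `"junction"`, `"unassigned"`.
#' @export
classify_read <- function(read, model, stranded = FALSE) {
  stopifnot(inherits(read, "spliced_read"), inherits(model, "transcript_model"))
  if (any(read$blocks$end - read$blocks$start <= 0L)) {
    stop("read '", read$name, "' has a zero-length block", call. = FALSE)
  }
  if (read$seq_id != model$interval$seq_id) return("unassigned")
  if (stranded && read$strand %in% c("+", "-") &&
      read$strand != model$interval$strand) {
    return("unassigned")
  }
  bs <- read$blocks$start
  be <- read$blocks$end
  total <- sum(be - bs)
  in_span <- sum(overlap_width(bs, be, model$interval$start,
                               model$interval$end))
  if (in_span < total) return("unassigned")
  exonic <- 0L
  for (ex in model$exons) {
    exonic <- exonic + sum(overlap_width(bs, be, ex$start, ex$end))
  }
  intronic <- in_span - exonic
  if (exonic > 0L && intronic > 0L) "junction"
  else if (intronic > 0L) "intron"
  else "exon"
}

#' Count read classes for one library
#'
#' @param reads List of [spliced_read()] objects.
#' @param model A [transcript_model()].
#' @param library_id Library label.
#' @param stranded Passed to [classify_read()].
#' @return An object of class `read_class_counts`: list with `library_id`,
#'   counts `exon`, `intron`, `junction`, `unassigned`, `n_reads`, and an
#'   `intron_coverage` table (reads overlapping each intron of the model).
#' @export
count_library <- function(reads, model, library_id = "library",
                          stranded = FALSE) {
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  cls <- vapply(reads, classify_read, character(1), model = model,
                stranded = stranded)
  counts <- table(factor(cls, levels = c("exon", "intron", "junction",
                                         "unassigned")))
  ivs <- introns(model)
  cov <- integer(length(ivs))
  for (i in seq_along(ivs)) {
    iv <- ivs[[i]]
    cov[i] <- sum(vapply(reads, function(r) {
      r$seq_id == iv$seq_id &&
        any(overlap_width(r$blocks$start, r$blocks$end, iv$start, iv$end) > 0L)
    }, logical(1)))
  }
  intron_coverage <- data.frame(
    intron = seq_along(ivs),
    start = vapply(ivs, function(iv) iv$start, integer(1)),
    end = vapply(ivs, function(iv) iv$end, integer(1)),
    reads = cov
  )
  structure(list(library_id = library_id,
                 exon = unname(counts[["exon"]]),
                 intron = unname(counts[["intron"]]),
                 junction = unname(counts[["junction"]]),
                 unassigned = unname(counts[["unassigned"]]),
                 n_reads = length(reads),
                 intron_coverage = intron_coverage),
            class = "read_class_counts")
}

#' Summarise intron retention across libraries
#'
#' The intron fraction of a library is `(intron + junction) / (exon + intron
#' + junction)`: junction reads demonstrate unspliced molecules and count as
#' retention evidence, while the raw per-class counts are always preserved in
#' the output. The compartment log2 ratio contrasts the nuclear and cytosolic
#' intron fractions and is defined only when the cytosolic fraction is
#' positive.
#'
#' @param counts List of `read_class_counts` (one per library).
#' @param nuclear,cytosolic Library ids used for the compartment ratio
#'   (`NA` ratio when either is absent).
#' @return List with `per_library` (`data.frame` of raw counts and
#'   `intron_fraction`), `intron_coverage` (per-library list), and
#'   `compartment_log2_ratio`.
#' @export
summarize_retention <- function(counts, nuclear = "nuclear",
                                cytosolic = "cytosolic") {
  stopifnot(length(counts) >= 1L)
  df <- do.call(rbind, lapply(counts, function(x) {
    stopifnot(inherits(x, "read_class_counts"))
    data.frame(library_id = x$library_id, exon = x$exon, intron = x$intron,
               junction = x$junction, unassigned = x$unassigned,
               stringsAsFactors = FALSE)
  }))
  assigned <- df$exon + df$intron + df$junction
  if (all(assigned == 0L)) {
    stop("no transcript-overlapping reads", call. = FALSE)
  }
  df$intron_fraction <- ifelse(assigned > 0L,
                               (df$intron + df$junction) / assigned, NA_real_)
  ratio <- NA_real_
  if (nuclear %in% df$library_id && cytosolic %in% df$library_id) {
    fn <- df$intron_fraction[df$library_id == nuclear]
    fc <- df$intron_fraction[df$library_id == cytosolic]
    if (!is.na(fn) && !is.na(fc) && fc > 0) ratio <- log2(fn / fc)
  }
  list(per_library = df,
       intron_coverage = stats::setNames(
         lapply(counts, function(x) x$intron_coverage),
         vapply(counts, function(x) x$library_id, character(1))),
       compartment_log2_ratio = ratio)
}
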