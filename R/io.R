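# Readers and writers for the external formats consumed and produced by the
# analysis: FASTA, GFF3, CTSS BED6, bedGraph, BED12 spliced reads and TSV
# expression matrices. Every reader normalises to the internal 0-based
# half-open convention and every reader/writer pair round-trips valid files.
# Parsers are line-oriented so that malformed input is reported with its line
# number.

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  idx <- which(nzchar(trimws(lines)))
  list(lines = lines[idx], lineno = idx)
}

num_fmt <- function(x) sprintf("%.10g", x)

## ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path FASTA file; sequences over `{A,C,G,T,N}` (case-insensitive).
#' @return Named character vector mapping sequence id (first
#'   whitespace-delimited header token) to the upper-cased sequence.
#' @export
read_fasta <- function(path) {
  ln <- read_nonempty_lines(path)
  if (length(ln$lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- character()
  seqs <- list()
  cur <- NULL
  for (i in seq_along(ln$lines)) {
    line <- ln$lines[i]
    no <- ln$lineno[i]
    if (startsWith(line, ">")) {
      header <- trimws(sub("^>", "", line))
      id <- strsplit(header, "\\s+")[[1L]][1L]
      if (is.na(id) || !nzchar(id)) {
        stop("FASTA parse error at line ", no, ": empty header", call. = FALSE)
      }
      if (id %in% ids) {
        stop("FASTA parse error at line ", no, ": duplicate id '", id, "'",
             call. = FALSE)
      }
      ids <- c(ids, id)
      seqs[[id]] <- character()
      cur <- id
    } else {
      if (is.null(cur)) {
        stop("FASTA parse error at line ", no,
             ": sequence data before any '>' header", call. = FALSE)
      }
      s <- trimws(line)
      if (grepl("[^ACGTNacgtn]", s)) {
        stop("FASTA parse error at line ", no,
             ": characters outside A/C/G/T/N", call. = FALSE)
      }
      seqs[[cur]] <- c(seqs[[cur]], toupper(s))
    }
  }
  out <- vapply(seqs, paste, character(1), collapse = "")
  out[ids]
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param line_width Bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq.int(1L, n, by = line_width)
      writeLines(substring(s, starts, pmin(starts + line_width - 1L, n)), con)
    }
  }
  invisible(path)
}

## ---- GFF3 ------------------------------------------------------------------

parse_gff_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2L) p[2L] else "",
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  vals
}

transcript_types <- c("transcript", "mRNA", "ncRNA", "lnc_RNA", "lincRNA",
                      "antisense_RNA")

#' Read transcript models from a GFF3 file
#'
#' Parses gene / transcript (mRNA, ncRNA, ...) / exon features linked by
#' `ID`/`Parent` attributes. GFF3 1-based inclusive coordinates are converted
#' to the internal 0-based half-open convention; exons are grouped per
#' transcript and sorted by start. `mRNA` features become `biotype = "coding"`,
#' all other transcript types `"noncoding"`.
#'
#' @param path GFF3 file.
#' @return List of [transcript_model()] objects, in file order of the
#'   transcript features.
#' @export
read_gff3 <- function(path) {
  ln <- read_nonempty_lines(path)
  keep <- !startsWith(ln$lines, "#")
  lines <- ln$lines[keep]
  linenos <- ln$lineno[keep]
  tx <- list()
  exon_rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    no <- linenos[i]
    if (length(f) != 9L) {
      stop("GFF3 parse error at line ", no, ": expected 9 tab-separated ",
           "fields, got ", length(f), call. = FALSE)
    }
    type <- f[3L]
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 < start1) {
      stop("GFF3 parse error at line ", no, ": bad coordinates", call. = FALSE)
    }
    strand <- f[7L]
    attrs <- parse_gff_attrs(f[9L])
    if (type %in% transcript_types) {
      id <- attrs[["ID"]]
      if (is.null(id) || is.na(id)) {
        stop("GFF3 parse error at line ", no, ": transcript without ID",
             call. = FALSE)
      }
      tx[[id]] <- list(
        transcript_id = id,
        gene_id = if ("Parent" %in% names(attrs)) attrs[["Parent"]] else id,
        seq_id = f[1L], start = start1 - 1L, end = end1, strand = strand,
        biotype = if (type == "mRNA") "coding" else "noncoding",
        exons = list(), lineno = no
      )
    } else if (type == "exon") {
      parents <- strsplit(attrs[["Parent"]], ",", fixed = TRUE)[[1L]]
      if (length(parents) == 0L || any(!nzchar(parents))) {
        stop("GFF3 parse error at line ", no, ": exon without Parent",
             call. = FALSE)
      }
      for (p in parents) {
        exon_rows[[length(exon_rows) + 1L]] <- list(
          parent = p, seq_id = f[1L], start = start1 - 1L, end = end1,
          strand = strand, lineno = no
        )
      }
    }
    # gene and other feature types carry no structure we need beyond the
    # transcript's own Parent link; they are accepted and skipped.
  }
  for (ex in exon_rows) {
    p <- ex$parent
    if (!p %in% names(tx)) {
      stop("GFF3 error at line ", ex$lineno, ": exon with unknown Parent '",
           p, "'", call. = FALSE)
    }
    if (ex$strand != tx[[p]]$strand) {
      stop("GFF3 error at line ", ex$lineno,
           ": strand mixing within transcript '", p, "' (exon on '",
           ex$strand, "', transcript on '", tx[[p]]$strand, "')",
           call. = FALSE)
    }
    if (ex$seq_id != tx[[p]]$seq_id) {
      stop("GFF3 error at line ", ex$lineno, ": exon seq_id differs from ",
           "transcript '", p, "'", call. = FALSE)
    }
    tx[[p]]$exons[[length(tx[[p]]$exons) + 1L]] <-
      genomic_interval(ex$seq_id, ex$start, ex$end, ex$strand)
  }
  lapply(unname(tx), function(t) {
    if (length(t$exons) == 0L) {
      stop("GFF3 error: transcript '", t$transcript_id, "' has no exons",
           call. = FALSE)
    }
    transcript_model(
      t$transcript_id, t$gene_id,
      genomic_interval(t$seq_id, t$start, t$end, t$strand),
      t$exons, t$biotype
    )
  })
}

#' Write transcript models to a GFF3 file
#'
#' Emits gene, transcript (`mRNA` for coding, `ncRNA` for noncoding) and exon
#' features; internal 0-based half-open coordinates are printed back as GFF3
#' 1-based inclusive.
#'
#' @param models List of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- gene_spans(models)
  fmt <- function(seq_id, type, start0, end0, strand, attrs) {
    sprintf("%s\tcneduo\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seq_id, type, start0 + 1L, end0, strand, attrs)
  }
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    writeLines(fmt(g$seq_id, "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$gene_id)), con)
  }
  for (m in models) {
    type <- if (m$biotype == "coding") "mRNA" else "ncRNA"
    iv <- m$interval
    writeLines(fmt(iv$seq_id, type, iv$start, iv$end, iv$strand,
                   paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)),
               con)
    for (j in seq_along(m$exons)) {
      ex <- m$exons[[j]]
      writeLines(fmt(ex$seq_id, "exon", ex$start, ex$end, ex$strand,
                     paste0("ID=", m$transcript_id, ".exon", j,
                            ";Parent=", m$transcript_id)), con)
    }
  }
  invisible(path)
}

## ---- CTSS BED6 -------------------------------------------------------------

#' Read CAGE transcription start site tags (CTSS BED6)
#'
#' Single-base stranded records; the BED score column carries the tag count,
#' the name column is unused.
#'
#' @param path BED6 file.
#' @return `data.frame` with columns `seq_id`, `pos` (0-based), `count`,
#'   `strand`. Zero rows for an empty (header-only) file.
#' @export
read_ctss_bed <- function(path) {
  ln <- read_nonempty_lines(path)
  keep <- !startsWith(ln$lines, "#") & !startsWith(ln$lines, "track")
  lines <- ln$lines[keep]
  linenos <- ln$lineno[keep]
  n <- length(lines)
  seq_id <- character(n); pos <- integer(n); count <- integer(n)
  strand <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    no <- linenos[i]
    if (length(f) < 6L) {
      stop("CTSS BED parse error at line ", no, ": expected 6 fields",
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s < 0L) {
      stop("CTSS BED parse error at line ", no, ": bad coordinates",
           call. = FALSE)
    }
    if (e != s + 1L) {
      stop("CTSS BED parse error at line ", no,
           ": CTSS records must be single-base", call. = FALSE)
    }
    cnt <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(cnt) || cnt < 0 || cnt != round(cnt)) {
      stop("CTSS BED parse error at line ", no,
           ": score must be a non-negative integer tag count", call. = FALSE)
    }
    if (!f[6L] %in% c("+", "-")) {
      stop("CTSS BED parse error at line ", no, ": strand must be + or -",
           call. = FALSE)
    }
    seq_id[i] <- f[1L]; pos[i] <- s; count[i] <- as.integer(cnt)
    strand[i] <- f[6L]
  }
  data.frame(seq_id = seq_id, pos = pos, count = count, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write CTSS records as BED6
#' @param ctss `data.frame` as returned by [read_ctss_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctss_bed <- function(ctss, path) {
  stopifnot(all(c("seq_id", "pos", "count", "strand") %in% names(ctss)))
  lines <- sprintf("%s\t%d\t%d\t.\t%d\t%s", ctss$seq_id, ctss$pos,
                   ctss$pos + 1L, ctss$count, ctss$strand)
  writeLines(lines, path)
  invisible(path)
}

## ---- bedGraph --------------------------------------------------------------

#' Construct a per-base signal track
#'
#' A non-negative signal (reads per million) over one named sequence, stored
#' as sorted non-overlapping constant-value intervals (bedGraph semantics).
#' Positions not covered by any interval read as 0.
#'
#' @param seq_id Sequence name.
#' @param start,end Integer vectors of 0-based half-open interval bounds.
#' @param value Numeric vector of non-negative values.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(seq_id, start, end, value) {
  stopifnot(length(start) == length(end), length(start) == length(value))
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end) | start < 0L | end <= start)) {
    stop("signal_track intervals require 0 <= start < end", call. = FALSE)
  }
  if (any(is.na(value) | value < 0)) {
    stop("signal_track values must be non-negative", call. = FALSE)
  }
  o <- order(start)
  start <- start[o]; end <- end[o]; value <- as.numeric(value[o])
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    stop("signal_track intervals must be non-overlapping", call. = FALSE)
  }
  structure(list(seq_id = seq_id,
                 data = data.frame(start = start, end = end, value = value)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track on %s: %d interval(s), span [%d, %d)\n",
              x$seq_id, nrow(x$data),
              if (nrow(x$data)) min(x$data$start) else 0L,
              if (nrow(x$data)) max(x$data$end) else 0L))
  invisible(x)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file over a single sequence.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path) {
  ln <- read_nonempty_lines(path)
  keep <- !startsWith(ln$lines, "#") & !startsWith(ln$lines, "track")
  lines <- ln$lines[keep]
  linenos <- ln$lineno[keep]
  n <- length(lines)
  if (n == 0L) stop("empty bedGraph file: ", path, call. = FALSE)
  seq_id <- character(n); s <- integer(n); e <- integer(n); v <- numeric(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    no <- linenos[i]
    if (length(f) < 4L) {
      stop("bedGraph parse error at line ", no, ": expected 4 fields",
           call. = FALSE)
    }
    s[i] <- suppressWarnings(as.integer(f[2L]))
    e[i] <- suppressWarnings(as.integer(f[3L]))
    v[i] <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(s[i]) || is.na(e[i]) || s[i] < 0L || e[i] <= s[i]) {
      stop("bedGraph parse error at line ", no, ": bad coordinates",
           call. = FALSE)
    }
    if (is.na(v[i]) || v[i] < 0) {
      stop("bedGraph parse error at line ", no,
           ": value must be a non-negative number", call. = FALSE)
    }
    seq_id[i] <- f[1L]
  }
  if (length(unique(seq_id)) != 1L) {
    stop("bedGraph file spans multiple sequences; one track per sequence ",
         "expected: ", path, call. = FALSE)
  }
  signal_track(seq_id[1L], s, e, v)
}

#' Write a signal track as bedGraph
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  d <- track$data
  writeLines(sprintf("%s\t%d\t%d\t%s", track$seq_id, d$start, d$end,
                     num_fmt(d$value)), path)
  invisible(path)
}

#' Per-base values of a signal track over a window
#'
#' @param track A `signal_track`.
#' @param from,to 0-based half-open window. Positions not covered by the
#'   track read as 0; their count is attached as attribute `n_uncovered`.
#' @return Numeric vector of length `to - from`.
#' @export
track_values <- function(track, from, to) {
  stopifnot(inherits(track, "signal_track"), to > from)
  from <- as.integer(from); to <- as.integer(to)
  v <- numeric(to - from)
  covered <- logical(to - from)
  d <- track$data
  hit <- which(d$end > from & d$start < to)
  for (i in hit) {
    a <- max(d$start[i], from); b <- min(d$end[i], to)
    idx <- (a - from + 1L):(b - from)
    v[idx] <- d$value[i]
    covered[idx] <- TRUE
  }
  attr(v, "n_uncovered") <- sum(!covered)
  v
}

## ---- BED12 spliced reads ---------------------------------------------------

#' Construct a spliced read
#'
#' An aligned read with one or more aligned segments (blocks) on a sequence;
#' the BED12 representation of a spliced alignment.
#'
#' @param seq_id Sequence name.
#' @param start,end 0-based half-open outer span.
#' @param name Read name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param block_starts,block_ends Absolute 0-based half-open block bounds;
#'   blocks must be non-empty, ascending, non-overlapping, the first starting
#'   at `start` and the last ending at `end`.
#' @param score Numeric score (0 by default).
#' @return An object of class `spliced_read`.
#' @export
spliced_read <- function(seq_id, start, end, name = ".", strand = ".",
                         block_starts = start, block_ends = end, score = 0) {
  start <- as.integer(start); end <- as.integer(end)
  bs <- as.integer(block_starts); be <- as.integer(block_ends)
  if (length(bs) != length(be) || length(bs) == 0L) {
    stop("blocks must be non-empty and paired", call. = FALSE)
  }
  if (any(be - bs <= 0L)) {
    stop("zero-length block in read '", name, "'", call. = FALSE)
  }
  if (is.unsorted(bs, strictly = TRUE) ||
      (length(bs) > 1L && any(bs[-1L] < be[-length(be)]))) {
    stop("blocks must be ascending and non-overlapping in read '", name, "'",
         call. = FALSE)
  }
  if (bs[1L] != start || be[length(be)] != end) {
    stop("blocks must cover read start and end in read '", name, "'",
         call. = FALSE)
  }
  structure(list(seq_id = seq_id, start = start, end = end, name = name,
                 score = score, strand = strand,
                 blocks = data.frame(start = bs, end = be)),
            class = "spliced_read")
}

#' Read spliced reads from a BED12 file
#' @param path BED12 file (blocks = aligned segments).
#' @return List of [spliced_read()] objects.
#' @export
read_bed12 <- function(path) {
  ln <- read_nonempty_lines(path)
  keep <- !startsWith(ln$lines, "#") & !startsWith(ln$lines, "track")
  lines <- ln$lines[keep]
  linenos <- ln$lineno[keep]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    no <- linenos[i]
    if (length(f) < 12L) {
      stop("BED12 parse error at line ", no, ": expected 12 fields",
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    score <- suppressWarnings(as.numeric(f[5L]))
    nblock <- suppressWarnings(as.integer(f[10L]))
    if (is.na(s) || is.na(e) || s < 0L || e <= s) {
      stop("BED12 parse error at line ", no, ": bad coordinates",
           call. = FALSE)
    }
    if (is.na(score)) {
      stop("BED12 parse error at line ", no, ": non-numeric score",
           call. = FALSE)
    }
    sizes <- suppressWarnings(as.integer(strsplit(sub(",$", "", f[11L]),
                                                  ",", fixed = TRUE)[[1L]]))
    offs <- suppressWarnings(as.integer(strsplit(sub(",$", "", f[12L]),
                                                 ",", fixed = TRUE)[[1L]]))
    if (is.na(nblock) || length(sizes) != nblock || length(offs) != nblock ||
        anyNA(sizes) || anyNA(offs)) {
      stop("BED12 parse error at line ", no, ": inconsistent block fields",
           call. = FALSE)
    }
    out[[i]] <- tryCatch(
      spliced_read(f[1L], s, e, name = f[4L], strand = f[6L],
                   block_starts = s + offs, block_ends = s + offs + sizes,
                   score = score),
      error = function(err) {
        stop("BED12 parse error at line ", no, ": ", conditionMessage(err),
             call. = FALSE)
      }
    )
  }
  out
}

#' Write spliced reads as BED12
#' @param reads List of `spliced_read` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path) {
  lines <- vapply(reads, function(r) {
    stopifnot(inherits(r, "spliced_read"))
    sizes <- r$blocks$end - r$blocks$start
    offs <- r$blocks$start - r$start
    sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            r$seq_id, r$start, r$end, r$name, num_fmt(r$score), r$strand,
            r$start, r$end, nrow(r$blocks),
            paste(sizes, collapse = ","), paste(offs, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- Expression matrix TSV -------------------------------------------------

#' Read an expression matrix (TSV, features x samples, TPM)
#'
#' First header field names the feature-id column; remaining header fields are
#' sample ids. Values must be non-negative numbers.
#'
#' @param path TSV file.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression_tsv <- function(path) {
  ln <- read_nonempty_lines(path)
  if (length(ln$lines) < 1L) stop("empty expression file: ", path,
                                  call. = FALSE)
  header <- strsplit(ln$lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("expression TSV parse error at line ", ln$lineno[1L],
         ": header must name at least one sample", call. = FALSE)
  }
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    stop("expression TSV parse error: duplicate sample ids", call. = FALSE)
  }
  body <- ln$lines[-1L]
  linenos <- ln$lineno[-1L]
  feat <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    no <- linenos[i]
    if (length(f) != length(header)) {
      stop("expression TSV parse error at line ", no, ": expected ",
           length(header), " fields, got ", length(f), call. = FALSE)
    }
    x <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(x)) {
      stop("expression TSV parse error at line ", no, ": non-numeric value",
           call. = FALSE)
    }
    if (any(x < 0)) {
      stop("expression TSV parse error at line ", no, ": negative TPM",
           call. = FALSE)
    }
    feat[i] <- f[1L]
    vals[i, ] <- x
  }
  if (anyDuplicated(feat)) {
    stop("expression TSV parse error: duplicate feature ids", call. = FALSE)
  }
  rownames(vals) <- feat
  colnames(vals) <- samples
  vals
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], num_fmt(mat[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}
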