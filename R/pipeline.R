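# End-to-end orchestration: simulate -> write/read all formats -> discover ->
# orient -> complementarity -> retention -> state -> correlate, from a single
# seeded configuration, with a machine-readable run report scoring every
# stage against the truth ledger.

#' Run the full analysis pipeline on synthetic data
#'
#' Stages run in dependency order; all randomness flows from the config's
#' root seed, so a given config is bit-reproducible. Every generated file is
#' written to `out_dir` and read back through the format readers before
#' analysis, so the run also exercises the I/O round trip.
#'
#' @param config A [sim_config()], a list of its arguments, or the path to a
#'   YAML file of them.
#' @param out_dir Output directory for generated files and the JSON report
#'   (created if needed).
#' @param min_identity,seed_len Homology-scan parameters.
#' @return An object of class `cne_run_report`: per-stage summaries and
#'   ledger-vs-result recovery scores in `[0, 1]`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cneduo_run_"),
                         min_identity = 0.75, seed_len = 7L) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_sim_config(config)
  } else if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), out_dir = out_dir, stages = list())

  ## stage: simulate ----------------------------------------------------------
  anc <- simulate_ancestral_cluster(config)
  sim <- simulate_wgd_and_divergence(anc, config)
  ledger <- sim$ledger
  paths <- list()
  for (sp in sim$species) {
    fa <- file.path(out_dir, paste0(sp, ".fa"))
    gff <- file.path(out_dir, paste0(sp, ".gff3"))
    write_fasta(sim$genomes[[sp]], fa)
    write_gff3(sim$annotations[[sp]], gff)
    paths[[sp]] <- list(fasta = fa, gff = gff)
  }
  ape::write.tree(sim$tree, file.path(out_dir, "species.nwk"))
  report$stages$simulate <- list(
    n_species = length(sim$species),
    cne_length = config$cne_length,
    n_planted_events = nrow(ledger$events)
  )

  ## stage: discover ----------------------------------------------------------
  query <- ledger$anc_cne
  hits_by_species <- list()
  n_expected <- 0L
  n_recovered <- 0L
  for (sp in sim$species) {
    genome <- read_fasta(paths[[sp]]$fasta)
    ann <- read_gff3(paths[[sp]]$gff)
    hits <- scan_homologs(query, genome, min_identity = min_identity,
                          seed_len = seed_len)
    if (nrow(hits) > 0L) {
      hits$cluster <- vapply(seq_len(nrow(hits)), function(i) {
        assign_synteny(hits[i, ], ann)
      }, character(1))
    }
    hits_by_species[[sp]] <- hits
    for (cl in c("C", "D")) {
      truth <- ledger$cne[[sp]][[cl]]
      if (is.null(truth)) next
      n_expected <- n_expected + 1L
      ok <- nrow(hits) > 0L && any(
        hits$cluster == cl & hits$seq_id == truth$seq_id &
          hits$start < truth$end & hits$end > truth$start
      )
      if (ok) n_recovered <- n_recovered + 1L
    }
  }
  matrix_pa <- build_presence_matrix(hits_by_species, sim$species)
  utils::write.table(
    data.frame(species = rownames(matrix_pa), matrix_pa, row.names = NULL),
    file.path(out_dir, "presence_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  discovery_recovery <- if (n_expected > 0L) n_recovered / n_expected else NA
  report$stages$discover <- list(
    n_hits = sum(vapply(hits_by_species, nrow, integer(1))),
    presence_matrix = matrix_pa,
    recovery = discovery_recovery
  )

  ## stage: orient + complementarity ------------------------------------------
  pairs <- list()
  orientation_correct <- 0L
  orientation_total <- 0L
  for (sp in sim$species) {
    truth <- sim$pairs[[sp]]
    if (is.null(truth)) next
    ann <- read_gff3(paths[[sp]]$gff)
    genome <- read_fasta(paths[[sp]]$fasta)
    h <- hits_by_species[[sp]]
    seqs <- list()
    prov <- list()
    for (cl in c("C", "D")) {
      hc <- h[h$cluster == cl, , drop = FALSE]
      if (nrow(hc) != 1L) {
        seqs <- NULL
        break
      }
      ori <- infer_orientation(hc[1L, ], ann)
      window <- substr(genome[[hc$seq_id]], hc$start + 1L, hc$end)
      seqs[[cl]] <- if (ori$strand == "-") revcomp(window) else window
      prov[[cl]] <- ori$provenance
      orientation_total <- orientation_total + 1L
      if (ori$strand == ledger$host_strand[[cl]]) {
        orientation_correct <- orientation_correct + 1L
      }
    }
    if (!is.null(seqs) && !grepl("N", paste0(seqs$C, seqs$D), fixed = TRUE)) {
      pairs[[sp]] <- oriented_pair(sp, seqs$C, seqs$D, prov$C, prov$D)
    }
  }
  scores <- vapply(pairs, function(p) complementarity_profile(p)$score,
                   numeric(1))
  comp_res <- if (length(pairs) == length(sim$tree$tip.label)) {
    detect_compensatory_events(pairs, sim$tree)
  } else NULL
  event_scores <- score_event_recovery(
    if (is.null(comp_res)) NULL else comp_res$calls, ledger$events
  )
  if (!is.null(comp_res)) {
    utils::write.table(comp_res$calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$stages$complementarity <- list(
    n_pairs = length(pairs),
    mean_score = if (length(scores)) mean(scores) else NA_real_,
    orientation_accuracy = if (orientation_total > 0L)
      orientation_correct / orientation_total else NA_real_,
    n_calls = if (is.null(comp_res)) NA_integer_ else nrow(comp_res$calls),
    event_precision = event_scores$precision,
    event_recall = event_scores$recall
  )

  ## stage: retention ----------------------------------------------------------
  sp1 <- sim$species[1L]
  ann1 <- read_gff3(paths[[sp1]]$gff)
  host <- Filter(function(m) grepl("cne_host_C", m$transcript_id), ann1)
  retention <- NULL
  if (length(host) == 1L) {
    libs <- simulate_intron_retained_reads(host[[1L]], config)
    counts <- list()
    for (lib in names(libs)) {
      bed <- file.path(out_dir, paste0(lib, ".bed12"))
      write_bed12(libs[[lib]], bed)
      counts[[lib]] <- count_library(read_bed12(bed), host[[1L]],
                                     library_id = lib)
    }
    retention <- summarize_retention(counts)
    est <- retention$per_library$intron_fraction[
      retention$per_library$library_id == "whole_cell"]
    report$stages$retention <- list(
      per_library = retention$per_library,
      compartment_log2_ratio = retention$compartment_log2_ratio,
      abs_error = abs(est - config$retention_fraction),
      recovery = 1 - min(1, abs(est - config$retention_fraction))
    )
  }

  ## stage: regulatory state ---------------------------------------------------
  element <- genomic_interval(paste0(sp1, "_C"), CNE_START,
                              CNE_START + config$cne_length, "-")
  state_results <- list()
  n_correct <- 0L
  spacing_measured <- NA_integer_
  for (st in c("closed", "poised", "active")) {
    cage <- simulate_cage_and_signals(element, st, config)
    ctss_path <- file.path(out_dir, paste0("ctss_", st, ".bed"))
    write_ctss_bed(cage$ctss, ctss_path)
    tracks <- list()
    for (mark in names(cage$tracks)) {
      bg <- file.path(out_dir, sprintf("%s_%s.bedGraph", mark, st))
      write_bedgraph(cage$tracks[[mark]], bg)
      tracks[[mark]] <- read_bedgraph(bg)
    }
    ctss <- if (file.size(ctss_path) > 0L) read_ctss_bed(ctss_path) else
      cage$ctss
    clusters <- cluster_ctss(ctss)
    bidir <- find_bidirectional_pairs(clusters, element)
    ev <- signal_features(tracks, element)
    call <- call_state(ev, bidir, overlaps_promoter = FALSE,
                       cell_type = st, element = element)
    expected <- switch(st, closed = "closed", poised = "poised_enhancer",
                       active = "active_enhancer")
    if (call$state == expected) n_correct <- n_correct + 1L
    if (st == "active" && nrow(bidir) > 0L) {
      spacing_measured <- bidir$spacing[1L]
    }
    state_results[[st]] <- call$state
  }
  report$stages$state <- list(
    calls = unlist(state_results),
    accuracy = n_correct / 3,
    spacing_measured = spacing_measured,
    spacing_planted = config$cage_spacing
  )

  ## stage: coexpression --------------------------------------------------------
  expr <- simulate_expression_matrix(config)
  expr_path <- file.path(out_dir, "expression.tsv")
  write_expression_tsv(expr$matrix, expr_path)
  mat <- read_expression_tsv(expr_path)
  genes <- names(config$couplings)
  tab <- cis_trans_table(mat, "CNE", genes,
                         threshold = config$expr_threshold)
  utils::write.table(tab, file.path(out_dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sign_ok <- vapply(genes, function(g) {
    r <- tab$r[tab$gene == g]
    !is.na(r) && sign(r) == sign(config$couplings[[g]])
  }, logical(1))
  groups <- group_cell_types(mat, "CNE", config$expr_threshold)
  report$stages$coexpression <- list(
    table = tab,
    sign_recovery = mean(sign_ok),
    n_expressing = length(groups$expressing),
    n_non_expressing = length(groups$non_expressing),
    partition_matches_ledger =
      setequal(groups$expressing, expr$ledger$expressing)
  )

  report$recovery <- list(
    discovery = discovery_recovery,
    orientation = report$stages$complementarity$orientation_accuracy,
    events_precision = event_scores$precision,
    events_recall = event_scores$recall,
    retention = if (is.null(retention)) NA_real_ else
      report$stages$retention$recovery,
    state = report$stages$state$accuracy,
    coexpression_sign = report$stages$coexpression$sign_recovery
  )
  class(report) <- "cne_run_report"
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

# Flatten a run report into JSON-friendly structures.
report_to_json <- function(report) {
  x <- unclass(report)
  x$stages$discover$presence_matrix <-
    as.data.frame(x$stages$discover$presence_matrix)
  x$config$couplings <- as.list(x$config$couplings)
  x
}

#' Score detected compensatory calls against the planted ledger
#'
#' A planted event is recovered when a call matches its branch, column pair
#' and class.
#'
#' @param calls Calls `data.frame` from [detect_compensatory_events()] (or
#'   `NULL`).
#' @param planted Ledger events `data.frame`.
#' @return List with `precision`, `recall`, `n_calls`, `n_planted`.
#' @export
score_event_recovery <- function(calls, planted) {
  # double substitutions with no complementarity transition (class NA:
  # non-complementary before and after) are outside the gain/retention/loss
  # taxonomy and are not scored
  planted <- planted[!is.na(planted$class), , drop = FALSE]
  n_planted <- nrow(planted)
  if (is.null(calls)) {
    return(list(precision = NA_real_, recall = NA_real_,
                n_calls = NA_integer_, n_planted = n_planted))
  }
  key <- function(df) paste(df$branch, df$c_col, df$d_col, df$class)
  hit <- key(calls) %in% key(planted)
  precision <- if (nrow(calls) > 0L) mean(hit) else
    if (n_planted == 0L) 1 else 0
  recall <- if (n_planted > 0L) mean(key(planted) %in% key(calls)) else 1
  list(precision = precision, recall = recall, n_calls = nrow(calls),
       n_planted = n_planted)
}

#' @export
print.cne_run_report <- function(x, ...) {
  cat("cneduo run report\n")
  cat(sprintf("  species: %d, planted events: %d\n",
              x$stages$simulate$n_species,
              x$stages$simulate$n_planted_events))
  r <- x$recovery
  cat(sprintf("  discovery recovery:   %s\n", format(r$discovery)))
  cat(sprintf("  orientation accuracy: %s\n", format(r$orientation)))
  cat(sprintf("  event precision/recall: %s / %s\n",
              format(r$events_precision), format(r$events_recall)))
  cat(sprintf("  retention recovery:   %s\n", format(r$retention)))
  cat(sprintf("  state-call accuracy:  %s\n", format(r$state)))
  cat(sprintf("  coexpression sign recovery: %s\n",
              format(r$coexpression_sign)))
  invisible(x)
}
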