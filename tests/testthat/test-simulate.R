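test_that("configs validate their invariants", {
  expect_error(sim_config(cne_length = 0), "cne_length")
  expect_error(sim_config(retention_fraction = 1.2), "retention_fraction")
  expect_error(sim_config(couplings = c(g = 1.5)), "coupling")
  expect_error(sim_config(cluster_length = 1000), "too short")
  expect_silent(cfg <- sim_config(seed = 1))
  expect_equal(cfg$cne_length, 32L)
  expect_equal(cfg$cage_spacing, 180L)
})

test_that("the ancestral cluster plants one CNE strictly between the genes", {
  cfg <- sim_config(seed = 101)
  anc <- simulate_ancestral_cluster(cfg)
  iv <- anc$ledger$cne_interval
  expect_equal(iv_width(iv), 32L)
  spans <- cneduo:::gene_spans(anc$models)
  g11 <- spans[spans$gene_id == "gene11", ]
  g12 <- spans[spans$gene_id == "gene12", ]
  expect_gte(iv$start, g11$end)
  expect_lte(iv$end, g12$start)
  expect_equal(nchar(anc$ledger$cne_seq), 32L)
})

test_that("same seed gives byte-identical generated files", {
  for (pass in 1:2) {
    cfg <- sim_config(seed = 102)
    anc <- simulate_ancestral_cluster(cfg)
    sim <- simulate_wgd_and_divergence(anc, cfg)
    fa <- file.path(tempdir(), sprintf("det_%d.fa", pass))
    write_fasta(sim$genomes$sp1, fa)
    libs <- simulate_intron_retained_reads(
      Filter(function(m) grepl("cne_host_C", m$transcript_id),
             sim$annotations$sp1)[[1]], cfg)
    bed <- file.path(tempdir(), sprintf("det_%d.bed12", pass))
    write_bed12(libs$nuclear, bed)
  }
  expect_identical(readLines(file.path(tempdir(), "det_1.fa")),
                   readLines(file.path(tempdir(), "det_2.fa")))
  expect_identical(readLines(file.path(tempdir(), "det_1.bed12")),
                   readLines(file.path(tempdir(), "det_2.bed12")))
})

test_that("zero-rate divergence preserves the ancestor and complementarity", {
  cfg <- sim_config(seed = 103, sub_rate = 0, n_compensatory_events = 0L)
  anc <- simulate_ancestral_cluster(cfg)
  sim <- simulate_wgd_and_divergence(anc, cfg)
  for (sp in sim$species) {
    c_cne <- substr(sim$genomes[[sp]][[paste0(sp, "_C")]], 1451, 1482)
    expect_equal(c_cne, anc$ledger$cne_seq)
    expect_equal(complementarity_profile(sim$pairs[[sp]])$score, 1)
  }
  expect_equal(nrow(sim$ledger$events), 0L)
})

test_that("every generated file parses back through the readers", {
  cfg <- sim_config(seed = 104, n_samples = 20L)
  anc <- simulate_ancestral_cluster(cfg)
  sim <- simulate_wgd_and_divergence(anc, cfg)
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fa"); gff <- file.path(td, "g.gff3")
  write_fasta(sim$genomes$sp2, fa)
  write_gff3(sim$annotations$sp2, gff)
  expect_identical(read_fasta(fa), sim$genomes$sp2)
  expect_equal(read_gff3(gff), sim$annotations$sp2)

  host <- Filter(function(m) grepl("cne_host_C", m$transcript_id),
                 sim$annotations$sp2)[[1]]
  cfg_small <- sim_config(seed = 104, read_depth = 200L)
  libs <- simulate_intron_retained_reads(host, cfg_small)
  bed <- file.path(td, "r.bed12")
  write_bed12(libs$whole_cell, bed)
  expect_equal(read_bed12(bed), libs$whole_cell)

  el <- genomic_interval("sp2_C", 1450L, 1482L, "-")
  cage <- simulate_cage_and_signals(el, "active", cfg)
  cb <- file.path(td, "c.bed"); bgf <- file.path(td, "t.bedGraph")
  write_ctss_bed(cage$ctss, cb)
  expect_identical(read_ctss_bed(cb), cage$ctss)
  write_bedgraph(cage$tracks$dhs, bgf)
  expect_equal(read_bedgraph(bgf), cage$tracks$dhs)

  expr <- simulate_expression_matrix(cfg)
  tsv <- file.path(td, "e.tsv")
  write_expression_tsv(round(expr$matrix, 4), tsv)
  expect_equal(read_expression_tsv(tsv), round(expr$matrix, 4))
})

test_that("the truth ledger is complete and consistent", {
  cfg <- sim_config(seed = 105, sub_rate = 0.01, n_compensatory_events = 3L)
  sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
  led <- sim$ledger
  planted <- led$events[led$events$origin == "planted", ]
  expect_equal(nrow(planted), 3L)
  expect_false(any(duplicated(planted[, c("branch", "c_col")])))
  expect_true(all(planted$d_col == cfg$cne_length + 1L - planted$c_col))
  expect_true(all(planted$class %in% c("gain", "retention", "loss")))
  for (sp in sim$species) {
    expect_equal(iv_width(led$cne[[sp]]$C), cfg$cne_length)
    expect_equal(iv_width(led$cne[[sp]]$D), cfg$cne_length)
  }
  expect_error(
    simulate_wgd_and_divergence(
      simulate_ancestral_cluster(sim_config(seed = 1, cne_length = 8L)),
      sim_config(seed = 1, cne_length = 8L, n_compensatory_events = 9L)
    ),
    "exceeds available columns"
  )
})

test_that("expression zeroing matches the configured fraction exactly", {
  cfg <- sim_config(seed = 106, n_samples = 50L, zero_fraction = 0.3)
  sim <- simulate_expression_matrix(cfg)
  expect_equal(sum(sim$matrix["CNE", ] == 0), 15L)
  expect_setequal(colnames(sim$matrix)[sim$matrix["CNE", ] == 0],
                  sim$ledger$zeroed)
  expect_true(all(sim$matrix["CNE", sim$ledger$expressing] >=
                    cfg$expr_threshold))
  expect_error(simulate_expression_matrix(sim_config(seed = 1,
                                                     n_samples = 5L)),
               "n_samples")
})
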