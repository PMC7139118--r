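test_that("read classification follows exon/intron/junction geometry", {
  m <- toy_model()  # exons [100,150) and [200,300), intron [150,200)
  expect_equal(classify_read(read1("chrT", 110L, 140L), m), "exon")
  expect_equal(classify_read(read1("chrT", 145L, 165L), m), "junction")
  expect_equal(classify_read(read1("chrT", 160L, 190L), m), "intron")
  # spliced read matching the model's junction is exonic
  spl <- read1("chrT", 140L, 210L, block_starts = c(140L, 200L),
               block_ends = c(150L, 210L))
  expect_equal(classify_read(spl, m), "exon")
  # any base outside the span is unassigned
  expect_equal(classify_read(read1("chrT", 90L, 120L), m), "unassigned")
  expect_equal(classify_read(read1("chrZ", 110L, 140L), m), "unassigned")
})

test_that("strand-matched mode filters opposite-strand reads", {
  m <- toy_model(strand = "+")
  r <- read1("chrT", 110L, 140L, strand = "-")
  expect_equal(classify_read(r, m), "exon")
  expect_equal(classify_read(r, m, stranded = TRUE), "unassigned")
})

test_that("counts conserve reads and summary fractions are exact arithmetic", {
  m <- toy_model()
  reads <- c(
    replicate(10, read1("chrT", 110L, 130L), simplify = FALSE),
    replicate(5, read1("chrT", 160L, 180L), simplify = FALSE),
    replicate(1, read1("chrT", 145L, 165L), simplify = FALSE),
    replicate(2, read1("chrT", 50L, 80L), simplify = FALSE)
  )
  cc <- count_library(reads, m, "lib")
  expect_equal(cc$exon + cc$intron + cc$junction + cc$unassigned, 18L)
  expect_equal(c(cc$exon, cc$intron, cc$junction, cc$unassigned),
               c(10L, 5L, 1L, 2L))
  s <- summarize_retention(list(cc))
  expect_equal(s$per_library$intron_fraction, 6 / 16)
  expect_equal(cc$intron_coverage$reads, 6L)
})

test_that("compartment ratio contrasts nuclear and cytosolic fractions", {
  mk <- function(lib, exon, intron) {
    structure(list(library_id = lib, exon = exon, intron = intron,
                   junction = 0L, unassigned = 0L,
                   n_reads = exon + intron,
                   intron_coverage = data.frame()),
              class = "read_class_counts")
  }
  s <- summarize_retention(list(mk("nuclear", 60L, 40L),
                                mk("cytosolic", 96L, 4L)))
  expect_equal(s$compartment_log2_ratio, log2(0.4 / 0.04), tolerance = 1e-12)
  expect_error(summarize_retention(list(mk("a", 0L, 0L))),
               "no transcript-overlapping reads")
})

test_that("simulated libraries recover the planted retention fraction", {
  cfg <- sim_config(seed = 71, retention_fraction = 0.4, read_depth = 10000L)
  sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
  host <- Filter(function(m) grepl("cne_host_C", m$transcript_id),
                 sim$annotations$sp1)[[1]]
  libs <- simulate_intron_retained_reads(host, cfg)
  expect_named(libs, c("whole_cell", "nuclear", "cytosolic"))
  counts <- lapply(names(libs), function(lib) {
    count_library(libs[[lib]], host, lib)
  })
  s <- summarize_retention(counts)
  pl <- s$per_library
  expect_true(all(pl$exon + pl$intron + pl$junction + pl$unassigned ==
                    10000L))
  wc <- pl$intron_fraction[pl$library_id == "whole_cell"]
  expect_lt(abs(wc - 0.4), 0.02)  # binomial 99% interval at depth 1e4
  nuc <- pl$intron_fraction[pl$library_id == "nuclear"]
  cyt <- pl$intron_fraction[pl$library_id == "cytosolic"]
  expect_gt(nuc, cyt)
})

test_that("zero retention gives zero intronic evidence in all libraries", {
  cfg <- sim_config(seed = 72, retention_fraction = 0, read_depth = 500L)
  sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
  host <- Filter(function(m) grepl("cne_host_C", m$transcript_id),
                 sim$annotations$sp1)[[1]]
  libs <- simulate_intron_retained_reads(host, cfg)
  for (lib in names(libs)) {
    cc <- count_library(libs[[lib]], host, lib)
    expect_equal(cc$intron, 0L)
    expect_equal(cc$junction, 0L)
  }
})

test_that("expected intron fraction increases with the planted fraction", {
  med <- vapply(c(0.1, 0.3, 0.5), function(rf) {
    ests <- vapply(1:5, function(r) {
      cfg <- sim_config(seed = 730 + r, retention_fraction = rf,
                        read_depth = 2000L)
      sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
      host <- Filter(function(m) grepl("cne_host_C", m$transcript_id),
                     sim$annotations$sp1)[[1]]
      libs <- simulate_intron_retained_reads(host, cfg)
      cc <- count_library(libs$whole_cell, host, "whole_cell")
      (cc$intron + cc$junction) / (cc$exon + cc$intron + cc$junction)
    }, numeric(1))
    median(ests)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("intronless transcripts are rejected by the read simulator", {
  m <- transcript_model("t", "g", genomic_interval("chrT", 100L, 300L, "+"),
                        list(genomic_interval("chrT", 100L, 300L, "+")),
                        "noncoding")
  expect_error(simulate_intron_retained_reads(m, sim_config(seed = 1)),
               "no intron")
})
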