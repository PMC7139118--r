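test_that("CTSS clustering follows the gap rule with leftmost-dominant ties", {
  one <- data.frame(seq_id = "chr1", pos = 100L, count = 5L, strand = "+")
  cl <- cluster_ctss(one)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$dominant, 100L)
  expect_equal(cl$total, 5L)

  two <- data.frame(seq_id = "chr1", pos = c(10L, 12L), count = c(5L, 3L),
                    strand = c("+", "+"))
  cl2 <- cluster_ctss(two, max_gap = 20L)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$dominant, 10L)
  expect_equal(cl2$total, 8L)

  far <- data.frame(seq_id = "chr1", pos = c(10L, 100L), count = c(5L, 3L),
                    strand = c("+", "+"))
  expect_equal(nrow(cluster_ctss(far, max_gap = 20L)), 2L)

  tie <- data.frame(seq_id = "chr1", pos = c(10L, 14L), count = c(4L, 4L),
                    strand = c("-", "-"))
  expect_equal(cluster_ctss(tie)$dominant, 10L)

  expect_equal(nrow(cluster_ctss(one[0, ])), 0L)
})

test_that("clustering is invariant to input record order", {
  set.seed(81)
  for (rep in 1:5) {
    ctss <- data.frame(
      seq_id = "chr1", pos = sample(0:500, 40),
      count = sample(1:30, 40, replace = TRUE),
      strand = sample(c("+", "-"), 40, replace = TRUE),
      stringsAsFactors = FALSE
    )
    a <- cluster_ctss(ctss)
    b <- cluster_ctss(ctss[sample(nrow(ctss)), ])
    expect_equal(a, b)
  }
})

test_that("bidirectional pairs require divergent geometry around the element", {
  el <- genomic_interval("chr1", 1000L, 1032L)
  cl <- data.frame(
    seq_id = "chr1", start = c(955L, 1070L), end = c(961L, 1076L),
    strand = c("-", "+"), dominant = c(960L, 1072L), total = c(30L, 28L),
    stringsAsFactors = FALSE
  )
  pr <- find_bidirectional_pairs(cl, el, window = 300L,
                                 spacing_band = c(100L, 250L))
  expect_equal(nrow(pr), 1L)
  expect_true(pr$divergent)
  expect_true(pr$nucleosome_scale)
  expect_equal(pr$spacing, 112L)

  # two plus-strand clusters cannot pair
  cl2 <- cl; cl2$strand <- c("+", "+")
  expect_equal(nrow(find_bidirectional_pairs(cl2, el)), 0L)
  # convergent geometry (plus left of minus) is rejected
  cl3 <- cl; cl3$strand <- c("+", "-")
  expect_equal(nrow(find_bidirectional_pairs(cl3, el)), 0L)
})

test_that("signal features behave on flat tracks", {
  el <- genomic_interval("chr1", 6000L, 6032L)
  flat0 <- signal_track("chr1", 0L, 12000L, 0)
  ev0 <- suppressWarnings(
    signal_features(list(dhs = flat0, h3k4me1 = flat0, h3k27ac = flat0,
                         h3k27me3 = flat0, p300 = flat0), el)
  )
  expect_equal(ev0$dhs_openness, 0)
  expect_false(ev0$h3k4me1_bimodal)
  expect_equal(ev0$h3k27ac_level, 0)

  flatc <- signal_track("chr1", 0L, 12000L, 3.7)
  evc <- signal_features(list(dhs = flatc), el)
  expect_equal(evc$dhs_openness, 1)
})

test_that("the decision ladder is strictly ordered", {
  base_ev <- list(dhs_openness = 5, h3k4me1_bimodal = TRUE,
                  h3k27ac_level = 5, h3k27me3_level = 5, p300_level = 3)
  no_pairs <- data.frame(divergent = logical())
  el <- genomic_interval("chr1", 100L, 132L)
  # promoter overlap dominates everything
  expect_equal(call_state(base_ev, no_pairs, overlaps_promoter = TRUE,
                          element = el)$state, "promoter_ambiguous")
  # closed chromatin beats marks
  ev_closed <- modifyList(base_ev, list(dhs_openness = 1))
  expect_equal(call_state(ev_closed, no_pairs, element = el)$state, "closed")
  # active (K27ac) outranks poised even with K27me3 high
  expect_equal(call_state(base_ev, no_pairs, element = el)$state,
               "active_enhancer")
  # divergent eRNA alone is sufficient for active
  ev_erna <- modifyList(base_ev, list(h3k27ac_level = 1,
                                      h3k27me3_level = 1,
                                      h3k4me1_bimodal = FALSE))
  pairs <- data.frame(divergent = TRUE)
  expect_equal(call_state(ev_erna, pairs, element = el)$state,
               "active_enhancer")
  # open + bimodal K4me1 + K27me3 = poised
  ev_poised <- modifyList(base_ev, list(h3k27ac_level = 1))
  expect_equal(call_state(ev_poised, no_pairs, element = el)$state,
               "poised_enhancer")
  # open but featureless falls back to closed with a note
  ev_none <- modifyList(base_ev, list(h3k27ac_level = 1, h3k27me3_level = 1,
                                      h3k4me1_bimodal = FALSE))
  call <- call_state(ev_none, no_pairs, element = el)
  expect_equal(call$state, "closed")
  expect_true(call$evidence$low_confidence)
  expect_error(call_state(list(dhs_openness = 1), no_pairs, element = el),
               "missing required evidence")
})

test_that("simulated chromatin states are called correctly without noise", {
  cfg <- sim_config(seed = 82, noise_level = 0)
  el <- genomic_interval("spX_C", 1450L, 1482L, "-")
  expected <- c(closed = "closed", poised = "poised_enhancer",
                active = "active_enhancer")
  for (st in names(expected)) {
    cage <- simulate_cage_and_signals(el, st, cfg)
    bidir <- find_bidirectional_pairs(cluster_ctss(cage$ctss), el)
    call <- call_state(signal_features(cage$tracks, el), bidir,
                       cell_type = st, element = el)
    expect_equal(call$state, unname(expected[st]))
    if (st == "closed") expect_equal(nrow(cage$ctss), 0L)
    if (st == "poised") {
      # broad repressive mark over the element with a depleted core
      k27 <- cage$tracks$h3k27me3
      center <- (el$start + el$end) %/% 2L
      broad <- mean(track_values(k27, el$start - 1000L, el$end + 1000L))
      baseline <- mean(track_values(k27, el$start - 4500L, el$start - 3500L))
      core <- mean(track_values(k27, el$start, el$end))
      expect_gt(broad, 5 * baseline)
      expect_lt(core, broad)
      expect_equal(nrow(cage$ctss), 0L)
    }
    if (st == "active") {
      expect_equal(nrow(bidir[bidir$nucleosome_scale, ]), 1L)
      expect_lte(abs(bidir$spacing[1L] - cfg$cage_spacing), 10L)
      expect_equal(bidir$spacing[1L], cage$truth$spacing)
    }
  }
  expect_error(simulate_cage_and_signals(el, "weird", cfg), "unknown state")
})

test_that("expressing/non-expressing grouping matches the threshold", {
  mat <- matrix(c(0, 0.5, 2, 7), nrow = 1,
                dimnames = list("HOTAIR", paste0("s", 1:4)))
  g <- group_cell_types(mat, "HOTAIR", threshold = 1)
  expect_equal(unname(g$sizes), c(2L, 2L))
  expect_setequal(g$expressing, c("s3", "s4"))

  zeros <- matrix(0, nrow = 1, ncol = 4,
                  dimnames = list("HOTAIR", paste0("s", 1:4)))
  expect_equal(unname(group_cell_types(zeros, "HOTAIR")$sizes["expressing"]),
               0L)
  expect_error(group_cell_types(mat, "nope"), "absent")
})

test_that("a planted 10 vs 19 expressing split is recovered from the matrix", {
  cfg <- sim_config(seed = 83, n_samples = 29L, zero_fraction = 19 / 29)
  sim <- simulate_expression_matrix(cfg)
  g <- group_cell_types(sim$matrix, "CNE", threshold = cfg$expr_threshold)
  expect_equal(unname(g$sizes), c(10L, 19L))
  expect_setequal(g$expressing, sim$ledger$expressing)
})
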