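test_that("identical leaves imply zero events and zero calls", {
  set.seed(61)
  s <- random_dna(12)
  d <- revcomp(s)
  pairs <- setNames(lapply(c("A", "B", "C", "D"), function(sp) {
    oriented_pair(sp, s, d)
  }), c("A", "B", "C", "D"))
  res <- detect_compensatory_events(pairs, "((A,B),(C,D));")
  expect_equal(nrow(res$events), 0L)
  expect_equal(nrow(res$calls), 0L)
  expect_false(res$multifurcating)
})

test_that("a cherry-specific paired double substitution yields one retention call", {
  # leaves A and B carry a complement-preserving double change at a paired
  # column; exhaustive enumeration confirms the single-change-per-side
  # minimum, and the call lands on the (A,B)-ancestor branch
  set.seed(62)
  L <- 10
  s <- random_dna(L)
  d <- revcomp(s)
  i <- 4L
  j <- L + 1L - i
  sv <- strsplit(s, "")[[1]]
  dv <- strsplit(d, "")[[1]]
  new <- setdiff(c("A", "C", "G", "T"), sv[i])[1]
  sv2 <- sv; sv2[i] <- new
  dv2 <- dv; dv2[j] <- chartr("ACGT", "TGCA", new)
  derived_c <- paste(sv2, collapse = "")
  derived_d <- paste(dv2, collapse = "")
  pairs <- list(A = oriented_pair("A", derived_c, derived_d),
                B = oriented_pair("B", derived_c, derived_d),
                C = oriented_pair("C", s, d),
                D = oriented_pair("D", s, d))
  tree <- "((A,B),(C,D));"
  # oracle: one change is the minimum for each side's changed column
  states_c <- setNames(c(sv2[i], sv2[i], sv[i], sv[i]),
                       c("A", "B", "C", "D"))
  expect_equal(exhaustive_min_changes(tree, states_c)$min, 1L)
  res <- detect_compensatory_events(pairs, tree)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$branch, "A|B")
  expect_equal(res$calls$c_col, i)
  expect_equal(res$calls$d_col, j)
  expect_equal(res$calls$class, "retention")
})

test_that("reconstruction is minimum-change and co-optimal on small trees", {
  skip_if_not_installed("phangorn")
  set.seed(63)
  trees <- c("((A,B),(C,D));", "(((A,B),C),(D,E));",
             "((((A,B),C),D),(E,F));", "((A,B),(C,D),E);")
  for (tr in trees) {
    phy <- ape::read.tree(text = tr)
    tips <- phy$tip.label
    for (rep in 1:12) {
      states <- setNames(sample(c("A", "C", "G", "T"), length(tips),
                                replace = TRUE), tips)
      rec <- fitch_reconstruct(phy, states)
      oracle <- exhaustive_min_changes(phy, states)
      expect_equal(rec$n_changes, oracle$min)
      # the chosen internal labeling must be among the co-optimal set
      internal <- rec$node_states[(length(tips) + 1):length(rec$node_states)]
      found <- any(apply(oracle$optimal_internal, 1, function(row) {
        all(row == internal)
      }))
      expect_true(found)
      # phangorn's Fitch score is an independent oracle for the minimum
      pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                    dimnames = list(tips, NULL)),
                             type = "DNA")
      expect_equal(rec$n_changes,
                   phangorn::parsimony(phy, pd, method = "fitch"))
    }
  }
})

test_that("multifurcating trees are handled and flagged", {
  set.seed(64)
  s <- random_dna(8)
  d <- revcomp(s)
  sv <- strsplit(s, "")[[1]]
  dv <- strsplit(d, "")[[1]]
  new <- setdiff(c("A", "C", "G", "T"), sv[2])[1]
  sv[2] <- new
  dv[7] <- chartr("ACGT", "TGCA", new)
  pairs <- list(A = oriented_pair("A", paste(sv, collapse = ""),
                                  paste(dv, collapse = "")),
                B = oriented_pair("B", s, d),
                C = oriented_pair("C", s, d),
                D = oriented_pair("D", s, d))
  res <- detect_compensatory_events(pairs, "(A,B,C,D);")
  expect_true(res$multifurcating)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$branch, "A")
})

test_that("a leaf without a pair is rejected", {
  set.seed(65)
  s <- random_dna(8)
  pairs <- list(A = oriented_pair("A", s, revcomp(s)))
  expect_error(detect_compensatory_events(pairs, "((A,B),(C,D));"),
               "leaf without")
})

test_that("planted events are recovered exactly at rate zero", {
  for (k in 1:3) {
    cfg <- sim_config(seed = 600 + k, sub_rate = 0,
                      n_compensatory_events = k)
    sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
    res <- detect_compensatory_events(sim$pairs, sim$tree)
    expect_equal(nrow(res$calls), k)
    key <- function(df) paste(df$branch, df$c_col, df$d_col, df$class)
    expect_setequal(key(res$calls), key(sim$ledger$events))
  }
})

test_that("gain events restore an ancestrally broken column", {
  cfg <- sim_config(seed = 66, sub_rate = 0, n_compensatory_events = 1L,
                    event_classes = "gain")
  sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
  expect_equal(sim$ledger$events$class, "gain")
  expect_equal(nrow(sim$ledger$ancestral_breaks), 1L)
  res <- detect_compensatory_events(sim$pairs, sim$tree)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$class, "gain")
  expect_equal(res$calls$branch, sim$ledger$events$branch)
})
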