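test_that("exact query copies are recovered with identity 1 on both strands", {
  set.seed(1)
  q <- random_dna(32)
  flank <- function(n) random_dna(n)
  g_plus <- paste0(flank(500), q, flank(468))
  h <- scan_homologs(q, c(chrA = g_plus))
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 500L)
  expect_equal(h$end, 532L)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1)
  expect_equal(h$matched_seq, q)

  g_minus <- paste0(flank(300), revcomp(q), flank(200))
  h2 <- scan_homologs(q, c(chrB = g_minus))
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 1)
  expect_equal(h2$matched_seq, q)
})

test_that("identity below threshold discards the planted site", {
  set.seed(2)
  q <- random_dna(32)
  qv <- strsplit(q, "")[[1]]
  pos <- sample(32, 12)
  for (i in pos) qv[i] <- setdiff(c("A", "C", "G", "T"), qv[i])[1]
  mut <- paste(qv, collapse = "")
  # direct count: 20 of 32 positions match = 0.625
  expect_equal(sum(strsplit(q, "")[[1]] == strsplit(mut, "")[[1]]), 20L)
  g <- paste0(random_dna(400), mut, random_dna(400))
  h <- scan_homologs(q, c(chr = g), min_identity = 0.8)
  expect_true(nrow(h) == 0L || all(h$start != 400L))
})

test_that("query validation and merging are deterministic", {
  expect_error(scan_homologs("ACGU", c(x = "ACGTACGTACGTACGT")), "A/C/G/T/N")
  # a periodic query matches overlapping windows; the merge keeps the
  # leftmost of the equal-identity candidates
  set.seed(3)
  q <- strrep("ACGT", 5)
  g <- paste0(random_dna(100), strrep("ACGT", 6), random_dna(100))
  h <- scan_homologs(q, c(chr = g), min_identity = 1, seed_len = 8)
  plus <- h[h$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 100L)
  expect_equal(plus$identity, 1)
})

test_that("seed-and-extend equals the brute-force all-window oracle", {
  # with at most 3 mismatches in a 32-mer, a run of >= 8 exact matches is
  # guaranteed (pigeonhole), so every above-threshold window is seeded and
  # the two scans must agree exactly
  set.seed(4)
  for (rep in 1:8) {
    q <- random_dna(32)
    mutate <- function(s, k) {
      v <- strsplit(s, "")[[1]]
      for (i in sample(length(v), k)) {
        v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
      }
      paste(v, collapse = "")
    }
    g1 <- paste0(random_dna(700), mutate(q, 3), random_dna(300),
                 revcomp(mutate(q, 2)), random_dna(500))
    g2 <- paste0(random_dna(400), mutate(q, 3), random_dna(250))
    genome <- c(c1 = g1, c2 = g2)
    mine <- scan_homologs(q, genome, min_identity = 0.75, seed_len = 8)
    oracle <- brute_force_scan(q, genome, min_identity = 0.75)
    expect_equal(mine[, c("seq_id", "start", "end", "strand", "identity")],
                 oracle)
  }
})

test_that("scanning is strand-symmetric", {
  set.seed(5)
  for (rep in 1:5) {
    q <- random_dna(24)
    core <- random_dna(300)
    h_fwd <- scan_homologs(q, c(chr = paste0(core, q, core)),
                           min_identity = 0.9, seed_len = 10)
    h_rev <- scan_homologs(q, c(chr = paste0(core, revcomp(q), core)),
                           min_identity = 0.9, seed_len = 10)
    expect_equal(nrow(h_fwd), nrow(h_rev))
    expect_equal(h_fwd$start, h_rev$start)
    expect_setequal(paste(h_fwd$strand, h_rev$strand),
                    c("+ -"))
  }
})

make_cluster_annotation <- function(seq_id, prefix) {
  gene <- function(gid, s, e) {
    transcript_model(paste0("t_", gid), gid,
                     genomic_interval(seq_id, s, e, "+"),
                     list(genomic_interval(seq_id, s, e, "+")), "coding")
  }
  list(gene(paste0(prefix, "c11"), 100L, 300L),
       gene(paste0(prefix, "c12"), 700L, 900L))
}

test_that("synteny assignment requires strictly-between placement", {
  ann <- make_cluster_annotation("chrC", "gene_")
  hit_between <- list(seq_id = "chrC", start = 400L, end = 432L)
  expect_equal(assign_synteny(hit_between, ann), "C")
  hit_inside <- list(seq_id = "chrC", start = 150L, end = 182L)
  expect_equal(assign_synteny(hit_inside, ann), "unassigned")
  hit_touching <- list(seq_id = "chrC", start = 290L, end = 322L)
  expect_equal(assign_synteny(hit_touching, ann), "unassigned")
  hit_elsewhere <- list(seq_id = "chrX", start = 400L, end = 432L)
  expect_equal(assign_synteny(hit_elsewhere, ann), "unassigned")
})

test_that("presence matrix reflects per-species cluster hits", {
  hits <- list(
    sp1 = data.frame(cluster = c("C", "D")),
    sp2 = data.frame(cluster = "D"),
    sp3 = data.frame(cluster = character())
  )
  m <- build_presence_matrix(hits, c("sp1", "sp2", "sp3", "sp4"),
                             no_assembly = "sp4")
  expect_equal(unname(m["sp1", ]), c("present", "present"))
  expect_equal(unname(m["sp2", ]), c("absent", "present"))
  expect_equal(unname(m["sp3", ]), c("absent", "absent"))
  expect_equal(unname(m["sp4", ]), c("no_assembly", "no_assembly"))
  expect_error(build_presence_matrix(hits, c("sp1", "sp2")), "not in species")
})

test_that("simulated C-copy loss yields an (absent, present) row", {
  cfg <- sim_config(seed = 61, sub_rate = 0, drop_c_in = "sp3")
  sim <- simulate_wgd_and_divergence(simulate_ancestral_cluster(cfg), cfg)
  hits_by_species <- lapply(sim$species, function(sp) {
    h <- scan_homologs(sim$ledger$anc_cne, sim$genomes[[sp]])
    if (nrow(h) > 0L) {
      h$cluster <- vapply(seq_len(nrow(h)), function(i) {
        assign_synteny(h[i, ], sim$annotations[[sp]])
      }, character(1))
    }
    h
  })
  names(hits_by_species) <- sim$species
  m <- build_presence_matrix(hits_by_species, sim$species)
  expect_equal(unname(m["sp3", ]), c("absent", "present"))
  expect_equal(unname(m["sp1", ]), c("present", "present"))
})
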