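# Seeded synthetic-data generator: emulates every input the analysis
# consumes (genomes, annotations, spliced reads, CAGE tags, chromatin signal
# tracks, expression matrices) with the statistical structure the method
# assumes, and records a ground-truth ledger so every downstream stage can be
# scored without consortium downloads.
#
# Fixed cluster layout (per cluster sequence, coordinates in bp):
#   gene11 [200, 700)+ ... CNE [1450, 1450+L) ... gene12 [2300, 2800)+
#   C-side host (intron-retained, strand -): exons [1150,1350) and
#     [1550+L, 1750+L); the CNE sits inside the single intron.
#   D-side host (promoter-overlapping, strand -): single exon
#     [1100, 1450+L+55); its TSS is the last base, so the CNE starts 55 nt
#     downstream of the dominant TSS in transcript coordinates.
# The D-copy CNE is planted as the reverse complement of the C-copy, so in
# host-transcript orientation the two copies are perfectly complementary at
# the root.

CNE_START <- 1450L
GENE11_SPAN <- c(200L, 700L)
GENE12_SPAN <- c(2300L, 2800L)
D_TSS_OFFSET <- 55L

#' Build a simulation configuration
#'
#' Validates and assembles the parameters of all generators. Defaults encode
#' the study conditions: a 32-nt element, nucleosome-scale (180 bp) divergent
#' CAGE spacing, an order-of-magnitude cytosolic depletion of intron
#' retention, and a cis-positive / trans-negative coupling panel.
#'
#' @param seed Integer root seed; every generator derives its stream from it.
#' @param cne_length Planted element length (>= 8).
#' @param n_species Number of extant species (used to build the default
#'   balanced tree when `tree` is `NULL`).
#' @param tree Newick text; defaults to a balanced (recursive bisection)
#'   tree over `sp1..spN`.
#' @param sub_rate Per-site substitution probability per branch
#'   (Jukes-Cantor).
#' @param n_compensatory_events Number of planted compensatory
#'   double-substitution events.
#' @param event_classes Optional character vector of classes (from
#'   `"retention"`, `"loss"`, `"gain"`) recycled over events; `NULL` samples
#'   from retention/loss.
#' @param retention_fraction Intron mass of the read-class multinomial in
#'   whole-cell and nuclear libraries (cytosolic gets a tenth of it).
#' @param junction_share Share of the intron mass emitted as
#'   junction-spanning (unspliced boundary) reads.
#' @param read_depth Reads per library.
#' @param read_length Read length (bp).
#' @param cage_spacing Planted distance (bp) between the dominant divergent
#'   TSSs flanking the element (nucleosome scale).
#' @param couplings Named numeric vector in `[-1, 1]`: per-gene coupling of
#'   log-expression to the latent element activity.
#' @param n_samples Samples in the expression matrix (>= 10).
#' @param zero_fraction Fraction of samples zeroed for the element feature
#'   (non-expressing cell types).
#' @param nc_fold Planted fold of the noncoding over the coding promoter
#'   transcript.
#' @param noise_level Chromatin-signal noise, as a fraction of each track's
#'   signal amplitude.
#' @param promoter_coupling Amplitude coupling of the host-promoter CTSS to
#'   the element CTSS.
#' @param expr_threshold TPM threshold defining expressing samples.
#' @param drop_c_in Species in which the C-cluster copy is lost
#'   (teleost-like lineage loss).
#' @param unannotated_hosts Species whose annotations omit the host
#'   transcripts, forcing orientation inference from the flank rule.
#' @param cluster_length Length of each cluster sequence (>= 2900).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, cne_length = 32L, n_species = 6L,
                       tree = NULL, sub_rate = 0.02,
                       n_compensatory_events = 2L, event_classes = NULL,
                       retention_fraction = 0.4, junction_share = 0.15,
                       read_depth = 10000L, read_length = 50L,
                       cage_spacing = 180L,
                       couplings = c(HOXC11 = 0.9, HOXC12 = 0.5,
                                     HOXD10 = -0.3, HOXD11 = -0.9),
                       n_samples = 200L, zero_fraction = 0.3, nc_fold = 3,
                       noise_level = 0.05, promoter_coupling = 0.8,
                       expr_threshold = 1, drop_c_in = character(),
                       unannotated_hosts = character(),
                       cluster_length = 3000L) {
  seed <- as.integer(seed)
  cne_length <- as.integer(cne_length)
  if (is.na(cne_length) || cne_length < 8L) {
    stop("cne_length must be an integer >= 8", call. = FALSE)
  }
  if (retention_fraction < 0 || retention_fraction > 1) {
    stop("retention_fraction must be in [0, 1]", call. = FALSE)
  }
  if (junction_share < 0 || junction_share > 1) {
    stop("junction_share must be in [0, 1]", call. = FALSE)
  }
  if (length(couplings) > 0 &&
      (is.null(names(couplings)) || any(!nzchar(names(couplings))))) {
    stop("couplings must be a named vector", call. = FALSE)
  }
  if (any(abs(couplings) > 1)) {
    stop("|coupling| must be <= 1", call. = FALSE)
  }
  if (zero_fraction < 0 || zero_fraction >= 1) {
    stop("zero_fraction must be in [0, 1)", call. = FALSE)
  }
  if (sub_rate < 0 || sub_rate > 0.75) {
    stop("sub_rate must be in [0, 0.75]", call. = FALSE)
  }
  if (!is.null(event_classes) &&
      !all(event_classes %in% c("retention", "loss", "gain"))) {
    stop("event_classes must be among retention/loss/gain", call. = FALSE)
  }
  if (is.null(tree)) {
    if (n_species < 2L) stop("n_species must be >= 2", call. = FALSE)
    tree <- balanced_tree(n_species)
  }
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) stop("tree is not valid Newick", call. = FALSE)
  cluster_length <- as.integer(cluster_length)
  if (cluster_length < 2900L || CNE_START + cne_length + 300L > GENE12_SPAN[1L]) {
    stop("cluster too short to host genes and CNE (need cluster_length >= ",
         "2900 and cne_length <= ", GENE12_SPAN[1L] - CNE_START - 300L, ")",
         call. = FALSE)
  }
  structure(list(
    seed = seed, cne_length = cne_length, n_species = length(phy$tip.label),
    tree = tree, sub_rate = sub_rate,
    n_compensatory_events = as.integer(n_compensatory_events),
    event_classes = event_classes, retention_fraction = retention_fraction,
    junction_share = junction_share, read_depth = as.integer(read_depth),
    read_length = as.integer(read_length),
    cage_spacing = as.integer(cage_spacing), couplings = couplings,
    n_samples = as.integer(n_samples), zero_fraction = zero_fraction,
    nc_fold = nc_fold, noise_level = noise_level,
    promoter_coupling = promoter_coupling, expr_threshold = expr_threshold,
    drop_c_in = drop_c_in, unannotated_hosts = unannotated_hosts,
    cluster_length = cluster_length
  ), class = "sim_config")
}

# Balanced Newick tree over sp1..spN (recursive bisection). A shallow
# balanced clade keeps root-to-leaf divergence moderate, as expected for a
# conserved element that remains recognisable across the clade.
balanced_tree <- function(n) {
  build <- function(lo, hi) {
    if (lo == hi) return(sprintf("sp%d", lo))
    mid <- (lo + hi) %/% 2L
    sprintf("(%s,%s)", build(lo, mid), build(mid + 1L, hi))
  }
  paste0(build(1L, n), ";")
}

#' Load a simulation configuration from a YAML file
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$couplings)) args$couplings <- unlist(args$couplings)
  do.call(sim_config, args)
}

# JC-style mutation: each position substituted with probability `rate`,
# uniformly to one of the other three bases.
mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  idx <- which(stats::runif(length(chars)) < rate)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

## ---- ancestral cluster -----------------------------------------------------

#' Simulate the ancestral cluster
#'
#' One random cluster sequence with two flanking genes and exactly one
#' planted CNE of `cne_length` strictly between them; flanking sequence
#' uniform over `A/C/G/T`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named sequence vector), `models` (transcript
#'   models of the two genes), and `ledger` (planted CNE interval and
#'   sequence).
#' @export
simulate_ancestral_cluster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$cne_length
  seq <- random_dna(config$cluster_length)
  cne_iv <- genomic_interval("ancestral_CD", CNE_START, CNE_START + L)
  models <- list(
    transcript_model("t_gene11", "gene11",
                     genomic_interval("ancestral_CD", GENE11_SPAN[1L],
                                      GENE11_SPAN[2L], "+"),
                     list(genomic_interval("ancestral_CD", GENE11_SPAN[1L],
                                           GENE11_SPAN[2L], "+")),
                     "coding"),
    transcript_model("t_gene12", "gene12",
                     genomic_interval("ancestral_CD", GENE12_SPAN[1L],
                                      GENE12_SPAN[2L], "+"),
                     list(genomic_interval("ancestral_CD", GENE12_SPAN[1L],
                                           GENE12_SPAN[2L], "+")),
                     "coding")
  )
  list(
    genome = c(ancestral_CD = seq),
    models = models,
    ledger = list(cne_interval = cne_iv,
                  cne_seq = substr(seq, CNE_START + 1L, CNE_START + L))
  )
}

## ---- WGD and divergence ----------------------------------------------------

# Annotation models for one species' C and D cluster sequences.
species_annotation <- function(sp, L, with_hosts = TRUE) {
  gene_tx <- function(seq_id, gid, span) {
    transcript_model(paste0("t_", gid), gid,
                     genomic_interval(seq_id, span[1L], span[2L], "+"),
                     list(genomic_interval(seq_id, span[1L], span[2L], "+")),
                     "coding")
  }
  cseq <- paste0(sp, "_C")
  dseq <- paste0(sp, "_D")
  models <- list(
    gene_tx(cseq, paste0(sp, "_gene_c11"), GENE11_SPAN),
    gene_tx(cseq, paste0(sp, "_gene_c12"), GENE12_SPAN),
    gene_tx(dseq, paste0(sp, "_gene_d11"), GENE11_SPAN),
    gene_tx(dseq, paste0(sp, "_gene_d12"), GENE12_SPAN)
  )
  if (with_hosts) {
    e2s <- 1550L + L
    models <- c(models, list(
      transcript_model(paste0(sp, "_cne_host_C"), paste0(sp, "_cne_host_C"),
                       genomic_interval(cseq, 1150L, 1750L + L, "-"),
                       list(genomic_interval(cseq, 1150L, 1350L, "-"),
                            genomic_interval(cseq, e2s, e2s + 200L, "-")),
                       "noncoding"),
      transcript_model(paste0(sp, "_nc_host_D"), paste0(sp, "_nc_host_D"),
                       genomic_interval(dseq, 1100L,
                                        CNE_START + L + D_TSS_OFFSET, "-"),
                       list(genomic_interval(dseq, 1100L,
                                             CNE_START + L + D_TSS_OFFSET,
                                             "-")),
                       "noncoding")
    ))
  }
  models
}

# Plan compensatory events: distinct minority-clade branches and distinct
# columns. A gain event requires a non-complementary state before the
# branch; it is enabled by planting the ancestral (root) pair
# non-complementary at that column, which every leaf outside the event's
# clade then supports.
plan_events <- function(ti, bids, n_events, classes, L) {
  ntip <- ti$ntip
  edge <- ti$tree$edge
  clade_size <- integer(nrow(edge))
  sizes <- integer(ntip + ti$nnode)
  sizes[seq_len(ntip)] <- 1L
  for (n in ti$post_internal) sizes[n] <- sum(sizes[ti$children[[n]]])
  for (i in seq_len(nrow(edge))) clade_size[i] <- sizes[edge[i, 2L]]
  max_minority <- max(1L, floor((ntip - 1L) / 2L))
  eligible <- which(clade_size <= max_minority)
  if (n_events > L) {
    stop("event count exceeds available columns (", L, ")", call. = FALSE)
  }
  if (n_events == 0L) {
    return(data.frame(edge = integer(), branch = character(),
                      c_col = integer(), class = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(eligible) < n_events) {
    stop("tree too small: only ", length(eligible),
         " minority-clade branches for ", n_events, " events",
         call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- sample(c("retention", "loss"), n_events, replace = TRUE)
  } else {
    classes <- rep_len(classes, n_events)
  }
  cols <- sample(seq_len(L), n_events)
  edges <- eligible[sample.int(length(eligible), n_events)]
  data.frame(edge = edges, branch = bids[edge[edges, 2L]], c_col = cols,
             class = classes, stringsAsFactors = FALSE)
}

#' Simulate whole-genome duplication and lineage divergence
#'
#' Each extant species carries a C-cluster and a D-cluster copy of the
#' ancestral cluster; the D-copy CNE is planted as the reverse complement of
#' the C-copy, so the two copies are perfectly complementary in
#' host-transcript orientation at the root. Substitutions are drawn per
#' branch at `sub_rate` per site (Jukes-Cantor); `n_compensatory_events`
#' double substitutions are placed on minority-clade branches at paired
#' columns and recorded in the ledger with their realised class (a `gain`
#' event's column is planted ancestrally non-complementary, recorded in the
#' ledger's `ancestral_breaks`).
#' Species in `drop_c_in` lose the C-copy CNE (teleost-like lineage loss).
#'
#' @param ancestor Output of [simulate_ancestral_cluster()].
#' @param config The same [sim_config()].
#' @return List with `species`, `genomes` (per species, named sequences
#'   `<sp>_C`, `<sp>_D`), `annotations` (per species, transcript models),
#'   `pairs` (per species [oriented_pair()] ground truth; `NULL` for
#'   C-dropped species), `tree` (`phylo`), and `ledger`.
#' @export
simulate_wgd_and_divergence <- function(ancestor, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  L <- config$cne_length
  tree <- ape::read.tree(text = config$tree)
  ti <- tree_index(tree)
  bids <- clade_ids(ti)
  anc_seq <- ancestor$genome[[1L]]
  anc_cne <- ancestor$ledger$cne_seq
  cne_from <- CNE_START + 1L
  cne_to <- CNE_START + L

  plan <- plan_events(ti, bids, config$n_compensatory_events,
                      config$event_classes, L)

  # transcript-oriented root states (hosts on the minus strand)
  root_state <- list(
    c_t = seq_chars(revcomp(anc_cne)),
    d_t = seq_chars(anc_cne),
    c_bg = seq_chars(anc_seq),
    d_bg = seq_chars(anc_seq)
  )
  # background sequences carry the CNE slot too; it is overwritten from the
  # transcript-oriented state at the leaves, so mask is irrelevant there.

  events_ledger <- list()
  ancestral_breaks <- list()
  # a planted gain requires the column to be non-complementary before the
  # event branch: break the ancestral pair at that column with a single
  # C-side change, supported by every lineage outside the event's clade
  for (k in which(plan$class == "gain")) {
    i <- plan$c_col[k]
    old <- root_state$c_t[i]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    root_state$c_t[i] <- new
    ancestral_breaks[[length(ancestral_breaks) + 1L]] <- data.frame(
      side = "C", column = i, from = old, to = new,
      stringsAsFactors = FALSE
    )
  }

  # Events are planted as net branch transitions: the ledger from-states are
  # the parent-node states (what a branch-level reconstruction sees), the
  # final states guarantee a change on BOTH sides, and the recipe adapts to
  # the parent complementarity state so the realised class is never
  # undefined (a retention/loss request on a noise-broken column becomes a
  # gain, and vice versa; the ledger records the realised class).
  apply_events <- function(state, parent_state, ei) {
    rows <- plan[plan$edge == ei, , drop = FALSE]
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(nrow(rows))) {
      i <- rows$c_col[k]
      j <- L + 1L - i
      cp <- parent_state$c_t[i]
      dp <- parent_state$d_t[j]
      before <- wc_pair(cp, dp)
      cls <- rows$class[k]
      if (!before) {
        # only a gain is realisable from a non-complementary column
        c_new <- sample(setdiff(bases, c(cp, comp_base(dp))), 1L)
        d_new <- comp_base(c_new)
      } else if (cls == "loss") {
        c_new <- sample(setdiff(bases, cp), 1L)
        d_new <- sample(setdiff(bases, c(dp, comp_base(c_new))), 1L)
      } else {
        # retention (also requested-gain on a still-complementary column)
        c_new <- sample(setdiff(bases, cp), 1L)
        d_new <- comp_base(c_new)
      }
      state$c_t[i] <- c_new
      state$d_t[j] <- d_new
      realised <- classify_call(before, wc_pair(c_new, d_new))
      events_ledger[[length(events_ledger) + 1L]] <<- data.frame(
        branch = bids[ti$tree$edge[ei, 2L]], c_col = i, d_col = j,
        class = realised, c_from = cp, c_to = c_new,
        d_from = dp, d_to = d_new, origin = "planted",
        stringsAsFactors = FALSE
      )
    }
    state
  }

  node_states <- vector("list", ti$ntip + ti$nnode)
  node_states[[ti$root]] <- root_state
  for (n in ti$pre_all) {
    if (n == ti$root) next
    ei <- which(ti$tree$edge[, 2L] == n)
    parent <- ti$tree$edge[ei, 1L]
    parent_state <- node_states[[parent]]
    st <- parent_state
    st$c_t <- mutate_chars(st$c_t, config$sub_rate)
    st$d_t <- mutate_chars(st$d_t, config$sub_rate)
    st$c_bg <- mutate_chars(st$c_bg, config$sub_rate)
    st$d_bg <- mutate_chars(st$d_bg, config$sub_rate)
    st <- apply_events(st, parent_state, ei)
    # the rate process can itself produce a double substitution at a paired
    # column; that is a true co-substitution event and belongs in the truth
    # ledger (origin "noise") even though it was not planted
    planted_cols <- plan$c_col[plan$edge == ei]
    for (i in seq_len(L)) {
      if (i %in% planted_cols) next
      j <- L + 1L - i
      if (st$c_t[i] != parent_state$c_t[i] &&
          st$d_t[j] != parent_state$d_t[j]) {
        events_ledger[[length(events_ledger) + 1L]] <- data.frame(
          branch = bids[ti$tree$edge[ei, 2L]], c_col = i, d_col = j,
          class = classify_call(
            wc_pair(parent_state$c_t[i], parent_state$d_t[j]),
            wc_pair(st$c_t[i], st$d_t[j])
          ),
          c_from = parent_state$c_t[i], c_to = st$c_t[i],
          d_from = parent_state$d_t[j], d_to = st$d_t[j],
          origin = "noise", stringsAsFactors = FALSE
        )
      }
    }
    node_states[[n]] <- st
  }

  species <- tree$tip.label
  genomes <- list()
  annotations <- list()
  pairs <- list()
  cne_ledger <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    st <- node_states[[i]]
    c_seq <- st$c_bg
    d_seq <- st$d_bg
    c_seq[cne_from:cne_to] <- seq_chars(revcomp(paste(st$c_t, collapse = "")))
    d_seq[cne_from:cne_to] <- seq_chars(revcomp(paste(st$d_t, collapse = "")))
    dropped <- sp %in% config$drop_c_in
    if (dropped) {
      c_seq[cne_from:cne_to] <- seq_chars(random_dna(L))
    }
    genomes[[sp]] <- stats::setNames(
      c(paste(c_seq, collapse = ""), paste(d_seq, collapse = "")),
      paste0(sp, c("_C", "_D"))
    )
    annotations[[sp]] <- species_annotation(
      sp, L, with_hosts = !sp %in% config$unannotated_hosts
    )
    pairs[[sp]] <- if (dropped) NULL else
      oriented_pair(sp, paste(st$c_t, collapse = ""),
                    paste(st$d_t, collapse = ""))
    cne_ledger[[sp]] <- list(
      C = if (dropped) NULL else
        genomic_interval(paste0(sp, "_C"), CNE_START, CNE_START + L, "-"),
      D = genomic_interval(paste0(sp, "_D"), CNE_START, CNE_START + L, "-")
    )
  }
  events <- if (length(events_ledger)) do.call(rbind, events_ledger) else
    data.frame(branch = character(), c_col = integer(), d_col = integer(),
               class = character(), c_from = character(),
               c_to = character(), d_from = character(),
               d_to = character(), origin = character(),
               stringsAsFactors = FALSE)
  breaks <- if (length(ancestral_breaks)) {
    do.call(rbind, ancestral_breaks)
  } else {
    data.frame(side = character(), column = integer(), from = character(),
               to = character(), stringsAsFactors = FALSE)
  }
  list(
    species = species, genomes = genomes, annotations = annotations,
    pairs = pairs, tree = tree,
    ledger = list(cne = cne_ledger, events = events,
                  ancestral_breaks = breaks, anc_cne = anc_cne,
                  drop_c_in = config$drop_c_in, tree = config$tree,
                  host_strand = c(C = "-", D = "-"))
  )
}

## ---- intron-retained reads -------------------------------------------------

#' Simulate spliced reads over an intron-retained transcript
#'
#' Three libraries (`whole_cell`, `nuclear`, `cytosolic`) of `read_depth`
#' reads each. Read classes follow a multinomial whose intron mass (pure
#' intronic plus junction-spanning reads) equals `retention_fraction` in the
#' whole-cell and nuclear libraries and `retention_fraction / 10` in the
#' cytosolic library; placement is uniform within the chosen class. Exonic
#' reads crossing a splice junction are emitted spliced (two blocks);
#' junction reads are contiguous blocks crossing an exon/intron boundary
#' with at least one base on each side.
#'
#' @param model An intron-containing [transcript_model()].
#' @param config A [sim_config()].
#' @return Named list (library -> list of [spliced_read()]).
#' @export
simulate_intron_retained_reads <- function(model, config) {
  stopifnot(inherits(model, "transcript_model"),
            inherits(config, "sim_config"))
  ivs <- introns(model)
  if (length(ivs) == 0L) {
    stop("transcript '", model$transcript_id, "' has no intron", call. = FALSE)
  }
  set.seed(config$seed + 2000L)
  rl <- config$read_length
  js <- config$junction_share
  masses <- c(whole_cell = config$retention_fraction,
              nuclear = config$retention_fraction,
              cytosolic = config$retention_fraction / 10)
  exon_w <- vapply(model$exons, iv_width, integer(1))
  W <- sum(exon_w)
  rl_ex <- min(rl, W)
  cum <- cumsum(c(0L, exon_w))
  # spliced-transcript coordinate -> genome blocks
  tx_to_blocks <- function(s, len) {
    bs <- integer(0); be <- integer(0)
    remaining <- len
    pos <- s
    while (remaining > 0L) {
      ex_i <- findInterval(pos, cum, rightmost.closed = FALSE)
      ex <- model$exons[[ex_i]]
      off <- pos - cum[ex_i]
      take <- min(remaining, exon_w[ex_i] - off)
      bs <- c(bs, ex$start + off)
      be <- c(be, ex$start + off + take)
      pos <- pos + take
      remaining <- remaining - take
    }
    list(bs = bs, be = be)
  }
  intron_positions <- do.call(rbind, lapply(ivs, function(iv) {
    w <- iv$end - iv$start
    rli <- min(rl, w)
    data.frame(start = iv$start, last = iv$end - rli, len = rli)
  }))
  boundaries <- unlist(lapply(ivs, function(iv) c(iv$start, iv$end)))
  out <- list()
  for (lib in names(masses)) {
    m <- masses[[lib]]
    p <- c(exon = 1 - m, intron = (1 - js) * m, junction = js * m)
    counts <- as.vector(stats::rmultinom(1L, config$read_depth, p))
    reads <- vector("list", config$read_depth)
    idx <- 1L
    mk <- function(bs, be, nm) {
      spliced_read(model$interval$seq_id, bs[1L], be[length(be)], name = nm,
                   strand = ".", block_starts = bs, block_ends = be)
    }
    if (counts[1L] > 0L) {
      starts <- sample.int(W - rl_ex + 1L, counts[1L], replace = TRUE) - 1L
      for (s in starts) {
        b <- tx_to_blocks(s, rl_ex)
        reads[[idx]] <- mk(b$bs, b$be, sprintf("%s_exon_%d", lib, idx))
        idx <- idx + 1L
      }
    }
    if (counts[2L] > 0L) {
      for (k in seq_len(counts[2L])) {
        ri <- sample.int(nrow(intron_positions), 1L)
        s <- intron_positions$start[ri] +
          sample.int(intron_positions$last[ri] - intron_positions$start[ri] +
                       1L, 1L) - 1L
        reads[[idx]] <- mk(s, s + intron_positions$len[ri],
                           sprintf("%s_intron_%d", lib, idx))
        idx <- idx + 1L
      }
    }
    if (counts[3L] > 0L) {
      for (k in seq_len(counts[3L])) {
        b <- sample(boundaries, 1L)
        o <- sample.int(rl - 1L, 1L)  # bases left of the boundary
        s <- max(model$interval$start, b - o)
        e <- min(model$interval$end, s + rl)
        reads[[idx]] <- mk(s, e, sprintf("%s_junction_%d", lib, idx))
        idx <- idx + 1L
      }
    }
    out[[lib]] <- reads[seq_len(idx - 1L)]
  }
  out
}

## ---- CAGE and chromatin signals --------------------------------------------

gauss_bump <- function(x, mu, sd) exp(-0.5 * ((x - mu) / sd)^2)

#' Simulate CAGE tags and chromatin signal tracks around an element
#'
#' Emits CTSS records and five signal tracks (`dhs`, `h3k4me1`, `h3k27ac`,
#' `h3k27me3`, `p300`) over element +/- 1.5 kb according to the planted
#' state:
#' \itemize{
#'   \item `active`: divergent CTSS clusters whose dominant positions flank
#'     the element separated by `cage_spacing` bp (small per-side jitter),
#'     open DHS, bimodal H3K4me1, high H3K27ac, p300 present; a host-promoter
#'     CTSS cluster 1.2 kb away with amplitude `promoter_coupling` times the
#'     element's.
#'   \item `poised`: open DHS, bimodal H3K4me1, broad H3K27me3 with a
#'     central dip at the element (nucleosome-depleted core), p300 present,
#'     no CTSS.
#'   \item `closed`: baseline noise only, no CTSS.
#' }
#'
#' @param element `genomic_interval` of the element.
#' @param state `"closed"`, `"poised"` or `"active"`.
#' @param config A [sim_config()].
#' @return List with `ctss` (CTSS `data.frame`), `tracks` (named list of
#'   [signal_track()]), and `truth` (planted state and TSS geometry).
#' @export
simulate_cage_and_signals <- function(element, state, config) {
  stopifnot(inherits(element, "genomic_interval"),
            inherits(config, "sim_config"))
  if (!state %in% c("closed", "poised", "active")) {
    stop("unknown state label '", state, "'", call. = FALSE)
  }
  set.seed(config$seed + 3000L)
  # window must cover the feature extractor's local-background span
  # (element +/- 10x flank at the default flank of 500 bp)
  ws <- max(0L, element$start - 5000L)
  we <- element$end + 5000L
  x <- ws:(we - 1L)
  center <- (element$start + element$end) %/% 2L
  b0 <- 0.2
  amp <- c(dhs = 8, h3k4me1 = 6, h3k27ac = 6, h3k27me3 = 5, p300 = 4)
  open <- state %in% c("poised", "active")
  shapes <- list(
    dhs = if (open) amp[["dhs"]] * gauss_bump(x, center, 200) else 0,
    h3k4me1 = if (open) {
      amp[["h3k4me1"]] * (gauss_bump(x, element$start - 250L, 80) +
                            gauss_bump(x, element$end + 250L, 80))
    } else 0,
    h3k27ac = if (state == "active") {
      amp[["h3k27ac"]] * (gauss_bump(x, element$start - 150L, 120) +
                            gauss_bump(x, element$end + 150L, 120))
    } else 0,
    h3k27me3 = if (state == "poised") {
      amp[["h3k27me3"]] * (abs(x - center) <= 1000) *
        (1 - 0.8 * gauss_bump(x, center, iv_width(element)))
    } else 0,
    p300 = if (open) amp[["p300"]] * gauss_bump(x, center, 150) else 0
  )
  tracks <- list()
  for (mark in names(shapes)) {
    v <- pmax(0, b0 + shapes[[mark]] +
                stats::rnorm(length(x), 0, config$noise_level * amp[[mark]]))
    tracks[[mark]] <- signal_track(element$seq_id, x, x + 1L, round(v, 4))
  }
  truth <- list(state = state, minus_tss = NA_integer_,
                plus_tss = NA_integer_, spacing = NA_integer_,
                element = element)
  ctss <- data.frame(seq_id = character(), pos = integer(),
                     count = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  if (state == "active") {
    jm <- sample(-2:2, 1L)
    jp <- sample(-2:2, 1L)
    m_pos <- center - config$cage_spacing %/% 2L + jm
    p_pos <- center + (config$cage_spacing - config$cage_spacing %/% 2L) + jp
    prom_pos <- center + 1200L
    ctss <- data.frame(
      seq_id = element$seq_id,
      pos = c(m_pos, m_pos - 3L, m_pos + 3L,
              p_pos, p_pos - 3L, p_pos + 3L,
              prom_pos, prom_pos + 2L),
      count = c(30L, 8L, 5L, 28L, 7L, 4L,
                as.integer(round(config$promoter_coupling * 30)),
                as.integer(round(config$promoter_coupling * 8))),
      strand = c("-", "-", "-", "+", "+", "+", "-", "-"),
      stringsAsFactors = FALSE
    )
    truth$minus_tss <- m_pos
    truth$plus_tss <- p_pos
    truth$spacing <- p_pos - m_pos
  }
  list(ctss = ctss, tracks = tracks, truth = truth)
}

## ---- expression matrix -----------------------------------------------------

#' Simulate an expression matrix with planted cis/trans couplings
#'
#' A latent element activity is drawn log-normal per sample; each target
#' gene's log expression is its coupling times the (centred) latent log
#' activity plus Gaussian noise, exponentiated to TPM. A `zero_fraction` of
#' samples is zeroed for the element feature (non-expressing cell types);
#' the remaining (expressing) samples draw the element TPM from the
#' left-truncated tail at `expr_threshold`, so the planted
#' expressing/non-expressing partition is exact. A noncoding promoter
#' feature `ncHOXD11` is planted at `nc_fold` times the `HOXD11` coding
#' feature when the latter is in the coupling panel.
#'
#' @param config A [sim_config()] with `n_samples >= 10`.
#' @return List with `matrix` (features x samples TPM) and `ledger`
#'   (couplings, zeroed and expressing sample ids, `nc_fold`).
#' @export
simulate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  if (n < 10L) stop("n_samples must be >= 10", call. = FALSE)
  if (any(abs(config$couplings) > 1)) {
    stop("|coupling| must be <= 1", call. = FALSE)
  }
  set.seed(config$seed + 4000L)
  samples <- sprintf("s%03d", seq_len(n))
  lz <- stats::rnorm(n, 2, 1)
  n_zero <- round(config$zero_fraction * n)
  zeroed <- if (n_zero > 0L) sort(sample.int(n, n_zero)) else integer(0)
  expressing <- setdiff(seq_len(n), zeroed)
  # expressing samples: left-truncate the latent at the expression threshold
  lthr <- log(config$expr_threshold)
  for (iter in 1:100) {
    low <- intersect(expressing, which(lz < lthr))
    if (length(low) == 0L) break
    lz[low] <- stats::rnorm(length(low), 2, 1)
  }
  lz[lz < lthr & seq_len(n) %in% expressing] <- lthr
  cne <- exp(lz)
  cne[zeroed] <- 0
  rows <- list(CNE = cne)
  for (g in names(config$couplings)) {
    lg <- 2 + config$couplings[[g]] * (lz - 2) + stats::rnorm(n, 0, 0.5)
    rows[[g]] <- exp(lg)
  }
  if ("HOXD11" %in% names(config$couplings)) {
    rows[["ncHOXD11"]] <- config$nc_fold * rows[["HOXD11"]] *
      exp(stats::rnorm(n, 0, 0.1))
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  colnames(mat) <- samples
  list(
    matrix = mat,
    ledger = list(couplings = config$couplings,
                  zeroed = samples[zeroed],
                  expressing = samples[expressing],
                  nc_fold = config$nc_fold,
                  expr_threshold = config$expr_threshold)
  )
}
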