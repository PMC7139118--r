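# cneduo

Analysis of a duplicated conserved noncoding element (CNE) shared by two
paralogous, syntenic gene clusters — the situation of the ~32-nt element
with one copy inside the *HOTAIR* lncRNA (HoxC cluster) and a paralogous
copy near the *HOXD11* noncoding promoter, both left behind by the second
round of whole-genome duplication.

The package is aimed at comparative and regulatory genomicists who want to
test, on their own loci or on fully synthetic data, the chain of inference
such a pair supports:

1. **Discovery** — ungapped seed-and-extend homology scanning of both
   genome strands (`scan_homologs()`), synteny assignment between the
   flanking paralog genes (`assign_synteny()`), and the cross-species
   presence/absence matrix (`build_presence_matrix()`).
2. **Complementarity** — with both copies written 5'→3' in host-transcript
   orientation, column *i* of one copy pairs with column *L*+1−*i* of the
   other (antiparallel hybridisation); `complementarity_profile()` scores
   the fraction of Watson–Crick-paired columns, equivalently
   `matches(seq_c, revcomp(seq_d)) / L`.
3. **Compensatory substitutions** — Fitch parsimony ancestral
   reconstruction per column on a species tree; a compensatory call is a
   branch carrying substitutions on both sides at a paired column pair,
   classed as gain / retention / loss of complementarity
   (`detect_compensatory_events()`). Reconstruction ambiguity is resolved
   in favour of co-substitution, strictly among equally-parsimonious
   labelings (unit-cost Sankoff feasibility).
4. **Intron retention** — exon / intron / junction classification of
   spliced reads against a transcript model, retention fraction
   (intron+junction over assigned) and the nuclear/cytosolic log2
   enrichment (`classify_read()`, `summarize_retention()`).
5. **Enhancer state** — CAGE tag clustering, divergent enhancer-RNA pair
   detection at nucleosome-scale spacing (100–250 bp band), chromatin
   features (DHS openness, H3K4me1 bimodality, H3K27ac/H3K27me3/p300
   levels) and a deterministic decision ladder over
   closed / poised_enhancer / active_enhancer / promoter_ambiguous
   (`cluster_ctss()`, `find_bidirectional_pairs()`, `call_state()`).
6. **Cis/trans co-expression** — correlations on co-expressed sample
   subsets with BH adjustment (`cis_trans_table()`), and noncoding/coding
   promoter usage ratios (`promoter_ratio()`).

A seeded synthetic-data generator (`sim_config()`, `simulate_*()`) emulates
every input — genomes with the planted duplicated element, annotations,
spliced reads, CTSS tags, chromatin signal tracks, expression matrices —
and records a ground-truth ledger, so each stage is scored by recovery of
planted structure. `run_pipeline()` runs the whole arc from one (YAML)
config. File formats: FASTA, GFF3, BED6 (CTSS), BED12 (spliced reads),
bedGraph and TSV expression matrices, all through line-level readers and
writers with round-trip guarantees.

## Worked example

```r
library(cneduo)
cfg <- sim_config(seed = 7)                      # 6 species, 32-nt element
anc <- simulate_ancestral_cluster(cfg)
sim <- simulate_wgd_and_divergence(anc, cfg)

hits <- scan_homologs(anc$ledger$cne_seq, sim$genomes$sp1)
hits$cluster <- vapply(seq_len(nrow(hits)), function(i)
  assign_synteny(hits[i, ], sim$annotations$sp1), character(1))
hits
#>   seq_id start  end strand identity                      matched_seq cluster
#> 1  sp1_C  1450 1482      +  0.90625 CGTCAGTGTACAACAGGGAAGACATACTGGCG       C
#> 2  sp1_D  1450 1482      -  0.96875 CGTCAGTGTAGAACTGGGAAGGAATACTGGCG       D
```

Both copies are found between the clusters' gene11/gene12 pairs: one per
cluster, the D-side copy on the opposite strand (the inverted syntenic
arrangement). Their identities reflect the lineage divergence drawn at 0.02
substitutions/site/branch.

```r
complementarity_profile(sim$pairs$sp1)$score
#> [1] 0.875

detect_compensatory_events(sim$pairs, sim$tree)$calls
#>   branch c_col d_col     class c_from c_to d_from d_to relabelled
#> 1    sp5     5    28 retention      A    C      T    G      FALSE
#> 2    sp6    17    16 retention      C    A      G    T      FALSE
```

28 of 32 columns are still complementary after divergence, and the two
planted compensatory double substitutions are recovered on their branches
with the right column pairs and classes (column 5 pairs with column
32+1−5 = 28).

```r
report <- run_pipeline(
  system.file("extdata", "demo_config.yaml", package = "cneduo"))
print(report)
#> cneduo run report
#>   species: 6, planted events: 2
#>   discovery recovery:   1
#>   orientation accuracy: 1
#>   event precision/recall: 1 / 1
#>   retention recovery:   0.9934
#>   state-call accuracy:  1
#>   coexpression sign recovery: 1
```

The report scores every stage against the ledger: all planted copies
discovered and oriented, both events recovered, the planted retention
fraction (0.4) estimated within 0.007, the three planted chromatin states
(closed / poised / active) called correctly, and all four planted coupling
signs (+0.9, +0.5, −0.3, −0.9) recovered from the expression matrix.

## Documentation

The methods vignette (`vignettes/cne-paralog-analysis.Rmd`) describes the
models and conventions in detail: coordinate and orientation conventions,
the scan's seed-length sensitivity argument, the parsimony
ambiguity-resolution rule, the state-call decision ladder and its
thresholds, exactly what the synthetic generator does and does not emulate,
and known limitations.
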