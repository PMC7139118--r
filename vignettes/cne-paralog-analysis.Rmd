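---
title: "Analysing a duplicated conserved noncoding element: methods and models"
author: "cneduo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a duplicated conserved noncoding element: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cneduo)
```

## The problem

Whole-genome duplication (WGD) at the base of the vertebrates left paralogous
gene clusters — HoxC and HoxD among them — that can retain duplicated copies
of short conserved noncoding elements (CNEs). `cneduo` implements the
analysis arc for one such case: a ~32-nt element with one copy inside a
lncRNA locus (HOTAIR-like, between the cluster's 11th and 12th genes) and a
paralogous copy in the syntenic position of the sister cluster, embedded in a
noncoding transcript near a coding gene's promoter. The interesting
properties of such a pair are:

* **paralogy by synteny** — both copies sit strictly between the 11th and
  12th paralog genes of their clusters;
* **orientation-aware complementarity** — written 5'→3' in their
  host-transcript orientations, the two copies base-pair antiparallel,
  suggesting RNA–RNA hybridisation in *trans*;
* **compensatory evolution** — substitutions at paired columns co-occur on
  the same lineage, preserving (or switching) the pairing state;
* **transcription of the element** — intron retention embeds the element in
  a mature transcript; bidirectional CAGE tags at nucleosome-scale spacing
  mark it as an active enhancer RNA in expressing cells, while
  H3K4me1/H3K27me3/p300 mark it as a poised enhancer in stem cells;
* **cis/trans co-expression** — element expression correlates positively
  with same-cluster genes and negatively with the paralogous locus.

The consortium datasets behind the original observations (FANTOM5, GTEx,
ENCODE, Roadmap) are not reproducible at desk scale, so the package pairs
every analysis stage with a seeded synthetic-data generator and a
ground-truth ledger; all quantitative claims the test suite and acceptance
script make are recoveries of planted structure.

## Coordinate and orientation conventions

All internal coordinates are 0-based half-open (BED convention); GFF3's
1-based inclusive coordinates are converted at the boundary in both
directions. Unknown strand (`.`) is accepted only for non-transcribed
features (reads, signal windows).

Complementarity is evaluated between two sequences each written 5'→3' in
its host-transcript orientation. Because two 5'→3' RNAs hybridise
antiparallel, column *i* (1-based) of the C-side sequence pairs with column
*L* + 1 − *i* of the D-side sequence; a column is complementary when the
bases Watson–Crick pair (A:T, C:G at the DNA level). G·T wobble is excluded
by default — the pairing state is treated as a discrete two-colour property —
and can be enabled with `allow_wobble = TRUE`.

## Homology scan

`scan_homologs()` is an ungapped seed-and-extend scan of both genome
strands: exact seeds of length `seed_len` at any query offset anchor
candidate windows, each extended to the full query length and scored as
`identity = matches / L`. Overlapping same-strand hits merge to the
maximal-identity (tie: leftmost) hit. Gapped alignment is deliberately out
of scope: the element is short and its cross-species alignment is
fixed-width.

`seed_len` defaults to 7, the word-size convention for short queries. The
choice matters: a 32-nt window at the 0.75 identity floor can carry 8
mismatches, and by pigeonhole its longest exact run may be as short as 3 —
a 12-mer seed silently discards windows the identity threshold accepts. With
seed 7 the scan recovers essentially every above-threshold window; residual
misses in the simulations are copies that have genuinely drifted below the
identity floor.

Synteny assignment (`assign_synteny()`) labels a hit `C` or `D` only when it
lies strictly between the spans of the cluster's two flanking genes — no
overlap with either span — mirroring the intergenic placement that defines
the element. `build_presence_matrix()` assembles the per-species
presence/absence matrix, with `no_assembly` rows for species without
genomes.

## Orientation inference

Where an annotated transcript overlaps a hit, its strand is authoritative
(`provenance = "annotated"`). Otherwise `infer_orientation()` applies a
flank rule — antisense to the cluster's `gene11`-patterned gene — and
reports `provenance = "inferred"` so downstream users can filter to
annotated-only evidence. The flank rule is a modelling choice: it encodes
the observed arrangement (the lncRNA host runs antisense to the neighbouring
coding genes) and is the package's stand-in for transcript-model evidence
that real analyses would look up per species.

## Compensatory-substitution detection

For every column of each side, ancestral states are reconstructed by Fitch
parsimony on the species tree (`fitch_reconstruct()`), with deterministic
tie resolution: internal-node ties resolve toward the parent state, the root
tie toward the majority leaf state, residual ties alphabetically.
Multifurcating trees use the generalised (state-count) Fitch rule and are
flagged. A substitution event is a branch whose child state differs from its
parent state; a compensatory call is a branch carrying events on both sides
at an antiparallel-paired column pair, classed by the pairing state before
versus after the branch: **gain** (unpaired → paired), **retention** (paired
→ paired through a double change), **loss** (paired → unpaired).

Two well-known properties of parsimony shape the implementation:

1. *The reconstruction is rarely unique.* The Fitch first-pass state sets do
   not contain every state that appears in some most-parsimonious labeling,
   so the deterministic labeling can scatter a genuine co-substitution
   across adjacent branches, or assign parent states under which the
   double change has no defined class. `detect_compensatory_events()`
   therefore resolves reconstruction ambiguity *in favour of the
   compensatory pattern, never at the expense of parsimony*: unit-cost
   Sankoff tables provide, per column, the exact set of edges that can carry
   a change in at least one minimum-change labeling; when one side's event
   cannot be paired but an equally-parsimonious labeling of the other side
   co-locates its event on the same branch, that labeling is adopted, and
   when a paired change has an undefined class, an equally-parsimonious
   choice of edge states with a defined class is preferred. Every
   adjustment is verified to preserve the minimum change count and is
   flagged (`relabelled`) in the output.
2. *Events adjacent to the root cannot be polarised from leaves alone.* The
   same mechanism resolves this case deterministically, co-locating the
   pair on one root-child edge.

The rationale for this preference is the biological hypothesis under test:
if paired columns co-evolve, reconstructions exhibiting co-substitution are
the parsimonious explanations of interest, and breaking ties away from them
would build the null hypothesis into the reconstruction.

## Intron retention

`classify_read()` places each spliced read (BED12 blocks) into `exon`
(every aligned base exonic), `intron` (every base intronic), `junction`
(bases on both sides of an exon/intron boundary in one model) or
`unassigned` (any base outside the transcript span). Classification is
unstranded by default, matching unstranded total-RNA libraries; a
strand-matched mode exists. The retention fraction is
(intron + junction) / (exon + intron + junction): junction reads are direct
evidence of unspliced molecules, and the raw class counts are always kept
alongside. The nuclear/cytosolic contrast is summarised as
log2(nuclear fraction / cytosolic fraction), defined only when the
cytosolic fraction is positive.

## Enhancer-state calling

`cluster_ctss()` groups CAGE transcription start site tags per strand by
single linkage with a 20 bp default gap, the common tag-cluster convention;
the cluster's dominant position is its highest-count base (tie: leftmost).
`find_bidirectional_pairs()` enumerates divergent (−, +) cluster pairs whose
dominant positions flank (or overlap) the element within a 300 bp window;
spacing is the distance between dominant positions and is flagged
`nucleosome_scale` inside the default band of 100–250 bp (147 bp core
nucleosome plus linker).

`signal_features()` reduces each bedGraph track to: core mean (over the
element), flank means (±500 bp by default), and a level defined as the
element-region mean over the local background (the mean over element ±10×
flank, excluding element ± flank). DHS openness is core over background;
H3K4me1 bimodality requires both flanks to reach 1.5× the core mean and to
be positive. Uncovered positions read as zero and are counted in the
evidence (`n_uncovered`) with a warning.

`call_state()` is a strictly ordered, deterministic ladder: (1) declared
promoter overlap → `promoter_ambiguous` (chromatin signals cannot separate
an enhancer from an overlapping promoter, which is exactly the situation of
the D-side copy in the ncRNA promoter); (2) DHS openness < 2 → `closed`;
(3) open with high H3K27ac or ≥1 divergent pair → `active_enhancer`
(bidirectional CAGE is the decisive active hallmark, so active outranks
poised); (4) open, H3K4me1-bimodal and H3K27me3-high → `poised_enhancer`;
(5) otherwise `closed` with a low-confidence note. The numeric thresholds
(openness 2.0, mark high 2.0× background, bimodal ratio 1.5, expressing at
TPM ≥ 1) are documented defaults, not claims about any consortium's
cutoffs.

## Co-expression

`correlate_features()` defaults to Pearson correlation on log2(TPM + 1)
("pearson-log"), with Spearman as the alternative; the estimator used by the
original analyses is not recorded, so both are first-class and the
acceptance checks exercise the default. `cis_trans_table()` computes one row
per candidate gene on the co-expressed subset (both features ≥ 1 TPM, the
same threshold as the expressing/non-expressing grouping),
Benjamini–Hochberg-adjusts across the table, and keeps raw p-values
alongside q-values. `promoter_ratio()` reports per-sample
log2((nc + 0.5)/(coding + 0.5)) — the 0.5 pseudocount keeps zero-TPM samples
defined — with the median and a two-sided sign test.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every generator derives its
random stream from the one root seed, so outputs are byte-reproducible.

**Genomes and evolution.** One ancestral ~3 kb cluster carries two coding
genes and the planted element (32 nt by default) strictly between them. WGD
is emulated by giving each extant species a C- and a D-cluster copy; the
D-copy element is planted as the reverse complement of the C-copy, making
the pair perfectly complementary in host-transcript orientation at the
root. Lineages then diverge by Jukes–Cantor substitutions at a per-branch,
per-site rate (0.02 by default) on a balanced tree over `n_species`
(default 6); a balanced, shallow topology keeps root-to-leaf divergence
moderate, which is the defining property of a *conserved* element — on deep
pectinate trees at higher rates the element drifts below the identity
threshold, emulating lineage-specific loss of detectability rather than
recovery (the `drop_c_in` option emulates outright copy loss, as in the
teleost lineage). The C-side host is an intron-retained two-exon antisense
transcript whose intron contains the element; the D-side host is a
single-exon antisense transcript whose dominant TSS lies 55 nt upstream of
the element in transcript coordinates, so the element overlaps the
promoter.

**Compensatory events.** Planted events are net branch transitions: on a
minority-clade branch (so the root polarisation is well-posed) both paired
columns change between the parent node and the child, with recipes chosen
so the realised class (recorded in the ledger) is always defined — a
retention/loss request on a column that noise has already unpaired becomes
a gain, and vice versa. Gains are enabled by planting the ancestral pair
non-complementary at that column, which every outgroup lineage supports.
The rate process itself occasionally produces a genuine double substitution
at a paired column; such events are recorded in the ledger with
`origin = "noise"` so that detector scoring counts them as the true
positives they are. Double changes with no defined class transition
(unpaired before and after) fall outside the gain/retention/loss taxonomy
and are excluded from scoring.

**Reads.** Three libraries (whole-cell, nuclear, cytosolic) of 10⁴ reads by
default. Read classes follow a multinomial whose intronic mass (pure
intronic + junction reads, split 85/15) equals the retention fraction in
whole-cell and nuclear libraries and a tenth of it in the cytosolic library
— the order-of-magnitude depletion is a modelling choice standing in for
"depleted"; placement is uniform within class, and exonic reads crossing
the splice junction are emitted spliced.

**CAGE and chromatin.** Signal tracks cover element ± 5 kb (so the feature
extractor's background span is fully covered) at a 0.2 RPM baseline with
Gaussian noise scaled to each track's amplitude (5% default, 20% in the
robustness checks). Active: divergent CTSS clusters whose dominant
positions are 180 bp apart (± ≤2 bp jitter per side), open DHS, H3K27ac,
bimodal H3K4me1, p300, plus a host-promoter CTSS cluster scaled by the
promoter coupling. Poised: open DHS, bimodal H3K4me1 (flanking bumps ±250 bp
from the element edges, giving a genuine central dip at the
nucleosome-depleted core), broad H3K27me3 over ±1 kb with a central dip,
p300, no CTSS. Closed: baseline only, no CTSS.

**Expression.** A log-normal latent element activity per sample drives each
target gene's log expression through its coupling (defaults +0.9, +0.5,
−0.3, −0.9 for a cis-positive/trans-negative panel) plus Gaussian noise
(SD 0.5 on the natural-log scale); a configurable fraction of samples
(default 0.3) is zeroed for the element feature to represent non-expressing
cell types, and expressing samples draw from the latent distribution
left-truncated at the expression threshold so the planted partition is
exact. The noncoding promoter feature is planted at `nc_fold` (default 3)
times its coding partner with small log-noise.

**What the generator does not emulate.** Indels and alignment uncertainty;
read errors and mapping ambiguity; realistic chromatin-state emission
distributions (ChromHMM-like); batch effects, library-size variation and
compositional artefacts in expression; selection acting on the element
(divergence is neutral drift at the configured rate). Passing tests
therefore demonstrate that the implementations recover planted structure
under the stated noise models — not that the defaults match any particular
consortium dataset.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at sizes chosen to make the
statistical properties sharp: discovery recovery on 50 shallow 4-species
clades at 0.05 substitutions/site/branch (the scale of the worked examples;
see above for why deep clades are a different, unscored regime);
compensatory precision/recall on 100 six-species replicates at 0.02;
retention at read depth 10⁴ against the binomial 99% interval; state calls
on 100 replicates at 20% amplitude noise; null-correlation calibration on
500–1,000 replicates at 200 samples. The end-to-end demo configuration
(`inst/extdata/demo_config.yaml`) completes in well under five minutes on
one CPU.

## A short tour

```{r tour, eval = FALSE}
library(cneduo)
report <- run_pipeline(
  system.file("extdata", "demo_config.yaml", package = "cneduo"),
  out_dir = "cneduo_demo"
)
print(report)
report$stages$discover$presence_matrix
report$stages$coexpression$table
```

## Known limitations

* The homology scan is ungapped; an indel in the element would shift the
  fixed-width alignment and suppress downstream column pairing.
* Fitch parsimony (even with the co-location rule) cannot polarise
  root-adjacent events or separate equally-parsimonious class assignments;
  calls carry a `relabelled` flag so such cases can be audited.
* Classification against one designated transcript model ignores isoform
  mixtures; isoform-aware quantification is out of scope.
* The enhancer-state thresholds are sensible defaults, not calibrated to
  any reference epigenome; `promoter_ambiguous` is driven by annotation,
  never inferred from signal.
* Correlation on co-expressed subsets conditions on expression, which can
  attenuate or inflate associations relative to the full panel; both raw
  and adjusted p-values are reported.
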