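---
title: "Quantifying early partner choice by strain-level metabarcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early partner choice by strain-level metabarcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epcquant)
library(dplyr)
```

## The problem

When a legume root is exposed to a community of compatible rhizobia, the
strains that actually occupy its nodules are a strongly non-random sample of
the inoculum: the plant and the bacteria together perform an *early partner
choice* (EPC). `epcquant` implements a complete analysis chain for measuring
this phenotype with a natural DNA barcode: a fixed-length variable fragment
of a symbiosis gene (in the motivating system, a 309-bp fragment of *nodD*
carried on the symbiosis plasmid) amplified from whole nodulated root
systems after inoculation with a mixed community of barcode-distinguishable
strains.

The package covers five stages:

1. **Barcode design** (`scan_windows()`, `select_barcode()`,
   `build_reference()`, `select_core_collection()`): choose the window of a
   marker-gene alignment that maximizes the number of distinct alleles
   between conserved primer sites, and assemble a strain collection with
   unique barcodes.
2. **Exact-match quantification** (`merge_pairs()`, `demultiplex()`,
   `trim_primers()`, `dereplicate()`, `flag_chimeras()`, `assign_exact()`,
   `tabulate_counts()`, or the `quantify_reads()` wrapper): paired reads are
   merged, demultiplexed by exact 5' tag, primer-trimmed, dereplicated with
   expected-error tracking, and counted only when **strictly identical** to a
   reference allele.
3. **The EPC index** (`compute_epc()`, `summarize_replicates()`,
   `filter_undetected()`, `cluster_profiles()`): a strain's EPC index in a
   sample is its percentage of all assigned barcode reads; condition-level
   values are means over biological replicates with CV% as the reliability
   measure.
4. **Association genetics** (`kruskal_wallis()`, `dunn_posthoc()`,
   `pool_species()`, `contrast_genes()`, `validate_candidates()`,
   `check_presence()`, `bidirectional_best_hits()`): nonparametric tests of
   EPC against strain classifications, and a top-*k* versus bottom-*k*
   presence/absence screen for candidate genes.
5. **Genome context** (`pairwise_ani()`, `assign_genospecies()`,
   `p_distance()`, `nj_tree()`, `assign_nod_groups()`,
   `classify_replicon()`): fragment-based average nucleotide identity with
   genospecies clustering at 95%, neighbor joining over concatenated
   nodulation genes, and repABC-based plasmid replicon classes.

A first-class synthetic-data module (`simulate_panel()`,
`simulate_pangenome()`, `simulate_host_propensities()`, `simulate_reads()`,
`simulate_study()`) generates every input with full ground truth, so the
whole chain is testable end to end without any external download.

## The exact-match quantification model

The pipeline deliberately avoids denoising: a read contributes to a strain's
count only if, after merging and trimming, it is string-equal to that
strain's reference allele. Sequencing errors therefore *discard* reads
rather than reassigning them. Because substitution errors strike all strains
at the same per-base rate and all alleles have the same length, the
surviving reads remain an unbiased multinomial sample of the amplicon pool —
the EPC index is a ratio estimator whose accuracy depends only on the
*assigned* depth, not the raw depth. At 0.5% per-base error and a 309-bp
allele roughly 40% of merged read pairs survive strict matching, which at
~1.4 × 10^4 read pairs per sample still leaves thousands of informative
reads.

Processing choices worth knowing:

* **Merging** scans every ungapped offset of the forward read against the
  reverse complement of the reverse read, scoring +1/−2, and accepts the
  best offset with overlap ≥ `min_overlap` (default 16) and mismatch
  fraction ≤ 0.25. Indels are not modeled: amplicons of a fixed locus are
  indel-free by construction. Posterior qualities use
  `min(Q1 + Q2, 41)` at agreements and `|Q1 − Q2|` (keeping the higher-Q
  base) at conflicts. This is a contract-level merger, not a bit-for-bit
  reproduction of any external tool.
* **Demultiplexing** requires a full-length, zero-mismatch match of the 5'
  sample tag (6 bp by default in the simulator).
* **Primer trimming** anchors the forward primer at the 5' end and the
  reverse-complemented reverse primer at the 3' end; each may be truncated
  at a read boundary down to 2/3 of its length, with a 10% per-alignment
  mismatch budget. Both primers must be found.
* **Expected error** is `sum(10^(-Q/10))`; dereplication tracks the minimum
  EE per unique sequence. EE is reported for QC, not used to filter, because
  strict identity already removes error-bearing reads.
* **Chimera flagging** is a minimal two-parent single-crossover test (each
  parent ≥ 2× more abundant, hybrid model ≥ 2 mismatches better than any
  single parent). It only flags: counting never uses the flag, matching a
  workflow in which chimera checking was a negative QC.

## The EPC index and its statistics

For sample *j* with assigned counts `n_sj`, `EPC[s, j] = 100 n_sj / Σ_s
n_sj`. Condition-level indexes are means over the (default four) biological
replicate *percentages*, not pooled counts — under unequal depth the two
differ, and the mean-of-replicates convention treats each replicate as one
biological observation. CV% is `100 · sd/mean` with the sample (n−1) sd; the
package leaves CV missing when the mean is 0. A strain is dropped only when
it has zero reads in *every* sample — a deliberately permissive detection
rule, so rare-but-real strains stay in the analysis.

Host and strain profiles are clustered with agglomerative hierarchical
clustering (Euclidean distance, complete linkage by default — the classical
heatmap defaults); rows and columns are label-sorted before clustering so
results are order-invariant.

## Association tests

`kruskal_wallis()` computes the tie-corrected H statistic,

`H = [12/(N(N+1)) Σ n_i (R̄_i − (N+1)/2)²] / [1 − Σ(t³−t)/(N³−N)]`,

with a chi-square p on k−1 df, and an exact permutation p (full enumeration
of group-label assignments) for small samples — `stats::kruskal.test` serves
as an independent cross-check in the test suite. `dunn_posthoc()` implements
the rank-based pairwise z test with the standard tie term and Bonferroni
correction, plus a compact letter display built by greedy insert–absorb over
median-sorted groups (two groups share a letter iff not significantly
different). No installed package provides the Dunn test, hence the in-house
implementation.

Species-level pooling stacks each strain × cultivar mean EPC as one
observation. This preserves pseudo-replication deliberately: the per-level n
values reported alongside make the convention explicit and reproducible.

### The gene contrast

`contrast_genes()` screens for genes present in **all** of the top-*k*
strains and absent in **all** of the bottom-*k* (or the reverse), with
k = 5 by default and 4 supported, and optional restriction to a strain
subset (e.g. only nodX carriers). Candidates are then validated with a
Kruskal-Wallis test of EPC between carriers and non-carriers over all
detected strains (`validate_candidates()`).

Presence/absence itself is decided by `check_presence()`: the best
`local_align()` hit must **strictly exceed** 70% nucleotide identity and 70%
query coverage. `local_align()` is an ungapped seed-and-extend aligner
(exact 11-mer seeds, x-drop 20, +1/−2 scoring) written for this package; it
is a contract-level engine for the thresholding decision, not a
score-compatible replacement for a full local aligner, and the acceptance
checks use the simulator's truth matrix rather than parity with any external
tool.

## Genome-context classification

`pairwise_ani()` follows the classical fragment recipe: 1020-bp consecutive
fragments of genome A, each locally aligned to genome B, retained when the
hit has identity > 30% over ≥ 70% of the fragment; one-way ANI is the mean
retained identity and the reported value averages both directions.
Genospecies are single-linkage connected components at ANI ≥ 95, with
strains below 92 to everything else flagged as outside the species complex.
The recipe is not bit-compatible with any specific ANI program; the 95%
boundary is the conventional species threshold.

Nodulation-gene phylogeny uses p-distances (gaps pairwise-deleted) and
`ape::nj()`. Because the groupings of interest were historically drawn on a
tree without numeric criteria, `assign_nod_groups()` makes them explicit as
two nested single-linkage cuts (defaults: 0.10 for the coarse "Nod type",
0.03 for the fine "Nod group" — configuration, not dogma; published labels
can always be supplied as metadata instead). Replicon (Rh) classes require a
repA best hit above a similarity floor *and* cognate repB and repC presence
on the same replicon.

## What the simulator emulates — and what it does not

`simulate_study()` defaults encode the design this package models: 9 host
genotypes × 4 biological replicates, a 32-strain panel with one 2-strain
barcode collision (31 distinct alleles), 14 203 read pairs per sample,
2 × 250 bp reads over a 6-bp tag + 20-bp primers + 309-bp allele molecule,
and 0.5% per-base substitution error.

* **Host effects** are multiplicative: each planted gene multiplies the
  propensity of its carrier strains by `effect_size` (default 10) in its
  host; per-replicate proportions are Dirichlet draws around the host truth
  with total concentration 100. The motivating study never models EPC
  generatively; this is the simplest composable model that reproduces its
  qualitative structure (host clustering, gene-EPC associations).
* **Quality/error model** is two-state: each base is low-quality (Q12) with
  the mixing probability that makes the marginal per-base error rate equal
  the requested rate, high-quality (Q38) otherwise, and errors are i.i.d.
  substitutions at the state's nominal rate. This is enough to exercise
  expected-error logic; it is *not* an instrument error profile. Indels, PCR
  bias, chimeras (off by default) and read-length heterogeneity are not
  modeled — so passing tests say nothing about indel robustness on real
  data.
* **Pangenome spectrum**: null accessory genes are either "cloud" (carried
  by ≤ 4 of 32 strains) or "core" (≥ 29), mimicking the U-shaped gene
  frequency spectrum of bacterial pangenomes with a sparse mid-frequency
  shell. In this regime a null gene cannot perfectly separate a top-5 from a
  bottom-5 set, so ground truth for the contrast screen is unambiguous; a
  beta-distributed shell mode (`spectrum = "shell"`) is available for
  studying coincidental candidates. Planted genes are carried by exactly 5
  strains by default.
* **Genospecies/replicon scaffolding**: genomes are a genospecies-structured
  backbone (0.5% within, 6% between clusters, from a 20-kb root by default)
  plus carried genes plus a repABC cassette; repA variants differ ~15%
  between replicon groups.

## Numerical and scale choices

Tests and the acceptance script run the full study design (36 samples ×
14 203 read pairs ≈ 5.1 × 10^5 pairs) through the complete chain in about
2–3 minutes on one CPU; statistical suites use 2 000 null simulations for
the type-I error of the Kruskal-Wallis test and 50 replicate simulations for
planted-gene recovery; ANI and NJ checks use 5–6 kb genomes and 4–12-taxon
trees. Recovery of EPC from simulated reads is judged against the *realized*
per-replicate mixture proportions, standardized by the multinomial standard
error at the assigned depth (`epc_recovery_deviations()`): under a correct
pipeline these z values are approximately standard normal, and the
acceptance band is |z| ≤ 4.

Degenerate inputs are handled explicitly: all-zero samples yield missing EPC
columns with a warning; conditions with no usable replicate raise an error;
ties in window selection resolve leftmost; ties in best-hit scoring resolve
by label order; clustering sorts labels before linkage so input order never
matters.

## Known limitations

* Multiple sequence alignment is out of scope — `scan_windows()` and
  `p_distance()` require pre-aligned input.
* The merger, aligner and chimera test are contract-level implementations:
  they honor the documented decision rules but are not bit-compatible with
  external read-merging, local-alignment or chimera-detection tools.
* Strict exact matching cannot distinguish strains sharing a barcode allele;
  collision groups are quantified as a unit. In the gene contrast a group
  counts as carrying a gene only when every member does (and as lacking it
  only when none does); groups with discordant members are ambiguous and can
  never be candidates, so barcode collisions reduce power rather than
  producing false candidates.
* Species-level pooling inherits pseudo-replication from its convention;
  treat the pooled p-values as descriptive, as the per-level n values make
  plain.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(hosts = c("H1", "H2", "H3"), n_strains = 12,
                        depth = 3000, seed = 1)
q <- quantify_reads(study$reads$reads, study$sample_sheet, study$reference)
summ <- summarize_replicates(compute_epc(q$counts), study$sample_sheet)
glance(summ)
autoplot(cluster_profiles(summ))

ranked <- rank_strains(summ, "H1", q$counts)
contrast_genes(ranked, study$pangenome, k_top = 5, k_bottom = 5)
```
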