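---
title: "Building pseudomolecules from a SNP linkage map: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building pseudomolecules from a SNP linkage map: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A draft plant genome typically arrives as tens of thousands of scaffolds.
When a dense SNP linkage map is available for the same species, the markers
mapped onto the scaffolds let us (i) place scaffolds on chromosomes, (ii)
discover mis-assembled *chimeric* scaffolds whose markers point at two
different genomic locations, (iii) orient scaffolds by comparing physical and
genetic marker order, and (iv) concatenate the ordered, oriented scaffolds
into chromosome-scale *pseudomolecules*. `mapanchor` implements this
procedure as composable tibble-in/tibble-out functions, together with the
summary statistics that accompany a draft genome report (N50, GC%, core-gene
completeness percentages, k-mer genome-size estimation) and the standard
comparative-genomics computations downstream of such an assembly
(reciprocal-best-hit orthologue pairing, synteny dot plots, Nei–Gojobori Ks,
calibrated divergence times).

## The anchoring model

**Bins.** Markers that co-segregate sit at the same genetic position. Map
software reports this as identical printed cM values, so `build_bins()`
groups markers by linkage group and cM rounded to `cm_precision` decimals
(default 2, the usual output precision; it is configurable because different
map programs print differently).

**Anchoring.** A scaffold with at least `min_markers` mapped markers
(default 1) is assigned the linkage group carrying most of its markers, and
the map position is the mean of its markers' bin cM — a bin with more
markers weighs proportionally more.

**Chimera detection.** Walking a scaffold's markers in physical order, a
split is triggered between adjacent markers that (a) belong to different
linkage groups (`multi_lg`), or (b) sit more than `max_intra_lg_gap_cm`
(default 20 cM) apart on the same group (`intra_lg_gap`). The breakpoint is
the floor midpoint of the two flanking markers' bp positions: with no
further information about where the mis-join lies, the midpoint is the
unbiased deterministic choice. Contiguous marker runs on one side form one
piece; pieces are named `<scaffold>.1`, `.2`, … and tile the original
sequence exactly, so no base is gained or lost.

**Orientation.** The sign of the Kendall rank correlation between physical
position and bin cM gives the strand. Rank correlation rather than strict
monotonicity tolerates a single noisy marker. With fewer than two distinct
physical or genetic positions, or a tied correlation, the orientation is
undetermined: the scaffold is kept on its original strand and flagged
`ambiguous_orientation`, which mirrors the implicit default of leaving
sequence untouched unless the map demands otherwise. Unoriented scaffolds
are still placed at their map position.

**Ordering and construction.** Within a linkage group scaffolds sort by map
position; ties break by descending length, then id, so the order is a pure
function of the anchor set. Pseudomolecules (`chr1..chrK` in map order) are
the oriented scaffolds joined with a fixed gap of 10,000 N — the
conventional constant-gap encoding when mate-pair evidence for true gap
sizes is absent. Scaffolds without markers form the unplaced pool and are
reported, not concatenated. AGP rows are emitted in lockstep with the
sequence; `reconstruct_from_agp()` inverts the construction and is tested to
be byte-exact.

Internally all coordinates are 0-based half-open; every file format (AGP,
placements) is 1-based inclusive, converted only at the I/O boundary so
off-by-one drift has a single place to happen (and be tested).

## Assembly statistics

N50 uses the descending cumulative-sum convention: the length at which the
running total first reaches half the assembly. GC% excludes N and ambiguity
codes from the denominator — a heavily gapped pseudomolecule should report
base composition, not gap content; reported percentages round half-up to one
decimal. Completeness percentages (`completeness_percent()`) consume an
externally produced found/total tally (e.g. a CEGMA-style core-gene count);
running such tools is out of scope.

The k-mer genome-size estimator takes a depth histogram and finds the first
local minimum at depth ≥ `min_depth` (the error/signal valley), takes the
modal depth beyond it as the coverage peak, and returns
`sum(depth x count) / peak` over post-valley depths. If the histogram rises
immediately there is no error spike and the valley is forced just below
`min_depth`. A monotonically decreasing histogram has no coverage peak and
is a hard error. Note a sampling subtlety used by the tests: at integer mean
coverage λ the Poisson pmf has tied modes at λ−1 and λ, so recovery tests
use non-integer λ where the mode is `floor(λ)`.

## Comparative computations

Reciprocal best hits filter both hit tables at E ≤ 1e-10, pick each query's
best subject by bit score (ties: E-value, identity, then id), and keep pairs
agreeing in both directions.

`ng86_ks()` implements the Nei–Gojobori (1986) counting method: synonymous
site fractions per codon from the standard genetic code (changes producing
stop codons count as nonsynonymous, so sites always total 3 per codon — a
conservation property the tests enforce against independent enumeration of
all 61 x 61 sense-codon pairs), difference counts averaged over all
orderings of single-step mutational pathways with stop-crossing pathways
excluded, and the Jukes–Cantor correction `-(3/4)ln(1 - (4/3)p)` applied to
pS and pN. `Ks` is flagged undefined (not an error) when `pS ≥ 3/4`. NG86
was chosen because it is the canonical fully specified counting estimator;
model-rich Ks tools differ mainly beyond the divergence range where the Ks
histograms here are read.

`calibrate_times()` converts branch lengths to ages under a uniform-rate
assumption: a node's height is its mean path length to descendant tips, all
heights are scaled so the calibration MRCA sits at the given age (114.0 MYA
is the conventional Arabidopsis–Medicago split used for legume trees), and
ages are finally clipped child-to-parent so they decrease tipward even on
non-ultrametric inputs. Doubling all branch lengths leaves ages unchanged.

## The synthetic-data generator

`simulate_genome()` emulates the structure of a real anchoring input set at
desk scale: 8 chromosomes of 2 Mb with i.i.d. bases at GC 0.33, a strictly
monotone linear map of 3.8 cM/Mb (the genome-wide rate implied by a
~2,000 cM map on a ~550 Mb genome), 100 markers/Mb, fragmentation at uniform
random breakpoints with 50 kb mean pieces, 10% of scaffolds inverted and 5%
fused into cross-chromosome chimeras, with optional same-chromosome fusions
and Gaussian cM jitter. Scaffold ids are assigned in shuffled order so they
carry no positional hint. Truth tables record every scaffold part's source
interval, strand and fusion status, and every marker's true position; all
randomness flows from the single seed.

What it does **not** emulate: repeat-induced mis-assembly structure,
recombination suppression around centromeres (a plateau map function is the
natural extension), marker genotyping error other than cM jitter, and
segregation distortion. Passing recovery tests therefore demonstrate
correctness of the anchoring logic, not performance on real maps.

`evaluate_recovery()` scores a run against truth. Two metric definitions
deserve note:

* *Chimera sensitivity* is reported against **map-visible** fusions — those
  with at least one mapped marker on two or more source parts. At 100
  markers/Mb a short fused part frequently carries no marker at all, and
  such a fusion is indistinguishable from an intact scaffold for any
  map-based detector; the all-planted recall is reported separately as
  `chimera_sensitivity_all`.
* *Orientation accuracy* is scored over units with ≥ 2 distinct genetic
  positions. Under marker jitter of SD 0.5 cM the within-scaffold genetic
  span (~0.19 cM for a 50 kb scaffold on this map) is far below the noise,
  so orientation recovery degrades to near chance at this simulation scale —
  an information limit of the data, not of the estimator; the recovery tests
  document this rather than masking it.

## Worked example

```{r, eval = FALSE}
library(mapanchor)

ds <- simulate_genome(sim_config(seed = 42))
run <- run_pipeline(ds$scaffolds, ds$marker_map, ds$placements)
run
glance(run)            # tallies: anchored before/after, split counts, percent
tidy(run)              # per-pseudomolecule table
evaluate_recovery(run, ds$truth)

write_run(run, "run42")  # FASTA + AGP + anchor tables + JSON report
```

Problem sizes throughout the test-suite were chosen at desk scale — 16 Mb
synthetic genomes, ~1,600 markers, ~320 scaffolds for end-to-end runs, and
smaller 3-chromosome genomes for unit tests — large enough for every rate
and correlation to be meaningful, small enough to iterate on quickly.

## Known limitations

* Anchoring uses marker counts only; genotype likelihoods and map
  confidence intervals are not modelled.
* Breakpoints are midpoints between flanking markers; real mis-join
  coordinates may sit anywhere in that interval, so split pieces carry up to
  half an inter-marker spacing of mis-assigned sequence.
* The gap constant (10 kb N) is a reporting convention, not an estimate.
* `calibrate_times()` is a calibration-scaling of a given tree; it does not
  infer trees or model rate variation.
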