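# mapanchor

Build chromosome-scale **pseudomolecules** from a fragmented draft assembly
and a dense SNP **linkage map**, and compute the summary and comparative
statistics that accompany a draft plant-genome report.

Given scaffolds (FASTA), a marker map (`marker_id`, linkage group, cM) and
marker-to-scaffold placements (`marker_id`, `scaffold_id`, bp), the pipeline:

1. groups co-segregating markers into **bins** (identical rounded cM);
2. **anchors** each scaffold at the marker-count-weighted mean bin cM of its
   markers;
3. detects **chimeric** scaffolds — markers on two linkage groups, or a
   within-group cM jump above a threshold (default 20 cM) — and **splits**
   them at the floor midpoint between the flanking markers, so after
   splitting `n_after = n_before − n_split + n_pieces`;
4. **orients** each scaffold by the sign of the Kendall rank correlation
   between physical (bp) and genetic (cM) marker positions;
5. **orders** scaffolds along each linkage group (position, then descending
   length, then id) and joins them with fixed 10,000 N gaps into
   `chr1..chrK`, emitting FASTA plus AGP v2.1 with exact round-trip
   reconstruction.

Alongside: assembly summaries (N50 by the descending cumulative-half
convention, GC% excluding Ns, half-up one-decimal percentages), k-mer
histogram genome-size estimation (valley → peak → `Σ d·count / peak`),
reciprocal-best-hit orthologue pairing, synteny dot-plot coordinates,
**Nei–Gojobori (1986)** Ka/Ks with Jukes–Cantor correction
(`d = −(3/4)·ln(1 − (4/3)p)`), Ks histograms, and uniform-rate divergence
times calibrated at a single node (e.g. Arabidopsis–Medicago at 114.0 MYA).
A seeded simulator generates fragmented genomes with planted inversions and
chimeras plus truth tables, and `evaluate_recovery()` scores a run against
them.

## Worked example

```r
library(mapanchor)

ds  <- simulate_genome(sim_config(seed = 42))   # 8 x 2 Mb chromosomes
run <- run_pipeline(ds$scaffolds, ds$marker_map, ds$placements)
run
#> <anchor_run: 315 scaffolds, 16,000,000 bp>
#>   anchored before splitting: 269
#>   chimeras split: 2 (-> 4 pieces); anchored after: 271
#>   anchored bases: 15,534,000 bp (97.1% of assembly)
#>   pseudomolecules: 8
```

269 scaffolds carried mapped markers; two were split (each into two pieces)
because their markers pointed at two chromosomes, giving 271 anchored
sequences covering 97.1% of the 16 Mb assembly. `tidy(run)` lists the
pseudomolecules:

```r
tidy(run)
#>   name  lg    length_bp n_components n_gap_bases
#> 1 chr1  LG1     2256302           33      320000
#> 2 chr2  LG2     2338793           37      360000
#> ...                                  (8 rows; gaps = 10,000 N per join)
```

Scoring against the simulator's truth tables:

```r
evaluate_recovery(run, ds$truth)
#>   orientation_accuracy chimera_sensitivity chimera_precision order_spearman_min
#> 1                    1                   1                 1                  1
```

Every orientable scaffold was put on the correct strand, every map-visible
planted fusion was found with no false splits, and scaffold order along
every linkage group matches the true chromosome order exactly.
`write_run(run, dir)` writes the pseudomolecule FASTA, the AGP, anchor and
chimera tables, and a self-consistent JSON report. A thin command-line
wrapper over the same functions is installed at
`system.file("scripts", "mapanchor.R", package = "mapanchor")` with
`simulate`, `anchor`, `stats` and `validate` subcommands.

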