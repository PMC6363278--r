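# ladscape

Reorganization of lamina-associated domains (LADs) between two cellular
conditions, quantified end to end: from binned lamin A/C and lamin B1
ChIP-seq count tracks to LAD calls, joint A/B class maps, base-pair fate
transitions, gene-expression linkage, and radial nuclear positioning in 3D
bead-on-string models and 2D FISH measurements.

## Who this is for

Nuclear-organization groups comparing lamin A and lamin B genome
association across a perturbation (drug treatment, differentiation,
disease allele). The package covers the post-alignment analysis layer:
read alignment, Hi-C processing and 3D model optimization are upstream
tools whose outputs (binned counts, bead structures) this package
consumes. A synthetic-data generator with planted ground truth makes every
stage verifiable offline.

## The model in brief

- **Ratio tracks.** Per fixed bin, `log2(chip / (input * T_chip/T_input))`
  after per-chromosome depth matching (exact read down-sampling of the
  deeper track). Bins without usable signal are masked.
- **Domain calling.** Bins at analysis size `BS` score `+1` when the
  log-ratio is at least a threshold `tau`, else `-GP` (GapPenalty).
  Called LADs are the disjoint maximal-scoring segments of this sequence
  (Ruzzo–Tompa): no extension, truncation or union of adjacent segments
  can raise any segment's score. `tau`, `BS` and `GP` are auto-estimated
  (two-class threshold; fraction-stability bin ladder; background/signal
  bin-count ratio), and a 10-run jittered stability protocol quantifies
  technical variability as "variable subdomains" before a final call with
  run-averaged parameters.
- **Class algebra.** Per base: in both lamin sets → `A-B`; one → `A-only`
  / `B-only`; neither → `iLAD`. Coverage Jaccard index `|∩|/|∪|`, per-class
  size ANOVA (two-way on log size, Tukey HSD), and a 4×4 base-pair fate
  matrix between conditions (the alluvial diagram's data).
- **Expression link.** A gene belongs to the class at its TSS; genes with
  `|ΔFPKM| < 0.05` are "stably expressed"; fate cells are tested with
  unpaired (Welch) t-tests at the `α = 0.01` convention.
- **Radial positioning.** Bead distance to the nucleus center divided by
  the nucleus radius (default 5 µm): 0 = center, 1 = periphery. Classes
  map to beads by ≥ 1 bp overlap; fates are compared between condition
  ensembles with unpaired t-tests. 2D FISH spots are normalized by the
  ray-to-boundary distance in the nucleus ellipse — for a circle exactly
  `|spot − center| / r`.

## Worked example

```r
library(ladscape)

genome <- lad_genome()                       # 4 x 30 Mb, 10 kb bins
truth  <- plant_architecture(genome, default_transition_plan(), seed = 42)
cfg    <- sim_config(seed = 7)

counts  <- simulate_chip_counts(genome, truth$control, "A", cfg, seed = 11)
matched <- match_depth(counts$chip, counts$input, seed = 12)
track   <- build_ratio_track(matched$chip, matched$input)

rep <- stability_protocol(track, n_runs = 10, seed = 13)
rep
#> <stability_report> 10 runs; GP 2.359 (sd 0.155), BS 80000 bp; 17 final
#> domains, 36.16 Mb; variable subdomains: 0 (median 0 kb)
jaccard(rep$lads, lamin_set(truth$control, "A"))
#> [1] 0.9759036
```

The stability report says: ten jittered auto-estimation runs put the gap
penalty near 2.4 (run-to-run SD 0.16) at an 80 kb analysis bin, the final
run-averaged call found 17 lamin A domains covering ~36 Mb, and at this
signal strength the jitter produced no variable subdomains. The Jaccard
index of 0.98 against the planted truth means called and true coverage
are nearly identical. (Variable subdomains become nonzero on noisier
inputs; the printed values are what this exact seeded example produces.)

The full synthetic pipeline — tracks for both lamins and conditions, LAD
calling, classification, fate matrix, expression report, 3D ensembles and
FISH tables — is one call:

```r
res <- run_all(default_run_config(seed = 1), out_dir = "ladscape_run")
```

or from the shell (the launcher installs to `<library>/ladscape/exec/`):

```sh
Rscript -e 'ladscape::lad_cli()' run-all --seed 1 --out-dir ladscape_run
```

## Scope notes

No read-level simulation or BAM/bigWig handling in the core path, no Hi-C
processing, no 3D optimization, no image processing; structures and spot
coordinates are consumed (TSV, CMM-like XML) or synthesized.
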