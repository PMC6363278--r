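---
title: "Quantifying LAD dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LAD dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladscape)
```

# The problem

Lamina-associated domains (LADs) are megabase-scale genomic regions that
contact the nuclear lamina and show broad enrichment in lamin ChIP-seq.
Lamin A/C and lamin B1 define partially overlapping LAD repertoires, so
the genome splits into four classes: `A-B` (both lamins), `A-only`,
`B-only`, and inter-LAD (`iLAD`). When cells are perturbed, regions can
keep their class, exchange one lamin for the other, or detach entirely —
and these *fates* may correlate with gene expression and with how far a
locus sits from the nuclear center. `ladscape` implements this analysis
as a tested pipeline over synthetic or real binned inputs.

# Track construction

Input and ChIP binned counts are depth-matched **per chromosome** by
down-sampling the deeper track without replacement (a multivariate
hypergeometric draw, equivalent to discarding random reads) until totals
match exactly; down-sampling a second time is then a no-op. The ratio
track is `log2(chip / (input * T_chip / T_input))` per bin, with the
total-count factor making the values invariant to uniform rescaling of
either track's depth.

Two numerical choices matter:

* **Masking, not smoothing.** Bins with zero input have no denominator;
  bins with zero ChIP would be `-Inf`. Both are masked (`NA`) and the
  domain caller treats masked bins as non-enriched. No pseudocount is
  added — at realistic depths (tens of reads per bin) zero-count bins are
  vanishingly rare, and a pseudocount would bias exactly the low-coverage
  bins where the ratio is least trustworthy.
* **A consequence of per-chromosome matching.** After matching, each
  chromosome's ChIP and input totals are equal, so the *background*
  log-ratio on a chromosome is depressed by roughly
  `-log2(1 + (4^{enrichment} - 1) x coverage share)` — chromosomes with more
  LAD signal have lower backgrounds. Any global threshold must therefore
  sit in the gap *between* the background and enriched modes, not inside
  the background bulk (see below).

# Domain calling

Bins at analysis size `BS` score `+1` if the value is at least `tau`,
else `-GP`. Called domains are **all maximal scoring segments** of this
sequence (the Ruzzo–Tompa decomposition): disjoint segments such that no
extension, truncation, or union of adjacent segments increases any
segment's score. Segments scoring below `min_score` (default 3
enriched-bin equivalents) are dropped. The implementation is checked
against an independent brute-force enumeration of the maximal-segment
characterization on hundreds of random tracks, and coverage is verified
to be non-increasing in `GP`.

A note on ties: two enriched runs separated by a zero-cost bridge
(`GP = 0`) score the same merged or split. The stack algorithm reports
them split; the brute-force oracle agrees because the merged candidate
fails the strict left-minimum/right-maximum characterization. With any
`GP > 0` the question does not arise.

## Auto-estimation

The auto-estimation heuristics are this package's own constructions with
the conventional parameter semantics (they do not reproduce any external
tool's estimates):

* `tau` — a two-class **Otsu threshold** on the unmasked values. An
  early design used the genome-wide median; it fails whenever LAD
  coverage is below 50% because the median then sits inside the
  background bulk, and with per-chromosome background offsets whole
  low-coverage chromosomes end up above threshold. The between-mode Otsu
  cut is deterministic, lands near zero on pure noise, and lies between
  the background and enriched means on planted data.
* `BS` — smallest size on a doubling ladder of the native bin size at
  which the enriched-bin fraction changes by < 1 percentage point versus
  the next step. Intuition: once bins are large enough to average out
  background noise, the enriched fraction stops moving (it approaches the
  true coverage fraction).
* `GP` — the **non-enriched / enriched** bin-count ratio at the chosen
  `BS`. The rarer enrichment is, the more a bridged gap must cost. (The
  inverted ratio, enriched/non-enriched, was tried first and
  under-penalizes: with ~30% coverage it yields GP ≈ 0.4 and maximal
  segments bridge megabase inter-LAD gaps, because two segments merge
  whenever the gap costs less than the smaller segment's score.) On the
  default synthetic data this lands at GP ≈ 1.5–3.6 and BS 20–80 kb,
  the same order as published LAD-caller settings on real data, and
  recovers planted truth at Jaccard ≥ 0.94.

## Stability protocol

Technical variability is emulated by re-running auto-estimation `n_runs`
times (default 10) with a seeded Gaussian jitter on `GP` (SD = 0.1 × GP)
and calling domains each time. Bases covered by *some but not all* runs
are the **variable subdomains**; their median length summarizes caller
stability. The final call fixes `GP`/`BS` to run averages. With zero
jitter all runs are identical and the variable set is empty — a test
anchors this.

# Class algebra and fates

Class partitioning, Jaccard indices and the fate matrix are exact
interval algebra on merged, 0-based half-open coverage sets
(`GenomicRanges` internally; conversion at the I/O boundary). The fate
matrix counts **base pairs**, not domains: alluvial flow widths are a
base-pair notion. A per-domain majority-overlap view (≥ 50%, ties broken
`A-B` > `B-only` > `A-only` > `iLAD`) is provided separately for labeling
individual named LADs; both views are emitted because either weighting is
defensible for a fate diagram.

For Jaccard comparisons at the lamin level, "lamin A LADs" means
`A-B ∪ A-only` (what a lamin A ChIP caller sees), mirrored for lamin B;
class-level Jaccards compare single classes across conditions.

Size comparisons use a two-way ANOVA on log10 size with factors class and
condition, followed by Tukey's HSD on the class:condition groups. Log
scale because LAD sizes span ~0.5–15 Mb and are right-skewed.

# Expression linkage

A gene belongs to the class at its TSS (half-open: a TSS at a run's end
coordinate belongs to the next run; minus-strand TSS = interval end − 1,
BED convention; one TSS per gene record is required). The
stable-expression filter is strict: `|ΔFPKM| < 0.05`. Fate cells are
tested with **Welch** t-tests by default — the choice of unequal-variance
vs pooled is configurable since only "unpaired t-tests" is conventional —
and raw p-values are read against α = 0.01; a Benjamini–Hochberg column
is available but off by default to match that convention.

# Radial positioning

Bead-on-string structures (one bead per TAD, bead radius proportional to
TAD length) are summarized by `d/R`: bead-center distance to the nucleus
center over the nucleus radius (default 5 µm). A bead carries every class
overlapping it by at least 1 bp (configurable), because TADs are larger
than many class runs; beads with no lamin class form the inter-LAD group.
Fate-pair comparisons pool bead distances **per bead per model** across
the ensemble (pooling per region first would discard within-region
variation; the choice is recorded here because either is defensible) and
assume all structures of an ensemble share one TAD segmentation, as
ensemble modeling tools produce. FISH probes are located by their
midpoint — BAC-scale probes (~0.2 Mb) are much smaller than TADs, so an
overlap vote adds nothing.

2D FISH normalization divides the spot's distance from the nucleus
center by the center-to-boundary distance along the ray through the spot.
For an axis-aligned ellipse this has the closed form
`sqrt((vx/a)^2 + (vy/b)^2)`; for a circle it reduces exactly to
`|spot − center| / r`. The geometric rule for non-circular nuclei is an
interpretation (measured data normalized "to the radius" is ambiguous for
ellipses); ray intersection is the natural one and is exact for circles.

# The synthetic world

The generator states one simulated world; its defaults are fixed and not
tuned to test outcomes:

* **Genome**: 4 × 30 Mb chromosomes, 10 kb bins — desk-scale but large
  enough for 0.5–15 Mb LADs.
* **Architecture**: the default transition plan plants 25 domains
  covering 44% of the genome with the qualitative fate structure expected
  under the modeled perturbation (A-B mostly persists, a fraction loses
  lamin A; most A-only becomes inter-LAD, the rest switches toward lamin
  B; B-only mostly persists, about a third gains lamin A; minor de novo
  LADs in former inter-LADs). Domains are bin-aligned and separated by at
  least one inter-LAD bin so truth recovery is unambiguous.
* **Counts**: negative binomial (dispersion 0.05, configurable; the count
  distribution is a modeling choice — nothing upstream specifies one),
  input mean 50 reads/bin, in-LAD ChIP enrichment 2 log2 units. The
  enrichment level is chosen for detectability, not fidelity — no
  quantitative lamin ChIP enrichment is specified upstream.
* **Structures**: bead radial coordinate drawn from a Beta distribution
  rescaled to (0, R), mean matched to the class target (defaults `iLAD`
  0.5, `A-only` 0.7, `A-B` and `B-only` 0.9 — the expected ordering with
  inter-LADs most central and lamin-B-bound classes most peripheral),
  concentration 50, directions uniform on the sphere. Chain connectivity
  is *not* enforced: only radial statistics are consumed downstream.
* **Expression**: lognormal baseline FPKM (meanlog log 8, sdlog 0.8);
  treated FPKM applies `2^(effect + N(0, 0.3))` divided by
  `exp((0.3 ln 2)^2 / 2)` so the noise is mean-preserving — zero-effect
  transitions have expected FPKM change exactly 0, which keeps the null
  cells honest nulls.
* **FISH**: two spots per nucleus, elliptical nuclei with semi-axes
  uniform in 3.5–5.5 µm, normalized positions Normal(target, 0.05)
  truncated to [0, 1]. The spread is deliberately tight so that planted
  targets are sharply realized; real FISH distributions are broader, so
  power in real data will be lower than in these tests.

What a green test establishes: the estimators recover *this* world's
parameters. Real data differ in ways the generator does not emulate —
copy-number variation, mappability holes, chromatin-state-dependent input
bias, spatially correlated noise along the chromosome, chain constraints
in 3D models, and optical artifacts in FISH. The caller's parameter
estimates on real tracks should not be expected to match any external
tool's values.

# Implementation notes

Interval containers and I/O are `GenomicRanges`/`rtracklayer` throughout.
Three inner kernels are plain-vector implementations for speed — the
Jaccard index (merge-and-sweep over start/end vectors), the fate matrix
(one overlap join instead of sixteen pairwise intersections), and track
rebinning (matrix column sums) — each property-tested against the
corresponding `GenomicRanges` reference computation or a per-base oracle.

# Degenerate inputs and edge policies

* Constant ratio tracks: auto-estimation refuses (`degenerate input`).
* Both coverage sets empty: the Jaccard ratio is undefined and an error,
  not 0.
* Fate cells or class pools with fewer than 2 observations are reported
  with their `n` and no test; identical constant groups are a t-test
  error surfaced as such.
* Bead centers at or beyond R violate the structure invariant and error
  at construction.
* Empty interval files are empty sets, not errors; malformed lines report
  the first offending line number.

# Known limitations

* The caller scores bins binarily (`+1 / -GP`); it does not weight by
  enrichment magnitude, and no FDR is attached to domains.
* Auto-estimation assumes a roughly bimodal value distribution; tracks
  with coverage near 0% or a continuum of enrichment levels will defeat
  the Otsu cut.
* The per-chromosome placement of planted domains balances total load,
  not per-class load, so individual chromosomes can be class-skewed (as
  real chromosomes are).
* `run_all` derives stage seeds as fixed offsets of the master seed;
  reproducibility holds per stage, so upstream config changes do not
  perturb downstream stages' random streams.
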