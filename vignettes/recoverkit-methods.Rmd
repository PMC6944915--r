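---
title: "Methods: screen statistics, focus detection, and junction classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen statistics, focus detection, and junction classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoverkit)
```

recoverkit implements the three quantitative procedures that carry a
G2-checkpoint-recovery study from raw readouts to conclusions: hit calling in
a multi-plate siRNA screen of mitotic entry after irradiation, automated
counting of ionizing-radiation-induced foci (IRIF) of DNA-damage markers
(γH2AX, 53BP1) in confocal images, and classification of I-SceI reporter
repair junctions into end-joining event categories. Because such studies
rarely deposit machine-readable raw data, the package pairs each procedure
with a ground-truthed simulator; every accuracy claim made by the test suite
is a claim about recovery of planted truth under the simulator's assumptions,
which this vignette spells out.

## Screen statistics

### Model

Each well of the screen reports the fraction of mitosis-marker-positive
(phospho-histone H3 or MPM2) cells after irradiation of G2-synchronized
cells — a proxy for checkpoint recovery. For well readout $x$ the Z-score is

$$ z = \frac{x - \hat\mu}{\hat\sigma}, $$

with $\hat\mu$, $\hat\sigma$ the mean and sample standard deviation
(divisor $n-1$) of the reference population. The reference is, by default,
the non-control wells of the same plate within the same replicate
(`scope = "per_plate"`): plate-to-plate shifts in staining and imaging
dominate well-level variation in 96-well screens, so plate-wise
standardization is the conservative choice. A whole-replicate reference
(`scope = "per_screen"`) and inclusion of control wells are available as
options because the choice is not identifiable from a finished screen. Small
control groups are also why the sample (not population) SD is used
throughout.

Per-replicate Z-scores are averaged (mean by default, median as a
robustness option) and hits are called with asymmetric inclusive cutoffs:
`z_mean >= 2` for increased recovery, `z_mean <= -1` for decreased. A cutoff
"value of 2" is read as a threshold attained, hence inclusive boundaries.
No multiple-testing correction is applied at the primary-screen stage; the
deconvolution step is the error control.

### Deconvolution

A pooled hit is rescreened with its individual oligos. An oligo counts as
*altered* in an experiment when its readout deviates from the mean of the
same plate-and-experiment negative-control (luciferase) wells by more than
`sd_threshold` (default 0.5) times the control wells' sample SD; an oligo
validates when altered in at least 2 experiments, and a gene validates when
at least 2 of its 4 oligos validate. The reference population whose SD
anchors the 0.5 threshold is taken to be the negative-control wells of that
experiment — the only population the table's invariants guarantee — with the
multiplier exposed as configuration.

### Normalizations

Relative mitotic entry (RME) is the mitotic fraction after irradiation over
the untreated mitotic fraction; survival is the irradiated over untreated
optical density; reporter repair efficiency is the marker-positive fraction
among transfected (mCherry+) cells. All three are expressed relative to the
negative-control knockdown, which is set to exactly 1 by construction.
Group comparisons use the classical two-tailed unpaired equal-variance
t-test (`stats::t.test(var.equal = TRUE)`).

### Screen simulator

`simulate_screen()` draws null well fractions from a Gaussian on the mitotic
fraction, truncated to $[0,1]$ (defaults: mean 0.30, SD 0.05 — a typical
post-irradiation recovery fraction with well-to-well noise of a sixth of the
signal; no distributional parameters are identifiable from a finished
screen, so these are stated assumptions, not estimates). A count-based mode
(binomial sampling of ~1000 cells at the well's latent fraction) is
available for realism. Plates carry 2 luciferase wells (negative control)
and PPM1D/BTRC wells (positive controls, planted at −5 SD, consistent with
their role as strong recovery regulators).

Planted hits default to |effect| = 5 SD. This is a deliberate design point:
with 41 hits among 529 genes, the planted effects themselves inflate the
reference SD by a factor $\sqrt{1 + f\,\mathbb{E}[e^2]}$ ($f \approx 0.078$),
so the attainable |z| saturates near $1/\sqrt{f} \approx 3.6$ however large
the effect. At 3 SD the expected z of an increased hit sits almost on the
cutoff of 2 and recovery is fragile; at 5 SD the expected z is ≈ 2.9 with
comfortable margins on both sensitivity and the false-discovery proportion
under the default asymmetric cutoffs. Validated screen hits correspond to
strong, reproducible displacements, which 5 SD represents.

On a null screen the mean of $R$ per-replicate Z-scores has SD
$1/\sqrt{R}$, so the expected fraction of $|\bar z| \ge 2$ genes with three
replicates is $2\Phi(-2\sqrt{3}) \approx 5\times10^{-4}$; the test suite
checks the observed count against this tail within three binomial standard
errors.

## Focus detection

### Pipeline

`run_irif_pipeline()` composes four stages in acquisition order:

1. **Nucleus segmentation** (`segment_nuclei`): the DAPI channel is
   median-filtered (radius 2 px), thresholded (Otsu by default; an absolute
   threshold is available for reproducibility across acquisitions), holes
   filled, and touching nuclei split by a watershed on the distance
   transform of the mask — i.e. flooding the negated distance map from its
   local maxima. Objects under `min_nucleus_area` (200 px) and, by default,
   nuclei touching the image border are removed; border exclusion is the
   automated stand-in for the manual curation of partial nuclei that
   interactive workflows apply. Labels are renumbered 1..K in raster order
   of first pixel so numbering is deterministic. These steps run on
   EBImage; intensities are rescaled to $[0,1]$ internally because
   EBImage's filters operate on that range.
2. **Maximum-intensity projection** (`max_project`): per-pixel maximum over
   z; identity for single planes. All geometry afterwards is 2D.
3. **Difference-of-Gaussians subtraction** (`dog_subtract`): the focus
   channel is band-passed as $G_{\sigma_1} * I - G_{\sigma_2} * I$ with
   defaults $\sigma_1 = 1$, $\sigma_2 = 3$ px, matched to foci of roughly
   3–6 px diameter. Constants are annihilated; the output may be negative
   and is deliberately not clamped — thresholding is the detector's job.
4. **Two-criterion detection** (`detect_foci`): for each nucleus the
   background of its DoG values is summarized by the median, and a
   background SD as $1.4826 \times \mathrm{MAD}$ — a robust scale estimate
   that true foci (bright outliers occupying a small pixel fraction) do not
   inflate; the plain SD is available via `robust_background = FALSE`. The
   image-wide reference SD is the **median over nuclei** of these
   per-nucleus SDs. A pixel passes when its DoG value exceeds its nucleus's
   background median by `k_sd` (typical 2–4, default 3) times the reference
   SD **and** exceeds an absolute minimum `abs_min`. Connected components
   of passing pixels (8-connectivity by default, 4 as option) within a
   single nucleus with area ≥ `min_focus_area` become foci. The area rule
   "larger than two pixels" is implemented strictly (default
   `min_focus_area = 3`); the inclusive variant (≥ 2) is one parameter away.
   Nuclei under 10 px are excluded from detection — no meaningful
   background statistic exists there.

Coordinates are 0-based (row, column) on the projected image; areas are in
pixels. Focus centroids are unweighted pixel centroids.

The detector is intentionally equivalent to an explicit per-pixel threshold
test followed by flood fill; the test suite asserts exact agreement with
such a brute-force oracle on random instances, so the production
implementation (union-find labelling constrained to stay within one
nucleus) cannot drift from the definition.

### Image simulator

`simulate_images()` renders filled noisy ellipses (DAPI) and isotropic 2D
Gaussian foci (σ 1.5 px) over a flat background with additive Gaussian
noise (Poisson shot noise as an option). Focus amplitudes are expressed in
units of the noise SD, making "SNR ≥ 5" scenes well defined. Foci are
placed at least 5–6 px apart within the inner 80% of the ellipse; in
Poisson count mode, draws whose placement cannot satisfy the separation
constraint are redrawn, i.e. counts are conditioned on geometric
feasibility. The simulator does not model point-spread functions,
illumination gradients, focus clustering, or overlapping nuclei — so
passing recovery tests demonstrate correctness of the detection rule, not
robustness to every optical artifact of real confocal data; the `k_sd` and
`abs_min` parameters exist precisely because real experiments need
per-experiment tuning.

## Junction classification

### Model

Repair of a single I-SceI break in the integrated reporter is read out by
Sanger sequencing of cloned amplicons. Each read is anchored to the
reference amplicon by its longest exactly matching prefix and suffix
(an `N` matches nothing). Exact matching is appropriate for high-quality
Sanger reads of single clones; a mismatch-tolerant mode would add little
but ambiguity. Both raw anchors must reach `min_anchor` (default 10 nt),
otherwise the read is reported `unclassified` — kept as its own explicit
category rather than silently discarded or forced into a bin. The gate is
applied to the raw (untrimmed) match lengths; the right anchor is then
trimmed so the anchors overlap on neither the read nor the reference,
preferring the longer left anchor. The trimmed geometry yields the
reference gap (deletion size) and the unmatched read middle (insertion),
and the category follows:

| category  | deletion | insertion |
|-----------|----------|-----------|
| direct    | 0        | none      |
| deletion  | > 0      | none      |
| delins    | > 0      | present   |
| insertion | 0        | present   |

Every classified read satisfies the conservation law
$|read| = |ref| - \text{del} + |\text{ins}|$.

Under microhomology the deletion placement is ambiguous; pure deletions are
canonicalized to the leftmost equivalent placement. The microhomology
length is the number of alternative equal-size placements producing the
identical repaired sequence — equivalently the extent to which the flanks
can be slid while matching — and is capped at the deletion size, as in a
homopolymer run a two-base deletion cannot meaningfully use more than two
bases of homology. Microhomology is scored for simple deletions only;
delins junctions carry inserted sequence whose origin the assay cannot
resolve. Spectra bin deletion sizes (default bins 1, 2–5, 6–20, 21–100,
>100 nt; simple deletions plus delins by default) and microhomology lengths
(0, 1–2, 3–5, ≥6 nt; simple deletions only) into half-open integer bins;
the bin edges are configurable because published figures rarely state them
exactly.

### Junction simulator

`simulate_junction_reads()` plants one event per read at the cut site of a
shipped 240-nt synthetic amplicon (cut at 120; a stand-in sequence, not any
real reporter). Category counts are deterministic rounded proportions, so
planted and recovered counts can be compared exactly. Deletion sizes follow
a geometric distribution (mean 10, capped at 40 nt — small deletions
dominate end-joining spectra); for each deletion a placement realizing the
targeted microhomology is searched among all placements touching the cut,
redrawing size and target when the reference does not admit the
combination. Insert ends are chosen to mismatch their flanks so the planted
parse is the unique parsimonious one — without this, anchor extension would
(correctly) report a different but equivalent event and exact round-trip
comparison would be ill-posed. A per-base substitution error rate is
available (default 0).

## Numerical and interface choices

- Every simulator takes an integer seed, uses a private keyed RNG stream,
  and restores the caller's RNG state, so regenerating one artifact never
  perturbs another and identical seeds give byte-identical outputs.
- Degenerate inputs fail loudly where silence would corrupt statistics
  (zero reference SD, fewer than two control wells, empty untreated gates)
  and warn where an empty result is meaningful (blank images, unanchorable
  reads, sub-10-px nuclei).
- `run_pipeline()` executes stages in dependency order, writes every table
  as CSV, serializes the merged effective config, and emits an MD5 manifest;
  run directories are write-once so outputs cannot be silently clobbered.
- Problem sizes used by the test suite and the acceptance script — 529-gene
  screens with 3 replicates, ten 256×256 scenes of 5 nuclei (≈ 50 nuclei,
  ≈ 470 foci), 1,000 junction reads — were chosen as the smallest sizes at
  which the binomial/correlation criteria are statistically meaningful.

## Known limitations

- Segmentation quality is Otsu-limited; dim or highly variable DAPI
  staining may need the absolute threshold. There is no manual correction;
  border exclusion is the only automated QC.
- Detection is 2D after projection; axially separated foci that project
  onto each other merge, as in any projection-based count.
- The junction caller assumes reads span both flanks of the single cut;
  chimeric clones and two-cut distal joints are out of scope.
- The simulators are calibrated for structural realism, not photorealism;
  quantitative claims transfer to real data only insofar as its noise
  resembles the stated models.
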