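---
title: "Methods: quantifying stress-induced condensates with condensateR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stress-induced condensates with condensateR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateR)
```

condensateR implements the quantitative procedures used to characterize
stress-induced ribonucleoprotein condensates: how much of a protein lives in
a condensate versus the nucleoid versus the dilute phase (single-molecule
tracking), how foci look in segmented cells (robust thresholding,
colocalization, FRAP), when purified components phase-separate in vitro
(droplet segmentation and phase calls), what condensation does to transcript
fate (rifampicin-chase decay, untemplated poly(A) tails), and whether these
effects concentrate in particular functional gene sets (enrichment
statistics). This vignette records the models, the parameter conventions,
and the design decisions behind each stage, and what the synthetic-data
tests do and do not establish.

## Single-molecule diffusion states

Each localization stream is decomposed into three diffusive states. The
per-track model is the lag-linear MSD, `MSD(kτ) = 4 D kτ + 4 σ²`, fit by
ordinary least squares over lags 1–5 for tracks of at least 7 localizations
(`fit_msd`); `σ` is the static localization error. Population-level
decomposition uses the empirical cumulative distribution of single-frame
squared displacements pooled over tracks of at least 4 frames
(`pooled_squared_displacements`, `empirical_cdf`), fit by unweighted
nonlinear least squares to

$$P(r^2,\tau) = 1 - \left(\alpha_1 e^{-r^2/(\frac{8}{3}D_1\tau)} +
\alpha_2 e^{-r^2/(\frac{8}{3}D_2\tau)} +
(1-\alpha_1-\alpha_2)e^{-r^2/(\frac{8}{3}D_3\tau)}\right).$$

Two conventions deserve comment:

- **The 8/3 scale.** For instantaneously sampled 2-D Brownian motion the
  single-lag mean squared displacement is `4Dτ`; continuous camera
  integration over the frame blurs each position and reduces the apparent
  single-lag MSD to `(8/3)Dτ`. The model is implemented with 8/3 as its
  default (`msd_factor = 8/3`), with the instantaneous-sampling value 4
  selectable. The trajectory simulator emits instantaneous positions (no
  motion blur — photophysics is out of scope), so fitting simulated data
  with the 8/3 scale recovers every `D` inflated by exactly 3/2 while the
  weights `α`, which carry all downstream meaning, are recovered unbiased:
  a common mis-scale maps an exponential mixture onto another exponential
  mixture with the same weights. The end-to-end tests therefore assert
  recovery of fractions, not of absolute `D`, from trajectory simulations;
  absolute `D` recovery is asserted on displacements drawn from the CDF
  model itself.
- **No localization-error term in the CDF.** The printed mixture has no `σ²`
  offset and none is added. With the defaults (σ = 30 nm, τ = 20 ms) the
  noise floor `4σ²` inflates the apparent slow-state scale; this shifts
  fitted `D₁`/`D₂` upward but again leaves the weights essentially intact,
  which the parameter-recovery tests quantify.

Fitting uses stick-breaking weights (`α₁ = p₁`, `α₂ = (1−p₁)p₂`) so the
simplex constraint is exact, bounded Levenberg–Marquardt with three seeded
starts from displacement quantiles, and a Nelder–Mead fallback on
transformed parameters when LM fails (it can, when the subset pool is
nearly single-state). States are reported in increasing-D order with ties
broken by weight; fits with two `D` within 5% are flagged degenerate —
expected and harmless for the focus-overlap subset, where the two slow
states carry almost all weight.

Stable foci are detected on a composite image that accumulates one count
per localization per containing pixel, normalized to [0, 1] so the
scale-dependent blob threshold is meaningful. Blobs come from a
scale-normalized Laplacian-of-Gaussian detector (sigmas 3–5 px, threshold
0.1, radius = σ√2) — written in-house because no installed R package
provides multiscale LoG blob detection — and each blob's pixel support is
the disk of its radius, with contested pixels going to the nearest center.
A focus is kept only when at least 10 trajectories of at least 10 frames
each overlap it for at least 70% of their localizations; 10 frames is the
median simulated track length, mirroring the acquisition it emulates.
Track overlap is pixel-based: a localization overlaps a focus iff its
containing pixel belongs to the region. Tracks are "In" at 100% overlap,
"In/out" at 25–99%, "Out" below 25%.

The state fractions combine the full-pool fit and the In + In/out subset
fit: `F_condensate = (N_In + N_InOut)/N_total · (α₁+α₂)` of the subset fit,
`F_free = α₃` of the full fit, `F_nucleoid` the remainder; all are shares
of analysed displacements. The subset fit leaves `D₃` unconstrained, and
consistency with free diffusion (`D₃ > 1 µm²/s`) is checked post hoc with a
warning rather than imposed.

**What the simulations emulate.** Brownian walks with per-state diffusion
coefficients, geometric track lengths (median 10 frames), i.i.d. Gaussian
localization noise, and condensate confinement as a radially reflecting
boundary — the simplest mechanism that produces focus-overlapping slow
tracks. They do not emulate blinking/bleaching, motion blur, nucleoid
geometry, or state switching within a track; passing recovery tests
demonstrates the estimator chain is faithful under the model's own
assumptions, not that those assumptions hold in any particular microscope.

## In vivo focus quantitation

Cell masks (an upstream segmentation product; `make_cell_masks` builds
synthetic ones) are dilated by 4 px — Euclidean, via distance transform —
and replaced by their convex hulls to form the final cell boundaries;
contested pixels go to the nearest original-mask centroid
(`expand_cell_masks`). The focus threshold is global per image: median plus
3.5 times the raw median absolute deviation (no 1.4826 consistency factor —
the procedure specifies "median absolute deviation", not a normal-scale
estimate) of the pooled within-cell intensities, using the expanded
boundaries. Focal centers are 8-neighbourhood local maxima strictly above
the threshold (a plateau pixel counts when no neighbour is strictly
greater); regions grow over strictly supra-threshold pixels by orthogonal
(4-)connectivity, and are kept with at least 3 px and at least one center.
The whole chain is translation-equivariant: adding a constant to the image
and recomputing the threshold reproduces identical calls, which the suite
asserts end-to-end. Background for intensity ratios is the expanded cell
minus all focus pixels; the measurement channel may differ from the calling
channel (cross-channel ratios, and the log2 option, cover both intensity
presentations). P-body counting in mammalian images is the same calling
operation per cell with `normalize_to_control` for the ratio-to-control
presentation.

Colocalization is the Spearman rank correlation over each cell's pixels
with the per-field mean as the field summary; cells with a constant channel
are excluded with a warning. FRAP traces are normalized to the mean of the
three pre-bleach frames, the bleach frame defines `t = 0`, and
`y(t) = baseline + (plateau − baseline)(1 − e^{−kt})` is fit by bounded
nonlinear least squares; `t½ = ln 2 / k` with a normal-approximation 95%
CI. Non-recovering traces (rate at its bound or plateau at baseline) are
flagged rather than reported.

## In vitro droplet quantitation

The droplet pipeline is CLAHE (EBImage's implementation; clip-limit
conventions differ between libraries, so the limit is exposed as
`clahe_limit` with EBImage semantics), Gaussian blur (σ = 2 px), Canny edge
detection, morphological closing with a 3-px-radius disk, filling of
enclosed regions, and an area floor of 150 px. Canny is written in-house
(Sobel gradients, non-maximum suppression with bilinear interpolation along
the true gradient direction, hysteresis): no installed R package provides
it. Hysteresis thresholds are automatic — Otsu on the nonzero gradient
magnitudes with a floor (`canny_min_high = 0.3` on contrast-normalized
images) below which a field is considered edge-free; the floor separates
true droplet rims (magnitudes near 1 after normalization) from
CLAHE-amplified noise gradients (below ~0.27), and all of these unprinted
constants are config-visible.

Shape metrics per candidate: pixel area; perimeter by Freeman chain code
from Moore boundary tracing (straight steps 1, diagonal √2 — a weighted
convention that matches 2πr on rasterized disks to within discretization
error); circularity `4π·area/perimeter²`; major/minor axes and eccentricity
from central second moments (with the 1/12 unit-pixel correction); solidity
against the rasterized convex hull; extent against the bounding box. The
five filters are applied verbatim: circularity ≥ 0.4, axis ratio < 1.4,
eccentricity < 0.8, solidity > 0.9, extent in (0.55, 0.95). A filled square
fails on extent, a 2:1 ellipse on axis ratio and eccentricity. Note the
segmentation returns the filled region including its edge band, which
biases areas upward by roughly one pixel of radius (~6% for a 10-px disk);
truth-recovery tests budget 10%.

Phase calls: counts and total areas per field are log10(x+1)-scaled (so
zero-droplet fields are representable), pooled across all fields of all
conditions, Otsu-thresholded (an in-house histogram Otsu for numeric
samples, oracle-tested against exhaustive search), and a condition is
positive iff the median of its fields exceeds either threshold. An
all-identical metric yields no threshold, a warning, and all-negative
calls.

## Rifampicin-chase decay

Counts are normalized per sample to relative abundances and genomic
features rescaled by the median relative abundance of qualifying spike-ins
(relative abundance > 5·10⁻⁴). Spike-in rows are carried through the output
normalized identically, which makes the operation exactly idempotent and
scale-invariant per sample (both are asserted). One analytic property is
worth recording: if some spike-ins sit near the qualifying cutoff, the
qualifying set grows as the transcriptome decays and the per-sample median
drifts, biasing fitted decay constants upward — with a borderline spike mix
we measured ~25% upward bias at b = 40 min. The simulator's default spike
mix (expected counts 300–8000) therefore stays above the cutoff at every
timepoint, which is also what a well-designed spike-in titration does.

Per-gene fits minimize `Σ(y − a·e^{−t/b})²` over replicate-level points
(keeping degrees of freedom honest), with both parameters bounded at zero
and initialized at a = 0.001, b = 20 — the stated initialization; the
Levenberg–Marquardt implementation is insensitive to the scale mismatch
when abundances are large. The decay-constant p-value is the t statistic of
`b` (df = n − 2) from the fit covariance, with BH q-values across genes —
the procedure names a q-value without naming the FDR method; BH is the
standard choice. Genes pass at q < 0.1 and R² > 0.5. The 5–65 min window
flags "measurable" constants but does not remove fits (the range is a
reporting window; fits outside it are retained and flagged). Stability
categories are a pure function of the decay-constant pair — stable vs
unstable: above 65 min in one genotype and below 55 in the other;
directional: both below 65 with a ≥ 10 min difference — property-tested
against a transliteration over a τ×τ grid. The genotype comparison is an
unpaired two-sided Wilcoxon rank-sum on the kept decay constants with the
median shift reported as a percentage.

## Untemplated poly(A) tails

Tail length per read is the maximal uninterrupted run of 'T' at the
adapter-adjacent terminus — not the total T count, which would include
templated bases; both modes are selectable (`mode = "total"`), since the
source procedure's wording ("the number of 'T' bases") is ambiguous and the
run reading is the one consistent with untemplated tails. Reads are
assigned to the gene whose strand matches and whose 3′ window (50 bases
before to 250 after the 3′ end, in transcription direction; 301 bases,
1-based inclusive) contains the read's tail-side end, resolving multi-window
hits to the nearest 3′ end — the operon-level ambiguity this inherits is a
known limitation. GFF3 (1-based inclusive) and BED (0-based half-open)
annotations normalize to the same internal windows; window arithmetic is
oracle-tested.

The per-gene model is a zero-inflated negative binomial over all
observations of the 2×2 design: one log-link mean per condition, a single
zero-inflation probability, a single overdispersion. The likelihood is
maximized in-house (BFGS on log-means, logit-inflation, log-size; iteration
cap 500; multi-start over inflation 0.05/0.3/0.6), with `MASS::glm.nb` as
the independent oracle in the no-inflation limit. Reported per-condition
mean tails are both the NB mean `µ` and `(1−π)µ`; condition contrasts are
Wald tests on the log-mean difference using the inverse observed Hessian —
the significance recipe is unstated in the source procedure, and Wald is
the simplest choice consistent with a fitted covariance. All-zero genes
return inflation 1 with unidentifiable means, flagged.

## Enrichment statistics

Effect sizes are cut into equally populated rank bins (quintiles by
default; ties broken by stable input order, with a warning when all values
tie). Term-by-bin enrichment is the 2×2 odds ratio with +0.5 added to every
cell (the small-sample correction, which keeps degenerate tables finite:
a (10,0;0,10) table gives exactly 441) and the Yates continuity-corrected
chi-square p-value; CIs are Woolf on the corrected table. Overlap
significance between annotation sets uses uniform resampling of the query
from the universe with the add-one estimator `p = (1 + #{null ≥ obs})/(n+1)`,
which never returns 0 and is deliberately conservative under ties. Because
overlap counts are discrete, that conservative estimator is super-uniform
under the null; for calibration checks the `tie_break = "randomized"`
variant splits ties uniformly and is exactly uniform under the null — the
calibration test uses it, while the conservative form remains the default
for reporting. The proportion test is the one-sample z as printed, with an
exact-binomial option; the normal p converges to the exact one from above
as n grows (worst-case relative gap ~8% at n = 1000 over the p0 grid — the
convergence, not a small-n guarantee, is what the suite asserts).

## Reproducibility and problem sizes

Every generator and every stochastic routine takes an explicit seed and is
byte-identical on rerun; `run_stage()` wraps the pipelines with
unknown-key-rejecting configs and writes a resolved-config JSON next to
each run's outputs. The test suite and the acceptance script size their
simulations to what the estimators need rather than to the original
datasets: 5,000 pooled displacements for mixture recovery, 2,500 tracks for
the end-to-end fraction property, 20 fields × 5 spots for focus
precision/recall, 60 genes per decay constant, 10⁴ reads per gene for ZINB
recovery, 200 × 200 permutations for calibration. These sizes make the
recovery targets (weights within ±0.05, fractions within ±0.07, decay
constants within 10%, tail means within 10%) comfortably testable while
keeping a full run to a few minutes.

## Known limitations

- The trajectory simulator has no state switching within tracks, no motion
  blur and no photophysics; fraction recovery under switching dynamics is
  untested.
- Blob segmentation assigns a disk of radius σ√2 per detection — adequate
  for compact polar foci, crude for irregular condensates.
- Droplet areas carry the edge-band bias noted above; absolute-area
  comparisons across very different droplet sizes should use matched
  segmentation settings.
- The ZINB's shared dispersion across conditions is an identification
  choice inherited from the design (16 samples per gene); genes with
  condition-specific overdispersion will show inflated Wald significance.
- The permutation test resamples proteins uniformly, ignoring annotation
  multiplicity; richer nulls (degree-preserving) are out of scope.
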