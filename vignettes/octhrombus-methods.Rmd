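---
title: "Quantitative OCT thrombus typing: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative OCT thrombus typing: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octhrombus)
```

## The problem

Intracoronary thrombus seen on intravascular optical coherence tomography
(OCT) is conventionally typed by eye: *red* (erythrocyte-rich) thrombus
backscatters strongly at its luminal surface and casts a signal-free shadow,
so the abluminal border disappears; *white* (platelet-rich) thrombus
backscatters weakly and lets the vessel wall behind it remain visible.
Visual grading — a six-stage thrombus attenuation score (TAS), 1 = purely
white to 6 = purely red, collapsed to white (1–3) vs red (4–6) — is
subjective and only moderately reproducible. This package implements a
computer image-analysis alternative: per-pixel optical parameters are
estimated inside manually traced thrombus regions, summarised into nine
statistics per channel, aggregated per patient, and used to discriminate red
from white thrombus via ROC analysis, with observer-agreement statistics to
quantify reproducibility.

## The optical model and estimators

All computation happens in the polar domain: rows are A-lines, columns are
depth samples, depth of sample $j$ (0-based) is $j \cdot \Delta z$ with
$\Delta z$ the axial pitch in mm. Under the single-scattering model the
detected intensity along an A-line is

$$I(z) = A\,\beta\,\mu(z)\,\exp\!\Big(-2\int_0^z \mu(u)\,du\Big),$$

with $\mu$ the attenuation coefficient (mm$^{-1}$) and $\beta$ proportional
to the backscatter coefficient. Because the remaining tail integral at depth
$z$ equals $A\beta\,e^{-2\int_0^z\mu}/2$ (for locally constant $\beta$), the
attenuation follows *depth-resolved*, pixel by pixel, from the ratio of the
local intensity to the remaining integrated intensity. On sampled data,

$$\hat\mu_j \;=\; \frac{1}{2\Delta z}\,
  \log\!\Big(1 + \frac{I_j}{\sum_{k>j} I_k}\Big)
  \qquad(\texttt{method = "exact"}),$$

which is the exact discrete solution of the model: on pure Beer–Lambert data
it returns the true $\mu$ with no discretisation bias. The widely used
first-order form $\hat\mu_j = I_j / (2\Delta z \sum_{k>j} I_k)$ is available
as `method = "linear"`; it overestimates by the factor
$(e^{2\mu\Delta z}-1)/(2\mu\Delta z)$, about $+0.3\%$ at
$\mu = 0.6\,$mm$^{-1}$ and $+2\%$ at $4\,$mm$^{-1}$ with
$\Delta z = 5\,\mu$m. The exact form was made the default precisely because
the recovery requirement for the package (within 2% up to
$\mu = 4\,$mm$^{-1}$) is not attainable by the linearised estimator at this
pitch; the two agree to first order everywhere.

The backscatter term is the log-scale residual of the same model: with
transmission estimated from the data as
$T_j = \sum_{k \ge j} I_k / \sum_{k \ge j_0} I_k$ ($j_0$ = catheter offset),

$$b_j = \log_{10}\!\frac{I_j}{\hat\mu_j\,T_j} + \text{gain}.$$

Because $\hat\mu$ and $T$ come from the same tail sums, $b$ telescopes to a
near-constant per A-line proportional to the log of the total collected
light — which is exactly what makes it a backscatter measure: doubling
$\beta$ shifts $b$ by $\log_{10} 2$ while leaving $\hat\mu$ unchanged. The
absolute scale of $b$ is arbitrary; the shipped `gain = 5` only positions the
numbers, and no agreement with any particular vendor's internal scaling is
claimed. Only differences in $b$ are meaningful.

### Numerical choices

* **Noise floor.** A per-frame scalar, by default the median intensity of the
  catheter-interior region (samples before `catheter_offset`), subtracted
  before integration with negative residuals clamped to zero. This stabilises
  the tail integral; the choice of the median (rather than the mean) makes it
  robust to bright catheter reflections.
* **Speckle pre-filter.** Fully developed speckle is exponentially
  distributed with unit mean, whose *median* is $\ln 2 \approx 0.69$ — so the
  median of raw per-pixel ratio estimates would sit ~31% below truth no
  matter how many pixels are pooled. The estimator therefore applies a small
  boxcar filter (default 5×5, `smooth = c(2, 2)`) before estimation. A
  depth-direction boxcar maps $c\,r^j$ to $c' r^j$, so it preserves
  exponential decay rates exactly in the interior and leaves the noiseless
  closed-form results untouched.
* **Tail handling.** The truncated tail integral biases the deepest samples
  upward (by a factor $1/(1-r^m)$ with $m$ samples remaining), so the deepest
  `tail_guard_fraction` (default 10%) of each A-line is flagged invalid
  rather than corrected; region statistics ignore invalid pixels. An
  alternative `tail_mode = "extrapolate"` appends the geometric continuation
  $I_n\,\hat r/(1-\hat r)$ with $\hat r$ fitted on the deepest 32 samples.
* **Outlier cap.** $\hat\mu$ is clamped at `mu_cap = 20` mm$^{-1}$ at valid
  pixels to bound speckle-driven outliers.
* **Degenerate inputs.** All-zero A-lines, zero-denominator pixels and the
  catheter interior are invalid, never exceptions; empty masks yield missing
  excluded fractions; regions with fewer than two pixels report missing
  dispersion/shape statistics (0/0 is *missing*, not zero).

## Region statistics and aggregation

A minimum-attenuation threshold (0.15 mm$^{-1}$ default; 0.5 mm$^{-1}$ as
the sensitivity alternative) filters the traced region once; the same
filtered pixel set feeds all three channels (attenuation, backscatter,
grayscale). Whether the reference software filtered grayscale statistics
through the attenuation threshold is not documented; one shared membership
per run was chosen and is flagged here. Per channel, nine statistics are
computed: median, mean, SD, skewness, kurtosis, and the 5th/10th/90th/95th
percentiles. Percentiles interpolate linearly between order statistics
(type 7); skewness is the moment coefficient $g_1$ and kurtosis is *excess*
kurtosis — chosen because published backscatter kurtosis values for this
application are negative, which is impossible under the raw (Pearson)
convention for a near-symmetric channel. Patient-level values are
pixel-count-weighted means across frames (typically the three cross-sections
with the largest thrombus areas), and the normalized ratio variable is the
weighted 95th-percentile attenuation divided by the weighted median
grayscale intensity. When a cross-section contains several fragments, the
reference fragment is the largest, ties broken toward the higher mean valid
attenuation, then the lowest label.

## Classification and agreement

`roc_curve()` computes the Mann–Whitney AUC with ties counted 0.5, orients
itself so AUC ≥ 0.5 (recording whether low or high values indicate red), and
selects the cutoff maximising Youden's $J$ over midpoints between adjacent
distinct values; $J$ ties break toward higher specificity (compared in exact
integer arithmetic, since floating-point $J$ can split mathematical ties).
Published cutoffs are printed on the observed scale, and the convention used
there is unknown — the midpoint convention is a documented divergence risk.
Classification at a cutoff uses strict inequality; a value exactly at the
cutoff is white. The AUC confidence interval uses the DeLong method for
determinism. Shipped default cutoffs (median attenuation < 0.568 mm$^{-1}$,
mean backscatter < 5.35, mean grayscale < 120.1, ratio > 0.022 mm$^{-1}$
⇒ red) come from clinical data and are configuration defaults, not
properties of the phantoms.

Agreement statistics follow the standard definitions: Bland–Altman limits of
agreement $\bar d \pm 1.96\,\mathrm{SD}(d)$ with the $n-1$ SD, the mean
relative difference as $100\,\bar d$ over the grand mean of the pooled
paired values, ICC(A,1) (two-way, absolute agreement, *single* measures —
each observer contributes one tracing per session, so single measures is the
faithful choice; published tables do not state it) with the F-based
Satterthwaite interval, unweighted Cohen's kappa on the binary labels, and
Spearman correlation as mid-rank Pearson with the $t$ approximation.
"Mean absolute difference" in the reference tables is interpreted as the
mean *signed* difference in absolute units — those tables contain negative
entries, which |d| cannot produce.

## What the phantom generator emulates — and what it does not

`simulate_frame()` evaluates the forward model exactly (exclusive cumulative
attenuation, so a homogeneous noiseless medium reproduces the analytic decay
to rounding), over a geometry of catheter interior, contrast-filled lumen,
an optional thrombus block (angular span × depth span), and vessel wall.
Speckle is unit-mean exponential, multiplying the signal; the noise floor is
multiplied by an *independent* unit-mean exponential draw. That second choice
deviates from treating the floor as a noiseless constant, deliberately: with
a known constant floor the depth-resolved estimator recovers the true
attenuation even deep inside a shadow (the model is exactly invertible), and
the clinically observed *inverse* relationship between attenuation and red
thrombus could never emerge. With a fluctuating floor, shadow pixels carry no
depth decay, so their attenuation estimates are low — the shadow, realised
purely by high $\mu$ rather than painted in, is what drags red-thrombus
medians down, and the 0.5 mm$^{-1}$ threshold then strips those pixels out,
mirroring the published sensitivity analysis.

Class defaults state the phenomenology once: $\mu$ = 1.2 (white) vs 4.5
(red) mm$^{-1}$; $\beta$ = 0.10 (white) vs 0.05 (red) against a wall at
$\mu$ = 2.0, $\beta$ = 0.12. Red's $\mu\beta$ product still makes it ~2×
brighter than white at the luminal surface (the classic bright cap), while
its depth-integrated collected light — which is what the mean grayscale and
the backscatter term respond to — is lower, because total collected light
scales with $\beta$ alone once the beam is fully extinguished inside the
ROI. A cohort draws per-patient $(\mu, \beta)$ from class-wise normals
(SDs ~10%), jitters the thrombus geometry per frame, maps true TAS from the
class half and the within-class attenuation tercile, and perturbs synthetic
observer readings by ±1 step with a configurable confusion probability
(clamped to 1–6).

The generator does **not** emulate: beam profile and focus roll-off,
catheter sheath reflections, non-uniform rotational distortion, residual
blood speckle, Cartesian rendering, or multiple scattering. A green
end-to-end test therefore establishes that the estimators, statistics and
decision machinery behave as designed on physics-faithful single-scattering
data — not that the shipped clinical cutoffs are correct, and not that
absolute backscatter values match any particular scanner or software.

Geometry matters for the emergent inversion: the ROI must span the full
thrombus depth and be deep relative to the red penetration depth
($\approx 1/2\mu \approx 0.11$ mm). With shallow ROIs the bright cap
dominates and red thrombus measures *higher*, not lower — the same
sensitivity the visual TAS has to how much shadow the reader includes.

## Worked example

```{r example, eval = FALSE}
coh <- simulate_cohort(cohort_spec(n_white = 13, n_red = 17, seed = 2026))
df <- analyze_cohort(coh, threshold_mm = 0.15)   # ~40 s on one CPU
roc_curve(df$mean_grayscale, df$class)
#> <roc_result AUC 0.986 (95% CI 0.96-1.00), cutoff 48.17 (lower = red),
#>  sens 1.00 spec 0.92, n = 17 red / 13 white>
roc_curve(df$mean_backscatter, df$class)
#> <roc_result AUC 1.000 (95% CI 1.00-1.00), cutoff 6.899 (lower = red),
#>  sens 1.00 spec 1.00, n = 17 red / 13 white>
spearman(df$mean_grayscale, df$tas)$rho
#> [1] -0.7603527
```

Lower mean grayscale and backscatter indicate red thrombus on this synthetic
cohort, and both correlate inversely with the six-stage TAS — the directions
the method is designed to reproduce.

## Known limitations

* The backscatter term's absolute scale is arbitrary (gain-shifted); only
  comparisons within one processing configuration are meaningful.
* The depth-resolved estimator assumes locally constant $\beta$ below each
  pixel; a brighter wall behind a traced thrombus biases in-thrombus
  estimates downward by the $\beta$ ratio. This is a property of the method,
  not of the implementation, and is visible in the homogeneous-recovery
  tests.
* Fragment selection, thresholds and cutoffs are reproductions of a
  described procedure; no clinical data ships with the package, so clinical
  values can only be validated against new data.
* TIFF support covers baseline grayscale uncompressed stacks (8/16-bit
  integer, 32-bit float), which is sufficient for the package's own exports
  and typical research exports, not the full TIFF 6.0 feature set.
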