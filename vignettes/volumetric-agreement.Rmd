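---
title: "Volumetric agreement limits for automated segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric agreement limits for automated segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volagree)
```

## The measurement problem

Automated segmentation models for structures that are monitored
volumetrically — the motivating case is vestibular schwannoma on
contrast-enhanced T1 MRI — are usually judged by geometric overlap and
surface-distance metrics (Dice, ASSD, HD95). Those metrics say how well
a contour matches a reference contour; they do not say whether the
*volume* the model reports can be trusted for the clinical task, which
is detecting change over time against the backdrop of ordinary human
inter-observer variability. A model can have an excellent Dice score
and still produce volumes that drift systematically outside what a
panel of human annotators would ever produce.

`volagree` separates the two questions. The geometric layer
(`dice()`, `assd()`, `hd95()`, `rve()`, `pairwise_metrics()`) scores
label maps. The clinimetric layer quantifies human inter-observer
variability as *limits of agreement with the mean* (LOAM), makes those
limits volume-dependent with a sliding window, and asks of a candidate
annotator — typically an AI model — two questions:

1. Per tumor, does the candidate's volume deviate from the human
   consensus by more than the upper agreement limit?
2. If the candidate is added to the observer panel as one more
   annotator, do the re-estimated agreement limits stay statistically
   indistinguishable from the human-only limits?

## The LOAM model

For subject $i$ and observer $j$, with volumes $V_{ij}$ and subject
consensus $\bar V_i = \frac1m \sum_j V_{ij}$, the analysis works on
percent deviations

$$ d_{ij} = 100\,\frac{V_{ij} - \bar V_i}{\bar V_i}, $$

which by construction sum to zero within each subject. The remaining
structure is a two-way decomposition

$$ d_{ij} = b_j + e_{ij}, \qquad
   b_j \sim N(0, \sigma^2_{\mathrm{obs}}), \quad
   e_{ij} \sim N(0, \sigma^2_{\mathrm{res}}), $$

with a systematic observer effect $b_j$ (a rater who consistently
contours generously) and residual disagreement $e_{ij}$. `loam()`
estimates the two components by the ANOVA method of moments on the
balanced design: the residual mean square estimates
$\sigma^2_{\mathrm{res}}$ directly and the observer mean square has
expectation $n\,\sigma^2_{\mathrm{obs}} + \sigma^2_{\mathrm{res}}$.
Negative moment estimates of $\sigma^2_{\mathrm{obs}}$ are truncated at
zero, the standard safeguard that keeps the limit real-valued.

The limit of agreement with the mean is

$$ \mathrm{LOAM} = z \sqrt{\tfrac{m-1}{m}
   \left(\sigma^2_{\mathrm{obs}} + \sigma^2_{\mathrm{res}}\right)},
   \qquad z = 1.96 \text{ by default}. $$

The factor $(m-1)/m$ appears because a deviation *from the mean of m
observers, the observer itself included* carries only that share of
the total variance. $z$ is configurable; 1.96 (the two-sided normal
95% level) is the default because the observer count, not the normal
quantile, dominates the uncertainty at panel sizes like $m = 5$.

Deviations are analysed on the percent scale rather than on log
volumes: the quantities reported downstream (deviation limits,
exceedances in percentage points) live on that scale, and for the
error magnitudes involved (a few percent) the two scales agree to
first order.

## Confidence intervals: why a generalized pivotal construction

With five observers, $\sigma^2_{\mathrm{obs}}$ is estimated from what
is effectively four degrees of freedom, so the sampling distribution of
the LOAM estimate is strongly right-skewed and very wide. This is the
dominant design constraint for the whole pipeline and it drove one
deliberate choice.

A plug-in parametric bootstrap (draw $b_j$ and $e_{ij}$ from the
*estimated* normals, refit, take the percentile interval) treats the
estimated components as if they were true, ignores exactly that
four-degree-of-freedom uncertainty, and in our calibration simulations
covers the true LOAM well below the nominal 95%. The default
`ci = "gpq"` therefore uses a generalized-pivotal-quantity
construction instead: the two observed mean squares are inverted
through their scaled chi-square sampling distributions
($\mathrm{MS} \sim E[\mathrm{MS}]\,\chi^2_{\mathrm{df}}/\mathrm{df}$
for the balanced normal model), each Monte Carlo draw is mapped through
the LOAM formula, and the 2.5/97.5 percentiles of the draws form the
interval. The test suite verifies by simulation (500 panels at the
study design, 500 draws each) that empirical coverage lies within
[92%, 98%]. The plug-in bootstrap remains available as
`ci = "bootstrap"` for comparison.

An honest consequence worth stating plainly: at $m = 5$ the upper CI
bound — the *upper agreement limit* used as the comparability
threshold — sits typically 40–70% above the LOAM point estimate. That
is not conservatism of the method; it is the information actually
available from five observers. All Monte Carlo CIs are seeded, and
seeded fits restore the caller's RNG stream.

## The volume-dependent band

Inter-observer variability in tumor contouring is larger, in relative
terms, for small volumes. `sliding_window_loam()` sorts subjects by
consensus volume, fits `loam()` on each contiguous window
(`window_size = 40`, `step = 1` by default), and anchors each fit at
the window's median volume. Between anchors the LOAM and CI curves are
interpolated linearly on the log-volume axis (volumes span orders of
magnitude, and relative error structure is closer to linear in log
volume); beyond the outermost anchors the curves are extrapolated as
constants, so the band is defined on the whole observed range and
`upper_agreement_limit()` never extrapolates a trend it has not seen.
A window of 40 keeps roughly 160 residual degrees of freedom per fit
at the 100-subject design — small enough to resolve the volume trend,
large enough for stable per-window components. Ties among anchor
volumes are averaged before interpolation; a full-width window yields
a single-anchor, constant band equal to the global fit.

## Classifying a candidate annotator

`classify_candidate()` computes the signed deviation
$\Delta V\% = 100\,(V^{\mathrm{cand}}_i - \bar V_i)/\bar V_i$ against
the *human* consensus and compares it with the upper agreement limit
at $\bar V_i$. The default rule is deliberately one-sided — a
candidate is comparable when $\Delta V\%$ is *below* the upper limit —
mirroring the clinical framing in which over-segmentation against the
human consensus is the salient failure. The documented asymmetry is
that gross under-segmentation ($\Delta V\% \ll 0$) is never flagged by
this rule; `rule = "two_sided"` compares $|\Delta V\%|$ instead and is
the safer choice outside that framing. Exceedances are reported in
percentage points (deviation minus limit), only for incomparable
subjects, and the quartile summary stratifies by consensus volume with
boundary ties assigned to the lower quartile.

`refit_with_candidate()` appends the candidate as an $(m{+}1)$-th
observer column and recomputes everything, consensus means included —
the candidate shifts the consensus, which is precisely the point of
the re-estimation. `compare_bands()` then evaluates both bands' CIs on
a shared log-spaced grid and reports the fraction of the volume
spectrum on which the intervals intersect. This is a descriptive
comparison, not a hypothesis test: full overlap is read as "the new
limits are statistically indistinguishable", vanishing overlap as a
real change in inter-observer variability.

## What the synthetic generator emulates — and what it does not

`simulate_volume_matrix()` reproduces the *design* of the motivating
study: 100 subjects, 5 observers, lognormal true volumes with median
903 mm³ and log-SD 2.06 (chosen so the interquartile range of a drawn
panel matches the roughly 190–3,100 mm³ spread of the emulated test
set), and multiplicative observer error
$V_{ij} = T_i \exp(b_j + e_{ij})$ with $\sigma_{\mathrm{obs}} = 0.03$
and $\sigma_{\mathrm{res}} = 0.05$ on the log scale. Those two
defaults were chosen to put the true LOAM near 10%, the magnitude
regime the volumetric-agreement literature reports for this task; the
small-sigma closed form
$100\,z\sqrt{\frac{m-1}{m}(\sigma^2_{\mathrm{obs}}+\sigma^2_{\mathrm{res}})}
\approx 10.22\%$ is returned with every draw as the ground truth for
estimator checks. Multiplicative error makes percent deviations
volume-free by default; the volume dependence that the sliding window
exists to detect is injected explicitly (`volume_dependent_noise`
inflates $\sigma_{\mathrm{res}}$ below a volume threshold), so the
band's behaviour can be tested with the phenomenon switched on and
off. The default candidate draws its error SD as
$\sqrt{\sigma^2_{\mathrm{obs}}+\sigma^2_{\mathrm{res}}}$, making it
marginally indistinguishable from one more human.

One classification check uses a deliberately lower-variability panel
($\sigma_{\mathrm{obs}} = 0.015$, $\sigma_{\mathrm{res}} = 0.035$):
the scenario it probes is a +25%-biased candidate facing upper
agreement limits in the 10–12% range, and with the honest GPQ
intervals the default panel's upper limits land well above that range;
the smaller sigmas place the band, not the threshold, where that
scenario specifies. The assertion thresholds themselves are never
derived from the measured values.

What the generator does *not* emulate: real tumor morphology, rater
drift over time, non-lognormal volume distributions, missing
annotations, or any spatial correlation between observers' errors.
Passing tests therefore demonstrate that the estimators and decision
rules behave correctly under the stated error model — not that any
particular clinical dataset satisfies that model.

`simulate_observer_masks()` supplies the geometric layer's end-to-end
fixture: voxelized ellipsoids (analytic volume available for
discretization checks) with, per observer, a smooth random radial
boundary displacement — white noise on the (θ, φ) sphere grid,
Gaussian-smoothed with angular scale `smoothness`, scaled to
`boundary_noise_sd` mm. Ellipsoids are shapes, not schwannomas; the
phantoms exist to exercise surface metrics, NIfTI round trips and the
reporting pipeline, not to look like pathology.

## Geometric conventions

Fixed so that exhaustive oracles in the test suite are exact, since
published conventions differ between toolkits:

* Surface = foreground voxels with at least one of six face-connected
  neighbours background, the array border counting as background.
* Distances are Euclidean between voxel centers in physical mm; no
  mesh extraction.
* HD95 is the 95th percentile, with linear interpolation between order
  statistics, of the *pooled* directed distance set (both directions
  concatenated) — the same set whose mean is the ASSD — rather than
  the maximum of two directed percentiles. Published numbers computed
  under other conventions can differ slightly on the same masks.
* Dice of two empty masks is 100%, of one empty mask 0%; ASSD/HD95 on
  an empty mask raise an error, and the batch layer records them as
  missing. An empty prediction is a detection failure and must
  surface, never score 0 mm.
* RVE is reported as an absolute value; signed information lives in
  $\Delta V\%$.
* Masks of one subject must share lattice and spacing; resampling is
  upstream preprocessing and is out of scope.

## Numerical choices and degenerate inputs

* All percentiles (CIs, HD95, quartile boundaries) use the linear
  interpolation convention of `quantile(type = 7)`.
* A panel with zero variability yields LOAM 0 with a degenerate [0, 0]
  interval rather than a Monte Carlo interval around 0.
* Variance components are truncated at zero before the square root.
* Windows require at least 10 subjects; the complete-design
  requirement (no missing cells, all volumes positive) is enforced at
  construction.
* Every seeded entry point derives per-window/per-replicate seeds
  deterministically from the user seed, and run directories record the
  resolved configuration, seed and package version as JSON, so every
  CSV output is byte-reproducible.

## Problem sizes used by the test and acceptance runs

The simulation-based checks run at the emulated study design (n = 100,
m = 5) with 50–500 replicates per property, window step 10 and 200–500
Monte Carlo CI draws — sizes chosen to keep each property's Monte
Carlo error well inside its assertion margin while the full suite
stays in the tens of seconds. The oracle comparisons for the geometric
metrics use 50 random mask pairs on lattices up to 12³, where the
exhaustive all-pairs oracle is exact and cheap.

## Known limitations

* Complete balanced designs only; no missing-data LOAM, no intraclass
  correlation or kappa-family statistics.
* The one-sided default rule inherits the asymmetry discussed above.
* With $m = 5$ the upper agreement limit carries large Monte Carlo-free
  sampling uncertainty; users comparing against externally published
  limits should expect our honest intervals to be wider than plug-in
  ones.
* The band's constant extrapolation means the limit at volumes outside
  the observed range is the nearest window's, which is defensible
  interpolation policy but not evidence about unobserved volumes.
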