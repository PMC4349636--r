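---
title: "Methods: Poisson-partition linkage estimation and phase calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson-partition linkage estimation and phase calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropphase)
```

## The measurement and its model

A duplex droplet-PCR well partitions a genomic DNA sample into on the
order of 20,000 droplets of 0.85 nL, with fluorescent probes reading one
allele at each of two loci. After thresholding, every droplet falls in one
of four classes — double-positive, A-only, B-only, double-negative — and
those four counts are the entire sufficient statistic this package works
from.

The model treats the sample as a mix of three molecular species: fragments
carrying only sequence *A*, only sequence *B*, and fragments physically
carrying both (*A–B* linked). Molecules are dilute and partition
independently, so each species' count per droplet is Poisson with mean
$\lambda_{fA}$, $\lambda_{fB}$, $\lambda_{AB}$. The class probabilities
follow from the Poisson zero classes:

$$P(A^-) = e^{-\lambda_A},\quad P(B^-) = e^{-\lambda_B},\quad
  P(A^-B^-) = e^{-(\lambda_{fA}+\lambda_{fB}+\lambda_{AB})},$$

with $\lambda_A = \lambda_{fA}+\lambda_{AB}$ the total rate of A-bearing
molecules. Inverting these gives the estimator in `estimate_lambdas()`:
the two channel-negative fractions identify $\lambda_A$ and $\lambda_B$,
and the *excess* of double negatives over the independence product
$e^{-\lambda_A}e^{-\lambda_B}$ identifies the linked rate,
$\hat\lambda_{AB} = \hat\lambda_A + \hat\lambda_B + \ln(n_{nn}/N)$.
These are the maximum-likelihood estimates under multinomial sampling of
the four classes. Linked molecules *increase* double positives relative to
chance; equivalently (and this is the algebraically convenient form) they
increase double negatives relative to the product of the channel
negatives.

Two reporting quantities derive from the rates. Concentrations in
copies/µL are $\lambda / v$ with $v$ the droplet volume (default
0.85 nL, configurable). Percent linkage is

$$\%\text{linkage} = 100\,\frac{\lambda_{AB}}{\lambda_{\text{anchor}}},$$

the percentage of molecules carrying one assayed sequence that still
physically carry the other. It is invariant to DNA input concentration
(both numerator and denominator scale with input), which makes it a
property of the DNA sample rather than of the well.

**Anchor choice.** The definition is inherently asymmetric ("molecules
containing *A* that also contain *B*"), but the two loci of a duplex are
near-equimolar in genomic DNA. The default anchor is the *smaller* of
$\hat\lambda_A, \hat\lambda_B$: it is symmetric in the two loci, keeps the
ratio bounded by 100%, and is conservative (it can only make linkage look
larger, never hide it). `anchor_rule = "locus_A"` / `"locus_B"` give the
literal asymmetric definitions.

**Clamping.** Under the null, sampling noise makes $\hat\lambda_{AB}$
negative about half the time. Reported estimates clamp at zero (percent
linkage lives on [0, 100]); the raw value is retained internally and used
when the bootstrap needs an unbiased generating model.

## Significance, intervals, detection limit

`linkage_chisq_test()` is the Pearson chi-square on the 2×2 table, 1 df,
no continuity correction — class counts here are in the thousands, where
the correction is immaterial. Linkage signals are routinely astronomical
(statistics in the thousands), so the p-value is computed on the log scale
(`pchisq(log.p = TRUE)`); `p_value` underflows to zero below ~1e−308 and
`log10_p` stays informative (cis wells at a few kb give
$p \approx 10^{-3000}$).

`linkage_confidence_interval()` is a parametric bootstrap: class counts
are resampled from the multinomial implied by the fitted rates (using the
*unclamped* linked rate, so null intervals are not biased upward), percent
linkage is re-estimated per replicate, and the percentile interval is
returned. 1000 replicates by default, fully determined by the seed in
`partition_config()`. One honest consequence worth knowing: because the
four-class model is saturated, the fitted multinomial equals the observed
class proportions, so this coincides with a multinomial resampling
bootstrap of the observed table. Coverage at the study's loading is
checked empirically in the test suite (200 outer simulations at nominal
95%, required within 92–98%).

`min_detectable_linkage()` quantifies when a cis sample becomes
indistinguishable from trans: it bisects over percent linkage, simulating
wells (common random numbers across grid points, for a smooth power curve)
until it finds the smallest value at which the chi-square test at level
α rejects with the requested power. At 20,000 droplets and 0.17
copies/droplet/locus, α = 10⁻³, power 0.95, the threshold is below 5%.
If even 100% linkage cannot reach the requested power, the function warns
and returns `NA` ("not detectable").

**Degenerate inputs.** A well with no double-negative droplets (or no
negatives in one channel) is a hard error, not a warning: the rate
estimate diverges and nothing downstream is meaningful. The remedy is
diluting the sample, not massaging the numbers.

## Amplitude classification under cross-reacting probes

Allele probes often fluoresce, at reduced intensity, on the non-targeted
allele. Each channel then shows up to four amplitude levels —
target-only > target+non-target mixture > non-target-only > empty — and a
two-channel well shows up to 16 droplet populations. Phasing only needs
the binary question per channel: does the droplet contain the *targeted*
allele? That means one cut per channel, between the non-target and
mixture levels, collapsing the 16 populations into the four classes.

`fit_thresholds()` fits the levels per channel with an equal-variance
one-dimensional Gaussian mixture: EM initialized from evenly spaced
centers across the amplitude range, component count chosen by BIC over
1–4, run on an evenly rank-spaced subset of 2,000 droplets so cost is
independent of well size. A mixture model is the right tool here because
the level populations are extremely unbalanced — at typical loading the
empty level holds ~84% of droplets and the mixture level well under 1% —
and centroid-based clustering (k-means) provably prefers splitting the
huge empty cluster to separating the small upper levels, which would put
the cut *below* the non-target level and count locus occupancy rather
than targeted-allele occupancy (making even trans samples look linked).
The likelihood, by contrast, gains enormously from giving the small,
well-separated upper levels their own components and almost nothing from
splitting a single Gaussian.

The cut is then: four fitted levels → midpoint of the 2nd and 3rd sorted
level means; two or three levels (e.g. no cross-reactivity, or an
unpopulated mixture level) → midpoint of the widest gap between adjacent
level means; a single level (an all-empty well) → above the observed
maximum, so every droplet is negative. Droplets exactly on a cut are
called negative — conservative against manufacturing false linkage.
Classification is invariant under affine rescaling of a channel when
thresholds are refitted, and manual cuts can always be supplied via
`channel_thresholds()`.

With the default fluorescence geometry (levels 1000/2500/6000/8000, noise
SD 300) the smallest inter-level gap is ~5 noise SDs, and the per-droplet
misclassification rate is far below the 0.1% the test suite requires.

## Fragmentation and the distance model

Extraction breaks chromosomes at essentially random positions, which the
package models as a Poisson break process: two sequences separated by
$d$ kb stay on one fragment with probability $e^{-d/L}$, where $L$ is the
mean intact fragment scale. This is the unique memoryless model consistent
with an exponential distance decay, and it makes expected percent linkage
of cis alleles $100\,e^{-d/L}$. `fit_fragment_survival()` recovers $L$
from a measured (distance, %linkage) series by nonlinear least squares on
the percent scale (unweighted by default; log-scale fitting available),
with the curve forced through 100% at $d = 0$ — the natural boundary
condition, since a sequence is always "linked" to itself. Replicates at a
distance are averaged first; control points and degenerate 0%/100% points
are excluded with a warning; a single usable point uses the closed form
$L = d / \ln(100/\text{pct})$. The calibration 42% at 60 kb gives
$L = 69.16$ kb and predicts 4.8% at 210 kb.

Real extracts are not single-scale; the simulator accepts a two-component
mixture of fragment scales (`mean_intact_kb` + `weights`) to mimic, e.g.,
silica-column vs precipitation chemistries; the default is a single
component.

## Phase calling

A duplex is **linked** when both the statistical and the practical bar are
met: $p < \alpha$ (default 10⁻³) *and* %linkage ≥ 2%. The 2% floor is the
empirical upper bound of the unlinked background at study loading — the
test suite verifies that the median estimated %linkage across simulated
trans wells is far below it, and the floor keeps a well with gigantic
droplet counts from turning a biologically meaningless 0.3% into a
"significant" call. Both knobs are configurable.

A **quad-duplex** design assays all four allele pairings (AB, Ab, aB, ab)
of a compound heterozygote. Exactly one complementary pair can be truly
linked, and the call uses the *joint* pattern: AB+ab linked with Ab+aB
unlinked yields `cis_AB` (haplotypes A–B / a–b); the mirror pattern yields
`cis_Ab`; anything else is `indeterminate` — all-unlinked flags DNA too
fragmented to phase, and any contradictory pattern (which would imply two
haplotypes sharing an allele) is never resolved by majority vote, because
the redundancy exists precisely to catch such failures. Every
non-indeterminate call's haplotypes carry opposite alleles at both loci by
construction, and this complementarity is asserted.

`trio_expected_phase()` provides the orthogonal truth for validation:
when parental genotypes force which allele each parent transmitted at
each locus, the child's phase follows; if both parents are double
heterozygotes (or one locus is otherwise ambiguous) it returns `unknown`,
and non-Mendelian genotype combinations are an error.

## The simulator and what passing means

`simulate_experiment()` composes the generative chain: diplotype →
fragmentation split (intact probability $e^{-d/L}$ per haplotype) →
independent Poisson partitioning of every species → per-channel
four-level amplitude rendering with Gaussian noise — with ground truth
(species means, per-droplet occupancy, true counts, true %linkage)
attached, and seeded end to end (one seed per well; identical
configuration and seed reproduce amplitude CSVs byte-identically).

Defaults are the study conditions: 20,000 droplets/well, 0.85 nL,
100 copies/µL per haplotype (≈ 0.17 molecules/droplet/locus, the typical
~10–20 ng genomic DNA loading), fragment scales 69–72 kb as measured for
precipitation-extracted DNA, and the fluorescence geometry above.

The simulator deliberately omits several features of real data: PCR
efficiency variation and "rain" (droplets between clusters), droplet
volume variability, 2-D cluster shape and rotation, multi-well amplitude
drift, and partial/coalesced droplets. Passing tests therefore shows the
statistical machinery is correct under the partition model, not that the
classifier would survive heavy rain — on such data the manual threshold
override is the honest path.

## Numerical choices and problem sizes

All randomness flows through explicit seeds (`withr::with_seed`), never
global state; derived seeds stay far below 2³¹. The test suite exercises:
estimator round-trips on exact expected fractions (tolerance 1e−12);
consistency at 10⁶ sampled droplets (within 3 delta-method SEs);
Kolmogorov–Smirnov uniformity of 500 null p-values; bootstrap coverage
over 200 outer simulations; fragment-scale recovery within 15% on a
21-well simulated mile-marker series; 14 trio assays and 13 quad-duplex
scenarios end-to-end at full 20,000-droplet scale; and 100-plus simulated
trans wells for the null background. These sizes keep the full suite
under half a minute while leaving every check several standard errors of
headroom.

## Known limitations

Single-well analysis only (no multi-well merging); two loci per call
(longer ranges by transitive chaining of pairwise calls, a usage pattern
rather than an operation); no modeling of probe dropout or of the
fragment-length distribution beyond the (optionally two-component)
exponential survival scale; duplicate wells are reported side by side,
not pooled.
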