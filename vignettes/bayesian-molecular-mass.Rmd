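---
title: "Concentration-independent molecular mass from SAXS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration-independent molecular mass from SAXS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(saxsmm)
```

## The problem

The molecular mass (MM) of a protein in solution is one of the first
quantities a SAXS experiment must deliver: it distinguishes monomers from
oligomers, flags aggregation and degradation, and anchors all subsequent
modelling. Concentration-dependent MM determination needs the sample
concentration, the intensity on an absolute scale, and a partial specific
volume — quantities that are frequently unavailable or unreliable, notably
for in-line SEC-SAXS where the eluting concentration is unknown.

`saxsmm` implements the concentration-independent alternative: four
estimators that require nothing beyond a single background-subtracted 1-D
profile $I(s)$, $s = 4\pi\sin\theta/\lambda$, and a Bayesian consensus that
combines them into a single MAP estimate with a 90% credibility interval.

## The four estimators

All four are deliberately invariant to the overall intensity scale, which
removes any dependence on calibration or units.

**Porod-invariant mass (`mm_qp`).** The Porod invariant
$Q_p = \int_0^\infty s^2 I(s)\,ds$ fixes, for a uniform-density particle,
the excluded volume $V_p = 2\pi^2 I(0) / Q_p$; the mass follows by the fixed
empirical specific volume, $\mathrm{MM\,[Da]} = V_p\,[\mathrm{\AA^3}] / 1.37$.
Neither integration limit is tabulated: the low-angle gap is closed
analytically with the Guinier form, the data are integrated up to
$s R_g = 8$, and the remainder is an analytic Porod tail (below).

**Corrected apparent volume (`mm_mow`).** Integrating the $I/I(0)$-normalized
curve only up to a fixed $s_{max}$ (default 0.3 Å⁻¹) yields an apparent
volume $V' = 2\pi^2 / Q'$ that underestimates the true volume in a
size-dependent way. A single log-log affine correction
$\log V = a \log V' + b$ is fitted on the synthetic training corpus
(the analogous published correction-factor tables are not re-used here),
and mass follows with the protein mass density
$\rho = 0.83\times10^{-3}$ kDa Å⁻³.

**Volume of correlation (`mm_vc`).**
$V_c = I(0) / \int_0^{s_{upper}} s\,I(s)\,ds$ (units Å², default
$s_{upper} = 0.3$ Å⁻¹) is related to $V_p$ through the correlation length
$l_c$: $V_c = V_p / (2\pi l_c)$. The ratio $Q_R = V_c^2 / R_g$ is
proportional to the MM on a log–log plot; the power law
$\mathrm{MM} = (Q_R / c)^k$ is fitted on the training corpus.

**Size-and-shape neighbours (`mm_ss`).** The normalized-Kratky apparent
volumes at $sR_g = 3, 4, 5$ form a size-free shape descriptor; together with
$R_g$ they span a four-dimensional size-and-shape space populated by the
training particles. The estimate is the inverse-distance-weighted mean mass
of the five nearest neighbours (self-excluded — ranks 2 to 6 — when a
training particle is scored against an index that contains it).

## The Bayesian consensus

The mass axis is discretized into bins (below), each bin a hypothesis $H$.
For each method $m$, a likelihood table is trained by 2-D-histogramming
(estimate, truth) pairs from the training corpus, adding a Laplace
pseudo-count of one to every cell, and normalizing each evidence row. For a
new profile the posterior is the product over the *present* methods,
$P(H \mid E) \propto P(H) \prod_m P(E_m \mid H)$, accumulated in log space;
a method that fails on a profile simply contributes nothing. The point
estimate is the centre of the MAP bin (ties resolved toward the lowest
mass, a deterministic rule), reported with the MAP bin's posterior mass as
a probability score and with a credibility interval: bins are accumulated
in decreasing posterior order until 90% of the mass is reached, and the
contiguous envelope of that set is reported — it always contains the MAP
bin, and matches the way a single uncertainty bar is drawn per case.

For sequential frames (SEC-SAXS), `forward_prior()` re-uses the previous
frame's posterior as the next prior, mixed with a 1% uniform floor so that
a bin suppressed by one frame can recover later. A database-shaped
(non-uniform) prior is supported via the `prior` argument but is not the
default, as it brings no consistent improvement.

### Binning

Bins follow the training mass distribution: the central 90% of the log-mass
distribution is cut into equal-count (quantile) bins — narrowest where
masses are densest, and guaranteeing the uniform per-bin structure count
the likelihood tables rely on — while the 5% extremes on each side are cut
into equal-width bins. The axis is clamped at 0.7 kDa and 1300 kDa; masses
outside map to the first/last bin. Defaults: 100 bins, of which 10 per
tail. The tail allocation is deliberately larger than the tails' 5% mass
share: tail bins cover sparse mass ranges, and keeping them narrow bounds
the error introduced when an estimate slips by one bin near the edges of
the calibrated range. Bin centres are geometric means of the bin edges
(the axis is log-structured). Performance comparisons use *binned* relative
errors — differences between bin centres — since sub-bin precision is not
experimentally meaningful.

## The synthetic corpus

Training and validation use a fully synthetic stand-in for a
structure-database-derived corpus, built from analytic orientationally
averaged form factors (no atomic coordinates): solid sphere (compact),
prolate ellipsoid (extended, axial ratio 2.5–6), oblate ellipsoid (flat,
0.15–0.35), torus (ring, radius ratio 2–4), concentric two-density sphere
(compact-hollow, cavity 0.4–0.6 at half density), spherical shell
(hollow-sphere, cavity 0.65–0.85) and the Debye Gaussian-chain function
(random-chain). Masses are log-uniform over 7–300 kDa; solid-shape
geometry is sized so volume × 0.83 × 10⁻³ kDa Å⁻³ equals the mass; chains
take $R_g = 2.54\,N^{0.522}$ Å with $N$ the residue count — the empirical
scaling of denatured proteins — since a chain has no meaningful
uniform-density volume. The compact class is doubled in count, echoing the
globular skew of structural databases. Profiles use the conventional
simulated-curve grid: 1001 points to 0.6 Å⁻¹. A 3% Gaussian polydispersity
of the overall size removes the exact form-factor zeros of the
high-symmetry shapes (which would make $\ln I$ undefined at isolated
points); it is implemented exactly through the similarity scaling
$I(q; xR) = x^6 I(xq; R)$.

Noise: the error template $\sigma(s) = a\sqrt{I(s) + 10^{-3} I_0}$
reproduces the characteristic growth of relative noise at high angles; $a$
is set so that median$(I)$/median$(\sigma)$ equals the target SNR exactly
(levels 32, 11, 4, 2, 1). Buffer mismatch adds or subtracts a constant:
$n \times$ the mean intensity over 0.4–0.6 Å⁻¹, $n \in \{0.1, 0.2, 0.4,
0.6, 0.9\}$, applied to the SNR = 4 profile of each test particle. Training
uses the ideal curves plus the four milder noise levels; the test split
sees all 16 conditions (ideal, 5 SNRs, 10 mismatch variants).

**What the generator does not emulate.** Atomic-detail scattering (internal
density fluctuations, hydration shell) is absent, so high-angle intensities
are lower, relative to $I(0)$, than for real protein curves: the
buffer-mismatch perturbation is correspondingly gentler here than on
database-derived curves, and Porod-type estimators are more noise-robust
than their field implementations. Passing tests therefore demonstrate the
machinery and its calibration on this corpus, not instrument-level realism.
Interparticle structure factors and instrumental smearing are likewise out
of scope.

## Numerical choices

* **Quadrature.** Trapezoidal on the tabulated grid everywhere; the
  untabulated $s \to 0$ segment of every invariant is integrated
  analytically with the fitted Guinier form.
* **Porod tail.** Under the Porod law the cumulative invariant approaches
  its limit as $Q(s) = Q_\infty - K/s$. The tail beyond $sR_g = 8$ is
  obtained by fitting that form by least squares over the last 55% of the
  integrated range. Fitting the *cumulative* self-averages the form-factor
  oscillation (a pointwise fit of $s^4 I$ is phase-sensitive when the
  window spans less than a full oscillation) and damps noise. Validated
  against dense-grid quadrature of the closed-form sphere (0.7–1.3%
  agreement with $\tfrac{4}{3}\pi R^3$) and the 3:1 ellipsoid (within 3%).
  For strongly anisometric or hollow bodies the Porod regime is not reached
  at $sR_g = 8$ and the excluded volume deviates more — the known weakness
  of Porod-volume masses for such shapes; profiles ending before
  $sR_g = 8$ are integrated to their end and flagged `truncated`.
* **Automatic Guinier range.** The validity bound $sR_g \le 1.3$ is
  enforced by iterating the window end to self-consistency; a small set of
  trimmed start points is scored by weighted-fit $R^2$ with a shortness
  penalty, ties toward the longer, lower-angle window. Points are weighted
  by $(I/\sigma)^2$ when errors are present. The unweighted Guinier slope
  of a sphere carries an intrinsic $+0.7\%$ $R_g$ bias at a window reaching
  $sR_g = 0.8$ (the curvature of $\ln I$), shrinking as the window
  tightens; tests account for it.
* **Estimator calibrations.** The MoW correction and the $V_c$ power law
  are fitted by least absolute deviations (IRLS). These are
  globular-protein laws; with all seven shape classes in training, ordinary
  least squares lets chains and thin shells tilt the line and biases the
  calibrated estimators by 15–20% even for globular particles.
* **kNN standardization.** Coordinates are z-scored ($R_g$
  log-transformed first) — the axes are incommensurate. Alternatives
  (median/MAD scaling, log-transformed $V'$) were evaluated and bring no
  improvement; plain z-scoring is kept. Inverse-distance weights
  $w_i = 1/(d_i + 10^{-9})$ with an exact-match short-circuit.
* **Degenerate inputs.** Negative intensities are accepted everywhere they
  can legitimately occur (subtracted data); a non-positive $Q_p$ or
  $\int s I$ aborts the affected estimator, which the evidence layer
  records as an absent method rather than a failed profile.

## Problem sizes and expectations at this scale

Likelihood tables of this kind are, in production settings, trained on
hundreds of thousands of structure-derived curves; this package's bundled
experiments run on a desk-scale corpus — 2000 particles (compact doubled), 80/20 particle-level
split, likelihood tables from ~8000 training profiles — chosen as the
largest corpus that keeps the full train-plus-evaluate cycle inside a few
minutes on one CPU. Two consequences are worth stating plainly:

* Consensus accuracy is class-dependent. Compact, extended, flat and
  compact-hollow particles reach 85–99% of cases within 10% binned error;
  hollow spheres (~50%) and random chains (~65%) are intrinsically hard:
  the shell's $V'$ triplet barely encodes its cavity fraction, so mass at
  fixed $(V', R_g)$ is underdetermined by a factor of ~2 across the cavity
  range, and chains are near-degenerate with high-aspect ellipsoids in the
  entire 4-D coordinate set. Pooled over the balanced corpus this yields
  ~80–84% of cases within 10% — lower than on a globular-dominated corpus,
  where the hard classes are rare.
* Interval calibration is robust: 85–90% of ideal-condition cases contain
  the truth in the 90% interval, consistent with mild overconfidence from
  finite likelihood tables.

## Known limitations

* The two-density compact-hollow body has $V_p \ne$ material volume by
  construction (the invariant weights density squared); its Porod-route
  mass is accordingly biased — real physics, absorbed by the likelihood
  tables, but visible in raw estimates.
* The fixed divisor 1.37 Å³/Da exceeds the dry specific volume 1/0.83 =
  1.21 Å³/Da; on this corpus (mass = dry volume × density by construction)
  the Porod route is therefore ~12% low for compact bodies before the
  tables correct it. On database-derived curves the gap is filled by
  hydration-shell and fluctuation contributions to the apparent volume.
* All calibrations assume unmodified proteins: bound metals, glycans,
  lipids or nucleic acids change the mass density and break the
  volume-to-mass conversions.
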