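---
title: "Ratiometric Raman phenotyping and heterogeneity quantification: methods"
author: "RamanPIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric Raman phenotyping and heterogeneity quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanPIR)
```

# Scope

RamanPIR implements a label-free, univariate phenotyping workflow for single
cells measured by Raman microspectroscopy in the biological fingerprint
region (600–1800 cm⁻¹), together with the statistics needed to decide when a
population average has converged and how heterogeneous a population is.
The workflow is:

1. average statistically many baselined spectra per population, tracking the
   per-channel SD and SE envelopes;
2. extract band intensities by multi-Gaussian fitting over windowed,
   locally-baselined regions, with amplitude uncertainties;
3. form peak intensity ratios (PIRs) with propagated SEs, classify each band
   pair's discriminating power across four reference cell lines, and collect
   the discriminating pairs into per-band biomarker panels;
4. classify query cells/populations by per-PIR nearest-neighbour matching
   against the panels;
5. quantify heterogeneity as the decay constant τ of the %SE-vs-N
   convergence curve of a chosen PIR;
6. validate the univariate stratification with PCA-LDA under leave-one-out
   cross-validation;
7. image the spatial distribution of a PIR over a single nucleus and
   summarise it as an N-normalised frequency-of-occurrence histogram.

Because raw single-cell Raman data of this kind are not publicly
distributable, the package ships a seeded synthetic generator that emulates
the data structure (band composition, repeat-spectra-per-cell sampling,
inter-cell variability, rare subpopulations, mapped acquisitions), so every
stage is exercised end-to-end in the test suite without downloads.

# The data model

A spectrum is a pair (wavenumber axis, intensities) with metadata
(population, cell id, optional map position). Populations are channels ×
spectra matrices on a common axis (`RamanSpectrumSet`). An
`AverageSpectrum` stores the per-channel mean together with the sample SD
(n − 1 denominator) and SE = SD/√N; the validity method enforces
SE = SD/√N exactly. With a single spectrum the SD is reported as 0 with a
warning rather than NA, which keeps convergence curves defined from N = 1.

## The synthetic generator

Each band is a Gaussian `A · exp(−(x − c)² / 2σ²)`; the line shape is
Gaussian throughout because the fitting model is Gaussian (no
Lorentzian/Voigt option). The default grid is 600–1800 cm⁻¹ at 1 cm⁻¹
steps; an instrument's ±3 cm⁻¹ spectral resolution is represented through
the band widths (σ ≈ 5–11 cm⁻¹), not the grid step. Eleven bands at 639,
779, 932, 971, 999, 1060, 1085, 1445, 1473, 1573 and 1654 cm⁻¹ cover the
protein / lipid / nucleic-acid features that matter for stromal-cell
phenotyping.

Variability has two multiplicative log-normal levels, both mean-1:
between cells (`interCellCV`, default 0.10; drawn once per cell and shared
by its repeat spectra) and between repeat spectra within a cell
(`intraCellCV`, default 0.05). Log-normal factors keep amplitudes positive
by construction. Acquisition adds a per-spectrum linear baseline (uniform
slope and offset draws) and additive Gaussian noise (default SD 0.5
intensity units, ≈0.6% of the strongest band). Five repeat spectra per cell
nucleus is the default sampling design. No raw-noise figures were available
to calibrate against, so these defaults were chosen once to make the SE
envelopes of a ~200-spectrum average visually comparable to published
population averages, and are not revisited per analysis.

Four built-in reference profiles ("Y101-like" … "Y202-like") emulate two
differentiation-competent and two incompetent clonal mesenchymal stromal
cell lines. They differ in the 932/971/1060/1085/1445/1473/1654 amplitudes:
the 971 band separates all four lines (the cell-type-stratifying marker),
while the 1060/1473/1654 amplitudes differ mostly *between* the two groups,
with within-group differences (≈0.5%) deliberately placed below the
estimation noise so that both "full" and "group" discrimination classes are
realised. These amplitudes are fixture constants, not measurements.

What the generator does **not** model: fluorescence background and
photobleaching, cosmic rays, detector response, wavenumber miscalibration,
cell-cycle structure. Passing tests therefore demonstrate the correctness
and statistical behaviour of the pipeline on data with the declared
structure — not robustness to every artefact of real acquisitions.

# Peak fitting

`fitWindow()` fits `Σ Gaussians + b₀ + b₁(x − lo)` inside a window by
bounded Levenberg–Marquardt least squares. Each window carries its own
linear baseline because windows are locally baselined by construction.
Defaults: seven windows grouping the overlapping neighbours (932/971/999,
1060/1085, 1445/1473) for joint fitting; centers may drift at most ±5 cm⁻¹
(above the ±3 cm⁻¹ resolution, below typical band separations); amplitudes
are bounded below at 0 and a fit ending at a bound is flagged rather than
silently accepted; two fitted centers closer than 2 cm⁻¹ flag both peaks as
degenerate. "Intensity" always means the fitted Gaussian amplitude (peak
height), not the band area — ratios of heights are what the panel method
tabulates.

Uncertainties: for a plain spectrum, the parameter covariance is the usual
residual-variance-scaled `(JᵀJ)⁻¹` with an analytically computed Jacobian.
For an `AverageSpectrum`, the channel SE envelope enters as inverse-variance
weights and the covariance is the known-variance form `(JᵀWJ)⁻¹` — this is
the mechanism by which the population's SE envelope propagates into the
amplitude SE, and thence into the PIR SE, and it is what makes the %SE of a
PIR scale as 1/√N for iid populations. A Monte-Carlo test verifies the
reported amplitude SE against the empirical spread over noise replicates.

`autoFitPair()` is the robust per-pixel mode used for maps: one Gaussian per
band in a fixed ±30 cm⁻¹ window, initial amplitude from the local data
range. It targets the strong 1654 and 1085 bands, which remain resolvable at
single-spectrum signal-to-noise where a full multipeak fit would not be. A
pixel is invalid when either fit fails or its amplitude is within 2 SE of
zero; invalid pixels are masked, never imputed.

# PIRs, discrimination rules, panels

`computePIR()` forms `value = I_num/I_den` and propagates the SE in
quadrature: `se = value · √((se_num/I_num)² + (se_den/I_den)²)`. The
canonical orientation puts the lower-wavenumber band in the numerator so
that every unordered pair appears exactly once (marker counts follow this
convention; `reorientPIRs()` flips for display). First-order propagation is
accurate to ≈1% at 5% band CV but degrades above ~8% denominator CV (≈4% SD
understatement at 10% CV) — a documented limitation; the method operates on
converged averages whose band CVs are well below that.

Discrimination uses ±1 SE intervals, matching error-bar separation:

* **full** discrimination: all pairwise intervals of the four reference
  values are disjoint, strictly (touching intervals fail);
* **group** stratification: the union interval of one biological group is
  strictly disjoint from the union interval of the other.

Both rules are invariant under common rescaling of values and SEs. Panels
collect, per reference band (defaults 932, 971, 1060, 1085, 1445, 1473),
the band pairs involving that band whose class is not "none"; a pair of two
reference bands legitimately appears in both panels (logged). No
multiple-testing correction is applied over the 55-pair search, by design —
the panel is a descriptive screen, not an inferential claim.

# Nearest-neighbour classification

Each query PIR is matched to the reference line minimising
|query − reference|; K = 1 with simple vote pooling. Equidistant references
(at floating-point resolution) split the vote equally, which avoids order
dependence. A match is also labelled "within uncertainty" when the distance
does not exceed the sum of query and matched-reference SEs; both tallies
(all matches, and the within-uncertainty fraction) are reported, since they
answer different questions. Per-line percentages are tallied per panel and
pooled across panels marker-weighted — i.e. votes are concatenated, not
panel-averaged — and group aggregates are computed from the unrounded
per-line values before any display rounding (half-up to whole percent).
Marker-weighted pooling is what makes group sums reproduce published
aggregation examples exactly from their per-line rows.

# Heterogeneity: %SE convergence and τ

For a chosen PIR, spectra are added to the average in a seeded random order;
at each N in the schedule (every integer from 10 to 50, then steps of 5 —
dense early where the statistic moves, sparse later to bound repeated
peak-fit cost) the two bands are refitted on the cumulative average and
%SE = 100·se/value is recorded. Failed fits skip the point; a curve losing
more than 20% of its schedule is flagged and excluded from summaries.

`fitTau()` fits `A·exp(−N/τ) + B` with A, τ > 0 and B ≥ 0 (curves plateau
at a floor, hence the offset). Initialisation uses a log-linear estimate of
τ with multi-start fallback, which eliminates a degenerate τ → 0 local
minimum; noiseless curves are recovered to machine precision, and τ is
invariant under curve scaling and linear in stretching of the N axis. With
several orderings the spread of τ is reported; with a single ordering the
fit's own covariance SD stands in, mirroring single-replicate uncertainty
reporting.

Why does τ rank heterogeneity at all? For iid sampling the *expected* %SE
curve is scale-invariant (≈ c/√N), so a homogeneous and a heterogeneous
population would give the same expected τ. The discriminating signal is in
the curve's shape fluctuations: when a divergent rare subpopulation is
present, the sample SD — and hence the %SE — jumps when the first rare cell
enters the average, stalling the decay. The package's calibrated
demonstration (`tauHeterogeneityStudy()`) therefore uses **cell-blocked**
ordering (cells enter the average one at a time, as they are acquired on
the instrument), under which the first-arrival time of a rare cell is
spread over the whole schedule and the effect is strong: 40 cells × 5
spectra, 10% rare cells with 971 × 3 / 1085 × 0.5 amplitudes, 971/1085 PIR,
mean τ over 5 orderings per replicate, 20 paired replicates. Under uniform
spectrum-level permutation the effect exists but is weak, which is itself
informative: τ measured on fully randomised orderings mostly reflects
sampling noise. Uniform permutation remains the default for
`pirPercentSECurve()`; the blocked ordering is an explicit option.

# PCA-LDA validation

PCA is mean-centred (no variance scaling) via `prcomp`, with the sign
convention that each loading's largest-magnitude element is positive. The
PC count is chosen as the smallest k reaching a cumulative-variance target
inside **every** leave-one-out fold; the entire pipeline — centring, PCA,
PC selection, LDA — is refitted with the held-out sample excluded, which is
stricter than protocols that fit PCA once globally, and is verified against
an independently-written fold-by-fold reference in the tests. LDA uses
pooled within-class covariance (`MASS::lda`) with a diagonal-shrinkage
fallback when the within-class scatter is singular.

The conventional target of 0.91 is the default. On the synthetic
demonstration the variance structure is low-rank (eleven bands), the top
two PCs already reach 91%, and the class-discriminating directions sit in
lower-variance components; the packaged four-class demonstration therefore
selects PCs at a 0.99 target (≈7 PCs), reaching ≥90% LOOCV accuracy at
inter-cell CV 0.05 with 12 cells per class. Real spectra, with hundreds of
effective channels, need many more PCs to reach 91%, so the default remains
appropriate there. The identical-distribution null control scores at chance
(25% for four classes) within a 99% binomial interval; note LOOCV is known
to score slightly *below* chance on null data because removing the held-out
sample shifts the training means away from it.

# Maps and histograms

`computePIRMap()` auto-fits the band pair per pixel independently (no
parameter sharing across pixels) and masks failures. Histograms normalise
to the valid-pixel count N, which travels with the result alongside the
total pixel count, because the two denominators genuinely differ between
cells and both are reportable. Default binning is 20 fixed-width bins over
the pooled range of the maps being compared (`pooledBinEdges()`), keeping
curves comparable across populations. Out-of-range values are clipped into
the end bins with a message.

# Numerical choices and degenerate inputs

* Trapezoidal integration for area normalisation; non-uniform grids are
  supported; zero/negative area is an error, not a silent pass-through.
* The smoothing-spline parameter is a package-defined [0, 1] scale — 0 is
  the interpolating limit (input returned unchanged), values in (0, 1] map
  to `smooth.spline(spar = …)`. Other software's smoothing conventions are
  not portable to this scale; 0.65 is the default used by the multivariate
  chain.
* Two preprocessing chains are deliberate: the ratiometric path is linear
  baseline → average only (peak fitting handles local baselines itself);
  the multivariate path interpolates to a common grid, baselines, averages
  per cell, area-normalises and smooths. Population SD/SE envelopes on the
  ratiometric path use raw spectra as the averaging unit (per-cell averages
  are available via `averageByCell()` where wanted).
* All stochastic steps take explicit integer seeds; seeded functions save
  and restore the caller's RNG state. Identical (configuration, seed) give
  bit-identical outputs, which the pipeline tests assert at the byte level.

# Problem sizes used in the packaged analyses

Reference populations are 40 cells × 5 spectra (200 spectra/line) — within
the 100–555 spectra range typical of converged population averages; query
populations 20 cells; maps 20 × 20 = 400 pixels (within the 360–484
single-nucleus design range); the τ study uses 20 paired replicates × 5
orderings. These sizes give stable statistics while keeping the full suite
and the acceptance script each well inside a few minutes on one CPU.

# Known limitations

* First-order SE propagation understates ratio SDs above ~8% band CV.
* τ depends on the N schedule and the ordering policy; comparisons are only
  meaningful with both held fixed (the package logs both on every curve).
* The generator's simplified noise model means test results bound what can
  be claimed for real spectra; fluorescence baselines in particular would
  require despiking/background-removal steps that are out of scope here.
* Discrimination classes are sensitive to the reference populations' N
  through their SEs: more spectra shrink intervals and promote "group"
  markers to "full". Panels should be rebuilt, not reused, when reference
  data change.
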