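---
title: "Models and methods behind specphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind specphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specphen)
```

`specphen` screens juvenile cereal panels for predictors of later biomass
accumulation and stress tolerance. This vignette explains the quantities
the package computes, the choices made where the underlying measurement
conventions leave room, and what the synthetic validation panel does and
does not establish.

## The measurement model

### Reflectance and the NDI scan

Spectra enter as white-referenced reflectance on a fixed wavelength grid.
The canonical grid is 400–800 nm in 3 nm steps, which contains 134 bands
(400, 403, …, 799 nm). Whether an 800 nm band exists depends on how the
instrument anchors its lattice; we anchor at 400 nm and emit bands on the
step lattice only, so 799 nm is the last band. Functions take the grid as
an argument, and files written by the package carry the grid explicitly, so
non-default grids are honoured end to end.

For a spectrum $I_\lambda$ the normalized difference index of a wavelength
pair is

$$\mathrm{NDI}(\lambda_1, \lambda_2) =
  \frac{I_{\lambda_1} - I_{\lambda_2}}{I_{\lambda_1} + I_{\lambda_2}}.$$

`ndi_matrix()` evaluates this for all pairs at once. Two edge conventions
matter:

* **0/0 is defined as 0.** Two dark bands carry no contrast information;
  returning 0 rather than NaN keeps downstream correlation maps finite.
* **Negative reflectance after white division is clipped to 0** with a
  warning — values below the dark level are sensor noise, and the NDI is
  undefined for negative intensities.

The matrix is exactly antisymmetric with a zero diagonal; we symmetrize
`(m - t(m))/2` after the vectorized computation so antisymmetry holds to
the last bit rather than merely to rounding.

Region-of-interest handling is deliberately thin: a cube plus a logical
mask gives a mean spectrum (`roi_mean_spectrum()`). Leaf segmentation is
upstream of this package; a convenience NDVI-threshold masker
(`ndvi_mask()`, NDI(770, 670) > 0.3) exists for quick work but the
analysis path assumes externally drawn masks. When replicate (pot-level)
spectra exist, NDIs are computed per pot and then averaged per cultivar,
not the other way round — index-then-average keeps the nonlinearity of the
ratio out of the averaging.

### PAM induction features

From pulse series $(F, F_m')$ with dark references $(F_0, F_m)$ the
standard saturation-pulse quantities are

$$\Phi_{PSII} = \frac{F_m' - F}{F_m'}, \qquad
  NPQ = \frac{F_m - F_m'}{F_m'}, \qquad
  F_v/F_m = \frac{F_m - F_0}{F_m}.$$

`chlf_features()` reduces each trace to six scalars. Definitions that the
raw convention leaves open were fixed as follows:

* **Steady state** is the mean over the final 120 s of the light period
  (`steady_window`). At the usual 30 s cadence that is at least four
  pulses — enough to suppress pulse noise without reaching back into the
  transient.
* **$t_{1/2}(\Phi_{PSIIef})$** is the earliest upward crossing of half the
  steady-state level, linearly interpolated between pulses. The steady
  level is computed first, then the crossing is sought from the start of
  the trace; a trace already above half at its first pulse gets that
  pulse's time.
* **$t(NPQ_{max})$** is the earliest sample attaining the global NPQ
  maximum — "time to reach the maximum" implies first arrival, so plateau
  ties resolve to the earliest time.

### Tolerance statistics

Drought tolerance is expressed as ratios to control:
$\mathrm{DTI} = 100\,DW_{drought}/DW_{control}$ and the analogous residual
level for any physiological parameter. Values above 100 % are legitimate
and occur in real panels.

Heat tolerance comes from a stepped hot-plate ramp (default 25→55 °C in
5 °C steps every 5 min, 10 min hold at 55 °C, $\Phi_{PSII}$ sampled every
60 s — a 40-minute assay). `heat_tolerance()` reports:

* **`t_dec`** — the plate *set-point* at which $\Phi_{PSII}$ first falls
  below its baseline. The baseline is the mean over the final 120 s of the
  initial 25 °C step. $\Phi_{PSII}$ characteristically rises ~10 % during
  early heating before collapsing, so only crossings after the trace has
  exceeded its baseline count; this prevents initial noise from
  registering as a spurious decline. Traces that never rise use the first
  crossing directly; traces that never fall are censored at the end
  temperature and flagged. `t_dec` is quantized in protocol steps per
  replicate; cultivar means over replicates therefore take intermediate
  values, which is how fractional cultivar-level `t_dec` values arise.
  We use the set-point rather than interpolated leaf temperature because
  replicate-mean `t_dec` values in practice behave like averages of
  stepped values.
* **`phi_psii_resid`** — the mean $\Phi_{PSII}$ over the final 60 s as a
  percentage of baseline.

### Correlation mapping

Trait–band and trait–NDI screens use Pearson correlation with the exact
$t$ transform for two-tailed p-values ($t = r\sqrt{(n-2)/(1-r^2)}$,
$n - 2$ df). Correlations operate on **cultivar means** (typically
$n = 11$, df = 9); replicate-level correlation would mix within- and
between-cultivar variance and overstate significance. No multiple-testing
correction is applied by default — the maps are screening instruments and
the raw $p < 0.05$ convention matches how such maps are read;
`stats::p.adjust` can be applied to the tidied output when a corrected map
is wanted.

Significance masks are summarised structurally: maximal contiguous runs of
significant bands (spectrum; `min_run = 2` bands) and 4-connected
components of significant wavelength pairs (heatmap; `min_area = 4`
cells). The minima suppress single-cell speckle, which chance alone
produces in a 134 × 134 map even under the null; genuinely informative
regions in this domain span tens of cells.

### Group comparison

Cultivar comparisons use one-way ANOVA assuming equal variances followed
by Tukey HSD (both from base R), with a Kolmogorov–Smirnov normality check
available. The compact letter display is computed by the insert-and-absorb
algorithm with a final redundancy sweep; the letter-sharing relation
equals the non-significance relation exactly, and the letter count is
checked in the test suite against a brute-force minimum clique cover on
small group structures. Letters are assigned alphabetically in order of
each letter set's first group.

## The synthetic panel

Raw imaging data for real panels are rarely shareable, so validation rests
on a generator (`generate_panel()`) that produces a panel with the same
statistical skeleton the analyses assume. Three latent factors per
cultivar drive everything:

* **Vigor $V$** — chlorophyll content and photosynthetic capacity. The
  reflectance model is a visible background plus a logistic red edge
  (midpoint 705 nm, scale 16 nm) onto a NIR plateau, minus Gaussian
  absorption wells at 450 nm (SD 25 nm) and 670 nm (SD 18 nm); well depth
  and plateau height grow with $V$. $\Phi_{PSIIef}$ and dry weight grow
  with $V$; the induction half-time, NPQ magnitudes and transient times
  shrink with it. Centres and slopes were chosen to span the magnitudes
  typical of juvenile wheat panels ($\Phi_{PSIIef}$ roughly 0.45–0.61,
  $NPQ_{max}$ 1.2–1.9, $t_{1/2}$ 105–230 s, dry weight 29–77 mg).
* **Heat tolerance $H$** — shifts the thermal midpoint of a logistic
  quantum-yield shutdown (width 3.5 °C) multiplied by a mild linear
  stimulation term, reproducing the rise-then-collapse shape of heat-ramp
  traces. $corr(V, H) = -0.7$ by default: in such panels the vigorous
  cultivars tend to be the heat-sensitive ones, and the default encodes
  that sign structure.
* **Drought tolerance $D$** — drives DTI and the residual fluorescence
  parameters. **Independent of $V$ and $H$ by default**
  (`drought_coupling = 0`): drought tolerance is deliberately *not*
  predictable from spectra or fluorescence, so any significant region a
  drought scan produces on generator output is a false positive. This is
  the null structure against which the mapping machinery's type-I
  behaviour is calibrated.

The induction curves are
$\Phi_{PSII}(t) = \Phi_{PSIIef}\,(1 - 2^{-t/t_{1/2}})$ and an NPQ curve
composed of a fast saturating baseline to $NPQ_s$ plus a symmetric
Gaussian transient peaking at $t(NPQ_{max})$; the bump width has a floor
($\max(0.45\,t_{peak}, 80\ \mathrm{s})$) so the peak stays resolvable at a
30 s pulse cadence. Dark yields $F_0$/$F_m$ are back-computed so the PAM
equations reproduce the curves exactly. The plate temperature seen by the
heat model is the set-point smoothed by a first-order thermal lag
(time constant 40 s).

**Ground truth.** The generator stores, per cultivar, the features of its
*continuous* curves evaluated densely (0.5 s) under the same reference
definitions (final-window means, interpolated half-crossing, earliest
maximum), plus the analytically derived `t_dec`. Recovery tests compare the
cadence-limited extractors against this dense truth, so the tolerances
(half a sampling interval for times, 2 % for levels) measure pure
discretization error, as they should.

Replicate noise defaults were set from the SEM·√n magnitudes such panels
print; `noise_scale` rescales all of them at once (0 = noise-free).
Identical `(config, seed)` pairs give identical panels.

**What passing tests show — and what they do not.** The generator is
phenomenological, not radiative-transfer-based: no PROSPECT-style leaf
optics, no scattering geometry, no instrument stray light; band noise is
white rather than spectrally correlated; latent relations are linear with
Gaussian noise. Recovery and calibration results therefore validate the
*algorithms* — that the extractors invert the curve definitions, that the
scan's false-positive rate is nominal under a true null, that sign
structure propagates — not the biological fidelity of any particular real
panel.

## Numerical choices and problem sizes

* Pearson p-values use `pt()` on the $t$ transform; tests cross-check
  against the incomplete-beta closed form and `cor.test` to 1e-12.
* The NDI scan correlates the upper triangle only and mirrors results, so
  heatmap antisymmetry/symmetry are exact by construction.
* Degenerate inputs error early and namedly: zero-variance traits, grids
  that disagree, white references with non-positive bands, masks that
  select nothing, traces shorter than their protocol.
* The validation suite runs at deliberately modest sizes — 50-spectrum
  oracle sweeps, 1000-vector Pearson sweeps, 110 zero-noise recovery
  draws, 200 null-panel simulations, 20-seed sign checks, and
  exhaustive-plus-sampled letter-display structures up to 6 groups —
  sizes at which each check is already conclusive for the property it
  targets while the whole suite stays fast enough to run on every change.

## Known limitations

* Leaf segmentation and thermal-image ROI analysis are out of scope;
  plate temperature is taken from the protocol schedule, not from
  thermography.
* `t_dec` is quantized per replicate by design; panels needing finer
  thermal resolution need a finer protocol, not interpolation.
* The compact letter display's minimal-count property is verified
  exhaustively only for small group structures; for the panel sizes this
  package targets (≤ ~12 groups) the insert-and-absorb construction with
  redundancy sweep is expected, but not proven, minimal.
* With 11 cultivars, correlation screens have limited power and wide
  confidence bands; the maps are hypothesis generators, not confirmatory
  statistics.
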