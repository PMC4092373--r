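---
title: "Methods: DPV deconvolution and flavin-cytochrome binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DPV deconvolution and flavin-cytochrome binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpvkit)
```

## The measurement and the model

Electrode-respiring bacteria such as *Shewanella oneidensis* MR-1 deliver
respiratory electrons to electrodes through outer-membrane *c*-type
cytochromes (OM c-Cyts: MtrC, OmcA). Cell-secreted flavins — riboflavin
(RF) and flavin mononucleotide (FMN) — bind these cytochromes as one-electron
cofactors (oxidized/semiquinone cycling), which shifts their formal
potential positively and narrows the thermodynamic cost of interfacial
electron transfer relative to the two-electron chemistry of free flavins in
solution. Differential pulse voltammetry (DPV) of intact biofilms resolves
these couples as peaks riding on a smooth charging current; the two
observables that discriminate bound from free flavin are the peak potential
$E_p$ and the half-width $\Delta E_{p/2}$ (full width at half maximum).

`dpvkit` models the DPV response of a reversible $n$-electron couple as a
difference of Nernstian occupancies sampled at the two pulse edges:

$$\delta i(E) \propto \frac{1}{1+e^{(E-E_0)/k}} - \frac{1}{1+e^{(E+s\,\Delta E-E_0)/k}},
\qquad k = \frac{RT}{nF},$$

with pulse amplitude $\Delta E$ and scan sign $s$ (+1 anodic). This is
exact for a surface-confined reversible couple that relaxes fully between
pulses, and it reproduces the three properties the analysis actually uses —
peak position ($E_0 - s\,\Delta E/2$), half-width, and height — for the
solution couples as well, which is why no diffusion model is included
(peak-current transport corrections are out of scope). In the
small-amplitude limit the half-width approaches
$2(RT/nF)\ln(3+2\sqrt2) \approx 90.6/n$ mV at 298 K; at the instrument
settings emulated here (50 mV amplitude, 303.15 K) the theoretical widths
are:

```{r widths}
c(n1 = theoretical_half_width(1, 50, 303.15),
  n2 = theoretical_half_width(2, 50, 303.15))
```

Electron-count inference (`classify_n`) assigns the candidate $n$ whose
theoretical width is nearest the observed one. Because width decreases with
$n$, any broadening beyond the ideal one-electron width (kinetic and
energetic dispersion in a heterogeneous biofilm) still maps to $n = 1$; no
quantitative dispersion model is attempted. A call is flagged ambiguous
when the two nearest candidates differ by less than 5 mV in discrepancy.

### Defaults worth knowing

* Temperature 303.15 K (the 30 °C reactor temperature), not 25 °C.
* Anodic scan by default: the cells oxidize lactate, the electrode is the
  acceptor; anodic currents are positive. Whether the original
  voltammograms were recorded anodically is not stated anywhere we could
  check; the respiratory context makes anodic the natural choice, and all
  width/position logic is direction-symmetric.
* Potentials are stored in volts vs SHE internally; millivolts appear only
  in reports and file headers. The Ag/AgCl(sat. KCl) to SHE offset defaults
  to +0.199 V and is configurable (`convert_reference`); the round numbers
  quoted for this cell (+0.2 V Ag/AgCl = +0.4 V SHE) imply 0.200 V.
* Pulse waveform: 5 mV increment, 50 mV amplitude, 300 ms width, 5 s
  period, sampled over the last 10 ms of the pulse.

## Synthetic data: what it emulates, what it does not

No measurement files are distributed with the study this package emulates,
so a first-class generator (`make_dpv_fixture`, `make_titration`,
`make_current_trace`) reproduces the *reported* observables with realistic
statistical structure. The fixture registry pins the flavin peaks at the
reported positions and widths: free RF/FMN at $E_p=-260$ mV with the exact
two-electron width (the reported 60 mV is consistent with theory within a
few mV); bound FMN in the wild type at $-145$ mV / 130 mV; bound RF at
$-110$ mV (width "more than double" the free width is all that is reported
— the 130 mV default is our decision); bound RF in the *mtrC* deletion at
$-102$ mV / 150 mV.

Everything else in a fixture is invented and flagged (`invented = TRUE` in
the metadata) so no test or report treats it as a reference value:

* **Heme envelope.** The multi-heme background of the cytochromes is a
  broad Gaussian (center $-0.05$ V, FWHM 250 mV, height 1.2 µA cm⁻²). The
  published deconvolutions show such a component but never quantify it.
* **Charging baseline.** Cubic polynomial plus a gentle exponential tail at
  the negative scan edge (amplitude 0.25 µA cm⁻², decay length 0.1 V, on a
  ~10 µA cm⁻² charging current). The generator's role is to produce data
  with the structure the published analysis assumes — a smooth charging
  current that continues through the peak region and is representable by a
  low-order polynomial over peak-free windows — so the tail is kept gentle;
  a pathological baseline would simply make the documented analysis
  inapplicable, which is not the situation being emulated.
* **Noise.** Gaussian, 0.5% of the tallest peak for voltammograms, 1% of
  the plateau for current traces, 5% multiplicative on titration peak
  magnitudes. All randomness flows through explicit seeds via a private RNG
  stream; the global `.Random.seed` is untouched.

The titration generator scales the bound-FMN peak as
$i(C) = i_{\max} C/(C+K_d)$ with $K_d = 10$ µM, and calibrates
$i_{\max} = 7\times\frac{52+10}{52} \approx 8.35$ µA cm⁻² so that the
*observable* at 52 µM equals the reported 7 µA cm⁻². This choice exposes,
rather than hides, the known tension in the original arithmetic: 52 µM
occupies only 84% of the sites if $K_d = 10$ µM, so an estimator that
treats the 52 µM point as saturating must come out low (below). The free
flavin peak grows linearly in concentration (unsaturated solution couple).
The default concentration ladder (0.5, 1, 2, 5, 10, 20, 52 µM) brackets the
expected $K_d$ the way a practitioner would design the series.

Current traces are logistic rises to strain/flavin-dependent plateaus (WT
with either flavin: 15 µA cm⁻²; deletion strains without their cognate
flavin: a lag below 0.1 µA cm⁻² then a low plateau; ∆omcA+FMN and
∆mtrC+RF: ten times the no-flavin current), plus a 0.05 µA cm⁻² no-lactate
background. A flavin addition multiplies the background-subtracted current
by the tabulated enhancement factor with a first-order rise
($\tau = 200$ s, invented) so the 1000 s sampling rule is genuinely
exercised — the measured EF sits ~0.7% below the injected target, inside
any stated tolerance. Only the $-0.2$ V entries of the EF table (FMN 15,
RF 3) are reported values; the rest are invented subject to the reported
qualitative constraints (EF grows toward negative potentials; FMN EF
non-decreasing in pH; RF minimal at pH 7, maximal at pH 6) and carry
`figure_derived_invented = TRUE`.

What passing tests do *not* show about real data: the generator draws peaks
from the same shape family the fit assumes, has homoscedastic noise, no
drift, no potential-dependent capacitance steps and no overlapping
secondary flavin states. Recovery tolerances met here are a statement about
the pipeline's correctness, not about field performance on arbitrary
instruments.

## Baseline subtraction and weighted orthogonal-distance deconvolution

The analysis chain follows the published recipe: fit the charging baseline
over regions sufficiently far from the peaks assuming it continues smoothly
underneath them, subtract, then fit the residual with a sum of model peaks
by minimizing the sum of squared *weighted orthogonal distances*.

**Baseline.** `fit_baseline` performs least squares of a cubic (degree
configurable; a polynomial-plus-exponential model is also available) over
windows that are either user-supplied or chosen automatically as the
complement of $E_p \pm 2W$ exclusion zones around detected peaks. Two
practical safeguards matter on real-shaped data: exclusion half-widths are
capped (0.2 V) so a broad envelope cannot consume the entire scan, and
windows must stay anchored near both scan edges — a cubic fitted to a
one-sided window extrapolates disastrously. Samples that still sit
significantly above the running fit (flanks of broad envelopes escaping the
zones) are trimmed iteratively, with the trim threshold floored at the
point-noise scale and at most ~half the window mass removable, which keeps
the trimming from running away on noisy scans.

**Why refinement is needed.** With a 250 mV-wide heme envelope on a 700 mV
scan there are no windows truly free of envelope tails: a single windowed
cubic absorbs 0.3-0.4 µA cm⁻² of heme flank, and that smooth error then
trades off against the strongly overlapped flavin/heme components. The
identifiability experiment is instructive: under an *exact* baseline the
deconvolution recovers every fixture to machine precision from any
reasonable start, so the entire recovery error budget is baseline error.
`analyze_dpv` therefore iterates the textbook peak-stripping loop: subtract
the currently fitted components from the raw scan, refit the cubic over the
peak-free windows of the stripped signal (now decontaminated of envelope
flanks), re-subtract, re-deconvolve. Because the joint problem is
multi-modal, each member of a small grid of starting values (flavin width
110/130/150 mV × heme height 0.3/0.6 of the signal) runs its own
refinement trajectory, and trajectories are compared on the one scale that
is commensurable across different baselines: the total misfit of
baseline + components against the raw data. On noise-free fixtures this
chain recovers $E_p$ to < 0.3 mV and widths to < 4 mV; at the default 0.5%
noise the median $|E_p|$ error over 50 seeds stays well under 1 mV.

**ODR.** No ODRPACK binding exists in the R dependency set used here, so
the weighted orthogonal-distance objective is implemented directly: latent
abscissa shifts $\delta_i$ (one per sample) join the peak parameters in a
Levenberg-Marquardt problem with residuals
$[(y_i - f(x_i+\delta_i))/\sigma_y,\ \delta_i/\sigma_x]$, solved by
`minpack.lm::nls.lm`. Defaults: $\sigma_x = \mathrm{increment}/\sqrt{12}$
(the quantization noise of the 5 mV staircase, ≈1.44 mV) and $\sigma_y$
the MAD of the outer 10% of samples, floored at $10^{-3}$ of the signal
maximum so noise-free fixtures remain well-posed. With $\sigma_x = 0$ the
deltas are dropped and the fit is ordinary least squares; the test suite
pins the ODR→OLS equivalence in that limit, and the accepted-step deviance
trace is asserted monotone (the optimizer's contract). Peak shapes are
selectable per component: sigmoid-difference for flavins, Gaussian for the
heme envelope. Internally each peak is parameterized as
$(E_p, \log w, \log h)$, keeping widths and heights positive without
constraints; the covariance is reported on that internal scale.
Convergence: relative parameter change $<10^{-8}$ or 200 iterations, with
non-convergence raised as a diagnostic error carrying the last iterate.
An optional low-order polynomial background term inside `deconvolve` exists
but is off by default — on these fixtures it is degenerate with the peak
widths and the stripping loop is the better answer.

**Reports.** `summarize_peaks` converts each component to the figure-style
row: $E_p$ (mV), $\Delta E_{p/2}$ (mV, the FWHM of the fitted component),
height, charge, apparent $n$ (inverting the half-width relation; `NA` when
the width is at or below the pulse amplitude, which the reversible model
cannot produce). Charge is the trapezoidal area over potential divided by
the staircase scan rate (increment/period) and is labeled a proxy — DPV
peak intensity is not strictly quantitative.

## Binding analysis

Occupancy is the Langmuir isotherm $\theta = C/(C+K_d)$; at 1 µM and
$K_d = 10$ µM, $\theta = 9.1\%$, i.e. ~10% of cytochrome sites carry a
flavin cofactor at physiological flavin levels. Two $K_d$ estimators are
provided deliberately:

* `fit_langmuir` — nonlinear least squares of $i_{\max}C/(C+K_d)$,
  initialized from the observed maximum and the interpolated half-max
  concentration, standard errors from the Jacobian. This is the
  statistically sound estimator: 100-replicate simulations at 5% noise
  recover $K_d = 10$ µM with ~9% median relative error on the 8-point
  design, with RMSE decreasing as points are added.
* `kd_from_half_saturation` — the saturating-endpoint shortcut used in the
  original argument: take the highest-concentration current as $i_{\max}$
  and read off the concentration at half of it by linear interpolation.
  On the default titration this returns ≈7.3-8.6 µM depending on noise —
  systematically below the true 10 µM because 52 µM does not saturate
  ($\theta = 0.84$). Both estimators are reported side by side so the
  approximation error is visible rather than hidden.

`estimate_site_concentration` converts a monolayer biofilm into a molar
site concentration: a close-packed monolayer of cells (invented footprint
2 µm²) on the 3.14 cm² electrode, 10-30% of each cell's surface covered by
cytochromes of ~50 nm² footprint (also invented), dissolved in the 5 mL
reactor volume. The defaults give ≈0.4 nM — sub-nanomolar, an
order-of-magnitude statement only, and the two footprints are flagged as
invented in the result object.

## Enhancement factors

`enhancement_factor` implements the protocol verbatim: the pre-addition
current is the mean over the 60 s before the event (the original text says
only "immediately before", so a short averaging window is our
operationalization), the post-addition current is the point value 1000 s
after the event by linear interpolation, both are corrected by the
no-lactate background at the same potential, and EF is their ratio. A
missing background defaults to zero with a warning; a pre-addition current
at or below background raises an undefined-EF error rather than returning a
sign-flipped ratio. EF is by construction invariant to common offsets and
to current-unit rescaling, and both invariances are property-tested.
`build_panel` aggregates replicate results into mean ± SEM per
(axis value, flavin) cell, warning when a panel cell mixes inconsistent
settings of the other axis.

## Numerical choices and degenerate inputs

* Half-width ↔ scale inversions (`kscale_from_width`,
  `apparent_n_from_width`) use monotone bisection; the sigmoid-difference
  width is bounded below by the pulse amplitude, and requests below that
  bound error out (or return `NA` for apparent $n$).
* Pulse amplitudes below $10^{-6} k$ switch to the closed-form
  logistic-derivative limit, where root finding loses precision.
* Peak detection detrends with an asymmetric least-squares cubic
  (positive residuals down-weighted to 0.01) so the rough baseline hugs
  the lower envelope; prominence is topographic and ties order toward more
  negative potential.
* Degenerate deconvolutions (more components than the data resolve) yield
  an ill-conditioned covariance warning with `NA` covariance, not a crash.
* File formats store doubles at 17 significant digits; round trips are
  bit-lossless.

## Problem sizes

Simulated scans are 141 points (−0.45 … +0.25 V at 5 mV); traces sample
45 h at 50 s (3241 points); the Monte-Carlo binding studies use 100
replicates per design and the noise-recovery study 50 seeds — sizes chosen
so the complete workflow (`analysis/01…05`) and the test suite run in a few
minutes on a single core while keeping Monte-Carlo standard errors a small
fraction of the tolerances being asserted.

## Known limitations

* Reversible, fully relaxed couples only: no Butler-Volmer kinetics, no
  staircase transient simulation, no diffusion-layer physics.
* The heme envelope is a single Gaussian; real multi-heme backgrounds are
  sums of many couples and may be asymmetric.
* Apparent $n$ from width has no dispersion model behind it; widths beyond
  the ideal one-electron width are *called* one-electron, not explained.
* The EF table outside the two reported −0.2 V values is invented; panel
  tests assert trends, not those bar heights.
* Titration voltammograms inherit the fixture's heme/baseline, so the
  bound and free flavin peaks are the only concentration-dependent parts.
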