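# dpvkit

Analysis toolkit for whole-cell voltammetry of electrode-respiring
bacteria: differential pulse voltammetry (DPV) peak deconvolution,
electron-count inference from peak half-widths, Langmuir analysis of
flavin-cytochrome binding, and enhancement-factor analysis of
chronoamperometry traces.

## The scientific problem

*Shewanella oneidensis* MR-1 respires onto electrodes through
outer-membrane *c*-type cytochromes (MtrC, OmcA). Secreted flavins —
riboflavin (RF) and flavin mononucleotide (FMN) — bind these cytochromes as
one-electron cofactors (oxidized/semiquinone cycling) rather than acting
only as diffusing two-electron shuttles. Whole-cell DPV resolves the bound
and free couples as peaks over a smooth charging current, and two numbers
carry the mechanistic argument:

* the **peak potential** E_p — free flavins sit near −260 mV vs SHE, the
  cytochrome-bound forms near −145 mV (FMN/MtrC) and −110 mV (RF/OmcA);
* the **half-width** ΔE_p/2 — for a reversible n-electron couple the DPV
  full width at half maximum is ≈ `2(RT/nF) ln(3+2√2)` in the
  small-amplitude limit (≈ 90.6/n mV at 298 K), so ~60 mV widths indicate
  n = 2 (free flavin) and ~130–150 mV widths indicate a broadened n = 1
  couple (bound flavin).

The package implements the full chain: a closed-form Nernstian
sigmoid-difference forward model of the DPV response, charging-baseline
estimation and subtraction over peak-free windows, multi-peak deconvolution
by **weighted orthogonal-distance regression** (flavin peaks as
sigmoid-differences, the multi-heme background as a Gaussian envelope),
half-width → electron-count classification, Langmuir binding analysis
(occupancy θ = C/(C+K_d), K_d by nonlinear fit and by the saturating-
endpoint shortcut), an order-of-magnitude estimate of the cytochrome site
concentration over the electrode, and the pre/post-addition
enhancement-factor protocol with potential/pH panels. Because no
measurement files are deposited for this system, a first-class synthetic
generator emulates the voltammograms, titration series and
current-production traces, parameterized by the study's printed values;
everything it invents beyond those values is flagged in metadata.

## Worked example

```r
library(dpvkit)

# A synthetic whole-cell voltammogram: bound FMN over the heme envelope
v <- make_dpv_fixture("bound_FMN_WT", noise_sd = 0)
a <- analyze_dpv(v, components = c("flavin", "heme"))
a$peaks[, c("role", "Ep_mV", "half_width_mV", "height_uA_cm2", "apparent_n")]
#>     role     Ep_mV half_width_mV height_uA_cm2 apparent_n
#> 1 flavin -144.8771      128.4163      2.418128  0.7544701
#> 2   heme  -56.9437      263.9359      1.327578  0.3529281

classify_n(a$peaks$half_width_mV[1], amplitude_mV = 50, T_K = 303.15)
#> n = 1 (observed width 128.4 mV; theoretical n1: 100.5, n2: 62.2; margin 38.2 mV)
```

The flavin component is recovered at −145 mV with a ~129 mV half-width:
far broader than the 62 mV two-electron width, so the call is a
one-electron couple — the signature of cytochrome-bound flavin. The
apparent n < 1 quantifies the extra broadening (dispersion) without
interpreting it.

```r
# Binding: both Kd estimators on the default FMN titration (true Kd 10 uM)
tt <- make_titration(seed = 1)
fit_langmuir(tt)
#> Langmuir fit (n = 7): Kd = 9.95 +- 0.86 uM, i_max = 8.39 +- 0.27 uA cm-2
kd_from_half_saturation(tt)   # the saturating-endpoint shortcut, biased low
#> [1] 7.348149
100 * langmuir_occupancy(1.0, 10)  # % of sites occupied at physiological 1 uM
#> [1] 9.090909
```

```r
# Enhancement factor of an FMN addition at -0.2 V vs SHE
ev <- flavin_addition(40 * 3600, "FMN", 2)
tr <- make_current_trace("WT", "FMN", 2, -0.2, 7.8, events = list(ev),
                         noise_sd = 0)
bg <- make_background_trace("WT", -0.2, 7.8, noise_sd = 0)
enhancement_factor(tr, ev, bg)
#> EF = 14.91 (FMN at -0.2 V vs SHE, pH 7.8; pre 5.05, post 74.6, bg 0.05 uA cm-2)
```

## The analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study-style analysis from scratch, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_data.R` | generates all voltammogram fixtures, the titration and the trace set |
| `02_deconvolve_voltammograms.R` | baseline subtraction + ODR deconvolution; peak report |
| `03_electron_count.R` | electron-count calls from the fitted half-widths |
| `04_binding_titration.R` | Langmuir fits, K_d recovery study, site concentration |
| `05_enhancement_panels.R` | enhancement factors, potential/pH panels, mutant rescue ratios |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_data.R`.

The methods vignette (`vignettes/dpv-deconvolution-methods.Rmd`) documents
the model assumptions, the baseline-refinement scheme, the ODR
implementation, every invented generator default and the package's known
limitations.

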