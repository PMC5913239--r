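# gpcrtraffic

Quantitative pharmacology of GPCR agonist action across signalling,
binding-kinetic and trafficking readouts, built around the GLP-1 receptor.

Modern agonist characterization asks more than "how potent?": agonists at
the same receptor can preferentially engage one intracellular pathway over
another (biased agonism), stay bound for seconds or hours (residence time),
and drive very different receptor internalization, recycling and
degradation — and these properties, not acute potency, can determine
long-term responses such as sustained insulin secretion. `gpcrtraffic`
implements the computations that turn raw plate-reader and flow-cytometry
measurements into those quantities, for pharmacologists profiling agonist
panels:

* **Signal bias** — joint operational-model fits per pathway,
  `E([A]) = basal + (Em − basal) / (1 + ((1 + [A]/K_A)/(10^{log(τ/K_A)}[A]))^n)`,
  yielding Δlog(τ/K_A) (vs. a reference agonist, per experiment) and
  ΔΔlog(τ/K_A) (between pathways) with propagated 95% CIs, significance
  calls, bias factors `10^ΔΔ`, and web-of-bias radar coordinates.
* **Binding kinetics** — nonspecific-binding subtraction, one-phase
  dissociation fits, the Motulsky–Mahan closed form for competitive
  association (with an analytic repeated-root branch), global fitting of
  competitor k_on/k_off across ≥ 4 concentrations, and the exact identities
  residence time = 1/k_off, K_d = k_off/k_on.
* **Trafficking** — the stripping-corrected internalization percentage
  `100·[(F₊Me(t)/F₋Me(t)) − (F₊Me(t₀)/F₋Me(t₀))]/[1 − F₊Me(t₀)/F₋Me(t₀)]`,
  two-strip recycling percentages (both conventions), plate-reader surface
  loss/recovery, DERET ratio time courses, and endosomal-pH estimation via
  ligand-specific fluorescence calibrations anchored by bafilomycin.
* **Response indices** — four-parameter logistic fits, assay-max
  normalization, percent release, insulin stimulation index, F/F_baseline
  traces, baseline-relative AUC.
* **Profiles** — per-agonist feature matrices (k_off, Δlog(τ/K_A) for two
  pathways, internalization, recycling), standardized PCA, and the
  internalization-vs-secretion regressions.
* **Synthetic data** — every assay simulated from a ground-truth panel
  (operational parameters, rate constants, a three-compartment
  surface/endosome/degraded trafficking model solved analytically), so the
  whole pipeline is testable by parameter recovery with no external data.

## Worked example

Simulate the demonstration panel — six agonists spanning a reference
(`ex4`), a G-biased fast-recycling analog (`exF1`), a β-arrestin-biased
strong internalizer (`exD3`) and three intermediate profiles — and run the
full analysis:

```r
library(gpcrtraffic)
res <- run_pipeline(list(seed = 7))

res$bias_contrast[, c("agonist", "ddelta_log_tka", "ci_lo", "ci_hi",
                      "significant", "bias_factor")]
#>   agonist ddelta_log_tka  ci_lo   ci_hi significant bias_factor
#> 1    dula       -0.03525 -0.168  0.0972       FALSE       0.922
#> 2     ex4        0.00000  0.000  0.0000       FALSE       1.000
#> 3    exD3       -0.87028 -0.974 -0.7668        TRUE       0.135
#> 4    exF1        0.31229  0.251  0.3737        TRUE       2.053
#> 5    lixi       -0.00269 -0.126  0.1206       FALSE       0.994
#> 6    sema       -0.00321 -0.107  0.1009       FALSE       0.993
```

ΔΔlog(τ/K_A) contrasts cAMP against β-arrestin-2: `exD3` is significantly
β-arrestin-biased (ΔΔ = −0.87, planted −0.9; bias factor 0.13) and `exF1`
significantly G-biased (ΔΔ = +0.31, planted +0.3); the unbiased agonists'
CIs cross zero.

```r
res$kinetics
#>   agonist     k_on  k_off residence_time      K_d converged
#> 1     ex4 49756585 0.0491           20.4 9.87e-10      TRUE
#> 2    exF1 29773707 0.1922            5.2 6.46e-09      TRUE
#> 3    exD3 39636238 0.0180           55.6 4.54e-10      TRUE
#> ...
```

Competitive-association fits recover the planted rate constants (ex4 truth:
k_on 5×10⁷ M⁻¹min⁻¹, k_off 0.05 min⁻¹, residence time 20 min) within ~1%.

```r
res$regression
#> ISI vs internalization_pct: slope -0.03706 (p = 0.00657), r^2 = 0.871, n = 6
```

The planted negative coupling between net internalization and prolonged
insulin secretion (fold over glucose-only control) is recovered as a
negative, significant slope; in `res$pca` the fast-recycling, G-biased
agonist separates from all others on PC1.

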