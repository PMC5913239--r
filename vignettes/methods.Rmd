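---
title: "Quantifying agonist bias, binding kinetics and receptor trafficking"
author: "gpcrtraffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying agonist bias, binding kinetics and receptor trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrtraffic)
```

# Scope

`gpcrtraffic` implements the quantitative layer of a multi-assay agonist
characterization workflow for G-protein-coupled receptors, developed around
the GLP-1 receptor: signal-bias quantification with the operational model of
agonism, receptor-binding kinetics by competitive association, receptor
internalization/recycling/downregulation metrics, endosomal-pH estimation,
secretion indices, and the synthesis of all readouts into per-agonist
profiles (PCA and structure–function regressions). Because such datasets are
rarely deposited, the package ships a synthetic-data module that simulates
every assay from a known ground-truth panel; every downstream stage can
therefore be validated by parameter recovery rather than by eye.

# Signal bias: the operational model and ΔΔlog(τ/K~A~)

Concentration–response data for one pathway are fitted jointly across
agonists with the operational model in its transduction-coefficient
parameterization,

$$E([A]) = \mathrm{basal} + \frac{E_m - \mathrm{basal}}
  {1 + \left( \frac{1 + [A]/K_A}{10^{\log(\tau/K_A)}\,[A]} \right)^{n}},$$

with the system parameters $E_m$, basal and transducer slope $n$ shared
across agonists within a pathway and experiment, and $\log K_A$ (functional
affinity) and $\log(\tau/K_A)$ (the log transduction coefficient) estimated
per agonist. Parameterizing directly in $\log(\tau/K_A)$ makes the bias
coefficient a fit parameter rather than a ratio of two poorly identified
parameters.

**Identifiability.** For $n = 1$ the per-agonist curve collapses to a
two-parameter hyperbola ($E_{\max}$, EC$_{50}$), so the joint model has a
one-dimensional exact degeneracy: $E_m$ can trade against all $\tau$ values,
shifting every $\log(\tau/K_A)$ in a pathway by a common constant while the
fit is unchanged. This is precisely why absolute transduction coefficients
are not reported; the within-pathway difference
$\Delta\log(\tau/K_A)$ (test minus reference agonist, computed within each
experiment) and the between-pathway contrast
$\Delta\Delta\log(\tau/K_A) = \Delta_A - \Delta_B$ are invariant along the
ridge and are the package's primary outputs. The test suite asserts absolute
recovery only on panels with $n \ne 1$, where the model is identified.

Error propagation follows the replicate structure: intra-experiment
replicates are averaged first; $\Delta\log(\tau/K_A)$ is computed per
experiment; the cross-experiment mean and SEM give
$\mathrm{SE}_{\Delta\Delta} = \sqrt{\mathrm{SEM}_A^2 + \mathrm{SEM}_B^2}$,
and an agonist is called biased when the 95% CI of $\Delta\Delta$ excludes
zero. Two CI multipliers are available: the conventional normal multiplier
1.96 (`ci = "z"`) and a Student-t multiplier with Welch–Satterthwaite
degrees of freedom (`ci = "t"`). With the 4–6 experiments typical of these
assays the z call is anti-conservative by construction (its analytic type-I
rate is ≈ 8–9% at $n = 5$, since the SEMs are estimated from four degrees of
freedom each); the t call is the calibrated form of the same decision and is
what the packaged pipeline and calibration checks use. Both are exposed
because published bias tables typically quote the z form.

Agonists whose response span never exceeds the noise floor (3× the pooled
replicate SD by default) are flagged `quantifiable = FALSE`; no estimates
are invented for them and the flag propagates as `NA` through bias tables,
contrasts, web-of-bias coordinates and feature matrices.

Web-of-bias coordinates are $10^{\Delta\log(\tau/K_A)}$ additionally
normalized to a reference pathway, so the reference agonist maps to 1 on
every spoke and every agonist maps to 1 on the reference pathway.

# Binding kinetics

Surface dissociation after washout and receptor blockade is fitted as
one-phase exponential decay $B(t) = B_0 e^{-k_{\mathrm{off}} t}$ with the
plateau fixed at zero: after nonspecific-binding subtraction, specific
binding must decay to zero under complete blockade.

Competitive association traces — a labelled tracer at concentration $L$ and
an unlabelled competitor at $I$ added simultaneously — follow the
Motulsky–Mahan closed form. With $K_A = k_1 L + k_2$, $K_B = k_3 I + k_4$,
$S = \sqrt{(K_A - K_B)^2 + 4 k_1 k_3 L I}$, $K_F = (K_A+K_B+S)/2$ and
$K_S = (K_A+K_B-S)/2$:

$$RL(t) = \frac{B_{\max} k_1 L}{K_F - K_S} \left[
  \frac{k_4 (K_F - K_S)}{K_F K_S}
  + \frac{k_4 - K_F}{K_F} e^{-K_F t}
  - \frac{k_4 - K_S}{K_S} e^{-K_S t} \right].$$

When $|K_F - K_S|/K_F < 10^{-9}$ the difference quotient is replaced by the
series-expanded repeated-root limit
$B_{\max} k_1 L \left[ \tfrac{k_4}{m^2}(1 - e^{-mt})
- \tfrac{(k_4 - m)t}{m} e^{-mt} \right]$ with $m = (K_F+K_S)/2$, avoiding
catastrophic cancellation. The closed form is verified in the tests against
direct numerical integration of the two-ligand mass-action ODE system over
random parameter grids, including the near-degenerate regime.

`fit_competitive()` fits $k_3, k_4$ (the competitor's $k_{\mathrm{on}}$,
$k_{\mathrm{off}}$) globally across four or more competitor concentrations
on the log10 scale, with tracer $k_1, k_2, B_{\max}$ taken from
competitor-free traces (co-fitting $B_{\max}$ is optional; by default it is
shared within an assay). Residence time $= 1/k_{\mathrm{off}}$ and
$K_d = k_{\mathrm{off}}/k_{\mathrm{on}}$ are exact identities, never
re-estimated. Time is in minutes and concentrations in molar throughout, so
residence times are reported in minutes.

# Trafficking metrics

The stripping-based flow-cytometry internalization percentage is

$$100 \cdot \frac{F_{+\mathrm{Me}}(t_x)/F_{-\mathrm{Me}}(t_x) -
  F_{+\mathrm{Me}}(t_0)/F_{-\mathrm{Me}}(t_0)}
  {1 - F_{+\mathrm{Me}}(t_0)/F_{-\mathrm{Me}}(t_0)},$$

whose $t_0$ term corrects for imperfect stripping and which is invariant to
common rescaling of all fluorescences. Values slightly outside [0, 100] are
reported as-is with a flag (never clipped), preserving the error structure
for downstream statistics.

The two-strip recycling protocol admits two conventions; the package
reports the fraction of the 15-min internalized pool that returned to the
surface as the primary output and the absolute percentage of total receptor
as an optional column, rather than silently choosing one.

DERET surface-loss traces are ratio-normalized (620/520), anchored per well
at $t_0$ to remove labelling variation, and expressed relative to the
vehicle time course. Internalization relieves fluorescein quenching of the
terbium donor, so surface loss increases with the ratio.

Endosomal pH is estimated by the bafilomycin ratio method: bafilomycin
collapses the endosomal proton gradient (assumed pH 7.4), the expected
intensity at the unknown pH is
$F_{\mathrm{ctl}}/F_{\mathrm{baf}} \times \mathrm{calib}(7.4)$ — the ratio
cancels ligand loading — and the ligand-specific linear calibration is
inverted. Estimates outside the calibration range carry an extrapolation
flag.

# Secretion and response indices

Percent release is $100\,s/(s + r)$ with $s$ secreted and $r$ residual
content; the denominator (the total synthesized pool) is a recorded
convention since assays differ in whether residual content is measured. The
insulin stimulation index is the fold increase of the mean over the
glucose-only control, so the control is 1 by construction and the index is
invariant to unit rescaling. Trace utilities provide $F/F_{\mathrm{baseline}}$
normalization and trapezoidal AUC relative to a caller-chosen baseline
(value at agonist addition, or a pre-agonist window mean — both conventions
appear in practice, so the baseline is a per-call argument).

# Agonist profiles

`assemble_features()` builds the agonist × feature matrix used for
profiling: $k_{\mathrm{off}}$ normalized to the reference agonist within
each assay before averaging (the rate constant, not residence time, so that
larger values mean faster dissociation), $\Delta\log(\tau/K_A)$ for the two
contrasted pathways, and internalization and recycling percentages at a
fixed time point. Missing cells stay masked; `pca_profile()` refuses masked
cells and offers explicit row dropping, never imputation. Features are
z-scored before the decomposition, making scores invariant to affine
rescaling of any input column.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Dose–response**: 8 log-spaced concentrations (10^−11.5^–10^−6.5^ M),
  3 intra-experiment replicates, 5 independent experiments, Gaussian noise
  with CV 10% truncated at zero — the scale of the cAMP/β-arrestin assays
  being emulated.
* **Binding**: 10 nM tracer, four competitor concentrations spanning
  3 nM–100 nM, reads every 2 min to 60 min, 1% noise; a competitor-free and
  an excess-competitor (10 μM, nonspecific) trace are always included.
* **Trafficking**: the three-state compartment model
  $\dot S = -k_e S + k_r I$, $\dot I = k_e S - (k_r + k_d) I$, with the
  degraded pool $D$ absorbing the balance, is solved analytically via its
  eigenvalues (repeated-root limit handled in closed form) so that no
  integrator tolerance enters round-trip tests; $S + I + D$ is conserved to
  < 10^−9^. FACS stripping efficiency defaults to 90% so the $t_0$
  correction of the internalization formula is genuinely exercised.
  Degraded receptor is modelled as non-fluorescent, so the stripping
  readout reports the endosomal pool — on short time scales this tracks
  $I/(S+I+D)$ to within a few percentage points, and the tests assert
  exactly that tolerance.
* **Endosomal pH**: per-ligand linear calibrations with slopes of
  120–220 AU/pH over pH 4.5–8, random loading factors that must cancel in
  the ratio estimator, and cellular intensities averaged over 8 serial
  reads, mirroring the repeated fluorescence reads of the emulated
  protocol.
* **Secretion**: cumulative release over 16 h modelled as a baseline rate
  plus $\mathrm{coupling} \times \mathrm{occupancy} \times \int S(t)/S(0)\,dt$.
  This coupling law is an explicit generator convention — it plants the
  negative relation between net internalization and prolonged secretion that
  the profiling stage must recover — and is not a mechanistic claim; no
  quantitative trafficking-to-secretion model exists to copy.

A single global seed fans out to independent per-generator streams, so the
full pipeline run is reproducible while the assays remain uncorrelated. All
noise is Gaussian on the linear scale, truncated at zero where the readout
is physically non-negative.

The demonstration panel (`demo_truth()`) plants six agonists spanning the
phenotypes of interest: a reference; a G-biased, fast-dissociating, weakly
internalizing, fast-recycling analog whose β-arrestin-1 response sits below
the noise floor (exercising the unquantifiable path end to end); a
β-arrestin-biased, slowly dissociating, strongly internalizing analog; and
three intermediate licensed-drug-like profiles.

What the generators do **not** emulate: receptor reserve differences between
cell systems, kinetic (time-dependent) bias, ligand depletion and rebinding
in binding assays, heteroscedastic or correlated plate effects, and any
mechanistic β-arrestin/G-protein network. Passing tests therefore
demonstrate correctness of the computations under idealized assay noise,
not robustness to every artefact of real plate data.

# Numerical choices

* Operational-model fitting: L-BFGS-B on bounded parameters (slope
  $n \in [0.2, 5]$, $\log K_A \in [-13, -2]$, $\log(\tau/K_A) \in [0, 15]$),
  starting values read off each curve's half-maximum crossing, followed by a
  restart from the first optimum — the $E_m$/τ ridge is shallow and the
  restart escapes premature termination on it. Standard errors come from the
  Gauss–Newton approximation at the optimum (optional, since the
  cross-experiment SEM drives the bias statistics).
* 4PL fits use Levenberg–Marquardt (`minpack.lm`), which is robust to the
  zero-residual case that defeats Gauss–Newton on noiseless data; flat data
  (span below 3× the replicate SD) is flagged `no_response` rather than
  fitted.
* Competitive fits optimize $\log_{10} k_3, \log_{10} k_4$, which makes the
  search scale-free across the ~10 orders of magnitude separating the two
  rates.
* Degenerate inputs error early with informative messages (classed
  condition `gpcrtraffic_input_error`): zero-width calibrations, failed
  stripping ($t_0$ ratio ≥ 1), zero control means, disjoint time grids.

# Problem sizes

The packaged checks run the bias recovery at 6 agonists × 3 pathways ×
5 experiments, calibrate the significance call on 500 null simulations,
verify the Motulsky–Mahan closed form on 100 random parameter sets against
an ODE oracle, and run the full demo pipeline (all assays, six agonists)
twice for determinism. These sizes were chosen so the whole validation is
comfortable on a laptop while keeping Monte-Carlo standard errors small
(±1% on the type-I rate at 500 simulations).

# Known limitations

* Absolute $\log(\tau/K_A)$ values are reported but are only meaningful up
  to the shared offset discussed above when $n = 1$; comparisons must go
  through Δ and ΔΔ.
* The FACS recycling percentage convention in the literature is ambiguous;
  both readings are emitted, neither asserted as canonical.
* Tracer parameters are assumed known (or estimated upstream) for the
  competitive fit; mis-specified tracer kinetics bias the competitor rates,
  which the cross-method consistency test (dissociation fit vs competitive
  fit) is designed to catch.
* No heteroscedastic weighting, biphasic dose–response models, two-site
  binding, or antagonism (Schild) analysis.
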