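---
title: "Methods: dermal PBPK transport, stepwise calibration and population PD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dermal PBPK transport, stepwise calibration and population PD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its modeling choices: the
assumptions behind the transport engine, the meaning and defaults of the
tunable parameters, what the synthetic-data generator does and does not
emulate, the numerical decisions, and the known limitations. Code chunks are
illustrative and not evaluated at build time.

## 1. The compartmental transport model

All three experimental stages — release through a synthetic membrane (IVRT),
permeation through dermatomed skin (IVPT), and the exposure series driving
the pharmacodynamic endpoints — are views of one engine: well-mixed
compartments exchanging drug across interfaces by the generalized flux law

$$J = P \cdot A \cdot \left(C_\text{source} - \frac{C_\text{target}}{K_p}\right),
\qquad J = 0 \text{ for } t < t_\text{lag},$$

with the compartment balance $V_L\,dC_L/dt = J_\text{in} - J_\text{out}$.
Assumptions this entails:

* **Well-mixed compartments.** No spatial gradients within a layer; the
  stratum corneum is one effective compartment, not a brick-and-mortar
  microstructure.
* **Linear, passive transport.** No binding saturation, metabolism or active
  transport; consequently the system is linear in amounts and doubling the
  drug load doubles every amount trajectory.
* **Bidirectional interfaces.** The flux law carries its own direction via
  the sign of the driving force; the package forbids a second (reverse)
  interface between the same pair to prevent double counting. At steady
  state $C_\text{target}/C_\text{source} = K_p$.
* **Closed systems.** Both Franz-cell models conserve mass exactly; the only
  exits are bookkept explicitly (sample withdrawals, which are recorded, not
  lost).

The state variable is amount (µg), not concentration, so conservation is a
direct row sum and is asserted in tests to a relative 1e-6. Internal units
are fixed (h, mL, cm², cm/h, µg, µg/mL, g/cm³); converters live only at the
I/O boundary (e.g. layer thicknesses are entered in µm, applied gel mass in
mg).

### Numerical choices

* Integration uses a stiff-capable solver (`deSolve::lsoda`) with tight
  defaults `rtol = 1e-8`, `atol = 1e-10`: partition coefficients span many
  orders of magnitude (gel phases vs SC lipids), which makes the system
  stiff.
* A lag is a hard gate on the flux, and the integrator is *restarted* at
  every lag boundary. Within each segment the active subsystem is linear and
  time-invariant, so the discontinuity never crosses a solver step. Output
  points that coincide with a segment boundary (within 1e-9 h) take the
  boundary state.
* Output amounts are clipped at zero; the pre-clipping minimum is kept as a
  diagnostic and tested never to fall below `-atol`.
* The test suite cross-checks the integrator against the matrix-exponential
  solution of randomly generated linear systems (`Matrix::expm`) to a
  relative 1e-5, and against the closed-form solution of the symmetric
  two-compartment system to 1e-6.

## 2. IVRT: two-phase gel release

The gel donor is modeled as two phases: discrete solid drug particles (DP)
suspended in a viscous polymer-like continuous phase (CP). All drug starts
in DP (a suspension of a poorly soluble drug). Four compartments — DP, CP,
membrane (volume = orifice area × thickness × porosity), receptor — and
three interfaces, with the release lag gating DP → CP.

Tunable parameters (per formulation):

| parameter | units | default | meaning |
|---|---|---|---|
| `drug_mass_fraction` | – | 0.001 | 0.1 % w/w gel |
| `applied_mass` | mg | 500 | dose loading: 500 µg of drug |
| `density_discrete` / `density_continuous` | g/cm³ | 1.3 / 1.0 | phase densities |
| `fraction_discrete` | – | 0.01 | drug particles are a trace phase |
| `P_dp_cp`, `Kp_dp_cp` | cm/h, – | 2.9e-6, 8.5e-6 | release kinetics and particle/gel partition |
| `release_lag` | h | 0 | onset delay |

Where the delay acts is not observable from release data alone; the gate
sits on DP → CP (release from the particles) by default because the delayed
formulations differ in their release onset, and the location is
configurable. Membrane permeability (0.5 cm/h) and a non-selective membrane
partition of 1 reflect an inert cellulose membrane.

The shipped example formulations (`default_formulations()`) are **synthetic
placeholders**, not measured properties of any marketed product. They were
designed once, jointly, to satisfy three requirements and then frozen:

1. *Scale realism*: cumulative release of a few µg/cm² over 24 h (well under
   1 % of dose, as expected for a log P ≈ 7 drug), epidermis accumulation of
   order 0.1 µg/mg, dermis ~50-fold lower per weight, receptor trace below
   the 0.05 µg/mL LOQ.
2. *Censoring realism*: receptor concentrations cross the LOQ mid-study, so
   early samples are recorded as 0 (`bloq`), with the fastest formulation
   quantifiable first.
3. *Identifiability*: the release operates near ~50 % saturation of the
   DP/CP equilibrium over the 24 h window, so the initial slope identifies
   `P_dp_cp`, the late-time flattening identifies `Kp_dp_cp`, and the onset
   identifies the lag from the stated 6-replicate design. A configuration
   far from saturation leaves `Kp_dp_cp` unidentified; one at high
   saturation leaves `P_dp_cp` unidentified.

The default sampling schedule (13 points over 24 h, denser early) resolves
the post-lag transient; withdrawals are 0.5 mL with replacement.

**Sample-and-replace.** `simulate_release_sampled()` replays the withdrawal
protocol (integrate to each sampling time, record the concentration, remove
`C·V_s`), and `sampling_corrected_cumulative()` reconstructs
$Q(t_n) = (C_n V_\text{rec} + \sum_{i<n} C_i V_s)/A$. Within the sampled
simulation this reconstruction is an exact mass-balance identity (tested to
1e-8). Against the *closed* (no-withdrawal) simulation the sampled protocol
releases a few percent more, because withdrawals keep the receptor closer to
sink conditions — a genuine protocol effect, not an artifact; the release
calibration therefore uses the protocol-faithful forward model, without
which the generating parameters cannot attain a zero objective.

## 3. IVPT: the dermal model

Seven compartments (DP, CP, SC, sebum, VE, DM, receptor) and nine
interfaces, including a trans-follicular pathway fed from the gel continuous
phase (CP → SB, through follicular openings taken as 0.1 % of the exposed
area) that can deliver drug to SC, VE and DM in parallel. Dermatomed skin:
DM → receptor is the only exit, with no systemic clearance (a clearance sink
is an explicit extension point).

Default anatomy (all configurable): SC 12 µm, VE 53 µm, DM 735 µm over
0.69 cm², epidermis density 1.2 g/cm³ and dermis 1.5 g/cm³ — chosen so that
thickness × area × density reproduces tissue weights of ~1 mg (SC), ~4.4 mg
(VE) and ~75 mg (DM) at a total thickness of 800 µm. Sebum volume defaults
to 0.1 % of the SC volume, consistent with the follicular area fraction.
The receptor holds 4.9 mL.

Default transport parameters encode lipophilic physics: strong partitioning
from the aqueous continuous phase into SC lipids (`Kp` CP→SC = 2000),
unfavorable egress into viable tissue (`Kp` SC→VE = 0.01), moderate VE→DM
transfer and minimal receptor permeation. They are synthetic placeholders in
the same sense as the release parameters.

`layer_accumulation()` reports what a mechanical separation measures:
epidermis = (SC + VE + sebum)/(SC + VE weight) in µg/mg, dermis = DM/weight.
The sebum amount cannot be isolated by separation; it is assigned to the
epidermis fraction by default (the infundibulum opens at the epidermal
level) and can be assigned to dermis or excluded. Percent recovery
`100·(epidermis + dermis + residual donor + receptor)/dose` is exactly 100 %
on simulated output and quantifies assay mass balance on experimental data.

Exposure for the PD stage: the SC concentration is SC amount / SC volume;
the infundibular exposure is 0.1 % of it, the same fraction as the
follicular surface-area share.

## 4. Stepwise calibration

Stage 1 (release) frees only `{Kp_dp_cp, P_dp_cp, release_lag}` per
formulation against IVRT data. Stage 2 (skin) consumes stage-1 results
unchanged and frees only the CP→SC partition coefficient and the partition
coefficients at DM-involving interfaces (VE→DM, SB→DM, DM→REC), fitted once
on pooled data across formulations — so any difference between formulations
in the IVPT predictions is attributable to the release parameters alone.
Freeing any other parameter is a configuration error, and the tests assert
that a skin-stage fit leaves the release parameters bit-identical.

The optimizer is a bounded derivative-free simplex search (Nelder–Mead on a
bounded-logit reparameterization, with a refinement restart and optional
seeded multi-start); a manual, iterative exploration is not reproducible
engineering, but a `--grid`-style multi-start emulates it. The objective is
the sum of squared deviations on replicate-pooled profiles; a `1/obs²`
weighted variant is provided and is the maximum-likelihood-consistent choice
when measurement noise is proportional (the synthetic generator's error
model), which is why the recovery tests use it. Observations recorded as 0
because they fell below the LOQ are excluded from the objective and from the
ratio metrics (MAPE, AFE): a zero carries no quantitative information and
would otherwise force division by zero. `n_points` in the metrics report
records how many pairs each metric used.

The six-metric battery: RMSE, MAPE (over positive observations), AFE
(geometric-mean fold error, $10^{\overline{\log_{10}(p/o)}}$, ideal 1; the
absolute variant AAFE is reported alongside because the two differ when
over- and under-predictions cancel), bias (mean error, ideal 0), R² (share
of variance explained; negative when the predictions do worse than the
observed mean) and Pearson r. An independent naive reimplementation in the
test suite agrees to a relative 1e-10 on 1000 random pairs.

**Morris screening** (`morris_screen`) implements the standard
one-at-a-time elementary-effects method on a `levels`-point grid: `mu_star`
(mean |EE|) ranks influence, `sigma` (EE standard deviation) flags
interaction/nonlinearity. Trajectories whose model output is non-finite are
dropped with a warning; a fixed seed reproduces the result exactly.

## 5. Population pharmacodynamics

Structural model: direct-response sigmoid Emax,
$E = E_{max} C^n/(EC_{50}^n + C^n) + E_0$, with `Emax` allowed either sign
(both clinical endpoints — infundibular cross-sectional area and SC
thickness — decrease with exposure, so `Emax` is negative and `E0` is the
positive baseline). Disabling sigmoidicity fixes $n = 1$. Residual error is
proportional, $y = f(1 + b\varepsilon)$ with the exponent fixed at 1;
between-subject variability is log-normal,
$\theta_i = \theta_{pop} e^{\eta_i}$, by default on every structural
parameter, with per-parameter disable switches. `E0` is a constant
per-subject baseline (zero exposure returns `E0` exactly); a time-varying
natural drift of the baseline is not modeled — with observations at three
time points it is not separable from the drug effect.

**Estimation** is deliberately deterministic: safeguarded iterative
two-stage (ITS) with a Laplace-approximated marginal likelihood, rather than
a stochastic EM. Each outer iteration (i) computes every subject's empirical
Bayes estimate — the mode of
$\tfrac12\,\text{neg2ll}(\theta_{pop}e^\eta) + \tfrac12\sum\eta^2/\omega^2$
— and its local Hessian; (ii) proposes population updates: fixed effects by
the geometric mean of individual parameters, BSV variances by the centered
second moment of the EBEs *plus* the mean Laplace posterior variance (the
shrinkage correction, without which $\omega^2$ is biased low), and the error
parameter by the RMS relative residual. A proposal is accepted only if the
Laplace OFV does not increase; otherwise the step is halved in log space (up
to five times), which makes the OFV trace monotone non-increasing by
construction. A final bounded simplex polish then refines *all* population
parameters — including structural fixed effects that carry no BSV, which the
moment updates cannot move — again accepted only on OFV improvement. With
all BSV variances at zero the model collapses to a pooled fixed-effects fit
by direct likelihood optimization (the error parameter profiled out).

The Laplace OFV for subject $i$ with mode $\hat\eta$ and Hessian $H$ of the
negative log joint is
$-2\log L_i \approx 2\,l(\hat\eta) - d\log 2\pi + \log\det H$; Hessians are
central finite differences (step 1e-4), falling back to the prior curvature
when not positive definite. Information criteria: AIC = OFV + 2P,
BIC = OFV + P·ln(N subjects), and BICc splits the penalty by level —
subject-level parameters (fixed effects, ω²) by ln(N subjects), the error
parameter by ln(N observations). This split is one defensible reading of a
"corrected" BIC; the exact composition used by commercial tools is not
published, and the package treats the choice as a reporting convention, not
an inferential one.

**Diagnostics.** `vpc()` simulates the design under the fitted model
(default 1000 replicates; 10 000 reproduces the heavier published setting)
and returns the 10th/50th/90th percentile trajectories with confidence
bands. `residual_diagnostics()` returns IWRES $(y - f_i)/(b f_i)$ against
individual predictions and simulation-rank NPDE (inverse-normal of the
observation's rank among `n_sim` seeded replicates); under the true model
both are approximately standard normal, and the tests assert |mean| < 0.15
and |sd − 1| < 0.15 at 500 observations. `ebe_by_formulation()` summarizes
individual parameters by formulation (median, IQR) for covariate
exploration when formal covariate modeling is not supportable at the sample
size.

### The recovery experiment

The package's strongest self-check regenerates data and refits: 50 subjects,
13 observations each (0–48 h every 4 h), exposure ramping to ~4× EC50, BSV
on `Emax`, `EC50`, `E0` (ω² 0.04/0.09/0.04), Hill coefficient 2 estimated as
a pure fixed effect, `b = 0.1`. Recovery criteria: every fixed effect within
15 %, every ω within 30 %. The design carries BSV on three parameters
because the variance of a subject-level Hill coefficient is not recoverable
to that precision from 50 subjects even at the exact likelihood optimum —
the information is confounded with the EC50 variance — and a recovery test
should test the estimator, not the design's identifiability limit. Under a
*sparse* clinical design (6 subjects, 3 time points) recovery degrades
substantially; the pipeline still runs it, reports the estimates, and makes
no recovery claim.

## 6. What the synthetic generator emulates — and what it does not

Emulated: the replicate structure (6 Franz cells per formulation),
proportional measurement noise (default CV 5 %), the 0.05 µg/mL LOQ with
below-LOQ values stored as zero plus a `bloq` flag, sample-and-replace
receptor kinetics, destructive tissue sampling at 8/12/24/36 h with exact
100 % mass balance before noise, sparse clinical sampling (baseline, ~5 h
for the 4–6 h window, 48 h) with log-normal BSV and proportional error, and
a fast → slow release ordering across the three example formulations.
Random effects implying a non-positive structural prediction (a negative
area or thickness) are redrawn — a truncated-BSV convention that keeps the
generator consistent with the proportional-error likelihood.

Not emulated: inter-donor skin variability (one skin parameter set per
study, which is also the calibration assumption), formulation rheology and
viscosity effects on diffusivity, evaporation and metamorphosis of the
vehicle, analytical carry-over, correlated noise across time points within a
cell, hair-follicle imaging endpoints' segmentation error structure, and any
systemic clearance from the dermis. Passing tests therefore demonstrate the
estimators and the transport engine are correct under the stated error
model, not that the shipped parameter values describe any real formulation
— the shipped values are placeholders pending calibration on real curves.

## 7. Known limitations

* The SC is a single effective compartment; steep within-SC gradients and
  brick-and-mortar tortuosity are out of scope.
* Calibration identifies at most what the data constrain: with heavy LOQ
  censoring (a slow formulation) the partition coefficient is weakly
  identified, and the fit flags bound hits rather than failing.
* The Laplace OFV is an approximation; for very sparse subjects (2–3
  observations, 3–4 random effects) the posterior can be strongly
  non-Gaussian and the ITS estimates inherit that bias.
* `percent_recovery` near 100 % on experimental data indicates assay mass
  balance, not model validity.
* The PD stage treats exposure as the model-predicted concentration at the
  observation time (direct response); hysteresis, effect compartments and
  indirect response models are out of scope.
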