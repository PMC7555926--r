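---
title: "Modelling nerve excitability in diet-induced prediabetes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nerve excitability in diet-induced prediabetes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`axotrace` reproduces, in silico, the analysis pipeline of a nerve
excitability study in cafeteria-diet (CAF) prediabetic rats: a biophysical
model of a myelinated motor axon is driven through threshold-tracking
protocols, its membrane parameters are fitted to group-mean excitability
indices by weighted least squares, and the resulting single-parameter
perturbation scan asks which biophysical change best explains the group
difference.  A companion layer implements the study's metabolic index
computations, the up–down tactile threshold estimator, normality-gated
group tests and correlation screens, and a seeded synthetic-cohort
generator so that the full pipeline runs without any external data.

# The axon model

The axon is reduced to two electrical compartments: a node of Ranvier and
its internode, coupled by the Barrett–Barrett conductance `G_BB` that
represents the current paths through and underneath the myelin sheath.
Each compartment obeys a current balance (outward currents positive, units
pA = nS × mV, ms = pF/nS):

$$C_n \dot V_n = -\big(I_{NaT} + I_{NaP} + I_{Ks,n} + I_{Kf,n} + I_{Lk,n}
  + f_{pump} I_{pump}\big) - G_{BB}(V_n - V_i) + I_{stim}$$
$$C_i \dot V_i = -\big(I_{Ks,i} + I_{Kf,i} + I_H + I_{Lk,i} +
  (1-f_{pump}) I_{pump}\big) + G_{BB}(V_n - V_i)$$

with ohmic driving forces \(G\,x\,(V - E)\) and Hodgkin–Huxley-style gates:
transient Na\(^+\) activation/inactivation \(m^3 h\), persistent Na\(^+\)
\(p^3\) (a fraction `f_NaP` of the Na conductance), slow K\(^+\) \(s\) in
both compartments, fast K\(^+\) \(n_f^4\), and the
hyperpolarization-activated conductance \(q\) (HCN) in the internode.  The
Na\(^+\)/K\(^+\)-pump is a voltage-independent net outward current
`I_pump` split between the compartments by `f_pump_node`.

Ohmic driving forces were chosen over GHK flux equations for
implementability; the baseline calibration step absorbs the difference, and
no claim is made that the shipped coefficients equal those of any other
software.  Ion-concentration dynamics (periaxonal K\(^+\) accumulation)
are out of scope; the pump parameter acts purely electrically.

## Gating kinetics and their functional forms

Rates are evaluated from a per-gate coefficient table supporting four
functional forms (rising/falling linoid, exponential, sigmoid), with the
removable singularity of the linoid form handled by its analytic limit
\(A\,C\) at \(V = B\), and Q10 temperature scaling
\(Q_{10}^{(T - T_{ref})/10}\) applied to both rates.  The *shipped
defaults* use sigmoid α/β pairs: with
\(\alpha = A_\alpha/(1+e^{-(V-B)/C})\) and the mirrored β, the steady
state is exactly sigmoid while the time constant varies smoothly between
\(1/A_\alpha\) and \(1/A_\beta\).  This family was chosen after classic
linoid/exponential pairs proved numerically fragile here: their time
constants collapse at spike voltages, letting slow K activate fully during
a 1 ms action potential, which produces recovery cycles unlike recorded
rodent data.  The default coefficients are calibration inputs, not
physiological claims.

## Numerical integration

Trajectories use an adaptive Dormand–Prince RK45 integrator implemented in
C++ with steps forced onto stimulus edges, a step cap near edges and during
suprathreshold excursions (so spikes cannot be stepped over), gates clamped
to [0, 1], and a relative tolerance of 1e-8 by default.  A smooth
regularisation bounds gate time constants from below
(`tau_floor`, default 0.02 ms): both rates are scaled by
\(1/(1 + (\alpha+\beta)\tau_{floor})\), which leaves every steady state
unchanged while capping stiffness.  Action potentials are scored as upward
crossings of 0 mV at the node, located by within-step interpolation.

The model is always run *unclamped*: `resting_state()` re-solves the full
equilibrium (relaxation integration followed by a damped Newton polish on
the two potentials with gates at steady state) after any parameter change,
so that perturbations such as a reduced pump current are allowed to move
the resting membrane potential — this is the mechanism by which the pump
manipulation acts on every excitability index.

# Threshold tracking

In a single-axon model the response is all-or-none, so the experimental
"40% of maximal compound action potential" tracking target reduces to the
minimal current that elicits a spike.  `find_threshold()` bisects on the
amplitude of a 1 ms test pulse until the bracket is narrower than 0.5% and
reports the midpoint; a brute-force amplitude scan (`threshold_scan()`)
serves as the independent oracle in the tests.  The four paradigms follow
the standard TROND-style protocol constraints: strength–duration at
0.2–1.0 ms reduced by Weiss's law to rheobase and SDTC; threshold
electrotonus with 100 ms conditioning at ±20/±40% of threshold;
a current–threshold relation measured at the end of 200 ms conditioning
from +50% to −100% in 10% steps; and a recovery cycle after a supramaximal
(2× threshold) conditioning stimulus with a minimum interstimulus interval
of 2.5 ms.  The exact delay/ISI lattices are config-exposed defaults
(log-spaced, honouring the printed constraints); indices defined at
printed time points (refractoriness at 2.5 ms, superexcitability at 5 ms,
TEd over 10–20 ms) do not depend on lattice choices, while subexcitability
(the largest late threshold increase, window 10–100 ms) depends mildly on
them.

Superexcitability is reported as percentage threshold *reduction*
(positive = more excitable).  This is the only convention under which the
recorded group values (chow −0.65, CAF 2.14, with CAF "increased") are
mutually consistent.

Because thresholds are bisected to a 0.5% bracket, remeasuring the control
threshold can legitimately move percentage indices by up to about one
point; the tests assert stability at that bracket-tolerance level.

# Fitting and the perturbation scan

The discrepancy between simulated and recorded curves is the weighted
mean-squared error over the four paradigms (weights 0.5, 1, 1, 3 for
strength–duration, electrotonus, current–threshold and recovery cycle),
with percentage threshold change as the compared quantity and
100·log10(threshold) for strength–duration; it is symmetric, zero only on
identity, and lattice-size invariant.  Whether recorded-data errors should
additionally be normalised per point by measurement SD is unknowable from
the study; the weight-only form is the documented default.

Baseline calibration (`calibrate_chow_baseline()`) minimises the SEM-scaled
squared error of the five recorded indices over nine membrane parameters
with a seeded multi-start Nelder–Mead simplex (objective is
simulator-defined, so the search is derivative-free; conductances are
searched on a log scale, fractions on a logit scale).  Curve fitting
(`fit_parameters()`) minimises the discrepancy on the recorded lattices;
single-parameter fits use golden-section search, multi-parameter fits a
simplex seeded from the best single-parameter solution, which guarantees
that adding a parameter never worsens the fit.  The perturbation scan runs
each of the twelve candidate parameters alone and ranks them by percentage
discrepancy reduction; `add_second_parameter()` reports the incremental
benefit of each second parameter on top of the winner.

The recorded waveforms behind the study's own fit are unpublished, so the
printed 66% reduction is not a reproduction target; the procedure is
instead validated by parameter recovery on synthetic recordings with known
truth (a −15 pA pump change plus 1% log-threshold noise).

## Two-stage parameter recovery

Recovering a perturbed parameter from noisy recordings uses a two-stage
scan (`two_stage_scan()`): every candidate is first fitted with an equal
bounded budget on lean protocol lattices (26 points) to shortlist the
best explanations, and the top three are then re-fitted and re-ranked on
dense lattices (a full recovery cycle and current–threshold relation).
Both stages matter quantitatively: on the lean lattices alone, 1%
recording noise interacting with threshold quantisation both biases the
recovered pump change by several pA and lets mimicking conductances
outscore the true parameter, while the dense stage is unbiased to within
the stated ±2 pA and discriminates most mimics.  Two supporting
numerical choices follow from the same analysis: synthetic recordings
and fitting simulations use a finer bisection tolerance (0.25%) than
interactive protocol runs, so that quantisation stays well below the
recording noise.  Even so, at 1% noise the ranking is not perfectly
reliable in this model: a nodal slow-K conductance increase explains
roughly two in ten noisy recordings slightly better than the true pump
change, because without the periaxonal-K mechanism (below) the pump's
remaining curve signature overlaps the slow-K axis.

## Default parameters and the pump split

The shipped defaults were calibrated offline with the same seeded simplex
machinery the package exposes, against a joint objective: the chow-group
indices from the parameter set itself, and the CAF-group indices from the
same set with the pump current reduced by 15 pA.  Two design choices
matter for pump sensitivity:

* The overall conductance scale puts the 1 ms threshold at O(100–500 pA),
  the scale at which threshold-tracking axon models operate; at a 10×
  larger scale a 15 pA pump change is electrically negligible.
* `f_pump_node` defaults to a calibrated constant rather than the
  capacitance-proportional split, which would route ~99% of the pump to
  the low-resistance internode and mute the manipulation entirely.  The
  split is fully configurable, and no claim is made about the true nodal
  fraction of pump density.

## What a standing pump change can and cannot reproduce

Reducing the pump depolarizes the resting potential (unclamped mode), and
the model then reproduces most of the recorded cafeteria-group signature:
refractoriness rises, depolarizing threshold electrotonus falls slightly,
the I/V slope and subexcitability barely move.  It does **not** reproduce
the increase in superexcitability at 5 ms.  This is a property of the
model class, not a fitting failure: in a two-compartment ohmic model with
fixed reversal potentials, any standing depolarization — pump reduction
at either compartment, or a static depolarizing shift of the internodal
K\(^+\) reversal (implemented as the optional `k_EK_pump` coupling,
shipped disabled) — lowers the 5 ms superexcitability, because the
resting Na inactivation and slow-K engagement costs at the node always
outweigh the depolarizing-afterpotential gain.  The mechanism that links
a pump deficit to *increased* superexcitability physiologically is
per-impulse periaxonal K\(^+\) accumulation: each action potential
transiently depolarizes the local K\(^+\) reversal, and a weaker pump
clears it more slowly, enlarging the depolarizing afterpotential.  That
is an ion-concentration dynamic and therefore outside this package's
model scope.  Consequently the pump-only re-fit against the CAF indices
finds a small (near-zero, weakly negative) pump change and a
superexcitability around −1.3 rather than +2.1; the corresponding
acceptance check fails by design and this limitation is stated here
rather than papered over.  Parameter *recovery* (identifying and
quantifying a known pump change from synthetic recordings) is unaffected
and fully validated.

# Study statistics

The metabolic indices are exact formula implementations: HOMA-IR =
insulin (mU/L) × glucose (mmol/L)/22.5; TyG = ln(triglycerides (mg/dL) ×
glucose (mg/dL)/2); Lee index = weight(g)^(1/3)/length(cm) with the
rounded 0.33 exponent available as an option (about a 2% difference at
adult weights); glucose-tolerance AUC by the trapezoid over 0–180 min.
Note that the recorded group-mean TyG values (9.87/10.30) are not
reproducible from the printed formula applied to the group-mean
triglycerides and glucose (which give ≈8.5); the formula as printed is
implemented and the inconsistency left unresolved.

Correlation p-values use the exact t-transform
\(t = r\sqrt{n-2}/\sqrt{1-r^2}\) (two-sided, df = n−2); Spearman applies
the same transform to midrank correlations (the standard large-sample
approximation).  Group comparisons are gated by Shapiro–Wilk normality on
each group (α = 0.05): both normal → unpaired equal-variance t-test,
otherwise Mann–Whitney U with midranks.  One reported association
(r = −0.527, p = 0.043, n = 16) is inconsistent with the Pearson
t-transform (which gives 0.036) and may be a Spearman p; it is not used as
an exact check.

The up–down 50% paw-withdrawal threshold uses the Chaplan-form estimator
\(10^{x_f + k\delta}\) on the 10-filament 0.4–15 g set with the boundary
rules (continuous positives → 0.4 g, continuous negatives → 15 g).  The
pattern coefficients *k* are generated by a brute-force probit
maximum-likelihood oracle on the idealized uniform log-force lattice with
slope σ = δ (the classical up–down assumption); the packaged table
(`inst/extdata/vonfrey_k_table.csv`) is reproducible via
`build_vonfrey_k_table()`, and the probit MLE itself is exported as an
alternative estimator.  Estimates are clamped to the physical 0.4–15 g
range of the set.

# The synthetic cohort

The generator emulates the study's *statistical* structure, not its
biology: per-group multivariate normals over the recorded group means with
SD = SEM·√14, a configurable pooled correlation structure between
superexcitability and the metabolic measures (targets from the reported
associations: fat mass 0.497, body weight 0.483, lean mass 0.469, HDL
−0.495, leptin 0.484, rpWAT 0.506), gamma-pulse glucose excursions on the
study's sampling lattice, probit-governed up–down response sequences, and
model-generated excitability curves with multiplicative log-threshold
noise.  Pooled targets are converted to within-group correlations
analytically (the between-group mean separation contributes
\(d_x d_y/4\) to the pooled covariance); the defaults were chosen jointly
positive-semidefinite so no repair is needed, and any non-PSD user
configuration is repaired to the nearest correlation matrix with the
repair logged.  Fat mass, lean mass and fasting insulin are not tabulated
in the study; their generator means (70/190 g fat, 420/480 g lean,
12/35 mU/L insulin) are representative values for 15-week chow- versus
cafeteria-fed Sprague-Dawley rats and are config-exposed.

What passing tests on synthetic cohorts demonstrate is that the analysis
layer recovers structure the generator put in (effect directions,
correlation magnitudes, estimator consistency); they cannot validate the
biological claims of any real dataset, non-normal tails, measurement
artefacts, or missingness patterns, none of which are modelled.

# Problem sizes and runtime choices

The calibration objective evaluates only the lattice points each index
needs (about 18 threshold searches per evaluation) with a 3-restart,
400-evaluation budget, stopping as soon as every index lies within 0.8
SEM of its target — below 1 SEM by enough margin that an independently
re-measured index stays within one SEM despite bisection jitter.  The
scan stages use the 26-point lean and 57-point dense lattices described
above with bounded per-candidate budgets.  Batch runs relax the solver
step cap and tolerance (0.5 ms / 1e-5), which leaves every index
unchanged at the bisection precision; threshold searches integrate each
conditioning waveform once and bisect only over the 3 ms test window.
Monte-Carlo checks use 1000 replicate cohorts (correlation structure),
400 sequences (up–down consistency) and 10 noisy recordings (parameter
recovery).

# Known limitations

* Two compartments and ohmic currents: no paranodal cable structure, no
  ion accumulation, no GHK rectification; the pump acts only through its
  standing current.
* Single axon: stimulus–response and CMAP-amplitude phenomena have no
  analogue; sensory excitability is not modelled.
* The calibrated coefficients are one point in a degenerate set — many
  parameter combinations reproduce five indices; only the directions probed
  by the perturbation machinery are constrained by data.
* Subexcitability and the non-printed lattice points depend mildly on the
  chosen default lattices.
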