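---
title: "Finite-dose penetration through a three-compartment cuticular membrane: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-dose penetration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuticleflux)
```

# The system being modelled

An isolated fruit cuticular membrane (CM) is clamped between two glass
half-cells of roughly 150 mL each. The donor cell starts with a hydrophobic
solute (phenanthrene in the motivating experiments) at 0.05–0.46 mg/L; the
receiver starts clean. Small aliquots (0.3–0.5 mL) are withdrawn
periodically from both cells for HPLC quantification and are not replaced,
so cell volumes shrink over a two-week run and the withdrawn mass must be
book-kept. Because the donor is never replenished, the system is
*finite-dose*: the driving gradient decays, and the receiver accumulation
curve is sigmoidal — hold-up, quasi-linear, plateau.

The membrane itself is treated as three stacked compartments with very
different sorption affinities: epicuticular waxes (EW, outermost, strong
sorbent), cuticle proper (CP, cutin and intracuticular waxes — by far the
largest reservoir), and the cuticular layer (CL, cutan and
polysaccharides, the weakest sorbent). Sorption is linear:
a compartment exposed to solution concentration $c$ holds
$K_{d,X}\,c\,m_X$ at equilibrium.

# The five-pool exchange model

## State and rate law

The simulator tracks masses in five well-mixed pools along the chain
donor | EW | CP | CL | receiver. Each pool carries a solution-scale
activity $a_i = M_i / W_i$, with capacity $W_i$ equal to the cell volume
(L) for the solutions and $K_{d,X} m_X$ (L, mass in kg) for a compartment.
The net flow across interface $i$ is

$$F_i = k_i\,(a_i - a_{i+1}) \quad [\mathrm{mg/h}],$$

with conductance $k_i$ in L/h. Two consequences follow by construction:

* **Detailed balance.** All net flows vanish exactly when every activity
  equals $c_\mathrm{eq} = M_0 / (V_d + V_r + \sum_X K_{d,X} m_X)$, so the
  simulator's long-time state is the closed-form sorption equilibrium of
  `equilibrium_state()` (tested to 0.1 %).
* **Conservation.** The generator's columns sum to zero; states are
  propagated between events by matrix exponentials (`Matrix::expm`), which
  is exact for a linear constant-coefficient system — no step-size error,
  nonnegative states, and mass conserved to machine precision including
  the aliquot loss ledgers.

Temperature enters by scaling all four conductances with
$Q_{10}^{(T - T_\mathrm{ref})/10}$ under a piecewise-constant temperature
program; every segment boundary and every sampling event restarts the
propagation, so discontinuities are exact.

Aliquot withdrawals remove `c * v` mg from the sampled cell, shrink its
volume, and append to that cell's cumulative loss ledger (samples are
quenched in acetonitrile for HPLC, not returned). Recorded states at an
event time are post-sampling; concentrations are unchanged by removal.

A membrane compartment with zero capacity (a dewaxed membrane's EW, or a
zero $K_d$) is bridged by the series combination of its two interface
conductances, which keeps the chain well-defined for degenerate membranes.

## Orientation

`orientation = "reverse"` mounts the membrane with the inner (CL) side
facing the donor — the chain becomes donor | CL | CP | EW | receiver with
the interface conductances reversed. With symmetric conductances
($k_1 = k_4$, $k_2 = k_3$) the reverse receiver curve reproduces the
forward one exactly, which is the package's encoding of the observed
reversibility of cuticular transport. The mass-balance inversion is
orientation-aware: whichever face touches a solution is equilibrium-tied
to that solution.

# Estimators

`cumulative_penetrated()` computes the receiver-side loss-corrected series
$M_t = c_r V_r + \sum M_{\Delta r,t}$, per area and per dose.
`segment_phases()` scans every contiguous window of at least 4 points and
keeps the longest (in time span) whose OLS fit reaches $R^2 \ge 0.995$,
ties broken toward the earlier window. Exactly flat windows have undefined
$R^2$ (zero ordinate variance) and are excluded: a constant series carries
no rate information, so an all-flat curve raises the segmentation error
rather than returning an arbitrary window. `fit_linear_phase()` then gives
$J_\mathrm{max}$ (slope), the hold-up time ($-$intercept/slope, clipped at
0) and $R^2$.

The permeance is pure unit algebra: a flux in g·m⁻²·h⁻¹ divided by a
concentration in mg/L (= g/m³) is m/h, so $P = (J/\Delta c)/3600$ m/s with
no other factors. Two conventions for $\Delta c$ are exposed: the
concentration gradient interpolated at the linear-window midpoint
(single-experiment mode), and the dose–response mode
`dose_response_fit()`, a through-origin regression of $J_\mathrm{max}$ on
$C_{d,0}$ whose slope/3600 reproduces the published permeance form (zero
dose must force zero flux, hence no intercept; $R^2$ is computed about the
through-origin model). When matching printed two-significant-figure
values, truncation rather than rounding is used (0.0028/3600 =
7.78×10⁻⁷ prints as 7.7×10⁻⁷).

`temperature_segment_fit()` fits each constant-temperature period
independently and reports slope ratios. Within each segment the fit is
restricted to the segment's own linear sub-window (same scan, minimum 3
points): the first segment of a cold-started run contains the hold-up
phase, and regressing through it would understate that segment's rate and
inflate every fold. When no sub-window reaches the threshold the whole
segment is used and flagged.

`invert_compartments()` implements the sorption-equilibrium mass balance
(see the README for the formulas) and never clamps the CP remainder:
early negative CP values are the recognized diagnostic of
pre-equilibrium. The negative-load guard that rejects corrupt inputs is a
*fraction of the dose* (default 5 %), not machine tolerance, because 2 %
multiplicative measurement noise routinely makes the inferred membrane
load slightly negative in the first hours of a run.
`flux_decomposition()` differentiates the series with central differences
(one-sided, and flagged, at the endpoints); an optional 3-point running
median is available for noisy data but off by default.

# The synthetic-experiment generator

`make_scenario()` + `synthesize_experiment()` emulate the laboratory
design: 150 mL cells, a 12 mg membrane with mass fractions 6.2 / 64.8 /
29.0 % (EW/CP/CL), sorption surrogates $K_{d,EW}$ = 48,880 and $K_{d,CL}$
= 7,090 L/kg, and a whole-membrane $K_d$ per species (48,880 green pepper;
40,747 tomato; 54,017 apple) closed into $K_{d,CP}$ by
`effective_cp_partition()` — the mass-weighted mean of the compartment
coefficients must equal the whole-membrane value. Observation noise is
mean-preserving multiplicative lognormal (default CV 2 %, motivated by
HPLC-fluorescence repeatability; the source reports no analytical CV) with
a detection floor (default 5×10⁻⁴ mg/L) below which concentrations are
reported as 0 — this is what censors the receiver signal during hold-up.
The observed loss ledgers are rebuilt from the *reported* concentrations,
as an analyst would; the simulation keeps the exact ones. Everything is
deterministic given the scenario seed.

The default schedule samples both cells at 0, 12, 24 h and then every 24 h
to 360 h with 0.4 mL aliquots; the temperature preset samples denser (12 /
6 / 4-hourly in its 15 / 25 / 35 °C periods, within the reported "4 to 17
samples" per period). The exact laboratory times were published only as
figure points; these are plausible reconstructions and are configurable.

## The exposed area

The source material prints two mutually inconsistent geometries: a
membrane area of 7.85×10⁻² m² next to the penetration equations, and a
"1 mm diameter" round hole in the methods (7.85×10⁻⁷ m²) — five orders of
magnitude apart, and *neither* is consistent with the printed kinetics.
With a dose of $M_0 = 0.34 \times 0.15 \approx 0.05$ mg, a rate of
0.0016 g·m⁻²·h⁻¹ over 7.85×10⁻² m² would move 0.126 mg/h, draining the
dose in minutes; over 7.85×10⁻⁷ m² the receiver would never approach
equilibrium within the run, so no sigmoid, no plateau, and a relative
penetration of a fraction of a percent. The presets therefore use
**A = 7.85×10⁻⁶ m²** — the printed mantissa with the exponent fixed by
self-consistency. At that order of magnitude the printed maximal rate, a
receiver equilibrium share of ~17 % of the dose, an extended (hundreds of
hours) quasi-linear phase and a hold-up resolvable by periodic sampling
coexist. `membrane_spec()` keeps the printed 7.85×10⁻² m² as its
documented default constant, and all three conventions are selectable —
area is an ordinary field.

## Calibrated kinetics

The source reports no rate constants, so the preset conductances are
calibrated once (`scripts/calibrate.R`) and frozen:

* The **structure** $k = \kappa \times (5,\ 0.12,\ 1,\ 0.4)$ for
  (donor–EW, EW–CP, CP–CL, CL–receiver) was selected by grid search so the
  green-pepper preset jointly shows a hold-up inside the published 18–48 h,
  a 3–6-fold decline of the donor–receiver gradient across the linear
  window, and the charging-phase flux ordering $J_2 > J_3 > J_4$. Slow
  EW→CP exchange makes CP charge gradually (the hold-up), and the moderate
  CL→receiver conductance adds a small-capacity delay without slowing the
  flux's approach to steadiness.
* The **scale** $\kappa$ per species is bisected so the noiseless
  default-schedule run, analysed with the package's own estimators, hits
  the published maximal rate at $C_{d,0}$ = 0.34 mg/L (0.0016 / 0.0012 /
  0.00079 g·m⁻²·h⁻¹ for green pepper / tomato / apple).
* The **temperature coefficient**. A microscopic $Q_{10}$ = 1.92 would
  make the instantaneous rate ratio between 15 and 35 °C equal 3.69, the
  midpoint of the published 3.0–4.4 measured fold. But the published fold
  is a ratio of *segment regression slopes* from a cold-started run, and
  in a compartment chain with these capacities the first (15 °C, 0–144 h)
  segment never reaches its quasi-steady flux — its fitted slope
  understates the true 15 °C rate, and the measured fold with
  $Q_{10}$ = 1.92 lands far above the published range for every rate
  structure that also satisfies the hold-up and gradient phenomenology.
  This is a structural property of well-mixed compartments (exponential
  approach) versus real Fickian lag (much sharper onset), not a tuning
  issue. Since the published observable is the measured fold, the
  preset default $Q_{10}$ is calibrated the same way as the rate
  constants — bisected so the default temperature-program preset's
  measured fold is 3.7 (giving $Q_{10} \approx 1.58$) — and the
  microscopic 1.92 remains selectable via the `Q10` override.

The dewaxed preset removes EW (mass fractions renormalized over the
remaining 11.256 mg) and, critically, removes the wax *resistance*: the
donor then meets CP through a bare interface as fast as the former
donor|EW one (implemented by doubling both bridged conductances so their
series equals the boundary value). Without this, dewaxing would merely
delete a small capacity and accumulation would barely change; with it, CP
charges much faster, reproducing the observed enhancement.

The bi-solute preset simulates pyrene (0.06 mg/L) as a fully independent
system — linear sorption has no competition, so superposition is exact and
the primary solute's trajectories are bit-identical with and without the
competitor. The PYR sorption constants shipped (3× the PHE ones) are
illustrative, not literature values, and are flagged as such.

# What a green test establishes — and what it does not

The generator reproduces the *statistical and structural* features of the
laboratory design: finite dose, shrinking volumes, loss ledgers, censored
hold-up, sigmoidal accumulation, species ordering, temperature response,
dewaxing and orientation effects. It does not reproduce: spatially
resolved diffusion through the membrane depth (pools are well-mixed, so
the lag-to-linear transition is smoother than Fickian), nonlinear or
competitive sorption isotherms, extraction/recovery artifacts, or
between-membrane biological variability (a single membrane parameter set
per scenario). Estimator-recovery results on synthetic data therefore
validate the pipeline's internal consistency, not the biology.

# Numerical choices

* Propagation by 5×5 matrix exponentials per (segment, step) pair, cached;
  exact for the linear system, hence no tolerance knobs. The stated-world
  equivalent of stiff-safe integration at rtol 10⁻⁹ is met trivially.
* Sampled observations are independent of the dense-grid spacing `dt_h`
  (events are exact), so recovery studies run with a coarse grid for
  speed.
* Linear-window threshold 0.995 with ≥ 4 points; ties toward the earlier
  window. On noiseless data a tighter threshold (e.g. 0.9995) locks the
  window onto the flux plateau and recovers the instantaneous peak flux
  within a few percent; the default is kept at 0.995 for noisy data.
* Finite differences: central interior, one-sided flagged endpoints;
  median prefilter optional and off by default.
* Seeds: every stochastic path flows through the scenario seed; derived
  per-replicate seeds stay below 2³¹.

# Known limitations

* Three well-mixed pools cannot reproduce a sharp Fickian lag; the
  temperature-fold calibration above is the visible consequence.
* $K_d$ values are consumed as constants and are temperature-independent;
  only mobilities scale with temperature.
* The CP remainder inherits every error in $M_0$, the ledgers and the two
  boundary equilibria; no uncertainty propagation is attempted (point
  estimates, matching the source's treatment).
* The dose–response and single-experiment $\Delta c$ conventions for $P$
  differ by design; the dose–response mode is canonical for comparison
  with printed values.
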