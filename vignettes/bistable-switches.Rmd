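---
title: "Bistable switch motifs for cell cycle checkpoints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable switch motifs for cell cycle checkpoints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
model equations and their assumptions, the parameters that matter, the
numerical machinery, and the design decisions taken where the problem left
them open. All quantitative statements here are recomputed by the test
suite or by `scripts/acceptance.R`; none are asserted from memory.

## The SIMM motif

A checkpoint inhibitor I is a stoichiometric inhibitor *and* a two-step
substrate of the activator enzyme A it opposes. Working in units
U ≈ 10 nM and T ≈ 1 min, and writing `C = [A:I]`, `C_M = [A:IM]`,
`A = A_T − C − C_M`, the mass-action equations of `build_simm()` are

$$
\begin{aligned}
dI/dt    &= -k_{as1} A I + k_{di1} C + k_{dm1} I_M \\
dI_M/dt  &= k_{cat1} C - k_{as2} A I_M + k_{di2} C_M + k_{dm2} I_{MM} - k_{dm1} I_M \\
dI_{MM}/dt &= k_{cat2} C_M - k_{dm2} I_{MM} \\
dC/dt    &= k_{as1} A I - (k_{di1} + k_{cat1}) C \\
dC_M/dt  &= k_{as2} A I_M - (k_{di2} + k_{cat2}) C_M
\end{aligned}
$$

with $A_T = A + C + C_M$ and $I_T = I + C + I_M + C_M + I_{MM}$ conserved.
Elementary steps are used deliberately: enzyme and substrate are comparably
abundant in these checkpoints, so Michaelis–Menten rate laws (which assume
substrate excess) are invalid. The de-modifying enzyme is treated as a
mass-action catalyst, its concentration absorbed into $k_{dm1}, k_{dm2}$.

The preset (`switch_params("simm")`) encodes the defining asymmetry: the
first modification is tight and slow ($K_{m1} = (k_{di1}+k_{cat1})/k_{as1}
= 0.01$ U), the second loose and fast ($K_{m2} = 1.02$ U). The inhibitor
must be released between the two modifications (a distributive mechanism);
`processive_fraction_model()` lets a fraction `p_frac` of A:I turnover skip
the release and produce the doubly modified form directly.

Two reductions follow from $K_{m2} \gg K_{m1}$:

* **SIMM\*** (`build_simm_star()`): the second step becomes one bimolecular
  event $A + I_M \to A + I_{MM}$ with
  $k_m = k_{cat2}k_{as2}/(k_{cat2}+k_{di2}) \approx k_{as2}$.
* **TQSSA** (`build_tqssa()`): the tight complex is eliminated through the
  total functional inhibitor $\hat I = I + C$. The complex is the smaller
  root of $C^2 - (A_T + \hat I + K_{m1})C + A_T\hat I = 0$ — the only root
  with $0 \le C \le \min(A_T, \hat I)$ — evaluated in the product form
  $2A_T\hat I/(b + \sqrt{b^2 - 4A_T\hat I})$, $b = A_T + \hat I + K_{m1}$,
  which is numerically stable and continues smoothly to slightly negative
  arguments (important for root finding near the admissible boundary).
  The two slow variables $(\hat I, I_{MM})$ give the phase planes in which
  engaged and disengaged states and their separatrix are visible.

## Cell-cycle instantiations

**Sic1–Clb (G1/S)** (`build_sic_clb()`): SIMM\* with synthesis $k_s$ and
background decay $k_d$ on all Sic1 forms. The doubly phosphorylated form is
degraded so fast that it is a pure sink — `SicT` never contains it. Free
species follow the conservation identities
$[\mathrm{Sic}] = [\mathrm{SicT}] - [\mathrm{Clb{:}Sic}] - [\mathrm{SicP}]$
and $[\mathrm{Clb}] = [\mathrm{ClbT}] - [\mathrm{Clb{:}Sic}]$. `ClbT` is
the bifurcation signal.

**Cln–Sic1–Clb** (`build_cln_sic_clb()`): adds a Cln:Cdk1 module. "Cln is
not inhibited by Sic1" is encoded purely kinetically: weak binding
($k_{as,n} = 2$ vs $k_{as,b} = 100$ U⁻¹T⁻¹) and fast processing
($k_{cat,n} = 2$ vs $k_{cat,b} = 0.5$ T⁻¹), so Cln:Sic is a transient
intermediate rather than a trap. The `(ClbT, ClnT)` control plane has a
V-shaped bistable region; the cell-cycle loop crosses its upper boundary
(disengage) during late G1 and its lower boundary (re-engage) at division.

**MCC–APC (mitotic checkpoint)** (`build_mcc_apc()`): the inhibitor is the
mitotic checkpoint complex, assembled from free Mad2 by tensionless
kinetochores at rate $k_a N_T (1 - X_{tens})[\mathrm{Mad2}]$ (the composite
$k_a N_T$ is stored as printed). APC ubiquitinates the MCC it binds
($k_{cat}$, through the TQSSA complex with $K_m = 0.01$ U), a
de-ubiquitinase recycles MCCU ($k_{du}$), and the second, mass-action
ubiquitination by free APC ($k_u$) destroys Cdc20 and returns Mad2 to the
pool. Securin degradation by free APC reports anaphase onset.

**CycB–MCC–APC** (`build_cycb_mcc_apc()`): the APC:MCC complex becomes an
explicit variable, cyclin B is an APC substrate, and the MCC-activating
capacity of tensionless centromeres, $X_{0A}$, requires CycB kinase:
$dX_{0A}/dt = k_{an}[\mathrm{CycB}]((1 - X_{tens}) - X_{0A}) -
k_{in}[\mathrm{CAPP}]X_{0A}$, with MCC assembly $k_a N_T X_{0A}[\mathrm{Mad2}]$.
This form was chosen so that holding $X_{0A} = 1 - X_{tens}$ and setting
$k_{an} = 0$ recovers the MCC–APC assembly term exactly. Once APC destroys
CycB, tensionless kinetochores cannot reactivate the MCC: the down-sweep in
$X_{tens}$ has no re-engagement fold, making anaphase irreversible.

### The totals `APCT` and `Mad2T`

These totals are not part of the published rate-constant tables; they are
**assumptions of this package**, set to `APCT = 1 U`, `Mad2T = 2 U` and
overridable like any parameter. They were fixed once by requiring the
checkpoint models to reproduce three published behaviours simultaneously:
the engaged branch persisting to $X_{tens} \approx 0.97$, re-engagement
near $0.89$, and an in-vitro release lag of roughly 45 T. An excess of
Mad2 over APC is also structurally necessary: with `Mad2T ≤ APCT` the MCC
can never sequester all APC and the engaged state does not exist. The lag
itself is a diffusion-of-excess effect — free APC stays near
$K_m \cdot \mathrm{APCT}/(\hat M - \mathrm{APCT})$ while the functional-MCC
excess $\hat M - \mathrm{APCT}$ is worked off, giving a lag that scales
like the square of the initial excess — which pins the excess near 1 U.

## The analysis layer

* **Steady states** (`find_steady_states()`): damped Newton from a Latin
  hypercube of the admissible box (`lhs::randomLHS`, fixed seed, default
  64 starts) plus engaged/disengaged corner guesses. Conserved directions
  are removed by substituting the conservation identities (e.g. SIMM roots
  are found in $(I_M, I_{MM}, C, C_M)$ with $I$ eliminated), so Jacobians
  at hyperbolic roots are nonsingular. Roots are deduplicated at relative
  tolerance $10^{-6}$ with an absolute floor of $5\times10^{-5}$: just
  past a saddle-node the residual landscape flattens and Newton returns a
  small cloud of pseudo-roots that the relative rule alone would count
  twice. Stability is the sign of the leading eigenvalue real part of the
  reduced Jacobian (central differences, step scaled to coordinate size)
  with margin $10^{-6}$ T⁻¹; anything inside the margin is flagged
  degenerate rather than silently classified. Accepted roots must have
  residual below $10^{-9}$ U/T.
* **Classification**: engaged/disengaged labels come from the free-activator
  fraction (free A over $A_T$, free Clb over `ClbT`, free APC over `APCT`):
  engaged below 0.1, disengaged above 0.5, intermediate between. The cuts
  are conventions; they are far from both attractors in every preset.
* **Folds** (`sweep_signal_response()`): root counts on a parameter grid;
  each count change is bisected to relative tolerance $10^{-4}$; a change
  larger than 2 triggers local grid refinement. No pseudo-arclength
  continuation is used — root-count bisection is simpler and adequate for
  these ≤ 6-variable S-shaped systems.
* **Quasi-static continuation** (`find_threshold()`): the occupied branch
  is tracked by relaxing the previous settled state after each small
  parameter step; the fold is bracketed where the settled state lands on
  the *opposite* checkpoint label and bisected. The opposite-label rule
  matters: a branch may drift through the intermediate band while it still
  exists (the MCC–APC disengaged branch does, below $X_{tens}\approx0.91$).
  Sweep and continuation are genuinely independent routes to the same
  fold, and the tests require them to agree.
* **Driven conserved totals**: `I_T` and `A_T` of the SIMM family do not
  appear in the conserved RHS, so protocols that move them act on the
  state: `A_T` enters through the derived free enzyme; an increase of
  `I_T` arrives as free unmodified inhibitor, a decrease removes material
  proportionally from all pools (step events scale the state). This is the
  physically meaningful reading of "the signal degrades the inhibitor".
  One consequence the tests document: an instantaneous bolus restoring
  2 U of unmodified inhibitor against 1 U of enzyme re-engages the
  switch — irreversibility is a property of gradual signal return, and the
  lock-off scenario restores the total at 0.02 U/T accordingly.
* **Control planes** (`map_control_plane()`): per x-column, a y fold search
  (root-count sweep + bisection) assembles the lower/upper loci;
  `plane_membership()` classifies points against the loci and matches the
  root-count parity oracle at probe points.
* **Integration**: `deSolve::lsoda` throughout (stiff systems; rtol
  $10^{-9}$–$10^{-10}$). `integrate_to_steady_state()` integrates in
  growing, capped time chunks until the RHS max-norm falls below
  tolerance; near folds relaxation is critically slow, which is why the
  default settle horizon is generous. Transient solver overshoot below
  zero is clamped inside the RHS evaluation rather than raised as an
  error; the tight-binding closure continues smoothly through zero so the
  clamp never destroys derivative information.

## Scenarios and what they do (and do not) emulate

The scenarios are the package's synthetic experiments; their schedules are
idealisations. `X_tens` is an external input in all of them — kinetochore
attachment mechanics are not modelled.

* **In-vitro release**: engaged steady state at $X_{tens} = 0$, tension
  stepped to 1. Reported lag = first time functional MCC
  ($[\mathrm{MCC}]+[\mathrm{APC{:}MCC}]$) falls to `APCT`. After the lag
  the decline accelerates (autocatalytic release). The lag is monotone
  increasing in $k_{du}$ and decreasing in $k_u$.
* **In-vivo release**: a piecewise-linear tension ramp 0 → 1 → 0. With
  CycB coupling the final state is disengaged regardless of the
  down-ramp speed; the basic MCC–APC model re-engages on the way down.
* **G1/S cycle** (`g1s_cycle_scenario()`): `ClnT` and `ClbT` become
  states with synthesis switched on at Start, Cln synthesis off at
  t = 30, division events at t = 50. The cyclin rates (synthesis
  0.012/0.06 U T⁻¹, basal decay 0.01 T⁻¹, post-shut-off decays
  0.25/0.1 T⁻¹) are **this package's convention**, chosen once so the
  projected path crosses the control-plane's upper fold exactly once while
  both cyclins rise and re-enters the engaged region only when Clb falls;
  they are not published values, and the absolute transition time is
  therefore qualitative. The G1/S detection rule (free active Clb exceeds
  50% of `ClbT`) and the anaphase rule (securin below 10% of its engaged
  level) are declared conventions. Detection lags the fold crossing by the
  slow escape from the vanished state (order 10 T), so crossing and
  detection are checked for ordering and proximity, not coincidence.

## Robustness scans

`scan_disengage_threshold()` perturbs each checkpoint rate constant on a
log grid spanning a 2-fold range (the default operationalisation of a
"broad range") and recomputes $X_{disengage}$; points with no fold are
marked, not dropped. `sensitivity_irreversibility_region()` applies the
declared criteria — sensitivity: $X_{disengage} > 0.95$; irreversibility:
no re-engagement fold on $X_{tens} \in [0,1]$ — over the same kind of
grid and reports the passing fraction. Two findings the tests record
honestly: under 2-fold perturbations the minimum $X_{disengage}$ of the
MCC–APC model falls to about 0.90 (halving the assembly rate alone maps a
threshold $x$ to $1 - 2(1-x)$), and the unperturbed CycB model's own
threshold sits near 0.94, just below the 0.95 sensitivity cut, because the
APC-driven loss of CycB feeds back on centromere activity and weakens the
engaged branch near its fold. The combined criterion region is accordingly
narrow.

In the partial-processivity variant, the tests freeze what the root-count
oracle computes: bistability at the neutral point survives not only ~20%
processive flux but, in this branching-at-catalysis formulation, the fully
processive limit as well — singly modified inhibitor regenerated by
de-modification still sequesters the enzyme.

## Problem sizes and determinism

Defaults are sized for interactive use: 15–40 grid points per sweep, 64
Newton starts (16–24 with warm starts inside sweeps), control planes of
5–20 columns. All stochastic choices are start-point sampling under an
explicit seed; every analysis re-run with the same seed is bit-identical,
and fold locations are insensitive to the seed at the reported precision.

## Known limitations

* Deterministic ODEs only; no stochastic simulation.
* Fold (saddle-node) detection only; no Hopf or global bifurcations, no
  cusp tracking beyond assembling fold loci pointwise.
* The Wee1/Cdc25 and Cdh1 switches are described by wiring only in the
  source material and are not modelled.
* The `.ode` dialect is restricted (`par`, `init`, `aux`, `number`,
  derivative lines, `done`); other XPPAUT directives are skipped with a
  warning.
* Checkpoint labels use fixed activity cuts; exotic parameter sets could
  place an attractor inside the intermediate band, where protocols will
  report `intermediate` rather than guess.
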