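# simmswitch

Bistable switch motifs for cell cycle checkpoints: mass-action ODE models,
steady-state and saddle-node (fold) analysis, control-plane mapping, and
checkpoint-release simulation, in R.

## The scientific problem

Irreversible cell cycle transitions (G1/S, metaphase → anaphase, …) are
guarded by checkpoint proteins: an **inhibitor** I stalls the transition and
an **activator** enzyme A drives it. In many checkpoints the inhibitor is
simultaneously a *stoichiometric inhibitor* and a *multi-step substrate* of
the very enzyme it opposes — Sic1 versus Clb:Cdk1 at the budding-yeast G1/S
transition, the mitotic checkpoint complex (MCC) versus the
anaphase-promoting complex (APC) at metaphase → anaphase. This
substrate–inhibitor-multiply-modified (SIMM) wiring is a double-negative
feedback loop and generates **bistability**: a checkpoint-engaged state
(inhibitor abundant, activator sequestered) coexists with a
checkpoint-disengaged state (inhibitor destroyed, activator free), separated
by saddle-node (fold) thresholds. Crossing the upper fold and returning
leaves the system disengaged — the transition is irreversible.

The core motif is implemented as elementary mass-action steps (enzyme and
substrate are comparably abundant, so Michaelis–Menten rate laws are not
valid):

    A + I  ⇌  A:I   →  A + IM      (k_as1, k_di1, k_cat1; tight, slow)
    A + IM ⇌  A:IM  →  A + IMM     (k_as2, k_di2, k_cat2; loose, fast)
    IM → I,  IMM → IM              (k_dm1, k_dm2; de-modification)

with conservation laws `A_T = A + C + C_M` and
`I_T = I + C + I_M + C_M + I_MM`. Because the second step's Michaelis
constant `K_m2 = (k_di2 + k_cat2)/k_as2 = 1.02 U` is large, it can be
collapsed to one mass-action step with
`k_m = k_cat2·k_as2/(k_cat2 + k_di2)` (the SIMM\* motif), and a total
quasi-steady-state approximation (TQSSA) on the tight complex — the smaller
root of `C² − (A_T + Î + K_m1)·C + A_T·Î = 0` — reduces the system to two
slow variables for phase-plane analysis. Units throughout: U ≈ 10 nM
(concentration), T ≈ 1 min (time).

The package ships six model instantiations with their published parameter
presets (`simm`, `simm_star`, `sic_clb`, `cln_sic_clb`, `mcc_apc`,
`cycb_mcc_apc`), plus the TQSSA reduction and a partial-processivity
variant, and the analysis layer: multi-start damped-Newton steady states
with eigenvalue stability, fold detection by root-count bisection and by
quasi-static continuation (two independent routes, cross-checked),
two-parameter control planes, hysteresis protocols, time-course scenarios
(G1/S cycle, in-vitro and in-vivo mitotic-checkpoint release), robustness
scans, and a restricted XPPAUT `.ode` dialect reader/writer.

## Worked example

Steady states of the simplified motif inside the bistable zone, and the
mitotic checkpoint's disengagement threshold:

```r
library(simmswitch)

m <- build_simm_star(switch_params("simm_star", A_T = 2, I_T = 6))
find_steady_states(m)
#> 3 steady state(s)
#> steady state [engaged, stable]: I=2.6347, I_M=0.99622, I_MM=0.37669, C=1.9924
#>   residual 3.55e-15, max Re(eig) -0.4442
#> steady state [engaged, unstable]: I=0.34469, I_M=0.97181, I_MM=2.7399, C=1.9436
#>   residual 2.22e-15, max Re(eig) 0.9085
#> steady state [disengaged, stable]: I=0.0006607, I_M=0.061975, I_MM=5.8134, C=0.12395
#>   residual 1.19e-13, max Re(eig) -0.4713

mm <- build_mcc_apc(switch_params("mcc_apc"))
find_threshold(mm, sweep_symbol = "X_tens", from = 0, to = 1,
               start_label = "engaged")
#> fold: X_tens = 0.957461 (the engaged branch disappears)

tr <- mitotic_release_in_vitro()
attr(tr, "lag_time")
#> [1] 46.65868
```

The three roots are the engaged attractor (activator locked in the tight
complex, `C ≈ A_T`), the separatrix, and the disengaged attractor (inhibitor
driven into its doubly modified form `I_MM`). The fold at
`X_tens ≈ 0.96` means the spindle checkpoint holds until essentially every
centromere is under tension — one misaligned chromosome (X_tens = 0.98 with
~46 chromosomes) keeps it engaged. The ~47 T lag before functional MCC falls
to the APC level reproduces the slow in-vitro release caused by rapid MCCU
de-ubiquitination.

A command-line front end for sweeps, control planes, scenarios, scans and
`.ode` export is installed at
`system.file("cli", "simmswitch.R", package = "simmswitch")`.

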