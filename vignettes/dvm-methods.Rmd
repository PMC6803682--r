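---
title: "Modelling optimal diel vertical migration in a stage-structured copepod population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling optimal diel vertical migration in a stage-structured copepod population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dvmopt)
```

## The model

Herbivorous copepods such as *Calanus euxinus* in the Black Sea migrate tens
to more than a hundred metres up and down every day: they graze on
phytoplankton in shallow water at night and sit in deep, dark, oxygen-poor
water during the day. `dvmopt` asks which daily trajectory each
developmental stage *should* follow, defining "should" by long-term
competitive outcome rather than by any ad-hoc fitness currency.

The population is a three-stage von Foerster (age-structured transport)
model. Stage membership is set by carbon body weight: young juveniles
(CI--III) grow from `W_Y` to `W_J`, older juveniles (CIV--V) from `W_J` to
the adult weight `W_A`, and adults reproduce for a fixed period `T0`.
An inherited strategy `v` is a triple of daily depth trajectories
`h_Y(t), h_J(t), h_A(t)` (one day is `t` in `[0, 1]`, `t = 0` midnight,
`t = 0.5` midday). The trajectory determines, through the water-column
profiles, the scalar life-history coefficients:

* fecundity `b` — the adult's daily assimilated carbon surplus divided by
  the egg weight `W_0`;
* stage mortalities `a_Y, a_J, a_A` — daily averages of visual predation
  (a depth sigmoid shared with the light/food profile, modulated by the
  diel factor `1 - cos(2 pi t)`), unfavorable-zone mortality near the warm
  surface layer (above `h_u`) and the hypoxic deep layer (below `h_d`),
  plus a constant natural mortality `gamma_i0`;
* maturation ages `tau_1 < tau_2 < tau_3 = tau_2 + T0` — from integrating
  the growth law `dW/dt = kappa_i W^0.8`, whose constant `kappa_i` is the
  daily feeding-minus-metabolism integral of the stage (all three
  weight-dependent rates share the 0.8 allometric exponent, so growth
  separates exactly).

The long-term fate of a strategy competing against others is governed by
the dominant root `lambda*` of the characteristic (Euler--Lotka) equation
of the linearised model,

```
1 = b exp(-a_Y tau_1 - a_J (tau_2 - tau_1)) *
      integral_{tau_2}^{tau_3} exp(-lambda theta - a_A (theta - tau_2)) d theta,
```

and the evolutionary fitness is `J = lambda* / R`, where `R > 0` is the
coefficient of the shared density-dependent mortality term. `R` is
strategy-independent, so it scales fitness without reordering strategies;
the package keeps `R = 1`. The strategy maximising `J` excludes every other
strategy in pairwise competition — a claim the package does not only state
but verifies by direct simulation (`simulate_selection()`,
`ranking_check()`).

Written as a single implicit equation (`characteristic_residual()`), the
characteristic equation also possesses the root `J = -a_A / R`, an artifact
of clearing the Euler--Lotka denominator. `solve_fitness()` returns the
renewal root `lambda*/R`: it is the growth rate the cohort simulator
actually realises, and selecting the artifact root would make optimisation
degenerate (any non-reproducing strategy with negligible adult mortality
would look perfect). For `b = 0` there is no renewal root and the
degenerate value `-a_A / R` is returned.

## Trajectories and indicator conventions

Trajectories are piecewise linear with five phases (shallow residence over
midnight, descent, deep residence over midday, ascent, shallow residence),
the empirically supported shape: migration speeds are roughly constant and
residence depths roughly flat. With equal descent and ascent speeds the
optimum is symmetric about midday, leaving three free parameters per stage
(`H0`, `H1`, `t0`) — nine in all.

The printed sources for the feeding and activity indicators conflict with
one another, so the package fixes them as follows and documents the choice:

* **Feeding `S_i`**: 1 on the shallow (night) residence segments only.
  Animals moving faster than the critical feeding speed do not graze, which
  removes the ramps; the deep daytime residence is non-feeding quiescence.
  (Allowing feeding at the deep segment invites a pathological optimum in
  which the "deep" segment parks at ~45 m inside the food layer and feeds
  around the clock — contradicting the quiescent-daytime biology the model
  is meant to capture.)
* **Active metabolism `S_i1`**: 1 during the feeding phases and the ascent;
  descent is passive sinking and the deep residence is quiescent, both
  paying basal cost only.
* A non-migrating stage (`H1 = H0`) feeds and is active around the clock.

The critical feeding speed itself never appears as a number: any value
strictly between zero and the migration speed yields the same indicators,
so it is not a parameter of the implementation.

## Parameter conventions and two resolved ambiguities

All rates are stored per day (`x 24` for the per-hour metabolic costs;
speeds in m/h become m/day). Allometric constants are calibrated so that
each weight-dependent rate equals its adult value at `W = W_A`.

Two printed parameter entries are internally inconsistent, and the package
resolves them as follows:

* The metabolic-profile steepness is `sigma_m = 0.065` 1/m (the printed
  default `0.65` falls outside its own printed range 0.04--0.065 and is
  read as a typo).
* The metabolic half-maximum depth is tied to the hypoxic boundary,
  `h_m = h_d - delta_hm` with `delta_hm = 12` m by default. The basal cost
  drops where oxygen does, just above `h_d`; this coupling is what makes
  the optimal daytime depth track the hypoxic boundary in `h_d` scans. A
  literal reading (`h_m = 12` m, costs vanishing below the surface layer)
  would decouple metabolism from the oxygen regime entirely and erase the
  model's central mechanism. Passing `h_m` explicitly to `dvm_params()`
  overrides the coupling.

## The maximum development age

Under the default parameterisation every feasible life cycle is
subcritical (`lambda* < 0`): survival through the heavily predated young
stage is low enough that no strategy achieves replacement. A declining
population rewards delay — the fitness of a strategy whose juveniles grow
ever more slowly approaches its juvenile survival rate `-a_J` from below,
which would be approached by postponing maturation indefinitely. That
open ridge is biologically meaningless for an annual species, so a
strategy must reach adulthood within `max_age` (default 365 days) to be
feasible. The bound is a biological constant of the species modelled, not
a tuning knob; under the defaults the optimal juvenile stage uses the full
allowance (`tau_2 = max_age`), i.e. the model's time allocation runs slow
even though its depth structure is sharp. Consequences of the subcritical
regime worth knowing about:

* the optimal young stage may add a brief midday excursion (amplitude
  ~30 m) on top of its shallow residence — observed young stages, and the
  original account of this model, have it strictly non-migrating;
* migration does not cease at high food supply, and replacing the diel
  predation factor by its time average weakens but does not abolish
  migration: both cessation results require time to be demographically
  precious (`lambda* > 0` or nearly so), which the printed parameter
  values do not produce.

These caveats are verified and reported honestly by the acceptance tests
rather than patched over.

## Numerical choices

* **Life-history integrals.** Stationary segments are closed-form. On the
  linear ramps, the metabolic and zone-mortality integrands integrate in
  closed form via `log cosh` antiderivatives; only predation (depth sigmoid
  times diel factor) needs quadrature — composite Gauss--Legendre with
  12-point panels sized to the sigmoid width (relative error well below
  1e-8). One full strategy evaluation costs well under a millisecond,
  which is what makes multistart optimisation and scans routine.
* **Root finding.** The Euler--Lotka form is solved in log space
  (`uniroot`, bracket expansion capped at 50 doublings, tolerance 1e-12),
  so survival factors of order `exp(-20)` cause no overflow. The residual
  of the characteristic equation is checked at the root (`< 1e-10`).
* **Optimisation.** Box bounds (`0 <= H <= h_max`, `0 <= t0 <= 0.5`) by
  logistic transform; ordering (`H1 >= H0`, the cycle must fit in a day)
  and feasibility (growth, development age, fecundity) by graded penalty.
  Nelder--Mead from 11 structured starts (static, classic DVM, midday-dip
  patterns) plus 16 seeded Latin-hypercube starts; the best five are
  polished by block-coordinate cycles (one stage at a time), which the
  near-separable structure makes far more reliable than 9-dimensional
  Nelder--Mead alone. Migrating optima that a collapsed variant matches to
  within 1e-7 in fitness are reported as non-migrating (ties break toward
  the smaller amplitude; amplitudes below 0.5 m are "no DVM"). A
  central-difference gradient at the optimum is reported as a stationarity
  diagnostic, with directions pinned by active constraints flagged.
* **Cohort simulator.** `dt = dtau` (default 0.05 d) moves the grid along
  characteristics exactly; per-cell survival uses the exact integral of the
  piecewise-constant mortality (stage boundaries split within cells);
  renewal weights cover `[tau_2, tau_3]` with exact partial cells. The age
  grid is truncated beyond the last reproductive age plus several adult
  mortality e-foldings. Uncoupled runs renormalise each step (ratios are
  unchanged — the shared coupling multiplies every strategy equally, which
  the test suite verifies) so declining populations can be followed in log
  scale indefinitely. Halving `dtau` moves measured growth rates by less
  than 0.2%.
* **Competition verdicts.** Reproduction concentrated in a 40-day age
  window makes densities oscillate on the generation period with very slow
  damping, so exclusion is judged on the envelope of the density ratio
  (block-wise maxima strictly decreasing, final ratio below 1e-6), the
  natural "eventually monotone decreasing" criterion for an oscillatory
  ratio.

## Scope of the synthetic experiments

The generator `random_strategies()` and the simulator emulate exactly the
model's own world: piecewise-linear symmetric trajectories, stage-wise
constant coefficients, a fixed environment, clonal inheritance. Passing
tests therefore show internal consistency of the optimisation/simulation
machinery — that the fitness ordering computed from the characteristic
equation is the ordering realised by the population dynamics — not that
real copepods maximise this particular `J`. Field realities deliberately
outside the model: year-round environmental variation, dynamic predator
and food feedbacks, lipid reserves and starvation physiology, moulting,
and mutation.

## A worked default run

```{r, eval = FALSE}
params <- dvm_params()        # summer scenario: h_d = 140 m, h_u = 20 m
opt <- dvm_optimize(params, seed = 1)
tidy(opt)                     # one row per stage
autoplot(opt)                 # the daily depth cycles
scan <- dvm_scan(params, "h_d", seq(90, 150, 15), warm_theta = opt$theta)
autoplot(scan)
```

At the defaults this takes about a minute and a half and yields a
non-migrating-to-shallow young stage around 33 m with a short midday dip,
and older juveniles and adults feeding near 33 m at night while sitting
near 120 m by day — the two-to-three-fold gap between the lit zone
(predation is negligible below about 60 m) and the daytime depth being
carried entirely by the metabolic relief just above the hypoxic boundary,
as the constant-cost comparison (`const_cost = TRUE`, daytime depth
collapsing to about 66 m) shows.
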