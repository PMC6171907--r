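---
title: "Local reservoir models of choice-based learning: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local reservoir models of choice-based learning: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resdec)
```

## The model

Choice-based learning (CBL) — the increased probability of repeating a
decision one has just made — is modelled here without any explicit memory
or reward variable. Instead, every decision dissipates energy into a
finite hidden environment, the *local reservoir*, and the reservoir's
finite capacity is the memory.

The reservoir is a ladder of `2N + 1` single-occupancy (fermionic) energy
levels: `N` lower levels and `N + 1` upper levels. A decision is an
excitation along one of `2N` arrows: the L-arrow at position *i* raises
lower level *i* to upper level *i + 1* (Decision L), the R-arrow at
position *i* raises it to upper level *i* (Decision R). An arrow is
*available* only while its source lower level is occupied and its target
upper level vacant. Executing an arrow therefore disables up to three
arrows — its own position's L and R arrows (shared source) and the
opposite-kind arrow into its target — so a Decision L removes two
R-arrows but only one L-arrow from play, biasing the next decision
toward L. That asymmetry is the entire mechanism. With many levels
(`N` large) the bias is negligible; with few it is strong.

## The discrete-cycle simulator

`run_trace()` and `decision_consistency_curve()` implement the
finite-lifetime dynamics. Each used resource recovers `lifetime` (τ)
cycles after the excitation: the vacated lower level refills and the
occupied upper level empties. One global cycle counter drives everything;
timers fire at the start of a cycle, before that cycle's decision, so
`lifetime = 1` means the reservoir is fully restocked every cycle and
decisions are an exactly fair, independent coin.

Two conventions deserve explanation because the dynamics force a choice
the model description alone does not make.

**Arrow selection.** Each cycle draws one of the `2N` arrow *slots*
uniformly at random; if the drawn arrow is available it fires, otherwise
the cycle passes with no decision. The obvious alternative — drawing
uniformly from the currently *available* set, so that every cycle with a
non-empty set produces a decision — turns out to change the model's
character qualitatively: with deterministic integer lifetimes, decision
*timing* then carries no randomness at all, and small reservoirs
(`N` comparable to τ) phase-lock into near-periodic decision patterns
whose type sequence repeats indefinitely (for example `N = 4`, τ = 10
settles into a fixed four-decision motif recurring every 10 cycles).
Long-lag decision consistency then never returns to 0.5 and the
consistency-versus-size curve is not monotone. Slot sampling leaves the
*conditional* decision distribution unchanged — given that a decision
occurs, it is uniform over the available arrows — while restoring
stochastic timing, and with it the expected behavior: consistency decays
to 0.5 within a few lifetimes for every size, and is monotone in `N`.

**Reading a decision "at cycle T₀".** Cycles without decisions exist
whenever τ > 1, so the consistency between "the decision at T₀" and "the
decision at T₀ + t" needs a rule for stalled cycles. The default
(`readout = "exact"`) uses only runs in which both cycles actually carry
a decision, and reports the number excluded; this matches the definition
of the consistency indicator literally and is the convention under which
the headline numbers (e.g. lag-8 consistency ≈ 0.7 at `N = 2`, τ = 10)
are computed. The alternative (`readout = "next-decision"`) substitutes
the first decision-bearing cycle at or after the nominal one; it uses
every run but mixes lags slightly, and yields somewhat lower values at
small `N` (≈ 0.65 in the same setting). Both are exposed; they coincide
whenever no cycle stalls (e.g. τ = 1).

Default protocol parameters: 3000 cycles per run, reference cycle
T₀ = 2000 (the state forgets its fully-stocked initial condition within
a few lifetimes, so this is a generous burn-in), 10,000 runs per curve.
The headline two-point calibration (sizes 2 and 50) in the acceptance
script uses 100,000 runs because the exact read-out retains only the
few percent of runs with decisions at both reference cycles when `N` is
small. All randomness flows through R's RNG; the compiled fast path and
the pure-R `step_cycle()` reference implementation consume draws
identically and produce bit-identical traces under one seed, which the
test suite asserts.

## The continuous-time rate model

`build_generator()` constructs the Markov generator over all `2^(2N+1)`
occupation micro-states from three rates: γ_in (refill of a vacant lower
level), γ_up (each available arrow), γ_out (emptying of an occupied upper
level). The convention is `dp/dt = G p` with columns summing to zero.
States are ordered canonically by binary encoding (lower-level bits
first); for `N = 1` a documented permutation maps to the conventional
8-state diagram indexing, under which the generator reproduces the
published rate matrix entry for entry (the test suite checks all 64
entries as linear forms in the rates by evaluating at three independent
rate triples).

`steady_state()` solves `G p = 0`, `Σp = 1` by least squares on the
stacked system; for positive rates the chain is irreducible so the
solution is unique. Dense solves are used throughout — state counts are
8 and 32 for the sizes of interest and remain practical to `N ≈ 5`.

**Decision-transition probabilities.** `P(L→L)` is formalized by first
passage on the embedded jump chain: `h_L(s)` is the probability that the
next UP-labeled jump from state `s` is an L-excitation, with IN/OUT
jumps treated as pass-through; conditioning on a steady-state L-decision
event (flux-weighting over all UP_L transitions) and averaging `h_L`
over post-decision states gives `P(L→L)`. `P(L→R)` is computed from the
independently solved `h_R` system, so the identity
`P(L→L) + P(L→R) = 1` is a genuine numerical check rather than a
definition. A Gillespie simulator of the same labeled chain
(`gillespie_reservoir()`) provides the stochastic cross-check, with
batch-means standard errors for occupations and binomial standard
errors for the empirical decision pairs.

This formulation reproduces the published qualitative structure: the
imbalance `P(L→L) − P(L→R)` is positive at `N = 2` for the
refill-limited regime (γ_in, γ_up, γ_out) = (1, 1, 10), non-positive for
the fast-excitation regime (1, 10, 1), and non-positive for every rate
combination at `N = 1` — a single lower level cannot favor repetition
because each decision blocks its own path.

**A reconciliation note.** The published closed-form expression for the
`N = 1` imbalance (`closed_form_imbalance_n1()`) evaluates to a positive
number for positive rates, while the `N = 1` reservoir provably shows no
CBL and the first-passage computation is correspondingly negative. The
package evaluates the printed expression verbatim and reports it
side-by-side with the first-passage value, asserting no equality between
them; the sign tension is inherent to the printed formula, not to the
implementation.

## The photon system

The single-photon decision maker uses the Malus law for the horizontal
detector port, `P(Decision 1) = cos²θ`, which is the standard physical
completion of the stated 50:50 behavior at θ = π/4. The half-waveplate's
internal 2× angle multiplication is abstracted away: θ *is* the
polarization angle and moves by ±Δ = ±π/R per decision. Termination is
strict — θ < 0 or θ > π/2 — so the boundary angles themselves remain
active. Terminated runs are excluded from later-cycle consistency means
and reported through `surviving_runs`; this exclusion is what produces
the observed collapse of small-R consistency after the first few cycles,
because the surviving remnant is selected for having alternated. Note
that the update rule is self-reinforcing (a decision makes itself more
likely next time), so even very fine resolutions have a non-negligible
termination probability within 500 decisions; the hard lower bound is
that no R = 1000 run can terminate before 250 decisions.

## Behavioral scoring and the synthetic participant

"Repetition consistency" compares an item's chosen/not-chosen indicator
at its k-th appearance with its (k + 1)-th, averaged over items — the
only stable unit when pairings are random. The partner item is ignored;
appearances against different partners are unweighted. The learning
score is `max(c₂ … c₍K−1₎) − c₁ + 0.5`, the 0.5 bias applied exactly
once at reporting so that 0.5 reads as "no learning".

One structural fact worth knowing when constructing examples: because
every trial contributes exactly one chosen item, the number of items
whose indicator flips between appearances always has the parity of the
trial count. A four-trial record therefore cannot score c₁ = 0.75; the
packaged toy fixture uses 8 items × 2 appearances (8 trials, 2 flips).

The synthetic participant (`simulate_participant()`) emulates the
statistical structure of the 28 × 8 protocol: latent Gaussian item
values drive choices through a noisy comparison, and with probability
`stickiness` an item chosen at its own previous appearance is re-chosen
when present. Defaults are unit value spread and unit comparison noise —
a moderate-consistency chooser; stickiness 0 with pure noise gives
chance-level consistency and stickiness 1 with noiseless values gives
strong (mean ≈ 0.76) but deliberately not perfect repetition, since an
item that lost its last appearance can still win a later pairing on
value. The generator emulates choice sequences only: it has no item
semantics, no inter-item correlation structure, and no session-order
effects, so passing tests demonstrate the scoring pipeline and the
monotone stickiness–consistency link, not fidelity to any real
population.

`estimate_reservoir_size()` inverts the simulated consistency-versus-N
curve (lifetime 10, lag 8) by piecewise-linear interpolation after a
`cummin` regularization that removes sub-Monte-Carlo non-monotonicities.
Observations at or below the curve's right endpoint return the largest
grid size with an `at-boundary` flag; observations above the curve
maximum return `above-curve`, since only a longer lifetime can
accommodate them.

## Numerical choices and degenerate inputs

* Reservoir and photon configurations validate `N ≥ 1`, τ ≥ 1, R ≥ 4;
  rates must be strictly positive (limits such as γ_up → 0 are probed in
  tests at 10⁻⁸, not supported as inputs).
* Steady-state solves report an error if the residual exceeds 10⁻⁸
  relative to the generator scale; tiny negative probabilities from
  round-off are clipped to zero before renormalization.
* Uniform integer draws use `floor(u · k)` with a guard at the upper
  boundary, in both R and C++, to keep the two paths draw-for-draw
  aligned.
* Schedules are built by rejection sampling of random perfect matchings
  on the item-appearance multiset (self-pairs rejected); with the
  protocol sizes used here rejection is rare and 1000 attempts bound the
  retry loop.

## Problem sizes

Test-suite simulations use 2,000–20,000 runs and reference cycles of a
few hundred where only a trend or a coarse mean is asserted, and the
full protocol (T₀ = 2000, 10,000 runs) where a published number is
checked; the two-point behavioral calibration uses 100,000 runs as noted
above. These sizes were chosen so that asserted tolerances sit at three
or more standard errors.

## Known limitations

* The reservoir is one-dimensional with nearest-neighbor excitations;
  multi-dimensional or networked reservoirs, more than two decisions,
  and agent feedback are out of scope.
* Symbolic closed forms are not attempted beyond the printed `N = 1`
  expression; everything at `N ≥ 2` is numerical.
* The photon module has no forgetting/forced-reversal mechanism; runs
  end at the polarization boundary.
* The behavioral module scores records and estimates sizes; it does not
  model individual differences across real participants, whose raw data
  are not distributed with the package.
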