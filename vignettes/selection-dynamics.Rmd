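---
title: "Models of in vitro ribozyme selection in selexdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of in vitro ribozyme selection in selexdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexdyn)
```

## The selection experiment as a model

An in vitro selection (SELEX) experiment enriches functional RNA from a
random-sequence library over repeated rounds of reaction, recovery and
amplification. `selexdyn` models each round with three quantities per
species:

* the **amplitude** `A`, the fraction of copies that ever react (the rest
  are trapped in misfolded states);
* the **relative rate** `k`, a first-order rate constant expressed in units
  of the reference catalyst's rate, so the best catalyst has `k = 1`;
* the **recovery probability** `Q`, the chance that a *reacted* molecule
  survives the separation and processing steps. Processing losses make `Q`
  substantially below 1; the worked defaults use `Q = 0.2`.

Time enters only through the dimensionless **scaled time**
`tau = kcat * Csub * t` (`scaled_time()`), so the probability that a copy of
species *i* reacts and is recovered in a round is

    R_i(tau) = Q * A_i * (1 - exp(-tau * k_i)).

Background (non-catalytic) sequences react at a small relative rate
(`kback = 0.001` by default) with `A = 1`, since the uncatalysed reaction
does not depend on folding. An **artefact** — a sequence the separation step
recovers without any reaction — has a constant recovery probability `Rart`
independent of `tau`.

All complements `1 - exp(-x)` are evaluated with `expm1()`, so the
high-stringency limit `R ~ Q A k tau` is computed without cancellation down
to `tau = 1e-8` and below; this matters for the `tau -> 0` enrichment
ceiling checks.

## Deterministic multi-round dynamics

Given frequencies `p_i(n-1)` entering round `n`, selection reweights and
renormalises:

    p_i(n) = p_i(n-1) * R_i(tau_n) / Rbar,   Rbar = sum_i p_i(n-1) R_i(tau_n).

`run_selection()` iterates this recursion under a `tau_schedule()`. Two
consequences drive the package's test surface:

* With constant `tau`, pairwise frequency ratios are geometric in `n`, so
  trajectories never cross; the winner is fixed by the ranking of
  `R_i(tau)` (amplitude-dominated at saturating `tau`).
* Decreasing `tau` switches the ranking towards the product `A_i k_i`
  (the high-stringency fitness), so curves can cross, and a tau-independent
  artefact eventually outgrows every catalyst if stringency keeps rising.

Frequencies are carried as plain doubles. Under the conditions modelled
here (founder frequencies of `1e-14`, at most a few tens of rounds, worst
per-round factors around `1e-6`) no frequency can approach the double
underflow threshold, so no special log-space representation is needed;
every trajectory row is renormalised to sum to 1 within `1e-12` (the
tolerance the tests assert).

## First-round stochasticity

Before round one, each functional library sequence is present in `c =
NRNA/NDNA` copies on average, and each copy survives reaction and recovery
independently with probability `QA`. The survival probability
`1 - exp(-QA c)` (`survival_probability()`) gives the familiar rules of
thumb: `c > 3` for 95% survival when `QA = 1`, and `c > 30` when
`QA = 0.1`. `min_copies_for_confidence()` searches integers directly rather
than rounding the real-valued solution, avoiding an off-by-one when the
boundary lands exactly on an integer.

Within the round, the number of recovered copies out of `N` is
binomial(`N`, `R`) (`recovery_count_pmf()`). The binomial **mode** is the
loss diagnostic: when `(N + 1) R < 1` the most likely outcome is losing the
sequence entirely even though the mean `N R` stays positive. Ties between
two equally likely adjacent counts (exactly when `(N + 1) R` is an integer)
are reported as the smaller count — the conservative choice for a loss
diagnostic — and the tie test uses a relative tolerance of `1e-12` so that
floating-point noise cannot hide an exact tie. Comparing `N = 30` with
`N = 3000` in `first_round_summary()` shows the mode-collapse threshold
moving by the expected factor `(3000 + 1)/(30 + 1) ~ 97` in `tau`.

## Counter-selection

For cofactor-dependent targets, each round first runs the reaction
*without* the cofactor and discards everything recovered, then runs the
positive reaction with it. The per-round pass probability is

    (1 - R_without(tau_counter)) * R_with(tau_positive),

with species classed as `constitutive` (same kinetics in both steps),
`strict` (background-like without the cofactor) or `leaky` (rate scaled by
`leak`, default 1/2, without it). The step order is fixed (counter first);
reversing it changes nothing in this model, so no order flag is exposed.
Because `Q A < 1`, a constitutive catalyst still slips past the counter
step with probability `1 - Q A (1 - exp(-tau k))`: counter-selection is
intrinsically weak, succeeds in the model only while both steps keep a
constant, saturating `tau`, and is overridden by the positive step as soon
as stringency rises there.

## Structure-matching combinatorics

A `structure_constraint()` holds a motif's conserved sites (`s` of them),
variable base pairs (`b`), and break points dividing it into `M` modules
between which insertions are tolerated. Under uniform base composition a
conserved site matches with probability 1/4 and a variable pair is one of
the six canonical pairs (GC, CG, AU, UA, GU, UG) with probability 6/16 =
3/8, giving the single-frame match probability `q = (1/4)^s (3/8)^b`.
Conserved stem bases must be entered as two conserved sites, not a pair —
the sequence requirement already enforces pairing — and the parser rejects
pairs touching a conserved position rather than guessing a score for a
half-conserved pair. Pseudoknotted pairs count exactly like nested ones.

Placements distribute the `Lran - Lstr` free bases into gaps before,
between and after the modules; stars-and-bars gives the frame count
`W = choose(Lran - Lstr + M, M)`, reducing to `Lran - Lstr + 1` for `M = 1`,
and 5'-anchoring (first module pinned, e.g. when chemistry acts on the 5'
end) forces the leading gap to zero. Treating frames as independent yields
the any-frame match probability `1 - (1 - q)^W ~ Wq` and, at mutational
distance `m` (number of violated constraints), the minimum-over-frames
distribution `P_W(m) = g(m)^W - g(m+1)^W` with `g(m)` the single-frame
upper tail. `g(m)^W` is evaluated as `exp(W * log1p(-h))` on the complement
`h = 1 - g`, preserving relative precision where `P_W` is tiny.

### What the scanner computes, and how the formula is validated

`min_distance_scan()` returns the *exact* minimum number of violated
constraints over all `W` placements. When no pair spans two modules the
scan runs a dynamic programme over module shifts (cost arrays plus suffix
minima, linear in `Lran` per module); cross-module pairs fall back to
direct placement enumeration. The two paths are tested against each other,
against a plain-R enumeration, and the enumerated placement count is tested
to equal `frame_count()`.

Three layers validate the distributions:

* `exhaustive_distance_distribution()` enumerates all `4^Lran` sequences
  (guarded to `Lran <= 12`) and must equal `single_frame_distribution()`
  *exactly* when `Lran = Lstr` — there is only one frame, so no
  approximation is involved.
* Monte Carlo sampling (`sample_min_distance_distribution()`) must agree
  with the exhaustive toys, and with the single-frame formula on a
  full-length motif at `Lran = Lstr`, within binomial sampling error.
* For `Lran > Lstr` the independence-of-frames assumption is an
  approximation, because frames share module placements. It is accurate in
  the **rare-match tail** (small `m`), where a union bound applies, and the
  tests assert agreement there. In the bulk of the minimum-distance
  distribution the approximation fails by far more than sampling noise:
  frames sharing two of three module offsets are strongly positively
  associated, which both depresses the rare tail slightly and spreads the
  bulk to larger `m`. The exhaustive toy comparison quantifies the same gap
  at `m = 0`, where the enumerated truth is bounded above by the formula.
  This is a property of the model, not of the implementation — the scanner
  itself is exact — and any conclusion drawn from `multi_frame_distribution()`
  should be restricted to small `m`, which is also the regime of practical
  interest (sequences within a few mutations of function).

The ribozyme-scale fixtures (`fixture_structure()`) reproduce the published
constraint counts of the hammerhead (`Lstr 39, s 13, b 8, M 3`), twister
(`54, 11, 17, 3`) and 5'-anchored triphosphorylation (`44, 13, 11, 2`)
motifs. The positions within the motifs are synthetic: every probability
computed from a constraint file depends only on the counts, so arbitrary
valid positions suffice, and the fixtures are named "-like" to say so.

## Cluster evolution with beneficial mutations

Sequencing real selections reveals clusters descended from single founder
molecules. Because near-matches vastly outnumber exact matches, founders
are usually suboptimal, and PCR supplies beneficial mutations during the
experiment. The model tracks, per cluster, three representative levels at
mutational distance `m = 0, 1, 2` with rates `k_i0 >= k_i1 >= k_i2` and
amplitudes `A_i0 >= A_i1 >= A_i2`, drawn by `generate_clusters()`:
`k0 ~ U(0.5, 1)`, `A0 ~ U(0.8, 1)`, each further level dividing the rate by
`U(2, 4)` and subtracting `U(0, 0.2)` from the amplitude. These ranges are
the study conditions of the worked 50-cluster example and are the
defaults; one seed governs the draw and the dynamics are deterministic
given the parameters.

Each round applies selection per level, then moves a fraction `pben` of
level-2 mass to level 1 and of level-1 mass to level 0 — but only for
levels whose *post-selection* frequency exceeds `pmin`. The gate encodes
expected copy numbers: with `Ntot` recovered molecules amplified `C =
lambda^ncyc`-fold, a level at frequency `p` produces about
`p Ntot C pben` beneficial copies per round, so mutations become near-certain
once `p > pmin = 1/(Ntot C pben)`. The worked defaults set `pben = 1e-4`
and `pmin = 1e-10` directly; `u = 1e-5` per base and
`beneficial_mutation_probability()` connect `pben` to polymerase error
rates (for a single mismatched site, `pben ~ u/3`). The defaults `lambda =
1.6`, `ncyc = 15` give `C ~ 1153`, a realistic per-round multiplication
near 1000. Deleterious mutations are omitted: selection keeps them rare, so
they barely move cluster frequencies, whereas a beneficial mutant sweeps
its cluster and changes the cluster's fitness.

The headline behaviour, asserted across 20 parameter seeds: cluster
frequency curves cross (fitnesses change mid-experiment), and at round 12
the cluster mean fitness `mean(A k)` is strongly correlated with the *next*
round's enrichment factor but essentially uncorrelated with the cluster's
log frequency — frequency integrates fitness over the whole history, not
the current mixture. With optimal founders and `pben = 0`, both
correlations are strong, isolating beneficial mutations as the cause.
`fitness_correlation_report()` returns both Pearson (on log10 frequency,
since frequencies span decades) and Spearman coefficients, because the
choice of measure is otherwise arbitrary; degenerate inputs produce `NA`
with a warning, never a silent 0.

## Problem sizes and numerical tolerances

The test suite and examples use: 20-round trajectories; 50-cluster
simulations over 20 seeds; exhaustive enumeration up to `Lran = 8`
(65,536 sequences; the guard allows 12); and Monte Carlo samples of `1e5`
to `1e6` sequences of length 80. At `1e6` samples the resolvable
probability floor is about `1e-4`, far above exact-match frequencies of
realistic motifs (`~1e-8` and below); those are the formulas' domain, and
the sampler documents this. Frequency conservation is asserted at `1e-12`
throughout; distribution normalisation at `1e-12`; the `tau -> 0`
enrichment limit at `1e-6` relative.

## Known limitations

* No thermodynamic folding: `q` counts constraint matches, not the
  stability of the matched structure against competing folds, so it
  overestimates the frequency of *functional* sequences.
* Frame independence is an approximation outside the small-`m` tail, as
  quantified above; `W` likewise overstates the benefit of long randomized
  regions because insertions can interfere with folding.
* Only the first round is treated stochastically; later rounds are
  deterministic, appropriate once survivors number in the hundreds.
* Mutation acts on three abstract distance classes per cluster, not on
  explicit sequences; PCR chimeras and amplification bias are out of scope.
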