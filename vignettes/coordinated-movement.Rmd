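---
title: "Coordinated movement and the evolution of cooperation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated movement and the evolution of cooperation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`coopmove` studies a finite population of `N` individuals on a complete
graph of `N` places, one home vertex per individual (the complete
territorial raider). Each round, every individual visits one place;
everyone standing on the same place forms a group, the groups play a
multiplayer game, and a birth–death event updates the population. The
quantity of interest is the fixation probability of a single mutant — the
chance its lineage takes over before going extinct.

A global home-fidelity parameter `h > 0` sets the target marginal of every
individual: probability `h/(h + N - 1)` of being at home and `1/(h + N - 1)`
at each other place (`territorial_apriori()`). `h = 1` is indifference,
large `h` keeps individuals home (small groups), small `h` pushes them out.

What distinguishes this package from independent-movement treatments is
*row-dependent* (coordinated) movement: an individual's choice may depend on
where others are moving *this* round. Four mechanisms are implemented:

* **independent** — everyone draws from their own marginal;
* **follow-the-majority** — individuals place sequentially in a uniformly
  random order; the first mover draws from the apriori, everyone after
  joins the currently fullest place (maximal herding: participants always
  end in one cluster);
* **Polya-urn** — sequential, with probability proportional to
  `B * a_m + Y_m` (apriori weight plus current occupancy); `B`
  interpolates from full herding (`B = 0`) to independence (`B -> Inf`);
* **wheel-and-base** — simultaneous: arcs of lengths `a_m` tile a circle,
  spikes separated by an angle `theta` spin over them with a uniform
  rotation; `theta = 0` herds everyone, `theta = 2*pi/N` with equal arcs
  disperses everyone.

### Faithful embedding for any home fidelity

The raw mechanisms are defined for a common apriori; the evolutionary
setting needs each individual biased towards its own home. The embedding
(`participation_split()`) splits each individual's move into three
actions, with probabilities depending on the sign of `h - 1`:

* `h > 1`: sit at home directly with probability `(h-1)/(h+N-1)`,
  otherwise (probability `N/(h+N-1)`) join the movement mechanism, which
  internally uses the *uniform* apriori over all `N` places;
* `h = 1`: everyone joins the mechanism;
* `h < 1`: join the mechanism with probability `Nh/(h+N-1)`, otherwise
  jump to a uniformly random non-home place.

Composing either branch with the uniform mechanism apriori reproduces the
territorial-raider marginal exactly, for every mechanism — the
*faithfulness* property, which the test suite verifies exactly (enumeration,
`N <= 4`, tolerance 1e-12) and statistically (`N = 10`, 1e5 draws, 4
standard errors). Individuals who do not join the mechanism are invisible
to it: a follow-the-majority participant never chases a home-stayer. This
invisibility is what keeps the marginals on target.

## Design choices where the construction was open

Several details of the mechanisms are under-determined and had to be fixed;
the package's choices are:

* **Follow-the-majority ties.** When several places tie for maximal
  occupancy, the mover picks among them proportionally to the apriori
  weights (uniform tie-breaking is available as an option). In the
  embedding this matters only degenerately: after the first mover there is
  always a unique maximum, so participants always form a single cluster at
  an apriori-distributed place — which is also why the exact pattern
  distribution of the mechanism is "one cluster, placed by the apriori"
  regardless of the tie rule.
* **Urn at `B = 0`.** The urn weights are pure occupancy, which is
  undefined for the first mover; the first mover draws from the apriori and
  everyone else necessarily joins (empty places have weight zero). This is
  exactly the follow-the-majority limit.
* **Wheel under partial participation.** When only a random subset of
  individuals joins the mechanism, spikes remain equally spaced by `theta`
  and are assigned to the participants in a uniformly random order. This
  preserves exchangeability and faithfulness.
* **Arc layout.** Places occupy consecutive half-open arcs in index order
  from position 0, and the rotation is uniform on the circumference. Any
  fixed layout gives the same marginals; this one is canonical and easy to
  test.
* **Theta quantization.** `theta` is rounded to 3 decimal places (in
  radians) by default. At the dispersal angle `theta = 2*pi/N` the
  unquantized wheel separates everyone forever, individuals only ever
  replace themselves, and an evolutionary run never absorbs; the rounding
  leaves a small co-location probability (about 5e-4 per adjacent spike
  pair at `N = 10`) that makes absorption reachable. The precision is
  configurable and quantization can be disabled for pure distribution
  studies.
* **Orderings.** Sequential mechanisms draw a fresh uniformly random
  ordering of the participants for every movement event. For the exact urn
  enumeration a single order suffices: urn draws are exchangeable, so the
  joint law of "who went where" does not depend on the order. The wheel is
  not order-exchangeable, so its exact distribution averages over all
  assignments of spikes to participants.

## Group statistics and replacement weights

`enumerate_placements()` computes the exact probability of every placement
configuration by summing over participation sets, mechanism outcomes and
non-participant choices (enumeration cap `N <= 6` by default; the wheel's
exact distribution integrates the rotation measure over arc-boundary
breakpoints). `estimate_placements()` is the Monte-Carlo counterpart for
larger populations, backed by a compiled sampler.

From a distribution, `pair_statistics()` derives the quantities the
evolutionary analysis consumes:

* `d_N` — the pair-meeting weight: the probability that a fixed pair
  shares a group of size `S + 2`, weighted by `1/(S + 1)`. It measures how
  much reward flows between any two individuals, and doubles as the
  off-diagonal replacement weight `w`.
* `w_s` — the self-weight: the probability of being alone.
* `w* = (w_s - w)/w` — the self-vs-pair contrast that governs how much
  the two dynamics differ.

Two identities hold configuration-by-configuration, hence exactly even in
Monte-Carlo estimates: `w_s + (N-1) w = 1` (each individual's replacement
weights sum to one) and `d_N = w`. Tests assert both at 1e-10 alongside
pair exchangeability. For independent movement,
`pair_statistics_independent()` evaluates `d_N` and `w_s` by binomial sums
for any `N` without enumeration.

## Games

Both games take a background payoff `R`, a reward `V` and a cost `C`, and
depend only on the group composition (`a` of type A, `b` of type B):

* **Public Goods** (`pgg_payoff()`): each cooperator pays `C`; its
  contribution `V` is shared equally among the *other* members, so a lone
  cooperator pays for nothing. A cooperator in a group earns
  `R - C + V (a-1)/(a+b-1)`, a defector `R + V a/(a+b-1)`.
* **Hawk–Dove** (`hd_payoff()`): with any hawk present doves concede and
  earn `R`; the hawks fight, one takes `V`, the losers pay `C`, so a hawk
  expects `R + (V - (a-1) C)/a`. All-dove groups split: `R + V/b`.

Payoff positivity is *not* enforced at the game level — the stochastic
dynamics need strictly positive fitness, and that validation happens where
fitness is consumed, so the payoff functions stay total.

## Fitness

The reference route (`mean_fitness()`) places `k` mutants on homes `1..k`
(any assignment is equivalent by exchangeability — asserted in tests) and
averages each type's payoff over the full group distribution. Two closed
forms sit on top of it, each guarded by equivalence tests against the
reference:

* **Public Goods, any mechanism:** `F_C = R - C + (k-1) V d_N`,
  `F_D = R + k V d_N`. The game is linear in pairwise encounters, so the
  whole movement mechanism enters only through `d_N`.
* **Hawk–Dove, independent movement:** dove fitness `R + tau V` and hawk
  fitness `R + omega V - nu C` with explicit `tau(h, N, k)`,
  `omega(h, N, k)`, `nu(h, N, k)` (`hd_fitness_closed()`). The printed form
  of `tau` carries an unsimplified factor (`k(N-1) + (N-k)(N-1)`, i.e.
  `N(N-1)`), which raised the suspicion of a transcription slip; the
  enumeration oracle confirms all three terms to 1e-14 over
  `N = 2..5`, `k = 1..N-1`, `h` in `{0.5, 1, 2, 10}`, so the forms are used
  as printed. A second, independently derived route
  (`hd_fitness_independent()`) evaluates the same quantities by binomial
  sums over the focal place's occupancy; it agrees with both and extends to
  very large `N`. Structurally `nu = 1 - omega`, since a hawk's payoff is
  `(V + C)/(1 + a') - C` in expectation over the other hawks `a'`.

In the infinite-population limit with dove proportion `p` (at `h = 1`),
the fitnesses converge to `R + V (e^p - 1)/(e p)` for the dove and
`R + V (1 - e^(p-1))/(1-p) - C (e^(p-1) - p)/(1-p)` for the hawk
(`infinite_population_fitness()`); the convergence is checked numerically
at `N = 1e3` and `1e4`.

## Fixation probabilities

All analytics reduce to the standard birth–death chain formula
`rho = 1/(1 + sum_j prod_{k<=j} delta_k/beta_k)`
(`fixation_from_ratios()`, products accumulated in log space so long
chains and strong selection cannot under- or overflow). The two dynamics
supply the ratios:

* **BDB** (selection on birth): reproducer chosen proportionally to
  fitness, victim through the replacement weights. On the complete graph
  the ratio collapses to `F_resident/F_mutant` (`bdb_ratios()`).
* **BDD** (selection on death): reproducer uniform, victim proportionally
  to inverse fitness. The ratio becomes
  `(N - k + (k + w*) F_R/F_M) / (k + (N - k + w*) F_M/F_R)`
  (`bdd_ratios()`), reducing to the BDB ratio when `w* = 0`.

`markov_fixation()` is the independent oracle: it assembles the full
`(N+1)`-state chain from the primitive transition rules (including staying
probabilities) and solves the boundary-value linear system. Tests require
closed forms and oracle to agree to 1e-10 relative across games, dynamics,
mechanisms and `h` — exactly, since both are evaluated from the same
fitness and weight inputs, this is a genuine check of the algebra, not of
sampling error. For `N <= 6` those inputs are exact; at `N = 10` the
row-dependent mechanisms use Monte-Carlo pair statistics (independent
movement keeps its closed sums), fed identically to both routes.

### Weak selection

For large background payoff `R` the Public Goods fixation probability
expands to `(1/N)(1 - (N-1)(V d_N + C)/(2R))` under BDB, with the factor
`(N + 2w*)/(N + w*)` multiplying the load under BDD
(`weak_selection_pgg()`). The expansion error decays like `1/R^2`
(verified: the absolute error shrinks ~100x between `R = 1e3` and `1e4`),
and the two dynamics coincide exactly at `w* = 0`.

`dove_neutral_ratio()` finds the cost-to-reward ratio `C/V` at which a
mutant dove is exactly neutral (`rho = 1/N`), by bisection on a bracket
expanded geometrically from `[0.5, 4]` to a 1e-12 tolerance; the residual
at the root is checked below 1e-10. A closed weak-selection series for the
same ratio is also evaluated for comparison; its printed form has two
ambiguities that we resolve and record rather than hide: the constant
`gamma` is taken to be Euler–Mascheroni, and the generalized harmonic sum
`H[n, a] = sum a^k/k` uses the base `a = (h+N-1)/(h+N-2)` (the printed
expression overloads `k` as both summation index and exponent). The numeric
root is authoritative; both values and their discrepancy are reported.

Two properties of the root are worth recording. At `N = 10` and moderate
home fidelity (`h` in `0.5..2`) it sits near 1.43 — above 1 but below the
classical pairwise neutrality value of 1.5, the multiplayer penalty on
hawks. As `h` grows the process approaches neutrality (everyone is alone,
every `C/V` is nearly neutral) and the root becomes weakly identified,
drifting upwards (~1.55 at `h = 10`); tests bound it only loosely there.
The root also falls with `N` (1.96 at `N = 5`, 1.31 at `N = 15`): bigger
potential groups hurt hawks more. Setting the infinite-population dove and
hawk fitnesses equal gives the equilibrium reward-to-cost ratio
(`equilibrium_ratio()`), `V/C = 0.688` at `p = 1/2`, i.e. `C = 1.453 V` —
the headline number the acceptance script recomputes.

## The agent-based simulator

`estimate_fixation()` runs the full stochastic process, one generation
being:

1. a movement realization; each group plays one round; every individual's
   fitness is its *realized* payoff from that single round;
2. everyone returns home;
3. a fresh movement realization with no game — these are the replacement
   groups;
4. one birth–death event. BDB: reproducer proportional to fitness over the
   whole population, victim uniform among the reproducer's co-group
   members; BDD: reproducer uniform, victim among co-group members with
   probability proportional to inverse fitness. A lone parent is replaced
   by its own offspring (a no-op for the type composition). Whether the
   BDB victim draw may include a non-lone parent is a switch
   (`bdb_include_parent`, default off: the offspring replaces *another*
   member).
5. the offspring takes the victim's vertex and the parent's type.

Runs start with the mutant on a uniformly random vertex and stop at
fixation or extinction, with a `max_steps` safeguard (default 1e7) for
processes that cannot absorb; non-absorbed runs are counted and excluded.
Estimates come with Wilson 95% intervals. The inner loop is compiled
(Rcpp); each replicate runs on a counter-derived xoshiro256++ substream,
so results are reproducible from the master seed alone and independent of
replicate order. All realizable payoffs are validated strictly positive up
front (e.g. crowded hawks with `V < (N-1)C - R` would otherwise go
negative silently).

The one-shot realized fitness is deliberately *not* the state-averaged
fitness of the analytic process — the analysis is an idealisation of this
simulation. An optional idealized mode substitutes the state-dependent mean
fitnesses (`fitness_tables()`), enabling direct statistical comparison with
the closed forms; tests confirm the idealized simulator's interval covers
the closed-form value. With realized fitness the two processes agree under
BDB but are known to diverge under BDD when self-weights are large (mostly
lone individuals): at `h = 100`, `N = 10` the simulator gives ~0.102
against an idealized 0.092. The tests encode exactly this: BDB coverage,
and "within 0.01 of 1/N" for both dynamics.

### What the simulations emulate — and what they do not

The simulator *is* the model: there is no external data, and the study
conditions are the ones the analysis states (`R = 10, V = 2, C = 1`,
`N = 10`, mechanisms at `h = 1` for the orderings). Passing tests therefore
show internal consistency of the stochastic process with the analytic
machinery and the predicted qualitative orderings (herding is worst for
cooperators and best for doves; near-complete dispersal is best for
cooperators); they say nothing about any real population's movement, and
the mechanisms themselves are stylizations of herding and dispersal, not
fitted behaviour.

## Problem sizes and numerical settings

The package's standing choices, stated once:

* enumeration cap `N <= 6` (exact distributions, fitness, pair statistics);
  beyond it, Monte Carlo with explicit sample sizes;
* faithfulness: exact at `N <= 4` (1e-12), Monte Carlo at `N = 10` with
  1e5 draws (4 standard errors);
* ordering experiments: `N = 10`, `h = 1`, 5e4 replicates (the analysis
  protocol's 1e6 is unnecessary for direction-of-effect contrasts —
  non-overlapping 95% intervals decide them), near-neutral checks at 2e4;
* root searches: bisection/`uniroot` at 1e-12, bracket `[0.5, 4]` expanded
  geometrically; chain products in log space;
* wheel quantization: 3 decimals in radians, configurable.

## Limitations

* Complete graphs only; no subpopulation structure, heterogeneous apriori
  targets, or history-dependent (Markov) movement.
* Closed-form Hawk–Dove fitnesses cover independent movement only;
  row-dependent Hawk–Dove goes through enumeration or simulation.
* Exact row-dependent pair statistics stop at the enumeration cap; beyond
  it they are Monte-Carlo estimates with quantified error.
* The BDD realized-fitness process differs from its idealisation at large
  self-weights (see above); only the idealized mode is directly comparable
  to the closed forms there.
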