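---
title: "Reputation heuristics, cooperation and polarization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation heuristics, cooperation and polarization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`heidercoop` simulates a finite population of `n` agents whose social state
is a signed **reputation matrix** `S`: entry `S[x, y]` in `[-1, 1]` is agent
x's relationship with (equivalently, opinion of) agent y. The diagonal is
fixed at 1 — an agent trusts no opinion more than its own, and no
relationship can be better than the one it has with itself. `S` starts as
the identity matrix: nobody knows anybody.

Each iteration has three stages:

1. **Random matching.** A uniformly random perfect matching pairs every
   agent with a partner (for odd `n` one uniformly chosen agent idles).
2. **Action choice.** Each agent plays C (cooperate) or D (defect) in a
   Prisoner's Dilemma. Reputation-sensitive agents aggregate gossip about
   the partner y: every third party i contributes its opinion `S[i, y]`,
   weighted by the focal agent's relationship `S[x, i]` with the opinion
   holder. The aggregate, the *relationship score* rs, is mapped to a
   cooperation probability by a logistic choice rule
   `p(C) = 1 / (1 + exp(-rs / temperature))` with temperature 0.2. All
   decisions in an iteration are made from the iteration-start snapshot of
   `S`.
3. **Relationship updating.** Mutual cooperation raises both directed
   relationships by the increment `r`; a cooperator lowers its opinion of a
   defecting partner by `r`; mutual defection lowers both. A defecting
   agent whose partner cooperated leaves its own opinion unchanged, which
   prevents dyads from oscillating between anti-correlated states. Values
   are clipped to `[-1, 1]` — beyond those bounds the logistic choice is
   saturated anyway, so the bound costs nothing behaviorally.

The weighting of third-party opinions is what distinguishes the agent
strategies, following the four structural-balance heuristics (a friend of a
friend is a friend; an enemy of a friend is an enemy; a friend of an enemy
is an enemy; an enemy of an enemy is a friend):

* **Heider agents** use the signed relationship as the weight — all four
  heuristics.
* **Friend-focused agents** zero negative weights — they only consult
  friends, so only the two friendship heuristics operate.
* **Enemy-focused agents** zero positive weights (except their own
  self-trust) — only the two enemy heuristics.
* **Incomplete Heider agents** drop only the "enemy of an enemy" product.
* **Defectors** always play D and neither score nor update.

One convention deserves emphasis: the partner's self-opinion (the `i = y`
term, which would contribute `S[x, y] * S[y, y] = S[x, y]` a second time)
is excluded from the sum. With it included, a single mutual cooperation at
increment r from a neutral start would produce a score of 2r; excluded, it
produces exactly r, which is what makes the analytic anchor points hold
(p rises from 0.5 to 0.62 at r = 0.1 and to 0.92 at r = 0.5). The agent's
own opinion still enters exactly once, through the `i = x` term carried by
the unit self-trust `S[x, x] = 1`; for enemy-focused agents this weight is
kept at 1 because direct experience is not "the opinion of a friend".

## Evolution

Payoffs follow the standard donation-game Prisoner's Dilemma: playing C
costs the actor `c` and delivers `b > c` to the partner; D is free and
gives nothing. Payoffs accumulate over `i` pairing iterations (one
*generation*), after which one uniformly chosen agent adapts its strategy
by a frequency-dependent Moran rule with exponential fitness: with
probability `u` it mutates to a uniformly random strategy from the
scenario's pool; otherwise it copies an agent drawn with probability
proportional to `exp(payoff)` (possibly itself). Payoffs then reset — the
fitness window is exactly one generation. Exponentials are computed after
subtracting the maximum payoff, which leaves the ratios unchanged and is
numerically required at parameter-grid corners (payoffs up to
`b * i = 256`).

**Relationship reset on adoption.** The update rule can be read as social
learning (the same person switches heuristics, keeping its relationships)
or as death–birth selection (a new strategy carrier replaces the old, with
no relationship history). The package defaults to the death–birth reading:
when the focal agent changes strategy, its relationship row and column
reset to neutral. This choice is forced by the model's macroscopic
behavior. With persistent relationships, a defector-majority population is
effectively absorbing at n = 100: converts inherit blank or stale rows,
get exploited, and the three-strategy dynamics never leave defection over
4 x 10^5 iterations. With reset, the dynamics show the expected
phenomenology — long friend-focused majorities with high in-clique
cooperation, recurrent Heider bursts that polarize the network, defector
invasions of polarized states, and completed
defection → community-building → polarization cycles. The social-learning
variant remains available via `reset_on_adoption = FALSE`.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `r` | relationship increment per interaction | 0.3 | 0.1 / 0.5 give slower / faster bonding; equivalent to rescaling temperature |
| `temperature` | logistic scale | 0.2 | fixed throughout the analyses |
| `b`, `c` | PD benefit and cost | 4, 1 | Rapoport index K = (b - c)/(b + c) |
| `i` | iterations per generation | 10 | fitness window of the Moran step |
| `u` | mutation probability | 0 (off) | 0.01 in the evolutionary scenarios |
| `k` | memory capacity | n - 1 | entries of largest magnitude retained, rest forgotten to 0 |
| `iterations` | total pairing rounds | — | 1e5 for network snapshots, 4e5 for evolutionary runs |

Memory constraints act at the end of every iteration on every row: the `k`
relationships of largest absolute value ("best friends and worst enemies")
are kept, all others are reset to the neutral 0 — a forgotten relationship
is indistinguishable from never having met, matching the identity
initialization. Exact-magnitude ties at the retention boundary are
resolved uniformly at random from the simulation's single RNG stream, so a
run is fully reproducible from its seed.

## Measurement layer

Polarization is measured on the **mutual-positive graph**: an undirected
edge links x and y iff both `S[x, y] > 0` and `S[y, x] > 0` (strictly — a
neutral, forgotten relationship is not a link), weighted by the mean of the
two directions. Communities are counted by Louvain modularity maximization
at resolution 1 under a fixed internal seed; isolated agents are singleton
communities. On disjoint unions of cliques the count provably equals the
number of connected components, which the tests use as an oracle.

The decline of the community count with the number of embedded Heider
agents is summarized by an exponential-decay regression. Two
parameterizations are supported: pure, `y = A exp(-x / tau)`, and offset,
`y = y0 + A exp(-x / tau)`. The package reports the **pure form** for this
quantity. The community count flattens near its polarized floor of about
two communities; an offset fit absorbs that floor into `y0` and returns a
much smaller tau describing only the initial drop, while the pure form
measures the overall multiplicative decline ("declines by a factor of
tau"), which is the scale on which a decay constant near 5 is obtainable
at all. `model_form` is recorded in every fit object.

Evolutionary trajectories are summarized by the plurality strategy of each
generation (`MIXED` on ties). From that sequence the package estimates a
maximum-likelihood Markov transition matrix (transition counting, `NA`
rows for unvisited states) and counts **fission–fusion cycles**: completed
ordered traversals defector-majority → friend-majority → Heider-majority →
defector-majority. `MIXED` generations are transparent to the phase
tracker — they neither advance nor reset it — and the defector phase that
closes one cycle opens the next. This is the minimal operationalization
consistent with the narrative; published cycle counts depend on the
(unstated) detection rule, so quantitative comparisons of cycle rates
carry that caveat. When cycle rates are expressed "per 1000 generations"
in cross-study comparisons, a generation is taken as the standard Moran
population sweep of `n` single-agent updates; a rate of more than ~10
cycles per 1000 *single updates* is arithmetically impossible at n = 100,
since a majority turnover needs at least ~34 updates per phase.

## Study conditions and desk scales

The preset experiments fix the study conditions: identity-initialized
matrices; `r = 0.3`; 1e5 iterations for non-evolutionary network
snapshots; n = 100, i = 10, b = 4, c = 1, u = 0.01 for evolutionary runs;
evolutionary runs start from an all-defector population (the hardest
initial condition, from which friend-focused cooperation must bootstrap).
Desk scale reduces only breadth, not the conditions themselves:
polarization uses population sizes {10, 20, 40} with 20 replicates (full
scale adds 60 and 120 with 50 replicates), the Heider gradient uses sizes
{20, 40} x 0–5 Heider agents x 20 replicates, and evolutionary preset runs
use 4 x 10^4–4 x 10^5 iterations. Every preset writes a manifest with all
parameters and derived seeds (base seed plus a run counter), so any output
is reproducible from the manifest alone.

## What the synthetic experiments do and do not show

All inputs are generated by the model itself; there is no external data.
Passing tests therefore demonstrate internal consistency with the model's
specification — the scoring algebra against a brute-force enumeration of
the four heuristics, the Moran rule against its closed form, Louvain
against connected components, regression recovery on synthetic decay — and
reproduction of the model's emergent phenomenology (two-faction
polarization of Heider populations, small scattered friend-focused
communities, defector exploitation of polarized networks, memory effects).
They do not validate the model against human data: real social networks
have heterogeneous meeting probabilities (explicitly not modelled here, to
keep group structure disentangled from meeting probability), noisy and
partial gossip, and non-stationary strategy sets.

## Numerical and degenerate-input choices

* Scores and updates run in compiled code; R wrappers validate arguments
  and share the same primitives, so unit tests exercise the long-run code
  path.
* A dyad of friend-focused agents starting neutral absorbs at a clip
  bound; the drift from 0 is negative ((1/4 - 1/2) r per meeting), so
  mutual enmity is the modal outcome (~77%) and mutual friendship arises
  in ~23% of runs — a useful reminder that the baseline logistic at rs = 0
  cooperates half the time but punishes asymmetrically.
* Constant responses are rejected by the decay fit (no decay scale);
  non-convergence raises an error carrying the data range rather than
  returning a silent `NA`.
* `estimate_transition_matrix` flags never-visited states with `NA` rows
  instead of fabricating a uniform row.
* Community counting preserves and restores the caller's RNG state, so
  mid-run measurement does not perturb a seeded trajectory.

## Known limitations

* The relationship score is a raw weighted sum; in dense positive networks
  it saturates the logistic and decisions become near-deterministic. A
  `normalize_rs` switch (divide by n - 1) is provided for exploration but
  is off in all presets.
* Cycle counts are sensitive to the phase-tracking rule and to run length;
  they should be compared across conditions within this package rather
  than against externally published counts.
* Louvain is the only community detector wired in; the measurement layer
  accepts any igraph graph, so alternatives can be applied externally.
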