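---
title: "Closed-loop neurofeedback control of weighted heuristic search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop neurofeedback control of weighted heuristic search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcisearch)
```

`bcisearch` implements, end to end, a closed-loop system in which a
simulated brain–computer interface (BCI) signal — prefrontal asymmetry
measured by functional near-infrared spectroscopy (fNIRS) under a
neurofeedback (NF) protocol — modulates the behaviour of a running
heuristic search.  The loop trades solution optimality for computation
speed: stronger volitional asymmetry maps to a larger heuristic weight,
which shrinks the explored search space under a provable cost bound.  This
vignette is the package's account of the model, its tunable parameters, and
the design decisions taken where more than one choice was defensible.

## 1. The search engine

The engine is best-first search over an explicit OPEN/CLOSED scheme with
the weighted evaluation

$$f(n) = (1-\omega)\,g(n) + \omega\,h(n), \qquad \omega \in [0.5, 1),$$

where $g$ is the accumulated path cost and $h$ an admissible heuristic.
$\omega = 0.5$ is an exact positive rescaling of the classical $g + h$, so
it reproduces admissible A\* ordering and optimal solutions;
$\omega > 0.5$ over-weights the heuristic and is no longer admissible, but
the suboptimality is bounded: the returned cost never exceeds
$\frac{\omega}{1-\omega} \, C^\*$ where $C^\*$ is the optimal cost.  Every
run returns a `bound_report` that checks this inequality against an
exhaustive oracle.

Three decisions were genuinely open and are fixed as follows:

* **Tie-breaking.** Equal $f$ is broken by larger $g$, then by first-in
  insertion order.  Preferring deeper nodes is the common convention and
  makes "$\omega=0.5$ equals A\*" exact rather than approximate.
* **Re-opening.** A closed state rediscovered with lower $g$ is re-opened,
  including after a weight change.  This guarantees the
  $\omega/(1-\omega)$ bound for every dynamic schedule, at the cost of
  occasional re-expansions.
* **Weight changes rebuild the whole OPEN list.**  When a trigger fires,
  every open node's $f$ is recomputed and the priority queue rebuilt.
  Lazy re-evaluation would be faster but harder to verify, and traces at
  this problem scale are small.

Dynamic re-weighting follows a `weight_schedule`: an initial weight plus
triggers `(fraction, weight)`.  "Fraction of the search space explored" is
operationalised as expanded nodes divided by a *reference exploration* —
the admissible A\* node count for the same instance, which the closed loop
computes up front (instances are pre-characterised, so this reference is
known before the monitored run).  With the `monotone` flag the applied
weight is the running maximum, so repeated interventions only ever tighten
the heuristic bias.

Two node counts are reported.  `nodes_expanded` counts expansion events,
including re-expansions of re-opened states; `nodes_explored` counts
distinct states expanded.  They coincide for consistent heuristics at
$\omega = 0.5$ and differ only through the re-opening policy.  Sweep
*reductions* are computed on `nodes_explored`: re-expansions are an
artefact of our bookkeeping, not additional exploration, and on
hard 8-puzzle instances they are also the reason an onset-weighted run can
expand a handful more events than one triggered at 10–25% — a short
admissible prefix fixes exact $g$ values near the root and avoids later
re-openings.  On distinct states the impact of earlier intervention is
monotone, as expected.

FOCAL (A\*$_\varepsilon$) search is implemented alongside: at each step the
FOCAL subset holds every open node within a factor $(1+\varepsilon)$ of the
best $f$, and the expanded node minimises a secondary heuristic inside it,
giving a $(1+\varepsilon)$ cost bound with an admissible primary heuristic.
FOCAL selection is a linear scan of OPEN — quadratic in the frontier, but
exact and entirely adequate at benchmark scale.

Costs are compared with a $10^{-9}$ tolerance; for the unit-cost 8-puzzle
and half-integer blends all comparisons are in fact exact in double
precision.  A node budget (default $5 \times 10^6$ expansions) bounds
degenerate configurations; exhausting it is reported as a flag, not an
error.

## 2. Benchmark domains and oracles

**8-puzzle.**  States are 9-digit strings, row-major, `0` the blank;
moves cost 1; the heuristic is the Manhattan distance of misplaced tiles
(admissible and consistent).  The optimality oracle is an exhaustive
breadth-first search from the goal over the reachable half of the
$9! = 362{,}880$ permutations, ranked by Lehmer code; it runs in well under
a second, is cached per goal, and doubles as the instance-difficulty
labeller (`generate_puzzle_instances` samples uniformly from all states at
or above a requested optimal solution length, so every instance carries a
verified label).  The distance table reproduces the known depth profile —
the diameter is 31 moves, with exactly 2 states at depth 31 and 221 at
depth 30.

**Grid path planning.**  Occupancy grids with 0-based `(row, col)` cells,
4-connected unit moves by default (8-connected with $\sqrt 2$ diagonals and
no corner-cutting available by configuration; the choice is a convention,
declared not derived), and the Euclidean straight-line heuristic, which is
admissible for both move sets.  The independent oracle is Dijkstra via
`igraph::distances()` over the free-cell graph — a deliberately separate
code path from the search engine.  Random maps block cells independently
with the requested density and are regenerated until start and goal
connect.

## 3. The synthetic fNIRS generator

A `virtual_subject` stands in for the human user.  Its asymmetry signal
(mean of four left HbO channels minus mean of four right channels, in
baseline-relative arbitrary units) decomposes into:

* `trait_asymmetry` — a stable resting offset, carried $+/-$ half by each
  hemisphere;
* `state_gain` — the volitional component: during the NF epoch, after a
  haemodynamic onset delay, the left–right difference rises along a
  saturating exponential towards the gain, and relaxes back afterwards.
  Non-responders have zero effective gain;
* `fatigue_decay` — a multiplicative per-block attenuation
  ($\text{gain} \times \text{decay}^{k}$ for block $k$), modelling the
  drop in BCI performance towards the later blocks of a session;
* `noise_sd` — per-channel white noise; and a slow linear drift common to
  all channels, which cancels exactly in the asymmetry score.

The block protocol defaults to rest (30 s) → NF (30 s) → washout (20 s) at
10 Hz — a typical continuous-wave fNIRS rate; the NF epoch is capped at
120 s.  The baseline is the final 10 s of the epoch preceding NF, and the
scored NF window discards the first 7 s of the epoch for the haemodynamic
onset; the response time constant is tied to the same 7 s delay.  A
counting epoch can replace rest as the baseline source, as some protocols
prefer; both are supported and which is "correct" is left to
configuration.

The response is a saturating exponential rather than a full double-gamma
haemodynamic response function: the modelled contract is the onset delay
and a plateau, and the simpler shape makes closed-form checks possible
(at the end of a 30 s NF epoch the response reaches
$1 - e^{-23/7} \approx 96\%$ of the programmed gain).  What the generator
deliberately does **not** emulate: motion artefacts, autocorrelated
physiological noise (cardiac, respiratory, Mayer waves), optical coupling
physics, HbR, and the valence/approach confound of real cognitive
strategies — `state_gain` aggregates whatever strategy the subject would
use.  Consequently, passing tests show the *pipeline* behaves correctly
under its stated model, not that real fNIRS data would yield the same
rejection rates; with autocorrelated noise the per-block t-test would be
anticonservative, which is a known simplification of real-time NF practice.

## 4. Scoring and the mapping

`score_block` computes the asymmetry series, references it to the baseline
mean ("zero asymmetry" regardless of absolute level), and applies a
one-sided two-sample Welch t-test (NF window > baseline; only left-dominant
asymmetry is rewarded), Cohen's $d$ with pooled standard deviation, and a
bootstrap: both windows are resampled with replacement (default 1,000
times) and `bootstrap_fraction` is the proportion of resamples whose NF
mean exceeds the baseline mean.  A block is *successful* when
$p < \alpha$ (default 0.05) **and** the bootstrap fraction reaches its
threshold (default 0.95).  A session succeeds when at least half of its
blocks do.  Degenerate zero-variance windows with separated means are
treated as maximal evidence with $d$ capped at `d_max`; zero variance with
equal means is an error, as no statistic is defined.

The mapping is linear in the effect size with a significance gate:

$$\omega = \omega_{\text{base}} + \frac{\min(\max(d, 0),\; d_{\max})}{d_{\max}}
  \,(\omega_{\max} - \omega_{\text{base}}),$$

with $\omega_{\text{base}} = 0.5$ (no input keeps the search admissible),
$\omega_{\max} = 0.6$ and $d_{\max} = 1.5$ by default.  The ceiling
brackets the operative weight range (0.55–0.575, where most of the
speed-up is already realised on these benchmarks) with headroom, and 1.5
is a conventionally very large standardised effect; both are configurable
and declared rather than inferred — no published constants exist for this
mapping.  Note one consequence of the saturation: across noisy blocks
programmed exactly at $d = d_{\max}$, the *mean* mapped weight sits
slightly below $\omega_{\max}$, because sampling variation below the
ceiling maps linearly but variation above it is clipped.

The abstract feedback channel is a normalised focusing value
`clamp((current − baseline)/target_gain, 0, 1)` — 1 denotes the narrowest
search beam.

## 5. The closed loop

For the 8-puzzle, one NF block is scored and installed as a single
monotone trigger at a configurable fraction (default 0.1, restricted to
[0, 0.25] — the early stage of the search, where re-weighting has the most
impact).  The search is conceptually paused at the trigger point until the
block score is available; no real-time co-scheduling is attempted.  For
grid planning, `n_updates` blocks are scored as the search progresses,
with triggers at progression fractions $0, 1/n, 2/n, \ldots$
(progression-driven rather than time-driven — the choice is ours) and the
running-maximum rule, so the weight only increases through time.  The
recorded search-space reduction is $1 - \text{nodes}/\text{reference}$.

## 6. Study conditions and problem sizes

The cohort sampler encodes the default study conditions: trait asymmetry
$\mathcal N(0, 0.3)$, responder gains $\mathcal N(0.5, 0.15)$ truncated at
0 against channel noise of 0.5 (per-block standardised effects near 1 for
a typical responder), fatigue 0.95 per block, sessions of 4 blocks.
`subject_with_effect()` inverts the response profile to program an exact
standardised window difference, which the power and calibration studies
use.

The packaged studies run at desk scale, chosen so the full suite completes
in well under a minute while keeping Monte-Carlo error far below the
asserted margins: 200 random solvable puzzles and 50 random grids for the
oracle and bound checks; 200 instances of difficulty ≥ 20 for the weight
sweep; the complete 223-state population of difficulty ≥ 30 for the
intervention-timing sweep (using the full population removes sampling noise
from a trend measured in fractions of a percent); 50 instances of
difficulty ≥ 28 for the backtracking contrast; 4,000 null blocks for type-I
calibration; 1,000 blocks against a 1,000-rep Monte-Carlo power oracle; and
20 responders versus 20 non-responders for the cohort direction test.

## 7. Known limitations

* The per-block t-test ignores autocorrelation (none is simulated; real
  data would need block-aware inference).
* The suboptimality bound is tight only in adversarial instances; on the
  8-puzzle the optimal solution is usually preserved even at
  $\omega = 0.6$.
* Human success rates from NF experiments are not reproduction targets:
  cohort outputs describe the simulated subject distributions only.
* FOCAL's linear-scan selection and the R-callback custom domain are
  correctness-first; they are not meant for large state spaces.

## A worked micro-example

```{r example}
inst <- generate_puzzle_instances(1, difficulty = 28, seed = 4)
subj <- virtual_subject(state_gain = 0.6, noise_sd = 0.5, seed = 4L)
lr <- run_closed_loop_puzzle(inst, subj, block_protocol())
lr$block_stats
lr
```

The block is scored, the effect size mapped onto a weight, and the
weighted run is compared against the admissible reference — with the cost
bound checked against the exhaustive oracle:

```{r bound}
lr$bound
```
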