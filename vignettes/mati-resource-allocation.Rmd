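---
title: "Methods: simulating and optimising multi-allelic trait introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and optimising multi-allelic trait introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matiMDP)
```

`matiMDP` couples a meiosis-level simulator of a marker-based introgression
program with a finite-horizon Markov decision process (MDP) that chooses the
number of progeny to produce each generation. This vignette documents the
model, its assumptions, the tunable parameters, and the design decisions
behind the implementation — the things a user should know before trusting a
fitted policy.

## The breeding process being modelled

A project starts from two homozygous founders: an elite recipient carrying
the desirable allele at most loci and a donor carrying it at the remaining
few. Each generation the program (1) screens the current progeny for an
*ideal* individual — homozygous desirable at all `N` loci, the success
condition; (2) decides how many progeny `K` to produce, constrained by the
remaining budget and the deadline (deciding `K = 0` with budget left
abandons the project); (3) selects the best pair of parents from the current
progeny plus the two parents of the previous generation; and (4) crosses
them. Generations are indexed from 0 (the founders); the generation-0
decision produces the F1.

## Meiosis and the genetic map

A genotype is an `N x 2` binary matrix (loci x homologs, 1 = desirable). A
gamete is simulated as a two-state Markov chain along the loci: it starts on
either homolog with probability 1/2 and switches between adjacent loci
`i, i+1` with probability `f_i`. Crossovers are independent — no
interference is modelled — and setting `f = 0.5` at every linkage-group
boundary makes one chain over all `N` loci reproduce independent assortment
of chromosomes exactly, which is why the map stores a single `f` vector of
length `N - 1` rather than per-chromosome structures.

The default synthetic map mirrors the package's case study: 100 markers
spread over 10 linkage groups with 8–12 markers each, positions uniform on a
100 cM chromosome, and within-group recombination frequencies from the
Haldane function `f = 0.5 (1 - exp(-2d/100))`. The per-chromosome genetic
length is a parameter (`map_length_cM`, default 100 cM — a typical crop
linkage-group length) because only the marker counts and the uniform-
position rule are fixed by the study design. Users with a real map load it
with `read_map_csv()`; nothing downstream depends on the map being
synthetic. Marker names keep the field's 1-based `CiMj` convention while
loci are handled 0-based internally.

## Predicted cross value

The selection metric is the probability that a gamete produced by a random
progeny of the pair carries the desirable allele at every locus. The exact
computation tracks eight joint origin states `(c1, c2, g)`: which homolog
each parental gamete is currently copying, and which of the progeny's two
chromosomes the final gamete is copying. All three coordinates switch
independently between adjacent loci with the local `f_i`; a state survives
locus `i` only if the allele it addresses is desirable; the PCV is the mass
surviving the last locus. The computation is linear in `N` with an 8 x 8
kernel, implemented in C++ (values as small as 1e-21 arise for realistic
founders, but remain far above double-precision underflow, so linear-space
accumulation is exact enough; `log10(PCV)` is reported, `-Inf` for 0).

A Monte-Carlo oracle (`pcv_mc_oracle()`) estimates the same probability by
simulating progeny and one gamete per progeny through the *same* meiosis
code path. The test suite treats the oracle as the arbiter: the dynamic
program must agree within three binomial standard errors across random
small-genome instances, and a hand-enumerated two-locus value
(`f(1-f)/4`) must be reproduced to 1e-12.

Selection maximises PCV over all unordered candidate pairs. Self-crosses
are excluded. The candidate pool is the progeny plus the retained previous
parents, which guarantees the selected-pair PCV never decreases — the
monotonicity that later makes the transition matrices upper-triangular.
With 1,000 progeny an exhaustive pair search is ~500k PCV evaluations, so
`screen_top` (default 100) first ranks candidates by desirable-allele count
and searches pairs among the top block; this is a disclosed approximation,
switched off by `screen_top = NULL`. Ties break towards the lowest index
pair, making runs deterministic given the random stream.

## From trajectories to a decision model

`preliminary_simulation()` runs the unconstrained loop (fixed `a`, no
budget) to success, `n_reps` times per non-zero action, recording the
selected-pair PCV `p_g` at each generation. The interval partition is built
from these trajectories: `m_0` is the founder-pair PCV; `m_1` the F1-pair
PCV, identical across runs because homozygous founders produce a unique F1
(the construction errors if not); `m_g = [min p_g, min p_{g+1})` for
`2 <= g <= G-1`, minima over all runs and actions; `m_G = 1`, the ideal
pair. `G` is the largest terminal generation observed. Intervals are
half-open; a value equal to an upper bound belongs to the next interval,
`p = 1` maps to `G`, and values below the partition clamp to the founder
index 0.

Transition counting walks each trajectory once per action:
`W^a[i, j] = N^a[i, j] / sum_j N^a[i, j]`. Rows never observed get a
self-transition of 1 — the conservative choice (no free progress) for
interval/action pairs outside the preliminary data. Stationarity of `W^a`
across epochs is an assumption inherited from the model design, not
something the package verifies.

## The MDP and its conventions

States are `(m_g, b)` for `g in 1..G-1` and remaining budget `b` in $1,000
units, plus absorbing `success` and `failure`. The unit equals the cost of
the smallest non-zero action (100 progeny at $10 each), so budget
bookkeeping is exact integer arithmetic. Under action `a` the budget moves
to `b - cost(a)`; interval mass moves by `W^a`, with column `G` collected
into `success`; non-success mass arriving at zero budget falls to
`failure`; choosing `a = 0` in a live state is failure (the project is
abandoned with budget on the table, as the process definition prescribes).
Actions costing more than `b` are infeasible rather than clipped.

Economic parameters (defaults in `mati_config()`): cost `10a` dollars,
revenue `2,000,000 - 100,000 t` on the epoch the process *first* reaches
success with `t <= T`, deadline `T = 8`. Revenue is granted on the
transition into success — the absorbing success state itself earns nothing
— which prevents collecting the market value once per epoch; concretely,
the epoch-`t` expected reward folds in `lambda * R(t+1) * P(success | s, a)`
and the terminal value is zero everywhere. The discount factor has no
published value in this problem family's parameter tables even though the
objective is a net present value; the package defaults to
`lambda = 0.95` per generation and exposes it (`lambda = 1` gives the
undiscounted model). Backward induction breaks ties towards the smallest
action, so policies are reproducible.

Two framing choices deserve emphasis. First, the interval state space
starts at `m_1`: because both founders are homozygous, every F1 is
identical and any non-zero generation-0 action reaches `m_1` with
certainty, so the dynamic allocator always spends the smallest non-zero
action (100 progeny) on the F1 cross and the solved horizon covers epochs
`1..T-1`. Second, beyond the solved horizon the dynamic policy returns 0 —
deadline exceeded means failure. Static policies instead truncate to the
largest affordable multiple of 100 (a 600-per-generation strategy on
$32,000 produces 600 in generations 1–5 and 200 in generation 6), matching
how a fixed-family-size program actually drains a budget.

The solver is validated two ways: `evaluate_policy()` must reproduce the
backward-induction value when fed its own decision table, and
`enumerate_policies_oracle()` — exact evaluation of *every* deterministic
Markov policy on instances small enough to enumerate — must agree with the
solver's value at every state. The in-model value of the solved policy is
also checked to dominate every static strategy at every budget, which is an
optimality corollary rather than an empirical finding.

## Experiments

* `ctp_analysis()` — the cost/time/probability view: terminal-generation
  histograms with binomial standard errors across a budget sweep.
* `compare_strategies()` — static `K = 100..700` versus the dynamic policy
  at a fixed budget, with both realised outcomes and exact in-model values.
* `optimize_budget()` — mean realised net revenue per budget, fitted with
  `y = a1 + a2 exp(a3 x)` (`a2, a3 < 0`) by Levenberg–Marquardt least
  squares with multi-start initialisation over the decay rate; the optimal
  budget is where the marginal return `a2 a3 exp(a3 x)` per extra $1,000
  falls to $1,000. The fit is checked by parameter recovery on data
  generated from the model plus noise.
* `allocation_breakdown()` — realised spend per generation, normalised by
  total spend; failed runs contribute their partial spend.

All experiment functions accept a precomputed CTP result so that one budget
sweep feeds the revenue curve and the breakdown without re-simulation, and
all honour a single master seed: identical seeds reproduce tables
bit-for-bit.

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the case study — marker counts,
founder composition, linkage-group boundaries — but draws its own marker
positions, so recombination frequencies between the donor loci differ from
any particular real map. Quantities that depend on those distances (founder
PCV, number of intervals `G`, success probabilities at a given budget, the
optimal total budget) therefore vary between generated maps; the shapes
(success probability non-decreasing in budget with diminishing returns,
dynamic allocation front-loading spend in early-to-mid generations) are
stable. Passing tests demonstrate correctness of the machinery on such
genomes, not calibration to any particular crop: real programs have
interference, genotyping error, phenotypic costs and non-binary allele
effects, none of which are modelled.

## Problem sizes and numerics

The test suite exercises the full machinery on a 10-marker, 2-chromosome
genome (preliminary fits with 12 repetitions per action over actions
{100, 200}), where a fit takes about a second, and validates the PCV and
solver kernels on 2–6-locus instances against their oracles. The
acceptance script runs the 100-marker case study at reduced replication —
30 preliminary repetitions per action, 100 replications per budget on a
$3,000-spaced grid, 60 per strategy in the comparison — sizes chosen to
keep a full from-scratch reproduction around ten minutes on one CPU while
leaving Monte-Carlo standard errors on reported probabilities below about
five percentage points. Row-stochasticity of every transition matrix is
enforced at 1e-12. Run-length safety caps (200 generations unconstrained,
100 budgeted) exist only to turn pathological configurations into errors;
realistic runs finish in under 15 generations.

## Known limitations

Single cross per generation and a single donor; no crossover interference;
PCV-based selection only (breeding-value or haplotype-score metrics are out
of scope); stationary empirical transitions estimated from preliminary
runs, so action/interval pairs rarely visited in those runs rely on the
conservative self-transition default; the revenue schedule is linear in
time and the cost linear in progeny count, with no fixed per-generation
costs.
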