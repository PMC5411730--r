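---
title: "Models and methods behind stepstone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stepstone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepstone)
```

`stepstone` studies how a metabolic network can expand into new nutrient
niches through series of single adaptive reaction acquisitions. This
vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made, and what its synthetic
test systems do and do not show about real data.

## Constraint-based model

A `metabolic_network` is a stoichiometric matrix $S$ (metabolites ×
reactions) with per-reaction flux bounds $l_i \le v_i \le u_i$. Flux
balance analysis (FBA) solves

$$\max\ v_{\text{biomass}} \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

the steady-state assumption plus capacity bounds. Environments are named
sets of open uptake exchanges: positive exchange flux is secretion (always
allowed), uptake is a negative lower bound on the exchange, and every
exchange not opened by the environment is closed for uptake. Unbounded
fluxes use the conventional cap of 1000 mmol·gDW⁻¹·h⁻¹; the unit is a
convention only — all analyses here depend on growth versus no growth, not
on flux magnitudes.

A network is *viable* in an environment when its FBA optimum exceeds
$10^{-6}$ biomass flux units. The tolerance sits strictly between LP
round-off and the $10^{-4}$ growth floor used by the gap-filling model, so
"viable" and "grows at the MILP floor" can never disagree on the systems
the package builds.

No LP solver ships with the R installation this package targets, so the LP
core is a dense bounded-variable two-phase primal simplex written in C++
(RcppArmadillo). Problems here have tens of rows, so the basis is simply
re-factorised every iteration, and Bland's rule engages after a run of
degenerate pivots to exclude cycling. Phase-1 infeasibility is declared
above an artificial mass of $10^{-9}$ — below the smallest constraint the
package ever imposes. The test suite cross-checks FBA optima against
`pracma::linprog` (an independent simplex) and asserts the mass-balance
residual $\|Sv\|_\infty \le 10^{-6}$ of every reported optimum.

## Curating a universal network

`curate_universal()` merges a host network with a universal reaction pool
and applies three filters:

1. **Duplicates.** Reactions are canonicalised as sorted
   (metabolite, coefficient) lists; a reversible reaction also matches its
   sign-flipped form, an irreversible one keeps its orientation. Pool
   copies of host reactions are dropped.
2. **Energy-generating cycles.** With *every* exchange closed, each
   energy-dissipation reaction (e.g. ATP hydrolysis) is maximised. A
   positive optimum exposes a perpetuum-mobile artifact. The minimal
   active supports are found by the gap-fill machinery run in "minimise
   active universal reactions subject to dissipation flux" mode, and a
   minimum-cardinality hitting set over the enumerated supports
   (lexicographic tie-break) is removed; detection and removal iterate to
   a fixed point. Because the closed-exchange system is homogeneous, a
   cycle sustaining any positive dissipation scales to dissipation 1
   within the caps, so detection runs at floor 1 rather than at the
   gap-filler's $\varepsilon = 10^{-8}$ — same answer, far better LP
   conditioning.
3. **Unconditionally blocked reactions.** With every exchange open in both
   directions — the most permissive medium expressible in the model —
   reactions whose flux-variability range is $(0,0)$ can never carry flux
   under any condition and are removed, iterating to a fixed point.

No filter ever removes a host-origin reaction; host-only cycles and
blocked host reactions are reported but kept. Curation is idempotent,
which the acceptance tests assert directly.

## Single-swap environments and novelty

Starting from a base minimal medium declaring one source per element (C,
N, P, S), `generate_environments()` closes the base source of one element
and opens one candidate nutrient's exchange at the default uptake bound
(10 units; any positive value preserves the viable/inviable dichotomy the
analysis uses). Non-swapped components stay open, so media differ from the
base by exactly one compound. An environment is *novel* when the host is
inviable but the pool-expanded network is viable — the niches reachable by
acquiring reactions.

## Minimal growth-enabling reaction sets

For a novel environment, the gap-filling model asks for the minimum number
of universal-origin reactions whose addition yields biomass flux at least
the growth floor $10^{-4}$. `build_milp()` constructs the model exactly:
reversible candidates are split into opposing irreversible directions so
candidate fluxes are non-negative; each direction gets a binary indicator
$b_i$ with linking constraints

$$b_i\,\varepsilon \le v'_i \le b_i\,u'_i, \qquad \varepsilon = 10^{-8},$$

an anti-parallel constraint $b_{\text{fwd}} + b_{\text{rev}} \le 1$ per
split pair, and the objective $\min \sum_i b_i$. $u'_i$ defaults to the
1000-unit cap, keeping the big-M linking finite while leaving
$\varepsilon$-level activity representable.

The solver is an LP-based branch-and-bound over *merged* candidate
reactions: a candidate is open (original bounds) or closed (zero). Opening
a reversible candidate is feasibility-equivalent to the split model with
the anti-parallel constraint because a futile forward-plus-reverse
two-cycle can always be cancelled without disturbing mass balance; the
reported indicators are then read off the sign of the verifying flux, so
no pair of opposing directions is ever simultaneously active. At each node
the relaxation LP minimises $\sum v'_i / u'_i$ over undecided candidates —
a valid lower bound on additional active reactions — and infeasibility of
the relaxation prunes the subtree. Incumbents come from greedily
minimalising the relaxation's support, which on these problems is usually
optimal at the root; the search then proves optimality. Every solution is
re-verified by a plain LP with only the chosen set open and each member
forced to carry at least $\varepsilon$ flux.

Alternative optima are collected the standard way: after each solution
with indicator vector $B$, the integer cut
$\sum_{i: B_i = 1} b_i \le \sum_i B_i - 1$ forbids rediscovering it (at
the merged level: the new set must not contain any found set), and solving
repeats until the optimum exceeds the minimal size or the model becomes
infeasible — at which point the enumeration is provably exhaustive. Any
set of minimal size is automatically subset-minimal, since a working
proper subset would contradict minimality. The test suite checks the
enumeration, as a set of sets, against exhaustive FBA over all candidate
subsets on dozens of random pool problems, and checks invariance under
candidate reordering.

## Stepping stones, accessibility, exaptation

`screen_singles()` and `screen_pairs()` activate one or two universal
reactions at a time (all others closed) and test growth across the novel
environments. A beneficial pair whose member also enables growth alone
somewhere is "beneficial with combined and individual effect"; that member
is a stepping stone, because the two-reaction innovation can then be
reached by two consecutive single-reaction adaptive steps under changing
environments. By default the quadratic pair scan is restricted to
candidates that appear in an enumerated minimal set or are solo-beneficial
— a restriction that cannot lose a size-2 minimal pair, since both members
of such a pair are in an enumerated set; `exhaustive = TRUE` scans all
pairs. Note that the exhaustive scan may add pairs in which a useless
reaction rides along with a solo-beneficial one; these are genuinely
beneficial as pairs and are classified accordingly.

A two-step environment is *accessible* when at least one of its minimal
pairs contains a stepping stone (`accessibility()`). `exaptation_overlap()`
reports, per environment, the fraction of its minimal sets entirely
contained in a minimal set of a different environment — reaction sets
adaptive in one niche re-used as parts of larger sets in another — plus
the mean over environments.

## Ancestral gene content and contingency statistics

Gene presence/absence profiles map to reaction profiles through GPR rules
(`AND` = enzyme complex, all genes required; `OR` = isoenzymes, any one
suffices), parsed by a small recursive-descent parser with positioned
error messages.

`reconstruct_ancestral()` infers ancestral presence on a rooted
bifurcating tree by Sankoff parsimony with asymmetric costs, default
gain:loss = 2:1, so that acquiring a gene is penalised twice as heavily as
losing one — the usual setting for gene-content evolution dominated by
horizontal transfer and rapid loss. Presence at the root is itself charged
as one gain, as if the tree hung from a stem edge leading out of an
all-absent origin. Without that stem charge an asymmetric scheme places
presence at the root for free, which manufactures spurious ancestral
presence exactly where gains — the events under study — should be
inferred. Among minimum-cost labelings, ambiguity is resolved by delayed
transformation (DELTRAN): in the root-to-tip pass an ambiguous node adopts
its parent's state, pushing changes toward the tips; an ambiguous root
resolves to absence. The DELTRAN output is itself a minimum-cost labeling,
which the tests verify against exhaustive enumeration of all internal
labelings on hundreds of random small trees.

Every tree edge then contributes one ancestor/descendant pattern
observation for a reaction pair (A, B). The contingent-gain fraction is

$$f = \frac{p_1}{p_1 + p_2}, \qquad
  p_1 = \frac{\#(a10 \to d11)}{\#(a10 \to dXX)}, \quad
  p_2 = \frac{\#(a00 \to d01)}{\#(a00 \to dXX)},$$

the rate of B gains on edges where A is already present versus edges where
both are absent; $f = 0.5$ under independence. The co-gain fraction is
$n_1/(n_1+n_2)$ with $n_1$ the simultaneous gains of both from a
doubly-absent ancestor and $n_2$ the single gains. Fractions with zero
denominators are undefined, excluded from all tests, and counted in the
reports.

Because these fractions are heavily tied (many pairs sit at exactly 0,
0.5, or 1), `stats::wilcox.test`'s exact machinery does not apply; the
package computes exact conditional null distributions by
generating-function dynamic programming over doubled midranks — sign flips
for the one-sample signed-rank test against 0.5, subset sums for the
two-group rank-sum test — and falls back to a tie-corrected normal
approximation only beyond 200 (or 100 combined) observations. The tests
verify both against brute-force enumeration of the null and, on tie-free
data, against `stats::wilcox.test`. The co-gain randomization test breaks
the observed pairing, reshuffles the pooled members into new pairs 1000
times, and reports $(n_1+1)/1001$ where $n_1$ counts replicates whose mean
co-gain fraction reaches the observed mean; a replicate with no defined
fraction cannot reach it.

## Synthetic study systems

`make_toy_scenario()` builds the whole metabolic test bed with known
ground truth: a viable host (four elemental uptakes, a catabolic reaction
coupling carbon to ATP, biomass, ATP maintenance) and a pool containing
planted one-step nutrients (one reaction each), two-step nutrients (two
reactions, with any number of disjoint alternative routes), decoys (a dead
end, a jointly-dependent shuttle pair), and an optional energy-generating
cycle for the curation tests. With `share_stepping_stone = TRUE`, a
two-step nutrient's first route converts it into the first one-step
nutrient, so the route's second reaction alone confers growth elsewhere —
the motif of a two-reaction innovation sharing a reaction with a
single-reaction innovation. Ground truth is verified by direct FBA at
generation time: the host fails on every planted nutrient, each recorded
set restores growth, every strict subset fails. Toy metabolites are
abstract and unit-stoichiometric, so LP answers stay analytically
checkable; nothing is mass- or charge-balanced, and candidate nutrients'
exchange reactions live in the pool but are never gap-fill candidates
(exchanges are environment boundary conditions, not acquirable enzymes).

`simulate_history()` provides the phylogenetic test bed: a random
bifurcating tree with unit branch lengths (`ape::rtree`) and gene pairs
(A, B) evolved root-to-tips — per edge, an absent gene is gained with
probability `gain_p`, a present one lost with probability `loss_p`, and
B's gain probability is multiplied by `kappa` on edges whose ancestor
carries A. B always starts absent; A's root state is present with
probability `root_p`.

The defaults — `gain_p = 0.03`, `loss_p = 0.05`, `root_p = 0.55` — were
chosen once, on these grounds. Desk-scale trees (64 tips, 126 edges) carry
few events per pair, and the ratio estimator $\hat f$ is then dominated by
zero counts on whichever side of its contrast has fewer exposure edges; it
is approximately unbiased only when A-present and A-absent branches are
both well represented. Forcing an all-absent root makes A-clades small and
late, and 2:1-cost parsimony then consolidates B's repeated in-clade gains
onto the clade's top edge, where they score as co-gains instead of
contingent gains. A near-ignorance root prior for A with slow gain and
somewhat faster loss yields presence mosaics on the tree that avoid both
pathologies. Under these defaults, at 64 tips with one independent tree
per pair, the full stack (simulate → reconstruct → tally → test) is
calibrated at `kappa = 1` (mean $\hat f$ within two standard errors of
0.5 over 200 trees) and detects `kappa = 5` contingency by the one-tailed
signed-rank test at 100 pairs. Independent trees per pair matter: a single
shared tree correlates all pairs through tree-shape luck and invalidates
the test's independence assumption.

Two caveats the synthetic systems make explicit. First, per-pair fractions
at this scale are discrete (mostly 0, values in (0.5, 1), or 1), so the
`kappa = 5` detection retains a small per-seed failure probability —
roughly one run in ten at the default conditions; significance is a
stochastic property of a 100-pair sample, not a deterministic one. Second,
power is *not* monotone in `kappa` after reconstruction: once
`kappa * gain_p` approaches saturation, B fills A-clades so quickly that
parsimony merges its gains with A's, and the contingent signal degrades
rather than grows. Tallies on the true simulated states, by contrast,
increase with `kappa` throughout, which the tests also check.

What the toys do not emulate: real stoichiometry, compartments and
transporters, graded fitness effects (growth is binarised), operon-level
co-transfer of neighbouring genes, tree-shape realism (no birth–death
calibration), and the scale of genome-wide profiles. Passing tests
demonstrate correctness of the algorithms and calibration of the
statistics on known ground truth — not that any particular biological
dataset will show these effects.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run: ~55 random gap-fill pools
of 8–30 candidates against exhaustive subset search; 200 random ≤8-tip
trees against exhaustive parsimony labelings; 200 (`kappa = 1`) plus 100
(`kappa = 5`) simulated 64-tip trees through the full contingency stack;
and one 1000-replicate co-gain randomization. These sizes keep every
answer independently verifiable by brute force while exercising all code
paths.

## Known limitations

* The simplex re-factorises the basis each iteration — appropriate for
  networks with tens of reactions, not thousands. Real genome-scale use
  would swap in an industrial LP/MILP solver behind the same interfaces.
* Branch-and-bound cost grows with minimal-set size; the package targets
  the 1–3-reaction regime that dominates the stepwise-expansion analysis.
* Weighted gap-filling, thermodynamic/loopless FBA, parsimonious FBA and
  gene-deletion analysis are out of scope.
* Maximum-parsimony ancestral states are point estimates; no uncertainty
  is propagated into the contingency statistics beyond the undefined-
  fraction exclusions.
* Polytomous trees are rejected rather than resolved; callers must
  resolve multifurcations first.
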