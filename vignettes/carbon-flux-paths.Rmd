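---
title: "Carbon flux paths: path finding under steady-state stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon flux paths: path finding under steady-state stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metabolite graphs make path finding in metabolism cheap: nodes are
metabolites, and a reaction contributes an arc from each of its substrates to
each of its products. But two well-known failure modes make naive shortest
paths biochemically meaningless:

1. **Spurious arcs.** In a phosphotransferase reaction such as
   `D-Glc + PEP -> G6P + Pyr`, the graph gains arcs `D-Glc -> Pyr` and
   `PEP -> G6P`, although no carbon atom travels along them. Currency
   metabolites (ATP, NADH, CoA) stitch the whole network together this way.
2. **Paths that cannot carry flux.** A path is a static object; metabolism
   runs in steady state. A route can exist in the graph while no non-negative
   flux distribution of the whole network can sustain it — the classical
   example being the conversion of fatty acids to sugars, which is possible
   if and only if the glyoxylate shunt is available, a fact invisible to any
   purely graph-based method.

`cfpath` implements *carbon flux paths* (CFPs): simple directed paths in a
metabolite graph restricted to arcs with effective carbon exchange, with the
additional requirement that the whole network admits a steady-state flux
distribution in which every step of the path is catalysed by an active
reaction. Both requirements are imposed jointly, as one mixed-integer linear
program (MILP).

## The model

Let $S_{cr}$ be the stoichiometric coefficient of metabolite $c$ in reaction
$r$ (negative for substrates, positive for products). Reversible reactions
are split into two irreversible directions (`<id>__fwd`, `<id>__rev`), so all
fluxes are non-negative; the set $B$ collects the resulting reverse pairs.
The binary data $d_{ijr}$ record whether reaction $r$ exchanges carbon
effectively from input $i$ to output $j$; only pairs with $d_{ijr}=1$ for
some $r$ become arcs.

Decision variables: $u_{ij}\in\{0,1\}$ (arc used by the path),
$z_r\in\{0,1\}$ (reaction active), $v_r\in[0,M]$ (flux). For a query from
source $\alpha$ to target $\beta$:

* **degree constraints** — exactly one arc leaves $\alpha$ and one enters
  $\beta$; no arc enters $\alpha$ or leaves $\beta$;
* **flow conservation** — at every other node, arcs in equal arcs out, and
  every node is entered at most once (simple path);
* **steady state** — $\sum_r S_{cr} v_r = 0$ for every internal metabolite
  $c$; external metabolites outside the growth medium $E_m$ satisfy
  $\sum_r S_{cr} v_r \ge 0$ (they may be produced, never net consumed);
  medium metabolites are unconstrained;
* **activity coupling** — $z_r \le v_r \le M z_r$: active reactions carry a
  flux between 1 (the scaled minimum) and $M$; inactive ones none;
* **reverse-pair exclusion** — $z_\lambda + z_\mu \le 1$ for
  $(\lambda,\mu)\in B$, so a split reaction never runs in both directions;
* **arc support** — $u_{ij} \le \sum_{r:\,d_{ijr}=1} z_r$: every arc the
  path uses must be carried by at least one active reaction. This is the
  constraint that welds the combinatorial path to the flux plane; note that
  it deliberately allows reactions to be active *off* the path, which is how
  the rest of the network balances the path's intermediates.

The objective minimises $\sum u_{ij}$ (path length), or
$\sum_j w_j u_{ij}$ for the weighted baseline strategy. Enumeration of the
$K$ shortest CFPs adds, after each solution with arc set $P_k$, the integer
cut $\sum_{(i,j)\in P_k} u_{ij} \le |P_k| - 1$. The cut also forbids strict
supersets of an enumerated arc set, which is desirable: a solution consisting
of a path plus a disjoint cycle is never reported (such a configuration is
strictly longer than the path alone, and the plain path is always feasible
whenever the composite is).

### Objective tie-handling and parsimony

Two numerical choices are worth stating explicitly:

* Among equal-length CFPs the order of enumeration is solver-dependent and
  declared unspecified; every comparison in the test suite therefore groups
  arc sets by length instead of relying on positions within a length class.
* The objective carries a tiny secondary term $\varepsilon \sum_r z_r$ with
  $\varepsilon \le 0.25/R$. It makes the reported supporting flux
  distribution parsimonious (no gratuitously active reactions) and can never
  trade against a single arc of path length, since $\varepsilon R < 1$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `big_M` | 1000 | flux upper bound; with the minimum non-zero flux scaled to 1, any steady state needing a flux ratio above `big_M`:1 becomes infeasible. Raise it for badly scaled networks; on all packaged fixtures, scaling it by 10 does not change any returned arc set (asserted in the tests). |
| `min_flux` | 1 | the scaled minimum non-zero flux |
| `flux_tolerance` | 1e-6 | verifier tolerance, chosen to sit above the backend's feasibility tolerance (~1e-7) |
| `int_tolerance` | 1e-6 | threshold for reading binaries from solver output |
| `time_limit_seconds` | none | per-solve wall clock; a limit hit is a distinct `"limit"` status and is *never* reported as "no path exists" |

Stoichiometric coefficients are stored as doubles and sign tests use a 1e-9
tolerance; stoichiometries in practice are small rationals, so this is far
below any meaningful coefficient.

## Solver backend

The formulation is expressed against a minimal facade (variables, linear
constraints, minimise, statuses `optimal` / `infeasible` / `unbounded` /
`limit`). The bundled backend serialises problems to JSON and solves them
with the HiGHS branch-and-bound engine via `scipy.optimize.milp` in a Python
subprocess; independent problems (connectivity queries, the oracle's LPs) are
batched into a single call. The backend is single-threaded and
deterministic, so repeated runs on the same inputs produce identical files;
the `random_seed` configuration field is accepted for interface
compatibility but has no effect.

## The independent oracle

Because the MILP couples path finding and flux feasibility, the test suite
needs ground truth computed another way. The brute-force oracle enumerates
*all* simple paths by depth-first search, then decides supportability per
path: for each choice of one supporting reaction per arc it solves a linear
feasibility problem (balances, medium bounds, chosen reactions forced to the
minimum flux, their reverse partners shut off). A feasible LP solution is
lifted to an integral certificate by cancelling reverse pairs (a reaction
and its reverse have exactly opposite columns, so subtracting the common
part preserves every balance) and rescaling so all non-zero fluxes lie in
$[1, M]$. In the rare case the lifting fails, the oracle falls back to a
MILP with the path's arcs pinned, so its verdict is always exact. The
enumeration route (DFS + per-path feasibility) shares no logic with the
integer-cut route it validates.

On twenty seeded random networks the full enumeration and the oracle return
identical families of arc sets — this is the strongest correctness check in
the package and is recomputed by `scripts/acceptance.R` on every run.

## What the fixtures emulate — and what they do not

* `toy_network()` is the minimal network in which path finding and
  stoichiometry visibly interact: one route from A to F whose balancing
  needs three off-path reactions, and a medium knock-out (removing the D
  source) that kills the flux path while leaving the graph path intact. Its
  drawn original is not machine readable; the reconstruction uses unit
  coefficients, the minimal choice consistent with every stated property.
* `glyoxylate_network()` reconstructs the fatty-acid-to-sugar question with
  textbook stoichiometries: the TCA cycle, anaplerosis, lumped
  gluconeogenesis, and optionally the glyoxylate shunt. Cofactors are
  internal and balanced; respiration is lumped into two oxidases consuming
  external O2 (so removing O2 from the medium silences succinate
  dehydrogenase through CoQ/CoQH2 imbalance); adenylate energetics are
  lumped into a reversible ATP/ADP+Pi interconversion; water and protons are
  omitted. AcCoA-to-G6P is supportable exactly when the shunt is present.
* `acetylation_shortcut_network()` isolates the reversibility pathology: a
  reversible group transfer whose forward and backward directions together
  form a meaningless two-step shortcut.
* `random_network(seed)` generates small connected instances: a linear
  backbone (guaranteeing one supportable route), import/export reactions,
  and random extra reactions — some creating supportable shortcuts, some
  not. Sizes stay at or below 12 graph nodes so the exponential oracle
  remains viable; the suite uses seeds 1–20 at those sizes.

What passing these tests does *not* show: behaviour at genome scale.
Genome-scale models bring compartments, thousands of reactions, curated
carbon-exchange tables and currency-metabolite structure that the fixtures
do not emulate; published genome-scale recovery percentages and connectivity
counts depend on a specific external model and curated arc list that are not
bundled, and are therefore out of scope here. The file formats and the whole
pipeline (model JSON/SBML, carbon TSV, medium, reference pathways, recovery
tables, curves) are the supported path to such data.

## Carbon tables: curated versus inferred

The package takes a curated arc table verbatim (it does not second-guess
decisions such as keeping or dropping cofactor pairs). When none exists,
`infer_carbon_arcs_from_formulas()` emits every input/output pair in which
both metabolites contain carbon. This over-approximates true atom transfer —
hexokinase yields spurious `D-Glc -> ADP` and `ATP -> G6P` pairs — so the
result is flagged `"heuristic"` and every curated table is, by construction,
a subgraph of it. Atom-level mapping from source to target is explicitly not
attempted: the guarantee is effective carbon exchange at every *step*, not
carbon transfer end to end.

## Degenerate inputs and edge behaviour

* Self-pairs in the carbon table cannot validate (a metabolite cannot have
  both signs in one reaction), and self-arcs are dropped at graph build; a
  simple path could never use them.
* Source and target may be external metabolites; no constraint beyond the
  degree conditions applies to endpoints.
* An empty carbon table yields a graph with all nodes and no arcs; every
  query on it is infeasible rather than an error.
* `infeasible` and `limit` are distinct solver outcomes everywhere,
  including inside connectivity curves, where a timed-out target is excluded
  from the curve entirely rather than counted unreachable.

## Design choices made here

Where the underlying formulation left genuine choices, this package decided:

* **"Fully matches"** in recovery scoring means exact equality of arc lists
  (the strictest reading, consistent with recovery being binary); accuracy
  is fractional overlap over the *reference's* arcs, a declared choice since
  competing definitions are not fully specified in the literature.
* **Solutions are identified by their u-arc set.** Two steady-state
  distributions supporting the same path are the same CFP; the enumeration
  cut operates on arcs only.
* **Split-id convention** `<id>__fwd` / `<id>__rev` makes the reverse-pair
  set reconstructible from ids alone, and lets one curated carbon table
  written against unsplit ids serve the split model
  (`align_carbon_table()` swaps input/output for the reverse copy).
* **Connectivity curves count external metabolites** as reachable targets —
  reachability is a property of the graph/flux system, not of the boundary.
* **Per-target connectivity queries are independent** and solved as one
  batch; execution order cannot affect results.

## Problem sizes used by the tests

The suite solves the toy (9 metabolites), the shortcut fixture (12), the
glyoxylate reconstruction (28), and random networks with 9 internal
metabolites and 16 reactions before splitting; enumeration runs to
exhaustion (at most 50 paths requested, observed counts are below 20).
These sizes keep the brute-force oracle exact and the full suite fast while
exercising every constraint family; the MILP itself has no such size
restriction.

## Known limitations

* Steady-state supportability is a *global network* property; the package
  guarantees a supporting flux distribution exists, not that it is unique or
  biologically realised.
* Carbon exchange is enforced stepwise, not end to end (no atom tracing).
* The heuristic carbon table over-connects; use curated tables when
  available.
* `big_M` trades numerical safety against the representable dynamic range of
  fluxes; extreme stoichiometric ratios may require raising it.

## A worked example

```{r, eval = FALSE}
library(cfpath)

b <- toy_network()
res <- find_carbon_flux_paths(b$network, b$carbon, b$medium,
                              source = "A", target = "F", k = 5)
tidy(res)
#> # A tibble: 1 × 5
#>       k length node_sequence n_active active_reactions
#>   <int>  <int> <chr>            <int> <chr>
#> 1     1      4 A->B->C->E->F        7 r1,r2,r3,r4,r5,r6,r7

# the same path is impossible once the D source leaves the medium
find_carbon_flux_paths(b$network, b$carbon, medium("A_ext", b$network),
                       "A", "F", k = 5) |> glance()
#> # A tibble: 1 × 8
#>   source target k_requested n_paths exhausted min_length max_length
#>   <chr>  <chr>        <int>   <int> <lgl>          <int>      <int>
#> 1 A      F                5       0 TRUE              NA         NA
#>   use_stoichiometry
#>   <lgl>
#> 1 TRUE
```
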