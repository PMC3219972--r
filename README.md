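# cfpath — carbon flux paths in metabolic networks

`cfpath` finds **carbon flux paths (CFPs)**: simple directed paths between
two metabolites of a stoichiometric metabolic network that (a) carry
effective carbon exchange at every step and (b) can operate inside a
steady-state flux distribution of the whole network. It is aimed at anyone
doing path-based analysis of metabolism — pathway recovery, reachability /
connectivity studies, interpretation of omics hits — who needs paths that
are flux-consistent rather than merely present in a graph.

Plain path finding on metabolite graphs fails in two characteristic ways:
spurious arcs through currency metabolites (in `D-Glc + PEP -> G6P + Pyr`
nothing carbon-wise travels `D-Glc -> Pyr`), and routes that exist in the
graph but cannot be sustained by any steady-state flux (the classical
fatty-acids-to-sugar question, answered by the glyoxylate shunt). CFPs fix
both at once.

## The model

With stoichiometric coefficients `S[c,r]` (inputs negative, outputs
positive), reversible reactions split into irreversible pairs `B`, and
carbon-exchange indicators `d[i,j,r]`, a query from α to β is the MILP

* binaries `u[i,j]` (arc used), `z[r]` (reaction active), continuous
  `v[r] ∈ [0, M]` (flux);
* degree constraints: one arc leaves α, one enters β, none enter α or leave
  β; flow conservation and in-degree ≤ 1 at every other node (simple path);
* steady state: `Σ_r S[c,r] v[r] = 0` for internal `c`;
  `Σ_r S[c,r] v[r] ≥ 0` for external `c` outside the growth medium `E_m`;
* activity coupling: `z[r] ≤ v[r] ≤ M z[r]` (active flux lies in `[1, M]`);
* reverse exclusion: `z[λ] + z[μ] ≤ 1` for `(λ,μ) ∈ B`;
* arc support: `u[i,j] ≤ Σ_{r : d[i,j,r]=1} z[r]` — the constraint linking
  the path to the flux plane;
* objective: minimise `Σ u[i,j]` (or node-weighted arcs for the
  "connectivity" baseline). K-shortest enumeration adds one integer cut
  `Σ_{(i,j)∈P_k} u[i,j] ≤ |P_k| − 1` per found path `P_k`.

Solved with HiGHS (via `scipy.optimize.milp` in a Python subprocess) behind
a small solver facade; runs are deterministic.

## A worked example

```r
library(cfpath)

b <- toy_network()          # 9 metabolites, 7 reactions, one route A -> F
res <- find_carbon_flux_paths(b$network, b$carbon, b$medium,
                              source = "A", target = "F", k = 5)
tidy(res)
#> # A tibble: 1 × 5
#>       k length node_sequence n_active active_reactions    
#>   <int>  <int> <chr>            <int> <chr>               
#> 1     1      4 A->B->C->E->F        7 r1,r2,r3,r4,r5,r6,r7
```

One CFP exists (enumeration stops exhausted after it): `A->B->C->E->F`, four
arcs. All seven reactions are active although only four carry the path —
the off-path reactions `r1`, `r6`, `r7` supply A, supply D and drain F, which
is exactly what steady state demands. Drop the D source from the medium and
the graph path survives but the flux path disappears:

```r
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

The same machinery answers the fatty-acid question on the packaged
central-carbon reconstruction: `glyoxylate_network(TRUE)` admits CFPs from
AcCoA to G6P, `glyoxylate_network(FALSE)` admits none — although six
graph-level paths still exist.

Beyond queries, the package provides recovery/accuracy scoring against
reference pathways (`recovery_rate()`, `stoichiometric_recovery_rate()`,
`accuracy_rate()`), connectivity curves with and without stoichiometry
(`connectivity_curve()`, with `autoplot()`), arc/metabolite frequency tables
over K solutions (`frequency_table()`, DOT export), baseline strategies
(`apply_strategy()`: topology / hubs / connectivity-weighted), SBML and JSON
model IO, a carbon-arc TSV format with a formula-based heuristic fallback,
and a CLI (`cli_main()`, `inst/scripts/cfpath`) with `find`, `connectivity`,
`validate` and `fixtures` subcommands.

## Scope notes

Published genome-scale results for this method (recovery percentages on 40
reference pathways, 834/1028-metabolite connectivity totals) require an
external genome-scale model and a hand-curated carbon-exchange arc list that
are not bundled; the formats and the full pipeline for such data are. Atom
tracing from source to target is out of scope by design: carbon exchange is
guaranteed stepwise, not end to end.
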