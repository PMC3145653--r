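# thfates

Simulation of reciprocal TH17 / induced-regulatory-T-cell (iTreg)
differentiation with sigmoidal gene-network ODEs.

## The scientific problem

Naive CD4+ T cells stimulated with TGF-β can commit to either of two
opposed lineages — pro-inflammatory TH17 cells (master regulator RORγt)
or anti-inflammatory iTreg cells (master regulator Foxp3) — and, puzzlingly,
a *single* TGF-β dose drives a clonal population into a *mixture* of
RORγt-only, Foxp3-only and double-expressing cells. `thfates` implements a
dynamical-systems explanation: a small regulatory circuit (mutual
antagonism plus auto-activation of the two master regulators) whose
steady states pass through sub-critical pitchfork bifurcations as TGF-β
rises, so that small cell-to-cell parameter variability scatters cells
across coexisting basins of attraction. Polarizing signals (IL-6 via
STAT3, all-trans retinoic acid) bias the outcome and can reprogram
committed cells.

## The model

Every species (protein activity, dimensionless, in `[0, 1]`) relaxes
toward a logistic function of its net regulatory input:

    dX_i/dt = γ_i [ F(σ_i W_i) − X_i ],
    W_i     = β_i + Σ_j ω_ij X_j + Σ_k ω_ik s_k,
    F(u)    = 1 / (1 + e^(−u))

with relaxation rate `γ_i` (1/time unit, one time unit ≈ 1 h), sigmoid
steepness `σ_i`, basal activation state `β_i`, interaction weights `ω_ij`
and external signal concentrations `s_k` (TGF-β, IL-6, ATRA). Three
networks ship with their published basal parameters:

| id | species | description |
|---|---|---|
| `symmetric` | RORγt, Foxp3 | perfectly symmetric two-gene switch, TGF-β acts directly |
| `symmetric_intermediates` | + UI, Smad | TGF-β routed through saturating transducers |
| `asymmetric` | + IL-17, STAT3 | broken symmetry, IL-6 and ATRA inputs, IL-17 readout |

Cell-to-cell variability: each kinetic parameter of a cell is drawn from
`Normal(basal, 0.05 · |basal|)` (CV = 5%); signal concentrations are
experiment inputs and are never sampled. A protein is "expressed" when its
activity exceeds 0.5.

## Worked example

```r
library(thfates)
m <- th_model("symmetric")

# the average cell is tristable at TGF-beta = 0.5
find_steady_states(m, c(TGFb = 0.5))
#> <steady_states> 5 found (3 stable) at signals: TGFb=0.5
#>    RORgt  Foxp3 stability  phenotype
#> 1 0.0739 0.9934    stable foxp3_only
#> 2 0.4410 0.9856  unstable foxp3_only
#> 3 0.9526 0.9526    stable     double
#> 4 0.9856 0.4410  unstable   ror_only
#> 5 0.9934 0.0739    stable   ror_only

# bifurcation structure of the average cell vs TGF-beta
br <- continue_branches(m, range = c(0, 1), step = 0.005)
branch_onsets(br, m)
#>    pitchfork double_onset
#>    0.2675781    0.3657031

# heterogeneous 1000-cell population: all three differentiated fates
# coexist near TGF-beta = 0.5
sr <- signal_response(m, c(0.2, 0.5), n_cells = 1000, seed = 1)
sr[, c("TGFb", "frac_naive", "frac_ror_only", "frac_foxp3_only",
       "frac_double")]
#>   TGFb frac_naive frac_ror_only frac_foxp3_only frac_double
#> 1  0.2      0.802        0.0941           0.104       0.000
#> 2  0.5      0.000        0.2590           0.277       0.464
```

The pitchfork at TGF-β ≈ 0.27 is where the naive low/low state
destabilizes into the two single-positive lineage branches; a stable
double-expressing ("re-stabilized co-expressing") state appears at ≈ 0.37
and becomes the plurality phenotype of an induced population above
TGF-β ≈ 0.5.

Reprogramming (asymmetric model): induce with TGF-β = 0.28, add IL-6 = 10
at t = 80 — Foxp3-expressing cells collapse and an IL-17-producing
subpopulation appears, unless ATRA = 1.5 was present at induction:

```r
mc <- th_model("asymmetric")
rp <- reprogram(mc, n_cells = 500, seed = 3)          # no ATRA
rp[rp$time %in% c(78, 250), c("time", "frac_foxp3_expr", "frac_il17")]
#>    time frac_foxp3_expr frac_il17
#> 40   78           0.192      0.00
#> 126 250           0.000      0.43
```

## Command line

```sh
inst/cli/thfates steady-states --model symmetric --tgfb 0.5 --out out/
inst/cli/thfates bifurcation   --model symmetric --range 0:1 --out out/
inst/cli/thfates signal-response --model asymmetric --n-cells 1000 \
    --tgfb 0:1:0.025 --seed 1 --out out/
```

Outputs are headered CSV tables plus a JSON run manifest; runs with a
fixed seed are byte-identical.

## See also

The methods vignette (`vignettes/methods.Rmd`) documents the model
assumptions, numerical choices, the population-sampling scheme, and known
limitations.
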