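---
title: "Modelling the lifecycle of sociocultural groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the lifecycle of sociocultural groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grouplife)
```

## The model

`grouplife` simulates the demography and territorial dynamics of human
sociocultural groups — bands, tribes, polities, religious communities — as
an ecology of *cells* on a square lattice of habitable patches. A cell is
the population occupying one patch; a *group* is a set of cells sharing an
identity. Small-scale groups (single-celled groups, SCGs) hold exactly one
patch. Large-scale, structured groups (multicellular groups, MCGs) hold two
or more, and are born only one way: by the fusion of several adjacent,
near-capacity SCGs on productive land. The analogy is with the evolution of
multicellularity — autonomous cells giving up independence to form a larger
organism that is harder to attack and can keep growing.

Each patch has one of two productivity classes, which fixes its carrying
capacity $K$ and yearly growth rate $r$:

| parameter | default | meaning |
|---|---|---|
| $K_H$, $K_L$ | 100, 50 persons | carrying capacity of high/low-productivity patches |
| $r_H$, $r_L$ | 0.03, 0.01 /yr | growth rate on high/low-productivity patches |
| LP:HP ratio | 1:1 | share of low- vs high-productivity patches |
| lattice | 33 × 33 | absorbing edges, von Neumann neighbourhoods |
| founding SCGs | 10 blue + 10 red | placed uniformly on HP resp. LP patches |
| initial population | 30 persons | per founding SCG |
| $c$ | 0.001 | weight of population size in war propensity |
| $c_1$ | 1 | attrition cost constant |
| fusion threshold $T$ | 4 | minimum number of blue SCGs that fuse |
| capacity fraction | 90% | fusion eligibility, strict inequality |
| decisions per year | 20 | cells sampled for an action each year |
| horizon | 600 years | default run length |
| replicates | 15 | default ensemble size |

A group's aggression level ("redness") is set by the land it holds: an SCG
on a low-productivity patch is *red* (redness 1, a warrior group, since
resource shortage drives conflict), an SCG on a high-productivity patch is
*blue* (redness 0, peaceful). An MCG's redness is the unweighted mean of
its member cells' rednesses — deliberately not population-weighted, so that
holding many poor border patches makes a group warlike even if most of its
people live on rich land.

## The yearly cycle

Each simulated year:

1. **Growth.** Every cell with $N \le K$ grows to $N(1+r)$. Growth is
   capacity-gated, not logistic: a cell at $K$ still grows once, overshoots
   by a single multiplicative step, and then freezes. The overshoot is what
   arms expansion — a frozen cell strictly above $K$ is the only kind that
   acts.
2. **Decisions.** 20 cells are sampled uniformly *without replacement*
   (all cells, in random order, if fewer exist). Each sampled cell at or
   below capacity stays static. An over-capacity cell picks one neighbour
   patch uniformly: empty → it **buds**; held by a foreign group → it
   attacks with probability $p_{war}$, else stays static; held by its own
   group → static. Cells created mid-year (buds, captured patches) do not
   act that year, and a slot whose cell has been destroyed by an earlier
   war is skipped.
3. **Fusion check**, once after *every* decision: if at least $T$ blue
   SCGs sit strictly above 90% of capacity, one of them is drawn uniformly
   as a reference; if at least $T-1$ of its four neighbour patches hold
   eligible blue SCGs, the reference and *all* its adjacent eligible
   neighbours merge into a brand-new MCG with a fresh identity marker.
   Member cells keep their patches and populations, so fusion conserves
   both exactly.

## Warfare and expansion kernels

*War propensity.* $p_{war} = \min(1,\; \text{redness} + c \cdot N_{group})$.
At the default $c = 0.001$ population barely matters for peaceful groups (a
blue group of 100 attacks with probability 0.1), red groups always fight,
and any large MCG is effectively always willing.

*Victory.* The linear (Lanchester) law on whole-group populations:
$p_A = N_A / (N_A + N_B)$. Victory odds are proportional to numbers, which
is the classical assumption for pre-modern massed combat; a squared law
(more appropriate for modern warfare) would accelerate dominance and is
deliberately not the default.

*Stakes.* If the attacker wins, the defender's engaged cell is annihilated
and the attacker colonises the captured patch with half of its engaged
cell's population (an MCG annexes the patch; an SCG founds a new
independent SCG of its lineage, exactly as in budding). If the defender
wins, the attacking cell is annihilated and no territory changes hands.

*Attrition.* The losing group additionally loses
$\Delta N = c_1 \cdot p_{winner} \cdot N_{winner}$ persons, removed
proportionally across its remaining cells; any cell driven below one
person disappears, and a group losing its last cell is extinct. The
attrition base is the winning *group's* population: casualties scale with
the size of the force inflicting them. This is a deliberate design choice
over the smaller alternative (the winning cell's population alone): with
cell-level attrition a war can never cost the loser more than one patch
plus a few stragglers, whole-landscape dominance never materialises within
a few thousand years, and the collapse of a large group's territory in a
single catastrophic defeat — the signature event of the late phase of
these simulations — cannot occur at all. With group-level attrition a war
between two large MCGs strips the loser of a sizeable fraction of its
cells at once, which is precisely what lets the MCG count fall and a
single group eventually dominate. For fights among SCGs the two readings
coincide (a one-cell group *is* its engaged cell).

*Budding.* A 50/50 split: the parent keeps half, the daughter takes half.
The even split is the least-committal choice; a fixed-size seeding variant
was considered and rejected as it introduces a second arbitrary constant.
A daughter of an SCG is a new independent SCG inheriting the parent's
heritable marker and coloured by its own patch (blue lineages turn red on
poor land); a daughter of an MCG joins the MCG.

## What the generator emulates — and what it does not

All inputs are generated internally; the landscape generator and the
initial placement *are* the study conditions. The generator reproduces:
two-class productivity with exact LP:HP quotas (half-up rounding, LP takes
the remainder); random layouts, or aggregated ones built from
non-overlapping 3×3 / 7×7 / 9×9 blocks of productive land (residual HP
patches attach to an existing block, so every HP patch lies in a
4-connected cluster of at least 9/49/81); and uniform placement of the 20
founding SCGs on their respective patch classes.

It does *not* emulate continuous productivity gradients, resource
depletion, internal group politics (scalar stress, fragmentation, identity
mutation), or migration within a group. Passing tests therefore say
nothing about those processes; they validate the lifecycle mechanics —
growth, budding, warfare, fusion, extinction — under stylised resource
geography.

## Numerical choices

* **Populations are real-valued.** Integer truncation would distort the
  slow growth regimes (at $r = 0.005$ a 30-person cell gains 0.15
  persons/year); the one-person cull after attrition is the only place a
  discreteness threshold enters.
* **Determinism.** A run is fully determined by `(params, seed)`. Replicate
  $i$ of an ensemble uses `base_seed + i - 1`; experiment variants offset
  base seeds by 1000 so streams never collide.
* **Degenerate inputs.** Zero growth below capacity is a fixed point (no
  cell ever crosses $K$, so no budding, war or fusion — verified in the
  test suite); zero decision slots reduce the model to pure capacity-gated
  growth; a war between two empty groups is a state error, not a coin
  flip; equal-population wars need no tie-break because the winner is a
  Bernoulli(½) draw.
* **Identity bookkeeping.** Registry keys (unique, never reused) identify
  groups; the heritable marker is a separate lineage label that budding
  copies and fusion mints fresh from a monotone counter. An MCG split into
  disconnected fragments by war remains one group, and one whittled down
  to a single cell keeps its MCG status — identity persists, only
  extinction ends it.
* **Census convention.** The census records the state at the *start* of
  each year (row one is the founding state), so a 600-year run yields
  exactly 600 census rows; the end state is kept as the result's final
  world. MCG size histograms use fixed bins 2–10, 11–20, …, 91–100,
  101–200, …, 401–500, >500; single-cell MCG remnants are counted in the
  smallest bin so counts always total the number of living MCGs.

## Problem sizes used in the tests

The unit suite runs on small lattices and short horizons built in code.
The acceptance-level checks use the full study conditions: 15-replicate
ensembles over 600 years for the threshold (T = 4, 3, 2), patch-ratio
(1:1, 3:1, 1:3) and slow-growth experiments, and a single 2500-year run
for long-horizon dominance — long enough for the "given enough time, one
group dominates the majority of the landscape" regime, which is often
still unsettled at 1660 years in this implementation.

## Known limitations

The war-propensity, victory and attrition kernels are minimal forms chosen
for behavioural plausibility; absolute event rates are sensitive to them
even where qualitative orderings are robust. In particular, this
implementation forms multicellular groups more freely than the historical
calibration it is patterned on: cumulative MCG births over 600 years run
high, and as a consequence the group-size distribution at year 600 still
carries substantial mid-size (51–100 cell) mass rather than the clean
U-shape of many small and a few very large groups with a scarce middle.
The fusion
rate is governed jointly by the per-decision fusion check, reference
selection among eligible groups, and the adjacency quorum; all three are
isolated behind the `fusion` module so alternative schemes can be swapped
in without touching the rest of the engine.

## A worked run

```{r example}
res <- run_simulation(sim_params(years = 300, seed = 1))
res
tail(res$census, 3)
first_mcg_emergence_year(res)
```

```{r ensemble, eval = FALSE}
# The threshold sensitivity analysis (minutes of compute):
ens <- run_experiment("threshold", n_reps = 15, base_seed = 1)
sapply(ens, function(e) ensemble_summary(e)$mcgs_formed$mean)
```
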