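---
title: "Coupling-driven gap analysis: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling-driven gap analysis: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgap)
```

## The idea

A genome-scale metabolic reconstruction constrains steady-state fluxes to
the polytope $\{v : Sv = 0,\ lb \le v \le ub\}$, where $S$ is the
stoichiometric matrix.  Two reactions are **fully coupled** when their
fluxes keep a fixed ratio $\lambda$ in every feasible state — structurally
obligate partners.  Genes encoding such partners are expected to be
co-expressed.  When a pair of reactions is predicted fully coupled but the
genes behind them are essentially uncorrelated across many expression
conditions, the more plausible explanation is that the reconstruction is
missing a reaction (or a transport route, or a wrongly fixed
irreversibility) that would give the network an alternative way to route
flux around one of the two reactions.  `fluxgap` turns that reasoning into
an optimization problem: find the smallest set of network modifications
that breaks the maximum number of these suspect couplings while leaving
well-supported couplings intact.

## Stage 1 — finding the inconsistencies

**Preprocessing.** The biomass reaction is removed before coupling
analysis: a common sink couples a large fraction of the network trivially.
Every metabolite the biomass consumed that cannot already leave the system
receives its own irreversible export, so precursors drain independently
(`preprocessBiomass`).

**Flux coupling** (`couplingTable`) is classified by linear-programming
probes.  Blocked reactions (zero flux in every feasible state) are removed
first.  For a pair $(i, j)$: if fixing $v_j = 0$ forces $v_i = 0$ and vice
versa, the pair is a candidate for full coupling; the ratio probe fixes
$v_j$ at half its maximum (and, for reactions that can run backward, half
its minimum) and brackets $v_i$.  Equal minimum and maximum means a
constant ratio, recorded signed — antiparallel reversible pairs get
$\lambda < 0$.  Mutual forcing without a constant ratio is recorded as
partial coupling; it is detected but unused downstream.  Coupling is
computed on the preprocessed network with its *original* reversibilities:
the irreversibility relaxation explored by the repair stage is a candidate
modification, not a property of the network being diagnosed.

**Gene coupling** (`geneCouplingGraph`) lifts coupling to genes through
the gene-protein-reaction (GPR) rules.  Deleting gene $g_1$ zeroes the
bounds of every reaction whose rule evaluates false without it; gene $g_2$
is *coupled to* $g_1$ if that deletion inactivates every unblocked reaction
mentioning $g_2$.  Only mutually coupled (fully coupled) gene pairs are
informative: they exclude genes with independent side functions (a gene
serving a second pathway survives its partner's deletion) and genes behind
OR-redundancy (an isozyme's deletion inactivates nothing).  A reaction is
"associated" with a gene when the gene appears anywhere in its rule, even
inside an OR — the conservative syntactic reading.

**The sets L and H** (`buildInconsistency`).  For each fully coupled gene
pair with a defined Pearson correlation, every fully coupled reaction pair
linking the two genes enters $L$ when $|r| < 0.2$ (inconsistencies to
resolve) or $H$ when $|r| > 0.8$ (couplings to preserve); the band between
the thresholds is deliberately uncommitted.  Absolute correlation is used
throughout: strong negative co-expression is still evidence of
co-regulation.  A reaction pair reachable from two gene pairs with
conflicting labels is excluded from both sets and reported — committing it
either way would be arbitrary.  Undefined correlations (zero variance,
fewer than three shared conditions) never enter either set.

The thresholds 0.2/0.8 are the package defaults and are exposed as
arguments; they are dimensionless correlation cutoffs and the analysis is
monotone in them (lowering `low` can only shrink $L$, raising `high` can
only shrink $H$).

## Stage 2 — the two-step repair program

The repair is a mixed-integer linear program over the network augmented
with a **universal candidate set**: either database-derived reactions
(mode `"kegg"`; same-metabolite-on-both-sides reactions and canonical
duplicates filtered out, reactions already in the model dropped) or
exchange reactions for every metabolite lacking one (mode `"exchange"`).
Reversible candidates are split into two irreversible forward columns so
candidate fluxes $y$ stay nonnegative, which is what makes "candidate $l$
is used" equivalent to $y_l > 0$.  Candidate-only metabolites are admitted
and receive their own steady-state rows — mass balance is imposed on *all*
metabolites, so a candidate chain must be fully connected to carry flux.

**Step 1** maximizes the number of resolved inconsistencies: find a single
witness flux vector $(v, y)$ with $Sv + Uy = 0$ such that as many $L$
pairs as possible deviate from their coupling ratio,
$|u_i - \lambda_i w_i| \ge \varepsilon$, while every $H$ pair satisfies
$p_j = \mu_j q_j$ exactly.  The deviation disjunction is linearized with
indicator binaries $e_i$ (positive deviation) and $f_i$ (negative
deviation) under a big-M bound, with $e_i + f_i \le 1$ and
$d_i \le e_i + f_i$; $d_i = 1$ marks the pair resolved.  In kegg mode
every model reaction is temporarily given a negative lower bound, so
reversibility relaxation is explored as a repair.  The margin
$\varepsilon = 10^{-6}$ separates a genuinely broken ratio from solver
noise; the big-M for pair $i$ is scaled as $(1 + |\lambda_i|) \cdot M$
because the deviation $u - \lambda w$ can reach $|\lambda|$ times the flux
bound.

**Step 2** fixes $\sum d_i = Z^*$ and minimizes the modification count:
$b_l = 1$ for each candidate carrying flux ($y_l \le M b_l$) plus
$h_m = 1$ for each originally irreversible reaction running backward
($v_m \ge -M h_m$ and $v_m \le -\varepsilon h_m + M(1 - h_m)$, so $h_m$ is
exactly "flux at most $-\varepsilon$").  Only reactions the witness
actually uses backward are counted.  In exchange mode the $h$ machinery is
dropped and irreversible reactions keep zero lower bounds: transport
hypotheses should not be entangled with directionality hypotheses.

**Alternate optima** are enumerated with integer cuts: each found selected
set $B_q$ adds $\sum_{B_q}(b, h) \le |B_q| - 1$, and enumeration stops
when the objective degrades or a configurable cap is reached.  Solver
tie-breaking is therefore irrelevant — the full optimum pool is reported in
a canonical order.

**Staged fallback** (`solveWithFallback`) runs kegg mode first; pairs left
unresolved feed a second exchange-mode program.  Each pair is annotated
`kegg_reaction`, `reversibility_change` (decided by re-testing the pair
with the added candidates but without the relaxations), `exchange`, or
`unresolved`.  One-by-one resolution re-instantiates the full two-step
program per pair with all $H$ constraints retained; the worked example
`makeFig2Network()` shows why the global mode can be strictly cheaper
(three shared candidates instead of two pairs of two).

**Verification** (`verifySolution`) closes a real gap in witness-based
certificates: a witness proves a ratio *can* deviate, but the augmented
network could re-couple a pair at a new ratio, and an $H$ pair constrained
only at the witness could silently decouple structurally.  The verifier
applies the solution (candidates added in their used direction,
$h$-marked reactions made reversible, everything else at original bounds)
and re-runs the full coupling classification; disagreements are reported
as data, not errors.

## Numerical core

No linear or integer programming library is available to this package, so
it carries its own: a dense bounded-variable two-phase simplex (Bland's
rule for entering variables, exact-minimum tie-break for leaving ones, a
periodic refactorization, and a post-solve feasibility audit that rejects
any point violating a row or bound by more than $10^{-6}$) and a
depth-first branch-and-bound over it.  Two decisions matter for
correctness here and were informed by adversarial cases:

* On a tie between a bound flip and a basis pivot, the pivot wins: a flip
  overshoots the true ratio limit by up to the tie tolerance *times the
  column magnitude*, which at big-M scale is exactly the $\varepsilon$
  that separates feasible from infeasible.
* A branch-and-bound node is closed by rounding only when the rounded
  point attains the node's LP bound.  An indicator variable can sit at
  $1 - \varepsilon/(M + \varepsilon) \approx 1 - 5\times10^{-10}$ —
  numerically a hair from integral, yet genuinely fractional; rounding it
  silently would declare feasible programs infeasible.

Tolerances: $10^{-9}$ (absolute) for blocked/forced-zero decisions,
$10^{-6}$ (relative) for ratio equality, integrality concluded below
$10^{-12}$.  All variables are box-bounded (defaults $\pm 1000$), so
unbounded programs cannot arise.

Both solvers are verified against independent combinatorial oracles rather
than against themselves: every vertex of a small flux polytope can be
enumerated exactly (pin $n - \mathrm{rank}(S)$ coordinates at bounds,
solve, test feasibility), which yields a complete coupling oracle
(`oracleCoupling`, refusing networks above 12 reactions), and the repair
program has an exhaustive subset oracle (`bruteForceRepair`) that searches
all candidate/relaxation subsets in order of size, deciding "pair
breakable" from polytope vertices.  The subset oracle equates the maximum
number of *simultaneously* breakable pairs with the number of
*individually* breakable ones; that identity holds generically (the
unbroken set of a breakable pair is a measure-zero slice of the feasible
polytope) and is valid for every fixture shipped here, where deviation
margins are of order one against $\varepsilon = 10^{-6}$.

## What the synthetic data emulate — and what they do not

`makeRandomNetwork` plants isolated two-enzyme pathways (an obligately
fully coupled reaction pair whose two genes are a fully coupled gene pair)
alongside branched decoy motifs whose genes are never fully coupled.
Expression profiles for planted gene pairs are constructed to hit the
target sample correlation *exactly* (a scaled-residual construction on
Gaussian draws, 50 conditions by default), so threshold recovery tests
measure the pipeline's logic, not sampling noise; decoy genes get
independent noise.  `makeFig1Network` and `makeFig2Network` reconstruct
the two worked examples from their defining properties and verify those
properties at generation time — generation fails rather than returning a
fixture that violates its own caption.

Real data differ in ways these fixtures deliberately do not model:
correlations estimated from heterogeneous compendia are noisy and
condition-dependent; GPRs are incomplete and sometimes wrong (the
`ablateGprs` utility probes exactly this failure mode); real universal
databases contain thousands of candidates with unbalanced stoichiometries
and naming mismatches, of which the loader's filters remove only the
mechanical classes; and genome-scale coupling computation needs the
preprocessing shortcuts of dedicated tools, not the plain LP probes used
here.  A green test suite therefore certifies the method's internal
consistency at desk scale, not its biological hit rate on a particular
organism.

Problem sizes were chosen to keep the full verification loop — 200 random
networks against the vertex oracle, 100 planted-recovery replicates,
exhaustive subset search on every repair fixture — in the minutes range on
one CPU; all are parameters, not ceilings.

## Decisions on genuinely open points

* Candidate database reactions introducing metabolites absent from the
  model are admitted, with steady-state rows; reports carry the candidate
  set so downstream curation can flag them.
* A gene pair needs *at least one* linking fully coupled reaction pair to
  contribute (not all of them); membership of each reaction pair in
  $L$/$H$ is decided pair-by-pair.
* $h$ is counted only for reactions the witness actually runs backward;
  relaxations that the solution does not use are free.
* Reported ratios, sets and solution pools are sorted lexicographically,
  so identical inputs give byte-identical reports regardless of solver
  path.

## Limitations

Everything scales with the hand-rolled solvers: the package is built for
reconstruction-fragment and fixture scale, not for a 2000-reaction model
with a 9000-candidate database.  Correlation is Pearson-only (rank and
information-theoretic measures are natural extensions behind the same
interface).  Reaction deletions, growth-consistency repairs and
likelihood-weighted candidate priors are out of scope.  Thermodynamic
direction assignment for added reactions is explicitly left to downstream
curation — a repair is reported in the direction the witness used, which
is a feasibility statement, not a free-energy one.
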