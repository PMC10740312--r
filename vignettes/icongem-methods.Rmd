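---
title: "Methods: co-expression-constrained flux prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression-constrained flux prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icongem)
```

## The model and its assumptions

Constraint-based analysis of a genome-scale metabolic model (GEM) treats
the cell at steady state: for the stoichiometric matrix $S$ and flux
vector $v$, $Sv = 0$ within bounds $L \le v \le U$. Flux balance
analysis picks the $v$ maximizing a biomass objective, but the optimum is
usually massively degenerate. This package resolves part of that
degeneracy with a signal that single-condition methods discard: the
correlation structure of gene expression across many conditions. The
premise is biological: genes whose transcripts rise and fall together
tend to act together, so the reactions they catalyze should carry flux
together.

### Template model

Measured fluxes and transcript abundances live in incompatible units,
so the model is first made unit-free. Each reaction's bounds are mapped
to the template convention
$\hat L_j = 0$ if $L_j \ge 0$, else $-T$; $\hat U_j = T$ if $U_j > 0$,
else $0$ — only the reversibility pattern of the original bounds
survives. $T$ is "the largest number": any value strictly dominating all
expression-derived bounds works, and `default_T()` uses ten times the
largest expression value (floor 1000) so no data-driven constraint is
ever clipped while keeping the LP well-scaled. Carbon input is then
opened in one of two modes: **DC** (determined carbon source) opens only
the user-named carbon exchange(s) at $-T$ and closes every other carbon
exchange, matching an experiment with a known feed; **AC** (all possible
carbon sources) opens every exchange whose metabolite contains carbon.
Carbon detection parses chemical formulas by element token, so Ca, Cl,
Co and friends do not count. Two choices here were genuinely open and
are resolved as follows: *non-carbon* nutrient exchanges (O₂, NH₄⁺, …)
simply keep their templated bounds, so a previously open uptake stays
open at $-T$; and the biomass reaction is templated like any other
reaction — the template rule admits no exception for it.

Reversible reactions are split into forward/backward column pairs
(backward = negated column, both in $[0, T]$), giving the nonnegative
split space $\bar S \bar v = 0$, $\bar v \ge 0$ in which all
optimization happens; `fold_solution()` nets each pair back to a signed
flux per original reaction.

### Expression bounds and the q-transform

Each column's GPR rule is evaluated on the selected condition's
expression values with the E-flux convention: AND nodes (enzyme
complexes) take the minimum of their children, OR nodes (isoenzymes) the
sum (a `max` variant is available), and the identity map $f(g) = g$
converts the result into the column's upper bound. Genes absent from the
expression table are treated as unmeasured and dropped from their parent
node — zeroing a whole pathway because one subunit lacks a probe would
be worse than ignoring the missing leaf. A column whose entire rule is
unmeasured, or that has no rule, is unconstrained at $T$ and never
participates in the objective.

$M_j$ is defined as the maximum of the column's evaluated bound over
*all conditions in the supplied compendium*. The source description of
this quantity is ambiguous (maximum over conditions, over genes, or
global); the per-column-over-conditions reading is adopted because it is
the only one that guarantees $q_j = 1 + \bar v_j / M_j \in [1, 2]$
whenever the expression bounds hold, which is what makes the objective
terms commensurable across reactions. Columns with $M_j = 0$ can carry
no flux; their $q$ is frozen at 1 and they are excluded from the pair
set.

### The pair set R

Every edge $(a, b)$ of the binarized co-expression network is lifted to
all column pairs $(i, j)$ with $a$ in column $i$'s rule and $b$ in
column $j$'s. Self-pairs and forward/backward siblings of one reversible
reaction (the $Rev$ set) are excluded — the latter would reward futile
cycles. The lift expands over split columns rather than original
reactions (an open choice, flagged): it keeps the objective expressible
in the $\bar v$ coordinates the solver uses, and the backward sibling of
an inactive direction simply contributes $q = 1$.

### The quadratic program and its solver

The solve maximizes $\sum_{(i,j) \in R} q_i q_j$ subject to mass
balance, expression bounds, the biomass requirement
$\bar c^\top \bar v \ge \alpha z^*$ (with $z^*$ the E-flux LP optimum
and $\alpha = 1$ by default) and per-pair complementarity
$\bar v_a \bar v_b = 0$ on $Rev$. The per-pair form is equivalent to the
aggregate sum-of-products constraint because all terms are nonnegative,
and it is much friendlier to enforce. The objective's Hessian is the
(indefinite) adjacency of $R$, so this is a nonconvex QP; its optimum
lies on the boundary of the LP polytope. The solver is deterministic
multistart local ascent:

1. **Starts**: the loop-cancelled E-flux optimizer, plus vertices of the
   polytope maximizing random linear objectives (10 starts by default,
   seeded; all LPs via a two-phase simplex).
2. **Ascent**: Frank–Wolfe steps — linearize the objective at the
   current point, find the best vertex by LP, then take the exact
   maximizer of the (univariate quadratic) objective on the connecting
   segment. Iterate to stationarity.
3. **Complementarity**: cancel each reversible pair (subtract the
   common minimum — this leaves $\bar S \bar v$, net fluxes and biomass
   untouched), clamp the losing direction to zero, and polish with a
   second ascent in the restricted polytope.

The best end point over all starts is returned with status
`"heuristic"`; because the E-flux point is always a start, the returned
objective never falls below the E-flux solution's — a guarantee the test
suite asserts on every fixture. With an empty $R$ the program collapses
to an LP and the status says so. On fixtures whose feasible set is
effectively one-dimensional after the biomass pin, the solver is checked
against a dense grid-search oracle at $10^{-3}$ resolution.

### FVA flexibility

Flexibility asks how much freedom remains at the optimum: stage 1 solves
the program above (objective value $Z^*$); stage 2 maximizes and
minimizes each reaction's net flux subject to the same constraints plus
the pin $\sum q_i q_j \ge Z^*(1 - 10^{-6})$ (relative, because absolute
pins are brittle in floating point), and reports
$F_i = |v^i_{\max} - v^i_{\min}|$. The pin is a nonconvex quadratic
constraint, so stage 2 uses penalty continuation: maximize
$\pm c^\top v + \lambda \cdot \text{objective}$ over a ladder
$\lambda \in 10^{-2} \ldots 10^{4}$, keep the candidates that satisfy
the pin, and always include the stage-1 point. This yields an *inner*
(conservative) approximation of the flexibility interval — reported
ranges can understate but never overstate the true freedom — and is
exact (pure LP) whenever $R$ is empty. Stage 2 re-imposes the full
constraint system including the $q$ definition, not just the linear
part. Subsystem flexibility averages $F_i$ within each subsystem label
and min–max normalizes the subsystem-by-condition matrix to $[0, 1]$
over all entries; an all-equal matrix normalizes to zeros with a
warning.

## Co-expression network construction

Expression cleaning removes genes with missing values, averages
duplicated gene ids and winsorizes per gene at median ± 5·MAD — a
deterministic, conservative outlier rule (the source procedure names
outlier handling but not a rule), with every action logged. Pearson
correlations are computed across conditions; constant genes get
correlation 0 with a warning (never an edge), and a two-condition table
is flagged as degenerate since every non-constant pair then has
$|r| = 1$.

Binarization uses the *signed* correlation with the $\ge$ convention:
$r \ge t$ makes an edge, negative correlations never do (an
absolute-value mode exists). The threshold is chosen by scanning a grid
(default 0.50–0.99 by 0.01) and, among candidates whose degree
distribution fits scale-free topology with $R^2 \ge 0.5$ (log–log
regression of binned degree frequency on degree; 10 logarithmic bins),
picking the one maximizing the number of connected components with at
least two nodes. Ties go to the smallest threshold, which retains the
most edges; if no candidate reaches $R^2 \ge 0.5$, the maximal-$R^2$
candidate is returned with a prominent warning. Component counting
stands in for the unspecified "spectrum clustering" of the source; a
spectral variant (Laplacian eigenvalues below $10^{-8}$) is available
behind a flag and agrees on cleanly separated graphs.

Network utilities follow the field's conventions: random rewiring
removes a fraction of edges and inserts the same number among the
*original* graph's non-edges (node and edge counts conserved exactly;
deterministic given a seed); STRING protein-links import keeps
interactions with combined score strictly above 900 and deduplicates
reciprocal lines; TOM similarity uses
$(l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$ with unit diagonal;
modules come from average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$, cut to a requested count and labelled ME1, ME2, …
by decreasing size.

## Accuracy evaluation

Measured fluxes rarely correspond to single model reactions. A mapping
spec declares, per measured reaction, either a **chain** (the conversion
runs through sequential model reactions; the predicted value is the
minimum *absolute* net flux along the chain, since a reversible
intermediate running backward still carries the pathway) or a
**parallel** set (alternative reactions accomplishing the conversion;
the predicted value is the sum of net fluxes, each oriented toward the
measured product by a declared sign). The spec is user-supplied —
automatic pathway search between substrate/product pairs would silently
change results and is out of scope. Agreement is scored with the
uncentered Pearson correlation (the cosine), which is invariant to
positive rescaling and therefore to the unit mismatch between predicted
and measured fluxes; plotting-time rescaling of the predicted vector
never affects it.

## The synthetic generator

`gen_toy_model()` builds a glucose exchange, $k$ parallel linear
pathways converging on a biomass precursor, and a biomass sink; each
internal reaction carries one unique gene and one pathway step is
reversible, so the split template always exercises the $Rev$ machinery.
`gen_expression()` gives each gene block one latent profile across
conditions; genes are affine transforms of their block's latent plus
Gaussian noise, shifted to positivity (shifts do not change Pearson
correlations) and scaled to a plausible transcript-abundance range. Two
genes sharing a latent with noise s.d. $s$ correlate at $1/(1+s^2)$ in
expectation; the default noise targets a within-block correlation of
0.9. What the generator deliberately does *not* emulate: count noise
(negative binomial), library-size effects, batch structure, or
correlated blocks of unequal size — so passing tests demonstrate correct
mechanics and signal recovery under clean block structure, not
performance on real transcriptomes.

The **branch fixture** is the package's parameter-recovery instrument:
two equal-capacity pathways feed biomass, pathway A's genes share a
block with the biomass gene, and the biomass gene's expression is halved
so biomass demand — not pathway capacity — is the binding constraint.
That last choice matters: it leaves the pathway split entirely free at
the FBA level, which is precisely the degeneracy the co-expression
objective is supposed to resolve. Ground truth routes everything through
pathway A.

The **condition-count robustness protocol** (`robustness_curve()`)
mirrors building networks from subsets of one expression compendium: per
replicate, one master dataset of 20 conditions is drawn and each tested
$N$ uses its first $N$ conditions (common random numbers, so errors
shrink monotonically along a replicate as conditions accumulate rather
than jumping between independent draws). Accuracy against the fixture's
ground truth is averaged over 50 replicates per $N$; the default of 50
keeps the Monte Carlo error of each mean well below the accuracy
differences between adjacent $N$. The toy network uses a fixed threshold
of 0.7, centered between the designed within-block population
correlation (≈ 0.92) and the between-block correlation (0) — toy gene
sets are far too small for the scale-free selection rule to be
meaningful, and a threshold too close to the within-block correlation
would miss true edges even with many conditions.

## Numerical choices

- All LPs are solved by a two-phase simplex in the nonnegative split
  space; mass-balance rows that are identically zero are dropped, and
  columns clamped to zero bounds are eliminated before the solve.
- The biomass requirement is imposed as
  $\bar c^\top \bar v \ge \alpha z^* (1 - 10^{-9})$ to keep the
  constraint active but never infeasible at the LP optimum's own
  rounding level.
- Feasibility tolerances asserted by the test suite: mass-balance
  residual $\le 10^{-6}$ relative, bound violations $\le 10^{-9}$,
  per-pair complementarity $\le 10^{-6}$, biomass within $10^{-6}$
  relative of $z^*$ at $\alpha = 1$.
- Frank–Wolfe line search is exact (the objective restricted to a
  segment is a univariate quadratic); ascent stops below a $10^{-12}$
  relative improvement.
- Multistart uses 10 starts by default, all derived from one seed
  (default 0); every stochastic element in the package takes an explicit
  seed.
- Degenerate inputs have defined behavior: empty pair set → exact LP
  with status `degenerate_no_pairs` and objective 0; all-zero expression
  → $z^* = 0$ and zero flux; constant genes → correlation 0; all-equal
  flexibility matrix → zeros plus warning.

## Problem sizes

The shipped experiments run on fixtures of 6–10 reactions (8–14 split
columns), 5–12 genes and 3–20 conditions, with 50-replicate robustness
curves — sizes at which the multistart ascent provably matches the
dense grid oracle and every solve completes in milliseconds. Organism-
scale models are readable (`read_sbml()`) and the machinery is
dimension-independent, but the bundled simplex and the heuristic QP
ascent are not tuned for thousands of columns; coupling the problem
objects to an industrial QP solver would be the natural extension.

## Known limitations

- The QP solver is a local-ascent heuristic: it certifies feasibility
  and E-flux dominance, not global optimality (global solves at organism
  scale are out of scope).
- Stage-2 FVA is an inner approximation under a nonconvex pin; reported
  flexibilities can understate the true range (never overstate).
- Pearson-based networks capture linear co-expression only, and at
  $N = 2$ conditions carry no information at all; the threshold
  selection criteria (scale-free $R^2$, component counts) need
  realistically sized gene sets to be meaningful.
- The accuracy mapping requires a user-curated spec; no automatic
  reaction-to-measurement inference is attempted.
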