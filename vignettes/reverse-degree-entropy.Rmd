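---
title: "Reverse-degree indices, graph entropies, and QSPR: methods and design"
author: "revent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-degree indices, graph entropies, and QSPR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revent)
```

## The model

A molecule is represented as a finite, simple, connected, undirected graph
$Z = (V, E)$ with $p$ vertices (heavy atoms) and $q$ edges (bonds).
Hydrogens are suppressed and bond orders ignored: an aromatic or double
bond contributes one edge. This is the standard chemical-graph convention;
it also means the package refuses multigraphs, self-loops, and
disconnected inputs (a degraded or multi-fragment structure is analyzed
fragment by fragment by the caller).

For maximum degree $\Delta$ the *reverse degree* of a vertex is

$$\Upsilon(v) = \Delta - d(v) + 1 \ge 1,$$

with the minimum value 1 attained at every maximum-degree vertex, and the
exact integer identity $\sum_v \Upsilon(v) = p(\Delta + 1) - 2q$.
**$\Delta$ is always the maximum degree of the input graph itself**, never
a global constant: embedding a graph in a larger structure changes every
reverse degree. This is the single most common source of confusion with
reverse-degree descriptors, so `reverseDegrees()` documents it and the
test suite checks the sum identity on every generated graph.

### Indices

Every index is an edge sum $\sum_{rs \in E} F(\Upsilon_r, \Upsilon_s)$
over a registered weight function: Randić $(ab)^\alpha$ (with $\alpha \in
\{1, -1, \tfrac12, -\tfrac12\}$ by default and arbitrary real exponents
behind an explicit override), atom-bond connectivity, geometric-
arithmetic, first/second/hyper Zagreb, forgotten, augmented Zagreb,
Balaban-type, redefined Zagreb 1–3, harmonic, symmetric division degree,
and inverse-sum-indeg. Two registered names are aliases — `mm2` is
randic($-1$) and `isi` is `rezg2` — and evaluate identically by
construction.

Because $F$ only sees the sorted pair $(\Upsilon_r, \Upsilon_s)$, the
multiset of such pairs — the *edge partition*, `edgePartition()` — is a
sufficient statistic, and `indexFromPartition()` computes any index as
$\sum_{\text{classes}} \text{count} \cdot F(a, b)$. An independent
per-edge brute-force route (`bruteForceIndex()`) recomputes every reverse
degree from scratch and is compared against the partition route on 200
seeded random graphs in the tests.

Two deliberate design points:

* **Augmented Zagreb on a (1,1) class** has a zero denominator. This is a
  domain error naming the offending class, not $\pm\infty$: the index is
  simply undefined there. Batch interfaces (`allIndices()`, the CLI)
  degrade gracefully by reporting the entry as undefined with a reason.
* **The Balaban-type weight uses the prefactor $q/(q - p + 2)$ exactly as
  the reverse-degree literature tabulates it**, although the classical
  Balaban index treats the cyclomatic number differently. Fidelity to the
  tabulated form wins; the weight is the only context-dependent one and
  requires the $(p, q)$ context.

### Entropies

The edge-weight entropy normalizes the per-edge weights into a
probability distribution and takes its Shannon entropy:

$$\mathcal{E}_F = \log\Big(\sum F\Big) - \frac{1}{\sum F}
  \sum_{rs \in E} F \log F
  \;=\; -\sum_{rs} \frac{F}{\sum F} \log \frac{F}{\sum F}.$$

It lies in $[0, \log q]$, reaching $\log q$ exactly when all per-edge
weights are equal (any regular graph), and is invariant to class order,
class splitting, and rescaling all weights by a positive constant. Zero
weights (the ABC weight on a (1,1) class) contribute nothing via the
$0 \log 0 = 0$ convention; if *all* weights vanish the entropy is
undefined and a structured error is raised.

The vertex-information entropy applies the same construction to a
positive vertex function, reverse degree by default. A frequently copied
simplification replaces the normalizer $\sum_j \Upsilon(r_j)$ by $2q$;
that substitution is an identity for plain degrees but **false for
reverse degrees**, where the true total is $p(\Delta+1) - 2q$. The
package implements the definition with the true normalizer and treats the
$2q$ form as an erratum.

**Logarithm base.** The base is a free parameter (natural log by default,
with 2 and 10 offered in the CLI) and is always recorded in the result;
changing base from $e$ to $b$ divides the value by $\ln b$ exactly.
Published tabulations of these entropies often omit the base; in the case
of the HA-PTX family we could not reproduce the published numeric table
under any of $e$, 2, 10 with either formula below, so the package targets
the qualitative behavior (monotone growth in $s$) rather than those
printed cells.

**Displayed-form diagnostic.** Derivations in the reverse-degree
literature often aggregate each class as $\log(\text{count} \cdot F^F)$
instead of $\text{count}\cdot F \log F$. The two are *not* mathematically
equivalent (the former adds a spurious $\log(\text{count})$ per class).
`displayedFormEntropy()` evaluates the class-aggregated form, clearly
labeled as a diagnostic, so users can compare against tabulations
computed that way. It is evaluated as $\log(\text{count}) + F\log F$ in
the log domain, since e.g. the hyper-Zagreb class weight 81 would
overflow $81^{81}$ in double precision.

## Parameterized families and closed forms

For polymer-like families the count of class $i$ at repeat level $s$ is
affine, $k_i s + c_i$ (`parameterizedPartition()`, validated so counts
are non-negative for every integer $s \ge s_{\min} = 1$; $s$ is
restricted to integers, the degradation regime $s < 1$ is deliberately
not modeled). Indices are linear in counts, so every index has the exact
closed form

$$\Big(\sum_i k_i F(a_i, b_i)\Big) s + \sum_i c_i F(a_i, b_i),$$

returned by `affineIndex()` as an `AffineForm`. Entropies are *not*
affine in $s$ and are reported numerically (`entropyTable()`).

The built-in HA-PTX fixture has nine classes with $q(s) = 96s$, and its
closed forms reproduce the published coefficients for the first Zagreb
(664, 4), hyper-Zagreb (4684, 60), forgotten (2418, 30) and ABC
(62.6009, −0.1082 at 4 dp) indices. Two published coefficients conflict
with the fixture itself and are treated as typographical errata, with the
derived values used everywhere: the second Zagreb slope must be 1133
(printed once as 113; note $1133 + 15$ equals the index at $s = 1$
computed directly from the classes), and the GA form evaluates to
$94.4586s + 0.0041$ rather than the printed $93.9919s + 1.9836$. The
Balaban-type index has no closed form over a family because no $p(s)$ is
carried; it is rejected with a context error.

## The synthetic generator

`randomConnectedGraph(n, extraEdges, seed)` draws a uniform random
labeled spanning tree via a random Prüfer sequence and adds
`extraEdges` distinct non-tree edges uniformly at random. It is
deterministic for a fixed seed and always satisfies the graph invariants.
It emulates the *combinatorial* features the estimators care about —
connectivity, variable degree spread, cycle content — and nothing
chemical: no valence bounds, no realistic ring-size distribution. Passing
property tests on these graphs therefore certifies the algebra (oracle
equivalence, entropy bounds, base laws) on a much wider class than
molecular graphs, but says nothing about chemical plausibility of inputs;
that is the caller's concern. Property suites use 200 graphs with
$n \le 30$ and up to 3 extra edges, a size chosen to exercise all degree
patterns the weights distinguish while keeping the whole suite inside a
half minute.

## QSPR harness

`qsprFit()` supports five families. Design choices, in decreasing order
of consequence:

* **Metrics are in-sample on all rows** (`fitMetrics()`,
  `compareModels()`). The published model-comparison tables this harness
  mirrors report single metric triples per model with no train/test split
  stated; with 13 observations any split would be noise. The vignette
  states this prominently because in-sample $R^2$ of flexible models is
  optimistic by construction.
* **Standardization.** Penalized fits (ridge/lasso/enet) standardize
  descriptors to zero mean and unit variance and report coefficients back
  on the original scale (predictions from either representation agree).
  OLS is fit unstandardized — it is scale-equivariant, so nothing is
  gained.
* **Penalty convention.** The glmnet objective
  $\frac{1}{2n}\mathrm{RSS} + \lambda(\text{mix}\,\|\beta\|_1 +
  \frac{1-\text{mix}}{2}\|\beta\|_2^2)$ is used throughout, so
  `lassoLambdaMax()` gives the exact all-zero threshold
  $\max_j |x_j^\top (y - \bar y)|/n$. Lasso and elastic net call glmnet's
  coordinate descent (threshold $10^{-12}$); ridge is solved in closed
  form under the same convention, because glmnet interprets the ridge
  $\lambda$ on the scale of an internally standardized response, which
  silently rescales the penalty by $\mathrm{sd}(y)$ — the closed form is
  checked in the tests against an independent numerical optimizer of the
  stated objective.
* **Rank deficiency.** With $n \le p$ (13 drugs can face 15 descriptors)
  OLS returns the minimum-norm SVD solution with a prominent
  rank-deficiency warning; published MLR rows in that regime are treated
  as not reproducible. Relatedly, a Pearson $r$ defined as
  cor(predicted, observed) is non-negative for in-sample OLS with
  intercept, so published negative MLR correlations cannot arise under
  this definition and are not targeted.
* **Defaults.** ridge $\lambda = 1$, lasso $\lambda = 0.1$, enet
  $\lambda = 0.1$, mix $= 0.5$, SVR radial with $C = 100$,
  $\varepsilon = 0.1$, $\gamma = 1/p$ — all explicit, all overridable, and
  a leave-one-out grid search (`looTune()`) is provided instead of hiding
  a tuning heuristic. Zero-variance descriptors are dropped with a
  warning; constant predictions make Pearson $r$ undefined and it is
  reported as 0 with a warning.
* `equationText()` renders linear fits in the sparse parenthesized style
  `550.1200 + (165.7870) E_ReZG3`, omitting exactly-zero coefficients;
  radial-kernel SVR has no linear equation and errors.

## Packaged drug tables

`loadQsprTables()` ships descriptor and property tables for thirteen
cancer drugs transcribed from their published source. Two caveats:

* The descriptor column `I` is never defined in the source; it is
  interpreted here as the inverse-sum-indeg index (`rezg2` on reverse
  degrees) and used as an opaque numeric descriptor either way.
* The available rendering of the source tables runs adjacent digit
  strings together. Property rows were disambiguated cell by cell against
  known physical constants (molecular weights, monoisotopic masses,
  TPSA, heavy-atom counts); descriptor rows against independently
  recomputed reverse-degree indices of each drug's structure. Twelve of
  thirteen descriptor rows admit a unique consistent split; the
  Abemaciclib row does not, and its stored values are the best-scoring
  complete parse — treat that row as uncertain. Values are otherwise
  stored exactly as printed, including internal oddities (the Tamoxifen
  molar volume repeats its molar refractivity). None of the package's
  validated results depend on these cells; they exist so the harness has
  a realistic, reproducible example.

## Numerical choices

* All index arithmetic in double precision; closed-form coefficients are
  compared at 4 decimal places where the published values are printed at
  that precision, and at $10^{-9}$ relative tolerance against the
  independent brute-force oracle.
* $0 \log 0 = 0$ by explicit branch, not by `ifelse` on the product.
* Entropy base must exceed 1; base changes are exact rescalings and are
  tested to $10^{-12}$.
* Class counts, slopes and intercepts are integers; evaluation rejects
  any negative count rather than clamping.
* Vertex labels are opaque strings; all outputs are label-stable and
  independent of insertion order (edges are stored sorted, classes in
  canonical $(a, b)$ order).

## Known limitations

* No aromaticity perception, stereochemistry, charges, or coordinates:
  the graph model is connectivity only.
* The SMILES adapter requires ChemmineR/ChemmineOB and hands multi-atom
  fragments back to the caller rather than picking a largest component.
* Entropies over a family are computed pointwise in $s$; no closed form
  exists and none is pretended.
* The QSPR harness quantifies association in-sample; it does not validate
  predictive transfer, and with 13 observations it cannot.
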