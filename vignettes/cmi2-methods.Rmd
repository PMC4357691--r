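---
title: "Conditional mutual inclusive information: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional mutual inclusive information: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmi2ni)
```

## The statistical model

All estimators in this package operate on a multivariate Gaussian model of
the expression profiles: a named mean vector and covariance matrix fitted
by `fit_gaussian()` (sample covariance, denominator m − 1). The Gaussian
assumption is what buys closed forms for every information quantity; for
intensity-scale expression data a natural-log transform (optionally with a
pseudocount) is the standard route to approximate normality and is
available as a preprocessing flag, but is off by default because
simulated and already-log-scaled inputs should not be transformed twice.
Kernel-density or binned estimation of the underlying densities is out of
scope by design: the package's contribution is the Gaussian route.

For two genes, mutual information is a log-determinant ratio,

$$\mathrm{MI}(X,Y) = \tfrac12 \ln \frac{|C(X)|\,|C(Y)|}{|C(X,Y)|},$$

and conditional mutual information given a set $Z$ is

$$\mathrm{CMI}(X;Y\mid Z) = \tfrac12 \ln
\frac{|C(X,Z)|\,|C(Y,Z)|}{|C(Z)|\,|C(X,Y,Z)|}.$$

Both are computed in nats (natural logarithm); the independence threshold
$\theta$ of the inference engine is therefore in nats as well. Base
choice only rescales thresholds, so internal consistency is the only
argument that matters.

## Interventional distributions and CMI2

MI overestimates association (it keeps edges relayed through an
intermediary); CMI underestimates it (it collapses to zero when a
conditioning gene nearly duplicates one of the pair). CMI2 measures the
cost of *removing* the edge: sever the directed edge $X \to Y$ by
replacing $Y$'s conditional law with its parent-averaged version,

$$P_{X\to Y}(x,y,z) = P(x,z)\int P(y\mid z,x')\,P(x')\,dx',$$

and define

$$\mathrm{CMI2}(X;Y\mid Z) = \tfrac12\left(
D_{\mathrm{KL}}(P\,\|\,P_{X\to Y}) + D_{\mathrm{KL}}(P\,\|\,P_{Y\to X})
\right).$$

For Gaussians the interventional joint is again Gaussian with the same
mean: the $(x,z)$ marginal is untouched and $y$'s covariances are rebuilt
from the averaged conditional. CMI2 decomposes as CMI plus two
nonnegative conditional-KL corrections, so $\mathrm{CMI2} \ge
\mathrm{CMI}$ always, with equality when $Z$ is independent of the pair;
with an empty conditioning set both interventional distributions reduce
to the product of marginals and CMI2 equals MI exactly (MI is the
zero-order case). The one-directional quantity
$C_{X\to Y} = D_{\mathrm{KL}}(P\,\|\,P_{X\to Y})$ is exposed as
`causal_strength()`; it is asymmetric and not used by the engine
directly.

### Two independent computational routes

`cmi2()` evaluates a closed form in precision-matrix algebra. The severed
joint factorizes as $P(x,z)\,q(y\mid z)$, so its precision matrix has a
zero $(x,y)$ entry, the $(x,z)$ marginal precision in the $(x,z)$ block,
and a rank-structured contribution from the averaged conditional
$q(y\mid z) = \mathcal N(\mu_y + \beta_z (z-\mu_z),\; s^2)$ with
$s^2 = \operatorname{Var}(y\mid x,z) + \beta_x^2 \operatorname{Var}(x)$,
where $(\beta_x, \beta_z)$ are the regression coefficients of $y$ on
$(x,z)$ read off the full precision matrix. Its log-determinant is
$\ln|\Sigma_{xz}| + \ln s^2$. Since the means agree, each KL term is
$\tfrac12(\operatorname{tr}(K\Sigma) - n + \ln|\Omega| - \ln|\Sigma|)$.

`cmi2_oracle()` computes the same quantity through the explicit
moment-space construction: `interventional_model()` rebuilds the severed
covariance from a covariance-side regression solve, and the generic
`kl_gaussian()` closed form (trace, log-determinants, mean shift) is
applied to the two model objects. The literature's printed block formulas
for the closed form contain transcription ambiguities, so the oracle
route — which follows the definition term by term — is treated as
normative, and the test suite requires the two routes to agree to 1e-8
over hundreds of random symmetric-positive-definite covariances of 3–6
variables with conditioning sets of size 1–3 (observed agreement is at
machine precision, ~1e-15). `kl_gaussian()` itself is spot-checked
against a $10^6$-draw Monte-Carlo estimate of
$\mathbb E_p[\ln p - \ln q]$ within three standard errors.

Whether covariances or correlations are used is immaterial: all three
measures are invariant to rescaling any variable, which is asserted by a
property test rather than assumed.

## The path-consistency engine

`infer_network()` starts from the complete graph. Order 0 scores every
pair with MI (or the absolute correlation for the `pcor` plug-in) and
deletes pairs below $\theta$. At order $L \ge 1$, each surviving pair
with $T \ge L$ common neighbours is scored over all $\binom{T}{L}$
conditioning sets; the aggregate — the maximum by default, the geometric
mean by option — decides deletion. Design choices that the algorithm
statement leaves open were resolved as follows:

* **Batched deletions.** Within one order, every test is evaluated
  against the graph as it stood at the order's start, and deletions are
  applied at order end. This makes the result independent of pair
  iteration order, which a within-order update would not be.
* **Termination.** Order 0 always advances to order 1 (an MI pass that
  deletes nothing must not prevent conditional tests — the mediated-chain
  case would otherwise never be examined); thereafter the loop ends when
  an order deletes nothing, when no pair retains enough common
  neighbours, or when `max_order` is reached. The engine never conditions
  on more than the final order $L$ variables, so $L + 2$ independent
  samples suffice in principle.
* **Score ledger.** Removed edges keep the aggregated score at which they
  were removed instead of being zeroed. A single run therefore yields a
  complete ranking of all pairs (`edge_ranking()`), from which ROC curves
  are built by threshold sweep — reconstructing a ranking from a binary
  PC-style output alone would not support ROC analysis.
* **Defaults.** $\theta = 0.03$ nats, aggregation `max`, measure `cmi2`,
  `max_order` unlimited. In practice $\theta$ is a per-dataset choice
  (0.01–0.05 is the usual range); for networks beyond ~100 genes
  `max_order = 1` keeps the enumeration tractable, and full enumeration
  (no sampling of conditioning sets) is retained as the only complexity
  control. Edge directionality is out of scope: the inferred object is a
  skeleton.

## Numerical policy

Determinants below 1e-300 or covariance condition numbers above 1e12
trigger the degeneracy policy: an error in `strict` mode, or — the
default, because near-duplicate expression profiles are *expected* inputs
for this measure — a ridge $\lambda I$ with $\lambda = 10^{-10}\,
\mathrm{tr}(\Sigma)/d$ plus a warning in `lenient` mode. Analytic
quantities are nonnegative: float negatives in $[-10^{-12}, 0)$ are
clamped to zero, anything below that raises an internal-consistency
error rather than being silently absorbed. The redundant-conditioner
fixture uses correlation 0.999 rather than 1 precisely so that it
exercises the near-degenerate regime without tripping the ridge.

## The synthetic generator

`random_dag()` / `simulate_expression()` implement a linear-Gaussian
structural equation model: genes in a fixed topological order, each
forward pair an edge with the requested density, weights uniform on
$\pm[0.5, 1]$, unit Gaussian noise by default. The implied joint is
exactly multivariate normal with covariance
$(I - W^\top)^{-1} D (I - W^\top)^{-\top}$, exposed by
`dag_covariance()`, so estimator ground truth is analytic — the regime
in which the package's own Gaussian assumption holds exactly. This is a
deliberate replacement for nonlinear ODE-based generators of
community benchmarks: passing tests here demonstrates correctness of the
estimators and engine under their stated model, not robustness to
nonlinearity, saturation, or non-Gaussian measurement noise in real
expression data. The weight range keeps per-edge signal comparable to
the noise floor; seeds are mandatory arguments and the RNG state is
restored after every draw.

`fixture_triples()` pins the three canonical scenarios as population
models (all variances 1): a direct pair with an unconnected third gene
(all measures agree), a mediated chain (MI overestimates; CMI and CMI2
both vanish), and a direct pair with a conditioner correlated 0.999 with
one endpoint (CMI collapses to ~0.002 while CMI2 stays at ~0.26).

## Evaluation conventions

Gold standards follow the DREAM edge-list dialect: two or three
tab-separated columns, an optional 0/1 indicator, explicit 0 rows treated
as known negatives, absent pairs negative, directions collapsed —
evaluation is undirected to match the method's output. Confusion counts
come in `pairs` mode (each unordered pair once) and `matrix` mode (each
off-diagonal cell, exactly doubling all counts — the convention under
which published benchmark tables report TP + FN equal to twice the edge
count). All five ratio metrics are identical between modes. Metrics with
zero denominators are reported as undefined (`NA`), never as zero, since
small networks routinely empty one class. AUC is computed by trapezoid
over a tie-grouped threshold sweep and equals the Mann–Whitney statistic
on the same ranking, which the suite verifies as two independent
computations.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on generated data:
oracle equivalence on 500 random covariances; skeleton recovery on
twenty 10-gene DAGs (density 0.25, 500 samples, $\theta = 0.05$), for
which mean AUC is required to reach 0.90 (observed ~0.94); the
mediated-chain pipeline at 1000 samples; Monte-Carlo KL checks at
$10^6$ draws. These sizes make every property measurable in seconds
while leaving the estimators' asymptotics visible (a dedicated test
checks that estimator error shrinks monotonically from 100 to 10000
samples).

## Known limitations

* The Gaussian assumption is structural: monotone-nonlinear but
  non-Gaussian dependence is only captured insofar as it survives the
  covariance.
* The engine outputs an undirected skeleton; orientation is not
  attempted.
* Conditioning-set selection beyond max/geometric-mean aggregation
  (e.g. optimized subset choice) is an open problem and out of scope.
* Full enumeration of conditioning sets is exponential in the order;
  `max_order` is the intended control for large networks.
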