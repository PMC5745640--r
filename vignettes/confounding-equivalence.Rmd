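---
title: "Confounding equivalence, non-collapsibility, and the choice of adjustment strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounding equivalence, non-collapsibility, and the choice of adjustment strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cequiv)
```

## The question the package answers

Given a causal diagram with binary exposure $X$, binary outcome $Y$ and
observed confounders, many covariate sets can be "valid" for adjustment.
Confounding equivalence (c-equivalence) formalizes when two sets $T$ and
$Z$ carry the same adjustment value: adjustment for either produces the
same asymptotic bias for the causal effect. The graphical test is a
disjunction — identical Markov boundaries relative to $X$, or joint
G-admissibility (the back-door criterion). The package asks what this
guarantee is worth *operationally* when the outcome model is logistic:
does adjusting for different members of a c-equivalent family with
logistic regression give the same answer, and does it give the *right*
answer, compared with a stabilized-IPW marginal structural model (MSM)?

The target estimand throughout is the average causal effect on the
log-odds-ratio scale,
$$\mathrm{ACE}^{\log(\mathrm{OR})}
  = \mathrm{logit}\,P(Y=1\mid do(X=1)) - \mathrm{logit}\,P(Y=1\mid do(X=0)),$$
computed exactly by the truncated-product (g-)formula on the model's joint
distribution.

## Graphical machinery

`causal_dag()` stores a labelled DAG with a single exposure/outcome pair.
d-separation (`d_separated()`) is implemented by the standard reachability
("Bayes-ball") scheme over $(node, direction)$ states; the test suite
checks it query-by-query against an independent brute-force oracle that
enumerates every undirected simple path and applies the collider rule to
each, over a thousand random DAGs.

Two deliberate semantics choices:

* **Blocking is full d-separation**, not vertex-hitting of a listed set of
  confounding paths. `is_g_admissible()` evaluates back-door condition (2)
  as d-separation of $X$ and $Y$ in the graph with the exposure's outgoing
  edges removed, which is equivalent to blocking every path with an arrow
  into $X$, collider rule included. This matters in the `fig1d` diagram,
  where $W$ is a collider of $Z$ and $T$: full enumeration finds **four**
  back-door paths ($X{\leftarrow}W{\rightarrow}Y$,
  $X{\leftarrow}Z{\rightarrow}W{\rightarrow}Y$,
  $X{\leftarrow}W{\leftarrow}T{\rightarrow}Y$ and the collider path
  $X{\leftarrow}Z{\rightarrow}W{\leftarrow}T{\rightarrow}Y$), one more
  than the three usually quoted for this diagram. The fourth path is
  closed when nothing is conditioned on and is re-blocked by $Z$ or $T$
  whenever $W$ is adjusted, so the admissibility classifications are
  unaffected — but the enumeration reports it honestly.
* **Markov boundaries are found by exhaustive subset search** in
  increasing cardinality with lexicographic tie-breaking. The sets in play
  have at most four members, so the $2^{|S|}$ search is trivial, and the
  exhaustive definition doubles as its own certificate (tests verify
  minimality by re-checking every proper subset). d-separation is a
  compositional graphoid with the intersection property, so the minimal
  boundary is unique; the `multiple` attribute exists as a guard and can
  never fire for DAG semantics.

## The data-generating process and its defaults

Each scenario is a binary logistic structural-equation model: root nodes
$\sim$ Bernoulli($\pi$), each child Bernoulli with success probability
$\mathrm{expit}(\alpha + \sum_e c_e \cdot \mathrm{parent}_e)$, effects
additive on the log-odds scale. The four registry diagrams `fig1a`–`fig1d`
range from a single confounding path to the collider configuration above,
each carrying its named adjustment-set groups (`A1`–`A3`, `B1`/`B2`,
`C1`–`C3`).

The benchmark study never fixes printed values for $\pi$, $\alpha$ or the
non-swept $c$'s, so the registry fixes them once as the package's own
study conditions:

| parameter | default | why |
|---|---|---|
| root prevalence $\pi$ | 0.5 | maximally informative binary covariates |
| intercepts $\alpha$ | $-1$ | keeps all node prevalences ≈ 0.2–0.7, avoiding separation at $n = 1000$ |
| edge effects $c_e$ | $\log 2$ | moderate, realistic odds ratios of 2; "positive and log-linearly additive" |

Sweeps vary one edge over a log-OR grid $0$–$1.6$ (outcome-side) or
$0$–$1.1$ (exposure-side); replicate sample size is $n = 1000$ subjects.
These choices are surfaced in configs and results, not claimed to replicate
any particular published curve — the qualitative claims (which strategies
are biased, which slopes are non-zero, which SE is smallest) are the
reproduction target, and they are insensitive to the exact grid.

What the generator emulates: independent subjects, faithful Bernoulli
sampling of the structural equations, every variable observed and binary.
What it does not: measurement error, missingness, continuous or
time-varying exposures, effect-measure modification (no interactions in
the DGP), unmeasured confounding. Passing tests therefore certify the
estimators' behaviour *under the assumed model*, not robustness to the
failures of it.

## Exact oracle

`joint_table()` enumerates all $2^k$ configurations ($k \le 20$); the
interventional distribution drops the exposure's conditional and fixes
$X=x$. Two population estimands are derived from the joint:

* `population_adjusted_coefficient(model, s)`: the exposure coefficient of
  the main-effects logistic regression of $Y$ on $(X, s)$ that maximizes
  the *expected* log-likelihood — the KL-projection, i.e. the
  $n\to\infty$ limit of the finite-sample fit. When the stratum log-OR is
  constant (e.g. $s \supseteq$ parents of $Y$ other than $X$) this equals
  that constant exactly; otherwise the projection is the only well-defined
  population target of "the adjusted logistic coefficient", which is why
  the package defines it this way rather than assuming a single stratum
  value. Solved by Newton iteration from zero, score-norm tolerance
  $10^{-10}$, 100-iteration cap; degenerate settings are rejected, never
  clipped.
* `population_ipw_estimand(model, s)`: the stabilized-weighted
  pseudo-population reduces algebraically to the adjustment formula
  $\mathrm{logit}\sum_s P(Y=1|x,s)P(s)$, which is computed directly, with
  an explicit positivity check.

The oracle reproduces the theory's identity chain in scenario 1:
$\beta_X^{\{T\}} = \beta_X^{\{Z,T\}} = c_3$ always; the $\{Z\}$-adjusted
coefficient equals $c_3$ iff $c_2 = 0$ or $c_3 = 0$, is attenuated below
$c_3$ when $c_2 \neq 0, c_3 > 0$, and sits above it when $c_3 < 0$. It
also exhibits the sharper scenario-2 point: $B_1 = \{Z\}$ and
$B_2 = \{Z,T\}$ are c-equivalent through the shared boundary $\{Z\}$, and
their IPW estimands coincide exactly, yet their logistic projections
differ — c-equivalence guarantees equal *bias*, logistic regression
changes the *estimand*.

## Estimators

* `fit_adjusted_logistic()`: `stats::glm` binomial fit; the model SE is
  the inverse observed information. Separation (glm's own warning, or
  fitted probabilities at the $10^{-8}$ boundary) yields
  `converged = FALSE` with a reason instead of a nonsense estimate;
  rank-deficient designs error.
* `compute_stabilized_weights()`: numerator intercept-only (sample
  exposure proportion); denominator **saturated** — the empirical exposure
  proportion per observed covariate pattern. With at most four binary
  covariates the saturated estimate is the nonparametric MLE of $P(X|s)$
  and matches the weight definition exactly; a smooth (main-effects)
  denominator model would add an avoidable approximation. Empirical
  positivity is enforced per pattern, naming offenders. Mean weight is 1
  by construction; no truncation is applied (defaults are moderate, and
  the weight range is reported as a diagnostic).
* `fit_ipw_msm()`: weighted quasibinomial fit of $Y$ on $X$ alone (same
  point estimates as binomial ML, tolerant of non-integer weights), robust
  sandwich SE with weights treated as known — standard MSM practice.

## Experiment layer and numerical choices

`run_replicates()` draws one sample per replicate and applies *every*
strategy to the same table, so method contrasts are paired; failures
(separation, positivity) exclude that replicate for that strategy only and
are counted, never re-drawn (a re-draw would break the pairing).
Per-replicate seeds come from a counter scheme,
$\mathrm{seed}_r = (\mathrm{master} \cdot 100003 + r) \bmod (2^{31}-1)$,
exact in doubles, so a run is reproducible from `(spec, master seed)`
alone and independent of global RNG state. `run_sweep()` rebuilds the
model at each grid value and recomputes the exact truth there (the truth
moves when outcome-side effects are swept); degenerate grid points are
flagged and skipped with a warning row.

Reported precision: the headline is the empirical SD of estimates across
converged replicates, with the mean model-based (or robust) SE alongside —
both are printed because either convention is defensible and they answer
different questions.

Problem sizes: the package's standard profile is 200 replicates of
$n = 1000$ per setting (the analysis drivers expose a `paper_scale` switch
for 1000 replicates), 500–1000 random DAGs for the d-separation
cross-check, and $n = 2\times10^5$ single samples for consistency checks.
Qualitative figure-shape claims are operationalized as statistics:
weighted-least-squares slope of mean bias over the grid with known
Monte-Carlo variances (flat iff $|z| < 3$), ordering of empirical SEs with
a 5% Monte-Carlo tolerance, and stability as a bias range under
$4\times$ MC SE.

## Known limitations

Single binary exposure and outcome; no latent-projection (ADMG) graphs, no
front-door or general ID-algorithm identification; no doubly-robust or
TMLE estimators; no bootstrap intervals. The exact oracle is limited to
$\le 20$ nodes by full enumeration. These bounds are inherent to the
study design the package reproduces, not incidental.
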