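---
title: "Boolean Function Networks: model, tests and design choices"
author: "bfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean Function Networks: model, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfnet)
```

## The model

`bfnet` infers directed gene regulatory links from time-course expression
data. The generative picture is a hidden Markov one: each gene $k$ has an
unobserved binary activity state $x_k(t)$, and the measured expression
level $y_k(t)$ is a continuous readout of that state. A regulatory link is
a delayed Boolean constraint: the target's state at time $t + \tau$ is a
Boolean function of the source's state at time $t$.

Rather than hard-thresholding the data, each profile is standardized by its
empirical CDF: an observation's rank probability is taken as
$P(x_k(t) = 1 \mid y_k(t))$. Tied observations share the probability
$(C + c)/m$, where $C$ counts strictly smaller values and $c$ the tie
multiplicity, so the transform depends on ranks only — any strictly
monotone transformation of the raw data (log, scaling, background shifts)
leaves all downstream results unchanged. The price of this robustness is
bounded confidence: with $m$ time points no state probability can be more
extreme than $1/m$, which caps the information a single time point can
contribute to a test statistic. Genes with constant profiles admit no
standardization (their inactive-state probability would be zero) and are
excluded with a warning.

## Boolean functions with indefinite outputs

Regulation is described by truth tables over $\{0, 1\}$ with a third
output symbol $\Omega$ ("either"). The six non-trivial unary functions are
equivalence (`f1`, up-regulation), negation (`f2`, down-regulation),
necessity and its negation (`f3`, `f4`) and sufficiency and its negation
(`f6`, `f5`). Necessity, for instance, states "the target cannot be on
unless the source is on": a definite 0 for source-off, $\Omega$ for
source-on. The 42 binary functions are all non-trivial two-input tables:
the ten fully definite ones that genuinely depend on both inputs (`F1` is
AND, `F5` is OR) and the thirty-two with exactly one indefinite cell.
Constants and single-input tables are excluded as trivial; notably this
means no catalog function ignores one of its inputs, which matters for the
directness test below.

A unary function is classified *positive* when its definite outputs equal
their inputs (monotone non-decreasing): `f1`, `f3`, `f6`. The source text
for this method never enumerates the positive set; the monotone reading is
the natural one and `classify_sign()` documents it.

## Test 1: pairwise links

For an ordered pair (source, target) and delay $\tau$, the likelihood of
the *linked* model multiplies, over aligned time points, terms
$\sum_{a,b} p_{ab}(t)\, w_{ab}$, where
$p_{ab}(t) = P(x_1(t) = a \mid y_1) \, P(x_2(t+\tau) = b \mid y_2)$ and the
weight of a definite transition is $(1-\varepsilon)/q_b$ when $b = f(a)$
and $\varepsilon/q_b$ otherwise ($q_b$ the target's marginal state
probability, a time average of its conditional probabilities); indefinite
outputs contribute weight 1. The *not-linked* model's likelihood is
identically 1, so the statistic is $2 \log R = 2\,\ell_\text{linked}$ at
the optimum over the six functions and the delay range. Significance is
an upper-tail $\chi^2$ probability thresholded at `p1`.

Numerical and inferential choices, all surfaced in `bfn_params()`:

* **$\varepsilon$ (default 0.005)** softens the 0/1 truth-table constraint
  so one violated time point costs $\log \varepsilon$ rather than
  $-\infty$. Shrinking it sharpens perfectly satisfied functions and can
  only raise their statistic, so link counts grow slightly as
  $\varepsilon$ decreases; the default matches the method's reference
  setting.
* **Degrees of freedom (default 1).** The linked model adds one
  constrained transition pattern, but the statistic is a *maximum* over
  six functions and several delays, so the $\chi^2_1$ reference is
  anti-conservative. We keep df = 1 as the documented default and expose
  it; users wanting stricter screening should lower `p1` (the reference
  analyses used 0.05 genome-wide and 0.005 for a focused gene set) or
  raise `chisq_df`.
* **Truncation at zero.** The unary catalog contains no saturated model,
  so the maximized linked log-likelihood can be marginally negative on
  profiles with mixed concordance; the statistic is truncated at 0,
  consistent with the one-sided test. The not-linked identity
  ($\ell \equiv 0$) is verified to $10^{-12}$ in the tests.
* **Alignment and ties.** Products run over $t = 1 \ldots m - \tau$ (end
  truncation); argmax ties break toward the lower function index, then
  the smaller delay, making scans deterministic.
* **Direction at $\tau = 0$.** Zero-lag links are symmetric in
  information; direction is meaningful when a regulator (TF) list is
  supplied as `sources`. Scanning all genes against all genes reports
  both orientations.
* **Multiple testing.** Raw p-values are thresholded, as in the reference
  protocol; `bfn_params(adjust = "BH")` enables Benjamini–Hochberg for
  users who prefer FDR control.

At least 10 time points are required for meaningful inference; the scan
warns below that.

## Test 2: direct or mediated?

A significant link $x_1 \to x_2$ (delay $\tau$) is re-examined against
every *candidate mediator* $x_3$: a gene with Test-1 links
$x_1 \to x_3$ (delay $\tau'$) and $x_3 \to x_2$ (delay $\tau''$) such that
$\tau' + \tau'' \le \tau$. The direct model drives the target by a binary
function of source and mediator (maximized over the 42-function catalog);
the mediated model drives it by a unary function of the mediator alone
(re-maximized over the six functions, not reused from Test 1), both over
the same aligned window, with the mediator read at $t + \tau'$ and the
target at $t + \tau$. The statistic $2(\ell_1 - \ell_0)$ is referred to
the same $\chi^2$ approximation and thresholded at `p2`: significant means
the two-regulator explanation is genuinely better — the link is *direct*;
otherwise it is bookkept as *indirect* with its best mediator. Links with
no composable mediator are kept (*unmediated*).

Two aggregation rules over multiple candidates are provided: the default
follows the literal argmax (the mediator maximizing $\ell_1 - \ell_0$); a
conservative `rule = "min"` declares a link direct only when the direct
model beats *every* mediator's indirect model. The literal rule arguably
under-tests directness (a single weak mediator cannot veto), which is why
both ship. One reading note: the delay pair is fixed by the Test-1 links —
the search re-optimizes over candidates, not over $\tau''$.

Because the binary catalog excludes input-ignoring tables, the direct
model does not formally nest the mediated one; the nesting identity is
still exact for ad-hoc input-ignoring tables (verified in the tests), and
in practice $\ell_1 \ge \ell_0$ at the optimum in all but degenerate
cases, with negative differences truncated at zero.

## Evaluation

Predicted edge sets are scored against a gold standard over an explicit
ordered-pair universe (sources × targets, self-pairs excluded; gold edges
outside the universe are dropped with a count). Seven metrics are
reported: sensitivity, specificity, precision, NPV and three Euclidean
distances from ideal performance — $C_1$ in (sensitivity, specificity),
$C_2$ in (PPV, NPV), $C_3$ in (sensitivity, PPV); smaller is better and
the square root *is* taken, which the published worked values confirm
(e.g. rates 0.3482/0.7548 give $C_1 = 0.6964$).

The classical zero-lag Pearson baseline (`pearson_baseline()`) and a
p-value-sweep ROC for the link scan (`test1_roc()`, Test 1 only — the
directness stage is not part of the sweep) support the comparison; on
planted networks with asymmetric necessity/sufficiency links the
likelihood scan dominates the correlation baseline's ROC area.

`phase_consistency()` implements the cell-cycle sanity check: a link is
consistent when the target's phase equals the source's or is its immediate
successor in the cyclic order M → G1 → S → G2 → M; composite labels
("G2/M") pass if any component does.

## The synthetic generator, and what passing tests mean

`planted_network()` / `simulate_network()` generate the model's own data:
root genes are i.i.d. Bernoulli(0.5) per time point, children apply their
delayed unary function (indefinite outputs resolved by an independent
Bernoulli draw, which makes necessity/sufficiency targets genuinely
asymmetric), and observations are Gaussian with state means 0 and 2 and
shared standard deviation 0.25 by default — an 8-standard-deviation
separation representing clearly resolved expression states; recovery
studies sweep the noise upward (0.1 to 2) to cross into heavy overlap.
`simulate_gate()` adds the one structure the pairwise generator cannot
express: a target driven by a *binary* function of a sparse source
(activation 0.4) and a dense co-regulator (0.8), the motif used to probe
the directness test with both inputs informative. `emit_observations()`
exposes the emission step for custom hidden structures.

Study sizes follow the data regime the method targets: 18–20 time points
(a typical synchronized time course), 2–8 genes per motif, 20–30 Monte
Carlo replicates where rates are reported. Within that regime, recovery of
a planted edge's function and delay at the default `p1 = 0.05` is nearly
certain at low noise, while at `p1 = 0.005` a single planted link's
statistic (around 7–10) sits near the threshold — the soft ECDF
probabilities bound per-point evidence, so strict genome-scale cutoffs
demand either more time points or the tie-concentrated profiles of
noise-free data. The directness test at these sizes separates chains from
gates reliably in the indirect direction; the direct verdict on a true
two-parent gate carries moderate power (roughly half of replicates at
`p2 = 0.05`), because the best unary mediator model already explains much
of an AND gate's behavior. Both rates are recomputed, not assumed, by
`scripts/acceptance.R`.

What these simulations do *not* emulate: autocorrelated continuous
dynamics, oscillatory co-expression, measurement-batch structure,
cross-regulating multi-parent networks, or missingness mechanisms beyond
random gaps. Passing recovery tests therefore demonstrates correctness of
the inference machinery on its own generative assumptions, not performance
on real microarray data.

## Limitations

* Pairwise only: multi-regulator structures beyond the directness test's
  two-input comparison are out of scope.
* The $\chi^2$ reference for a maximized statistic is approximate; p-values
  are screening scores, not calibrated error rates.
* Zero-lag links are reported in both orientations unless a regulator list
  constrains sources.
* Enrichment analysis of the (function, delay) target groups is delegated
  to external tools; `group_targets()` only prepares the gene sets.
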