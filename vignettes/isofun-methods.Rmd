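---
title: "Methods: isoform-level GO function prediction in isofun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-level GO function prediction in isofun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofun)
```

## The problem and the model

GO annotations are overwhelmingly gene-level, but alternative splicing
produces isoforms whose functions can differ. `isofun` scores every
(entity, GO term) pair on the log-odds scale by combining two signals that
exist at transcript resolution, trains where labels exist (genes), and
transfers to isoforms.

**Coexpression evidence.** Let $P_{q,g}$ be the Spearman correlation of
query entity $q$ with reference gene $g$ across samples. For term $j$ with
annotated gene set $A_j$, the evidence is the two-sample Wilcoxon rank-sum
z-score comparing $\{P_{q,g} : g \in A_j\}$ against
$\{P_{q,g} : g \notin A_j\}$, excluding $q$'s own gene. With rank sum $W$,
group sizes $n_1, n_2$, $n = n_1 + n_2$ and tie counts $t_k$ over the
pooled row,

$$z = \frac{W - n_1(n+1)/2}
  {\sqrt{\tfrac{n_1 n_2}{12}\Big((n+1) - \tfrac{\sum_k (t_k^3-t_k)}{n(n-1)}\Big)}}.$$

Positive $z$ means the annotated genes' correlations are stochastically
larger. The implementation ranks each query row once and obtains all
per-term rank sums by one sparse matrix product with the membership
matrix; it is assert-tested to be numerically identical to the scalar
computation. Design choices worth knowing:

* *Rank-sum, not signed-rank*: the comparison is between two independent
  gene groups.
* *No continuity correction by default*: with tens of annotated versus
  thousands of non-annotated genes the normal approximation is deep in its
  asymptotic regime; a `continuity` switch exists.
* *Ties*: mid-ranks with the tie-corrected variance; if ties drive the
  variance to zero the score is defined as 0.
* *Degenerate terms* (fewer than 2 genes in either group after exclusion)
  yield `NA` with a warning — never a silent zero — and the missingness
  propagates through the stacker to the final matrix.
* *Constant expression rows* have undefined Spearman correlation; they are
  kept (so matrix shapes are stable) with correlation 0 and flagged in an
  attribute.
* For isoform queries only the isoform's *host gene* is excluded from the
  comparison; annotations of all other genes are observed data, not
  predictions, so using them is not leakage.

**Domain evidence.** Per term, a logistic elastic-net regression of
membership on binary domain presence with all slopes constrained
$\ge 0$: a function may be predicted by the presence of domains, never by
their absence, which also makes predictions monotone when domains are
added — the property the isoform transfer relies on. Choices:

* Mixing parameter $\alpha = 0.5$, halfway between ridge and lasso, is
  exposed as a parameter; a pure-lasso or pure-ridge default would not be
  an elastic net.
* $\lambda$ path: 100 values log-spaced down from the data-driven maximum
  by $10^{-4}$; $\lambda$ is selected to maximize the mean out-of-fold
  AUROC over class-stratified folds (10 by default). The fold loop is
  written out explicitly rather than delegated, so the selection criterion
  is AUROC at every problem size, and the per-$\lambda$ CV trace is stored
  in the model for inspection (the selected $\lambda$ provably maximizes
  it).
* Binary features are *not* standardized: presence/absence already shares
  a scale, and standardizing would re-weight rare domains.
* Terms with fewer positives than folds reduce the fold count (floor 3,
  the smallest usable CV); with fewer than 3 positives the model falls
  back to in-sample AUROC selection, and with fewer than 2 genes in a
  class to the closed-form null intercept $\log(n_{pos}/n_{neg})$ — each
  fallback is recorded on the model object.
* No class weights: imbalance is handled by evaluation, not by distorting
  the likelihood.

**Combination.** Per term, membership is regressed on the fixed design
$(1, z, d, zd, z^2, d^2)$ — the squares and product capture second-order
interaction between the two evidence sources. Because strong terms are
often perfectly separable in $(z, d)$, maximum likelihood diverges; the
fit is instead maximum a posteriori with independent Cauchy priors (scale
2.5 on non-intercept coefficients, 10 on the intercept), the standard
weakly-informative, separation-robust recipe. Features are centred and
scaled by their training moments before the prior applies — prior scales
are only meaningful on a standardized scale — and predictions fold the
moments back in. The optimizer is damped Newton: the Hessian adds the
EM curvature of the Cauchy prior (from its normal scale-mixture
representation), every step is line-searched on the exact penalized
objective so it is monotone, and convergence is declared at
$\|\nabla\|_\infty < 10^{-8}$ within 100 iterations. Non-convergence keeps
the model flagged `converged = FALSE` rather than dropping it. The
stacker is trained on the training genes' own scores (matching the
pipeline's train-then-refit flow); `prior_scale = Inf` recovers the
unpenalized fit, which the tests verify against `glm`.

## Pipeline and evaluation protocol

`run_pipeline()` executes: filter → split → fit all three stages on
training genes → evaluate on held-out genes → refit every stage on all
genes → predict isoforms → gain/loss and consistency reports. Evaluation
strictly precedes the refit, so reported performance is always held-out.
During training the correlation reference set and annotation counts are
restricted to training genes, so no held-out label can reach a held-out
score; the refit for isoform transfer uses the complete gene set.

Filters keep GO terms annotated to 10–299 genes and domains present in
6–500 genes (both ends inclusive): terms below the range cannot support a
fit, terms above it are too generic to be informative; analogously for
domains. Gene expression is the sum of isoform TPMs, with no expression
filter; a gene carries every domain any of its isoforms carries.

*AUROC* uses the rank (Mann–Whitney) estimator with half credit for ties,
consistent with the Wilcoxon view used throughout. *AUPRC* uses the
non-interpolated step-curve (average-precision) estimator with ties
grouped; interpolated variants overestimate under heavy imbalance, which
is the operative regime — a random classifier's AUPRC equals the term's
prevalence, often below 0.05. "Perfect performance" means both areas
equal 1 on the test set (tolerance $10^{-12}$). Summaries report overall
medians, medians by term-size bin ($[10,20]$ closed, then $(20,27]$,
$(27,40]$, $(40,64]$, $(64,114]$, $(114,300]$), per-ontology medians when
CC/MF/BP labels are present, and restricted medians over terms with more
than 20 and fewer than 300 annotated genes for comparison with methods
trained on that range. Terms with undefined areas (no test positives, or
all-missing scores) are excluded from medians and counted.

*Expected logit.* $\log(n_{annotated}/n_{not\,annotated})$ over genes is
the log-odds a prevalence-only predictor would assign; it is the baseline
for gain/loss calls. An annotated term is *lost* by an isoform when
`logit − expected` falls strictly below the lower threshold; a
non-annotated term is *gained* when it rises strictly above the upper
threshold; values exactly at a threshold are unchanged. The thresholds are
user-set by design; the defaults ±2 (≈ a sevenfold odds change) are
deliberately conservative.

*Principal-isoform consistency.* For each term and each annotated
multi-isoform gene, the check asks whether the top-logit isoform is the
annotated principal one (ties all count as top). How gene-level checks
aggregate to a term-level verdict is genuinely ambiguous, so all three
readings are exposed — `any-gene`, `majority` (strictly more than half)
and `all-genes` — with `majority` as the default.

## The synthetic generator

`simulate_dataset()` plants exactly the structure the method is built to
detect. Each term $t$ has a latent standard-normal sample factor $f_t$;
a gene annotated to $t$ has latent expression
$\rho\, f_t + \sigma_\varepsilon \varepsilon$ (genes in several terms load
on the normalized sum of their factors), unannotated genes are pure noise.
Two genes solely annotated to the same term therefore have latent
correlation $\rho^2/(\rho^2 + \sigma_\varepsilon^2)$ — a closed form the
tests check against measured Spearman correlations (the latent-factor
model was chosen over copula sampling precisely for this). The latent
scale maps to TPM through a strictly increasing softplus link with
per-gene shift and lognormal size, which leaves every rank statistic
untouched while producing non-negative, TPM-like magnitudes.

Isoforms split their gene's TPM by Dirichlet usage shares, so
`aggregate_gene_expression()` inverts the generator exactly. *Faithful*
isoforms keep constant shares and are therefore rank-identical to their
gene; *unfaithful* ones share the remaining usage with sample-varying
lognormal weights and decorrelate. Keeping the faithful set's shares
exactly constant (rather than renormalizing all isoforms jointly) matters:
joint renormalization leaks the siblings' usage noise into the principal
isoform and blurs the planted contrast. The principal isoform is faithful
with probability 0.9 and always keeps all gene domains (so the gene's
domain set equals the union over its isoforms); alternatives drop each
domain with probability 0.3. A truth table records which isoform truly
carries each annotated function.

Defaults describe the package's reference study condition: 2,000 genes,
300 samples, 60 terms of 15–40 genes, $\rho = 0.5$ with
$\sigma_\varepsilon = \sqrt{1-\rho^2}$ (unit latent variance), 40% of
terms with 2 dedicated domains planted at true/false positive rates
0.9/0.02 among 120 domains (the rest background at 5% occupancy), isoform
count $1 + \mathrm{Poisson}(2)$ per gene, and ontology labels drawn at
roughly the observed BP/MF/CC proportions of annotation databases
(0.76/0.15/0.09). What the generator does *not* emulate: batch and
tissue structure, library-size artefacts, the GO DAG's
ancestor-propagation dependence between terms, annotation noise, and
read-level quantification uncertainty. Passing tests therefore show the
machinery is correct and the statistical design sound under its own
assumptions — not that real-data performance will match.

## Problem sizes, determinism, degenerate inputs

The test suite exercises the full pipeline at the reference condition
(2,000 genes, 400 held-out) once, property checks on ~150–300-gene
instances, and oracle equivalence on 200 random instances per statistic;
null calibration uses 20 replicates at 300 genes × 80 samples × 20 terms,
sizes chosen so the whole suite stays comfortably interactive. Every
random draw flows from an explicit seed (fold assignment included), and
two runs of one configuration produce byte-identical outputs; the
pipeline's manifest records config, seeds, package version and md5
checksums so this is checkable. Degenerate inputs follow one rule
throughout: impossible requests error with the offender named; undefined
statistics become `NA` with a warning and a count, and are excluded from
summaries rather than imputed.

## Known limitations

Predictions are per-term independent, so logits need not respect GO's
ancestor ordering; no DAG reconciliation is applied. The stacker reports
MAP point estimates without posterior uncertainty. Annotations are taken
as given (no ancestor propagation before filtering), and ontology labels
are optional metadata — per-ontology tables simply disappear when absent.
Domain evidence is limited to binary presence; domain copy number and
architecture are ignored.
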