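---
title: "Modeling multi-batch scRNA-seq counts: batch effects, dropout, and latent cell types"
author: "scBatchMix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multi-batch scRNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scBatchMix)
```

## The model

scBatchMix treats a genes-by-cells matrix of raw counts collected in $B$
batches as arising from a hierarchical zero-inflated negative binomial
mixture. Cell $i$ of batch $b$ carries a latent cell type
$W_{bi} \in \{1,\dots,K\}$ with batch-specific composition
$\Pr(W_{bi}=k)=\pi_{bk}$. Given its type, the *underlying* count of gene
$g$ is negative binomial,

$$X_{big} \mid W_{bi}=k \sim \mathrm{NB}(\mu_{big}, \phi_{bg}),
\qquad \log \mu_{big} = \alpha_g + \beta_{gk} + \nu_{bg} + \delta_{bi},$$

with $\alpha_g$ the log-scale baseline, $\beta_{gk}$ the cell-type effect,
$\nu_{bg}$ the location batch effect, $\delta_{bi}$ the cell-specific size
factor, and $\phi_{bg}$ the overdispersion
($\mathrm{Var} = \mu + \mu^2/\phi$). The observed count $Y$ equals $X$
unless a dropout occurred: $Z_{big}\mid X_{big}=x \sim
\mathrm{Bernoulli}(\mathrm{logistic}(\gamma_{b0} + \gamma_{b1} x))$ and
$Y=0$ whenever $Z=1$. Because the dropout probability depends on the
unobserved count itself (with $\gamma_{b1}<0$: lowly expressed molecules
drop out more), the missingness is *missing not at random*; ignoring it
biases both clustering and differential expression.

Identifiability requires anchors: $\beta_{g1}=0$ (type 1 is the baseline),
$\nu_{1g}=0$ (batch 1 is the reference), and $\delta_{b1}=0$ for the first
cell of every batch. The observed-data likelihood multiplies, per cell, a
mixture over types of per-gene observation probabilities; its zero branch
is the sum of a biological zero and the dropout series
$\sum_{x\ge 1}\mathrm{logistic}(\gamma_{b0}+\gamma_{b1}x)\,f_{NB}(x)$.

### Which designs are identifiable

Batch and type effects are confounded unless batches share enough types.
The package encodes the sufficient conditions as constructable designs:
*complete* (all types everywhere), *reference panel* (one batch has all
types, others at least two), *chain type* (consecutive batches share at
least two types), and the general *connected* design: build the graph
whose nodes are batches and whose edges join batches sharing at least two
types; a connected graph — checked by `checkDesign()` — certifies
identifiability up to label switching, given three standing regularity
conditions: (I) $\gamma_{b1}<0$; (II) every pair of types differs in at
least two genes; (III) effect-difference vectors are distinct across type
pairs. `buildDesign()` refuses presence matrices that violate the named
family, while `custom` accepts anything and lets `checkDesign()` render
the verdict.

## Priors and inference

Inference is fully Bayesian. Compositions get a Dirichlet($\xi$) prior;
$\gamma_{b0}$, $\alpha_g$, $\nu_{bg}$, $\delta_{bi}$ normal priors;
$-\gamma_{b1}$ and $\phi_{bg}$ gamma priors. Differential expression is
encoded by a spike-and-slab prior on $\beta_{gk}$ ($k\ge 2$): a latent
indicator $L_{gk}\sim\mathrm{Bernoulli}(p)$ selects between a spike
$N(0,\tau_{\beta 0}^2)$ (with a small-mean inverse-gamma prior on
$\tau_{\beta 0}^2$) and a wide slab $N(0,\tau_{\beta 1}^2)$,
$\tau_{\beta 1}^2 = 100$ fixed; $p$ gets a Beta prior. Defaults (see
`mixHyper()`) are weakly informative; all are overridable and recorded in
the fit object.

`fitBatchMix()` runs a Metropolis-within-Gibbs sampler whose sweep
updates, in order:

1. **(Z, X) at observed zeros** — drawn *jointly and exactly* from their
   full conditional: the dropout weight is the truncated series above
   (truncation at the smallest count with NB upper-tail mass below
   $10^{-14}$, so the truncation error is certified since the logistic
   factor is bounded by 1), and when the entry is a dropout the underlying
   count is drawn from the normalized series by inverse CDF. We chose the
   exact joint draw over a random-walk refresh of $X$: sampling $Z$ from
   its $X$-marginalized conditional and then only Metropolis-refreshing
   $X$ is a partially collapsed update that is not exactly invariant,
   whereas the exact draw is both correct and cheaper (the series is
   already computed for the $Z$ weight).
2. **W per cell** from its categorical conditional (complete-data NB
   likelihood over genes, in log space).
3. **pi per batch** — conjugate Dirichlet.
4. **gamma per batch** — joint random-walk Metropolis on the logistic
   regression of $Z$ on $X$ over entries with $X>0$ (entries with $X=0$
   carry no information about dropout), rejecting proposals with
   $\gamma_{b1}\ge 0$. Sufficient statistics are bucketed by count value,
   so the update is cheap.
5. **alpha, beta, nu, delta** — per-scalar random-walk Metropolis on
   their full conditionals; **phi** — log-scale random walk with the
   Jacobian correction. Anchored entries are never updated.
6. **(L, beta) jointly** — propose flipping $L_{gk}$ with a fresh
   $\beta_{gk}$ drawn from the proposed component; the component density
   cancels against the proposal, leaving likelihood ratio times the prior
   odds of $L$. This jump move is accepted rarely (a few per mille), by
   design: it is how $\beta$ crosses between spike and slab without
   closed-form marginals.
7. **Recentering of the anchored size factors** — the per-batch location
   of $\delta$ is identified only through each batch's anchor cell, so a
   joint shift of all non-anchor $\delta$ against $\nu$ (or, globally,
   against $\alpha$) is an almost-flat direction that scalar updates
   traverse extremely slowly. Two symmetric Metropolis moves sample it
   directly; only the anchor cells' likelihood terms enter the ratio.
8. **p** and **tau_beta0^2** — conjugate Beta and inverse-gamma.

Proposal scales adapt toward 30% acceptance during burn-in
(Robbins–Monro, frozen afterwards). All randomness flows through R's RNG:
a run is bit-reproducible given `seed`, and chain $c$ derives the sub-seed
$(\mathrm{seed} + 95279(c-1)) \bmod (2^{31}-1)$.

### Initialization and warm start

Chains initialize from the data: k-means on *batch-centered* log1p
library-size-scaled expression (centering per gene within batch, so that
additive batch effects do not drive the initial partition); $\alpha$ from
log means of nonzero counts; $\beta$ from cluster-contrast log means on
the centered scale (thresholded at 0.5 so the spike-and-slab state starts
sparse); $\nu$ from batch-contrast log means; $\delta$ by median-of-ratios
against the (batch, cluster) mean profile, so type effects cancel out of
the ratios; $\phi$ by per-(batch, gene) method of moments floored
at 0.1; zeros are provisionally declared dropouts with probability one
half with a shifted-NB imputation. During the first `wFreeze` burn-in
sweeps (default 100) the labels are held fixed while all parameters adapt
to the initial partition; without this warm start the first label update
would be driven by the crude initial parameters and can destroy a good
initialization irrecoverably. A purely zero initialization of $\beta$ is
unusable for the same reason: with $\beta \equiv 0$ all types have
identical likelihood and the first label sweep randomizes the partition.

### Choosing among candidate initial partitions

The sweep has no split–merge move, so a chain started in a mode where two
cell types are fused into one component — typical when the two types
never co-occur in a batch and must be told apart through the batch-effect
bridge of shared types — tends to stay there. k-means alone is an
unreliable guard: its within-cluster sum of squares often *prefers* the
fused mode, because splitting one large overdispersed type reduces WSS
more than separating two small distant ones. `initializeChain()`
therefore generates several candidate partitions (one multi-start
k-means, a set of single-start runs, and an overclustered K+3 solution
merged down to K by beam search) and ranks them with a label-invariant
model-based score: a short Poisson backfit alternating shared per-gene
batch multipliers (the cross-batch bridge) with per-(gene, type)
profiles, evaluated by the negative binomial log likelihood at a common
per-gene method-of-moments dispersion estimated from the overclustered —
least fused — grouping. Because that static score can misrank closely
competing partitions, `fitBatchMix()` then gives the top candidates
(default 3) a short frozen-label *pilot run* (default 60 sweeps) each, in
which every parameter block adapts to the fixed partition, and keeps the
candidate with the best observed-data log likelihood: the model itself
arbitrates. The practical symptom of a residual fused mode, should one
survive, is a near-empty extra cluster and a non-monotone log-likelihood
column in `selectK()` tables.

## Posterior summaries and downstream reports

`summarizePosterior()` aligns chains by their posterior-mode labels
(exact assignment by permutation enumeration for $K \le 8$), working on
the label-switching-invariant scale $\theta_{gk} = \alpha_g + \beta_{gk}$
and re-baselining afterwards. Continuous parameters are posterior means;
cell types are per-cell posterior modes; $\xi_{gk} = \Pr(L_{gk}=0\mid y)$
is the fraction of retained draws with $L_{gk}=0$.

**Imputation.** An observed zero is *called* a dropout when its posterior
dropout probability exceeds one half; at called entries the imputed count
is the rounded posterior mean of the $X$ draws conditional on $Z=1$ (the
mean minimizes squared error; conditioning avoids averaging in biological
zeros). Everywhere else the imputed count equals the observed one. The
majority-vote call keeps the reported per-batch dropout rate
$\rho_d$ — the proportion of *inferred* dropouts among observed zeros — an
interpretable posterior quantity rather than a count of entries that ever
sampled $Z=1$.

**Intrinsic genes.** The Bayesian FDR of a threshold $\kappa$ is the mean
of the $\xi_{gk}$ at or below $\kappa$ among those called. The search
takes candidate thresholds from observed $\xi$ values up to the cap 0.5
and selects the largest with estimated FDR strictly below the level
(default 0.05); genes with at least one called type effect are intrinsic.

**Convergence.** With two or more chains, `computeEPSR()` computes the
classic potential scale reduction
$\hat R = \sqrt{(\tfrac{n-1}{n}W + \tfrac{B}{n})/W}$ per scalar for three
monitored groups — $\theta_{gk}$, $\nu_{bg}$, $\phi_{bg}$ — and declares
convergence when more than 80% of each group falls below 1.3. Identical
chains give $\hat R = \sqrt{(n-1)/n} \approx 1$.

**Model selection.** `computeBIC()` evaluates
$-2\log L_o(\hat\Theta) + [K(B+G) + 2B + (2B-1)G + \sum_b(n_b-1)]
\log(\sum_b n_b G)$ at the posterior means; `selectK()` fits a range of K
and returns the argmin with the full table. The observed likelihood uses
the same certified-truncation zero kernel as the sampler.

**Posterior predictive check.** `dropoutReport()` simulates replicate
datasets from retained parameter draws (an evenly strided subset,
`ppcDraws`) and compares the replicate zero rate per batch with the
observed one; a reduced no-zero-inflation variant of the whole model
(`variant = "nzf"`, which fixes $Z\equiv 0$ and skips the dropout
updates) is available as the natural comparator.

## Batch-effects-corrected counts

`correctCounts()` maps each entry's imputed count through quantile
matching: draw $u$ uniformly from
$(F_{\mathrm{src}}(\hat x - 1), F_{\mathrm{src}}(\hat x)]$ under the
fitted source distribution
$\mathrm{NB}(\exp(\hat\alpha_g+\hat\beta_{g\hat w}+\hat\nu_{bg}+\hat\delta_{bi}),
\hat\phi_{bg})$, then return the $u$-quantile of the batch-free target
$\mathrm{NB}(\exp(\hat\alpha_g+\hat\beta_{g\hat w}), \hat\phi_{1g})$ — the
reference batch's overdispersion. Because $u$ is uniform over the CDF
interval, every integer whose target mass overlaps the interval is
attainable in proportion to the overlap, avoiding the bias of always
taking the minimum or maximum; when source and target coincide the map is
exactly the identity. The interval is half-open with $F(-1)=0$: a
measure-zero choice that cannot change distributions but makes the
identity case exact and the $\hat x = 0$ case well defined. The output is
integer counts free of batch effects and dropout zeros that need no
further cell-specific normalization.

## The simulator

`simulateTruth()` + `simulateData()` generate from exactly the model
above under any valid design, returning the full ground truth (X, Z, W,
all parameters, the DE gene set). Defaults are calibrated to the regime
multi-batch scRNA-seq studies report: baseline $\alpha\sim N(2,1)$;
each intrinsic gene (a configurable count) draws an independent log-scale
expression *level* per cell type from the symmetric four-point grid
$\{-3,-2,+2,+3\}$ — high, medium-high, medium-low, low — and the type
effect is the level contrast against the baseline type, so most differing
type pairs contrast by several log units at that gene; batch effects
$\nu \sim N(0, 2^2)$, at or above the scale
of the type effects; size factors $N(0, 0.5^2)$ anchored per batch;
$\phi \sim U(2,6)$; dropout intercepts $U(-0.6, 0.2)$ and slopes
$U(-0.25, -0.08)$. These settings give overall zero rates around 40–60%
with roughly a quarter to a half of zeros being dropouts. Draws are
repeated until condition (II) holds; condition (III) holds almost surely
for continuous draws (an explicit audit exists, off by default). A
realization from these defaults, not any real dataset, is what the test
suite and the acceptance script measure — passing them shows the method
recovers *its own model's* structure at the stated sizes; it does not
show robustness to model misspecification, ambient RNA, doublets, or
UMI-specific artifacts, which real data exhibit and the model does not
encode.

Compositions default to a seeded Dirichlet (concentration 5) over each
batch's present types; `buildDesign(..., pi = "balanced")` instead
equalizes expected cells per type across the study (iterative
proportional fitting blended with the uniform composition so no batch
degenerates to one type). The packaged checks pass explicit uniform or
balanced compositions rather than Dirichlet draws, because at desk-scale
batch sizes a Dirichlet realization can leave a present type with fewer
than ten cells, a regime the reference studies' simulations do not
enter; the K-selection check uses the balanced form since resolving K by
BIC requires every type's block to carry comparable evidence.

## Problem sizes used by the checks

The packaged checks run at deliberately scaled-down sizes chosen to keep
the full suite in the tens of minutes on one CPU: clustering and K
selection on a four-batch, five-type chain design with $G=500$ genes and
$n=(120,120,80,80)$ cells at 2000 iterations (1000 burn-in; $G=300$ and
1200 iterations for the K-selection sweep over $K=3..7$); FDR control
with 50 DE genes among 500 over five replicate simulations at the same
batch sizes and 800 iterations; parameter recovery on a two-batch,
three-type chain at $G=500$, $n=(200,200)$ and 600 iterations. Full-size
analyses simply scale these numbers up.

## Known limitations

* $K$ label alignment enumerates permutations exactly only for
  $K \le 8$; beyond that a greedy assignment is used.
* The nzf variant retains the full BIC penalty formula (including the
  dropout parameter count), so nzf-vs-full BIC comparisons are slightly
  conservative against the full model.
* Multi-chain summaries assume chains individually do not label-switch
  (true in practice for separated types); alignment is across chains, not
  within.
* No split–merge move (see above); at very small gene counts prefer the
  reference-panel design or more genes.
```
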