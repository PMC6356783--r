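---
title: "Feature-conditioned labeled topic models for gene function prediction"
author: "dmrllda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-conditioned labeled topic models for gene function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrllda)
```

## The model

A gene's protein sequence is tokenized into amino-acid blocks (k-mers) over
the 20-letter alphabet, giving a bag of words per gene; each Gene Ontology
term is a topic, and the label/topic spaces are identified one-to-one, so a
gene's admissible topics are exactly its annotated labels (the binary mask
$\Lambda_d$).  The departure from plain labeled LDA is the prior on the
gene–topic weights $\pi_d$: instead of a shared constant, each gene's
Dirichlet hyper-parameters are log-linear in its observed feature vector,

$$\alpha_{dt} = \exp(\hat y_d \hat\beta_t^\top),\qquad
\pi_d \sim \mathrm{Dir}(\alpha_d \odot \Lambda_d),$$

where $\hat y_d$ appends a constant default feature (value 1) whose weight
column serves as a per-topic intercept absorbing the overall concentration
scale.  Topics carry word distributions $\theta_t \sim \mathrm{Dir}(\lambda)$
and feature weights $\hat\beta_t \sim N(\mu, \sigma^2 I)$.  Tokens draw a
topic from $\pi_d$ and a word from $\theta$ of that topic.

Collapsing $\pi$ and $\theta$ yields the usual Dirichlet-multinomial
evidence, from which all three inference engines work:

* **CGS** resamples every token's topic from
  $p(t) \propto (\alpha_{dt} + N_{dt}^{\setminus dn})\Lambda_{dt}
  \,(\lambda_w + N_{tw}^{\setminus dn})/(\textstyle\sum_w \lambda_w +
  N_t^{\setminus dn})$ with the token removed from all counts (compiled
  inner loop; R's RNG so a seed fixes the chain).
* **CVB0** keeps per-(gene, word-type) responsibilities $\eta_{dwt}$ and
  iterates the zero-order update
  $\eta_{dwt} \propto (\alpha_{dt}\Lambda_{dt} + \gamma_{dt})
  (\lambda_w + \mu_{tw})/(\sum_w\lambda_w + \mu_t)$, where the expected
  counts use the word-type self-exclusion weight $(N_{dw}-1)$:
  $\gamma_{dt} = \sum_w (N_{dw}-1)\eta_{dwt}$ and likewise for
  $\mu_{tw}, \mu_t$.
* **CVB** multiplies each zero-order factor by the second-order correction
  $\exp\{-v/(2(a+m)^2)\}$ of the expected log count, with mean $m$ and
  variance $v$ of the excluded count.  The variance accumulators are the
  sums of per-assignment Bernoulli variances,
  $v = \sum (N_{dw}-1)\,\eta\,(1-\eta)$; the per-term alternatives
  sometimes written with an extra count factor can turn negative (e.g. a
  $\gamma(1-\gamma)$ form once $\gamma > 1$), which would invalidate the
  expansion, so the Bernoulli-sum form is used for all three statistics.

Point estimates smooth the (expected) counts:
$\hat\pi_{dt} \propto \alpha_{dt}\Lambda_{dt} + \mathbb{E}[N_{dt}]$ and
$\hat\theta_{tw} \propto \lambda_w + \mathbb{E}[N_{tw}]$.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| $\lambda$ | topic–word Dirichlet | $200/W$ | smooths rare words in proportion to vocabulary size |
| $\alpha_0$ | initial flat concentration | $50/T$ | the conventional starting point; quickly overridden by the learned weights |
| $\mu, \sigma^2$ | Gaussian prior on $\hat\beta$ | $0, 1$ | weak shrinkage toward feature-free behaviour |
| CGS schedule | sweeps / burn-in / record interval | 2000 / 1000 / 50 (20 records) | single chain; records averaged for the estimates |
| fold-in schedule | sweeps / burn-in / interval | 1000 / 500 / 50 | global parameters fixed; only $\pi_d$ is inferred |
| local loop (CVB/CVB0) | stopping rule | $(1/N_d)\sum_t |\Delta\gamma_{dt}| < 10^{-5}$, cap 100 | per-gene fixed point is cheap and converges fast |
| global loop | cap / early stop | 1000 passes / gene-averaged change $< 10^{-4}$ | the cap alone leaves no quantitative stopping rule, so the same change measure, averaged over genes, closes the loop |
| clip | bound on $\log\alpha$ | $\pm 30$ | guards gamma/digamma calls against un-standardized features |

Feature columns are z-scored by default (constant columns map to zero);
the transform is stored in the fitted model and re-applied verbatim to test
genes — raw features such as molecular weight ($\sim 5\times10^4$) would
otherwise overflow $\exp(y\beta^\top)$.

## Optimizing the feature weights

The weights maximize the collapsed evidence term
$\log F(\hat\beta) = -\sum_{t,f}(\beta_{tf}-\mu)^2/2\sigma^2 + \sum_d
\big[\log\Gamma(A_d) - \log\Gamma(A_d+N_d) + \sum_t
(\log\Gamma(a+n)-\log\Gamma(a))\big]$ over the label-masked terms.  Setting
the gradient to zero suggests the fixed point $\beta_{tf} \leftarrow \mu +
\sigma^2\sum_d y_{df}\,\alpha_{dt}\Lambda_{dt}\,[\psi(A_d)-\psi(A_d+N_d)+
\psi(a+n)-\psi(a)]$.  That map is not a contraction — on small instances
the undamped iteration oscillates with order-1 steps, and even a damped,
objective-monitored version cycles near the optimum.  `update_beta`
therefore runs a short damped, monitored fixed-point warm start and then
maximizes the objective directly by BFGS with the analytic gradient; the
accepted objective trace is non-decreasing by construction and the result
is a stationary point to high precision.  During Gibbs training the
optimization is interleaved every 20 sweeps from sweep 100 on (early counts
are too noisy to be worth fitting); each variational global pass re-runs it
on the expected counts.

## The synthetic generator

`sample_model()`/`sample_corpus()` forward-sample the generative process
exactly as written above, returning both the observable corpus and the
ground truth ($\theta$, $\hat\beta$, $\pi$, per-token assignments).
`sim_scenario()` fixes the default study conditions used by the tests:
$T=5$ topics, $W=30$ words, $F=2$ standard-normal features, $D=200$ genes
of $N_d=100$ tokens, label sets of size $1+\mathrm{Binomial}(2, 0.5)$.
The true intercept column is 0 and feature weights are unit scale, so the
realized $\alpha$ span roughly $0.1$–$5$: the magnitude regime that trained
feature-conditioned priors occupy on real gene data, where the prior
informs but does not overwhelm a 100-token document.

Two label regimes are provided.  Under `label_mode = "uniform"` the label
sets are drawn independently of the features; features then shape the
weights *among* a gene's labels but carry no information about which labels
it has.  Under `label_mode = "feature"` labels are drawn with probability
proportional to the gene's $\alpha$ row, emulating real annotation, where
biophysical features correlate with function membership itself.  The
distinction matters for what experiments can show: a feature-conditioned
prior can only improve *label ranking* of unannotated genes when the
features are informative about the label set, so the feature-benefit
comparison (below) uses the feature-coupled regime; under the uniform
regime the feature prior is pure ranking noise at test time and plain LLDA
is the better predictor.  Neither regime emulates real protein sequences,
GO-hierarchy structure, or correlated annotations — passing recovery tests
here demonstrates correctness of the inference machinery, not real-data
performance.

## Prediction, evaluation, label compression

For an unannotated gene, the label support defaults to all labels and
$\alpha_d$ comes from the gene's own features through the trained weights;
$\pi_d$ is inferred by fold-in Gibbs or the CVB0 local loop with
$\hat\theta$ fixed.  Scores are binarized either at the uniform level $1/L$
(inclusive, so flat scores switch every label on) or at a single global
threshold tuned by exhaustive scan to maximize micro-F1 on training-fold
predictions — both are provided because reported F1 values in this
literature rarely state their thresholding rule.  Average precision uses
the standard multi-label ranking form; the precision–recall areas use the
step-wise (non-interpolated) estimator with ties broken by stable label
index, in macro, pooled and frequency-weighted variants.  Labels with no
positive gene are excluded from the macro mean; genes with no true label
are excluded from the ranking metrics, with counts reported.

The optional Boolean matrix decomposition compresses a large label matrix
as $Y = C \circ B$ before training: the basis is a greedy exact cover over
distinct row patterns (a pattern is pruned when it is the Boolean OR of the
retained patterns it contains, heaviest first, so the result is
deterministic), and exactness is verified cell-for-cell.  Binary
predictions are recovered through $B$ by Boolean product; real-valued
scores by max-product, which preserves rankings.  Compression is off by
default — the model is fully functional on the raw label space.

## Numerical conventions and experiment sizes

Categorical draws use inverse-CDF on the normalized conditional; update
order is documents then vocabulary index, making every engine bit
reproducible given a seed.  Degenerate inputs: a training gene with no
label is an error; a constant feature column standardizes to zeros; an
empty record list is an error rather than a silent prior-only estimate.
The recovery experiments train on the default scenario above (both CGS at
its full 2000-sweep schedule and CVB0 to global convergence finish in well
under a minute); the feature-benefit comparison uses five seeds with a
150/50 train/test split and a 600-sweep chain per fit, a size chosen so
the whole comparison completes in a few minutes while the direction of the
effect is stable across seeds.  The local/global variational tolerances
above are the ones the stopping-rule tests assert.

## Known limitations

The CVB variant follows the word-type collapsed parameterization
throughout, so documents in which every word occurs once have zero
exclusion weights and its local statistics vanish; CVB0 and CGS are the
recommended engines (and CVB0's recovery matches CGS at equal budget on
the default scenario).  The BMD basis search is greedy and only verified
optimal on small instances; no GO-hierarchy (true-path) reasoning is
performed; and multi-chain Gibbs diagnostics are out of scope — the single
recorded chain follows the conventional schedule.
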