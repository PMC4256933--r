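---
title: "Bayesian neural networks for epistasis detection: models and methods"
author: "epibnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian neural networks for epistasis detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibnn)
```

## The problem

Case-control association studies ask which of many genotyped SNPs influence
disease status. Marginal single-SNP tests miss loci that act mainly through
gene-gene interaction (epistasis), while exhaustive interaction scans and
permutation-based significance become computationally infeasible beyond a few
hundred SNPs. `epibnn` takes a model-based route: a small neural network can
represent arbitrary genotype-phenotype relationships, including pure
interactions, and a Bayesian treatment of its weights yields a per-SNP
relevance measure with uncertainty, so significance can be assessed without
permutation.

## The model

For subject $i$ with inputs $x_i$ (minor-allele counts $0/1/2$, one column
per SNP, optionally followed by covariates), the network has one hidden
layer of $h$ logistic units and a two-unit softmax output:

$$h_k(x_i) = \phi\!\Big(b_k + \sum_{j} w_{kj} x_{ij}\Big), \qquad
  \phi(z) = \frac{1}{1+e^{-z}},$$

$$f_1(x_i) = \psi\!\Big(B_1 + \sum_k W_{k1}\, h_k(x_i)\Big),$$

with $\psi$ the softmax, so $f_2 = 1 - f_1$ exactly. The likelihood is
binomial, $\ell = \sum_i y_{i1}\log f_1(x_i) + y_{i2}\log(1 - f_1(x_i))$.
Class probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ before the
logarithm so extreme states cannot produce an infinite deviance; the
gradient uses the exact softmax expression.

**ARD prior.** All hidden-layer weights attached to the same input column
form a group with a shared zero-mean Gaussian prior,
$w_{\cdot j} \sim N(0, \sigma_j^2)$, and each group variance has an
Inverse-Gamma prior $\sigma_j^2 \sim IG(\alpha_0, \beta_0)$ (default
$\alpha_0 = 5$, $\beta_0 = 2$). An irrelevant SNP's weights are shrunk
toward zero and its posterior $\sigma_j^2$ concentrates on small values; a
relevant SNP needs large weights and drags $\sigma_j^2$ upward. This is the
automatic relevance determination mechanism. The output weights share one
variance with an $IG(0.1, 0.1)$ hyperprior — we read the
"Gaussian prior" hyperparameters $\alpha_0 = 0.1,\ \beta_0 = 0.1$ as the
Inverse-Gamma parameters of that shared variance, parallel to the ARD
structure, since no other reading gives them a role. Biases (hidden and
output) receive a fixed-variance Gaussian prior (variance 100) and belong
to no group; covariate columns, when present, form a single shared group
and are excluded from the relevance test.

Inputs are used as raw allele counts by default (`standardize = FALSE`):
each SNP then owns exactly $h$ hidden weights on a common scale, which is
what makes the group variances comparable across SNPs.

## Sampling

Weights are updated by Hamiltonian Monte Carlo: a leapfrog trajectory of
$L = 15$ steps guided by the gradient of the log posterior, followed by a
Metropolis accept/reject on the total energy. Momentum is only partially
refreshed between trajectories, $p \leftarrow \alpha p +
\sqrt{1-\alpha^2}\,\xi$ with persistence $\alpha = 0.75$, and is negated on
rejection, which preserves reversibility of the persistent-momentum chain.
After each trajectory the group variances are updated by one conjugate
Gibbs sweep: with $m_j$ weights of sum-of-squares $SS_j$ in group $j$,

$$\sigma_j^2 \mid w \;\sim\; IG\!\big(\alpha_0 + m_j/2,\; \beta_0 + SS_j/2\big).$$

The default run performs $T = 5000$ HMC iterations and records every 40th
state ($T / (25 + 100)$), giving 25 burn-in and 100 kept draws — the kept
draws are the inference sample. Weights are initialised from $N(0, 0.01^2)$
and variances at their prior mean (or $\beta_0/\alpha_0$ when
$\alpha_0 \le 1$, where the prior mean does not exist).

**Step-size adaptation.** The leapfrog integrator is stable only below a
step size set by the stiffest curvature of the log posterior, which grows
with the sample size: at $n = 2000$ a fixed step of $0.05$ sits beyond the
stability limit and the chain rejects essentially every proposal, while
$0.02$ mixes well. Because a frozen chain cannot produce calibrated
relevance probabilities, the sampler treats the configured `step_size`
(default $0.05$) as an initial value and tunes it by dual averaging toward
a target acceptance rate of $0.8$ during the burn-in iterations only,
freezing the averaged value before any kept draw is recorded. The kept
sample therefore comes from a valid fixed-step-size chain; the adapted
value is reported in the fitted object (`step_size_used`) and typically
lands near $0.02$–$0.03$ on 2,000-subject datasets. Setting
`adapt_step_size = FALSE` recovers a fully fixed-step sampler.

All randomness flows through R's RNG; a fitted chain is bit-reproducible
from its seed.

## The ARD significance test

For each kept draw $t$, SNP $j$'s relevance is $\mu_j^{(t)} =
\sqrt{\sigma_j^{2(t)}}$ — the square root tames the heavy right tail of
Inverse-Gamma draws. The null reference is the *average SNP* in the same
draw, $\mu_{null}^{(t)} = \tfrac1p \sum_j \mu_j^{(t)}$, so no extra model
fit is needed. The reported probability is

$$\Pr(\mu_j > \mu_{null}) = \frac{1}{T_{kept}} \sum_t
  \Big[\mathbb{1}\{\mu_j^{(t)} > \mu_{null}^{(t)}\} +
  \tfrac12 \mathbb{1}\{\mu_j^{(t)} = \mu_{null}^{(t)}\}\Big],$$

ties counting one half to avoid order dependence. SNP $j$ is declared
significant at cutoff $c$ when $\Pr(\mu_j > \mu_{null}) > c$: at the
default $c = 0.6$ a SNP must beat the average SNP in more than 60% of
posterior draws. The skew of the relevance values within a draw places the
cross-SNP mean above the typical SNP, so an exchangeable noise SNP exceeds
$\mu_{null}$ in only about 40% of draws; strongly causal SNPs exceed it in
essentially all draws. The gap between the noise bulk ($\approx 0.4$) and
the threshold ($0.6$) is what keeps the false-positive rate of the test in
the $10^{-3}$–$10^{-1}$ range across designs, while the distance to 1
costs little power. The endpoints are closed for sweeping: $c = 0$ flags
every SNP and $c = 1$ flags none.

Two design choices here deserve comment, because the relevance statistic
and its null are the least pinned-down part of the method. First, $\mu_{null}$ is the within-draw average SNP; an
alternative (`null = "prior"`) compares against the prior-median relevance
of a hypothetical irrelevant SNP, but in practice the posterior for noise
SNPs in moderate-dimensional fits straddles the prior reference and the
test loses specificity, so the self-calibrating average-SNP null is the
default. Second, the cutoff is applied to the probability directly
(`Pr > c`). The alternative reading — significant when `Pr > 1 - c`, which
makes a *low* cutoff conservative — places the threshold at $0.4$,
directly inside the noise bulk, and flags roughly half of all null SNPs in
every fit regardless of signal; it cannot reproduce the calibrated
false-positive behaviour that motivates the test, so the direct reading is
used even though verbal descriptions of the cutoff's endpoint behaviour
sometimes suggest the complementary one.

`roc_sweep()` modulates the cutoff from 0 to 1 in increments of 0.01 (101
grid points), averages true- and false-positive rates across datasets, and
integrates the curve by the trapezoidal rule; the closed endpoints pin the
curve to $(1,1)$ at $c = 0$ and $(0,0)$ at $c = 1$.

## Simulators

**Two-locus relative-risk models.** `risk_table()` reproduces the additive
(risk $\eta(1+\theta(m_A+m_B))$ in the minor-allele counts), threshold
(risk $\eta(1+\theta)$ once both loci carry a minor allele) and epistatic
(risk concentrated on the AA/bb, aa/BB corners and the Aa/Bb centre)
models. Genotypes at the two causal loci follow Hardy-Weinberg proportions
at a common MAF; disease status is sampled retrospectively under the
rare-disease approximation — case genotype pairs with probability
$\propto P(g)\,RR(g)$, control pairs $\propto P(g)$ — so the baseline
$\eta$ cancels and only relative risks matter. Background SNPs are
independent HWE draws with per-SNP MAFs uniform on $[0.05, 0.5]$ (the
study design leaves background frequencies unspecified; a uniform spread
over common variants is the conventional neutral choice). Causal columns
are placed at random, seeded positions. The default design is 1,000 cases,
1,000 controls and 998 background SNPs.

**Purely epistatic penetrance tables.** `pure_epistatic_table()` searches
for an absolute-penetrance table whose single-locus marginal penetrances
are constant (so neither locus has any marginal effect and all signal is
interaction) and whose broad-sense heritability
$h^2 = \sum_g P(g)(f_g - K)^2 / K(1-K)$ hits the target exactly. A random
$3\times3$ deviation table is projected onto the zero-marginal subspace
(HWE-weighted row means, then column means removed — one pass of each is
exact), scaled to the target variance around a prevalence $K$ drawn from
$[0.1, 0.4]$, and rejected if any entry leaves $[0,1]$. The construction
makes both constraints exact up to floating point; the generator leaves
prevalence free. Cases are drawn $\propto P(g) f_g$ and controls
$\propto P(g)(1 - f_g)$.

What these simulations do *not* emulate: linkage disequilibrium between
SNPs, missing genotypes, genotyping error, or population structure. A pass
on them shows the method detects the programmed signal under independence,
not that it is robust to those real-data features (covariate adjustment is
available for structure, as in the real-data analysis the design follows).

## Baseline and entropy web

The comparator is the Pearson $\chi^2$ test on each SNP's $2\times3$
phenotype-by-genotype table (2 df), Bonferroni-corrected at family-wise
$\alpha = 0.05$. Genotype categories with expected count below 1 are
collapsed into their neighbour (reducing the degrees of freedom) rather
than continuity-corrected; monomorphic SNPs return statistic 0 with a
warning.

For a selected SNP subset, `build_entropy_web()` reports each SNP's
main-effect information $100\, I(SNP; Y)/H(Y)$ and each pair's interaction
information $100\, I(A;B;Y)/H(Y)$, where $I(A;B;Y) = I(A,B;Y) - I(A;Y) -
I(B;Y)$; positive values are synergy, negative redundancy. Estimates are
plug-in maximum-likelihood values in bits, without small-sample bias
correction, matching the convention of the interaction-web literature this
display follows. Normalisation by the phenotype entropy is the default and
can be switched off (`normalize = FALSE`), since the percentage convention
is not universal.

## Numerical and design notes

* Probability clamp $10^{-12}$; non-finite gradients abort a trajectory and
  count as a rejection.
* The Gibbs full conditionals are sampled as $1/\text{Gamma}(\alpha,\text{rate}=\beta)$.
* Thinning is $\lfloor T/(burn+kept) \rfloor$; the chain runs exactly
  $thinning \times (burn + kept)$ iterations, so the default $T = 5000$
  yields 125 recorded states.
* Per-replicate seeds in the experiment harness are a deterministic hash of
  the master seed, cell coordinates and replicate index, so cells can be
  run independently and out of order.
* The power harness scores a replicate as a success only when *both*
  causal SNPs are significant; the false-positive rate is the mean fraction
  of the non-causal SNPs flagged.

## Problem sizes used by the test suite

A full-scale power study (thousands of 1,000-SNP datasets at 100
replicates per grid cell) is a cluster-scale computation. The package's own checks run a reduced but structurally
identical version: the additive-model power check uses 2 replicate
1,000-SNP datasets (1,000 cases/1,000 controls, $\theta = 1$, MAF 0.2) at
the full sampler settings, the pure-epistasis false-positive check uses 10
datasets of 50 SNPs, and `scripts/acceptance.R` recomputes the
pure-epistasis false-positive rate over the full study grid,
$h^2 \in \{0.05, 0.10\} \times$ MAF $\in \{0.05, 0.1, \dots, 0.5\}$, one
dataset per cell. Properties of the
integrator, the conjugate updates, the simulators, the $\chi^2$ baseline
and the information measures are checked exactly or against independent
oracles at small sizes.

## Known limitations

* One hidden layer, logistic activations, two classes only.
* Single chain; convergence diagnostics are limited to the acceptance rate
  and log-posterior trace.
* The ARD probability is relative to the dataset's own average SNP: in a
  dataset where *most* SNPs are causal the null reference is itself
  inflated and the test loses calibration.
* Hyperparameters $(\alpha_0, \beta_0)$ are fixed user inputs, not sampled.
* The pure-epistasis generator enforces its design constraints (flat
  marginals, target heritability) exactly, but is not a byte-level
  re-implementation of the external GAMETES tool.
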