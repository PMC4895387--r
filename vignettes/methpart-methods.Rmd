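---
title: "The methpart model: a Bayesian partition approach to three-way differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The methpart model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpart)
```

## The model and its assumptions

Bisulfite sequencing gives, per CpG locus $i$, replicate $j$ and condition
$k$ (1 = case, 2 = control), a methylated count $M_{ijk}$ out of coverage
$C_{ijk}$.  `methpart` assumes

$$M_{ijk} \mid C_{ijk}, p_{ik} \sim \mathrm{Binomial}(C_{ijk}, p_{ik}),$$

i.e. a common true methylation proportion per locus and condition (no
replicate-level biological variation — see Limitations).  Loci are
partitioned by a latent label $I_i \in \{0,1,2\}$:

* **equal** ($I_i=0$): $p_{i1}=p_{i2}$, one shared proportion with a
  $\mathrm{Beta}(\alpha_1,\beta_1)$ prior;
* **hypo** ($I_i=1$): $p_{i1}<p_{i2}$, independent
  $\mathrm{Beta}(\alpha_2,\beta_2)$ priors truncated to the ordered
  region, density $2 f(p_{i1}) f(p_{i2}) 1(p_{i1}<p_{i2})$;
* **hyper** ($I_i=2$): the mirror image with shapes
  $(\alpha_3,\beta_3)$.

Conjugacy integrates the proportions out exactly.  Writing
$N_{ijk}=C_{ijk}-M_{ijk}$ and pooling within conditions, the per-locus
collapsed marginal is a ratio of Beta functions for the equal group, and
for the directional groups one Beta-function ratio per condition times an
order-probability factor $2\,P(X<Y)$ (hypo; $2\,P(X>Y)$ for hyper), where
$X \sim \mathrm{Beta}(\alpha_2+\sum_j M_{ij1},\, \beta_2+\sum_j N_{ij1})$
and $Y$ is the control analogue.  This order probability is where the
directional evidence lives: symmetric data give exactly $1/2$, strongly
ordered data push it towards 0 or 1.

The membership vector has a multinomial$(\pi)$ prior whose probability
vector carries a Dirichlet$(k_0,k_1,k_2)$ prior; integrating $\pi$ out
yields a Dirichlet-multinomial partition prior that depends only on the
group counts $(l_0,l_1,l_2)$.  This is the coupling through which the
model borrows strength: the genome-wide abundance of each group
re-weights every locus's posterior, which is what gives the method its
power advantage at two replicates per condition.

The truncated ordered priors use the constant 2 as printed in their
definition.  For $\alpha=\beta$ (including the all-ones default) this is
the exact normalising constant; for $\alpha\neq\beta$ the exact constant
would be $1/P(p_1<p_2)$ under the untruncated product prior, which
deviates from 2.  We keep the constant 2 in all cases: it cancels from
nothing (it scales the directional marginals), but the all-ones default
is the only configuration we advertise.

An indicator-function reading of the equal-group prior would put its mass
on a measure-zero diagonal; the implementation uses the evident intent, a
single shared proportion, which the equal-group collapsed marginal
(pooling both conditions into one Beta ratio) confirms.

## Hyperparameters

All nine hyperparameters default to 1 — flat Beta priors on proportions
and a flat Dirichlet on the partition probabilities — the non-informative
choice.  They are exposed through `hyperparameters()`; all must be
strictly positive.  Binomial coefficients are identical across the three
group hypotheses of a locus and cancel in every posterior ratio, so
cached marginals exclude them (`include_coefficients = TRUE` restores
them for comparison against direct numerical integration).

## Sampling

The posterior over $\boldsymbol I$ is explored by Metropolis–Hastings
with two kernels, chosen with probability $1/2$ each:

* **relabel** — pick a non-empty group uniformly, a locus in it
  uniformly, and one of the two alternative labels uniformly;
* **exchange** — pick an unordered pair of distinct non-empty groups
  uniformly, one locus from each uniformly, and swap their labels.

When fewer than two groups are non-empty the relabel move is forced.
Group selection is restricted to non-empty groups, so the Hastings ratio
must (and does) account for the number of non-empty groups changing
across a relabel move; exchange moves leave all group sizes unchanged and
have unit Hastings ratio.  The acceptance probability is the standard
$\min\{1, \text{posterior ratio} \times \text{transition ratio}\}$.

Because the likelihood factorises over loci given $\boldsymbol I$, the
three collapsed log marginals per locus are precomputed once and every
proposal is evaluated in $O(1)$ from cached differences plus the change
in the Dirichlet-multinomial term.  The sampler's inner loop is compiled
(C++), uses R's RNG (a run is bit-reproducible given a seed), and fixes
the draw order per proposal: move type, group or pair index, locus
index/indices, alternative label (relabel only), acceptance uniform.

**Chain length and summarisation.**  One *sweep* is $L$ proposals
($L$ = number of loci).  Defaults: 2,000 sweeps, the first 50 % discarded
as burn-in, one membership snapshot recorded per post-burn-in sweep, no
thinning.  Posterior membership probabilities are the snapshot
frequencies over the common denominator, and each locus is called as its
highest-posterior group.  Exact ties are resolved conservatively to the
equal group — including a hypo–hyper tie, since a directional claim
without a strict winner is not defensible.  Initialisation is
uniform-random by default; all-equal and user-supplied starts are
available, and the two defaults agree within Monte-Carlo error on the
test fixtures, consistent with the inference being robust to the start.

**Numerical choices.**  All probability arithmetic is in log space
through `lgamma`/`lbeta`.  The order probability $P(X<Y)$ uses an exact
finite sum for integer shapes when both shape totals are at most 50
(covering typical RRBS-scale pooled counts at default priors) and
adaptive quadrature of $f_X(t)\,(1-F_Y(t))$ to absolute tolerance
$10^{-10}$ otherwise; it is clamped to $[10^{-300}, 1-10^{-16}]$ before
the log so that strongly anti-ordered data cannot produce an infinite
Metropolis–Hastings ratio.  Replicates with zero coverage contribute
empty factors, the natural limit of the collapsed marginals; loci with
zero pooled coverage in a condition are removed by the pre-analysis
filter instead.

## Pre-analysis filter

`filter_uninformative_loci()` removes loci that cannot carry differential
signal: every covered sample fully methylated, every covered sample
unmethylated, or zero pooled coverage in one condition.  The three
categories are counted separately so that real-data-style filtering
summaries can be reconstructed.

## Baselines

The package implements the two frequentist comparators as plain,
dependency-free versions of their common forms: the pooled two-proportion
$z$-test, and a per-locus binomial GLM with a condition indicator tested
by Wald (falling back to a likelihood-ratio test under separation).  The
GLM is deliberately the plain binomial logistic regression rather than a
wrapper around any particular package, so it runs on synthetic fixtures
with no external dependencies; an optional per-sample minimum-coverage
pre-filter (commonly 10 reads) is available but off by default.
Multiplicity control uses Storey $q$-values with $\hat\pi_0$ estimated at
the single point $\lambda=0.5$ rather than a spline over a $\lambda$
grid — one less smoothing dependency, and forcing $\hat\pi_0=1$
reproduces Benjamini–Hochberg exactly.  Directional calls for the
baselines follow the sign of the pooled proportion difference, with no
call when the difference is exactly zero.  An empirical-Bayes Wald test
over a beta-binomial model (as in dispersion-modelling packages) is out
of scope; externally computed p-values can be fed through
`run_baseline(method = "external")`.

## The synthetic-data generator

`simulation_design()` + `simulate_dataset()` emulate a two-condition
bisulfite experiment: truth labels drawn with fixed group fractions, true
proportions drawn per group, coverages per replicate from
$1+\mathrm{Poisson}(\lambda)$ (default $\lambda = 20$; an empirical
coverage table is accepted), counts binomial.  Defaults are the
benchmark's study conditions: 20,000 loci, two replicates per condition,
$\gamma = 0.2$ with its preset fractions (5.9 % hypo, 4.6 % hyper).

The effect-size dial is the $\gamma$ rule applied to proportion
differences $\hat d = \hat p_1 - \hat p_2$: $|\hat d| < 0.005$ equal,
$\hat d < -\gamma$ hypo, $\hat d > \gamma$ hyper, the band between
excluded.  Group-fraction presets exist for the two calibrated anchors
($\gamma = 0.01$: 43.28 %/29.44 %; $\gamma = 0.2$: 5.9 %/4.6 %); other
$\gamma$ values require explicit fractions rather than an invented
interpolation.

Proportion pools come in two forms.  *Empirical* pools reproduce the
reference procedure exactly when a user supplies per-locus proportion
estimates from a real dataset: the $\gamma$ rule partitions them, equal
loci contribute pooled estimates, directional loci contribute (case,
control) pairs.  *Parametric* pools — the packaged default, since no
external dataset is required to build or test — draw the equal group from
a bimodal Beta mixture (weights 0.4/0.4/0.2 on Beta(1,10), Beta(10,1),
Beta(2,2)), mimicking the U-shaped RRBS methylation landscape, and the
directional groups from Beta laws with means (0.2, 0.6) (hypo; mirrored
for hyper) and concentration 10, resampling until the pair satisfies the
same $\gamma$ rule that defines the truth groups.  The resampling step
matters: with the order constraint alone, near-zero effects would be
labelled "hypo" truth and no method could detect them, contradicting the
three-group construction in which the boundary band belongs to no group.

The optional *subject effect* draws per-replicate proportions
$p_{ijk} \sim \mathrm{Beta}(p_{ik} s, (1-p_{ik}) s)$ around the locus
proportion, default concentration $s = 50$ — at coverage $\sim 20$ this
puts replicate-level variation on the same scale as binomial noise,
a realistic mild violation of the model's shared-proportion assumption.

What the generator does *not* reproduce: spatial correlation along the
genome (loci are exchangeable here), empirical coverage heterogeneity
between samples and loci unless an empirical coverage table is supplied,
and the exact effect-size spectra of any particular tissue, which only
the empirical-pool path can provide.  Passing benchmarks on this
generator therefore demonstrates correctness of the inference under the
model's own generative assumptions plus mild perturbations — not
performance on any specific real dataset.

## Evaluation metrics

With truth and calls in $\{0,1,2\}$: discoveries are non-zero calls; FDR
is the fraction of truly equal loci among discoveries; mdFDR additionally
counts wrong-direction discoveries as false, so mdFDR $\geq$ FDR with
equality exactly when there are no directional mistakes; TPR is the
fraction of truly differential loci discovered in either direction.
TPR_hypo/TPR_hyper are directional by default — a truly hypo locus called
hyper does not count — consistent with mdFDR's treatment of direction;
`directional = FALSE` gives the permissive reading.  Ratios with zero
denominators are reported as `NA`, never as 0.  The benchmark harness
matches FDR across methods the way the original comparison protocol
does: the realized FDR of the Bayesian caller (averaged over replicates)
becomes the nominal $q$-value level of the baselines.

## Problem sizes used in the packaged checks

The packaged tests and the acceptance script validate the sampler against
a brute-force $3^L$ enumeration oracle on $L \le 6$ loci, chain
stationarity on an $L=3$ fixture over $10^6$ proposals (total-variation
distance to the enumerated 27-state posterior), collapsed marginals
against direct 1-D/2-D quadrature of prior $\times$ likelihood on
randomized small-count loci, and the full caller on 1,000-locus
simulations with five seeds (a scaled-down version of the 20,000-locus
design; the group structure, coverage model and effect sizes are
unchanged, and at 1,000 loci the partition prior already dominates its
own uncertainty).  The six-locus sampler-accuracy fixture uses strongly
identified directional loci deliberately: at coverages $\le 6$ an
equal-methylated locus has an intrinsically diffuse posterior
($\approx 0.3$–$0.5$ per group), whose snapshot-frequency estimate cannot
be pinned to $\pm 0.02$ by a 1,000-snapshot chain; the equal group's
correctness is covered by the enumeration, symmetry and stationarity
checks instead.

## Known limitations

* Adjacent-CpG correlation is not modelled; calls are per-locus.
* The shared-proportion assumption ignores replicate-level biological
  variation; simulations with the subject effect switched on show the
  inference degrades gracefully, but a properly hierarchical
  replicate model is future work.
* The sampler costs $O(L)$ per sweep; genome-scale inputs (hundreds of
  thousands of loci) are feasible but slow in wall-clock terms compared
  to the per-locus tests.
* Tie-breaking to the equal group is conservative by construction: it
  never manufactures a direction.
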