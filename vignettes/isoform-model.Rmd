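---
title: "Hierarchical Bayesian estimation of isoform expression from exon counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian estimation of isoform expression from exon counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodecon)
```

## The problem

Short mRNA-seq reads rarely identify a single transcript: most exons are
shared between splice isoforms of the same gene, so per-exon read counts are
mixtures of isoform expressions. `isodecon` deconvolves these mixtures. The
gene's annotation is first cut into **pseudo-exons** — maximal genomic
segments wholly inside or wholly outside every isoform — producing a binary
design matrix $X_g$ ($m_g$ segments $\times$ $s_g$ isoforms). Observed,
normalized segment expression is then modeled per gene $g$ and sample $l$ as

$$ y_{gil} = \sum_k I_{gkl}\,\beta_{gkl}\,X_{gik} + \varepsilon_{gil}, $$

i.e. $Y_{gl} \sim N_{m_g}(X_g \beta^*_{gl}, \Sigma_{gl})$ with every element
truncated below at zero, $\beta^*_{gkl} = I_{gkl}\beta_{gkl}$, and
$\Sigma_{gl} = \mathrm{diag}(1/\tau_{gl})$. The hierarchy is completed by

* $\tau_{gl} \sim \mathrm{Gamma}(\alpha_1, \alpha_2)$ — one noise precision
  per gene and sample; for a single-isoform gene all of its segments should
  carry the same expression, so within-gene spread is measurement noise;
* $\beta_{gkl} \sim N(\mu_{gk0}, 1/\tau_{gk0})$ truncated at zero, with
  $\tau_{gk0} \sim \mathrm{Gamma}(\alpha_1^0, \alpha_2^0)$ pooling the same
  isoform across samples — $1/\tau_{gk0}$ is the isoform's cross-condition
  expression variability;
* $I_{gkl} \sim \mathrm{Bernoulli}(p)$ — a spike-and-slab presence
  indicator (Kuo–Mallick form: the indicator multiplies an effect that keeps
  its own prior), which expresses the biological fact that most isoforms are
  simply absent in most conditions, regularizes the fit, and supports
  presence/absence calls directly.

Indicators are sample-specific ($I_{gkl}$, not $I_{gk}$): presence is a
property of an isoform *in a condition*, which is what makes the
indicator-based differential rule possible.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| $\alpha_1, \alpha_2$ | 0.01, 0.01 | diffuse prior on exon-noise precision (units: 1/expression²) |
| $\alpha_1^0, \alpha_2^0$ | 0.01, 0.01 | diffuse prior on isoform-level precision |
| $\mu_{gk0}$ | data anchor | prior mean of isoform expression (expression units) |
| $p$ | 0.5 | prior presence probability |
| chains / draws / burn-in | 2 / 8000 / 2000 | MCMC run length |

Inference is reported to be insensitive to reasonable hyperparameter
choices; the defaults are deliberately uninformative. The $\mu_{gk0}$ anchor
is the gene's 10%-trimmed mean of observed values divided by the mean
isoform multiplicity of its segments: values on shared segments are isoform
*sums*, and the undeflated trimmed mean systematically overshoots the
per-isoform scale for multi-isoform genes, which in turn degrades indicator
mixing (the prior — and therefore the Kuo–Mallick re-entry proposal — sits
far from the value an absent-coded isoform would need to re-enter with).

## The sampler

Full conjugacy is broken by the zero-truncation of the likelihood, so the
per-gene sampler is Metropolis-within-Gibbs:

* $I_{gkl}$ — exact Bernoulli full conditional; odds
  $p\,L(I{=}1)/[(1-p)L(I{=}0)]$ at the current $\beta$ value.
* $\beta_{gkl}$ — slice sampling (stepping out + shrinkage) on $[0,\infty)$
  when the isoform is active; a draw from its truncated-normal prior when
  inactive (this is what makes the indicator conditional exact).
* $\tau_{gl}, \tau_{gk0}$ — independence Metropolis with the conjugate
  Gamma proposal computed as if the likelihood were untruncated, accepted or
  rejected on the ratio of truncation normalizers $\prod_i \Phi(\mu_i
  \sqrt{\tau})^{-1}$. Acceptance rates are near 1 whenever $\mu_i\sqrt\tau$
  is a few units positive (truncation negligible), and the correction is
  exact otherwise.

Chains start from randomized overdispersed values ($\tau$ at jittered
method-of-moments from residuals, $\beta$ near the prior anchor, $I = 1$).
Each gene derives an RNG stream from the run seed and its gene identifier,
so multi-gene results are reproducible and independent of the order in
which genes are processed. Convergence is reported per parameter as split
$\widehat R$, Geyer effective sample size, and the Monte-Carlo standard
error, flagged when MCSE exceeds 5% of the posterior SD — the working
definition of "run long enough".

Degenerate inputs are handled rather than refused: duplicate design columns
(indistinguishable isoforms) sample anyway with a label-switching warning
recorded in the fit; an all-zero gene proceeds and simply concentrates its
indicators near zero.

## Normalization

Three normalizers produce the $y$ the model consumes:

* **RPKM** $= n_{il}/(\ell_i N_l) \times 10^9$ (reads per kilobase per
  million mapped reads).
* **Global**: each sample scaled so column totals match a reference (the
  across-sample mean total by default, or a named sample).
* **Percentile (10–90)**: each sample divided by the trimmed mean of its
  values strictly between its own 10th and 90th nearest-rank percentiles,
  relative to the across-sample mean of those trimmed means. Totals are
  deliberately *not* re-equalized afterwards: when one condition genuinely
  carries a very highly expressed top tail (the heat-shock-like behavior
  the generator emulates), global normalization forces every other decile
  of that sample downward, while percentile normalization equalizes the
  central bodies and leaves the genuine tail alone.

When the pipeline starts from read counts, the model's $y$ is the
normalized count divided by segment length in kilobases (the `fit` stage's
default `--y-scale length-kb`), so segment length drops out of the latent
expression scale the way it does in RPKM.

Design choices a user should know: the percentile scale summary is the
trimmed mean of the whole 10–90 body (not a single quantile such as the
upper quartile) — it is stabler than any single order statistic and matches
the decision not to rescale totals; zeros are *included* when computing the
percentiles (an excess of zeros is a feature of the data, not an artifact
to remove); all percentile computations package-wide use the nearest-rank
estimator (sorted value at rank $\lceil pn/100\rceil$), which is exactly
reproducible and estimator-free. The printed form of the RPKM formula in
the method's source is typographically garbled; the standard
reads/(kb × million mapped reads) definition is implemented.

## Posterior decision rules

* **Presence**: posterior mean of $I_{gkl}$.
* **High/low expression**: low when the 95th percentile of the isoform's
  expression PPI falls below the 10th percentile of all mean isoform
  expressions; high when the 5th PPI percentile exceeds the 90th percentile
  of the means.
* **Bayesian t**: per draw $t = (\beta^*_{l_1} - \beta^*_{l_2}) /
  \sqrt{1/(m_g\tau_{l_1}) + 1/(m_g\tau_{l_2})}$. The source describes this
  statistic but omits its formula; this reconstruction uses the standard
  difference-over-root-sum-of-variances form, with $m_g$ observations per
  sample so that the critical value depends on the exon count, as stated.
  Three rules are emitted: the 95% PPI excluding zero (R1); the PPI lying
  wholly in the extreme decile of all mean t statistics (R2); and the
  posterior mean t against the two-sided 5% critical value on $2(m_g - 1)$
  degrees of freedom (R3, defined only for $m_g \ge 2$).
* **Indicator differential**: declared when presence is confident in one
  sample ($\ge 0.95$) and confidently absent in the other ($\le 0.05$) —
  the rule that rescues exactly the comparisons a classical t statistic
  cannot make (zero counts in one library).
* **Variability**: posterior mean of $1/\tau_{gk0}$, classified against the
  35th/65th/90th nearest-rank percentiles of all isoforms, strict
  inequalities, ties falling in the middle class. A Gamma distribution is
  fitted to the variabilities by maximum likelihood with a QQ table and a
  configurable upper-tail exceedance fraction; the exact tail construction
  behind the source's headline percentages is unspecified, so that number
  is emitted, not claimed to match. The variability measure is only
  meaningful for isoforms expressed in at least one condition: an isoform
  absent everywhere samples its $(\beta, \tau_{k0})$ prior, whose
  near-scale-invariant tails make the posterior mean of $1/\tau_{k0}$
  essentially arbitrary. No multiplicity correction is applied anywhere —
  R2 is itself a rank-based selection — and this is deliberate.

## The synthetic world

The generator emulates the data regime the method was built for: ~50 genes
per run, 84% single-isoform (the rest carrying 2–4 cassette-exon isoforms:
the first isoform has all exons, each additional isoform skips one distinct
exon, so design columns are unique by construction), 1–10 exons per gene,
log-normal exon lengths clipped to 50–2000 b, six samples with unequal
library sizes, Bernoulli(0.5) presence, truncated-normal expression with
mean 10 and noise SD 2 (an effect about five noise SDs above zero —
recoverable but not trivial), Poisson read counts with rates proportional
to expression × segment length × library size, and one heavy-tailed sample
whose top 1% of rates is multiplied by 100. Cassette exons were chosen over
random exon subsets deliberately: subset-based isoform sets routinely
create exactly confounded combinations (two partial isoforms summing to a
full one) that no inference method can resolve, whereas skip-one-exon
designs stay identifiable.

What a green test does *not* establish: the generator draws from the
model's own likelihood, so recovery tests validate the sampler and the
decision rules, not the model's adequacy for real data (no positional or
GC bias, no 3′ bias, no splice-junction reads, no multi-gene reads, no
overdispersion beyond the model's own noise).

## Numerical choices and known limitations

* Coordinates are 1-based closed throughout, the native convention of the
  R/Bioconductor interval stack that performs the splitting; GFF3/GTF input
  needs no conversion.
* Abutting pseudo-exons with identical isoform membership are merged
  (minimal partition); whether the original construction merged such
  segments is unstated, so the choice is flagged here: merging reduces
  collinearity without information loss.
* Truncated-normal draws use inverse-CDF sampling, switching to a
  translated-exponential rejection sampler when the lower bound is more
  than five SDs above the mean.
* Under fully diffuse precision priors and genes with very few segments
  ($m_g \le 3$), the posterior keeps genuine mass on an "absent isoform +
  large noise variance" explanation; the $\beta^*$ posterior mean is
  consequently shrunk toward zero by roughly the absent-mode probability
  (about 10% at the generator defaults), while interval coverage and
  presence ranking remain accurate. This is a property of the model, not a
  sampler artifact (split $\widehat R \approx 1$), and mirrors why the
  method reports presence probabilities instead of hard point estimates
  for weakly-informed genes.
* The two-sided classical tests double the smaller exact tail (capped at
  1); with discrete counts this is mildly conservative, which is visible
  as a small positive bias in null p-values at low totals.
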