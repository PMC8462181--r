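---
title: "Hidden diversity: correcting community diversity metrics for imperfect detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden diversity: correcting community diversity metrics for imperfect detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Counts of animals at a site miss individuals. When the chance of missing
them differs between habitats -- say, forest canopy versus understory --
every diversity metric computed from the raw counts inherits that bias:
apparent differences between habitats may be artifacts of detection, and
real differences may be hidden. `hidiv` implements a framework for
quantifying that distortion. It has three layers:

1. a **stratified multispecies N-mixture model** that estimates true
   abundance from repeated counts,
2. **diversity metrics** (taxonomic, phylogenetic, functional; raw and as
   null-model standardized effect sizes) evaluated both on the observed
   data and on every posterior draw of the detection-corrected abundances,
3. the **hidden diversity (HD) statistic** per site and metric, with a
   classification of each site into *noise* versus *critical bias*.

## The abundance model

For species $k$ at site $i$ the true abundance is latent:

$$N_{ik} \sim \mathrm{Poisson}(\lambda_{ik}), \qquad
  y_{ijk} \sim \mathrm{Binomial}(N_{ik},\, p_{ijk})$$

with $y_{ijk}$ the count on occasion $j$. Abundance is constant across
occasions within a site (closure assumption; the package has no
open-population variant). The linear predictors are

$$\log \lambda_{ik} = \beta^{can}_k (1 - \mathrm{Strata}_i)
  + \beta^{und}_k\, \mathrm{Strata}_i + \beta^1_k\, \mathrm{Temp}_i
  + s_{SU(i)} + m_{SM(i)}$$

$$\operatorname{logit} p_{ijk} = \alpha^{can}_k (1 - \mathrm{Strata}_i)
  + \alpha^{und}_k\, \mathrm{Strata}_i + \alpha^1_k\, \mathrm{Date}_{ij}
  + \alpha^2_k\, \mathrm{Temp}_{ij}$$

where `Strata` is 0 for canopy and 1 for understory, `Temp`/`Date` are
z-scored covariates (`site_design()` records the constants), and $s$, $m$
are zero-mean normal random effects for sampling units and sampling
months. Each species-level parameter family is drawn from a community
hyperdistribution, e.g. $\beta^{can}_k \sim N(\mu_{\beta.can},
\sigma^2_{\beta.can})$. Hyperpriors are vague: Normal with precision 0.001
(variance 1000) on the means — written BUGS-style as Normal(0, 0.001) —
uniform(0, 1) on the *probability-scale* detection-intercept means (a
standard-logistic density on the stored logit scale), and uniform(0, 10)
on every standard deviation. `log_prior()` returns exactly this density
and is $-\infty$ outside the stated supports.

The sampling-month effect is declared as a generic site-to-group map
(`sm` in `site_design()`): the month effect can be wired to whole sites
or to site-month replicates, and the data structure does not force one
reading. The simulator's default assigns sites to months cyclically; real
analyses should supply the map that matches their design.

## The sampler

`fit_nmixture()` runs a Metropolis-within-Gibbs sampler written in C++.
Its design is dictated by the geometry of N-mixture posteriors, which are
notoriously slow to traverse with plain data augmentation:

* **Latent counts.** $N_{ik}$ has bounded support
  $[\max_j y_{ijk},\ \max_j y_{ijk} + \texttt{Nmax\_buffer}]$ (default
  buffer 100), so its full conditional is drawn *exactly* by enumerating
  the weight recursion
  $w(N{+}1)/w(N) = \lambda \prod_j (1-p_j) \cdot \prod_j \frac{N+1}{N+1-y_j} / (N+1)$,
  truncating once the remaining tail is numerically negligible
  (relative weight below $10^{-14}$).
* **Partial collapsing.** All species-parameter and random-effect updates
  integrate $N$ out over the same truncated support, so proposals are
  accepted against the *marginal* likelihood; $N$ is re-imputed from its
  exact conditional at the end of each sweep. This removes the
  $\lambda$--$N$ coupling that cripples coordinate-wise augmented
  samplers. Updates that do condition on $N$ never run after a
  marginalized update within a sweep, keeping the kernel valid.
* **Flat directions.** Three families of joint moves handle the remaining
  ridges: (i) *translations* that shift a community mean together with all
  its species parameters; (ii) *ridge moves* that shift an abundance
  intercept family and its stratum's detection intercept family in
  opposite directions ("more individuals seen less often"); (iii) *scale
  interweavings* that multiply a family's deviations and its sd (or a
  random-effect block and its sigma) by a common factor. An exact
  likelihood-free move exploits the identity that adding $d$ to every
  random effect while subtracting $d$ from both abundance intercept
  families leaves every $\lambda$ unchanged.
* **Adaptation.** All proposal scales adapt in windows of 50 iterations
  during burn-in only (target acceptance 0.2--0.5) and are frozen
  afterwards, so the post-burn-in chain is a fixed-kernel Markov chain.
* **Determinism.** The C++ code consumes R's RNG; chain $c$ seeds
  `seed + c - 1`, so a fit is bit-reproducible.

Correctness is tested three ways: the truncated marginal likelihood
against dense enumeration (to $10^{-10}$); the sampler's posterior mean
of $\lambda$ on a one-species toy against a grid approximation of the
posterior (within 3 Monte Carlo standard errors, batch-means); and
simulation-based recovery (below). The default configuration mirrors a
typical field-study run (3 chains, 150,000 iterations, 50,000 burn-in,
thinning 100, hence 3,000 retained draws — `retained_samples()`); tests
and examples use much smaller settings.

Convergence is monitored with the classic Gelman--Rubin $\hat R$
(`rhat()`), computed from between- and within-chain variances; a
split-chain variant is available via `split = TRUE`. Identical constant
chains report 1 by convention.

## Diversity metrics and standardized effect sizes

`hidden_diversity()` always computes taxonomic diversity (richness) and
total abundance. The observed community matrix is, by default, the
per-species *maximum* count over occasions -- the minimum number known
alive under closure, and the observed counterpart of $N_{ik}$ (a `"sum"`
collapse is available).

* **Branch-length metrics** (`"pd"`): Faith's PD on the phylogeny
  (SES.PD) and on a functional dendrogram (SES.FD). PD includes the path
  to the root of the pruned tree, so a one-species site scores its
  root-to-tip path length; conventions differ across software, so this
  one is documented and tested. PD is incidence-based; the
  abundance-weighting option applies to the distance-based metrics only.
* **Distance metrics** (`"mpd"`): mean pairwise distance on the
  cophenetic phylogenetic distances (SES.MPD) and on Gower trait
  distances (SES.MFD). Abundance weighting uses products of abundances
  over unordered pairs with the diagonal excluded,
  $\sum_{k<l} n_k n_l d_{kl} / \sum_{k<l} n_k n_l$; with
  `weighted = TRUE` the incidence variants SES.MPDi / SES.MFDi are
  reported alongside. (Note: some implementations include self-pairs in
  the weighted mean; this one does not.)
* **Functional distances**: Gower's coefficient via `vegan`, mixing
  continuous (range-normalized) and binary (simple mismatch) traits;
  zero-range traits are dropped with a warning. The functional
  dendrogram is UPGMA (average linkage) on those distances, with ties
  broken deterministically by species label.

Null models remove the richness effect: `tip_shuffle` permutes the
species-to-tip assignment (equivalently the distance-matrix labels),
`site_shuffle` permutes sampling units, `species_shuffle` permutes
species identities in the community matrix; on inputs pruned to the
community's species the tip and species shuffles act on the same label
set and share one permutation engine. SES is
$(\mathrm{obs} - \bar{x}_{null})/s_{null}$; a zero null spread leaves it
undefined and flagged, never zero. The default is `tip_shuffle` with 999
permutations (the pipeline default lowers `n_perm` to 99 because the null
is re-randomized inside every posterior draw).

## The hidden-diversity statistic

For each site and metric,

$$\mathrm{HD}_i = \frac{\mathrm{div.obs}_i - \overline{\mathrm{div.est}_i}}
  {\mathrm{sd}(\mathrm{div.est}_i)}$$

where the estimate distribution is the metric evaluated on every
posterior draw of $N$. The standard deviation is the sample sd
($n-1$ denominator) over draws -- a convention this package fixes and
documents. Positive HD means the observed data *overestimate* the
metric, negative *underestimate*; for richness and abundance HD can never
be positive on a fitted posterior, because the model corrects false
negatives only (every draw satisfies $N_{ik} \ge \max_j y_{ijk}$). The
raw difference $\mathrm{div.obs} - \overline{\mathrm{div.est}}$ is
exposed as an auxiliary column, since magnitude-style presentations of
the deviation are common; the standardized form is the primary statistic.

Within the pipeline the null-model randomization is re-run for each
posterior draw with a draw-indexed seed stream (`null$seed + d`), so null
uncertainty and detection uncertainty both propagate into
$\mathrm{sd}(\mathrm{div.est})$. Whether the observed SES should be
computed once or re-randomized per draw is genuinely open; the default is
once (`obs_null = "once"`), with `"per_draw"` averaging observed SES over
the same seed stream.

For SES metrics each site is classified by the signs of
(observed SES, posterior-mean SES): same sign is **noise** -- the
qualitative pattern survives detection correction, only its magnitude
shifts; observed positive with estimate negative is
**bias (overestimation)**; the reverse is **bias (underestimation)**. An
exact zero carries no direction and is conservatively classified as
noise, with a warning. `autoplot()` on the result draws the
quadrant scatter.

## The metacommunity simulator

`build_setting_grid()` reproduces a 12-setting validation design: one of
four community means (canopy/understory abundance, canopy/understory
detection) is moved to a low / intermediate / high level while everything
else stays at baseline, giving settings coded A--L. The exact numeric
levels used in the original validation are not printed in any text this
package relies on, so the defaults are package choices, configurable and
labeled non-canonical: expected site abundance 0.5 / 2 / 8 individuals
(log scale), detection probability 0.1 / 0.3 / 0.6 (logit scale);
baseline among-species sds 0.5 for intercepts and 0.25 for slopes, and
random-effect sds 0.25 -- values a field ecologist would call realistic
for a moderately heterogeneous insect assemblage. The default design
sizes mirror the motivating study: 35 species, 12 sites arranged as 6
site pairs x 2 strata (pairs share a sampling-unit random effect), 5
occasions with shared z-scored dates.

`simulate_metacommunity()` draws species parameters from the
hyperdistributions, assembles $\lambda$ and $p$ with the same link
functions as the model code, and generates $N \sim$ Poisson,
$y \sim$ Binomial. `recovery_check()` then reports, for every
hyperparameter and species parameter, whether the generating value falls
inside the central credible interval of a fit.

What the simulator does *not* emulate: spatial or temporal
autocorrelation beyond the two random-effect blocks, zero-inflation,
species interactions, trait- or phylogeny-structured detection, and
overdispersion relative to the Poisson. Passing recovery therefore shows
the estimator is self-consistent under the model's own assumptions -- not
that the model is adequate for any particular field data set.

## Problem sizes used in checks

The package's own validation study (tests and `scripts/acceptance.R`)
uses a scaled-down design chosen as a desk-scale replicate: 15 species x
12 sites x 5 occasions at the baseline setting, fit with 3 chains x 5,000
iterations (2,500 burn-in, thinning 1), repeated over 10 simulation
seeds. Reported are the aggregate 95%-CRI coverage across the 16
hyperparameters and the largest Gelman--Rubin $\hat R$. The likelihood
oracle uses dense enumeration up to 80--100 counts above the observed
maximum; the SES oracle enumerates all $4! = 24$ tip permutations of a
four-species toy tree.

## Numerical choices and degenerate inputs

* Truncation: `Nmax_buffer = 100` above the per-cell maximum count
  bounds the discrete support of both the oracle and the sampler;
  the truncated marginal is monotonically non-decreasing in the bound
  and stable to 10 decimal places well before 100 at the abundances
  considered here.
* Weight recursions run in linear space with rescaling at $10^{250}$ and
  a $10^{-14}$ relative-tail cutoff.
* Zero-variance covariates are centered and left unscaled.
* Sites with fewer than two species have undefined MPD (`NA` with a
  warning); empty sites have PD 0 and richness 0.
* A null or posterior spread of exactly zero flags the SES/HD as
  undefined (`"undefined_sd0"`), never 0.
* Ties in UPGMA agglomeration are resolved by sorting species labels
  before clustering.

## Limitations

The closure assumption and false-negatives-only correction are
inherited from the N-mixture framework: double counting or
misidentification (false positives) violate the model. Detection and
abundance are only weakly separable with few occasions; the sampler's
ridge moves make the *joint* posterior mixable, but wide credible
intervals on detection-side hyperparameters at 5 occasions are a property
of the design, not a software defect. The linear mixed model relating HD
to strata, often the next analysis step, is deliberately out of scope:
the HD table exported by `write_hidden_diversity()` is exactly the input
such a model consumes (e.g. with `lme4`).
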