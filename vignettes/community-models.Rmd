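---
title: "Hierarchical community models for a BACI riparian buffer experiment"
author: "riparOcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical community models for a BACI riparian buffer experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riparOcc)
```

## The problem

Riparian buffers — strips of unharvested forest left along streams when the
surrounding uplands are clearcut — are the main regulatory instrument for
protecting stream-associated wildlife in managed conifer forests. Whether the
widths mandated in practice (roughly 10–30 m) retain the breeding-bird
community is an empirical question that needs a before–after-control-impact
(BACI) experiment: sites surveyed before harvest and repeatedly afterwards,
with unharvested controls, narrow-buffer and wide-buffer treatments.

The data such an experiment produces are repeated point counts: for each
site, year, within-season visit and species, the number of birds detected.
Two facts dominate the analysis. First, detection is imperfect — a species
present at a site is recorded on any one visit only with probability well
below 1 — so raw counts confound occupancy/abundance with detectability, and
detectability itself changes when a treatment opens up the vegetation.
Second, most species are rare: species-by-species estimates are hopeless for
half the community, so information must be shared across species.

`riparOcc` implements the standard remedy: hierarchical multispecies
site-occupancy and N-mixture abundance models, fitted by MCMC, with all
derived community quantities (richness, similarity, turnover, local
extinction, total abundance, treatment contrasts, average predictive
comparisons) computed draw by draw from the posterior.

## The models

For species $i$, year $j$, site $k$ and visit $l$:

**Occupancy.** The latent presence indicator is
$z_{ijk} \sim \mathrm{Bern}(\psi_{ijk})$ and detections are
$y_{ijkl} \sim \mathrm{Bern}(p_{ijkl} \, z_{ijk})$ — a species absent from a
site can never be detected there. The process and observation models are
logit-linear:
$\mathrm{logit}(\psi_{ijk}) = x'_{jk}\alpha_i + u_k$ and
$\mathrm{logit}(p_{ijkl}) = w'_{jkl}\beta_i$.

**Abundance.** The latent site-year abundance is
$N_{ijk} \sim \mathrm{Pois}(\lambda_{ijk})$, assumed closed over the
season's visits, with counts $n_{ijkl} \sim \mathrm{Binom}(N_{ijk},
p_{ijkl})$ and $\log(\lambda_{ijk}) = x'_{jk}\alpha_i + u_k$.

**Community structure.** Species-level coefficients are exchangeable draws
from normal hyper-distributions, $\alpha_{i,c} \sim N(\mu_c, \sigma_c^2)$
(and likewise for $\beta$), which shrinks rare-species estimates toward the
community mean while letting well-observed species speak for themselves. A
site-level random effect $u_k \sim N(0, \sigma_{site}^2)$ plays the role of
a compound-symmetric correlation across the years of one site.

Three design-matrix variants mirror the experiment:

* **Design** — year dummies (1993 baseline), treatment dummies (Control
  baseline) and all eight year×treatment interactions; the detection model
  uses treatment-at-measurement coding (in the pre-harvest year every site
  is coded control, because no buffer existed yet) plus scaled Julian date
  and date².
* **Covariates** — treated sites in post-harvest years only; treatment
  labels are replaced by five continuous habitat covariates (buffer width,
  shrub cover, three tree-stem counts), centered and scaled.
* **RandomEffects** — the long-term years only, intercept + year on the
  process side, habitat covariates moved to the detection side; used to
  plot site-level richness and abundance against buffer width without
  forcing a width relationship.

## Fitting: marginalized likelihood, adaptive MCMC

No external MCMC engine is assumed. The sampler (C++) is
Metropolis-within-Gibbs on the *marginalized* likelihood: the latent $z$ is
summed out of every species-site-year term,
$$\Pr(y_{ijk\cdot}) = \psi \prod_l p^{y}(1-p)^{1-y}
  \; + \; (1-\psi)\,\mathbb{1}(\text{all } y = 0),$$
and the latent $N$ is summed from $\max_l n_l$ to a truncation bound $K$.
Marginalization mixes far better than sampling the latent states, and the
latent states are recovered exactly afterwards from their conditional
distributions (`conditionalZDraws()`, `conditionalNDraws()`).

Updates per iteration: per-species process and observation coefficient
blocks with Haario-style adapted multivariate normal proposals (empirical
covariance accumulated during burn-in, scale tuned to ~0.23 acceptance);
scalar random-walk updates for site effects and log hyper-sds (~0.44
target); conjugate Gibbs draws for the hyper-means. Two structural moves fix
the posterior's known pathologies:

* a **translation move** along the intercept/site-effect ridge (all species
  intercepts and the intercept hyper-mean shifted by $+\delta$, all site
  effects by $-\delta$; the likelihood is exactly invariant), without which
  chains park at arbitrary points of the ridge;
* a **group-scale move** for the hierarchical funnel (one process column's
  species deviations rescaled by $c$ together with its hyper-sd; the
  normal-prior terms cancel analytically against the Jacobian up to
  $\log c$).

Adaptation stops at the end of burn-in, so the retained draws come from a
fixed-kernel chain. All randomness flows through R's RNG: a seed gives
bit-identical chains.

### Numerical choices

* All probabilities are computed in log space; linear predictors are clamped
  at ±35 before exponentiation.
* Truncation bound: `defaultK()` uses max observed count + 100 and doubles
  the margin until the most demanding site-year's likelihood moves by less
  than 1e-8. Doubling $K$ beyond the default changes fitted log-likelihoods
  by less than 1e-6 (tested).
* Quantiles everywhere are type-7 (R's default); point estimates are
  posterior medians; intervals are equal-tailed 95%.
* Draws where a similarity/turnover denominator is zero (an empty community)
  are dropped and the dropped fraction is reported, since the estimators
  are undefined there.
* The covariate scaling record stores mean and sd so the inverse transform
  reproduces raw values to 1e-12 (tested).

### Priors

Field analyses of this design rarely publish their exact priors, so the
package uses documented weakly informative defaults: hyper-means
$N(0, 1.5^2)$ on the logit scale ($N(0, 2^2)$ for the log-link abundance
intercept), half-Cauchy(1) for the coefficient hyper-sds and the site-effect
sd. These are configurable via `priorConfig()`.

### MCMC protocol

The full field-study protocol is 3 chains × 400,000 iterations, 200,000
burn-in, 1/50 thinning; `mcmcConfig(nIter = 4e5, nBurn = 2e5, nThin = 50)`
reproduces it. The desk-scale default (3 × 4,000, burn 2,000, thin 2, two
species-block sweeps per iteration) runs in ~30 s on the default synthetic
world. At that scale Gelman–Rubin statistics above 1.1 are still common for
weakly identified interaction coefficients — `convergenceReport()` warns,
honestly; the parameter-recovery tests show the hyper-mean intervals are
nevertheless well calibrated (coverage ≥ 16/20 per slot across seeded
replicates).

## Derived community quantities

All are computed per posterior draw from the conditional latent states and
then summarized:

* richness $s_{jk} = \sum_i \hat z_{ijk}$, reported per site-year or
  averaged over a treatment's surveyed sites;
* Sørensen-type similarity
  $S_{j,k_1,k_2} = 2\sum_i z_1 z_2 / (\sum_i z_1 + \sum_i z_2)$;
* turnover $\tau$ and local extinction $\varepsilon$ between two years,
  both normalized by the *earlier* year's occupancy total (note $\tau$ may exceed 1 when arrivals outnumber the prior
  community — the verbal "probability" reading would normalize by the later
  year instead, an ambiguity we resolve in favour of the earlier-year denominator);
* total abundance $\sum_i \sum_k \hat N_{ijk}$ per treatment-year;
* BACI treatment contrasts: treatment main effect + year×treatment
  interaction (zero in the baseline year), exponentiated on request into a
  multiplicative odds (occupancy) or rate (abundance) change — a link-scale
  contrast of 1 is an $e \approx 2.7$-fold change;
* site-level summaries for the RandomEffects variant: per-draw means across
  years, summarized and paired with buffer width, controls flagged as the
  reference band. These intervals are sometimes labelled "confidence
  intervals" in this literature; here they are posterior quantile
  intervals like every other interval the package reports.

### Average predictive comparisons

For a covariate $u$ with the other inputs $v$ held at observed values,
$$\hat\Delta_u = \frac{\sum_{j,k,s} w_{jk}\,
  [E(y \mid u_k, v_j, \theta^s) - E(y \mid u_j, v_j, \theta^s)]\,
  \mathrm{sign}(u_k - u_j)}
  {\sum_{j,k,s} w_{jk}\,(u_k - u_j)\,\mathrm{sign}(u_k - u_j)}$$
over site-year pairs and posterior draws. The community versions sum the
species-specific expected responses ($\sum_i \psi_i$ for richness,
$\sum_i \lambda_i$ for total abundance), so the community comparison equals
the sum of per-species comparisons with shared weights (tested to 1e-10).
Weights default to $w_{jk} = 1/(1 + d_{jk})$ with $d$ the Mahalanobis
distance between the other-covariate vectors — "how likely a transition from
$u_j$ to $u_k$" — with uniform weights available for oracle checks. Pairs
with $u_j = u_k$ contribute zero to both sums and are skipped. The standard
error combines the posterior variance of $\hat\Delta$ across draws with the
weighted pairwise estimation variance; the cited methodology leaves the
exact combination open, so ours is documented in
`apcStandardError()` and unit-tested for its qualitative properties
(non-negativity, decomposition at a degenerate posterior, shrinkage as the
posterior concentrates) rather than claimed equivalent.

## The synthetic world

`simulationConfig()` encodes the experiment as its defaults: 3 treatments ×
6 replicate sites, surveyed in 1993, 1995–1996 and 2003–2004 with 6 visits
evenly spaced over days 105–181; one site per treatment (deterministically
the last) lost before the long-term resurvey, 18 → 15 sites; 28 species.
Buffer widths are drawn per treated site from the observed treatment-level
distributions — Normal(13.1, 9.1) narrow, Normal(29.9, 15.5) wide, truncated
at 0.5 m — and vegetation covariates within the observed ranges (shrub
truncated-N(12, 6) %, Douglas-fir stems truncated-N(25, 10), deciduous and
hemlock/cedar stems truncated-N(90, 25)). Controls have no buffer width;
variants that need one for control sites hold them at the treated-site mean
on the scaled scale.

Generating hyper-means default to a neutral world — occupancy intercept 0
(ψ ≈ 0.5), detection intercept logit(0.3), abundance intercept log(1.5),
all treatment/year/covariate slots 0 — with hyper-sds 0.5 and site sd 0.3.
Those values are a deliberate choice, not a fit: per-visit detection of 0.3
over 6 visits gives cumulative detection ≈ 0.88, typical of songbird point
counts and informative without being easy. `colonizationEffects()` supplies a
preset with positive long-term year×treatment interactions (stronger on the
wide treatment) representing delayed colonization of the buffers.

What the generator does *not* emulate: spatial autocorrelation between
stations (the analysis unit is the site), within-season emigration (closure
is assumed, as in the models), observer effects (the field protocol rotated
observers instead of modelling them), and double counting across adjacent
stations (site aggregation sums station counts as-is; a known bias channel
of the design itself). A green parameter-recovery test therefore establishes
that the estimator recovers the model's own world, not that the model is
true of real birds.

## Design choices that were genuinely open

* **Station aggregation**: counts are summed over a site's stations and
  occupancy is indicator(summed count > 0) — the standard reductions for
  a design whose experimental unit is the site, not the station.
* **Species rules**: Hermit/Townsend's warbler pooling happens *before* the
  ≥10-detection filter (so two rare forms can jointly survive), and
  "detections" counts individuals (counts summed); a species with exactly 10 detections is retained.
* **Date scaling**: mean/sd over all retained survey rows of the variant,
  then squared; the pooling level was an open choice.
* **Missing site-years** are carried as an absent row (mask), never imputed.
* **Split-chain R-hat** rather than the 1992 original: strictly more
  conservative; threshold 1.1 for warnings (the conventional cut-off).
* **PPC discrepancy**: Freeman–Tukey on site-visit responses by default
  (chi-square optional), a standard choice for binary and count responses.
* **Turnover normalization**: earlier-year denominator, see above.

## Known limitations

* Desk-scale chains are short; treat `convergenceReport()` warnings
  seriously and scale `mcmcConfig()` up for real analyses.
* The N-mixture sampler's cost grows with the truncation bound; very
  abundant species (counts ≫ 100) would need a smarter integrator.
* No data augmentation for never-observed species: richness is conditional
  on the observed species pool.
* APC standard errors are a documented reconstruction of the cited
  procedure, not a verified replica.

## A worked run

```{r, eval = FALSE}
cfg <- simulationConfig(effects = colonizationEffects())
sim <- simulateOccupancyDataset(cfg, seed = 42)
md  <- sim$modelData
fit <- fitOccupancy(md, mcmc = mcmcConfig(seed = 42))
zd  <- conditionalZDraws(fit, md)
speciesRichness(zd, "treatment-year")
treatmentContrasts(fit, 2004, "Wide", scale = "response")
```

The README shows this run's actual output; `scripts/acceptance.R` executes
the same pipeline end-to-end under a caller-supplied seed.
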