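---
title: "Occupancy, co-occurrence and the species interaction factor"
author: "occupair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy, co-occurrence and the species interaction factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occupair)
```

## The inference problem

Spoor (track) transect surveys record, for each site and sampling
occasion, whether sign of a species was found. Non-detection does not
mean absence: detection is imperfect and varies with substrate quality,
observer conditions, and serial dependence between consecutive passes of
the same trail. Occupancy models treat presence as a latent Bernoulli
state and detection as a second, conditional Bernoulli process, so that
questions about habitat use — and, here, about whether a subordinate
carnivore avoids or tracks a dominant one — are answered on the occupancy
scale rather than on the raw detection scale.

The design this package targets is a single-season ("closed") survey:
each site is a short trail stretch walked in two consecutive 1-km
occasions, so the occupancy state cannot change between occasions. Three
assumptions carry all interpretation: sites are closed over their two
occasions, species are never falsely identified (tracks are diagnostic to
an experienced tracker), and heterogeneity in occupancy or detection is
captured by covariates.

## Single-species model

For site $i$ with covariates $x_i$ and occasion covariates $w_{ik}$,

$$\mathrm{logit}(\psi_i) = x_i^\top \beta_\psi, \qquad
  \mathrm{logit}(p_{ik}) = w_{ik}^\top \beta_p,$$

and the marginal likelihood of history $h_i$ sums over the latent state:

$$L_i = \psi_i \prod_k p_{ik}^{h_{ik}} (1-p_{ik})^{1-h_{ik}}
        + (1-\psi_i)\, \mathbf{1}\{h_i \equiv 0\},$$

with missing occasions contributing nothing (missing-at-random occasion
handling). `site_lik_single()` exposes this site term; `occu_single()`
maximizes the product over sites.

Two detection covariates recur throughout. *Substrate* is a 3-level
quality class (1 = fine sand or shallow mud, best tracking substrate;
3 = grass or hard mud, worst) recorded per occasion; by default it enters
as a numeric covariate — the more parsimonious choice, with one slope —
but nothing prevents passing `factor(substrate)` in the detection formula
when a non-monotone effect is suspected. *Recapture*
(`make_recapture_covariate()`) is the lag-1 detection indicator: 0 on
occasion 1, the previous occasion's detection afterwards. It absorbs the
positive spatial autocorrelation expected between two consecutive
kilometres of the same trail. The two-occasion rule ("0 if not seen on
occasion 1, 1 if seen") generalizes to $K>2$ as lag-1 detection.

Continuous site covariates are z-standardized (`standardize_covariates()`,
sample SD with the $n-1$ denominator, matching mainstream statistical
software) and screened for collinearity with a Pearson correlation
criterion (`collinearity_screen()`). The screen uses $|r| > 0.6$ — the
absolute value is the standard reading of an unsigned exclusion criterion
— and drops the member of an offending pair that appears later in the
user's covariate list, a deterministic tie rule that makes runs
reproducible.

## Conditional two-species model

For a dominant species A (declared by the analyst, not estimated) and a
subordinate B, occupancy is parameterized conditionally:

* $\psi_A$: probability A occupies the site;
* $\psi_{BA}$: probability B occupies, given A present;
* $\psi_{Ba}$: probability B occupies, given A absent.

The four latent states $\{AB, Ab, aB, ab\}$ have probabilities
$\psi_A\psi_{BA}$, $\psi_A(1-\psi_{BA})$, $(1-\psi_A)\psi_{Ba}$,
$(1-\psi_A)(1-\psi_{Ba})$ (`joint_state_probs()`). Detection uses five
blocks: $p_A, p_B$ when a species is alone and $r_A, r_{BA}, r_{Ba}$ when
both are present, B's occasion-level probability switching on whether A
was *observed* that occasion. Because A's history is data, this
conditioning uses the realized detection, with a missing A occasion
counting as "not detected". The default `detection_constraint = "shared"`
sets $p_A = r_A$ and $p_B = r_{BA} = r_{Ba}$ — neither species changes
the other's detectability — which is the parameterization whose fitted
summaries show identical $p$ and $r$ columns; `"free"` estimates all
five blocks.

The SP variant (`interaction = FALSE`) constrains $\psi_{BA} = \psi_{Ba}$
with a single linear predictor; SP+INT frees them. Comparing the two by
AIC is the test of whether B's occupancy responds to A.

Two analytic properties anchor the implementation and are enforced by
enumeration tests: the site likelihood sums to 1 over all $2^{2K}$ joint
histories, and when $\psi_{BA}=\psi_{Ba}$ with shared B detection the
B-marginal collapses exactly to the single-species likelihood.

## The species interaction factor

$$\varphi = \frac{\psi_{AB}}{\psi_A \psi_B}, \qquad
  \psi_{AB} = \psi_A \psi_{BA}, \qquad
  \psi_B = \psi_A \psi_{BA} + (1-\psi_A)\psi_{Ba}.$$

$\varphi = 1$ iff $\psi_{BA} = \psi_{Ba}$; $\varphi < 1$ is avoidance,
$\varphi > 1$ co-occurrence beyond independence. The implementation
computes $\psi_B$ as $\psi_{Ba} + \psi_A(\psi_{BA} - \psi_{Ba})$ so the
independence identity holds *exactly* in floating point. A variant that
normalizes by the product of the conditional occupancies,
$\psi_{AB}/(\psi_{BA}\psi_{Ba})$, appears in some write-ups; it is
available behind `denominator = "conditional"` for comparison, but it is
not independence-normalized (equal conditionals do not give 1) and the
independence-normalized form is the one consistent with the established
SIF literature and with published point-estimate tables, so it is the
default.

`sif_estimate()` averages the site-level $\varphi_i$ arithmetically and
attaches a delta-method SE: the gradient of the site-mean map
$\beta \mapsto \bar\varphi(\beta)$ (central finite differences) is
propagated through the coefficient covariance. An association is flagged
significant when $\bar\varphi \pm 1.96\,\mathrm{SE}$ excludes 1. Averaging
the site-level factors is one of two defensible readings of a single
reported $\varphi$ per pair (the other being $\varphi$ at the covariate
means); the site-mean is the default and the profile function provides
the covariate-conditional view. `sif_profile()` evaluates
$\varphi$, $\psi_{BA}$, $\psi_{Ba}$, $\psi_A$ along a covariate grid with
all other covariates held at their means, back-transforming the grid to
the original scale when the covariate was standardized.

## Model selection

`aic()`, `rank_models()` and `candidate_set()` implement plain AIC
ranking ($\mathrm{AIC} = -2l + 2K$), $\Delta$AIC, Akaike weights
$e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ and model likelihoods
$e^{-\Delta_i/2}$. The candidate-set cutoff is strict
($\Delta\mathrm{AIC} < 2$), so a model exactly at the cutoff is excluded.
Weights are normalized over the supplied model list only; published
tables sometimes print weights implying a larger unlisted model set, so
set-relative weights need not match such tables row for row. No AICc or
QAIC correction is applied.

## Fitting: numerical choices

* **Optimizer.** Multi-start BFGS on the unconstrained logit-scale
  coefficients; the first start is $\beta = 0$ (all probabilities 0.5),
  the remaining `n_starts - 1` are uniform draws on $[-2, 2]$ from the
  user's seed. Ties are broken by first-found. Default `n_starts = 10`;
  intercept-only likelihoods are effectively unimodal and tests use 2–3
  starts.
* **Newton polish.** BFGS stops on relative objective change, which can
  leave coefficients $\sim 10^{-5}$ off in ill-conditioned
  parameterizations (e.g. raw-scale covariates). Up to two Newton steps
  with a numerical Hessian are applied at the incumbent optimum, which
  restores the invariance of fitted $\hat\psi_i$ to covariate
  standardization at $10^{-6}$ tolerance.
* **Pattern collapsing.** Sites sharing identical design rows and
  histories are collapsed to weighted unique patterns before
  optimization. This is exact and makes intercept-only fits on large
  surveys (at most $2^K$ or $2^{2K}$ patterns) essentially free.
* **Standard errors.** Inverse observed information (numerical Hessian at
  the optimum); delta method for derived quantities ($\hat\psi_i$ SEs on
  the probability scale, SIF means and profiles).
* **Non-convergence.** A fit is flagged unconverged — never an error —
  when the optimizer fails, the Hessian is singular, a species has no
  detections at all, or the optimum is on the boundary (any
  $|\mathrm{logit}|$ coefficient beyond 15, or a fitted probability
  within $10^{-6}$ of 0 or 1). Sparse-detection species are the normal
  case in carnivore surveys, and the pipeline treats a flagged fit as a
  result, falling back to null models where a covariate model fails.
* **Conditional occupancy.** `conditional_occupancy()` gives the
  empirical-Bayes probability a site is occupied given its history:
  1 after any detection (no false positives), and
  $\psi q/(\psi q + 1 - \psi)$ with $q = \prod_k(1-p_k)$ for all-zero
  histories.

## The hierarchical pipeline

`run_pipeline()` reproduces the multi-stage analysis per survey area:
standardize and screen landscape covariates; fit prey and threat
single-species models and attach their per-site occupancy estimates as
carnivore covariates; fit univariate carnivore models (single covariates
perform better in two-species models, and univariate screening keeps the
carnivore stage honest about its limited detections), ranked by AIC with
the top covariate carried forward and ties broken by listed covariate
order; fit SP and SP+INT two-species models per pair with substrate on
detection; rank them and compute the averaged SIF and its profile over
the dominant's top covariate. Areas are analyzed independently
throughout. Every fit appears in the run log with its convergence
status, and written outputs contain no timestamps so identical
config + seed gives identical files.

Whether to feed the carnivore models the *unconditional* model
prediction $\hat\psi_i$ or the history-conditioned occupancy is a real
fork: the unconditional prediction is a pure function of habitat, while
the conditional one injects the prey detection data themselves. The
pipeline defaults to the unconditional $\hat\psi_i$ (the smoother, purely
covariate-driven choice, and the one that keeps the carnivore stage free
of the prey histories' sampling noise); `conditional_prey = TRUE`
switches.

## What the simulators emulate

`sim_single()` and `sim_pair()` are generative mirrors of the two
likelihoods, with optional covariate effects, a 3-level substrate
detection covariate and (single-species) a lag-1 recapture effect;
enumeration tests confirm the simulated joint-history frequencies match
the likelihood's implied distribution.

`sim_study()` packages a full two-park emulation: 768 sites (269
"Kruger", 499 "Limpopo"), two occasions, substrate frequencies
(0.4, 0.4, 0.2) for classes 1–3 (a typical savanna trail mix; no field
frequencies are published, and the value is configurable), five
continuous landscape covariates, five prey/threat species and five
carnivores. Generating values were chosen once to reproduce the
qualitative structure of such surveys — the dominant follows water in one
park and prey occupancy in the other; the subordinates range from strong
co-occurrence (cheetah) through near-independence (spotted hyena) to
avoidance (wild dog in the well-protected park); wild dog is the rarest
carnivore; anthropogenic threats concentrate in the pastoralist park —
not any particular published estimate, since the original survey data are
not deposited. Prey covariates reach the carnivore stage as estimated
occupancy probabilities in (0, 1), mirroring the pipeline's
$\hat\psi$-as-covariate design.

What passing tests on these simulations do show: the estimators recover
their own generating process (occupancy parameters within stated bands at
$n = 3000$; SIF on the correct side of 1 with stated power at $n = 2000$),
the likelihoods are exactly normalized, and the pipeline is deterministic
end to end. What they cannot show: robustness to closure violations,
track misidentification, unmodeled detection heterogeneity, or spatial
dependence beyond the lag-1 recapture term — none of which the generator
produces.

## Problem sizes used in the checks

Parameter-recovery checks use 3000-site surveys; SIF directionality power
checks use 100 replicates of 2000 sites; the end-to-end pipeline check
uses the 768-site emulation with 3 optimizer starts; enumeration
identities use $K = 2, 3$ occasions. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the default test
run quick.

## Known limitations

* Single season only: no colonization/extinction dynamics.
* No false-positive detection model; a detection is taken as truth.
* Two species at a time, with dominance declared a priori; no
  three-species structure.
* The delta-method SIF interval is symmetric on the $\varphi$ scale and
  can be poor when $\varphi$ is large and its SE larger (a known feature
  of ratio statistics at low occupancy); a profile-likelihood or
  log-scale interval would be the next refinement.
* Weights and candidate sets are relative to the models actually fitted.
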