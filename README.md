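# occupair

Single-season occupancy models with imperfect detection for
detection/non-detection survey data, with a focus on **conditional
two-species (dominant/subordinate) models** and the **species interaction
factor (SIF)** used to quantify co-occurrence patterns in large-carnivore
guilds surveyed by spoor (track) transects.

## The problem

Walking a transect twice and recording whether a species' tracks were seen
gives detection/non-detection histories, not presences: a species can
occupy a site and leave no detectable sign on a given pass. Occupancy
models separate the probability a site is used, ψ, from the probability of
detecting the species on one occasion given use, p, so that habitat and
interaction inferences are not confounded by imperfect and heterogeneous
detectability. This package implements that machinery for ecologists
asking whether a subordinate carnivore uses the same sites as a dominant
one more or less often than expected by chance, and which habitat
covariates condition that association.

## The models

**Single species.** With site covariates x and occasion covariates w,

    logit(ψ_i) = x_i' β_ψ,    logit(p_ik) = w_ik' β_p,

and the likelihood of history h_i is
`ψ_i ∏_k p_ik^h_ik (1-p_ik)^(1-h_ik) + (1-ψ_i) I(h_i ≡ 0)`,
with missing occasions skipped. Detection covariates include a 3-level
substrate quality class and a "recapture" indicator equal to the previous
occasion's detection, which absorbs serial dependence between consecutive
occasions of the same transect.

**Two species.** For a dominant species A and subordinate B the occupancy
block is parameterized conditionally — ψA, ψBA = P(B | A present),
ψBa = P(B | A absent) — and detection distinguishes pA, pB (species alone)
from rA, rBA, rBa (both present; B's occasion-level detection depends on
whether A was detected on that occasion). The default constraint
pA = rA, pB = rBA = rBa assumes neither species alters the other's
detectability. The SP model variant forces ψBA = ψBa (no interaction);
SP+INT frees them.

**Species interaction factor.**

    φ = ψAB / (ψA ψB),   ψAB = ψA ψBA,   ψB = ψA ψBA + (1-ψA) ψBa.

φ = 1 exactly when ψBA = ψBa (independence), φ < 1 indicates avoidance of
A by B, φ > 1 co-occurrence. Site-level φ_i are averaged and a
delta-method SE propagates the coefficient covariance through the mean;
the association is called significant when the 95% CI excludes 1.

Models are compared by AIC with ΔAIC, Akaike weights, model likelihoods
exp(-Δ/2), and strict ΔAIC < 2 candidate sets.

## Worked example

```r
library(occupair)
d <- sim_pair(1000, psiA = 0.5, psiBA = 0.7, psiBa = 0.3, p = 0.6, seed = 42,
              species_names = c("lion", "leopard"))
fit <- occu_pair(d, speciesA = "lion", speciesB = "leopard",
                 n_starts = 5, seed = 1)
fit
#> Two-species occupancy model: lion (dominant) / leopard (subordinate)
#> Parameterization: SP+INT (psiBA != psiBa) | detection: shared
#> Coefficients:
#>  psiA_(Intercept) psiBA_(Intercept) psiBa_(Intercept)    pA_(Intercept)
#>           -0.1220            1.0239           -0.6408            0.2547
#>    pB_(Intercept)
#>            0.2838
#> -2l = 4391.77, K = 5, AIC = 4401.77
#> mean psiA = 0.470, psiBA = 0.736, psiBa = 0.345

sif_estimate(fit)
#> SIF lion-leopard: phi = 1.392 +/- 0.049 (95% CI 1.297-1.487) *
#> Interpretation: phi > 1, co-occurrence (CI excludes 1)
```

The fitted conditional occupancies recover the generating values (ψBA =
0.7, ψBa = 0.3 on the logit scale give 0.736 and 0.345 here), and the
interaction factor is significantly above 1: the subordinate co-occurs
with the dominant about 1.4 times more often than independence predicts.
Ranking the SP and SP+INT variants puts essentially all Akaike weight on
the interaction model for these data:

```r
rank_models(list("psi(.,.,SP)p(.)"     = occu_pair(d, interaction = FALSE),
                 "psi(.,.,SP+INT)p(.)" = fit))
#>                  name     aic delta_aic weight model_likelihood K neg2loglik
#> 1 psi(.,.,SP+INT)p(.) 4401.77       0.0      1                1 5    4391.77
#> 2     psi(.,.,SP)p(.) 4471.37      69.6      0                0 4    4463.37
```

The full hierarchical analysis — prey/threat occupancy estimated first and
fed to the carnivore models as covariates, univariate covariate screening,
SP/SP+INT ranking and SIF profiles per survey area — runs end to end with
`run_pipeline()`, either on your own CSV tables (see
`?read_detection_data` for the layout) or on the built-in two-park study
emulation (`sim_study()`).

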