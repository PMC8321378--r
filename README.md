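# spagen

Two-stage glaucoma detection from optic cup/disc segmentation masks of
fundus photographs, for vision scientists and medical-imaging researchers
who want an interpretable, data-efficient alternative to end-to-end deep
classifiers.

Glaucoma thins the neuroretinal rim between the optic cup and the disc
boundary.  `spagen` quantifies that geometry as a **24-direction
cup-to-disc ratio (CDR) profile** — the ratio of cup to disc radial extent
every 15° around the disc centroid — plus the cup-to-disc area ratio
(CDAR), and classifies eyes with **SpaGen**, a hierarchical Gaussian
generative model:

```
Y_{i,d} = β₀ + β_{G,0} I_G + β_CDAR·CDAR_i
          + Σ_k [group-specific sin/cos terms at 2πkd/24, k = 1,2]
          + z_i + e_{i,d},
z_i ~ N(0, σ_z²),  e_{i,d} ~ N(0, σ_G²) or N(0, σ_H²)
```

a 15-parameter model (1 prior + 11 fixed effects + 3 variances) whose
compound-symmetric covariance gives closed-form likelihoods.  New eyes are
scored by the Bayes posterior probability of glaucoma or by the equivalent
**Rim Deformation Score** (half the difference of squared Mahalanobis
distances from the healthy and glaucomatous distributions), which also
localizes *where* the rim deviates.

The package also provides:

* a compact U-shaped fully convolutional segmentation network with a
  mobile inverted-bottleneck (MBConv + squeeze-and-excitation) encoder,
  implemented — forward and backward — in base R;
* evaluation tools: Dice/Jaccard/accuracy, midrank AUROC, ROC-optimal
  threshold selection (closest point to the top-left corner),
  sensitivity/specificity/PPV/NPV, Bland–Altman agreement;
* synthetic-data generators (model-drawn profiles, rasterized ellipse
  masks with analytic profiles, pseudo-fundus images) so every stage is
  testable without clinical data;
* a CLI (`inst/scripts/spagen`) with subcommands `extract`, `fit`,
  `classify`, `simulate`, `segment-train`, `segment-predict`.

## Worked example

```r
library(spagen)
train <- sample_profiles(n_eyes = 400, seed = 1)   # labelled CDR profiles
fit <- spagen(train)
fit
#> SpaGen generative classifier
#>   CDR profile of 24 values and 2 variance parameters and CDAR (15)
#>   400 eyes (prevalence 0.253), logLik 12703.23
#>   variances: sigma_z2 = 0.00406, sigma_G2 = 0.00612, sigma_H2 = 0.00302

test <- sample_profiles(n_eyes = 400, seed = 2)
scores <- predict(fit, test)
head(scores, 3)
#>     eye_id    posterior       rds decision
#> 1 eye00001 7.088312e-01 10.104321 glaucoma
#> 2 eye00002 6.748549e-06 -2.691570  healthy
#> 3 eye00003 1.716818e-03  2.849042  healthy
diagnostic_summary(scores$posterior, test$label)
#> AUROC 0.996 | sens 0.984 spec 0.960 PPV 0.919 NPV 0.992 @ threshold 0.1517
```

The fit recovers the generating variances (σ_z² = 0.004, σ_G² = 0.006,
σ_H² = 0.003) and separates the groups at AUROC 0.996 on held-out eyes;
the printed threshold is the ROC point closest to the top-left corner.
The per-eye `posterior` is the Bayes probability of glaucoma and `rds`
the Rim Deformation Score (positive favours glaucoma).

Geometry works directly on masks:

```r
rm <- render_masks(size = 256,
  disc = list(center = c(128, 128), semiaxes = c(80, 60), rotation = 0.3),
  cup  = list(center = c(136, 124), semiaxes = c(40, 30), rotation = 0.1))
extract_cdr_profile(rm$mask, eye_id = "demo")
#> <cdr_profile 'demo': 24 directions, vCDR 0.488, CDAR 0.250>
```

`rm$profile` carries the exact ray–ellipse profile, which the rasterized
extraction matches within 0.02 per direction.

See `vignettes/spagen-methods.Rmd` for the model assumptions, parameter
accounting, numerical choices and the limits of what the synthetic data
can demonstrate.

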