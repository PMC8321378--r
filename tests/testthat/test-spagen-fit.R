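test_that("maximum likelihood recovers the generating parameters", {
  truth <- test_truth()
  tab <- suppressMessages(sample_profiles(500, params = truth, seed = 101))
  fit <- spagen(tab)
  expect_true(fit$converged)
  expect_identical(fit$n_params, 15L)

  z <- abs(fit$coefficients - truth_fixed[names(fit$coefficients)]) / fit$se
  expect_true(all(z < 3))
  expect_lt(abs(fit$params$sigma_z2 / truth$sigma_z2 - 1), 0.2)
  expect_lt(abs(fit$params$sigma_G2 / truth$sigma_G2 - 1), 0.2)
  expect_lt(abs(fit$params$sigma_H2 / truth$sigma_H2 - 1), 0.2)
  expect_equal(fit$params$prior_G, mean(tab$label == "glaucoma"))
})

test_that("a zero random-effect variance is recovered at the boundary", {
  p0 <- spagen_params(0.25, 0.12, 0.4, c(0, 0.06, 0, 0.03), c(0, 0.02, 0, 0.01),
                      sigma_z2 = 0, sigma_G2 = 0.006, sigma_H2 = 0.003,
                      prior_G = 0.26)
  tab <- suppressMessages(sample_profiles(1000, params = p0, seed = 7))
  fit <- spagen(tab)
  expect_lte(fit$params$sigma_z2, 0.005)
})

test_that("likelihood is additive: duplicating eyes doubles the log-likelihood", {
  tab <- suppressMessages(sample_profiles(120, seed = 19))
  fit1 <- spagen(tab)
  fit2 <- spagen(rbind(tab, tab))
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-6)
  expect_equal(fit2$loglik, 2 * fit1$loglik, tolerance = 1e-8)
})

test_that("fitting requires both groups and matching configuration", {
  tab <- suppressMessages(sample_profiles(60, seed = 3))
  solo <- tab[tab$label == "healthy", ]
  expect_error(spagen(solo), class = "spagen_input_error")
  expect_error(spagen(tab, config = spagen_config(n_dirs = 12)),
               class = "spagen_input_error")
  unlab <- tab; unlab$label <- NA
  expect_error(spagen(unlab), class = "spagen_input_error")
})

test_that("posterior probabilities follow the Bayes ratio", {
  truth <- test_truth()
  set.seed(31)
  for (i in 1:25) {
    y <- runif(24); cd <- runif(1)
    fG <- exp(dense_mvn_logdens(y, mean_vector(truth, "glaucoma", cd),
                                covariance_matrix(truth, "glaucoma")))
    fH <- exp(dense_mvn_logdens(y, mean_vector(truth, "healthy", cd),
                                covariance_matrix(truth, "healthy")))
    pG <- truth$prior_G
    expect_equal(posterior_glaucoma(y, cd, truth),
                 pG * fG / (pG * fG + (1 - pG) * fH), tolerance = 1e-10)
  }
  # degenerate priors and equal moments
  p1 <- truth; p1$prior_G <- 1 - 1e-12
  expect_equal(posterior_glaucoma(runif(24), 0.4, p1), 1.0, tolerance = 1e-9)
  peq <- spagen_params(0.4, 0, NA, rep(0, 4), rep(0, 4), 0.01, 0.02, 0.02,
                       prior_G = 0.5, config = spagen_config(use_cdar = FALSE))
  expect_equal(posterior_glaucoma(runif(24), fit = peq), 0.5)
  expect_error(posterior_glaucoma(runif(12), 0.4, truth),
               class = "spagen_input_error")
})

test_that("posterior is strictly increasing in the prior", {
  truth <- test_truth()
  set.seed(32)
  # a profile between the two group means, where both densities are positive
  cd <- 0.4
  y <- (mean_vector(truth, "glaucoma", cd) +
          mean_vector(truth, "healthy", cd)) / 2 + rnorm(24, 0, 0.02)
  priors <- seq(0.05, 0.95, by = 0.1)
  post <- vapply(priors, function(p) {
    pp <- truth; pp$prior_G <- p
    posterior_glaucoma(y, cd, pp)
  }, 0)
  expect_true(all(diff(post) > 0))
  expect_true(all(post >= 0 & post <= 1))
})

test_that("RDS equals the prior-adjusted posterior log-odds under a shared variance", {
  cfg <- spagen_config(n_variances = 1)
  par <- spagen_params(0.3, 0.1, 0.4, c(0, 0.05, 0, 0.02), c(0, 0.02, 0, 0.01),
                       0.004, 0.005, prior_G = 0.3, config = cfg)
  set.seed(41)
  for (i in 1:100) {
    y <- runif(24); cd <- runif(1)
    p <- posterior_glaucoma(y, cd, par)
    r <- rim_deformation_score(y, cd, par)
    expect_equal(log(p / (1 - p) * (1 - 0.3) / 0.3), r, tolerance = 1e-8)
    # the two equivalent decision rules agree
    expect_identical(classify(p, 0.5), classify(r, rds_threshold(0.5, 0.3), "rds"))
  }
  # y at the healthy mean: RDS is minus half the squared distance to mu_G
  muH <- mean_vector(par, "healthy", 0.4)
  expect_lte(rim_deformation_score(muH, 0.4, par), 0)
  # equal means and covariances: RDS identically zero
  peq <- spagen_params(0.4, 0, NA, c(0, 0.02, 0, 0.01), c(0, 0.02, 0, 0.01),
                       0.01, 0.02, config = spagen_config(use_cdar = FALSE,
                                                          n_variances = 1))
  expect_equal(rim_deformation_score(runif(24), fit = peq), 0, tolerance = 1e-10)
})

test_that("fits serialize to JSON and classify identically after reload", {
  tab <- suppressMessages(sample_profiles(150, seed = 55))
  fit <- spagen(tab)
  f <- withr::local_tempfile(fileext = ".json")
  write_spagen_fit(fit, f)
  back <- read_spagen_fit(f)
  expect_identical(back$n_params, 15L)
  y <- as.numeric(tab[1, paste0("d", 1:24)])
  expect_equal(posterior_glaucoma(y, tab$cdar[1], back$params),
               posterior_glaucoma(y, tab$cdar[1], fit), tolerance = 1e-12)
})

test_that("model methods expose the standard interface", {
  tab <- suppressMessages(sample_profiles(150, seed = 56))
  fit <- spagen(tab)
  expect_s3_class(fit, "spagen")
  expect_output(print(summary(fit)), "Fixed effects")
  expect_length(coef(fit), 11 + 4)
  ll <- logLik(fit)
  expect_identical(attr(ll, "df"), 15L)

  sc <- predict(fit)
  expect_named(sc, c("eye_id", "posterior", "rds", "decision"))
  expect_true(all(sc$posterior >= 0 & sc$posterior <= 1))
  # training-set separation is at least chance level
  expect_gte(roc_auroc(sc$posterior, tab$label), 0.5)

  r <- residuals(fit)
  expect_identical(dim(r), c(150L, 24L))
  rc <- residuals(fit, type = "conditional")
  expect_lt(mean(abs(rowMeans(rc))), mean(abs(rowMeans(r))))

  sim <- simulate(fit, seed = 9)
  expect_identical(nrow(sim), 150L)
})

test_that("the CDAR-only baseline sits between chance and the full model", {
  tab_tr <- suppressMessages(sample_profiles(800, seed = 71))
  tab_te <- suppressMessages(sample_profiles(800, seed = 72))
  fit <- spagen(tab_tr)
  base <- cdar_discriminant(tab_tr)
  expect_identical(base$n_params, 2L)
  a_full <- roc_auroc(predict(fit, tab_te)$posterior, tab_te$label)
  a_cdar <- roc_auroc(predict(base, tab_te), tab_te$label)
  expect_gt(a_cdar, 0.6)
  expect_lt(a_cdar, a_full)
})
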