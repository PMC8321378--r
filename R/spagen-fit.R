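#' Fit the SpaGen generative classifier by maximum likelihood
#'
#' Fits the hierarchical Gaussian profile model to labelled CDR profiles.
#' Fixed effects are profiled out by generalized least squares given the
#' variance components, which are optimized numerically on the log scale
#' (the Gaussian likelihood is well behaved and a single start is used).
#' The prior glaucoma probability is set to the training prevalence unless
#' supplied.
#'
#' @param data a profile table (see [read_profiles()]) with columns
#'   `eye_id`, `d1..dN`, `cdar`, and a `label` column of `"glaucoma"` /
#'   `"healthy"` values; at least two eyes per group.
#' @param config a [spagen_config()]; `n_dirs` must match the table.
#' @param prior optional prior glaucoma probability in (0, 1); default is
#'   the training prevalence.
#' @param control passed to [stats::optim()] (Nelder-Mead over the log
#'   variances); defaults tighten `reltol` to `1e-12`.
#' @return An object of class `spagen` with components `config`, `params`
#'   (a [spagen_params()]), `coefficients`, `se`, `vcov` (fixed effects,
#'   conditional on the variances), `loglik`, `converged`, `n_params`,
#'   `n_eyes`, `prevalence` and the training `data`.
#' @seealso [predict.spagen()], [rim_deformation_score()], [sample_profiles()]
#' @examples
#' truth <- default_generating_params()
#' tab <- sample_profiles(n_eyes = 200, params = truth, seed = 1)
#' fit <- spagen(tab)
#' fit
#' @export
spagen <- function(data, config = spagen_config(), prior = NULL,
                   control = list()) {
  pm <- profile_matrix(data)
  Y <- pm$Y
  if (ncol(Y) != config$n_dirs) {
    abort_input(sprintf("profile table has %d directions but config expects %d",
                        ncol(Y), config$n_dirs))
  }
  lab <- pm$label
  if (anyNA(lab)) abort_input("all eyes must be labelled for fitting")
  if (!all(lab %in% c("glaucoma", "healthy"))) {
    abort_input("labels must be 'glaucoma' or 'healthy'")
  }
  is_g <- lab == "glaucoma"
  if (sum(is_g) < 2L || sum(!is_g) < 2L) {
    abort_input("need at least two eyes in each diagnostic group")
  }
  cdar <- pm$cdar
  if (config$use_cdar && anyNA(cdar)) {
    abort_input("cdar column required: configuration uses CDAR")
  }

  d <- config$n_dirs
  B <- fourier_basis(d, config$n_harmonics)
  nf <- ncol(B)
  ones <- rep(1, d)
  zerB <- matrix(0, d, nf)
  p <- 2L + as.integer(config$use_cdar) + 2L * nf
  coef_names <- c("beta0", "betaG0",
                  if (config$use_cdar) "betaCDAR",
                  paste0("G_", colnames(B)), paste0("H_", colnames(B)))

  design_for <- function(i) {
    g <- is_g[i]
    cols <- list(ones, if (g) ones else rep(0, d))
    if (config$use_cdar) cols <- c(cols, list(cdar[i] * ones))
    cols <- c(cols, list(if (g) B else zerB), list(if (g) zerB else B))
    do.call(cbind, cols)
  }
  X_list <- lapply(seq_len(nrow(Y)), design_for)

  gls_beta <- function(sz2, s2G, s2H) {
    XtVX <- matrix(0, p, p)
    XtVy <- numeric(p)
    for (i in seq_len(nrow(Y))) {
      s2 <- if (is_g[i]) s2G else s2H
      a <- 1 / s2
      b <- sz2 / (s2 * (s2 + d * sz2))
      Xi <- X_list[[i]]
      cs <- colSums(Xi)
      XtVX <- XtVX + a * crossprod(Xi) - b * tcrossprod(cs)
      XtVy <- XtVy + a * crossprod(Xi, Y[i, ]) - b * cs * sum(Y[i, ])
    }
    list(beta = drop(solve(XtVX, XtVy)), XtVX = XtVX)
  }

  loglik_at <- function(sz2, s2G, s2H, beta) {
    ll <- 0
    for (i in seq_len(nrow(Y))) {
      s2 <- if (is_g[i]) s2G else s2H
      ll <- ll + mvn_logdens_cs(Y[i, ], drop(X_list[[i]] %*% beta), sz2, s2)
    }
    ll
  }

  # moment-based starting values from OLS residuals
  ols <- gls_beta(0, 1, 1)
  R <- Y - t(vapply(seq_len(nrow(Y)), function(i)
    drop(X_list[[i]] %*% ols$beta), numeric(d)))
  within <- apply(R, 1, stats::var)
  s2_start <- c(G = mean(within[is_g]), H = mean(within[!is_g]))
  rbar <- rowMeans(R)
  sz_start <- max(stats::var(rbar) - mean(s2_start) / d, 1e-5)

  unpack <- function(th) {
    sz2 <- exp(th[1])
    if (config$n_variances == 2L) {
      list(sz2 = sz2, s2G = exp(th[2]), s2H = exp(th[3]))
    } else {
      list(sz2 = sz2, s2G = exp(th[2]), s2H = exp(th[2]))
    }
  }
  nll <- function(th) {
    v <- unpack(th)
    bt <- gls_beta(v$sz2, v$s2G, v$s2H)
    -loglik_at(v$sz2, v$s2G, v$s2H, bt$beta)
  }
  th0 <- if (config$n_variances == 2L) {
    log(c(sz_start, s2_start[["G"]], s2_start[["H"]]))
  } else {
    log(c(sz_start, mean(s2_start)))
  }
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 2000), control)
  opt <- stats::optim(th0, nll, method = "Nelder-Mead", control = ctrl)
  converged <- opt$convergence == 0L
  if (!converged) {
    warn_spagen("variance optimization did not converge; returning partial fit",
                "spagen_convergence_warning")
  }

  v <- unpack(opt$par)
  bt <- gls_beta(v$sz2, v$s2G, v$s2H)
  beta <- stats::setNames(bt$beta, coef_names)
  vcov_beta <- solve(bt$XtVX)
  dimnames(vcov_beta) <- list(coef_names, coef_names)
  loglik <- loglik_at(v$sz2, v$s2G, v$s2H, bt$beta)

  prevalence <- mean(is_g)
  prior_G <- if (is.null(prior)) prevalence else prior
  if (prior_G <= 0 || prior_G >= 1) abort_input("prior must lie in (0, 1)")

  fi <- seq_len(2L * nf)
  params <- spagen_params(
    beta0 = beta[["beta0"]], betaG0 = beta[["betaG0"]],
    betaCDAR = if (config$use_cdar) beta[["betaCDAR"]] else NA_real_,
    fourierG = beta[2L + config$use_cdar + seq_len(nf)],
    fourierH = beta[2L + config$use_cdar + nf + seq_len(nf)],
    sigma_z2 = v$sz2, sigma_G2 = v$s2G, sigma_H2 = v$s2H,
    prior_G = prior_G, config = config)

  structure(list(config = config, params = params,
                 coefficients = beta, se = sqrt(diag(vcov_beta)),
                 vcov = vcov_beta, loglik = loglik, converged = converged,
                 n_params = count_parameters(config), n_eyes = nrow(Y),
                 prevalence = prevalence, data = data,
                 call = match.call()),
            class = "spagen")
}

#' @export
print.spagen <- function(x, ...) {
  cat("SpaGen generative classifier\n")
  cat(sprintf("  %s\n", config_name(x$config)))
  cat(sprintf("  %d eyes (prevalence %.3f), logLik %.2f%s\n",
              x$n_eyes, x$prevalence, x$loglik,
              if (x$converged) "" else " [not converged]"))
  cat(sprintf("  variances: sigma_z2 = %.3g, sigma_G2 = %.3g, sigma_H2 = %.3g\n",
              x$params$sigma_z2, x$params$sigma_G2, x$params$sigma_H2))
  invisible(x)
}

#' @export
summary.spagen <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$coefficients / object$se)
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.spagen"
  out
}

#' @export
print.summary.spagen <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects (GLS, conditional on variances):\n")
  stats::printCoefmat(x$coef_table, digits = 4)
  cat(sprintf("\nprior_G = %.3f; %d free parameters\n",
              x$fit$params$prior_G, x$fit$n_params))
  invisible(x)
}

#' @export
coef.spagen <- function(object, ...) {
  c(object$coefficients,
    sigma_z2 = object$params$sigma_z2, sigma_G2 = object$params$sigma_G2,
    sigma_H2 = object$params$sigma_H2, prior_G = object$params$prior_G)
}

#' @export
logLik.spagen <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_eyes,
            class = "logLik")
}

# Table-style human-readable configuration name.
config_name <- function(config) {
  sprintf("CDR profile of %d values and %d variance parameter%s%s (%d)",
          config$n_dirs, config$n_variances,
          if (config$n_variances > 1L) "s" else "",
          if (config$use_cdar) " and CDAR" else "",
          count_parameters(config))
}

# Squared Mahalanobis distance under compound-symmetric covariance.
mahalanobis2_cs <- function(y, mu, sigma_z2, sigma2) {
  r <- y - mu
  n <- length(r)
  (sum(r^2) - sigma_z2 / (sigma2 + n * sigma_z2) * sum(r)^2) / sigma2
}

params_of <- function(fit) if (inherits(fit, "spagen")) fit$params else fit

#' Posterior probability of glaucoma for a new eye
#'
#' Bayes posterior `pG * fG / (pG * fG + pH * fH)` where `fG`, `fH` are the
#' group Gaussian densities of the profile (given CDAR when configured) and
#' `pG`, `pH` the prior group probabilities.  Computed in log space.
#'
#' @param y numeric CDR profile of length `n_dirs`.
#' @param cdar CDAR value (required iff the model uses CDAR).
#' @param fit a fitted [spagen()] model (or a [spagen_params()] object).
#' @return Posterior probability in `[0, 1]`.
#' @export
posterior_glaucoma <- function(y, cdar = NA_real_, fit) {
  par <- params_of(fit)
  if (length(y) != par$config$n_dirs) {
    abort_input(sprintf("profile has length %d but model expects %d",
                        length(y), par$config$n_dirs))
  }
  lG <- mvn_logdens_cs(y, mean_vector(par, "glaucoma", cdar),
                       par$sigma_z2, par$sigma_G2)
  lH <- mvn_logdens_cs(y, mean_vector(par, "healthy", cdar),
                       par$sigma_z2, par$sigma_H2)
  stats::plogis(log(par$prior_G) + lG - log(1 - par$prior_G) - lH)
}

#' Rim Deformation Score
#'
#' Half the difference of the squared Mahalanobis distances of the profile
#' from the healthy and glaucomatous group distributions, each with its own
#' covariance:
#' `RDS = (d_M^2(y, mu_H) - d_M^2(y, mu_G)) / 2`.
#' Under a shared covariance this equals the prior-adjusted log-odds of the
#' posterior, so thresholding RDS and thresholding the posterior give the
#' same decisions.
#'
#' @inheritParams posterior_glaucoma
#' @return RDS (real; positive values favour glaucoma).
#' @export
rim_deformation_score <- function(y, cdar = NA_real_, fit) {
  par <- params_of(fit)
  if (length(y) != par$config$n_dirs) {
    abort_input(sprintf("profile has length %d but model expects %d",
                        length(y), par$config$n_dirs))
  }
  dH <- mahalanobis2_cs(y, mean_vector(par, "healthy", cdar),
                        par$sigma_z2, par$sigma_H2)
  dG <- mahalanobis2_cs(y, mean_vector(par, "glaucoma", cdar),
                        par$sigma_z2, par$sigma_G2)
  (dH - dG) / 2
}

#' Threshold decision rule
#'
#' Declares glaucoma when the score is greater than or equal to the
#' threshold, for either a posterior probability or an RDS score.  The RDS
#' threshold equivalent to a posterior threshold `p_th` under a shared
#' covariance is `log(p_th / (1 - p_th) * (1 - p_G) / p_G)`.
#'
#' @param score numeric score(s).
#' @param threshold decision threshold.
#' @param kind `"posterior"` or `"rds"` (documentation of the score scale;
#'   the rule is the same).
#' @return Character vector of `"glaucoma"` / `"healthy"`.
#' @export
classify <- function(score, threshold, kind = c("posterior", "rds")) {
  match.arg(kind)
  ifelse(score >= threshold, "glaucoma", "healthy")
}

#' Posterior-to-RDS threshold conversion
#'
#' @param p_th posterior probability threshold in (0, 1).
#' @param prior_G prior glaucoma probability in (0, 1).
#' @return The equivalent RDS threshold (exact under a shared group
#'   covariance).
#' @export
rds_threshold <- function(p_th, prior_G) {
  log(p_th / (1 - p_th) * (1 - prior_G) / prior_G)
}

#' Predict method for SpaGen fits
#'
#' @param object a fitted [spagen()] model.
#' @param newdata a profile table; defaults to the training data.
#' @param type `"scores"` (default: data.frame of posterior, RDS and
#'   decision), `"posterior"`, `"rds"` or `"decision"`.
#' @param threshold posterior threshold for the decision (default 0.5).
#' @param ... unused.
#' @return A data.frame (`type = "scores"`) or a vector.
#' @export
predict.spagen <- function(object, newdata = object$data,
                           type = c("scores", "posterior", "rds", "decision"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  pm <- profile_matrix(newdata)
  if (ncol(pm$Y) != object$config$n_dirs) {
    abort_input(sprintf("profile table has %d directions but model expects %d",
                        ncol(pm$Y), object$config$n_dirs))
  }
  if (object$config$use_cdar && anyNA(pm$cdar)) {
    abort_input("cdar column required: model uses CDAR")
  }
  post <- vapply(seq_len(nrow(pm$Y)), function(i)
    posterior_glaucoma(pm$Y[i, ], pm$cdar[i], object), 0)
  rds <- vapply(seq_len(nrow(pm$Y)), function(i)
    rim_deformation_score(pm$Y[i, ], pm$cdar[i], object), 0)
  dec <- classify(post, threshold)
  switch(type,
         scores = data.frame(eye_id = newdata$eye_id, posterior = post,
                             rds = rds, decision = dec,
                             stringsAsFactors = FALSE),
         posterior = post, rds = rds, decision = dec)
}

#' @export
residuals.spagen <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  pm <- profile_matrix(object$data)
  par <- object$params
  d <- object$config$n_dirs
  R <- t(vapply(seq_len(nrow(pm$Y)), function(i) {
    g <- if (pm$label[i] == "glaucoma") "glaucoma" else "healthy"
    pm$Y[i, ] - mean_vector(par, g, pm$cdar[i])
  }, numeric(d)))
  if (type == "conditional") {
    # subtract the BLUP of the per-eye random effect
    for (i in seq_len(nrow(R))) {
      s2 <- if (pm$label[i] == "glaucoma") par$sigma_G2 else par$sigma_H2
      shrink <- d * par$sigma_z2 / (s2 + d * par$sigma_z2)
      R[i, ] <- R[i, ] - shrink * mean(R[i, ])
    }
  }
  R
}

#' @export
simulate.spagen <- function(object, nsim = 1, seed = NULL,
                            n_eyes = object$n_eyes, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(nsim), function(k)
    sample_profiles(n_eyes = n_eyes, params = object$params,
                    glaucoma_fraction = object$prevalence))
  if (nsim == 1L) sims[[1]] else sims
}

#' @export
plot.spagen <- function(x, ...) {
  cfg <- x$config
  ang <- (seq_len(cfg$n_dirs) - 1) * 360 / cfg$n_dirs
  cd <- if (cfg$use_cdar) {
    pm <- profile_matrix(x$data)
    c(G = mean(pm$cdar[pm$label == "glaucoma"]),
      H = mean(pm$cdar[pm$label == "healthy"]))
  } else c(G = NA, H = NA)
  muG <- mean_vector(x$params, "glaucoma", cd[["G"]])
  muH <- mean_vector(x$params, "healthy", cd[["H"]])
  sdG <- sqrt(x$params$sigma_z2 + x$params$sigma_G2)
  sdH <- sqrt(x$params$sigma_z2 + x$params$sigma_H2)
  graphics::plot(ang, muG, type = "n", ylim = range(0, 1, muG + 2 * sdG, muH - 2 * sdH),
                 xlab = "direction (degrees)", ylab = "CDR",
                 main = "SpaGen group mean profiles (+/- 2 SD)", ...)
  graphics::polygon(c(ang, rev(ang)), c(muG + 2 * sdG, rev(muG - 2 * sdG)),
                    col = grDevices::adjustcolor("firebrick", 0.15), border = NA)
  graphics::polygon(c(ang, rev(ang)), c(muH + 2 * sdH, rev(muH - 2 * sdH)),
                    col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  graphics::lines(ang, muG, col = "firebrick", lwd = 2)
  graphics::lines(ang, muH, col = "steelblue", lwd = 2)
  graphics::legend("topright", c("glaucoma", "healthy"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

# --- serialization --------------------------------------------------------

#' Serialize or restore a SpaGen fit as flat JSON
#'
#' @param fit a fitted [spagen()] model.
#' @param path JSON file path.
#' @return `write_spagen_fit()`: `path`; `read_spagen_fit()`: a list with
#'   a `params` ([spagen_params()]) usable by [posterior_glaucoma()] and
#'   [rim_deformation_score()], plus `loglik`, `converged`, `n_params`.
#' @export
write_spagen_fit <- function(fit, path) {
  par <- fit$params
  cfg <- fit$config
  obj <- list(config = unclass(cfg),
              beta0 = par$beta0, betaG0 = par$betaG0, betaCDAR = par$betaCDAR,
              fourierG = par$fourierG, fourierH = par$fourierH,
              sigma_z2 = par$sigma_z2, sigma_G2 = par$sigma_G2,
              sigma_H2 = par$sigma_H2, prior_G = par$prior_G,
              loglik = fit$loglik, converged = fit$converged,
              n_params = fit$n_params, n_eyes = fit$n_eyes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spagen_fit
#' @export
read_spagen_fit <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s'", path))
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- spagen_config(o$config$use_cdar, o$config$n_variances,
                       o$config$n_dirs, o$config$n_harmonics)
  par <- spagen_params(o$beta0, o$betaG0, o$betaCDAR %||% NA_real_,
                       o$fourierG, o$fourierH, o$sigma_z2, o$sigma_G2,
                       o$sigma_H2, o$prior_G, cfg)
  list(config = cfg, params = par, loglik = o$loglik,
       converged = o$converged, n_params = o$n_params, n_eyes = o$n_eyes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CDAR-only baseline discriminant
#'
#' A two-parameter (intercept + slope) logistic discriminant on the
#' cup-to-disc area ratio alone, scored by the same ROC machinery as the
#' full model.  Serves as the minimal reference configuration.
#'
#' @param data labelled profile table with a `cdar` column.
#' @return Object of class `cdar_discriminant` with a `predict` method
#'   returning glaucoma probabilities.
#' @export
cdar_discriminant <- function(data) {
  if (anyNA(data$cdar)) abort_input("cdar column required")
  y <- data$label == "glaucoma"
  if (!any(y) || all(y)) abort_input("need both diagnostic groups")
  fit <- stats::glm(y ~ cdar, family = stats::binomial(), data = data)
  structure(list(glm = fit, coefficients = stats::coef(fit), n_params = 2L),
            class = "cdar_discriminant")
}

#' @export
predict.cdar_discriminant <- function(object, newdata, ...) {
  unname(stats::predict(object$glm, newdata = newdata, type = "response"))
}

#' @export
print.cdar_discriminant <- function(x, ...) {
  cat(sprintf("<cdar_discriminant (2): intercept %.3f, slope %.3f>\n",
              x$coefficients[1], x$coefficients[2]))
  invisible(x)
}
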