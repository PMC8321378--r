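#' SpaGen model configuration
#'
#' Describes one variant of the hierarchical Gaussian generative model of a
#' directional CDR profile.  The mean of a profile is a per-group Fourier
#' series in the direction angle (two harmonics by default) plus an overall
#' intercept, a glaucoma intercept shift and, optionally, a shared
#' cup-to-disc area ratio (CDAR) covariate.  The covariance of a profile is
#' compound symmetric: a per-eye random effect with variance `sigma_z2`
#' shared by all directions plus independent per-direction noise whose
#' variance is either shared between groups (`n_variances = 1`) or
#' group-specific (`n_variances = 2`).
#'
#' @param use_cdar include the CDAR fixed effect (default `TRUE`).
#' @param n_variances 1 (shared noise variance) or 2 (group-specific).
#' @param n_dirs number of profile directions (>= 4; default 24).
#' @param n_harmonics number of Fourier harmonics per group (default 2,
#'   i.e. sine/cosine at one and two cycles per revolution).
#' @return An object of class `spagen_config`.
#' @examples
#' count_parameters(spagen_config())                      # 15
#' count_parameters(spagen_config(use_cdar = FALSE, n_variances = 1))  # 13
#' @export
spagen_config <- function(use_cdar = TRUE, n_variances = 2L, n_dirs = 24L,
                          n_harmonics = 2L) {
  if (!n_variances %in% 1:2) abort_input("n_variances must be 1 or 2")
  if (n_dirs < 4L) abort_input("n_dirs must be at least 4")
  if (n_harmonics < 1L) abort_input("n_harmonics must be at least 1")
  structure(list(use_cdar = isTRUE(use_cdar),
                 n_variances = as.integer(n_variances),
                 n_dirs = as.integer(n_dirs),
                 n_harmonics = as.integer(n_harmonics)),
            class = "spagen_config")
}

#' @export
print.spagen_config <- function(x, ...) {
  cat(sprintf("<spagen_config: %d dirs, %d harmonic(s), %s, %d noise variance(s); %d parameters>\n",
              x$n_dirs, x$n_harmonics,
              if (x$use_cdar) "with CDAR" else "no CDAR",
              x$n_variances, count_parameters(x)))
  invisible(x)
}

#' Number of free parameters of a SpaGen configuration
#'
#' Counts 1 (the prior glaucoma probability) + the fixed effects (overall
#' intercept, glaucoma intercept shift, the CDAR coefficient when present,
#' and `2 * n_harmonics` Fourier coefficients per group) + the variance
#' components (the random-effect variance plus one or two noise variances).
#' The default configuration has 15 parameters (1 + 11 + 3).
#'
#' @param config a [spagen_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  fixed <- 2L + as.integer(config$use_cdar) + 2L * 2L * config$n_harmonics
  1L + fixed + 1L + config$n_variances
}

#' SpaGen parameter set
#'
#' @param beta0 overall intercept.
#' @param betaG0 glaucoma intercept shift.
#' @param betaCDAR CDAR coefficient (required iff the configuration uses
#'   CDAR; otherwise must be `NA` or 0).
#' @param fourierG,fourierH Fourier coefficients per group, length
#'   `2 * n_harmonics`, ordered sin/cos by increasing harmonic (for the
#'   default two harmonics: sin 2*pi*d/n, cos 2*pi*d/n, sin 4*pi*d/n,
#'   cos 4*pi*d/n).
#' @param sigma_z2 variance of the per-eye random effect (>= 0).
#' @param sigma_G2,sigma_H2 noise variances for the glaucomatous and healthy
#'   groups (> 0 for density evaluation; 0 admitted for noiseless forward
#'   simulation); must be equal when `n_variances = 1`.
#' @param prior_G prior probability of glaucoma, in (0, 1).
#' @param config a [spagen_config()].
#' @return An object of class `spagen_params`.
#' @export
spagen_params <- function(beta0, betaG0, betaCDAR = NA_real_, fourierG, fourierH,
                          sigma_z2, sigma_G2, sigma_H2 = sigma_G2,
                          prior_G = 0.5, config = spagen_config()) {
  nf <- 2L * config$n_harmonics
  if (length(fourierG) != nf || length(fourierH) != nf) {
    abort_input(sprintf("fourierG/fourierH must have length %d", nf))
  }
  if (config$use_cdar && !is.finite(betaCDAR)) {
    abort_input("betaCDAR required when the configuration uses CDAR")
  }
  if (sigma_z2 < 0) abort_input("sigma_z2 must be >= 0")
  # zero noise variances are admitted for forward simulation (noiseless
  # limit); density evaluation requires them strictly positive
  if (sigma_G2 < 0 || sigma_H2 < 0) abort_input("noise variances must be >= 0")
  if (config$n_variances == 1L && sigma_G2 != sigma_H2) {
    abort_input("n_variances = 1 requires sigma_G2 == sigma_H2")
  }
  if (prior_G <= 0 || prior_G >= 1) abort_input("prior_G must lie in (0, 1)")
  structure(list(beta0 = beta0, betaG0 = betaG0,
                 betaCDAR = if (config$use_cdar) betaCDAR else NA_real_,
                 fourierG = as.numeric(fourierG), fourierH = as.numeric(fourierH),
                 sigma_z2 = sigma_z2, sigma_G2 = sigma_G2, sigma_H2 = sigma_H2,
                 prior_G = prior_G, config = config),
            class = "spagen_params")
}

# Fourier design block: n_dirs x (2 * n_harmonics), columns sin/cos per
# harmonic at frequency 2*pi*k*d/n_dirs, d = 1..n_dirs.
fourier_basis <- function(n_dirs, n_harmonics) {
  d <- seq_len(n_dirs)
  cols <- lapply(seq_len(n_harmonics), function(k) {
    w <- 2 * pi * k * d / n_dirs
    cbind(sin(w), cos(w))
  })
  B <- do.call(cbind, cols)
  colnames(B) <- as.vector(vapply(seq_len(n_harmonics), function(k)
    c(sprintf("sin%d", k), sprintf("cos%d", k)), character(2)))
  B
}

#' Group mean profile under a SpaGen parameter set
#'
#' Element `d` of the mean is the overall intercept, plus the glaucoma shift
#' for glaucomatous eyes, plus the CDAR term when configured, plus that
#' group's Fourier series evaluated at direction `d`.
#'
#' @param params a [spagen_params()].
#' @param group `"glaucoma"` or `"healthy"`.
#' @param cdar CDAR value in `[0, 1]`; required iff the configuration uses
#'   CDAR.
#' @return Numeric vector of length `n_dirs`.
#' @export
mean_vector <- function(params, group = c("glaucoma", "healthy"), cdar = NA_real_) {
  group <- match.arg(group)
  cfg <- params$config
  mu <- rep(params$beta0, cfg$n_dirs)
  if (cfg$use_cdar) {
    if (!is.finite(cdar)) abort_input("cdar required: configuration uses CDAR")
    mu <- mu + params$betaCDAR * cdar
  }
  B <- fourier_basis(cfg$n_dirs, cfg$n_harmonics)
  if (group == "glaucoma") {
    mu <- mu + params$betaG0 + drop(B %*% params$fourierG)
  } else {
    mu <- mu + drop(B %*% params$fourierH)
  }
  mu
}

#' Marginal profile covariance under a SpaGen parameter set
#'
#' Integrating out the per-eye random effect gives the compound-symmetric
#' covariance `sigma_z2 * J + sigma_g2 * I` where `J` is all-ones, `I` the
#' identity and `sigma_g2` the group's noise variance.  Its eigenvalues are
#' `sigma_g2` (multiplicity `n_dirs - 1`) and
#' `sigma_g2 + n_dirs * sigma_z2` (multiplicity 1).
#'
#' @inheritParams mean_vector
#' @return `n_dirs x n_dirs` covariance matrix.
#' @export
covariance_matrix <- function(params, group = c("glaucoma", "healthy")) {
  group <- match.arg(group)
  s2 <- if (group == "glaucoma") params$sigma_G2 else params$sigma_H2
  n <- params$config$n_dirs
  matrix(params$sigma_z2, n, n) + diag(s2, n)
}

#' Group moments (mean and covariance) for one eye
#'
#' @inheritParams mean_vector
#' @return A list of class `group_moments` with elements `mean`, `cov`,
#'   `sigma_z2`, `sigma2`.
#' @export
group_moments <- function(params, group = c("glaucoma", "healthy"), cdar = NA_real_) {
  group <- match.arg(group)
  s2 <- if (group == "glaucoma") params$sigma_G2 else params$sigma_H2
  structure(list(mean = mean_vector(params, group, cdar),
                 cov = covariance_matrix(params, group),
                 sigma_z2 = params$sigma_z2, sigma2 = s2),
            class = "group_moments")
}

# Core closed-form compound-symmetry Gaussian log-density.
# V = sigma_z2 * J + sigma2 * I; uses
#   V^{-1} = (1/sigma2) (I - sigma_z2 / (sigma2 + n sigma_z2) J)
#   log|V| = (n - 1) log sigma2 + log(sigma2 + n sigma_z2)
mvn_logdens_cs <- function(y, mu, sigma_z2, sigma2) {
  n <- length(y)
  r <- y - mu
  tot <- sigma2 + n * sigma_z2
  if (sigma2 <= 0 || tot <= 0) abort_numeric("covariance is not positive definite")
  quad <- (sum(r^2) - sigma_z2 / tot * sum(r)^2) / sigma2
  logdet <- (n - 1) * log(sigma2) + log(tot)
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

#' Multivariate normal log-density under compound-symmetric moments
#'
#' Evaluates the Gaussian log-density of a profile under [group_moments()]
#' using the two-eigenvalue closed form of the compound-symmetric
#' covariance (no dense solve or determinant).  When called with a plain
#' mean/covariance pair, the compound-symmetry components are recovered
#' from the matrix (which must be compound symmetric).
#'
#' @param y numeric vector.
#' @param moments a [group_moments()] object, or a list with elements
#'   `mean` and `cov`.
#' @return Log-density (scalar).
#' @export
log_density <- function(y, moments) {
  if (is.null(moments$sigma2)) {
    V <- moments$cov
    n <- nrow(V)
    sz <- if (n > 1L) mean(V[upper.tri(V)]) else 0
    s2 <- mean(diag(V)) - sz
    if (n > 1L) {
      dev <- max(abs(V - (matrix(sz, n, n) + diag(s2, n))))
      if (dev > 1e-8 * max(abs(V))) {
        abort_input("covariance is not compound symmetric")
      }
    }
    moments <- list(mean = moments$mean, sigma_z2 = sz, sigma2 = s2)
  }
  if (length(y) != length(moments$mean)) abort_input("length mismatch between y and mean")
  if (any(!is.finite(y))) abort_input("y must be finite")
  mvn_logdens_cs(y, moments$mean, moments$sigma_z2, moments$sigma2)
}
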