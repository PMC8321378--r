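#' Default generating parameters for synthetic CDR profiles
#'
#' A realistic operating point for simulated eyes: healthy profiles around
#' CDR 0.4 with a mild elliptical shape, glaucomatous profiles elevated by
#' the intercept shift and the larger CDAR, with a stronger two-harmonic
#' deformation and a larger noise variance than healthy eyes.
#'
#' @param config a [spagen_config()] with two harmonics.
#' @return A [spagen_params()] object.
#' @export
default_generating_params <- function(config = spagen_config()) {
  if (config$n_harmonics != 2L) {
    abort_input("default generating parameters are defined for 2 harmonics")
  }
  spagen_params(
    beta0 = 0.25, betaG0 = 0.12,
    betaCDAR = if (config$use_cdar) 0.4 else NA_real_,
    fourierG = c(0, 0.06, 0, 0.03),
    fourierH = c(0, 0.02, 0, 0.01),
    sigma_z2 = 0.004,
    sigma_G2 = 0.006,
    sigma_H2 = if (config$n_variances == 2L) 0.003 else 0.006,
    prior_G = 0.26, config = config)
}

# Beta distribution shapes from a mean/sd pair (method of moments).
beta_shapes <- function(mean, sd) {
  v <- mean * (1 - mean) / sd^2 - 1
  if (v <= 0) abort_input("cdar law spread too large for a Beta on [0, 1]")
  c(shape1 = mean * v, shape2 = (1 - mean) * v)
}

#' Sample labelled CDR profiles from the generative model
#'
#' Forward simulation of the hierarchical model: each eye draws its group
#' from `glaucoma_fraction`, its CDAR from a Beta law with the group's
#' mean/spread, a per-eye random effect `z ~ N(0, sigma_z2)` and
#' independent directional noise `e_d ~ N(0, sigma_g2)`; the profile is the
#' group mean plus `z + e_d`, clipped to `[0, 1]` (the clipping rate is
#' attached as attribute `clip_rate`).
#'
#' @param n_eyes number of eyes to simulate.
#' @param params generating truth, a [spagen_params()].
#' @param glaucoma_fraction probability an eye is glaucomatous (default
#'   0.26, a typical screening-study prevalence).
#' @param cdar_law per-group `c(mean, sd)` of the Beta CDAR laws.
#' @param seed optional RNG seed.
#' @return A labelled profile table (data.frame in the CSV dialect), with
#'   attribute `clip_rate`.
#' @export
sample_profiles <- function(n_eyes, params = default_generating_params(),
                            glaucoma_fraction = 0.26,
                            cdar_law = list(glaucoma = c(mean = 0.50, sd = 0.12),
                                            healthy = c(mean = 0.35, sd = 0.12)),
                            seed = NULL) {
  if (n_eyes < 1L) abort_input("n_eyes must be >= 1")
  if (glaucoma_fraction <= 0 || glaucoma_fraction >= 1) {
    abort_input("glaucoma_fraction must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- params$config
  d <- cfg$n_dirs
  shG <- beta_shapes(cdar_law$glaucoma[["mean"]], cdar_law$glaucoma[["sd"]])
  shH <- beta_shapes(cdar_law$healthy[["mean"]], cdar_law$healthy[["sd"]])
  is_g <- stats::runif(n_eyes) < glaucoma_fraction
  cdar <- ifelse(is_g,
                 stats::rbeta(n_eyes, shG[1], shG[2]),
                 stats::rbeta(n_eyes, shH[1], shH[2]))
  z <- stats::rnorm(n_eyes, 0, sqrt(params$sigma_z2))
  Y <- matrix(0, n_eyes, d)
  for (i in seq_len(n_eyes)) {
    g <- if (is_g[i]) "glaucoma" else "healthy"
    s2 <- if (is_g[i]) params$sigma_G2 else params$sigma_H2
    Y[i, ] <- mean_vector(params, g, cdar[i]) + z[i] + stats::rnorm(d, 0, sqrt(s2))
  }
  clipped <- Y < 0 | Y > 1
  Y <- pmin(pmax(Y, 0), 1)
  tab <- data.frame(eye_id = sprintf("eye%05d", seq_len(n_eyes)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(d)) tab[[paste0("d", j)]] <- Y[, j]
  tab$cdar <- cdar
  up <- (round(d / 4) %% d) + 1L     # direction nearest 90 degrees
  down <- (round(3 * d / 4) %% d) + 1L
  tab$vcdr <- pmin((Y[, up] + Y[, down]) / 2, 1)  # vertical-direction proxy
  tab$label <- ifelse(is_g, "glaucoma", "healthy")
  attr(tab, "clip_rate") <- mean(clipped)
  if (any(clipped)) {
    message(sprintf("sample_profiles: clipped %.2f%% of CDR values to [0, 1]",
                    100 * mean(clipped)))
  }
  tab
}

# --- elliptical mask rendering -------------------------------------------

# Math coordinates: x along columns, y upwards (y = -row); angles CCW.
ellipse_rho <- function(px, py, center, semiaxes, rotation) {
  dx <- px - center[1]
  dy <- center[2] - py          # flip row axis to y-up
  q1 <- dx * cos(rotation) + dy * sin(rotation)
  q2 <- -dx * sin(rotation) + dy * cos(rotation)
  sqrt((q1 / semiaxes[1])^2 + (q2 / semiaxes[2])^2)
}

# Distance along ray (origin p0, angle a, CCW) to the outermost boundary
# point of an ellipse; 0 if the ray never meets it at t > 0.
ray_ellipse_distance <- function(p0, angle_deg, center, semiaxes, rotation) {
  a <- angle_deg * pi / 180
  u <- c(cos(a), sin(a))        # math coords, y-up
  d0 <- c(p0[1] - center[1], p0[2] - center[2])
  rot <- function(v) c(v[1] * cos(rotation) + v[2] * sin(rotation),
                       -v[1] * sin(rotation) + v[2] * cos(rotation))
  q0 <- rot(d0) / semiaxes
  qu <- rot(u) / semiaxes
  A <- sum(qu^2); B <- 2 * sum(q0 * qu); C <- sum(q0^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(0)
  ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  ts <- ts[ts > 0]
  if (!length(ts)) return(0)
  max(ts)
}

vertical_extent <- function(semiaxes, rotation) {
  2 * sqrt((semiaxes[1] * sin(rotation))^2 + (semiaxes[2] * cos(rotation))^2)
}

#' Render a synthetic elliptical cup/disc mask with its analytic profile
#'
#' Rasterizes a disc ellipse and a contained cup ellipse into a
#' [label_mask()] and returns the exact directional CDR profile given by
#' the ray-ellipse closed form from the disc centre, together with the
#' analytic CDAR (area ratio) and vCDR (vertical-extent ratio).  Optional
#' smooth angular boundary noise perturbs both rasterized contours.
#'
#' @param size image side length in pixels (square).
#' @param disc,cup lists with `center` (0-based `c(x, y)` pixel
#'   coordinates), `semiaxes` (`c(a, b)` in px) and optional `rotation`
#'   (radians, counter-clockwise).  The cup must be contained in the disc.
#' @param noise relative amplitude of smooth angular boundary noise
#'   (fraction of the local radius; 0 = exact ellipses).
#' @param n_dirs number of profile directions.
#' @param seed RNG seed for the boundary noise.
#' @return List with `mask` (a [label_mask()]), `profile` (the analytic
#'   [cdr_profile()]), `cdar`, `vcdr`.
#' @export
render_masks <- function(size = 256L,
                         disc = list(center = c(128, 128), semiaxes = c(80, 70),
                                     rotation = 0),
                         cup = list(center = c(128, 128), semiaxes = c(40, 35),
                                    rotation = 0),
                         noise = 0, n_dirs = 24L, seed = NULL) {
  disc$rotation <- disc$rotation %||% 0
  cup$rotation <- cup$rotation %||% 0
  # analytic containment check on the cup boundary
  phi <- seq(0, 2 * pi, length.out = 361L)[-361L]
  bx <- cup$center[1] + cup$semiaxes[1] * cos(phi) * cos(cup$rotation) -
    cup$semiaxes[2] * sin(phi) * sin(cup$rotation)
  by <- cup$center[2] - (cup$semiaxes[1] * cos(phi) * sin(cup$rotation) +
                           cup$semiaxes[2] * sin(phi) * cos(cup$rotation))
  if (any(ellipse_rho(bx, by, disc$center, disc$semiaxes, disc$rotation) > 1)) {
    abort_input("cup ellipse is not contained in the disc ellipse")
  }
  if (!is.null(seed)) set.seed(seed)
  px <- matrix(rep(seq_len(size) - 1, each = size), size, size)   # columns
  py <- matrix(rep(seq_len(size) - 1, times = size), size, size)  # rows
  rasterize <- function(ell) {
    rho <- ellipse_rho(px, py, ell$center, ell$semiaxes, ell$rotation)
    if (noise > 0) {
      th <- atan2(ell$center[2] - py, px - ell$center[1])
      co <- stats::rnorm(6, 0, noise / sqrt(3))
      eps <- co[1] * cos(th) + co[2] * sin(th) + co[3] * cos(2 * th) +
        co[4] * sin(2 * th) + co[5] * cos(3 * th) + co[6] * sin(3 * th)
      rho <- rho - eps
    }
    matrix(rho <= 1, size, size)
  }
  mask <- label_mask(rasterize(disc), rasterize(cup))
  angles <- (seq_len(n_dirs) - 1) * (360 / n_dirs)
  p0 <- c(disc$center[1], -disc$center[2])  # to y-up math coords
  mathify <- function(ell) list(center = c(ell$center[1], -ell$center[2]),
                                semiaxes = ell$semiaxes, rotation = ell$rotation)
  dm <- mathify(disc); cm <- mathify(cup)
  rd <- vapply(angles, function(a)
    ray_ellipse_distance(p0, a, dm$center, dm$semiaxes, dm$rotation), 0)
  rc <- vapply(angles, function(a)
    ray_ellipse_distance(p0, a, cm$center, cm$semiaxes, cm$rotation), 0)
  cdar <- prod(cup$semiaxes) / prod(disc$semiaxes)
  vcdr <- vertical_extent(cup$semiaxes, cup$rotation) /
    vertical_extent(disc$semiaxes, disc$rotation)
  prof <- cdr_profile("synthetic", pmin(pmax(rc / rd, 0), 1), cdar, vcdr)
  list(mask = mask, profile = prof, cdar = cdar, vcdr = vcdr)
}

#' Render a toy pseudo-fundus image from a label mask
#'
#' Colours background, disc and cup with well-separated warm intensity
#' distributions, adds mild Gaussian pixel noise and a black circular field
#' border, producing a learnable toy segmentation task for the network.
#' No attempt is made to imitate vessels or real fundus texture.
#'
#' @param mask a [label_mask()].
#' @param seed RNG seed for the pixel noise.
#' @param noise_sd pixel noise standard deviation (intensity units, image
#'   scale `[0, 1]`).
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
render_pseudo_fundus <- function(mask, seed = NULL, noise_sd = 0.03) {
  if (!is.null(seed)) set.seed(seed)
  lab <- unclass(mask)
  h <- nrow(lab); w <- ncol(lab)
  base <- list(c(0.55, 0.25, 0.10),   # background
               c(0.95, 0.75, 0.45),   # rim
               c(1.00, 0.95, 0.75))   # cup
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- base[[1]][ch] * (lab == 0L) + base[[2]][ch] * (lab == 1L) +
      base[[3]][ch] * (lab == 2L)
    img[, , ch] <- plane + stats::rnorm(h * w, 0, noise_sd)
  }
  # black circular field border
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  rr <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  cc <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  outside <- sqrt((rr - cy)^2 + (cc - cx)^2) > 0.48 * min(h, w)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[outside] <- 0
    img[, , ch] <- plane
  }
  pmin(pmax(img, 0), 1)
}
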