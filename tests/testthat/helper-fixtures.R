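# Shared fixtures and independent oracles, built in code at test time.

# Dense-matrix multivariate normal log-density: the brute-force oracle the
# closed-form likelihood is checked against (generic Cholesky solve).
dense_mvn_logdens <- function(y, mu, V) {
  L <- chol(V)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Rasterized filled circle as a logical matrix (1-based center row/col).
circle_region <- function(size, cx, cy, r) {
  px <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  py <- matrix(rep(seq_len(size) - 1, times = size), size, size)
  sqrt((px - cx)^2 + (py - cy)^2) <= r
}

# Axis-aligned filled ellipse region (0-based center, semi-axes a=cols, b=rows).
ellipse_region <- function(size, cx, cy, a, b) {
  px <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  py <- matrix(rep(seq_len(size) - 1, times = size), size, size)
  ((px - cx) / a)^2 + ((py - cy) / b)^2 <= 1
}

# A small generating truth shared by model tests.
test_truth <- function(config = spagen_config()) default_generating_params(config)

# Truth values of the default generating fixed effects, named as in the fit.
truth_fixed <- c(beta0 = 0.25, betaG0 = 0.12, betaCDAR = 0.4,
                 G_sin1 = 0, G_cos1 = 0.06, G_sin2 = 0, G_cos2 = 0.03,
                 H_sin1 = 0, H_cos1 = 0.02, H_sin2 = 0, H_cos2 = 0.01)

# Tiny network configuration used across the segmentation tests.
tiny_net_config <- function(size = 32L) {
  effunet_config(
    input_size = size, width = 0.25,
    stages = data.frame(expand = c(1, 4), kernel = c(3, 3), stride = c(2, 2),
                        repeats = c(1, 1), channels = c(4, 6)),
    stem_channels = 4, decoder_channels = c(6, 4))
}

# One small pseudo-fundus scene with known geometry.
toy_scene <- function(size = 64L, seed = 7L) {
  rm <- render_masks(size = size,
                     disc = list(center = c(size / 2, size / 2),
                                 semiaxes = c(0.31 * size, 0.27 * size)),
                     cup = list(center = c(size / 2 + 1, size / 2 - 1),
                                semiaxes = c(0.16 * size, 0.12 * size)))
  list(mask = rm$mask, profile = rm$profile,
       image = render_pseudo_fundus(rm$mask, seed = seed))
}
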