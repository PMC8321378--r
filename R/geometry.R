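#' @section Coordinate conventions:
#' Pixel coordinates are 0-based with `x` along columns and `y` along rows.
#' Angles are measured from the positive column axis (3 o'clock) and turn
#' counter-clockwise on the displayed image, i.e. 90 degrees points towards
#' decreasing row index.  The vertical direction used by [compute_vcdr()] is
#' the row axis.
#' @name spagen-geometry
#' @keywords internal
NULL

RAY_STEP <- 0.25  # px; fixed-step ray march resolution

# Distance from `center` (0-based c(x, y)) to the centre of the outermost
# TRUE pixel of `region` along the ray at `angle_deg`; 0 when no pixel of
# the region lies on the ray beyond the centre.  The ray is marched in
# 0.25-px steps and the distance is measured to the last covered pixel's
# centre, so a single-pixel region at the centre has extent 0.
ray_extent <- function(region, center, angle_deg) {
  a <- angle_deg * pi / 180
  u <- c(cos(a), -sin(a))
  rmax <- sqrt(nrow(region)^2 + ncol(region)^2)
  t <- seq(0, rmax, by = RAY_STEP)
  cols <- as.integer(round(center[1] + t * u[1])) + 1L
  rows <- as.integer(round(center[2] + t * u[2])) + 1L
  ok <- rows >= 1L & rows <= nrow(region) & cols >= 1L & cols <= ncol(region)
  hit <- logical(length(t))
  hit[ok] <- region[cbind(rows[ok], cols[ok])]
  if (!any(hit)) return(0)
  last <- max(which(hit))
  sqrt((cols[last] - 1L - center[1])^2 + (rows[last] - 1L - center[2])^2)
}

#' Distance from a point to a region boundary along a ray
#'
#' Marches a fixed-step ray (0.25 px) from `center` at `angle_deg` and
#' returns the distance of the outermost covered pixel of the region.
#'
#' @param region logical (or 0/1) matrix marking the region.
#' @param center 0-based `c(x, y)` coordinate; must lie inside the region.
#' @param angle_deg angle in degrees, 0 = positive column axis,
#'   counter-clockwise.
#' @return Distance in pixels.
#' @export
radial_boundary_distance <- function(region, center, angle_deg) {
  region <- disc_as_logical(region)
  r0 <- as.integer(round(center[2])) + 1L
  c0 <- as.integer(round(center[1])) + 1L
  if (r0 < 1L || r0 > nrow(region) || c0 < 1L || c0 > ncol(region) ||
      !region[r0, c0]) {
    abort_geometry("center does not lie inside the region")
  }
  ray_extent(region, center, angle_deg)
}

region_centroid <- function(region) {
  px <- which(region, arr.ind = TRUE)
  c(x = mean(px[, 2]) - 1, y = mean(px[, 1]) - 1)
}

#' Cup-to-disc ratio profile of one eye
#'
#' Container for the directional CDR profile: `n_dirs` CDR values sampled at
#' equal angular spacing around the disc centre, the cup-to-disc area ratio
#' (CDAR), the vertical CDR and an optional diagnosis label.
#'
#' @param eye_id identifier.
#' @param values numeric CDR values in `[0, 1]`, one per direction.
#' @param cdar cup-to-disc area ratio in `[0, 1]`.
#' @param vcdr vertical cup-to-disc ratio in `[0, 1]`.
#' @param label optional `"glaucoma"` or `"healthy"`.
#' @return An object of class `cdr_profile`.
#' @export
cdr_profile <- function(eye_id, values, cdar, vcdr, label = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 4L) abort_input("a CDR profile needs at least 4 directions")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    abort_input("CDR values must be finite and in [0, 1]")
  }
  for (v in c(cdar = cdar, vcdr = vcdr)) {
    if (!is.finite(v) || v < 0 || v > 1) abort_input("cdar/vcdr must be in [0, 1]")
  }
  if (!is.na(label) && !label %in% c("glaucoma", "healthy")) {
    abort_input("label must be 'glaucoma', 'healthy' or NA")
  }
  structure(list(eye_id = eye_id, values = values, cdar = as.numeric(cdar),
                 vcdr = as.numeric(vcdr), label = label),
            class = "cdr_profile")
}

#' @export
print.cdr_profile <- function(x, ...) {
  cat(sprintf("<cdr_profile '%s': %d directions, vCDR %.3f, CDAR %.3f%s>\n",
              x$eye_id, length(x$values), x$vcdr, x$cdar,
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Extract the directional CDR profile from a label mask
#'
#' Casts `n_dirs` rays from the disc-region centroid at equal angular
#' spacing (15 degrees for the default 24 directions, starting at 0 =
#' 3 o'clock, counter-clockwise) and records, per direction, the ratio of
#' the cup radial extent to the disc radial extent, clipped to `[0, 1]`.
#' A direction whose ray meets no cup pixel contributes 0.  The CDAR and
#' vertical CDR fields are filled in by [compute_cdar()] and
#' [compute_vcdr()].
#'
#' @param mask a [label_mask()].
#' @param n_dirs number of directions (>= 4); default 24.
#' @param smooth `"none"` (radii measured on the raw rasterized contours) or
#'   `"ellipse"` (radii taken on least-squares ellipses fitted to the disc
#'   and cup boundary pixels, emulating ellipse-fitted annotations).
#' @param eye_id,label carried into the returned profile.
#' @return A [cdr_profile()].
#' @examples
#' m <- render_masks(size = 128, disc = list(center = c(64, 64), semiaxes = c(40, 40)),
#'                   cup = list(center = c(64, 64), semiaxes = c(20, 20)))$mask
#' extract_cdr_profile(m)$values
#' @export
extract_cdr_profile <- function(mask, n_dirs = 24L, smooth = c("none", "ellipse"),
                                eye_id = "eye", label = NA_character_) {
  smooth <- match.arg(smooth)
  if (n_dirs < 4L) abort_input("n_dirs must be at least 4")
  disc <- disc_region(mask)
  cup <- cup_region(mask)
  if (!any(disc)) abort_degenerate("mask has no disc pixels")
  ctr <- region_centroid(disc)
  angles <- (seq_len(n_dirs) - 1) * (360 / n_dirs)
  if (smooth == "ellipse") {
    dconic <- fit_conic(disc)
    cconic <- if (any(cup)) fit_conic(cup) else NULL
    rd <- vapply(angles, function(a) conic_ray_distance(dconic, ctr, a), 0)
    rc <- if (is.null(cconic)) rep(0, n_dirs) else
      vapply(angles, function(a) conic_ray_distance(cconic, ctr, a), 0)
  } else {
    rd <- vapply(angles, function(a) ray_extent(disc, ctr, a), 0)
    rc <- vapply(angles, function(a) ray_extent(cup, ctr, a), 0)
  }
  if (any(rd <= 0)) abort_geometry("disc centroid falls outside the disc region")
  vals <- pmin(pmax(rc / rd, 0), 1)
  cdr_profile(eye_id, vals, compute_cdar(mask), compute_vcdr(mask), label)
}

#' Cup-to-disc area ratio
#'
#' Ratio of the cup pixel count to the disc-region pixel count (cup pixels
#' included in the disc region).
#'
#' @param mask a [label_mask()].
#' @return CDAR in `[0, 1]`.
#' @export
compute_cdar <- function(mask) {
  nd <- sum(disc_region(mask))
  if (nd == 0L) abort_degenerate("mask has no disc pixels")
  sum(cup_region(mask)) / nd
}

#' Vertical cup-to-disc ratio
#'
#' Ratio of the cup vertical extent to the disc vertical extent, both in
#' pixel rows, clipped to `[0, 1]`.
#'
#' @param mask a [label_mask()].
#' @return vCDR in `[0, 1]`.
#' @export
compute_vcdr <- function(mask) {
  disc <- disc_region(mask)
  cup <- cup_region(mask)
  if (!any(disc)) abort_degenerate("mask has no disc pixels")
  rows_of <- function(region) range(which(apply(region, 1, any)))
  dr <- rows_of(disc)
  dh <- dr[2] - dr[1] + 1L
  if (!any(cup)) return(0)
  cr <- rows_of(cup)
  ch <- cr[2] - cr[1] + 1L
  min(ch / dh, 1)
}

# --- least-squares conic (ellipse) fitting -------------------------------

# Boundary pixels: region pixels with at least one 4-neighbour outside.
region_boundary <- function(region) {
  nr <- nrow(region); nc <- ncol(region)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- region
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(region & !interior, arr.ind = TRUE)
}

# Total-least-squares conic a x^2 + b xy + c y^2 + d x + e y + f = 0 through
# the boundary points, via the smallest right singular vector of the design.
fit_conic <- function(region) {
  b <- region_boundary(region)
  if (nrow(b) < 6L) abort_geometry("too few boundary pixels for an ellipse fit")
  x <- b[, 2] - 1; y <- b[, 1] - 1
  mx <- mean(x); my <- mean(y); s <- mean(c(stats::sd(x), stats::sd(y)))
  xs <- (x - mx) / s; ys <- (y - my) / s
  D <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  v <- svd(D)$v[, 6]
  list(coef = v, mx = mx, my = my, s = s)
}

# Distance along the ray p + t*u (image convention, angle CCW) to the conic.
conic_ray_distance <- function(conic, center, angle_deg) {
  a <- angle_deg * pi / 180
  u <- c(cos(a), -sin(a)) / conic$s
  p <- c((center[1] - conic$mx) / conic$s, (center[2] - conic$my) / conic$s)
  k <- conic$coef
  f <- function(q) k[1] * q[1]^2 + k[2] * q[1] * q[2] + k[3] * q[2]^2 +
    k[4] * q[1] + k[5] * q[2] + k[6]
  # quadratic A t^2 + B t + C in t
  A <- k[1] * u[1]^2 + k[2] * u[1] * u[2] + k[3] * u[2]^2
  B <- 2 * k[1] * p[1] * u[1] + k[2] * (p[1] * u[2] + p[2] * u[1]) +
    2 * k[3] * p[2] * u[2] + k[4] * u[1] + k[5] * u[2]
  C <- f(p)
  disc <- B^2 - 4 * A * C
  if (disc < 0 || abs(A) < 1e-12) abort_geometry("ray does not meet the fitted ellipse")
  ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  ts <- ts[ts > 0]
  if (!length(ts)) abort_geometry("ray does not meet the fitted ellipse ahead of the center")
  min(ts)
}

# --- profile table I/O ----------------------------------------------------

#' Convert between CDR profiles and the tabular CSV dialect
#'
#' The on-disk dialect has columns `eye_id`, `d1..dN`, `cdar`, `vcdr`,
#' `label` (empty when unknown).
#'
#' @param profiles a list of [cdr_profile()] objects.
#' @return `profiles_to_table()`: a data.frame; `table_to_profiles()`: a list
#'   of [cdr_profile()].
#' @export
profiles_to_table <- function(profiles) {
  if (inherits(profiles, "cdr_profile")) profiles <- list(profiles)
  n <- length(profiles[[1]]$values)
  rows <- lapply(profiles, function(p) {
    stopifnot(length(p$values) == n)
    as.data.frame(c(list(eye_id = p$eye_id),
                    stats::setNames(as.list(p$values), paste0("d", seq_len(n))),
                    list(cdar = p$cdar, vcdr = p$vcdr, label = p$label)))
  })
  do.call(rbind, rows)
}

#' @rdname profiles_to_table
#' @param tab a data.frame in the profile dialect.
#' @export
table_to_profiles <- function(tab) {
  dcols <- grep("^d[0-9]+$", names(tab), value = TRUE)
  dcols <- dcols[order(as.integer(sub("^d", "", dcols)))]
  lapply(seq_len(nrow(tab)), function(i) {
    cdr_profile(tab$eye_id[i], as.numeric(tab[i, dcols]),
                tab$cdar[i], tab$vcdr[i],
                if ("label" %in% names(tab) && !is.na(tab$label[i]) &&
                    nzchar(tab$label[i])) tab$label[i] else NA_character_)
  })
}

#' Read/write profile tables
#' @param path CSV file path.
#' @param x data.frame (profile dialect) or list of [cdr_profile()].
#' @return `read_profiles()`: a data.frame; `write_profiles()`: `path`.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s'", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"eye_id" %in% names(tab) || !any(grepl("^d[0-9]+$", names(tab)))) {
    abort_input("not a CDR profile table: need eye_id and d1..dN columns")
  }
  if ("label" %in% names(tab)) tab$label[!nzchar(trimws(as.character(tab$label)))] <- NA
  tab
}

#' @rdname read_profiles
#' @export
write_profiles <- function(x, path) {
  if (!is.data.frame(x)) x <- profiles_to_table(x)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

# Extract the numeric profile matrix (n x n_dirs) and metadata from a table.
profile_matrix <- function(tab) {
  dcols <- grep("^d[0-9]+$", names(tab), value = TRUE)
  dcols <- dcols[order(as.integer(sub("^d", "", dcols)))]
  Y <- as.matrix(tab[, dcols, drop = FALSE])
  storage.mode(Y) <- "double"
  list(Y = Y,
       cdar = if ("cdar" %in% names(tab)) as.numeric(tab$cdar) else rep(NA_real_, nrow(tab)),
       label = if ("label" %in% names(tab)) as.character(tab$label) else rep(NA_character_, nrow(tab)))
}
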