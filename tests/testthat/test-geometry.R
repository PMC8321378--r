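test_that("label masks normalize the cup inside the disc", {
  disc <- matrix(FALSE, 32, 32); disc[8:24, 8:24] <- TRUE
  cup <- matrix(FALSE, 32, 32); cup[12:20, 12:20] <- TRUE
  m <- label_mask(disc, cup)
  expect_true(all(unclass(m)[cup] == 2L))
  expect_true(all(which(unclass(m) == 2L) %in% which(disc)))

  # cup pixels outside the disc are relabelled to disc with a warning
  cup_out <- cup; cup_out[2, 2:4] <- TRUE
  expect_warning(m2 <- label_mask(disc, cup_out), "3 cup pixel")
  expect_identical(unclass(m2)[2, 2:4], rep(1L, 3))

  expect_error(label_mask(matrix(0L, 8, 8)), class = "spagen_degenerate_mask_error")
  expect_error(label_mask(matrix(3L, 8, 8)), class = "spagen_input_error")
})

test_that("mask raster round trip preserves labels and encodings", {
  withr::local_seed(1)
  disc <- circle_region(48, 24, 24, 15)
  cup <- circle_region(48, 24, 24, 7)
  m <- label_mask(disc, cup)
  f <- withr::local_tempfile(fileext = ".png")
  write_raster(m, f, encoding = c(0, 128, 255))
  m2 <- load_mask(f, encoding = c(0, 128, 255))
  expect_identical(unclass(m2), unclass(m))

  expect_error(load_mask(tempfile()), class = "spagen_io_error")
  f0 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 16, 16), f0)
  expect_error(load_mask(f0), class = "spagen_degenerate_mask_error")
  fbad <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 37) / 255, 16, 16), fbad)
  expect_error(load_mask(fbad), class = "spagen_input_error")
})

test_that("radial distances match analytic circle and ellipse radii", {
  reg <- circle_region(128, 60, 64, 40)
  for (a in c(0, 33, 90, 147, 215, 301)) {
    expect_lt(abs(radial_boundary_distance(reg, c(60, 64), a) - 40), 1)
  }
  ell <- ellipse_region(160, 80, 80, 60, 30)
  expect_lt(abs(radial_boundary_distance(ell, c(80, 80), 0) - 60), 1)
  expect_lt(abs(radial_boundary_distance(ell, c(80, 80), 90) - 30), 1)
  expect_lt(abs(radial_boundary_distance(ell, c(80, 80), 180) - 60), 1)

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(radial_boundary_distance(single, c(4, 4), 45), 0)
  expect_error(radial_boundary_distance(ell, c(1, 1), 0),
               class = "spagen_geometry_error")
})

test_that("profile extraction recovers analytic ratios on similar shapes", {
  # concentric circles: all 24 values, vCDR and sqrt(CDAR) equal 0.5
  rm <- render_masks(size = 192, disc = list(center = c(96, 96), semiaxes = c(80, 80)),
                     cup = list(center = c(96, 96), semiaxes = c(40, 40)))
  p <- extract_cdr_profile(rm$mask)
  expect_length(p$values, 24)
  expect_true(all(abs(p$values - 0.5) < 0.02))
  expect_lt(abs(p$cdar - 0.25), 0.01)
  expect_lt(abs(p$vcdr - 0.5), 0.02)

  # similar concentric ellipses scaled by 0.6
  rm2 <- render_masks(size = 224, disc = list(center = c(112, 112), semiaxes = c(90, 65),
                                              rotation = 0.4),
                      cup = list(center = c(112, 112), semiaxes = c(54, 39),
                                 rotation = 0.4))
  p2 <- extract_cdr_profile(rm2$mask)
  expect_true(all(abs(p2$values - 0.6) < 0.02))
  expect_lt(abs(sqrt(p2$cdar) - 0.6), 0.02)
  expect_lt(abs(p2$vcdr - 0.6), 0.02)

  # empty cup: all zeros
  m3 <- label_mask(matrix(as.integer(circle_region(96, 48, 48, 30)), 96, 96))
  p3 <- extract_cdr_profile(m3)
  expect_true(all(p3$values == 0))
  expect_equal(p3$cdar, 0)
  expect_equal(p3$vcdr, 0)
})

test_that("profiles agree with the ray-ellipse oracle for offset cups", {
  rm <- render_masks(size = 256,
                     disc = list(center = c(128, 128), semiaxes = c(80, 60), rotation = 0.3),
                     cup = list(center = c(138, 124), semiaxes = c(40, 30), rotation = 0.1))
  p <- extract_cdr_profile(rm$mask)
  expect_true(all(abs(p$values - rm$profile$values) < 0.02))
  expect_lt(abs(p$cdar - rm$cdar), 0.01)
  # ellipse-fit smoothing stays close to the analytic oracle too
  ps <- extract_cdr_profile(rm$mask, smooth = "ellipse")
  expect_true(all(abs(ps$values - rm$profile$values) < 0.02))
})

test_that("profiles are invariant to translation and uniform scaling", {
  base <- render_masks(size = 200,
                       disc = list(center = c(100, 100), semiaxes = c(62, 48), rotation = 0.2),
                       cup = list(center = c(106, 97), semiaxes = c(30, 22), rotation = 0.2))
  p0 <- extract_cdr_profile(base$mask)
  shifted <- render_masks(size = 200,
                          disc = list(center = c(83, 112), semiaxes = c(62, 48), rotation = 0.2),
                          cup = list(center = c(89, 109), semiaxes = c(30, 22), rotation = 0.2))
  p1 <- extract_cdr_profile(shifted$mask)
  expect_true(all(abs(p1$values - p0$values) < 0.02))
  scaled <- render_masks(size = 300,
                         disc = list(center = c(150, 150), semiaxes = 1.5 * c(62, 48), rotation = 0.2),
                         cup = list(center = c(159, 145.5), semiaxes = 1.5 * c(30, 22), rotation = 0.2))
  p2 <- extract_cdr_profile(scaled$mask)
  expect_true(all(abs(p2$values - p0$values) < 0.02))
})

test_that("degenerate geometry is rejected", {
  expect_error(extract_cdr_profile(label_mask(matrix(1L, 8, 8)), n_dirs = 3),
               class = "spagen_input_error")
  # cup = disc gives CDAR and vCDR of exactly 1
  m <- label_mask(matrix(2L, 16, 16) * circle_region(16, 8, 8, 6))
  expect_equal(compute_cdar(m), 1.0)
  expect_equal(compute_vcdr(m), 1.0)
})

test_that("profile tables round-trip through CSV", {
  withr::local_seed(3)
  profs <- lapply(1:3, function(i)
    cdr_profile(paste0("eye", i), runif(24), runif(1), runif(1),
                sample(c("glaucoma", "healthy"), 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, f)
  tab <- read_profiles(f)
  expect_equal(nrow(tab), 3)
  back <- table_to_profiles(tab)
  expect_equal(back[[2]]$values, profs[[2]]$values)
  expect_equal(back[[2]]$label, profs[[2]]$label)
  # unlabeled profiles come back NA
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_profiles(list(cdr_profile("x", runif(24), 0.2, 0.3)), f2)
  expect_true(is.na(read_profiles(f2)$label[1]))
})
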