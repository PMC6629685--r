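test_that("volume_split sums z pairs over one checkerboard diagonal", {
  # constant volume: every sub-voxel is the sum of two z layers
  con <- frc_image(array(3, c(4, 4, 4)), 50)
  sp <- volume_split(con)
  expect_true(all(sp[[1]]$pixels == 6))
  expect_true(all(sp[[2]]$pixels == 6))
  expect_equal(dim(sp[[1]]), c(2L, 2L, 2L))
  expect_equal(sp[[1]]$spacing, c(100, 100, 100))
  # each used voxel contributes exactly once: totals over the two
  # diagonal parity classes are conserved
  set.seed(8)
  v <- frc_image(array(runif(6 * 6 * 6), c(6, 6, 6)), 50)
  sp2 <- volume_split(v)
  ee <- v$pixels[, seq(1, 6, 2), seq(1, 6, 2)]
  oo <- v$pixels[, seq(2, 6, 2), seq(2, 6, 2)]
  expect_equal(sum(sp2[[1]]$pixels), sum(ee))
  expect_equal(sum(sp2[[2]]$pixels), sum(oo))
  # odd dims truncated
  v5 <- frc_image(array(1, c(5, 5, 5)), 50)
  expect_equal(dim(volume_split(v5)[[1]]), c(2L, 2L, 2L))
})

test_that("anisotropy correction factor", {
  expect_equal(anisotropy_scale(0.3, 1), 1)
  expect_equal(anisotropy_scale(pi / 2, 2), 2)
  expect_equal(anisotropy_scale(0, 2), 1)
  expect_equal(anisotropy_scale(pi / 6, 3), 2)
  expect_error(anisotropy_scale(0, 0.5), ">= 1")
})

test_that("SFSC normalization, FSC reduction and section partition", {
  set.seed(12)
  v1 <- frc_image(array(rpois(24^3, 20), rep(24, 3)), 50)
  v2 <- frc_image(array(rpois(24^3, 20), rep(24, 3)), 50)
  # identical volumes: correlation 1 in every section
  sf_self <- sfsc(v1, v1, alpha = pi / 6)
  for (cur in sf_self$curves) {
    expect_true(all(abs(cur$correlation - 1) < 1e-9))
  }
  # alpha = 2*pi: single section equals the plain shell correlation
  sf_full <- sfsc(v1, v2, alpha = 2 * pi, window = FALSE)
  plain <- frc_curve(v1, v2)
  expect_equal(length(sf_full$curves), 1L)
  expect_equal(sf_full$curves[[1]]$correlation, plain$correlation,
               tolerance = 1e-12)
  expect_equal(sf_full$curves[[1]]$n_points, plain$n_points)
  # sections partition every shell: per-shell counts add up to plain FSC
  sf <- sfsc(v1, v2, alpha = pi / 6, window = FALSE, max_freq = 2)
  plain2 <- frc_curve(v1, v2, max_freq = 2)
  counts <- new.env()
  for (cur in sf$curves) {
    for (i in seq_along(cur$freq)) {
      key <- format(cur$freq[i], digits = 15)
      prev <- mget(key, envir = counts, ifnotfound = 0)[[1]]
      assign(key, prev + cur$n_points[i], envir = counts)
    }
  }
  for (i in seq_along(plain2$freq)) {
    key <- format(plain2$freq[i], digits = 15)
    expect_equal(mget(key, envir = counts, ifnotfound = 0)[[1]],
                 plain2$n_points[i])
  }
  # scale invariance in either volume
  sf_sc <- sfsc(frc_image(2.5 * v1$pixels, 50), v2, alpha = pi / 6,
                window = FALSE)
  sf_ref <- sfsc(v1, v2, alpha = pi / 6, window = FALSE)
  for (j in seq_along(sf_ref$curves)) {
    expect_equal(sf_sc$curves[[j]]$correlation,
                 sf_ref$curves[[j]]$correlation, tolerance = 1e-12)
  }
  # alpha must divide pi
  expect_error(sfsc(v1, v2, alpha = 1), "divide pi")
  # anisotropic sampling is rejected
  va <- frc_image(array(1, c(8, 8, 8)), c(100, 50, 50))
  expect_error(sfsc(va, va), "isotropically")
})

test_that("isotropic volumes give angle-independent resolutions", {
  ratios <- vapply(1:3, function(s) {
    spec <- acquisition_spec(kind = "filaments", shape = c(64, 64, 64),
                             pixel_size_nm = 40, fwhm_nm = c(200, 200, 200),
                             peak_photons = 500, seed = s)
    ims <- simulate_acquisition(make_phantom(spec), spec)
    dm <- sfsc(ims[[1]], ims[[2]])$resolutions$d_min_nm
    max(dm) / min(dm)
  }, numeric(1))
  expect_lte(stats::median(ratios), 1.15)
})

test_that("axial blur shows up in the axial sections", {
  # lateral FWHM w, axial 3w: the axial/lateral resolution ratio
  # reproduces the anisotropy and the lateral value tracks w
  spec <- acquisition_spec(kind = "filaments", shape = c(96, 96, 96),
                           pixel_size_nm = 40, fwhm_nm = 200,
                           peak_photons = 500, seed = 2)
  ims <- simulate_acquisition(make_phantom(spec), spec)
  sf <- sfsc(ims[[1]], ims[[2]])
  res <- sf$resolutions
  lat <- res$d_min_nm[which.min(pmin(res$angle_rad, pi - res$angle_rad))]
  axi <- res$d_min_nm[which.min(abs(res$angle_rad - pi / 2))]
  expect_gt(lat, 0.75 * 200)
  expect_lt(lat, 1.25 * 200)
  expect_gt(axi / lat, 2.25)
  expect_lt(axi / lat, 3.75)
})
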