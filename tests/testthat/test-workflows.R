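cal_wf <- NULL
get_cal <- function() {
  if (is.null(cal_wf)) {
    cal_wf <<- default_calibration(seed = 123, shape = c(128, 128))
  }
  cal_wf
}

test_that("frc_denoise clears power above the cutoff and keeps structure", {
  sc <- tiny_scene(seed = 2, shape = c(128, 128))
  img <- sc$images[[1]]
  rd <- suppressWarnings(restore(img, "frc_denoise", calibration = get_cal()))
  # no spectral power above the cutoff
  d <- dim(img)
  wrap <- function(n) ifelse(0:(n - 1) > n / 2, 0:(n - 1) - n, 0:(n - 1)) / n
  r <- sqrt(outer(wrap(d[1])^2, wrap(d[2])^2, `+`)) / 50
  S <- Mod(stats::fft(rd$image$pixels))^2
  expect_lt(sum(S[r > rd$report$params$cutoff_nm_inv]), 1e-12 * sum(S))
  # correlation to the noiseless signal not decreased by more than 1%
  gtb <- as.vector(sc$noiseless$pixels)
  c_in <- cor(as.vector(img$pixels), gtb)
  c_out <- cor(as.vector(rd$image$pixels), gtb)
  expect_gt(c_out, c_in - 0.01)
  expect_equal(rd$report$method, "frc_denoise")
})

test_that("blind Wiener improves the reported resolution", {
  sc <- tiny_scene(seed = 3, shape = c(128, 128))
  rw <- suppressWarnings(restore(sc$images[[1]], "blind_wiener",
                                 calibration = get_cal()))
  expect_lt(rw$report$d_min_out_nm, rw$report$d_min_in_nm)
  expect_length(rw$report$psf_fwhm_nm, 2)
})

test_that("blind RL pipeline records its trace; max_iter 0 is a no-op", {
  sc <- tiny_scene(seed = 4, shape = c(128, 128))
  img <- sc$images[[1]]
  rrl <- suppressWarnings(
    restore(img, "blind_rl", calibration = get_cal(),
            options = rl_options(max_iter = 8)))
  expect_lte(rrl$report$d_min_out_nm, rrl$report$d_min_in_nm)
  expect_s3_class(rrl$report$trace, "data.frame")
  expect_equal(rrl$report$params$iterations, max(rrl$report$trace$k))
  rl0 <- suppressWarnings(
    restore(img, "blind_rl", calibration = get_cal(),
            options = rl_options(max_iter = 0)))
  expect_equal(rl0$image$pixels, img$pixels)
  expect_equal(rl0$report$method, "blind_rl")
})

test_that("pipelines are deterministic and reports round-trip via JSON", {
  sc <- tiny_scene(seed = 5, shape = c(64, 64))
  r1 <- suppressWarnings(restore(sc$images[[1]], "frc_denoise"))
  r2 <- suppressWarnings(restore(sc$images[[1]], "frc_denoise"))
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$report, r2$report)
  js <- report_to_json(r1$report)
  back <- report_from_json(js)
  expect_equal(back$method, r1$report$method)
  expect_equal(back$d_min_in_nm, r1$report$d_min_in_nm, tolerance = 1e-12)
  expect_equal(back$d_min_out_nm, r1$report$d_min_out_nm, tolerance = 1e-12)
  expect_equal(unlist(back$params), unlist(r1$report$params),
               tolerance = 1e-12)
  # RL report including the trace table
  rrl <- suppressWarnings(
    restore(sc$images[[1]], "blind_rl", options = rl_options(max_iter = 3)))
  back_rl <- report_from_json(report_to_json(rrl$report))
  expect_equal(back_rl$trace$d_min_nm, rrl$report$trace$d_min_nm,
               tolerance = 1e-12)
})

test_that("3D restoration routes through SFSC-based anisotropic PSFs", {
  spec <- acquisition_spec(kind = "filaments", shape = c(48, 48, 48),
                           pixel_size_nm = 40, fwhm_nm = 200,
                           peak_photons = 500, seed = 7)
  ims <- simulate_acquisition(make_phantom(spec), spec)
  rw <- suppressWarnings(restore(ims[[1]], "blind_wiener"))
  expect_length(rw$report$psf_fwhm_nm, 3)
  # axial FWHM estimate exceeds the lateral one
  expect_gt(rw$report$psf_fwhm_nm[1], rw$report$psf_fwhm_nm[2])
  expect_equal(rw$report$frc_mode, "sfsc_single_volume")
})
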