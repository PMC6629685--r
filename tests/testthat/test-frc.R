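test_that("FRC normalization, symmetry and scale invariance", {
  set.seed(3)
  a <- frc_image(matrix(rpois(64 * 64, 30), 64, 64), 50)
  b <- frc_image(matrix(rpois(64 * 64, 30), 64, 64), 50)
  ca <- frc_curve(a, a)
  expect_true(all(abs(ca$correlation - 1) < 1e-9))
  # scale invariance in either argument
  c1 <- frc_curve(a, b)
  c2 <- frc_curve(frc_image(3.7 * a$pixels, 50), b)
  c3 <- frc_curve(a, frc_image(0.2 * b$pixels, 50))
  expect_equal(c1$correlation, c2$correlation, tolerance = 1e-12)
  expect_equal(c1$correlation, c3$correlation, tolerance = 1e-12)
  # symmetry
  c4 <- frc_curve(b, a)
  expect_equal(c1$correlation, c4$correlation, tolerance = 1e-12)
  # |corr| <= 1 + eps, frequencies increasing, counts positive
  expect_true(all(abs(c1$correlation) <= 1 + 1e-9))
  expect_true(all(diff(c1$freq) > 0))
  expect_true(all(c1$n_points >= 1))
  expect_lte(max(c1$freq), 0.5 + 1e-12)
  expect_error(frc_curve(a, frc_image(matrix(1, 8, 8), 50)), "dimensions")
})

test_that("frc_curve matches a brute-force ring evaluation", {
  for (s in 1:3) {
    set.seed(s)
    d <- list(c(8, 8), c(16, 16), c(12, 16))[[s]]
    a1 <- matrix(sample(0:50, prod(d), TRUE), d[1], d[2])
    a2 <- matrix(sample(0:50, prod(d), TRUE), d[1], d[2])
    got <- frc_curve(frc_image(a1, 50), frc_image(a2, 50))
    want <- frc_brute(a1, a2)
    expect_equal(got$freq, want$freq, tolerance = 1e-12)
    expect_equal(got$correlation, want$correlation, tolerance = 1e-12)
    expect_equal(got$n_points, as.integer(want$n_points))
  }
})

test_that("checkerboard split partitions the pixel lattice", {
  m <- outer(0:3, 0:3, function(r, c) 10 * r + c)
  sp <- checkerboard_split(frc_image(m, 50))
  expect_equal(sp$pair_a[[1]]$pixels, rbind(c(0, 2), c(20, 22)))
  expect_equal(sp$pair_a[[1]]$spacing, c(100, 100))
  # the four sub-images partition the original multiset (even dims)
  all_px <- sort(c(sp$pair_a[[1]]$pixels, sp$pair_a[[2]]$pixels,
                   sp$pair_b[[1]]$pixels, sp$pair_b[[2]]$pixels))
  expect_equal(all_px, sort(as.numeric(m)))
  # odd dimensions: trailing row/column truncated -> four 2x2 sub-images
  m5 <- matrix(runif(25), 5, 5)
  sp5 <- checkerboard_split(frc_image(m5, 50))
  for (sub in c(sp5$pair_a, sp5$pair_b)) expect_equal(dim(sub), c(2L, 2L))
})

test_that("one_image_frc averages the pair curves and handles degeneracies", {
  # anisotropic content (horizontal stripes): pair curves differ but the
  # averaged curve is finite and a result is produced
  stripes <- frc_image(matrix(rep(c(0, 40), each = 32, times = 32), 64, 64) +
                         matrix(rpois(64 * 64, 5), 64, 64), 50)
  oi <- one_image_frc(stripes)
  expect_true(all(is.finite(oi$curve$correlation)))
  expect_s3_class(oi$resolution, "frc_resolution")
  # frequency axis against the original pixel size
  expect_equal(oi$curve$pixel_size_nm, 50)
  # constant image: all-but-DC bins dropped, no crossing flagged
  con <- frc_image(matrix(5, 32, 32), 50)
  oc <- one_image_frc(con, window = FALSE)
  expect_true(all(oc$curve$freq == 0))
  expect_true(oc$resolution$no_crossing)
  # too-small image is an explicit error
  expect_error(one_image_frc(frc_image(matrix(1, 8, 8), 50)), "16x16")
})

test_that("threshold curves follow the SNR formula and its limits", {
  cur <- structure(list(freq = c(0, 0.1, 0.2, 0.3),
                        correlation = c(1, .9, .5, .2),
                        n_points = c(1, 100, 1e18, 4),
                        pixel_size_nm = 50, bin_width = 1),
                   class = "frc_curve")
  fixed <- make_threshold(cur, "fixed_1_7")
  expect_true(all(fixed$threshold == 1 / 7))
  # SNR_e = 0: T = 1/sqrt(N)
  t0 <- make_threshold(cur, "snr_e", snr_e = 0)
  expect_equal(t0$threshold[2], 0.1, tolerance = 1e-12)
  # N -> infinity: T -> SNR_e/(SNR_e + 1) = 1/3 at the one-bit SNR
  t5 <- make_threshold(cur, "snr_e", snr_e = 0.5)
  expect_equal(t5$threshold[3], 0.5 / 1.5, tolerance = 1e-8)
  expect_error(make_threshold(cur, "snr_e"), "snr_e")
})

test_that("resolution extraction interpolates the first crossing", {
  mk <- function(freq, corr) {
    structure(list(freq = freq, correlation = corr,
                   n_points = rep(10L, length(freq)), pixel_size_nm = 1,
                   bin_width = 1), class = "frc_curve")
  }
  # hand-computed linear interpolation between 0.2 and 0.1 against 1/7
  r <- resolution_from_curve(mk(c(0, 2, 2.5), c(1, 0.2, 0.1)))
  expect_equal(r$crossing_freq, 2 + 0.5 * (0.2 - 1 / 7) / (0.2 - 0.1),
               tolerance = 1e-12)
  expect_equal(r$d_min_nm, 1 / r$crossing_freq)
  # never drops below: flagged, sampling bound reported
  rn <- resolution_from_curve(mk(c(0, 1, 2), c(1, .9, .8)))
  expect_true(rn$no_crossing)
  expect_equal(rn$d_min_nm, 2)
  # dips below then rises: the FIRST crossing is taken
  rf <- resolution_from_curve(mk(c(0, 1, 2, 3, 4), c(1, .5, .1, .5, .1)))
  expect_lt(rf$crossing_freq, 2)
})

test_that("high-frequency correlation vanishes for independent noise", {
  # shared structure + independent white noise at peak SNR <= 1:
  # the top-quartile rings average to ~0
  means <- vapply(1:20, function(s) {
    set.seed(s)
    base <- smooth_structure(64)
    n1 <- matrix(rnorm(64 * 64), 64, 64)
    n2 <- matrix(rnorm(64 * 64), 64, 64)
    a <- frc_image(base + n1 - min(base + n1), 50)
    b <- frc_image(base + n2 - min(base + n2), 50)
    cur <- frc_curve(apply_window(a), apply_window(b))
    hi <- cur$freq >= stats::quantile(cur$freq, 0.75)
    mean(cur$correlation[hi])
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.1)
})
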