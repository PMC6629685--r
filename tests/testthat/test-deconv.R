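test_that("Wiener deconvolution contracts", {
  set.seed(2)
  img <- frc_image(matrix(runif(32 * 32) + 1, 32, 32), 50)
  # delta PSF with negligible regularization: identity
  delta_psf <- make_gaussian_psf(c(1e-6, 1e-6), 50, shape = c(1, 1))
  out <- wiener_deconvolve(img, delta_psf, snr_reg = 1e-9)
  expect_lt(max(abs(out$pixels - img$pixels)) / max(img$pixels), 1e-6)
  # linearity before clipping
  psf <- make_gaussian_psf(c(200, 200), 50)
  w1 <- wiener_deconvolve(img, psf, 0.1, clip = FALSE)
  w2 <- wiener_deconvolve(frc_image(3 * img$pixels, 50), psf, 0.1,
                          clip = FALSE)
  expect_equal(w2$pixels, 3 * w1$pixels, tolerance = 1e-9)
  # spacing mismatch
  psf_bad <- make_gaussian_psf(c(200, 200), 40)
  expect_error(wiener_deconvolve(img, psf_bad, 0.1), "spacing")
  expect_error(wiener_deconvolve(img, psf, -1), "snr_reg")
})

test_that("Wiener sharpens a noiseless blurred phantom", {
  cors <- vapply(1:10, function(s) {
    sc <- tiny_scene(seed = s, shape = c(64, 64))
    gt <- as.vector(sc$phantom$pixels)
    blurred <- sc$noiseless
    psf <- make_gaussian_psf(rep(250, 2), 50)
    w <- wiener_deconvolve(blurred, psf, snr_reg = 0.01)
    cor(as.vector(w$pixels), gt) - cor(as.vector(blurred$pixels), gt)
  }, numeric(1))
  expect_true(all(cors > 0))
})

test_that("RL update: fixed point, flux conservation, brute-force oracle", {
  set.seed(9)
  psf <- make_gaussian_psf(c(120, 120), 50)
  o <- matrix(runif(16 * 16) + 0.5, 16, 16)
  # at the exact solution the update is a fixed point
  i_sym <- frcrestore:::conv_fft(o, psf$kernel)
  expect_lt(max(abs(rl_step(o, i_sym, psf) - o)), 1e-12)
  # circular convolution conserves flux
  i_circ <- frcrestore:::conv_fft(o, psf$kernel, boundary = "circular")
  o2 <- rl_step(o, i_circ, psf, boundary = "circular")
  expect_lt(abs(sum(o2) - sum(o)) / sum(o), 1e-6)
  # frequency-domain implementation equals the direct spatial evaluation
  i_obs <- matrix(rpois(256, 40), 16, 16)
  for (b in c(0, 2)) {
    got <- rl_step(o, i_obs, psf, b = b)
    want <- rl_brute(o, i_obs, psf$kernel, b = b)
    expect_lt(max(abs(got - want)), 1e-9)
  }
  # estimates stay non-negative, all-zero estimate rejected
  expect_true(all(rl_step(o, i_obs, psf) >= 0))
  expect_error(rl_step(matrix(0, 16, 16), i_obs, psf), "all-zero")
  # TV factor leaves a constant estimate untouched (zero curvature)
  oc <- matrix(2, 16, 16)
  expect_equal(rl_step(oc, i_obs, psf, tv_lambda = 5e-4),
               rl_step(oc, i_obs, psf, tv_lambda = 0), tolerance = 1e-9)
})

test_that("tau1 and eta_k convergence metrics", {
  expect_equal(tau1(c(1, 1), c(1, 1)), 0)
  expect_equal(tau1(matrix(2, 2, 2), matrix(1, 2, 2)), 0.5)
  expect_equal(tau1(matrix(c(1, 3), 1), matrix(c(2, 2), 1)), 0.5)
  expect_error(tau1(matrix(0, 2, 2), matrix(1, 2, 2)), "non-positive")
  # converged run: ratio image is 1 everywhere -> eta = 0
  psf <- make_gaussian_psf(c(120, 120), 50)
  o <- matrix(runif(16 * 16) + 0.5, 16, 16)
  i <- frcrestore:::conv_fft(o, psf$kernel)
  expect_equal(eta_k(i, o, psf), 0)
  # scaling the image by 1/2 puts every ratio pixel in the middle band
  expect_equal(eta_k(i / 2, o, psf, epsilon = 0.05), 1)
  expect_error(eta_k(i, o, psf, epsilon = 0.7), "epsilon")
})

test_that("background estimation separates signal from background", {
  # clean two-level image
  img <- matrix(10, 32, 32)
  img[10:20, 10:20] <- 100
  expect_equal(estimate_background(frc_image(img, 50)), 10)
  # constant image: the constant, with a warning
  expect_warning(b <- estimate_background(frc_image(matrix(7, 8, 8), 50)),
                 "constant")
  expect_equal(b, 7)
  # noisy background mean recovered within 3 standard errors
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(rnorm(64 * 64, 10, 2), 64, 64)
    m[20:40, 20:40] <- 100
    estimate_background(m) - 10
  }, numeric(1))
  se <- 2 / sqrt(64 * 64 - 21^2)
  expect_lt(abs(mean(errs)), 3 * se + 0.1)
})

test_that("stopping rules trigger at the hand-computed iterations", {
  opts1 <- rl_options(stop_grad_threshold = -1)
  tr <- function(d) data.frame(k = seq_along(d) - 1, d_min_nm = d)
  # grads -40, -20, -0.5: threshold -1 stops when the 4th value arrives
  expect_false(stopping_check(tr(c(300, 260)), opts1)$stop)
  expect_false(stopping_check(tr(c(300, 260, 240)), opts1)$stop)
  s4 <- stopping_check(tr(c(300, 260, 240, 239.5)), opts1)
  expect_true(s4$stop)
  expect_equal(s4$reason, "threshold_reached")
  # steep monotone trace: continue
  expect_false(stopping_check(tr(c(340, 300, 270, 250)), opts1)$stop)
  # -0.2 threshold needs a shallower tail
  opts02 <- rl_options(stop_grad_threshold = -0.2)
  expect_false(stopping_check(tr(c(300, 260, 240, 239.5)), opts02)$stop)
  expect_true(stopping_check(tr(c(300, 260, 240, 239.9)), opts02)$stop)
  # threshold 0 = maximal resolution
  opts0 <- rl_options(stop_grad_threshold = 0)
  s0 <- stopping_check(tr(c(300, 260, 240, 240)), opts0)
  expect_true(s0$stop)
  expect_equal(s0$reason, "max_resolution")
  # gradient sign flip trips the failsafe before the threshold rule
  sf <- stopping_check(tr(c(300, 250, 240, 260)), opts1)
  expect_true(sf$stop)
  expect_equal(sf$reason, "failsafe_grad2")
  # failsafe off: the same trace stops by threshold instead
  snf <- stopping_check(tr(c(300, 250, 240, 260)),
                        rl_options(stop_grad_threshold = -1,
                                   failsafe = FALSE))
  expect_equal(snf$reason, "threshold_reached")
  # iteration cap
  capped <- stopping_check(tr(c(300, 260, 230)),
                           rl_options(max_iter = 2,
                                      stop_grad_threshold = -Inf))
  expect_equal(capped$reason, "max_iter")
  expect_error(rl_options(stop_grad_threshold = 1), "<= 0")
})

test_that("rl_deconvolve honours iteration contracts and improves d_min", {
  sc <- tiny_scene(seed = 6, shape = c(64, 64))
  img <- sc$images[[1]]
  psf <- make_gaussian_psf(rep(250, 2), 50)
  # exactly max_iter iterations when the gradient rule is disabled
  rl5 <- rl_deconvolve(img, psf,
                       rl_options(max_iter = 5, stop_grad_threshold = -Inf,
                                  failsafe = FALSE))
  expect_equal(max(rl5$trace$k), 5)
  expect_equal(attr(rl5$trace, "stop_reason"), "max_iter")
  expect_equal(nrow(rl5$trace), 6)          # iteration 0 = input
  expect_true(all(rl5$image$pixels >= 0))
  # trace difference columns are consistent
  expect_equal(rl5$trace$grad[-1], diff(rl5$trace$d_min_nm))
  expect_equal(rl5$trace$grad2[-(1:2)], diff(diff(rl5$trace$d_min_nm)))
  # resolution does not get worse than the input
  rl <- rl_deconvolve(img, psf, rl_options(max_iter = 12))
  expect_lte(rl$trace$d_min_nm[nrow(rl$trace)], rl$trace$d_min_nm[1])
  # max_iter = 0 returns the input unchanged
  rl0 <- rl_deconvolve(img, psf, rl_options(max_iter = 0))
  expect_equal(rl0$image$pixels, img$pixels)
})

test_that("background correction helps under strong uniform background", {
  sc <- tiny_scene(seed = 4, shape = c(96, 96), background = 50)
  img <- sc$images[[1]]
  psf <- make_gaussian_psf(rep(250, 2), 50)
  d_no <- rl_deconvolve(img, psf,
                        rl_options(max_iter = 10, stop_grad_threshold = 0))
  d_bg <- rl_deconvolve(img, psf,
                        rl_options(max_iter = 10, stop_grad_threshold = 0,
                                   background = "auto"))
  expect_gt(d_bg$background, 0)
  last <- function(x) x$trace$d_min_nm[nrow(x$trace)]
  expect_lte(last(d_bg), last(d_no))
})

test_that("tau1 decreases over the late iterations of a converging run", {
  sc <- tiny_scene(seed = 10, shape = c(64, 64))
  rl <- rl_deconvolve(sc$images[[1]], make_gaussian_psf(rep(250, 2), 50),
                      rl_options(max_iter = 12, stop_grad_threshold = -Inf,
                                 failsafe = FALSE))
  tau <- rl$trace$tau1[-1]
  late <- tau[(length(tau) - 3):length(tau)]
  expect_true(all(diff(late) < 0))
})
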