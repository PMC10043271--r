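test_that("saturating-exponential fit recovers exact inputs and rejects junk", {
  tt <- seq(0, 120, by = 1)
  y <- 8e-6 - (8e-6 - 5e-7) * exp(-tt / 20)
  fit <- fit_pore_radius(time_series(tt, y))
  expect_equal(unname(fit$estimates[["tau"]]), 20, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["R_inf"]]), 8e-6, tolerance = 1e-6)
  expect_true(fit$converged)
  # invariance to a time shift
  fit_sh <- fit_pore_radius(time_series(tt + 500, y))
  expect_equal(unname(fit_sh$estimates[["tau"]]), 20, tolerance = 1e-6)
  # constant trace cannot be fitted
  expect_error(fit_pore_radius(time_series(tt, rep(1e-6, length(tt)))),
               "converge")
  expect_error(fit_pore_radius(time_series(1:5, 1:5 * 1e-6)), "6 points")
  # growing-exponential variant
  yg <- 5e-7 * exp(tt / 30)
  fitg <- fit_pore_radius(time_series(tt, yg), form = "growing")
  expect_equal(unname(fitg$estimates[["tau"]]), 30, tolerance = 1e-6)
})

test_that("tau estimator is unbiased within 5% at 5% noise (n = 100)", {
  p <- liposome_params("actin")
  pt <- pore_timescale(p)
  trace <- pt$trace
  tau0 <- pt$tau
  set.seed(71)
  taus <- vapply(1:100, function(i) {
    noisy <- trace$y * (1 + stats::rnorm(length(trace$y), 0, 0.05))
    fit_pore_radius(time_series(trace$t, pmax(noisy, 0)))$estimates[["tau"]]
  }, numeric(1))
  expect_lt(abs(mean(taus) - tau0) / tau0, 0.05)
})

test_that("timescale normalization and the study group ratios", {
  expect_equal(normalize_tau(20, 20), 1)
  expect_equal(normalize_tau(80, 20), 4)
  expect_error(normalize_tau(20, 0), "tau_BL")
})

test_that("centre-depletion fit detects the onset and recovers tau_a", {
  tt <- seq(0, 400, by = 2)
  y <- 0.2 + 0.8 * exp(-pmax(tt - 30, 0) / 100)
  fit <- fit_center_depletion(time_series(tt, y))
  expect_equal(unname(fit$estimates[["tau_a"]]), 100, tolerance = 1e-3)
  expect_equal(attr(fit, "onset"), 30, tolerance = 4)
  # monotonically rising trace is rejected
  expect_error(fit_center_depletion(time_series(tt, 0.1 + tt / 400)),
               "rising")
  # Monte-Carlo bias < 5% at 5% noise
  set.seed(72)
  taus <- vapply(1:100, function(i) {
    noisy <- y * (1 + stats::rnorm(length(y), 0, 0.05))
    fit_center_depletion(time_series(tt, noisy))$estimates[["tau_a"]]
  }, numeric(1))
  expect_lt(abs(mean(taus) - 100) / 100, 0.05)
})

test_that("density fold normalizes by the baseline window and is scale free", {
  tt <- seq(0, 100, by = 1)
  y <- c(rep(2, 20), seq(2, 3.2, length.out = 81))
  ts <- time_series(tt, y)
  fold <- density_fold(ts, c(0, 19))
  expect_equal(fold$y[1], 1)
  expect_equal(fold$y[length(fold$y)], 1.6, tolerance = 1e-12)
  # constant trace maps to all ones
  expect_equal(density_fold(time_series(tt, rep(7, 101)), c(0, 50))$y,
               rep(1, 101))
  # multiplicative rescaling of the input leaves the output unchanged
  fold2 <- density_fold(time_series(tt, 13 * y), c(0, 19))
  expect_equal(fold2$y, fold$y, tolerance = 1e-12)
  expect_error(density_fold(time_series(tt, y), c(500, 600)), "window")
  expect_error(density_fold(time_series(tt, y - 2), c(0, 19)), "baseline")
})

test_that("kymograph PIV recovers rigid translation and linear strain", {
  set.seed(2)
  nx <- 240; nt <- 12
  tex <- as.numeric(stats::filter(stats::rnorm(nx + 200), c(.25, .5, .25),
                                  circular = TRUE))
  shift <- 3.25
  img <- t(vapply(0:(nt - 1), function(k) {
    stats::approx(seq_len(nx + 200), tex, xout = seq_len(nx) + 100 -
                    shift * k, rule = 2)$y
  }, numeric(nx)))
  dg <- displacement_gradient(kymograph(img, 1e-7, 1))
  nw <- ncol(dg$U)
  interior <- 6:(nw - 6)
  inc <- mean(diff(rowMeans(dg$U[, interior]))) / 1e-7
  expect_equal(inc, shift, tolerance = 0.05)
  expect_lt(max(abs(dg$dUdx[, interior])), 0.2)
  # static kymograph: identically zero displacement
  img0 <- matrix(rep(tex[1:nx], 5), 5, byrow = TRUE)
  dg0 <- displacement_gradient(kymograph(img0, 1e-7, 1))
  expect_equal(max(abs(dg0$U)), 0)
  # linear velocity ramp: constant strain rate within 10%
  rate <- 0.02
  img2 <- t(vapply(0:(nt - 1), function(k) {
    stats::approx(seq_len(nx + 200), tex,
                  xout = (seq_len(nx) + 100) * (1 - rate)^k, rule = 2)$y
  }, numeric(nx)))
  dg2 <- displacement_gradient(kymograph(img2, 1e-7, 1))
  expect_lt(abs(mean(dg2$dUdx[1, interior]) - rate), 0.1 * rate + 0.003)
  expect_error(displacement_gradient(kymograph(img[1:2, ], 1e-7, 1)),
               "time lines")
})

test_that("model fit to a clean trace reproduces truth with tiny residual", {
  p <- recovery_params()
  tg <- recovery_tgrid()
  g <- gen_pore_trace(p, 5e-7, tg, noise_sd = 0)
  fit <- fit_model_to_trace(g$trace, p, free = c("sigma0", "zeta"))
  expect_lt(fit$residual_rms / p$R_L, 1e-6)
  expect_equal(unname(fit$estimates[["sigma0"]]), 1, tolerance = 1e-3)
  expect_equal(unname(fit$estimates[["zeta"]]), 1, tolerance = 1e-2)
  expect_equal(fit$sigma_a_d, 1e-7, tolerance = 1e-3)
  # fluidization diagnostic: with zeta > 0 the ratio drops below 1 over time
  expect_lt(min(fit$eta_eff_ratio$y), 1)
})

test_that("fixing zeta to zero on a fluidized trace fits worse than freeing it", {
  p <- recovery_params()
  tg <- recovery_tgrid()
  g <- gen_pore_trace(p, 5e-7, tg, noise_sd = 0.01, seed = 5,
                      noise_type = "relative")
  free_fit <- fit_model_to_trace(g$trace, p, free = c("sigma0", "zeta"))
  p0 <- with_params(p, zeta = 0)
  fixed_fit <- fit_model_to_trace(g$trace, p0, free = "sigma0")
  expect_gt(fixed_fit$residual_rms, free_fit$residual_rms)
})

test_that("Welch comparison matches a hand-computed closed form", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  gc <- group_compare(a, b)
  # independent closed-form Welch computation
  se <- sqrt(stats::var(a) / 4 + stats::var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((stats::var(a) / 4)^2 / 3 + (stats::var(b) / 4)^2 / 3)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(gc$statistic, t_hand, tolerance = 1e-10)
  expect_equal(gc$p_value, p_hand, tolerance = 1e-10)
  # identical groups: p = 1
  expect_equal(group_compare(c(3, 3, 3), c(3, 3, 3))$p_value, 1)
  # large separation earns the three-star convention
  gc2 <- group_compare(stats::rnorm(20, 0, 0.1), stats::rnorm(20, 10, 0.1))
  expect_lt(gc2$p_value, 0.001)
  expect_identical(gc2$stars, "***")
  expect_error(group_compare(1, c(1, 2)), "n >= 2")
})

test_that("Fisher exact p equals brute-force hypergeometric enumeration", {
  # diagonal table against the enumeration oracle
  t1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(prevalence_compare(t1)$p_value, fisher_bruteforce(t1),
               tolerance = 1e-12)
  # identical rows: p = 1
  expect_equal(prevalence_compare(matrix(c(5, 5, 7, 7), 2,
                                         byrow = TRUE))$p_value, 1)
  # row swap leaves p unchanged
  t2 <- matrix(c(8, 3, 2, 9), 2)
  expect_equal(prevalence_compare(t2)$p_value,
               prevalence_compare(t2[2:1, ])$p_value, tolerance = 1e-12)
  expect_error(prevalence_compare(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  expect_error(prevalence_compare(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})
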