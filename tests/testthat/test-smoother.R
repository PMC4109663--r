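test_that("whitening matrix realizes the AR difference equation", {
  expect_equal(whitening_matrix(list(coeffs = numeric(0)), 4), diag(4))
  A <- whitening_matrix(list(coeffs = 0.8), 3)
  expect_equal(A, rbind(c(1, 0, 0), c(-0.8, 1, 0), c(0, -0.8, 1)))
  # applied to a long AR(1) realization the output is white with var sigma2
  x <- sample_ar_noise(ar1_spec(0.8, 1), 5000, seed = 8)
  w <- whitening_matrix(list(coeffs = 0.8), 5000) %*% x
  expect_equal(var(w[-1]), 1, tolerance = 0.05)
})

test_that("difference matrix is the inverse of repeated cumulative sums", {
  expect_equal(difference_matrix(1, 3), rbind(c(1, 0, 0), c(-1, 1, 0), c(0, -1, 1)))
  # second difference annihilates affine sequences except initial conditions
  F2 <- difference_matrix(2, 20)
  ramp <- 3 * (1:20) + 7
  expect_equal((F2 %*% ramp)[3:20], numeric(18))
  # invertibility; inverse performs m cumulative sums
  F2 <- difference_matrix(2, 50)
  expect_equal(solve(F2) %*% F2, diag(50), tolerance = 1e-10)
  v <- rnorm(50)
  expect_equal(as.numeric(solve(F2, v)), cumsum(cumsum(v)), tolerance = 1e-8)
})

test_that("smoother solves the penalized weighted least-squares problem", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    y <- rnorm(n)
    A <- whitening_matrix(list(coeffs = random_stable_ar()), n)
    F_mat <- difference_matrix(sample(1:3, 1), n)
    g <- 10^runif(1, -2, 2)
    u <- bayes_smooth(y, A, F_mat, g)
    expect_equal(u, qr_smooth_oracle(y, A, F_mat, g), tolerance = 1e-8)
  }
  expect_error(bayes_smooth(c(1, NA), diag(2), diag(2), 1), "non-finite")
})

test_that("smoother is linear and respects its limits", {
  set.seed(12)
  n <- 40
  A <- whitening_matrix(list(coeffs = c(0.6, -0.2)), n)
  F_mat <- difference_matrix(2, n)
  y1 <- rnorm(n); y2 <- rnorm(n)
  expect_equal(bayes_smooth(2 * y1 - 3 * y2, A, F_mat, 5),
               2 * bayes_smooth(y1, A, F_mat, 5) - 3 * bayes_smooth(y2, A, F_mat, 5),
               tolerance = 1e-10)
  # gamma = 0: identity
  expect_equal(bayes_smooth(y1, A, F_mat, 0), y1, tolerance = 1e-10)
  # huge gamma: roughness vanishes relative to the estimate's size
  y <- rnorm(200)
  A2 <- whitening_matrix(list(coeffs = 0.5), 200)
  F2 <- difference_matrix(2, 200)
  u <- bayes_smooth(y, A2, F2, 1e12)
  expect_lt(sqrt(sum((F2 %*% u)^2) / sum(u^2)), 1e-4)
})

test_that("wrss is the whitened residual energy", {
  set.seed(13)
  y <- rnorm(10); u <- rnorm(10)
  A <- whitening_matrix(list(coeffs = c(0.4, 0.1)), 10)
  expect_equal(wrss(y, y, A), 0)
  expect_equal(wrss(y, u, diag(10)), sum((y - u)^2))
  expect_equal(wrss(y, u, A), sum((A %*% (y - u))^2))
})

test_that("discrepancy tuning solves WRSS = n sigma^2 and WRSS is monotone", {
  set.seed(14)
  n <- 200
  y <- sample_ar_noise(ar1_spec(0.7, 1), n) +
    make_erp_template()$waveform
  A <- whitening_matrix(list(coeffs = 0.7), n)
  F_mat <- difference_matrix(2, n)
  res <- tune_gamma_discrepancy(y, A, F_mat, sigma2 = 1)
  expect_true(res$erp$converged)
  expect_equal(res$erp$wrss / (n * 1), 1, tolerance = 1e-3)
  expect_equal(wrss(y, res$erp$u_hat, A), res$erp$wrss, tolerance = 1e-8)

  gammas <- 10^seq(-4, 8, length.out = 20)
  w <- sapply(gammas, function(g) wrss(y, bayes_smooth(y, A, F_mat, g), A))
  expect_true(all(diff(w) >= -1e-8))
})

test_that("pure-noise epochs attract heavier smoothing than high-SNR targets", {
  tpl <- make_erp_template()
  ns <- ar1_spec(0.6, 4)
  res <- withr::with_seed(15, {
    sapply(1:100, function(i) {
      tgt <- baseline_correct(make_epoch(tpl, ns, "target", snr_db = 10))
      non <- baseline_correct(make_epoch(tpl, ns, "nontarget"))
      c(estimate_single_trial(tgt$pre[[1]], tgt$post[[1]])$gamma,
        estimate_single_trial(non$pre[[1]], non$post[[1]])$gamma)
    })
  })
  expect_gt(mean(log10(res[2, ])), mean(log10(res[1, ])))
})

test_that("FPE selects the generating order and white noise stays white", {
  res <- withr::with_seed(16, {
    lapply(1:100, function(i) {
      x <- sample_ar_noise(noise_spec(c(1.2, -0.5), 1), 100)
      fit_ar_fpe(x - mean(x), p_max = 10)
    })
  })
  orders <- sapply(res, `[[`, "p")
  expect_equal(as.integer(names(which.max(table(orders)))), 2L)
  coefs <- sapply(res[orders == 2], `[[`, "coeffs")
  expect_lt(max(abs(rowMeans(coefs) - c(1.2, -0.5))), 0.15)

  # on white noise the fitted innovation variance tracks the sample variance
  ratios <- withr::with_seed(17, {
    sapply(1:20, function(i) {
      wn <- rnorm(100, sd = 2)
      fit_ar_fpe(wn - mean(wn))$sigma2 / var(wn)
    })
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
  # FPE values computed and returned for every candidate order
  fit <- fit_ar_fpe(withr::with_seed(17, rnorm(100)))
  expect_length(fit$fpe_values, 10)
  expect_true(all(is.finite(fit$fpe_values)))
  expect_error(fit_ar_fpe(rep(0, 100)), "zero variance")
  expect_error(fit_ar_fpe(rnorm(100), p_max = 60), "p_max")
})

test_that("single-trial estimation recovers a noise-free template", {
  tpl <- make_erp_template()
  ep <- withr::with_seed(18, make_epoch(tpl, white_spec(1), "target", snr_db = Inf))
  ep <- baseline_correct(ep)
  est <- estimate_single_trial(ep$pre[[1]], ep$post[[1]], gamma_star = 1)
  rel_rmse <- sqrt(mean((est$u_hat - ep$post[[1]])^2) / mean(ep$post[[1]]^2))
  expect_lt(rel_rmse, 0.05)
})

test_that("smoothing shrinks nontarget epochs and preserves the average", {
  tpl <- make_erp_template()
  ns <- noise_spec()
  norms <- withr::with_seed(19, {
    sapply(1:30, function(i) {
      ep <- baseline_correct(make_epoch(tpl, ns, "nontarget"))
      est <- estimate_single_trial(ep$pre[[1]], ep$post[[1]])
      c(sqrt(sum(est$u_hat^2)), sqrt(sum(ep$post[[1]]^2)))
    })
  })
  expect_lt(mean(norms[1, ] / norms[2, ]), 0.6)

  # population level: the average of 50 estimates tracks the average of the
  # 50 raw target epochs up to the smoother's modest peak attenuation
  eps <- withr::with_seed(20, {
    purrr::map_dfr(1:50, ~ make_epoch(tpl, ns, "target", snr_db = 6))
  })
  eps <- baseline_correct(eps)
  est <- estimate_epochs(eps)
  avg_raw <- colMeans(do.call(rbind, eps$post))
  avg_est <- colMeans(do.call(rbind, est$u_hat))
  expect_lt(max(abs(avg_est - avg_raw)), 0.2 * max(abs(avg_raw)))
  expect_gt(cor(avg_est, avg_raw), 0.99)
})

test_that("gamma_star is the median of per-epoch discrepancy gammas", {
  expect_equal(bayeserp:::new_gamma_star(c(1, 10, 100))$value, 10)
  expect_equal(bayeserp:::new_gamma_star(c(1, 3))$value, 2)
  expect_equal(bayeserp:::new_gamma_star(7)$value, 7)
  expect_error(calibrate_gamma_star(tibble::tibble(pre = list(), post = list())),
               "no calibration epochs")

  eps <- generate_study(1, sessions_per_day = 0, n_calibration_sessions = 2,
                        seed = 21) |> baseline_correct()
  gs <- calibrate_gamma_star(eps)
  est <- estimate_epochs(eps)
  expect_equal(gs$value, median(est$gamma))
  expect_equal(gs$n_calibration_epochs, nrow(eps))
})
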