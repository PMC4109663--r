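#' Smoother configuration
#'
#' Collects the tunable parameters of the Bayesian single-trial estimator:
#' the order `m` of the integrated-white-noise prior (the expected ERP is
#' `m` discrete integrations of white noise; `m = 2` encodes a
#' doubly-integrated, i.e. smooth, process), the AR order search bound for
#' the prestimulus noise model, and the bracketing/tolerance settings of
#' the discrepancy search for the regularization ratio
#' `gamma = sigma^2 / lambda^2`.
#'
#' @param m Prior integration order (>= 1); default 2.
#' @param p_max AR order search upper bound for FPE selection; default 10.
#' @param gamma_bounds Positive bracket for the discrepancy root search.
#' @param discrepancy_rel_tol Relative tolerance on `WRSS - n sigma^2`.
#' @param max_iter Maximum bisection iterations.
#' @return A list of class `smoother_config`.
#' @export
smoother_config <- function(m = 2L, p_max = 10L,
                            gamma_bounds = c(1e-4, 1e8),
                            discrepancy_rel_tol = 1e-3,
                            max_iter = 60L) {
  stopifnot(m >= 1, p_max >= 1, gamma_bounds[1] > 0,
            gamma_bounds[1] < gamma_bounds[2])
  structure(list(m = as.integer(m), p_max = as.integer(p_max),
                 gamma_bounds = gamma_bounds,
                 discrepancy_rel_tol = discrepancy_rel_tol,
                 max_iter = as.integer(max_iter)),
            class = "smoother_config")
}

#' Fit an AR model to prestimulus data with FPE order selection
#'
#' Least-squares (covariance method) AR fits for every order
#' `p = 1..p_max`; the final prediction error
#' `FPE(p) = sigma_p^2 (N + p + 1) / (N - p - 1)` selects the order. The
#' innovation variance is the residual mean square over the `N - p`
#' prediction equations. Fits whose characteristic roots fall outside the
#' stationarity region are stabilized by reflecting the offending roots
#' inside the unit circle (leaving the spectrum's shape intact).
#'
#' @param prestim Zero-mean numeric vector (the 100 baseline-corrected
#'   prestimulus samples).
#' @param p_max Highest candidate order; must be `< length(prestim) / 2`.
#' @return An object of class `ar_model`: order `p`, `coeffs`, innovation
#'   variance `sigma2`, the selected `fpe` and the full `fpe_values` vector.
#' @export
fit_ar_fpe <- function(prestim, p_max = 10L) {
  N <- length(prestim)
  if (p_max >= N / 2) stop("`p_max` must be < length(prestim)/2", call. = FALSE)
  if (stats::var(prestim) == 0) {
    stop("prestimulus segment has zero variance; AR model undefined", call. = FALSE)
  }
  fits <- vector("list", p_max)
  fpe <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    y <- prestim[(p + 1):N]
    X <- sapply(seq_len(p), function(k) prestim[(p + 1 - k):(N - k)])
    X <- matrix(X, ncol = p)
    fit <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(fit)) {
      warning("AR fit of order ", p, " numerically singular; skipped", call. = FALSE)
      next
    }
    rss <- sum((y - X %*% fit)^2)
    sigma2 <- rss / (N - p)
    fpe[p] <- sigma2 * (N + p + 1) / (N - p - 1)
    fits[[p]] <- list(coeffs = as.numeric(fit), sigma2 = sigma2)
  }
  if (all(is.na(fpe))) stop("all AR orders failed to fit", call. = FALSE)
  p_sel <- which.min(fpe)
  best <- fits[[p_sel]]
  coeffs <- stabilize_ar(best$coeffs)
  structure(list(p = p_sel, coeffs = coeffs,
                 sigma2 = max(best$sigma2, .Machine$double.eps),
                 fpe = fpe[p_sel], fpe_values = fpe, n = N),
            class = "ar_model")
}

# reflect characteristic roots outside the unit circle to 1/conj(root)
stabilize_ar <- function(coeffs) {
  if (length(coeffs) == 0 || ar_is_stable(coeffs)) return(coeffs)
  # roots of z^p - a1 z^(p-1) - ... - ap (inverse characteristic roots)
  r <- polyroot(rev(c(-coeffs, 1)))
  bad <- Mod(r) >= 1
  r[bad] <- 1 / Conj(r[bad]) * 0.999
  # rebuild monic polynomial prod(z - r_i), read off -a
  poly <- 1
  for (ri in r) poly <- c(poly, 0) - c(0, poly * ri)
  Re(-poly[-1])
}

#' Noise whitening matrix of an AR model
#'
#' Lower-triangular banded Toeplitz matrix `A` with unit diagonal and
#' `-a_1..-a_p` on the first `p` subdiagonals: applied to a realization of
#' the AR process, `A v` is (up to the first `p` samples' transient)
#' white with variance `sigma2`. The noise covariance used by the smoother
#' is `sigma2 (A'A)^{-1}`.
#'
#' @param ar An [fit_ar_fpe()] model (or any list with `coeffs`).
#' @param n Matrix dimension.
#' @return Dense `n x n` matrix.
#' @export
whitening_matrix <- function(ar, n) {
  coeffs <- if (is.list(ar)) ar$coeffs else ar
  A <- diag(n)
  for (k in seq_along(coeffs)) {
    idx <- seq_len(n - k)
    A[cbind(idx + k, idx)] <- -coeffs[k]
  }
  A
}

#' m-th order difference matrix with zero initial conditions
#'
#' The inverse of the `m`-fold cumulative-sum operator: a lower-triangular
#' Toeplitz matrix `F` such that `F^{-1}` applied to a vector performs `m`
#' cumulative sums. With zero initial conditions `F` is invertible, so the
#' smoothness prior `lambda^2 (F'F)^{-1}` is proper.
#'
#' @param m Difference order (>= 1).
#' @param n Matrix dimension.
#' @return Dense `n x n` matrix.
#' @export
difference_matrix <- function(m, n) {
  stopifnot(m >= 1)
  D <- diag(n)
  idx <- seq_len(n - 1)
  D[cbind(idx + 1, idx)] <- -1
  Reduce(`%*%`, rep(list(D), m))
}

#' Bayesian linear smoother
#'
#' Computes the posterior-mean single-trial estimate
#' `u_hat = (A'A + gamma F'F)^{-1} A'A y`, the minimizer of the whitened
#' residual plus roughness penalty
#' `(y - u)' A'A (y - u) + gamma ||F u||^2`, via a Cholesky solve of the
#' banded normal matrix.
#'
#' @param y Numeric vector (one poststimulus sweep, microvolts).
#' @param A Whitening matrix from [whitening_matrix()].
#' @param F_mat Difference matrix from [difference_matrix()].
#' @param gamma Regularization ratio `sigma^2 / lambda^2` (>= 0); 0 returns
#'   `y` unchanged.
#' @return Numeric vector, the smoothed estimate.
#' @export
bayes_smooth <- function(y, A, F_mat, gamma) {
  if (!all(is.finite(y))) stop("`y` contains non-finite values", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  B <- crossprod(A)
  M <- B + gamma * crossprod(F_mat)
  ch <- chol(M)
  rhs <- B %*% y
  as.numeric(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
}

#' Weighted residual sum of squares
#'
#' The discrepancy functional `(y - u_hat)' A'A (y - u_hat)`, i.e. the
#' energy of the whitened residual. With `A = I` it reduces to the ordinary
#' residual sum of squares.
#'
#' @param y Data vector.
#' @param u_hat Estimate.
#' @param A Whitening matrix.
#' @return Nonnegative scalar.
#' @export
wrss <- function(y, u_hat, A) {
  r <- A %*% (y - u_hat)
  sum(r^2)
}

#' Tune the regularization ratio by the discrepancy criterion
#'
#' Finds `gamma` such that the weighted residual energy of the smoothed
#' estimate equals its expectation under the noise model,
#' `WRSS(gamma) = n sigma^2`. WRSS is nondecreasing in `gamma` (0 at
#' `gamma = 0`), so the root is located by bisection on `log10(gamma)`
#' within `config$gamma_bounds`. If the target is not bracketed the nearer
#' bound is returned with `converged = FALSE`.
#'
#' @param y Poststimulus data vector (length `n`).
#' @param A Whitening matrix (`n x n`).
#' @param F_mat Difference matrix (`n x n`).
#' @param sigma2 Innovation variance of the whitened noise (> 0).
#' @param config A [smoother_config()].
#' @return A list with elements `gamma` and `erp` (an `estimated_erp`
#'   carrying `u_hat`, `gamma`, `wrss`, `converged`).
#' @export
tune_gamma_discrepancy <- function(y, A, F_mat, sigma2,
                                   config = smoother_config()) {
  if (!all(is.finite(y))) stop("`y` contains non-finite values", call. = FALSE)
  stopifnot(sigma2 > 0)
  n <- length(y)
  target <- n * sigma2
  B <- crossprod(A)
  R <- crossprod(F_mat)
  By <- B %*% y

  solve_u <- function(gamma) {
    ch <- chol(B + gamma * R)
    as.numeric(backsolve(ch, backsolve(ch, By, transpose = TRUE)))
  }
  wrss_at <- function(u) {
    r <- A %*% (y - u)
    sum(r^2)
  }

  lo <- log10(config$gamma_bounds[1])
  hi <- log10(config$gamma_bounds[2])
  u_hi <- solve_u(10^hi)
  w_hi <- wrss_at(u_hi)
  if (w_hi < target) {
    return(finish_tuning(y, 10^hi, u_hi, w_hi, converged = FALSE))
  }
  u_lo <- solve_u(10^lo)
  w_lo <- wrss_at(u_lo)
  if (w_lo > target) {
    return(finish_tuning(y, 10^lo, u_lo, w_lo, converged = FALSE))
  }

  g <- NA_real_; u <- NULL; w <- NA_real_
  for (it in seq_len(config$max_iter)) {
    mid <- (lo + hi) / 2
    g <- 10^mid
    u <- solve_u(g)
    w <- wrss_at(u)
    if (abs(w - target) <= config$discrepancy_rel_tol * target) {
      return(finish_tuning(y, g, u, w, converged = TRUE))
    }
    if (w < target) lo <- mid else hi <- mid
  }
  finish_tuning(y, g, u, w,
                converged = abs(w - target) <= config$discrepancy_rel_tol * target)
}

finish_tuning <- function(y, gamma, u, w, converged) {
  erp <- structure(list(u_hat = u, gamma = gamma, ar = NULL, wrss = w,
                        converged = converged, fs_hz = FS_HZ),
                   class = "estimated_erp")
  list(gamma = gamma, erp = erp)
}

#' Estimate the single-trial ERP of one epoch
#'
#' The full per-epoch stage: an AR(p) noise model is identified from the
#' 100 baseline-corrected prestimulus samples (order by FPE), the
#' whitening matrix `A` and difference matrix `F` (order `m`) are built at
#' the poststimulus length, and the 200 poststimulus samples are smoothed.
#' During calibration (`gamma_star = NULL`) the regularization ratio is
#' tuned per epoch by the discrepancy criterion; during testing a fixed
#' `gamma_star` (the median of calibration gammas, see
#' [calibrate_gamma_star()]) is applied directly.
#'
#' @param pre Baseline-corrected prestimulus samples (length 100).
#' @param post Baseline-corrected poststimulus samples (length 200).
#' @param config A [smoother_config()].
#' @param gamma_star Optional fixed regularization ratio (or a
#'   `gamma_star` object); `NULL` triggers per-epoch discrepancy tuning.
#' @return An object of class `estimated_erp`: `u_hat` (length 200),
#'   `gamma`, the `ar` model, `wrss` and `converged` (`NA` in fixed-gamma
#'   mode, where no discrepancy equation is solved).
#' @export
estimate_single_trial <- function(pre, post, config = smoother_config(),
                                  gamma_star = NULL) {
  ar <- fit_ar_fpe(pre, p_max = config$p_max)
  n <- length(post)
  A <- whitening_matrix(ar, n)
  F_mat <- difference_matrix(config$m, n)
  if (is.null(gamma_star)) {
    res <- tune_gamma_discrepancy(post, A, F_mat, ar$sigma2, config)
    erp <- res$erp
  } else {
    g <- if (inherits(gamma_star, "gamma_star")) gamma_star$value else gamma_star
    u <- bayes_smooth(post, A, F_mat, g)
    erp <- structure(list(u_hat = u, gamma = g, ar = NULL,
                          wrss = wrss(post, u, A), converged = NA,
                          fs_hz = FS_HZ),
                     class = "estimated_erp")
  }
  erp$ar <- ar
  erp
}

#' Estimate single-trial ERPs for a whole epoch tibble
#'
#' Maps [estimate_single_trial()] over the rows of an epoch tibble,
#' returning the tibble augmented with the estimate and its diagnostics.
#' Epochs whose AR identification fails are dropped with a warning.
#'
#' @param epochs Baseline-corrected epoch tibble (list-columns `pre`,
#'   `post`).
#' @inheritParams estimate_single_trial
#' @return `epochs` plus columns `u_hat` (list), `gamma`, `ar_p`,
#'   `ar_sigma2`, `wrss`, `converged`.
#' @export
estimate_epochs <- function(epochs, config = smoother_config(),
                            gamma_star = NULL) {
  fits <- purrr::map2(epochs$pre, epochs$post, function(pre, post) {
    tryCatch(estimate_single_trial(pre, post, config, gamma_star),
             error = function(e) NULL)
  })
  ok <- !purrr::map_lgl(fits, is.null)
  if (any(!ok)) {
    warning(sum(!ok), " epoch(s) skipped: AR identification failed", call. = FALSE)
  }
  out <- epochs[ok, , drop = FALSE]
  fits <- fits[ok]
  out$u_hat <- purrr::map(fits, "u_hat")
  out$gamma <- purrr::map_dbl(fits, "gamma")
  out$ar_p <- purrr::map_int(fits, ~ .x$ar$p)
  out$ar_sigma2 <- purrr::map_dbl(fits, ~ .x$ar$sigma2)
  out$wrss <- purrr::map_dbl(fits, "wrss")
  out$converged <- purrr::map_lgl(fits, "converged")
  out
}

#' Fix the testing-phase regularization ratio from calibration epochs
#'
#' Runs per-epoch discrepancy tuning on every calibration epoch (targets
#' and nontargets alike) and returns the median of the tuned gammas — the
#' fixed value used when processing testing-day epochs, avoiding the
#' per-epoch cost of the discrepancy search in online-style operation.
#'
#' @param epochs Baseline-corrected calibration epoch tibble.
#' @param config A [smoother_config()].
#' @return An object of class `gamma_star` with `value`,
#'   `n_calibration_epochs` and the `source_gammas` vector.
#' @export
calibrate_gamma_star <- function(epochs, config = smoother_config()) {
  if (nrow(epochs) == 0) stop("no calibration epochs supplied", call. = FALSE)
  est <- estimate_epochs(epochs, config, gamma_star = NULL)
  new_gamma_star(est$gamma)
}

new_gamma_star <- function(gammas) {
  structure(list(value = median(gammas),
                 n_calibration_epochs = length(gammas),
                 source_gammas = gammas),
            class = "gamma_star")
}

#' @export
print.gamma_star <- function(x, ...) {
  cat("<gamma_star>", format(x$value, digits = 4), "(median of",
      x$n_calibration_epochs, "discrepancy-tuned epochs)\n")
  invisible(x)
}

#' @export
print.estimated_erp <- function(x, ...) {
  cat("<estimated_erp> n =", length(x$u_hat),
      "gamma =", format(x$gamma, digits = 4),
      "AR order =", if (is.null(x$ar)) NA else x$ar$p,
      "wrss =", format(x$wrss, digits = 4), "\n")
  invisible(x)
}
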