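#' Tidy an AR noise model
#'
#' @param x An [fit_ar_fpe()] model.
#' @param ... Unused.
#' @return Tibble with one row per lag coefficient.
#' @exportS3Method generics::tidy
tidy.ar_model <- function(x, ...) {
  tibble::tibble(term = paste0("a", seq_along(x$coeffs)), estimate = x$coeffs)
}

#' @rdname tidy.ar_model
#' @return `glance.ar_model`: one-row tibble with `p`, `sigma2`, `fpe`, `n`.
#' @exportS3Method generics::glance
glance.ar_model <- function(x, ...) {
  tibble::tibble(p = x$p, sigma2 = x$sigma2, fpe = x$fpe, n = x$n)
}

#' Tidy an estimated single-trial ERP
#'
#' @param x An `estimated_erp`.
#' @param ... Unused.
#' @return Tibble with `time_ms` and `amplitude` (one row per poststimulus
#'   sample).
#' @exportS3Method generics::tidy
tidy.estimated_erp <- function(x, ...) {
  tibble::tibble(
    time_ms = (seq_along(x$u_hat) - 1) / x$fs_hz * 1000,
    amplitude = x$u_hat
  )
}

#' @rdname tidy.estimated_erp
#' @return `glance.estimated_erp`: one-row tibble of diagnostics.
#' @exportS3Method generics::glance
glance.estimated_erp <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma,
    ar_p = if (is.null(x$ar)) NA_integer_ else x$ar$p,
    ar_sigma2 = if (is.null(x$ar)) NA_real_ else x$ar$sigma2,
    wrss = x$wrss,
    converged = x$converged
  )
}

#' Tidy a trained P300 classifier
#'
#' @param x A [train_classifier()] model.
#' @param ... Unused.
#' @return The cross-validation report (one row per grid point), or an
#'   empty tibble when none was recorded.
#' @exportS3Method generics::tidy
tidy.p300_classifier <- function(x, ...) {
  if (is.null(x$cv_report)) {
    return(tibble::tibble(C = numeric(), width = numeric(),
                          mean_val_accuracy = numeric()))
  }
  x$cv_report
}

#' @rdname tidy.p300_classifier
#' @return `glance.p300_classifier`: one-row tibble with the selected
#'   hyperparameters and support-vector count.
#' @exportS3Method generics::glance
glance.p300_classifier <- function(x, ...) {
  tibble::tibble(
    C = x$C, width = x$width,
    n_support_vectors = if (x$degenerate) NA_integer_ else x$fit$tot.nSV,
    degenerate = x$degenerate
  )
}

#' Tidy an SC/MC accuracy comparison
#'
#' @param x A [compare_sc_mc()] result.
#' @param ... Unused.
#' @return The per-group/day/system summary tibble.
#' @exportS3Method generics::tidy
tidy.sc_mc_comparison <- function(x, ...) x$summary

#' @rdname tidy.sc_mc_comparison
#' @return `glance.sc_mc_comparison`: one-row tibble with the headline
#'   scalars.
#' @exportS3Method generics::glance
glance.sc_mc_comparison <- function(x, ...) {
  tibble::tibble(
    max_abs_median_diff = x$max_abs_median_diff,
    best_max_improvement = x$best_max_improvement,
    min_wilcoxon_p = min(x$tests$wilcoxon_p),
    all_nonsignificant = all(x$tests$wilcoxon_p >= 0.05)
  )
}
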