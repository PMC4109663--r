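#' Names of the 78-element feature inventory
#'
#' Stable order: five non-overlapping 200-ms windows over 0-1000 ms, each
#' contributing maximum amplitude, maximum latency, minimum amplitude,
#' minimum latency and mean power (25 features); global maximum amplitude,
#' maximum latency and minimum amplitude over the full window (3); and the
#' 50 level-2 Haar approximation coefficients of the 200-sample waveform
#' (50).
#'
#' @return Character vector of length 78.
#' @export
feature_names <- function() {
  win <- unlist(lapply(1:5, function(w) {
    paste0("win", w, "_", c("max_amp", "max_lat_ms", "min_amp", "min_lat_ms", "mean_power"))
  }))
  c(win, "glob_max_amp", "glob_max_lat_ms", "glob_min_amp",
    sprintf("haar_a2_%02d", 1:50))
}

# orthonormal Haar analysis step: pairwise scaled sums
haar_approx_step <- function(x) {
  (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / sqrt(2)
}

#' Extract the 78-feature vector from one estimated single-trial ERP
#'
#' Latencies are reported in ms after stimulus onset (sample k maps to
#' (k-1)/fs_hz seconds); ties are broken by the earliest sample, so an
#' all-zero input yields window-start latencies. Mean power is the mean of
#' squared amplitudes within the window. The wavelet block is the level-2
#' Haar approximation (200 -> 100 -> 50 coefficients, no padding needed).
#'
#' @param erp An `estimated_erp` from [estimate_single_trial()], or a bare
#'   numeric vector of length 200.
#' @param fs_hz Sampling frequency (200).
#' @return Named numeric vector of length 78 in [feature_names()] order.
#' @export
extract_features <- function(erp, fs_hz = FS_HZ) {
  u <- if (inherits(erp, "estimated_erp")) erp$u_hat else as.numeric(erp)
  if (length(u) != N_POST) {
    stop("expected a ", N_POST, "-sample waveform, got ", length(u), call. = FALSE)
  }
  t_ms <- (seq_len(N_POST) - 1) / fs_hz * 1000
  win_len <- N_POST / 5L
  vals <- numeric(0)
  for (w in 1:5) {
    idx <- ((w - 1L) * win_len + 1L):(w * win_len)
    seg <- u[idx]
    i_max <- which.max(seg)
    i_min <- which.min(seg)
    vals <- c(vals, seg[i_max], t_ms[idx[i_max]], seg[i_min], t_ms[idx[i_min]],
              mean(seg^2))
  }
  g_max <- which.max(u)
  vals <- c(vals, u[g_max], t_ms[g_max], min(u))
  vals <- c(vals, haar_approx_step(haar_approx_step(u)))
  stats::setNames(vals, feature_names())
}

#' Feature matrix for a tibble of estimated epochs
#'
#' @param estimated Tibble from [estimate_epochs()] (list-column `u_hat`).
#' @param fs_hz Sampling frequency.
#' @return Tibble: the epochs' metadata columns (everything except the
#'   waveform list-columns) followed by the 78 feature columns.
#' @export
epoch_features <- function(estimated, fs_hz = FS_HZ) {
  feats <- purrr::map(estimated$u_hat, extract_features, fs_hz = fs_hz)
  fmat <- tibble::as_tibble(do.call(rbind, feats))
  meta <- dplyr::select(estimated, -dplyr::any_of(c("pre", "post", "signal", "u_hat")))
  dplyr::bind_cols(meta, fmat)
}

#' Column means and standard deviations of a training feature matrix
#'
#' @param features Feature tibble from [epoch_features()] (or any tibble
#'   containing the 78 feature columns).
#' @return Tibble with columns `name`, `mean`, `sd`.
#' @export
feature_stats <- function(features) {
  nm <- feature_names()
  stopifnot(all(nm %in% names(features)))
  tibble::tibble(
    name = nm,
    mean = purrr::map_dbl(nm, ~ mean(features[[.x]])),
    sd = purrr::map_dbl(nm, ~ sd(features[[.x]]))
  )
}

#' Standardize features with training-set statistics
#'
#' z-scores every feature column using the supplied training means and
#' standard deviations (never the data's own), mapping zero-variance
#' training columns to 0.
#'
#' @param features Feature tibble.
#' @param training_stats Tibble from [feature_stats()] computed on
#'   calibration data.
#' @return `features` with the 78 feature columns replaced by z-scores.
#' @export
standardize_features <- function(features, training_stats) {
  missing <- setdiff(training_stats$name, names(features))
  if (length(missing) > 0) {
    stop("feature tibble must contain all 78 feature columns; missing ",
         length(missing), call. = FALSE)
  }
  for (i in seq_len(nrow(training_stats))) {
    nm <- training_stats$name[i]
    s <- training_stats$sd[i]
    features[[nm]] <- if (s > 0) (features[[nm]] - training_stats$mean[i]) / s else
      rep(0, nrow(features))
  }
  features
}
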