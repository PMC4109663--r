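#' Extract fixed-length epochs from a continuous recording
#'
#' Cuts one 300-sample sweep around every stimulus onset: 100 samples
#' before (500 ms) and 200 from the onset on (1000 ms). The onset sample
#' itself is the first poststimulus sample, i.e. the poststimulus window is
#' the half-open index range `[onset, onset + 200)`. Onsets too close to
#' either edge of the recording are rejected with a warning.
#'
#' @param samples Numeric vector, the continuous single-channel recording
#'   (microvolts).
#' @param onsets Integer vector of 1-based onset sample indices, strictly
#'   increasing.
#' @param labels Character vector (`"target"`/`"nontarget"`), one per onset.
#' @param fs_hz Sampling frequency (must be 200 for the downstream chain).
#' @return A tibble of accepted epochs with list-columns `pre` and `post`,
#'   plus `onset`, `label` and `fs_hz`.
#' @export
extract_epochs <- function(samples, onsets, labels, fs_hz = FS_HZ) {
  stopifnot(length(onsets) == length(labels))
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("`onsets` must be strictly increasing", call. = FALSE)
  }
  ok <- onsets > N_PRE & onsets + N_POST - 1L <= length(samples)
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) rejected: window extends beyond the recording",
            call. = FALSE)
  }
  purrr::map_dfr(which(ok), function(i) {
    on <- onsets[i]
    tibble::tibble(
      onset = on,
      label = labels[i],
      pre = list(samples[(on - N_PRE):(on - 1L)]),
      post = list(samples[on:(on + N_POST - 1L)]),
      fs_hz = fs_hz
    )
  })
}

#' Baseline-correct epochs to the prestimulus mean
#'
#' Subtracts each epoch's prestimulus mean from both the pre- and
#' poststimulus samples, so the corrected prestimulus window has exactly
#' zero mean (a requirement of the AR noise identification). The operation
#' is idempotent.
#'
#' @param epochs Epoch tibble with list-columns `pre` and `post`.
#' @return The same tibble with shifted `pre` and `post`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(all(c("pre", "post") %in% names(epochs)))
  base <- purrr::map_dbl(epochs$pre, mean)
  epochs$pre <- purrr::map2(epochs$pre, base, `-`)
  epochs$post <- purrr::map2(epochs$post, base, `-`)
  epochs
}
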