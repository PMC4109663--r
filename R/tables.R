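#' Load the packaged SC/MC accuracy tables
#'
#' Reads the transcribed per-subject accuracy tables of the 21 ALS
#' patients and 9 healthy controls (testing days T1-T4, multichannel
#' system `MC` and single-channel prototype `SC`). The source files keep
#' the original comma-decimal cells; they are normalized to numeric on
#' load.
#'
#' @param path Directory containing `table1_als.csv` and
#'   `table2_controls.csv`; defaults to the copies shipped with the
#'   package.
#' @return Long tibble with columns `subject`, `group` (`"ALS"` /
#'   `"control"`), `day` (`"T1".."T4"`), `system` (`"MC"`/`"SC"`) and
#'   `accuracy` (percent).
#' @export
load_accuracy_tables <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", package = "bayeserp")
  read_one <- function(file, group) {
    wide <- read.csv2(file.path(path, file), stringsAsFactors = FALSE)
    long <- tidyr::pivot_longer(
      tibble::as_tibble(wide), -"subject",
      names_to = c("day", "system"), names_sep = "_", values_to = "accuracy"
    )
    dplyr::mutate(long, group = group, accuracy = as.numeric(.data$accuracy))
  }
  out <- dplyr::bind_rows(
    read_one("table1_als.csv", "ALS"),
    read_one("table2_controls.csv", "control")
  )
  stopifnot(all(out$accuracy >= 0 & out$accuracy <= 100),
            dplyr::n_distinct(out$subject[out$group == "ALS"]) == 21,
            dplyr::n_distinct(out$subject[out$group == "control"]) == 9)
  dplyr::select(out, "subject", "group", "day", "system", "accuracy")
}

#' Compare single-channel and multichannel accuracy distributions
#'
#' Reproduces the published comparison of the two systems from a long
#' accuracy table: per group, day and system the median, 25th/75th
#' percentiles (mid-point convention, see [percentile()]) and maximum; per
#' group and day the SC-MC median difference, the difference of maxima,
#' and the exact two-sided Wilcoxon signed-rank p-value of the paired
#' per-subject accuracies.
#'
#' @param tables Long tibble as returned by [load_accuracy_tables()].
#' @return Object of class `sc_mc_comparison`: list with tibbles `summary`
#'   (group x day x system statistics) and `tests` (group x day paired
#'   comparisons), plus scalars `max_abs_median_diff` and
#'   `best_max_improvement` (largest per-day SC-over-MC gain in maximum
#'   accuracy among the ALS patients).
#' @export
compare_sc_mc <- function(tables) {
  summary <- tables |>
    dplyr::group_by(.data$group, .data$day, .data$system) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$accuracy),
      p25 = percentile(.data$accuracy, 25),
      p75 = percentile(.data$accuracy, 75),
      max = max(.data$accuracy),
      .groups = "drop"
    )

  wide <- tidyr::pivot_wider(tables, names_from = "system", values_from = "accuracy")
  tests <- wide |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      median_diff = median(.data$SC) - median(.data$MC),
      max_diff = max(.data$SC) - max(.data$MC),
      wilcoxon_p = wilcoxon_paired(.data$SC, .data$MC)$p_value,
      .groups = "drop"
    )

  structure(
    list(summary = summary, tests = tests,
         max_abs_median_diff = max(abs(tests$median_diff)),
         best_max_improvement = max(tests$max_diff[tests$group == "ALS"])),
    class = "sc_mc_comparison"
  )
}

#' @export
print.sc_mc_comparison <- function(x, ...) {
  cat("<sc_mc_comparison>\n")
  cat("max |SC-MC median difference|:", x$max_abs_median_diff, "%\n")
  cat("best SC-over-MC gain in per-day maximum (patients):",
      x$best_max_improvement, "%\n")
  cat("smallest Wilcoxon p:", format(min(x$tests$wilcoxon_p), digits = 3), "\n")
  invisible(x)
}
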