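#' Pipeline configuration
#'
#' Bundles the smoother settings and the classifier model-selection
#' settings used by [run_day_evaluation()].
#'
#' @param smoother A [smoother_config()].
#' @param grid SVM hyperparameter grid tibble.
#' @param n_splits Repeated 80/20 splits for model selection.
#' @param split_fraction Training fraction per split.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(smoother = smoother_config(),
                            grid = default_svm_grid(),
                            n_splits = 20, split_fraction = 0.8) {
  structure(list(smoother = smoother, grid = grid, n_splits = n_splits,
                 split_fraction = split_fraction),
            class = "pipeline_config")
}

day_order <- function(day) {
  out <- integer(length(day))
  t <- day != "calibration"
  out[t] <- as.integer(sub("^T", "", day[t]))
  out
}

#' Evaluate one testing day of the single-channel pipeline
#'
#' Mirrors the day-by-day protocol: for testing day `T_i`, everything is
#' (re)calibrated per subject on all preceding sessions — the calibration
#' day plus testing days `T_1..T_{i-1}`. Calibration runs per-epoch
#' discrepancy tuning (yielding the fixed `gamma_star` as the median tuned
#' gamma and the training single-trial estimates), extracts and
#' standardizes features, selects SVM hyperparameters by repeated 80/20
#' splits and trains the classifier. Every flash of day `T_i` is then
#' smoothed with the fixed `gamma_star`, classified, and scored against
#' its true label; accuracy is the percentage of correctly classified
#' flashes.
#'
#' @param study Epoch tibble from [generate_study()] (raw epochs; baseline
#'   correction is applied internally).
#' @param day_index Testing day number `i` (classifies day `T_i`).
#' @param config A [pipeline_config()].
#' @param seed Optional seed for the model-selection splits.
#' @return Tibble with one row per subject: `subject_id`, `day`,
#'   `n_flashes`, `n_correct`, `accuracy` (percent), `gamma_star`, `C`,
#'   `width`.
#' @export
run_day_evaluation <- function(study, day_index, config = pipeline_config(),
                               seed = NULL) {
  stopifnot(day_index >= 1)
  test_day <- paste0("T", day_index)
  if (!test_day %in% study$day) stop("day ", test_day, " not present", call. = FALSE)
  purrr::map_dfr(unique(study$subject_id), function(sid) {
    sub <- dplyr::filter(study, .data$subject_id == sid)
    train <- dplyr::filter(sub, day_order(.data$day) < day_index) |> baseline_correct()
    test <- dplyr::filter(sub, .data$day == test_day) |> baseline_correct()

    # calibration: per-epoch discrepancy tuning gives gamma_star and the
    # training estimates in one pass
    train_est <- estimate_epochs(train, config$smoother, gamma_star = NULL)
    gstar <- new_gamma_star(train_est$gamma)

    train_feats <- epoch_features(train_est)
    stats <- feature_stats(train_feats)
    train_std <- standardize_features(train_feats, stats)
    sel <- select_hyperparameters(train_std, train_std$label, grid = config$grid,
                                  n_splits = config$n_splits,
                                  split_fraction = config$split_fraction,
                                  seed = seed)
    model <- train_classifier(train_feats, train_feats$label, sel$C, sel$width,
                              training_stats = stats, cv_report = sel$cv_report)

    test_est <- estimate_epochs(test, config$smoother, gamma_star = gstar)
    test_feats <- epoch_features(test_est)
    pred <- predict(model, test_feats)
    tibble::tibble(
      subject_id = sid, day = test_day,
      n_flashes = nrow(test_feats),
      n_correct = sum(pred == test_feats$label),
      accuracy = 100 * mean(pred == test_feats$label),
      gamma_star = gstar$value, C = sel$C, width = sel$width
    )
  })
}

#' Evaluate all testing days of a study
#'
#' @inheritParams run_day_evaluation
#' @param days Testing-day indices to evaluate (default: every `T*` day in
#'   the study).
#' @return Row-bound [run_day_evaluation()] results.
#' @export
evaluate_study <- function(study, days = NULL, config = pipeline_config(),
                           seed = NULL) {
  if (is.null(days)) {
    days <- sort(unique(day_order(study$day[study$day != "calibration"])))
  }
  purrr::map_dfr(days, function(i) {
    run_day_evaluation(study, i, config, seed = if (is.null(seed)) NULL else seed + i)
  })
}

#' Simulate the circle game of one feedback session
#'
#' Replays a stream of per-flash classifier decisions through the session
#' rules: a predicted target moves the circle one step towards the flashed
#' arrow's direction (1 = up, 2 = right, 3 = down, 4 = left), a predicted
#' nontarget leaves it still. The session terminates when any image is
#' reached (four steps along its axis) or after `max_flashes` flashes
#' (the 3 min 50 s timeout at 2.5 s ISI).
#'
#' @param predictions Character vector of `"target"`/`"nontarget"`
#'   decisions, in flash order.
#' @param directions Integer vector (1-4), the arrow flashed at each
#'   stimulus.
#' @param desired_direction The user's intended direction (1-4).
#' @param max_flashes Timeout, default 92.
#' @return Object of class `session_state`: final `position` (x, y, in
#'   steps), `flash_count`, `terminated` (`"reached"`, `"timeout"` or
#'   `"running"`), `reached_direction` (NA unless reached) and `success`
#'   (reached the desired image).
#' @export
simulate_session <- function(predictions, directions, desired_direction,
                             max_flashes = 92L) {
  stopifnot(length(predictions) == length(directions),
            desired_direction %in% 1:4)
  steps <- list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  pos <- c(x = 0, y = 0)
  n <- min(length(predictions), max_flashes)
  flash_count <- 0L
  terminated <- "running"
  reached <- NA_integer_
  for (k in seq_len(n)) {
    flash_count <- k
    if (predictions[k] == "target") {
      pos <- pos + steps[[directions[k]]]
      if (any(abs(pos) >= 4)) {
        reached <- if (abs(pos[2]) >= 4) {
          if (pos[2] > 0) 1L else 3L
        } else {
          if (pos[1] > 0) 2L else 4L
        }
        terminated <- "reached"
        break
      }
    }
  }
  if (terminated == "running" && flash_count >= max_flashes) terminated <- "timeout"
  structure(list(position = pos, flash_count = flash_count,
                 terminated = terminated, reached_direction = reached,
                 success = identical(reached, as.integer(desired_direction))),
            class = "session_state")
}

#' @export
print.session_state <- function(x, ...) {
  cat("<session_state>", x$terminated, "after", x$flash_count, "flashes;",
      "position (", x$position[1], ",", x$position[2], ")\n")
  invisible(x)
}
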