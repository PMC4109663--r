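#' Default RBF-SVM hyperparameter grid
#'
#' Powers of four: cost `C` in `4^(-2..6)`, kernel width (the RBF `gamma`
#' coefficient) in `4^(-7..1)`.
#'
#' @return Tibble with columns `C` and `width`, ordered by `C` then
#'   `width` (the tie-break order of [select_hyperparameters()]).
#' @export
default_svm_grid <- function() {
  tidyr::expand_grid(C = 4^(-2:6), width = 4^(-7:1)) |>
    dplyr::arrange(.data$C, .data$width)
}

feature_matrix <- function(features) {
  nm <- feature_names()
  if (!all(nm %in% names(features))) {
    stop("feature tibble must contain all 78 feature columns", call. = FALSE)
  }
  as.matrix(features[, nm])
}

# inverse-frequency class weights countering the 3:1 nontarget:target
# imbalance of the 4-arrow paradigm
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

stratified_split <- function(y, fraction) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(fraction * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1L)  # keep at least one validation case
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

fit_svm <- function(x, y, C, width, weights) {
  e1071::svm(x = x, y = y, kernel = "radial", cost = C, gamma = width,
             class.weights = weights, scale = FALSE)
}

#' Select SVM hyperparameters by repeated 80/20 splits
#'
#' For every grid point the mean validation accuracy over `n_splits`
#' stratified random splits of the calibration data (80% train / 20%
#' validation by default) is computed; the argmax is returned, ties broken
#' towards the smallest cost and then the smallest kernel width.
#'
#' @param features Standardized feature tibble (78 feature columns).
#' @param labels Character/factor vector, `"target"`/`"nontarget"`; both
#'   classes must be present.
#' @param grid Hyperparameter grid tibble (`C`, `width`).
#' @param n_splits Number of repeated splits (default 20).
#' @param split_fraction Training fraction of each split (default 0.8).
#' @param seed Optional integer seed; identical seeds give identical
#'   selections.
#' @return List with `C`, `width` and the `cv_report` tibble (per-point
#'   mean validation accuracy).
#' @export
select_hyperparameters <- function(features, labels, grid = default_svm_grid(),
                                   n_splits = 20, split_fraction = 0.8,
                                   seed = NULL) {
  y <- factor(labels, levels = c("nontarget", "target"))
  if (dplyr::n_distinct(y) < 2) {
    stop("both classes must be present in the calibration labels", call. = FALSE)
  }
  x <- feature_matrix(features)
  weights <- balanced_weights(y)
  with_seed_if(seed, {
    splits <- purrr::map(seq_len(n_splits), ~ stratified_split(y, split_fraction))
    acc <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
      mean(purrr::map_dbl(splits, function(tr) {
        fit <- fit_svm(x[tr, , drop = FALSE], y[tr], grid$C[i], grid$width[i], weights)
        mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }))
    })
    report <- dplyr::mutate(grid, mean_val_accuracy = acc)
    best <- which.max(acc)  # grid ordered by C then width -> tie-break built in
    list(C = grid$C[best], width = grid$width[best], cv_report = report)
  })
}

#' Train the target/nontarget SVM
#'
#' Fits an RBF-kernel SVM with inverse-class-frequency weights on
#' standardized calibration features. If every training row is identical
#' (degenerate features) the classifier falls back to always predicting
#' the majority class.
#'
#' @param features Feature tibble (raw scale).
#' @param labels `"target"`/`"nontarget"` per row.
#' @param C Cost parameter (> 0).
#' @param width RBF kernel width (> 0).
#' @param training_stats Optional [feature_stats()] tibble; computed from
#'   `features` when `NULL`. Stored in the model and applied to all inputs
#'   (train here, test at prediction time).
#' @param cv_report Optional report from [select_hyperparameters()], kept
#'   for inspection via [tidy()].
#' @return Object of class `p300_classifier`.
#' @export
train_classifier <- function(features, labels, C, width,
                             training_stats = NULL, cv_report = NULL) {
  stopifnot(C > 0, width > 0)
  y <- factor(labels, levels = c("nontarget", "target"))
  if (is.null(training_stats)) training_stats <- feature_stats(features)
  x <- feature_matrix(standardize_features(features, training_stats))
  weights <- balanced_weights(y)
  degenerate <- nrow(unique(x)) == 1L
  fit <- if (degenerate) NULL else fit_svm(x, y, C, width, weights)
  structure(list(fit = fit, C = C, width = width, class_weights = weights,
                 training_stats = training_stats, cv_report = cv_report,
                 majority = names(which.max(table(y))), degenerate = degenerate),
            class = "p300_classifier")
}

#' Predict target/nontarget labels
#'
#' @param object A [train_classifier()] model.
#' @param features Feature tibble on the raw scale; standardized internally
#'   with the model's training statistics.
#' @param ... Unused.
#' @return Character vector of `"target"`/`"nontarget"`.
#' @export
predict.p300_classifier <- function(object, features, ...) {
  x <- feature_matrix(standardize_features(features, object$training_stats))
  if (object$degenerate) return(rep(object$majority, nrow(x)))
  as.character(predict(object$fit, x))
}

#' @export
print.p300_classifier <- function(x, ...) {
  cat("<p300_classifier> RBF SVM, C =", x$C, "width =", x$width,
      if (x$degenerate) "(degenerate: majority-class fallback)" else "", "\n")
  invisible(x)
}
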