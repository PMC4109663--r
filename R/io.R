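#' Write an epoch tibble as per-session CSV files with JSON sidecars
#'
#' Each (subject, day, session) combination becomes one long-format CSV
#' (`flash`, `phase` = pre/post, `sample`, `value`) plus a JSON sidecar
#' carrying the per-flash metadata (labels, directions, sampling rate), and
#' a top-level `manifest.json` lists all sessions. Values round-trip
#' losslessly (shortest round-trippable decimal representation).
#'
#' @param epochs Epoch tibble from [generate_study()] or
#'   [extract_epochs()] (with `subject_id`, `day`, `session` columns).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_sessions <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- dplyr::distinct(epochs, .data$subject_id, .data$day, .data$session)
  for (i in seq_len(nrow(keys))) {
    sub <- dplyr::filter(epochs,
                         .data$subject_id == keys$subject_id[i],
                         .data$day == keys$day[i],
                         .data$session == keys$session[i])
    stem <- sprintf("%s_%s_s%02d", keys$subject_id[i], keys$day[i], keys$session[i])
    long <- purrr::map_dfr(seq_len(nrow(sub)), function(k) {
      tibble::tibble(
        flash = sub$flash[k],
        phase = rep(c("pre", "post"), c(length(sub$pre[[k]]), length(sub$post[[k]]))),
        sample = c(seq_along(sub$pre[[k]]), seq_along(sub$post[[k]])),
        value = c(sub$pre[[k]], sub$post[[k]])
      )
    })
    readr::write_csv(long, file.path(dir, paste0(stem, ".csv")))
    meta <- list(
      subject_id = keys$subject_id[i], day = keys$day[i],
      session = keys$session[i], fs_hz = sub$fs_hz[1],
      flashes = dplyr::select(sub, dplyr::any_of(c(
        "flash", "block", "direction", "desired_direction", "label")))
    )
    jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- dplyr::mutate(keys, file = sprintf("%s_%s_s%02d.csv",
                                                 .data$subject_id, .data$day, .data$session))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read epochs written by [write_sessions()]
#'
#' @param dir Directory containing the session CSV/JSON files and
#'   `manifest.json`.
#' @return Epoch tibble equivalent to the one written.
#' @export
read_sessions <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    stem <- sub("\\.csv$", "", manifest$file[i])
    long <- readr::read_csv(file.path(dir, paste0(stem, ".csv")),
                            show_col_types = FALSE)
    meta <- jsonlite::fromJSON(file.path(dir, paste0(stem, ".json")))
    flashes <- tibble::as_tibble(meta$flashes)
    purrr::map_dfr(seq_len(nrow(flashes)), function(k) {
      fl <- long[long$flash == flashes$flash[k], ]
      dplyr::bind_cols(
        tibble::tibble(subject_id = meta$subject_id, day = meta$day,
                       session = meta$session),
        flashes[k, ],
        tibble::tibble(
          pre = list(fl$value[fl$phase == "pre"]),
          post = list(fl$value[fl$phase == "post"]),
          fs_hz = meta$fs_hz
        )
      )
    })
  })
}

#' Serialize an estimated single-trial ERP
#'
#' Writes the waveform as a two-column CSV (`sample`, `value`) and the
#' diagnostics (gamma, AR order, innovation variance, WRSS, convergence)
#' as JSON next to it.
#'
#' @param erp An `estimated_erp`.
#' @param stem File path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return Invisibly, `erp`.
#' @export
write_estimated_erp <- function(erp, stem) {
  stopifnot(inherits(erp, "estimated_erp"))
  readr::write_csv(
    tibble::tibble(sample = seq_along(erp$u_hat), value = erp$u_hat),
    paste0(stem, ".csv")
  )
  jsonlite::write_json(
    list(gamma = erp$gamma, p = if (is.null(erp$ar)) NA else erp$ar$p,
         sigma2 = if (is.null(erp$ar)) NA else erp$ar$sigma2,
         wrss = erp$wrss, converged = erp$converged),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(erp)
}
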