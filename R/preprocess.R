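#' Classify trial records
#'
#' Assigns each trial one of five exhaustive, mutually exclusive labels:
#' go trials become `go_miss` (no response), `go_error` (response with the
#' wrong name or a disfluency) or `go_correct`; stop trials become
#' `stop_fail` (response emitted despite the stop-signal) or `stop_success`.
#'
#' @param records Trial-record data.frame (see [simulate_experiment()] or
#'   [read_trial_log()]). Practice rows (`block == 0`) are dropped.
#' @return The records with an added `label` factor column.
#' @export
classify_trials <- function(records) {
  if ("block" %in% names(records))
    records <- records[records$block != 0L, , drop = FALSE]
  if (any(records$responded & is.na(records$rt_ms)))
    stop("malformed record: responded trial without an RT")
  if (any(!records$responded & !is.na(records$rt_ms)))
    stop("malformed record: RT present on a non-response trial")
  is_go <- records$trial_type == "go"
  clean <- records$responded &
    !is.na(records$name_correct) & records$name_correct &
    !is.na(records$disfluent) & !records$disfluent
  label <- ifelse(is_go,
                  ifelse(!records$responded, "go_miss",
                         ifelse(clean, "go_correct", "go_error")),
                  ifelse(records$responded, "stop_fail", "stop_success"))
  records$label <- factor(label, levels = c("go_correct", "go_error",
                                            "go_miss", "stop_success",
                                            "stop_fail"))
  records
}

#' Trim outliers by a standard-deviation criterion
#'
#' Removes values lying outside `mean +/- k * SD`, where mean and sample SD
#' (n - 1 denominator) are computed once from the full input (single pass,
#' non-iterative). Values exactly on a bound are retained. Intended to be
#' applied per participant and distractor condition upstream.
#'
#' @param rts Numeric vector of response latencies.
#' @param k Criterion in SD units, default 2.5.
#' @return A list: `retained` (values within bounds), `removed` (indices
#'   into `rts` of removed values), `warn` (`TRUE` when fewer than 2 values
#'   were supplied and the input was passed through untouched).
#' @export
#' @examples
#' trim_outliers(c(rep(500, 9), 2000))$removed  # the 2000 ms value
trim_outliers <- function(rts, k = 2.5) {
  if (length(rts) < 2L)
    return(list(retained = rts, removed = integer(), warn = TRUE))
  m <- mean(rts)
  s <- stats::sd(rts)
  keep <- rts >= m - k * s & rts <= m + k * s
  list(retained = rts[keep], removed = which(!keep), warn = FALSE)
}

#' Summarise classified trials per participant and condition
#'
#' Produces the two standard summary tables of the task. The go summary
#' reports, per participant and distractor condition, the mean and SD of
#' correct naming latencies after SD trimming ([trim_outliers()], applied
#' per participant and condition, collapsed over blocks), plus error and
#' miss percentages computed over all go trials. The stop summary reports,
#' per participant, stop-signal delay and condition, the proportion of
#' failed inhibitions and the mean/SD of naming latencies on failed stop
#' trials. Cells with no eligible trials are flagged, never silently zero.
#'
#' @param classified Output of [classify_trials()].
#' @param k_trim Trimming criterion in SD units; `Inf` disables trimming.
#' @return A list of class `sst_summary` with data.frames `go_summary`
#'   (`participant`, `condition`, `n_go`, `n_correct`, `n_trimmed`,
#'   `mean_rt`, `sd_rt`, `error_pct`, `miss_pct`, `flag`) and `stop_summary`
#'   (`participant`, `ssd_ms`, `condition`, `n_stop`, `n_failed`,
#'   `p_failed`, `mean_failed_rt`, `sd_failed_rt`, `flag`).
#' @export
summarize_trials <- function(classified, k_trim = 2.5) {
  go <- classified[classified$trial_type == "go", , drop = FALSE]
  go_cells <- split(go, list(go$participant, go$condition), drop = TRUE)
  go_summary <- do.call(rbind, lapply(go_cells, function(cell) {
    rts <- cell$rt_ms[cell$label == "go_correct"]
    tr <- if (is.finite(k_trim)) trim_outliers(rts, k_trim) else
      list(retained = rts, removed = integer(), warn = FALSE)
    kept <- tr$retained
    data.frame(
      participant = cell$participant[1],
      condition = cell$condition[1],
      n_go = nrow(cell),
      n_correct = length(rts),
      n_trimmed = length(tr$removed),
      mean_rt = if (length(kept)) mean(kept) else NA_real_,
      sd_rt = if (length(kept) > 1L) stats::sd(kept) else NA_real_,
      error_pct = 100 * mean(cell$label == "go_error"),
      miss_pct = 100 * mean(cell$label == "go_miss"),
      flag = length(kept) == 0L,
      stringsAsFactors = FALSE)
  }))

  st <- classified[classified$trial_type == "stop", , drop = FALSE]
  st_cells <- split(st, list(st$participant, st$ssd_ms, st$condition),
                    drop = TRUE)
  stop_summary <- do.call(rbind, lapply(st_cells, function(cell) {
    failed <- cell$rt_ms[cell$label == "stop_fail"]
    data.frame(
      participant = cell$participant[1],
      ssd_ms = cell$ssd_ms[1],
      condition = cell$condition[1],
      n_stop = nrow(cell),
      n_failed = length(failed),
      p_failed = length(failed) / nrow(cell),
      mean_failed_rt = if (length(failed)) mean(failed) else NA_real_,
      sd_failed_rt = if (length(failed) > 1L) stats::sd(failed) else
        NA_real_,
      flag = nrow(cell) == 0L | length(failed) == 0L,
      stringsAsFactors = FALSE)
  }))
  rownames(go_summary) <- rownames(stop_summary) <- NULL
  structure(list(go_summary = go_summary, stop_summary = stop_summary),
            class = "sst_summary")
}

#' @export
print.sst_summary <- function(x, ...) {
  cat("go trials (per participant x condition):\n")
  print(utils::head(x$go_summary, 10), row.names = FALSE)
  if (nrow(x$go_summary) > 10) cat("  ...", nrow(x$go_summary), "rows\n")
  cat("stop trials (per participant x SSD x condition):\n")
  print(utils::head(x$stop_summary, 10), row.names = FALSE)
  if (nrow(x$stop_summary) > 10) cat("  ...", nrow(x$stop_summary), "rows\n")
  invisible(x)
}

#' Write / read a trial-log CSV
#'
#' Trial logs use the header `participant,block,position,picture,condition,`
#' `trial_type,ssd_ms,responded,rt_ms,name_correct,disfluent`, with empty
#' fields for absent values (`ssd_ms` on go trials; `rt_ms`, `name_correct`
#' and `disfluent` on trials without a response).
#'
#' @param records Trial-record data.frame.
#' @param path File path.
#' @return `read_trial_log` returns the records data.frame with proper
#'   column types.
#' @export
write_trial_log <- function(records, path) {
  cols <- c("participant", "block", "position", "picture", "condition",
            "trial_type", "ssd_ms", "responded", "rt_ms", "name_correct",
            "disfluent")
  utils::write.csv(records[, cols], path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant = "character"))
  rec$ssd_ms <- suppressWarnings(as.integer(rec$ssd_ms))
  rec$responded <- as.logical(rec$responded)
  rec$name_correct <- as.logical(rec$name_correct)
  rec$disfluent <- as.logical(rec$disfluent)
  rec
}
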