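#' Probability of responding given a stop-signal
#'
#' Counts, within one participant x delay x condition cell, the proportion
#' of stop trials on which a response was emitted despite the stop-signal.
#' Pooled over blocks.
#'
#' @param classified Output of [classify_trials()].
#' @param participant,ssd_ms,condition Cell selectors.
#' @return A list: `p` (proportion, `NA` when the cell is empty),
#'   `n_stop`, `n_respond`, `flag` (`TRUE` for an empty cell).
#' @export
p_respond <- function(classified, participant, ssd_ms, condition) {
  cell <- classified[classified$trial_type == "stop" &
                       classified$participant == participant &
                       !is.na(classified$ssd_ms) &
                       classified$ssd_ms == ssd_ms &
                       classified$condition == condition, , drop = FALSE]
  n <- nrow(cell)
  r <- sum(cell$label == "stop_fail")
  list(p = if (n > 0L) r / n else NA_real_,
       n_stop = n, n_respond = r, flag = n == 0L)
}

round_half_up <- function(x) floor(x + 0.5)

#' Stop-signal RT by the integration method
#'
#' Implements the integration method of the independent horse-race model
#' for fixed stop-signal delays. The go-RT distribution is rank ordered;
#' the finishing time of the stop process is read off at the nth go RT,
#' where `n = round(N * p)` (round half up, clamped to `[1, N]`), `N` the
#' number of go RTs and `p` the probability of responding given the
#' stop-signal at this delay. The estimate is `nth go RT - SSD`.
#'
#' With `p = 0` the stop process always wins and its finishing time is not
#' identified; the estimate is returned as `NA` with `flag = TRUE`.
#'
#' @param go_rts Go-trial naming latencies (ms), any order.
#' @param p Probability of responding given the stop-signal, in `[0, 1]`.
#' @param ssd_ms Stop-signal delay (ms).
#' @return A list: `n_go`, `p_respond`, `nth_index`, `nth_go_rt_ms`,
#'   `ssrt_ms`, `flag`.
#' @export
#' @examples
#' # go distribution with 50th-percentile RT 300 ms, p = 0.5, SSD 100 ms
#' ssrt_integration(seq(200, 400, by = 2), p = 0.5, ssd_ms = 100)$ssrt_ms
ssrt_integration <- function(go_rts, p, ssd_ms) {
  if (length(go_rts) == 0L) stop("go_rts must be non-empty")
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  n_go <- length(go_rts)
  if (p == 0) {
    return(list(n_go = n_go, p_respond = 0, nth_index = NA_integer_,
                nth_go_rt_ms = NA_real_, ssrt_ms = NA_real_, flag = TRUE))
  }
  sorted <- sort(go_rts, method = "radix")   # stable ascending order
  nth <- min(max(round_half_up(n_go * p), 1L), n_go)
  nth_rt <- sorted[nth]
  list(n_go = n_go, p_respond = p, nth_index = as.integer(nth),
       nth_go_rt_ms = nth_rt, ssrt_ms = nth_rt - ssd_ms, flag = FALSE)
}

#' Stop-signal RT by the mean method
#'
#' `mean(go RTs) - mean(SSD series)`; a valid estimator when the delay
#' series comes from one-up/one-down tracking holding the response rate
#' near 50% (see [simulate_tracking()]). For fixed delays prefer
#' [ssrt_integration()].
#'
#' @param go_rts Go-trial naming latencies (ms).
#' @param ssd_series Stop-signal delays over the tracking run (ms).
#' @return The estimate in ms.
#' @export
ssrt_mean <- function(go_rts, ssd_series) {
  if (length(go_rts) == 0L || length(ssd_series) == 0L)
    stop("go_rts and ssd_series must be non-empty")
  mean(go_rts) - mean(ssd_series)
}

#' Estimate SSRT per participant, delay and condition
#'
#' Applies [ssrt_integration()] to every participant x SSD x condition cell
#' of a classified cohort. The go-RT distribution entering each estimate is
#' the participant's correct go trials from the *matching* distractor
#' condition, pooled over blocks; by default untrimmed and without
#' imputation of missed responses. Cells without stop trials, without go
#' trials, or with `p = 0` are flagged and carry `NA` estimates.
#'
#' @param classified Output of [classify_trials()].
#' @param trim If `TRUE`, apply [trim_outliers()] (2.5 SD) to the go RTs
#'   before reading off the nth RT.
#' @param impute_misses If `TRUE`, score each missed go response as a
#'   latency at the response window maximum (`window_ms`).
#' @param window_ms Response window used for imputation (default 1250).
#' @return A data.frame with one row per cell: `participant`, `ssd_ms`,
#'   `condition`, `n_go`, `n_stop`, `n_respond`, `p_respond`, `nth_index`,
#'   `nth_go_rt_ms`, `ssrt_ms`, `flag`.
#' @export
estimate_table <- function(classified, trim = FALSE, impute_misses = FALSE,
                           window_ms = 1250) {
  stops <- classified[classified$trial_type == "stop", , drop = FALSE]
  cells <- unique(stops[, c("participant", "ssd_ms", "condition")])
  cells <- cells[order(cells$participant, cells$ssd_ms, cells$condition), ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pt <- cells$participant[i]; ssd <- cells$ssd_ms[i]
    cond <- cells$condition[i]
    go <- classified[classified$trial_type == "go" &
                       classified$participant == pt &
                       classified$condition == cond, , drop = FALSE]
    rts <- go$rt_ms[go$label == "go_correct"]
    if (trim) rts <- trim_outliers(rts)$retained
    if (impute_misses) rts <- c(rts, rep(window_ms,
                                         sum(go$label == "go_miss")))
    pr <- p_respond(classified, pt, ssd, cond)
    base <- data.frame(participant = pt, ssd_ms = ssd, condition = cond,
                       n_go = length(rts), n_stop = pr$n_stop,
                       n_respond = pr$n_respond, stringsAsFactors = FALSE)
    if (pr$flag || length(rts) == 0L || pr$p == 0) {
      cbind(base, data.frame(p_respond = if (pr$flag) NA_real_ else pr$p,
                             nth_index = NA_integer_,
                             nth_go_rt_ms = NA_real_, ssrt_ms = NA_real_,
                             flag = TRUE))
    } else {
      est <- ssrt_integration(rts, pr$p, ssd)
      cbind(base, data.frame(p_respond = est$p_respond,
                             nth_index = est$nth_index,
                             nth_go_rt_ms = est$nth_go_rt_ms,
                             ssrt_ms = est$ssrt_ms, flag = est$flag))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
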