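#' Ex-Gaussian random deviates
#'
#' Samples from the convolution of a normal and an exponential distribution,
#' the standard positively skewed model for response-time data. `tau = 0`
#' drops the exponential component; `sigma = 0` with `tau = 0` yields the
#' constant `mu`, which is the constant-latency mode used in analytic tests.
#'
#' @param n Number of deviates.
#' @param mu,sigma Mean and SD of the normal component (ms).
#' @param tau Mean of the exponential component (ms).
#' @return Numeric vector of length `n`. Mean is `mu + tau`, SD is
#'   `sqrt(sigma^2 + tau^2)`.
#' @export
rexgauss <- function(n, mu, sigma = 0, tau = 0) {
  if (any(sigma < 0) || any(tau < 0)) stop("sigma and tau must be >= 0")
  out <- stats::rnorm(n, mu, sigma)
  pos <- tau > 0
  if (length(tau) == 1L) {
    if (pos) out <- out + stats::rexp(n, 1 / tau)
  } else {
    out[pos] <- out[pos] + stats::rexp(sum(pos), 1 / tau[pos])
  }
  out
}

#' Shorthand for an ex-Gaussian parameter triple
#'
#' @param mu,sigma,tau Parameters in ms (see [rexgauss()]).
#' @return Named numeric vector `c(mu, sigma, tau)`.
#' @export
exg <- function(mu, sigma = 0, tau = 0) {
  c(mu = mu, sigma = sigma, tau = tau)
}

#' Parameters of the independent horse-race model
#'
#' Bundles the per-condition latency distributions of the go process
#' (picture naming) and the stop process, the post-race contamination
#' probabilities, and the response window. Latencies are ex-Gaussian; pass
#' `sigma = 0, tau = 0` for a constant latency. The go and stop processes
#' are contextually and stochastically independent by construction: the
#' response is emitted iff the go finishing time beats `SSD + stop latency`.
#'
#' @param go Named list with elements `related` and `unrelated`, each a
#'   vector `c(mu, sigma, tau)` in ms (see [rexgauss()]).
#' @param stop Same structure for the stop process.
#' @param p_omission Probability that the go process never produces an
#'   overt response (applies to go and stop trials alike).
#' @param p_name_error Probability that an emitted response uses the wrong
#'   picture name.
#' @param p_disfluency Probability that an emitted response is disfluent
#'   (repair, stutter, filler word).
#' @param response_window_ms Maximum picture display time; go finishes
#'   beyond it produce no observable response (default 1250 ms).
#' @return A list of class `race_params`.
#' @export
#' @examples
#' race_params(go = list(related = exg(630, 55, 95),
#'                       unrelated = exg(615, 55, 95)),
#'             stop = list(related = exg(355, 20, 30),
#'                         unrelated = exg(335, 20, 30)))
race_params <- function(go, stop,
                        p_omission = 0, p_name_error = 0,
                        p_disfluency = 0, response_window_ms = 1250) {
  for (side in list(go, stop)) {
    if (!all(c("related", "unrelated") %in% names(side)))
      stop("go and stop must name 'related' and 'unrelated' distributions")
    for (d in side[c("related", "unrelated")]) {
      if (length(d) != 3L || any(d[2:3] < 0))
        stop("each distribution is c(mu, sigma, tau) with sigma, tau >= 0")
    }
  }
  probs <- c(p_omission, p_name_error, p_disfluency)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (response_window_ms <= 0) stop("response_window_ms must be positive")
  structure(list(go = go, stop = stop, p_omission = p_omission,
                 p_name_error = p_name_error, p_disfluency = p_disfluency,
                 response_window_ms = response_window_ms),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  fmt <- function(d) sprintf("mu=%g sigma=%g tau=%g (mean %g ms)",
                             d[1], d[2], d[3], d[1] + d[3])
  cat("independent horse-race model parameters\n")
  for (cond in c("unrelated", "related")) {
    cat(sprintf("  go   %-9s %s\n", cond, fmt(x$go[[cond]])))
    cat(sprintf("  stop %-9s %s\n", cond, fmt(x$stop[[cond]])))
  }
  cat(sprintf("  p(omission)=%g  p(name error)=%g  p(disfluency)=%g\n",
              x$p_omission, x$p_name_error, x$p_disfluency))
  cat(sprintf("  response window %g ms\n", x$response_window_ms))
  invisible(x)
}

param_vec <- function(params, side, condition, field) {
  vapply(condition, function(cc) params[[side]][[cc]][[field]], 0)
}

# Core sampler: consumes the current RNG stream. Draw order is fixed
# (go latency, stop latency, omission, name error, disfluency) so results
# are reproducible from a single upstream set.seed().
simulate_records <- function(schedule, params) {
  n <- nrow(schedule)
  cond <- schedule$condition
  go_finish <- rexgauss(n,
                        param_vec(params, "go", cond, "mu"),
                        param_vec(params, "go", cond, "sigma"),
                        param_vec(params, "go", cond, "tau"))
  stop_finish <- rexgauss(n,
                          param_vec(params, "stop", cond, "mu"),
                          param_vec(params, "stop", cond, "sigma"),
                          param_vec(params, "stop", cond, "tau"))
  omitted <- stats::runif(n) < params$p_omission
  err <- stats::runif(n) < params$p_name_error
  disf <- stats::runif(n) < params$p_disfluency

  is_stop <- schedule$trial_type == "stop"
  go_wins <- rep(TRUE, n)
  go_wins[is_stop] <- go_finish[is_stop] <
    schedule$ssd_ms[is_stop] + stop_finish[is_stop]
  responded <- !omitted & go_wins & go_finish <= params$response_window_ms &
    go_finish > 0

  rec <- schedule
  rec$responded <- responded
  rec$rt_ms <- ifelse(responded, round(go_finish, 1), NA_real_)
  rec$name_correct <- ifelse(responded, !err, NA)
  rec$disfluent <- ifelse(responded, disf, NA)
  rec
}

#' Simulate a single trial
#'
#' Runs one race between the go and the stop process for a schedule entry,
#' using the current RNG stream. On go trials the response is emitted at the
#' sampled go finishing time unless it is omitted or exceeds the response
#' window. On stop trials the response is emitted iff the go finishing time
#' beats `SSD + stop finishing time`; a winning go finish beyond the window
#' is unobservable and counts as a successful stop.
#'
#' @param entry One schedule row (see [build_design()]).
#' @param params A [race_params()] object.
#' @return A one-row trial-record data.frame with added columns
#'   `responded`, `rt_ms`, `name_correct`, `disfluent`.
#' @export
run_trial <- function(entry, params) {
  if (nrow(entry) != 1L) stop("entry must be a single schedule row")
  simulate_records(entry, params)
}

#' Simulate a full experiment
#'
#' Vectorized wrapper of [run_trial()]: one trial record per schedule entry,
#' fully reproducible from `seed`.
#'
#' @param schedule Schedule data.frame.
#' @param params A [race_params()] object.
#' @param seed Integer seed.
#' @return Trial-record data.frame, one row per schedule row.
#' @export
simulate_experiment <- function(schedule, params, seed) {
  set.seed(seed)
  simulate_records(schedule, params)
}

#' Simulate one-up/one-down SSD tracking
#'
#' Runs a staircase of stop trials in which the stop-signal delay increases
#' by `step_ms` after every successful inhibition and decreases by `step_ms`
#' after every failed inhibition (floored at 0 ms), converging on a 50%
#' response rate. This is the dynamic alternative to the fixed-delay design;
#' its output feeds the mean method ([ssrt_mean()]).
#'
#' @param params A [race_params()] object.
#' @param initial_ssd_ms Starting delay (ms).
#' @param step_ms Staircase step, default 50 ms.
#' @param n_stop_trials Number of stop trials to run.
#' @param condition Distractor condition whose distributions drive the race.
#' @param seed Optional seed; `NULL` continues the current stream.
#' @return A data.frame with columns `trial`, `ssd_ms` (delay in force on
#'   that trial) and `responded`.
#' @export
simulate_tracking <- function(params, initial_ssd_ms, step_ms = 50L,
                              n_stop_trials, condition = "unrelated",
                              seed = NULL) {
  if (step_ms <= 0) stop("step_ms must be positive")
  if (!is.null(seed)) set.seed(seed)
  g <- params$go[[condition]]
  s <- params$stop[[condition]]
  go_finish <- rexgauss(n_stop_trials, g[1], g[2], g[3])
  stop_finish <- rexgauss(n_stop_trials, s[1], s[2], s[3])
  omitted <- stats::runif(n_stop_trials) < params$p_omission
  ssd <- numeric(n_stop_trials)
  responded <- logical(n_stop_trials)
  cur <- initial_ssd_ms
  for (i in seq_len(n_stop_trials)) {
    ssd[i] <- cur
    responded[i] <- !omitted[i] && go_finish[i] < cur + stop_finish[i] &&
      go_finish[i] <= params$response_window_ms
    cur <- max(0, cur + if (responded[i]) -step_ms else step_ms)
  }
  data.frame(trial = seq_len(n_stop_trials), ssd_ms = ssd,
             responded = responded)
}
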