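#' Calibrated default race-model parameters
#'
#' Returns the parameter set used by [generate_cohort()], calibrated once
#' against published group summaries of the picture-word interference
#' stop-signal task: trimmed correct go means near 700 ms (unrelated) and
#' 715 ms (related, a +15 ms semantic interference shift), a between-subject
#' go SD near 110 ms, an overall failed-inhibition rate near 34% across the
#' two fixed delays (250/325 ms), a +20 ms stop-latency shift in the related
#' condition, ~2.8% go errors and ~0.6% omissions. Ground truth for
#' recovery tests is always the injected parameter values, never the
#' published empirical cells.
#'
#' @return A list: `params` (a [race_params()] object), `go_shift_ms` (15),
#'   `stop_shift_ms` (20), `between_go_sd` (40), `between_stop_sd` (25).
#' @export
default_parameters <- function() {
  params <- race_params(
    go = list(unrelated = exg(615, 55, 95),
              related = exg(630, 55, 95)),
    stop = list(unrelated = exg(335, 20, 30),
                related = exg(355, 20, 30)),
    p_omission = 0.006,
    p_name_error = 0.02,
    p_disfluency = 0.008,
    response_window_ms = 1250
  )
  list(params = params, go_shift_ms = 15, stop_shift_ms = 20,
       between_go_sd = 40, between_stop_sd = 25)
}

shift_params <- function(params, go_off, stop_off) {
  for (cond in c("related", "unrelated")) {
    params$go[[cond]]["mu"] <- params$go[[cond]]["mu"] + go_off
    params$stop[[cond]]["mu"] <- params$stop[[cond]]["mu"] + stop_off
  }
  params
}

#' Generate a synthetic cohort
#'
#' Builds a counterbalanced schedule per participant ([build_design()],
#' alternating the two complementary delay assignments across participants),
#' simulates it under the independent horse-race model with
#' participant-level normal offsets on the go and stop means (SD 40 and
#' 25 ms), and optionally writes one trial-log CSV per participant plus a
#' `ground_truth.json` sidecar recording every injected parameter. Output
#' is fully deterministic given `seed`; the same seed yields byte-identical
#' files.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Master integer seed.
#' @param out Optional output directory (created if needed); when `NULL`
#'   nothing is written.
#' @param defaults Parameter bundle as returned by [default_parameters()].
#' @param stimuli Stimulus set; defaults to the packaged synthetic set.
#' @return Invisibly, a list: `records` (all trial records, row-bound),
#'   `truth` (parameters, shifts, per-participant offsets and seeds),
#'   `files` (paths written, or `NULL`).
#' @export
generate_cohort <- function(n_participants, seed, out = NULL,
                            defaults = default_parameters(),
                            stimuli = read_stimuli()) {
  if (n_participants < 1L) stop("n_participants must be >= 1")
  set.seed(seed)
  asg <- counterbalance_assignments(stimuli, seed = seed)
  go_off <- stats::rnorm(n_participants, 0, defaults$between_go_sd)
  stop_off <- stats::rnorm(n_participants, 0, defaults$between_stop_sd)
  design_seeds <- sample.int(2^20, n_participants)
  sim_seeds <- sample.int(2^20, n_participants)

  ids <- sprintf("p%02d", seq_len(n_participants))
  all_rec <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    a <- if (i %% 2L == 1L) asg$A else asg$B
    sched <- build_design(stimuli, a, seed = design_seeds[i],
                          participant_id = ids[i])
    p_i <- shift_params(defaults$params, go_off[i], stop_off[i])
    all_rec[[i]] <- simulate_experiment(sched, p_i, seed = sim_seeds[i])
  }

  truth <- list(
    seed = seed,
    params = list(go = lapply(defaults$params$go, as.list),
                  stop = lapply(defaults$params$stop, as.list),
                  p_omission = defaults$params$p_omission,
                  p_name_error = defaults$params$p_name_error,
                  p_disfluency = defaults$params$p_disfluency,
                  response_window_ms = defaults$params$response_window_ms),
    go_shift_ms = defaults$go_shift_ms,
    stop_shift_ms = defaults$stop_shift_ms,
    between_go_sd = defaults$between_go_sd,
    between_stop_sd = defaults$between_stop_sd,
    participants = data.frame(participant = ids, go_offset = go_off,
                              stop_offset = stop_off,
                              design_seed = design_seeds,
                              sim_seed = sim_seeds,
                              assignment = ifelse(seq_len(n_participants)
                                                  %% 2L == 1L, "A", "B"),
                              stringsAsFactors = FALSE)
  )

  files <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out)) stop("cannot create output directory: ", out)
    files <- character(0)
    for (i in seq_len(n_participants)) {
      f <- file.path(out, paste0("trial_log_", ids[i], ".csv"))
      write_trial_log(all_rec[[i]], f)
      files <- c(files, f)
    }
    gt <- file.path(out, "ground_truth.json")
    jsonlite::write_json(truth, gt, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
    files <- c(files, gt)
  }
  invisible(list(records = do.call(rbind, all_rec), truth = truth,
                 files = files))
}

#' Read back a ground-truth sidecar
#'
#' @param path Path to a `ground_truth.json` written by [generate_cohort()].
#' @return The ground-truth list; `params` is restored as a `race_params`
#'   object.
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- truth$params
  truth$params <- race_params(
    go = lapply(p$go, unlist), stop = lapply(p$stop, unlist),
    p_omission = p$p_omission, p_name_error = p$p_name_error,
    p_disfluency = p$p_disfluency,
    response_window_ms = p$response_window_ms)
  truth
}
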