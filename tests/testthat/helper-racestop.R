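# shared fixtures, built in code at test time

fixture_stimuli <- function() read_stimuli()

# tiny stimulus lookup for toy blocks: n items, alternating categories and
# onsets so adjacency constraints are satisfiable
toy_stimuli <- function(n, categories = NULL, onsets = NULL) {
  data.frame(
    picture = paste0("pic", seq_len(n)),
    category = if (is.null(categories)) paste0("cat", seq_len(n)) else
      categories,
    onset = if (is.null(onsets)) letters[(seq_len(n) - 1L) %% 26L + 1L] else
      onsets,
    related_distractor = paste0("rel", seq_len(n)),
    unrelated_distractor = paste0("unrel", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

toy_block <- function(stim, trial_type = "go", ssd = NA_integer_) {
  n <- nrow(stim)
  data.frame(
    participant = "t01", block = 1L, position = seq_len(2L * n),
    picture = rep(stim$picture, 2L),
    condition = rep(c("related", "unrelated"), each = n),
    trial_type = trial_type,
    ssd_ms = ssd,
    stringsAsFactors = FALSE
  )
}

# constant-latency parameters for analytic race checks
const_params <- function(go = 600, stop = 200, window = 1250,
                         p_omission = 0, p_name_error = 0,
                         p_disfluency = 0) {
  race_params(
    go = list(related = exg(go), unrelated = exg(go)),
    stop = list(related = exg(stop), unrelated = exg(stop)),
    p_omission = p_omission, p_name_error = p_name_error,
    p_disfluency = p_disfluency, response_window_ms = window
  )
}

# minimal hand-built trial records
make_record <- function(trial_type, responded, rt = NA_real_,
                        name_correct = NA, disfluent = NA,
                        condition = "related", ssd = NA_integer_,
                        participant = "p01") {
  data.frame(participant = participant, block = 1L, position = 1L,
             picture = "been", condition = condition,
             trial_type = trial_type, ssd_ms = ssd, responded = responded,
             rt_ms = rt, name_correct = name_correct, disfluent = disfluent,
             stringsAsFactors = FALSE)
}

# schedule of n_go go + n_stop stop trials in one condition, for direct
# simulator runs that bypass the full factorial design
flat_schedule <- function(n_go, n_stop, condition = "unrelated",
                          ssd = 250L, participant = "p01") {
  n <- n_go + n_stop
  data.frame(participant = participant, block = 1L, position = seq_len(n),
             picture = "been", condition = condition,
             trial_type = rep(c("go", "stop"), c(n_go, n_stop)),
             ssd_ms = c(rep(NA_integer_, n_go), rep(ssd, n_stop)),
             stringsAsFactors = FALSE)
}
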