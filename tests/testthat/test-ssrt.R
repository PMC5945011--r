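test_that("integration method reproduces the worked fixed-delay example", {
  # 50th-percentile go RT 300 ms, p(respond|signal) = 0.5, SSD 100 ms
  grid <- seq(200, 400, by = 2)   # odd length, symmetric around 300
  est <- ssrt_integration(grid, p = 0.5, ssd_ms = 100)
  expect_equal(est$ssrt_ms, 200)
  expect_equal(est$nth_go_rt_ms, 300)
  # order-invariant
  expect_equal(ssrt_integration(rev(grid), 0.5, 100)$ssrt_ms, 200)
})

test_that("nth-rank rule: round half up, clamped to [1, N]", {
  est <- ssrt_integration(c(500, 520, 540, 560, 580), p = 0.4,
                          ssd_ms = 250)
  expect_equal(est$nth_index, 2L)         # 5 * 0.4 = 2
  expect_equal(est$nth_go_rt_ms, 520)
  expect_equal(est$ssrt_ms, 270)

  # 5 * 0.5 = 2.5 rounds up to 3
  expect_equal(ssrt_integration(c(500, 520, 540, 560, 580), 0.5,
                                0)$nth_index, 3L)
  # clamp: tiny p maps to the fastest go RT, p = 1 to the slowest
  expect_equal(ssrt_integration(c(510, 410, 610), 0.01, 0)$nth_go_rt_ms,
               410)
  expect_equal(ssrt_integration(c(510, 410, 610), 1, 0)$nth_go_rt_ms, 610)
})

test_that("degenerate inputs are flagged or rejected", {
  for (p in c(0.2, 0.7, 1)) {
    expect_equal(ssrt_integration(rep(640, 8), p, 250)$ssrt_ms, 390)
  }
  und <- ssrt_integration(c(500, 600), p = 0, ssd_ms = 250)
  expect_true(und$flag)
  expect_true(is.na(und$ssrt_ms))
  expect_error(ssrt_integration(numeric(0), 0.5, 250), "non-empty")
  expect_error(ssrt_integration(c(500), 1.2, 250), "\\[0, 1\\]")
})

test_that("shift equivariance holds for arbitrary samples", {
  set.seed(99)
  for (i in 1:10) {
    rts <- rexgauss(sample(20:200, 1), 600, 50, 80)
    p <- runif(1, 0.05, 1)
    ssd <- sample(c(250, 325), 1)
    base <- ssrt_integration(rts, p, ssd)$ssrt_ms
    expect_equal(ssrt_integration(rts + 37, p, ssd)$ssrt_ms, base + 37)
    expect_equal(ssrt_integration(rts, p, ssd + 25)$ssrt_ms, base - 25)
  }
})

test_that("p_respond counts the cell, pooled over blocks", {
  rec <- do.call(rbind, c(
    replicate(4, make_record("stop", TRUE, 450, TRUE, FALSE, ssd = 250L),
              simplify = FALSE),
    replicate(6, make_record("stop", FALSE, ssd = 250L), simplify = FALSE)))
  rec$block <- rep(1:2, 5)
  rec$position <- seq_len(nrow(rec))
  cls <- classify_trials(rec)
  pr <- p_respond(cls, "p01", 250, "related")
  expect_equal(pr$p, 0.4)
  expect_equal(pr$n_stop, 10L)
  empty <- p_respond(cls, "p01", 325, "related")
  expect_true(empty$flag)
  expect_true(is.na(empty$p))
})

test_that("mean method is the arithmetic identity and recovers tracking", {
  expect_equal(ssrt_mean(rep(700, 4), rep(325, 9)), 375)
  expect_equal(ssrt_mean(rep(640, 3), rep(240, 3)), 400)

  # tracking against a constant stop latency, symmetric go distribution:
  # estimate within +/-15 ms of truth at 500 stop trials
  truth <- 350
  sym <- race_params(
    go = list(related = exg(700, 100), unrelated = exg(700, 100)),
    stop = list(related = exg(truth), unrelated = exg(truth)))
  tr <- simulate_tracking(sym, initial_ssd_ms = 250, step_ms = 50,
                          n_stop_trials = 500, seed = 17)
  set.seed(18)
  go_rts <- rexgauss(5000, 700, 100)
  est <- ssrt_mean(go_rts, tr$ssd_ms[101:500])   # post burn-in delays
  expect_lt(abs(est - truth), 15)

  # skewed (calibrated) go distribution: the staircase hovers where
  # P(go < SSD + s) = 0.5, so mean(SSD) ~ median(go) - s and the estimate
  # overshoots truth by mean(go) - median(go); recovery holds once that
  # skew bias is accounted for
  skewed <- race_params(
    go = list(related = exg(615, 55, 95), unrelated = exg(615, 55, 95)),
    stop = list(related = exg(truth), unrelated = exg(truth)))
  tr2 <- simulate_tracking(skewed, initial_ssd_ms = 250, step_ms = 50,
                           n_stop_trials = 500, seed = 17)
  set.seed(18)
  go2 <- rexgauss(5000, 615, 55, 95)
  est2 <- ssrt_mean(go2, tr2$ssd_ms[101:500])
  skew_bias <- mean(go2) - median(go2)
  expect_gt(est2, truth)                       # biased upward under skew
  expect_lt(abs(est2 - skew_bias - truth), 15)
})

test_that("estimate_table is per cell and per condition", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  scheds <- lapply(1:3, function(i)
    build_design(stim, asg, seed = i, participant_id = paste0("s", i)))
  rec <- do.call(rbind, lapply(scheds, simulate_experiment,
                               params = default_parameters()$params,
                               seed = 55))
  est <- estimate_table(classify_trials(rec))
  expect_equal(nrow(est), 12L)   # 3 participants x 2 SSDs x 2 conditions
  expect_true(all(est$n_stop == 20L))
  ok <- !est$flag
  expect_equal(est$ssrt_ms[ok], est$nth_go_rt_ms[ok] - est$ssd_ms[ok])
  expect_true(all(est$nth_index[ok] >= 1 & est$nth_index[ok] <= est$n_go[ok]))
})

test_that("per-condition estimates differ from pooled-go estimates", {
  # go distributions differ sharply between conditions; using the matching
  # condition's distribution is the contract
  go_rel <- replicate(60, make_record("go", TRUE, 800, TRUE, FALSE,
                                      condition = "related"),
                      simplify = FALSE)
  go_unr <- replicate(60, make_record("go", TRUE, 500, TRUE, FALSE,
                                      condition = "unrelated"),
                      simplify = FALSE)
  st <- c(replicate(5, make_record("stop", TRUE, 450, TRUE, FALSE,
                                   condition = "related", ssd = 250L),
                    simplify = FALSE),
          replicate(5, make_record("stop", FALSE, condition = "related",
                                   ssd = 250L), simplify = FALSE))
  rec <- do.call(rbind, c(go_rel, go_unr, st))
  rec$position <- seq_len(nrow(rec))
  cls <- classify_trials(rec)
  est <- estimate_table(cls)
  rel <- est[est$condition == "related" & !est$flag, ]
  expect_equal(rel$ssrt_ms, 800 - 250)       # related go RTs only
  pooled <- ssrt_integration(cls$rt_ms[cls$label == "go_correct"], 0.5,
                             250)$ssrt_ms
  expect_false(isTRUE(all.equal(rel$ssrt_ms, pooled)))
})

test_that("integration recovery converges to a constant stop latency", {
  truth <- 300
  params <- race_params(
    go = list(related = exg(615, 55, 95), unrelated = exg(615, 55, 95)),
    stop = list(related = exg(truth), unrelated = exg(truth)))
  sched <- rbind(flat_schedule(5000, 0), flat_schedule(0, 2000, ssd = 250L))
  rec <- simulate_experiment(sched, params, seed = 41)
  est <- estimate_table(classify_trials(rec))
  got <- est$ssrt_ms[est$ssd_ms == 250 & est$condition == "unrelated"]
  expect_lt(abs(got - truth), 10)
})
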