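test_that("stimulus fixture has the documented structure", {
  stim <- fixture_stimuli()
  expect_equal(nrow(stim), 40L)
  been <- stim[stim$picture == "been", ]
  expect_equal(been$related_distractor, "arm")
  expect_equal(been$unrelated_distractor, "tafel")
  expect_silent(validate_stimuli(stim))

  bad <- stim
  bad$unrelated_distractor[2] <- bad$related_distractor[2]
  expect_error(validate_stimuli(bad), "identical")
})

test_that("build_design reproduces the factorial structure", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  sched <- build_design(stim, asg, seed = 1)

  expect_equal(nrow(sched), 320L)
  expect_equal(as.vector(table(sched$block)), rep(80L, 4L))
  for (b in 1:4) {
    blk <- sched[sched$block == b, ]
    expect_equal(sum(blk$trial_type == "go"), 60L)
    expect_equal(sum(blk$trial_type == "stop"), 20L)
    expect_equal(sum(blk$trial_type == "stop" &
                       blk$condition == "related"), 10L)
    expect_equal(sum(!is.na(blk$ssd_ms) & blk$ssd_ms == 250), 10L)
    expect_equal(sum(!is.na(blk$ssd_ms) & blk$ssd_ms == 325), 10L)
  }
  # 25% stop trials overall; SSD presence iff stop
  expect_equal(mean(sched$trial_type == "stop"), 0.25)
  expect_true(all(is.na(sched$ssd_ms) == (sched$trial_type == "go")))
  # every picture's stop SSD follows the counterbalance assignment
  stops <- sched[sched$trial_type == "stop", ]
  expect_true(all(stops$ssd_ms[stops$picture %in% asg$ssd250] == 250))
  expect_true(all(stops$ssd_ms[stops$picture %in% asg$ssd325] == 325))
  # each picture x condition is a stop trial exactly once across blocks
  expect_true(all(table(stops$picture, stops$condition) == 1L))
})

test_that("build_design rejects invalid inputs", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  expect_error(build_design(stim[1:39, ], asg, seed = 1), "40 stimuli")
  bad <- asg
  bad$ssd325[1] <- bad$ssd250[1]   # overlap, no longer a partition
  expect_error(build_design(stim, bad, seed = 1), "partition")
})

test_that("counterbalance assignments are complementary and seeded", {
  stim <- fixture_stimuli()
  cb <- counterbalance_assignments(stim, seed = 11)
  expect_setequal(c(cb$A$ssd250, cb$A$ssd325), stim$picture)
  expect_equal(cb$A$ssd250, cb$B$ssd325)
  expect_equal(counterbalance_assignments(stim, seed = 11)$A$ssd250,
               cb$A$ssd250)
})

test_that("randomize_block output is a constrained permutation", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  sched <- build_design(stim, asg, seed = 5)
  blk <- sched[sched$block == 2, ]
  out <- randomize_block(blk, stim, seed = 7)
  expect_setequal(paste(out$picture, out$condition),
                  paste(blk$picture, blk$condition))
  # constraints hold: no same-category/onset neighbours, runs <= 4
  catg <- stim$category[match(out$picture, stim$picture)]
  ons <- stim$onset[match(out$picture, stim$picture)]
  expect_false(any(catg[-1] == catg[-80]))
  expect_false(any(ons[-1] == ons[-80]))
  expect_lte(max(rle(out$condition)$lengths), 4L)
})

test_that("randomize_block fails explicitly on unsatisfiable input", {
  stim <- toy_stimuli(2, categories = c("same", "same"))
  ent <- data.frame(participant = "t", block = 1L, position = 1:2,
                    picture = stim$picture, condition = "related",
                    trial_type = "go", ssd_ms = NA_integer_)
  expect_error(randomize_block(ent, stim, seed = 1, max_attempts = 50),
               "50 attempts")
})

test_that("a satisfiable toy block succeeds within the attempt budget", {
  # 6 trials, all categories/onsets distinct: every order is category/onset
  # valid, only the condition run-length rule bites, so success is certain
  stim <- toy_stimuli(3)
  ent <- toy_block(stim)
  out <- randomize_block(ent, stim, seed = 42, max_attempts = 1000)
  expect_equal(nrow(out), 6L)
  expect_lte(max(rle(out$condition)$lengths), 4L)
})

test_that("validate_design pinpoints constructed violations", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  sched <- build_design(stim, asg, seed = 9)

  expect_true(validate_design(sched, stim, asg)$ok)

  # five consecutive related trials -> one run-length violation located
  tampered <- sched
  blk1 <- which(tampered$block == 1)
  ord <- c(blk1[tampered$condition[blk1] == "related"][1:5],
           setdiff(blk1, blk1[tampered$condition[blk1] == "related"][1:5]))
  tampered[blk1, ] <- tampered[ord, ]
  tampered$position[blk1] <- 1:80
  v <- validate_design(tampered, stim)
  runs <- v$violations[v$violations$type == "condition_run", ]
  expect_gte(nrow(runs), 1L)
  expect_equal(runs$position[1], 5L)

  # dropping a trial -> count violations
  v2 <- validate_design(sched[-1, ], stim)
  expect_false(v2$ok)
  expect_true("block_size" %in% v2$violations$type)
  expect_true("n_trials" %in% v2$violations$type)

  # unknown picture is an error, not a violation row
  alien <- sched
  alien$picture[1] <- "zeppelin"
  expect_error(validate_design(alien, stim), "unknown picture")
})

test_that("practice block is generated but excluded from analyses", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  sched <- build_design(stim, asg, seed = 2, practice = TRUE)
  prac <- sched[sched$block == 0, ]
  expect_equal(nrow(prac), 8L)
  expect_equal(sum(prac$trial_type == "stop"), 2L)
  expect_equal(as.vector(table(prac$condition)), c(4L, 4L))
  # validator and classifier ignore block 0
  expect_true(validate_design(sched, stim, asg)$ok)
  rec <- simulate_experiment(sched, const_params(), seed = 1)
  expect_equal(nrow(classify_trials(rec)), 320L)
})

test_that("schedule CSV round-trips", {
  stim <- fixture_stimuli()
  asg <- counterbalance_assignments(stim, seed = 3)$A
  sched <- build_design(stim, asg, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_equal(back$picture, sched$picture)
  expect_equal(back$ssd_ms, sched$ssd_ms)
})
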