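#' Counterbalance assignment of pictures to stop-signal delays
#'
#' Splits the 40 pictures into two disjoint sets of 20: pictures whose stop
#' trials occur at the early delay (250 ms) and pictures whose stop trials
#' occur at the late delay (325 ms). Two complementary assignments are
#' returned so that delay-to-picture mapping can be counterbalanced across
#' participants (odd-numbered participants receive `A`, even-numbered `B`).
#'
#' @param stimuli A stimulus set from [read_stimuli()].
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with elements `A` and `B`, each a `cb_assignment`: a list
#'   with character vectors `ssd250` and `ssd325` (20 pictures each).
#' @export
counterbalance_assignments <- function(stimuli, seed = 1L) {
  check_stimulus_count(stimuli)
  set.seed(seed)
  first <- sort(sample(stimuli$picture, nrow(stimuli) / 2))
  second <- sort(setdiff(stimuli$picture, first))
  a <- structure(list(ssd250 = first, ssd325 = second),
                 class = "cb_assignment")
  b <- structure(list(ssd250 = second, ssd325 = first),
                 class = "cb_assignment")
  list(A = a, B = b)
}

check_stimulus_count <- function(stimuli, n = 40L) {
  if (nrow(stimuli) != n)
    stop("expected exactly ", n, " stimuli, got ", nrow(stimuli))
  invisible(stimuli)
}

check_assignment <- function(assignment, stimuli) {
  pics <- stimuli$picture
  if (length(intersect(assignment$ssd250, assignment$ssd325)) > 0L ||
      !setequal(c(assignment$ssd250, assignment$ssd325), pics) ||
      length(assignment$ssd250) != length(pics) / 2)
    stop("assignment must partition the stimulus set into two equal halves")
  invisible(assignment)
}

#' Build the full counterbalanced trial schedule
#'
#' Constructs the 320-trial schedule of the picture-word interference
#' stop-signal task: 4 blocks of 80 trials, each block presenting all 40
#' pictures once with a semantically related and once with an unrelated
#' distractor. Per block, 60 trials are go trials (30 related, 30 unrelated)
#' and 20 are stop trials (10 related, 10 unrelated; each stop-signal delay
#' 10 times). Across the four blocks every picture-by-condition combination
#' is a stop trial exactly once, at the delay dictated by `assignment`.
#' Within-block order is pseudorandomized by [randomize_block()].
#'
#' @param stimuli 40-row stimulus set.
#' @param assignment A `cb_assignment` (see [counterbalance_assignments()]).
#' @param seed Integer seed controlling stop-slot allocation and ordering.
#' @param participant_id Identifier written into every schedule row.
#' @param max_attempts Reshuffle budget per block before failing.
#' @param practice If `TRUE`, prepend a practice block (`block = 0`) of 8
#'   trials (4 related, 4 unrelated; 3 go + 1 stop per condition) built from
#'   `practice_stimuli`. Practice trials are excluded from all analyses.
#' @param practice_stimuli Optional 4-row stimulus set for the practice
#'   block; placeholder items are synthesised when omitted.
#' @return A data.frame with columns `participant`, `block`, `position`,
#'   `picture`, `condition`, `trial_type`, `ssd_ms` (`NA` on go trials).
#' @export
#' @examples
#' stim <- read_stimuli()
#' asg <- counterbalance_assignments(stim, seed = 1)$A
#' sched <- build_design(stim, asg, seed = 1)
#' table(sched$block, sched$trial_type)
build_design <- function(stimuli, assignment, seed,
                         participant_id = "p01", max_attempts = 10000L,
                         practice = FALSE, practice_stimuli = NULL) {
  check_stimulus_count(stimuli)
  check_assignment(assignment, stimuli)
  set.seed(seed)

  # Stop-slot allocation: for each delay group (20 pictures), split into 4
  # random subgroups of 5; subgroup i is a related-condition stop trial in
  # block i and an unrelated-condition stop trial in block i+1 (mod 4), so
  # every block draws 5 related + 5 unrelated stop trials from each delay
  # group, and no picture is a stop trial twice within a block.
  slot_map <- list()
  for (ssd in c(250L, 325L)) {
    grp <- if (ssd == 250L) assignment$ssd250 else assignment$ssd325
    sub <- split(sample(grp), rep(1:4, each = length(grp) / 4))
    for (b in 1:4) {
      slot_map[[paste(ssd, b, "related")]] <- sub[[b]]
      slot_map[[paste(ssd, b, "unrelated")]] <- sub[[b %% 4 + 1]]
    }
  }

  blocks <- lapply(1:4, function(b) {
    entries <- data.frame(
      participant = participant_id,
      block = b,
      position = NA_integer_,
      picture = rep(stimuli$picture, 2L),
      condition = rep(c("related", "unrelated"), each = nrow(stimuli)),
      trial_type = "go",
      ssd_ms = NA_integer_,
      stringsAsFactors = FALSE
    )
    for (ssd in c(250L, 325L)) for (cond in c("related", "unrelated")) {
      hit <- entries$picture %in% slot_map[[paste(ssd, b, cond)]] &
        entries$condition == cond
      entries$trial_type[hit] <- "stop"
      entries$ssd_ms[hit] <- ssd
    }
    out <- randomize_block(entries, stimuli, max_attempts = max_attempts)
    out$position <- seq_len(nrow(out))
    out
  })
  sched <- do.call(rbind, blocks)

  if (practice) {
    prac <- build_practice_block(participant_id, practice_stimuli)
    sched <- rbind(prac, sched)
  }
  rownames(sched) <- NULL
  sched
}

build_practice_block <- function(participant_id, practice_stimuli = NULL) {
  if (is.null(practice_stimuli)) {
    practice_stimuli <- data.frame(
      picture = paste0("oefen", 1:4),
      category = paste0("oefencat", 1:4),
      onset = c("q", "x", "y", "ij"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(practice_stimuli) != 4L)
    stop("practice block needs exactly 4 stimuli")
  data.frame(
    participant = participant_id,
    block = 0L,
    position = 1:8,
    picture = practice_stimuli$picture[c(1, 2, 3, 4, 1, 2, 3, 4)],
    condition = rep(c("related", "unrelated"), 4L),
    trial_type = c("go", "go", "go", "go", "go", "go", "stop", "stop"),
    ssd_ms = c(NA, NA, NA, NA, NA, NA, 250L, 325L),
    stringsAsFactors = FALSE
  )
}

block_constraints_ok <- function(cond, category, onset, max_run = 4L) {
  n <- length(cond)
  if (any(rle(cond)$lengths > max_run)) return(FALSE)
  if (any(category[-1] == category[-n])) return(FALSE)
  if (any(onset[-1] == onset[-n])) return(FALSE)
  TRUE
}

#' Pseudorandomize one block under adjacency constraints
#'
#' Reorders a block of trials under the constraints: no more than four
#' consecutive trials from the same distractor condition, no two
#' consecutive target pictures from the same semantic category, and no two
#' consecutive picture names starting with the same phoneme.
#'
#' Orders are drawn by constrained sequential sampling: positions are
#' filled left to right, choosing uniformly at random among the remaining
#' trials that do not violate a constraint against the trial just placed;
#' a dead end discards the partial order and restarts (one attempt).
#' This rejects invalid continuations early instead of reshuffling whole
#' blocks, whose raw acceptance rate is impractically low for realistic
#' stimulus sets, while still satisfying exactly the published constraint
#' set. A returned order is always verified in full before being accepted.
#'
#' @param entries Block of schedule rows (any multiset-valid block).
#' @param stimuli Stimulus set used to look up category and onset phoneme.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param max_attempts Restart budget; exceeding it is an explicit error
#'   carrying the attempt count, never a silent constraint relaxation.
#' @return A permutation of `entries` satisfying the constraints.
#' @export
randomize_block <- function(entries, stimuli, seed = NULL,
                            max_attempts = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match(entries$picture, stimuli$picture)
  if (anyNA(idx))
    stop("schedule contains pictures not in the stimulus set: ",
         paste(unique(entries$picture[is.na(idx)]), collapse = ", "))
  category <- stimuli$category[idx]
  onset <- stimuli$onset[idx]
  cond <- entries$condition
  n <- nrow(entries)
  for (attempt in seq_len(max_attempts)) {
    remaining <- sample.int(n)   # random tie-break priority
    ord <- integer(n)
    run <- 0L
    ok <- TRUE
    for (pos in seq_len(n)) {
      if (pos == 1L) {
        pick <- remaining[1L]
      } else {
        prev <- ord[pos - 1L]
        eligible <- category[remaining] != category[prev] &
          onset[remaining] != onset[prev]
        if (run >= 4L)
          eligible <- eligible & cond[remaining] != cond[prev]
        hit <- which(eligible)
        if (!length(hit)) { ok <- FALSE; break }
        pick <- remaining[hit[1L]]
      }
      run <- if (pos > 1L && cond[pick] == cond[ord[pos - 1L]])
        run + 1L else 1L
      ord[pos] <- pick
      remaining <- remaining[remaining != pick]
    }
    if (ok && block_constraints_ok(cond[ord], category[ord], onset[ord])) {
      out <- entries[ord, , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("randomize_block: no constraint-satisfying order found in ",
       max_attempts, " attempts")
}

#' Validate a schedule against the experimental design
#'
#' Checks a schedule for the published design structure (320 trials in 4
#' blocks of 80; per block 60 go and 20 stop trials, stop trials split 10
#' related / 10 unrelated with each delay occurring 10 times; every picture
#' once per condition per block; 40 distinct pictures) and for the
#' pseudorandomization constraints (condition run length at most 4, no
#' consecutive same-category or same-onset pictures). When `assignment` is
#' supplied, each picture's stop-trial delay is additionally checked against
#' the counterbalance assignment. Practice rows (`block == 0`) are ignored.
#'
#' @param schedule Schedule data.frame (see [build_design()]).
#' @param stimuli Stimulus set for category/onset lookup.
#' @param assignment Optional `cb_assignment` to check delays against.
#' @return A list of class `design_validation`: `ok` (logical), `counts`
#'   (per-block summary) and `violations` (data.frame with columns `block`,
#'   `position`, `type`, `detail`; zero rows iff the schedule conforms).
#' @export
validate_design <- function(schedule, stimuli, assignment = NULL) {
  schedule <- schedule[schedule$block != 0L, , drop = FALSE]
  unknown <- setdiff(unique(schedule$picture), stimuli$picture)
  if (length(unknown))
    stop("unknown picture names in schedule: ",
         paste(unknown, collapse = ", "))

  viol <- list()
  add <- function(block, position, type, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      block = block, position = position, type = type, detail = detail,
      stringsAsFactors = FALSE)
  }

  if (nrow(schedule) != 320L)
    add(NA, NA, "n_trials", paste0("expected 320 trials, got ",
                                   nrow(schedule)))
  if (length(unique(schedule$picture)) != 40L)
    add(NA, NA, "n_pictures", paste0("expected 40 distinct pictures, got ",
                                     length(unique(schedule$picture))))
  bad_ssd <- which(xor(schedule$trial_type == "stop",
                       !is.na(schedule$ssd_ms)))
  for (i in bad_ssd)
    add(schedule$block[i], schedule$position[i], "ssd_presence",
        "ssd_ms must be present iff trial_type is stop")

  counts <- list()
  for (b in sort(unique(schedule$block))) {
    blk <- schedule[schedule$block == b, , drop = FALSE]
    blk <- blk[order(blk$position), , drop = FALSE]
    n_go <- sum(blk$trial_type == "go")
    n_stop <- sum(blk$trial_type == "stop")
    stop_rel <- sum(blk$trial_type == "stop" & blk$condition == "related")
    n250 <- sum(!is.na(blk$ssd_ms) & blk$ssd_ms == 250)
    n325 <- sum(!is.na(blk$ssd_ms) & blk$ssd_ms == 325)
    counts[[length(counts) + 1L]] <- data.frame(
      block = b, n = nrow(blk), go = n_go, stop = n_stop,
      stop_related = stop_rel, stop_unrelated = n_stop - stop_rel,
      ssd250 = n250, ssd325 = n325)

    if (nrow(blk) != 80L)
      add(b, NA, "block_size", paste0("expected 80 trials, got ", nrow(blk)))
    if (n_go != 60L)
      add(b, NA, "go_count", paste0("expected 60 go trials, got ", n_go))
    if (n_stop != 20L)
      add(b, NA, "stop_count", paste0("expected 20 stop trials, got ",
                                      n_stop))
    if (n_stop == 20L && stop_rel != 10L)
      add(b, NA, "stop_condition_count",
          paste0("expected 10 related stop trials, got ", stop_rel))
    if (n250 != 10L || n325 != 10L)
      add(b, NA, "ssd_count",
          paste0("expected 10 stop trials per SSD, got ", n250, "/", n325))
    cell <- table(blk$picture, blk$condition)
    if (!(all(dim(cell) == c(40L, 2L)) && all(cell == 1L)))
      add(b, NA, "picture_coverage",
          "each picture must occur once per condition in every block")

    # adjacency and run-length constraints, with positions
    catg <- stimuli$category[match(blk$picture, stimuli$picture)]
    ons <- stimuli$onset[match(blk$picture, stimuli$picture)]
    runs <- rle(blk$condition)
    ends <- cumsum(runs$lengths)
    for (j in which(runs$lengths > 4L))
      add(b, blk$position[ends[j]], "condition_run",
          paste0(runs$lengths[j], " consecutive ", runs$values[j],
                 " trials"))
    for (i in which(catg[-1] == catg[-length(catg)]))
      add(b, blk$position[i + 1L], "category_adjacent",
          paste0("consecutive pictures from category '", catg[i], "'"))
    for (i in which(ons[-1] == ons[-length(ons)]))
      add(b, blk$position[i + 1L], "onset_adjacent",
          paste0("consecutive pictures with onset '", ons[i], "'"))
  }

  # cross-block: each picture x condition a stop trial exactly once, at the
  # assigned delay
  stops <- schedule[schedule$trial_type == "stop", , drop = FALSE]
  sc <- table(stops$picture, stops$condition)
  if (!(all(dim(sc) == c(40L, 2L)) && all(sc == 1L)))
    add(NA, NA, "stop_coverage",
        "each picture x condition must be a stop trial exactly once")
  per_pic_ssd <- tapply(stops$ssd_ms, stops$picture,
                        function(x) length(unique(x)))
  for (p in names(per_pic_ssd)[per_pic_ssd > 1L])
    add(NA, NA, "ssd_consistency",
        paste0("picture '", p, "' has stop trials at multiple SSDs"))
  if (!is.null(assignment)) {
    want <- ifelse(stops$picture %in% assignment$ssd250, 250L, 325L)
    for (i in which(stops$ssd_ms != want))
      add(stops$block[i], stops$position[i], "ssd_assignment",
          paste0("picture '", stops$picture[i], "' scheduled at SSD ",
                 stops$ssd_ms[i], ", assignment says ", want[i]))
  }

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(block = integer(), position = integer(),
               type = character(), detail = character())
  structure(list(ok = nrow(violations) == 0L,
                 counts = do.call(rbind, counts),
                 violations = violations),
            class = "design_validation")
}

#' @export
print.design_validation <- function(x, ...) {
  cat(if (x$ok) "schedule conforms to the design\n" else
    paste0(nrow(x$violations), " violation(s) found\n"))
  print(x$counts, row.names = FALSE)
  if (!x$ok) print(x$violations, row.names = FALSE)
  invisible(x)
}

#' Write / read a schedule CSV
#'
#' Schedule files use the header
#' `participant,block,position,picture,condition,trial_type,ssd_ms`
#' with an empty `ssd_ms` field on go trials.
#'
#' @param schedule Schedule data.frame.
#' @param path File path.
#' @return `read_schedule` returns the schedule data.frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- utils::read.csv(path, stringsAsFactors = FALSE)
  sched$ssd_ms <- suppressWarnings(as.integer(sched$ssd_ms))
  sched
}
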