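#' Paired sign-flip permutation test
#'
#' Tests whether the mean within-participant difference `mean(a - b)`
#' differs from zero by randomly flipping the sign of each participant's
#' difference. The two-sided p-value uses add-one smoothing,
#' `p = (#{|null| >= |obs|} + 1) / (n_perm + 1)`, so it is never zero. With
#' `exhaustive = TRUE` all `2^n` sign patterns are enumerated instead and
#' `p = #{|null| >= |obs|} / 2^n` (the identity pattern makes this exact).
#'
#' @param a,b Numeric vectors aligned by participant.
#' @param n_perm Number of random sign flips (ignored when exhaustive).
#' @param seed Optional seed for the random flips.
#' @param exhaustive Enumerate all sign patterns (requires `n <= 20`).
#' @return A list of class `paired_effect`: `effect` (mean difference),
#'   `n`, `p_value`, `n_permutations`, `seed`.
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(12, 520, 40); b <- a - rnorm(12, 15, 10)
#' paired_permutation(a, b, n_perm = 999, seed = 7)
paired_permutation <- function(a, b, n_perm = 10000L, seed = NULL,
                               exhaustive = FALSE) {
  if (length(a) != length(b)) stop("a and b must be aligned by participant")
  d <- a - b
  d <- d[stats::complete.cases(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete participants")
  obs <- mean(d)
  tol <- 1e-12 * max(1, abs(obs))
  if (exhaustive) {
    if (n > 20L) stop("exhaustive enumeration limited to n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.vector(signs %*% d) / n
    p <- mean(abs(null) >= abs(obs) - tol)
    n_used <- nrow(signs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                    nrow = n_perm)
    null <- as.vector(signs %*% d) / n
    p <- (sum(abs(null) >= abs(obs) - tol) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(effect = obs, n = n, p_value = p,
                 n_permutations = n_used,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "paired_effect")
}

#' @export
print.paired_effect <- function(x, ...) {
  cat(sprintf("paired sign-flip permutation: effect = %.2f, n = %d, p = %.4g (%d permutations)\n",
              x$effect, x$n, x$p_value, x$n_permutations))
  invisible(x)
}

#' Within-subject 2x2 factorial permutation test
#'
#' Sign-flip inference for a delay-by-condition design on per-participant
#' cell means (e.g. SSRT per SSD x distractor condition). Main effects are
#' tested on the marginal paired contrasts (late minus early delay averaged
#' over conditions; related minus unrelated averaged over delays), the
#' interaction on the per-participant double difference
#' `(related - unrelated | late) - (related - unrelated | early)`.
#' Participants with incomplete cells are dropped and counted.
#'
#' @param cells Data.frame with columns `participant`, `ssd_ms`,
#'   `condition`, `value`: one value per participant x delay x condition.
#' @param n_perm Number of random sign flips per contrast.
#' @param seed Optional seed.
#' @return A list of class `factorial_effects` with `paired_effect`
#'   elements `ssd`, `condition`, `interaction`, plus `n_complete` and
#'   `n_dropped`.
#' @export
factorial_permutation <- function(cells, n_perm = 10000L, seed = NULL) {
  ssds <- sort(unique(cells$ssd_ms))
  conds <- c("unrelated", "related")
  if (length(ssds) != 2L || !all(cells$condition %in% conds))
    stop("cells must span exactly 2 SSDs and conditions related/unrelated")
  wide <- lapply(split(cells, cells$participant), function(pp) {
    v <- matrix(NA_real_, 2, 2, dimnames = list(ssds, conds))
    for (i in seq_len(nrow(pp)))
      v[as.character(pp$ssd_ms[i]), pp$condition[i]] <- pp$value[i]
    v
  })
  complete <- vapply(wide, function(v) !anyNA(v), TRUE)
  n_dropped <- sum(!complete)
  wide <- wide[complete]
  if (length(wide) < 2L) stop("fewer than 2 complete participants")

  ssd_c <- vapply(wide, function(v) mean(v[2, ]) - mean(v[1, ]), 0)
  cond_c <- vapply(wide, function(v) mean(v[, "related"]) -
                     mean(v[, "unrelated"]), 0)
  int_c <- vapply(wide, function(v)
    (v[2, "related"] - v[2, "unrelated"]) -
      (v[1, "related"] - v[1, "unrelated"]), 0)

  if (!is.null(seed)) set.seed(seed)
  test <- function(contrast) paired_permutation(contrast,
                                                rep(0, length(contrast)),
                                                n_perm = n_perm)
  structure(list(ssd = test(ssd_c), condition = test(cond_c),
                 interaction = test(int_c),
                 n_complete = length(wide), n_dropped = n_dropped),
            class = "factorial_effects")
}

#' @export
print.factorial_effects <- function(x, ...) {
  cat(sprintf("2x2 within-subject permutation (%d complete, %d dropped)\n",
              x$n_complete, x$n_dropped))
  for (nm in c("ssd", "condition", "interaction"))
    cat(sprintf("  %-12s effect = %8.2f  p = %.4g\n", nm, x[[nm]]$effect,
                x[[nm]]$p_value))
  invisible(x)
}
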