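#' Rarity-based weights for sibship events
#'
#' Scores must reward rare events: the weight of event size `k` is the
#' (half-up rounded) reciprocal of its null mean count,
#' `w_k = round(1 / max(mean_c_k, 1/iterations))`, capped at `cap` so that
#' events never seen in the null get a large finite weight. Singletons carry
#' no weight (`w_1 = 0`).
#'
#' @param null A [null_summary()].
#' @param cap Maximum weight (default 1000).
#' @return An object of class `score_weights`: numeric vector `w_1..w_s` with
#'   attributes recording the provenance null.
#' @export
build_weights <- function(null, cap = 1000) {
  stopifnot(inherits(null, "null_summary"), cap > 0)
  m <- null$mean
  if (length(m) < 2L) stop("null has no event sizes k >= 2", call. = FALSE)
  w <- round_half_up(1 / pmax(m, 1 / null$iterations))
  w <- pmin(w, cap)
  w[1L] <- 0
  structure(stats::setNames(as.numeric(w), paste0("w", seq_along(w))),
            cap = cap,
            null_trc = null$trc_size, null_iterations = null$iterations,
            null_seed = null$seed,
            class = "score_weights")
}

#' Score a sibship composition
#'
#' Total score `sum_{k >= 2} c_k * w_k`: zero iff no family has two or more
#' sampled members, additive over disjoint compositions.
#'
#' @param comp A [sibship_composition()] or a plain counts vector
#'   (`c_1..c_s`).
#' @param weights A [build_weights()] object (or plain weight vector).
#' @return A single number.
#' @export
score_composition <- function(comp, weights) {
  c_k <- as.numeric(comp)
  w <- as.numeric(weights)
  len <- max(length(c_k), length(w))
  c_k <- c(c_k, numeric(len - length(c_k)))
  w <- c(w, numeric(len - length(w)))
  w[1L] <- 0
  sum(c_k * w)
}

#' Upper-tail probability of an empirical score
#'
#' Draws fresh samples from the cohort, scores each under the supplied
#' weights, and estimates `P(null score >= emp_score)` with add-one smoothing
#' (so the estimate is never exactly zero):
#' `(1 + #\{score >= emp\}) / (iterations + 1)`.
#'
#' @param emp_score Empirical score to test.
#' @param cohort A [build_cohort()] object (the null cohort).
#' @param n Sample size per draw.
#' @param weights A [build_weights()] object.
#' @param iterations Number of draws (>= 1000 recommended).
#' @param seed Optional integer seed.
#' @param keep_scores Also return the vector of null scores.
#' @return An object of class `score_result`: list with `score`,
#'   `tail_probability`, `iterations`, `trc_size`, `seed` (and `null_scores`
#'   if requested).
#' @export
tail_probability <- function(emp_score, cohort, n, weights, iterations = 1e4,
                             seed = NULL, keep_scores = FALSE) {
  stopifnot(inherits(cohort, "recruit_cohort"), iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  s <- cohort$family_size
  w <- c(as.numeric(weights), numeric(max(0, s - length(weights))))[seq_len(s)]
  w[1L] <- 0
  scores <- numeric(iterations)
  for (i in seq_len(iterations)) {
    scores[i] <- sum(draw_counts(cohort$size, s, n) * w)
  }
  res <- list(score = emp_score,
              tail_probability = (1 + sum(scores >= emp_score)) / (iterations + 1),
              iterations = as.integer(iterations),
              trc_size = cohort$size, seed = seed)
  if (keep_scores) res$null_scores <- scores
  structure(res, class = "score_result")
}

# Evaluate one candidate cohort size in the confidence search: draw the null
# once, derive weights from the same draws' means, and locate the empirical
# composition's score in that null.
eval_trc_candidate <- function(emp_counts, TRC, n, s, iterations, cap = 1000) {
  cohort <- build_cohort(TRC, s)
  acc <- acc2 <- numeric(s)
  comps <- matrix(0L, iterations, s)
  for (i in seq_len(iterations)) {
    ck <- draw_counts(cohort$size, s, n)
    comps[i, ] <- ck
    acc <- acc + ck
  }
  m <- acc / iterations
  w <- pmin(round_half_up(1 / pmax(m, 1 / iterations)), cap)
  w[1L] <- 0
  emp_score <- sum(emp_counts * w)
  null_scores <- as.numeric(comps %*% w)
  p <- (1 + sum(null_scores >= emp_score)) / (iterations + 1)
  list(TRC = cohort$size, p = p, emp_score = emp_score, weights = w)
}

#' Largest cohort size compatible with an empirical composition
#'
#' Searches for the largest family-structured cohort size `T_star` (a multiple
#' of `s`) whose sampling null still produces scores as extreme as the
#' empirical composition with probability at least `alpha`:
#' `P(null score >= empirical score) >= alpha`. Each candidate cohort defines
#' its own null and rarity weights, so the comparison is always internally
#' consistent. Larger cohorts make kin-clumping rarer, so acceptance is
#' monotone: the search brackets the boundary by doubling from the lower
#' bound, then bisects to a granularity of one family (`s` recruits).
#'
#' @param emp A [sibship_composition()] (the empirical sample).
#' @param n Sample size (taken from `emp` if missing).
#' @param s Family size.
#' @param alpha Acceptance level (default 0.05: the empirical score must lie
#'   below the null's `1 - alpha` quantile).
#' @param iterations Monte Carlo draws per candidate cohort.
#' @param seed Optional integer seed (the whole search is deterministic given
#'   it).
#' @param t_min,t_max Search bounds on the cohort size; `t_min` defaults to
#'   the smallest multiple of `s` holding `n`, `t_max` to `1e6`.
#' @param cap Weight cap passed through to the per-candidate weights.
#' @return An object of class `confidence_search`: list with `T_star`, the
#'   acceptance level, the evaluation `path` (data frame of candidate size,
#'   tail probability, empirical score) and a `boundary` flag set when no
#'   candidate in bounds was accepted (`"below"`) or none rejected
#'   (`"above"`).
#' @export
confidence_trc_search <- function(emp, n = attr(emp, "n"), s = 6, alpha = 0.05,
                                  iterations = 2000, seed = NULL,
                                  t_min = NULL, t_max = 1e6, cap = 1000) {
  stopifnot(alpha > 0, alpha < 1, iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(s)
  emp_counts <- c(as.numeric(emp), numeric(max(0, s - length(emp))))[seq_len(s)]
  if (is.null(t_min)) t_min <- as.integer(ceiling(n / s)) * s
  t_min <- max(t_min, as.integer(ceiling(n / s)) * s)
  path <- list()
  evalT <- function(TRC) {
    r <- eval_trc_candidate(emp_counts, TRC, n, s, iterations, cap)
    path[[length(path) + 1L]] <<- data.frame(TRC = r$TRC, p = r$p,
                                             emp_score = r$emp_score)
    r
  }
  # The acceptance region is an interval: cohorts barely larger than the
  # sample force compositions incompatible with the empirical one just as
  # surely as very large cohorts make its clumping too rare. Climb from the
  # lower bound to an accepted candidate first, then bracket the upper
  # boundary, which is the quantity of interest (the LARGEST compatible T).
  lo <- evalT(t_min)
  TT <- t_min
  while (lo$p < alpha && TT < t_max) {
    TT <- min(2 * TT, t_max)
    lo <- evalT(TT)
  }
  if (lo$p < alpha) {
    return(structure(list(T_star = NA_integer_, alpha = alpha,
                          path = do.call(rbind, path), boundary = "below",
                          iterations = iterations, seed = seed),
                     class = "confidence_search"))
  }
  # double until rejected
  t_lo <- TT
  t_hi <- NA
  repeat {
    TT <- min(2 * TT, t_max)
    r <- evalT(TT)
    if (r$p < alpha) { t_hi <- TT; break }
    t_lo <- TT
    if (TT >= t_max) break
  }
  if (is.na(t_hi)) {
    return(structure(list(T_star = as.integer(t_lo %/% s) * s, alpha = alpha,
                          path = do.call(rbind, path), boundary = "above",
                          iterations = iterations, seed = seed),
                     class = "confidence_search"))
  }
  # bisect to one family
  while (t_hi - t_lo > s) {
    mid <- ((t_lo + t_hi) %/% 2L) %/% s * s
    if (mid <= t_lo || mid >= t_hi) break
    r <- evalT(mid)
    if (r$p >= alpha) t_lo <- mid else t_hi <- mid
  }
  structure(list(T_star = as.integer(t_lo %/% s) * s, alpha = alpha,
                 path = do.call(rbind, path), boundary = "none",
                 iterations = iterations, seed = seed),
            class = "confidence_search")
}

#' @export
print.confidence_search <- function(x, ...) {
  cat(sprintf("Confidence cohort search: T* = %s at alpha = %g (%d draws/candidate)\n",
              format(x$T_star), x$alpha, x$iterations))
  if (x$boundary != "none") cat("  boundary condition:", x$boundary, "\n")
  invisible(x)
}
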