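#' Sibship composition of a sample
#'
#' The statistic everything downstream is built on: for a sample of `n`
#' recruits from a family-structured cohort, `c_k` counts the families with
#' exactly `k` sampled members ("sibship events": pairs are `k = 2`, triplets
#' `k = 3`, ...). A valid composition conserves the sample: `sum(k * c_k) = n`.
#'
#' @param counts Integer vector of length `s`; element `k` is `c_k`.
#' @param n Sample size the composition was tallied from.
#' @return An object of class `sibship_composition` (the counts vector with
#'   attributes `n` and `family_size`).
#' @export
sibship_composition <- function(counts, n) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("sibship counts must be nonnegative", call. = FALSE)
  if (sum(seq_along(counts) * counts) != n) {
    stop("invalid composition: sum(k * c_k) must equal the sample size n",
         call. = FALSE)
  }
  structure(counts, n = as.integer(n), family_size = length(counts),
            class = "sibship_composition")
}

# Tally one uniform without-replacement draw. Positional family labels mean
# the family of sampled index i is (i - 1) %/% s; run lengths of the sorted
# labels are the per-family sample sizes.
draw_counts <- function(N, s, n) {
  fam <- (sample.int(N, n) - 1L) %/% s
  sz <- rle(sort.int(fam, method = "quick"))$lengths
  tabulate(sz, nbins = s)
}

#' Draw one light-trap-sized sample from a cohort
#'
#' Chooses `n` distinct recruits uniformly without replacement from the
#' realized cohort and tallies its sibship composition.
#'
#' @param cohort A [build_cohort()] object.
#' @param n Sample size (the study's light-trap sample is 168).
#' @return A [sibship_composition()].
#' @examples
#' set.seed(1)
#' draw_sample(build_cohort(720, 6), 168)
#' @export
draw_sample <- function(cohort, n) {
  stopifnot(inherits(cohort, "recruit_cohort"))
  n <- as.integer(n)
  if (n > cohort$size) {
    stop(sprintf("cannot sample %d recruits from a cohort of %d", n, cohort$size),
         call. = FALSE)
  }
  sibship_composition(draw_counts(cohort$size, cohort$family_size, n), n)
}

#' Monte Carlo null of the sibship composition
#'
#' Repeats [draw_sample()] and summarizes the per-event-size counts: the null
#' distribution of sibship events when recruits arrive independently of their
#' kin.
#'
#' @param cohort A [build_cohort()] object.
#' @param n Sample size per draw.
#' @param iterations Number of independent draws (>= 1).
#' @param seed Optional integer seed; recorded in the result.
#' @return An object of class `null_summary`: list with `mean` and `se`
#'   (numeric vectors indexed by event size `k = 1..s`), `iterations`, `seed`,
#'   `n`, `trc_size` and `family_size`.
#' @examples
#' ns <- null_summary(build_cohort(720, 6), 168, iterations = 1000, seed = 1)
#' ns$mean[2] # ~34 sibling pairs
#' @export
null_summary <- function(cohort, n, iterations = 1e5, seed = NULL) {
  stopifnot(inherits(cohort, "recruit_cohort"), iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n > cohort$size) {
    stop(sprintf("cannot sample %d recruits from a cohort of %d", n, cohort$size),
         call. = FALSE)
  }
  s <- cohort$family_size
  N <- cohort$size
  acc <- acc2 <- numeric(s)
  for (i in seq_len(iterations)) {
    ck <- draw_counts(N, s, n)
    acc <- acc + ck
    acc2 <- acc2 + ck * ck
  }
  m <- acc / iterations
  v <- pmax(acc2 / iterations - m^2, 0)
  structure(
    list(mean = stats::setNames(m, paste0("c", seq_len(s))),
         se = stats::setNames(sqrt(v / iterations), paste0("c", seq_len(s))),
         iterations = as.integer(iterations), seed = seed,
         n = n, trc_size = N, family_size = s),
    class = "null_summary"
  )
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("Sibship null: %d draws of %d from a cohort of %d (families of %d)\n",
              x$iterations, x$n, x$trc_size, x$family_size))
  print(round(rbind(mean = x$mean, se = x$se), 4))
  invisible(x)
}

#' Exact expected sibship composition
#'
#' Closed-form oracle for the Monte Carlo null. Sampling `n` of `N = K * s`
#' recruits without replacement makes the number of sampled members of any one
#' family hypergeometric, so
#' `E[c_k] = K * choose(s, k) * choose(N - s, n - k) / choose(N, n)`,
#' computed in log space.
#'
#' @param N Realized cohort size (`K * s`).
#' @param K Number of families.
#' @param s Family size.
#' @param n Sample size.
#' @return Named numeric vector `c0..c_min(s,n)` of expected counts.
#' @examples
#' expected_composition(12, 2, 6, 2)["c2"] # 30/66
#' @export
expected_composition <- function(N, K, s, n) {
  stopifnot(N == K * s, n >= 0, n <= N, s >= 1, K >= 1)
  k <- 0:min(s, n)
  valid <- (n - k) <= (N - s)
  ek <- numeric(length(k))
  ek[valid] <- K * exp(lchoose(s, k[valid]) + lchoose(N - s, n - k[valid]) -
                         lchoose(N, n))
  stats::setNames(ek, paste0("c", k))
}
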