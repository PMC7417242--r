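test_that("weights are capped rounded reciprocals of null mean counts", {
  ns <- null_summary(build_cohort(720, 6), 168, 2000, seed = 5)
  fake <- ns
  fake$mean <- stats::setNames(c(100, 0.5, 0, 0.2, 0.001, 0), paste0("c", 1:6))
  fake$iterations <- 1e4L
  w <- build_weights(fake, cap = 1000)
  expect_equal(unname(w[1]), 0)         # singletons never score
  expect_equal(unname(w[2]), 2)         # reciprocal of 0.5
  expect_equal(unname(w[3]), 1000)      # unseen event hits the cap
  expect_equal(unname(w[4]), 5)
  expect_equal(unname(w[5]), 1000)      # 1/0.001 capped
})

test_that("weights grow monotonically with event rarity in a sparse null", {
  ns <- null_summary(build_cohort(5911, 6), 168, 2e4, seed = 6)
  w <- build_weights(ns)
  expect_lt(w[2], w[3])
  expect_lt(w[3], w[4])
  expect_lte(w[4], w[5])
  # rarity ordering mirrors the exact expectation
  ex <- expected_composition(5910, 985, 6, 168)
  expect_true(all(diff(ex[c("c2", "c3", "c4", "c5")]) < 0))
})

test_that("scores are zero without multi-member events and additive otherwise", {
  w <- c(0, 3, 10, 50, 200, 1000)
  expect_equal(score_composition(c(168, 0, 0, 0, 0, 0), w), 0)
  expect_equal(score_composition(c(0, 1, 0, 0, 0, 0), w), 3)
  a <- c(3, 2, 1, 0, 0, 0)
  b <- c(0, 1, 2, 1, 0, 0)
  expect_equal(score_composition(a + b, w),
               score_composition(a, w) + score_composition(b, w))
  # singleton weight is ignored even if supplied
  expect_equal(score_composition(c(5, 0, 0, 0, 0, 0), c(9, 0, 0, 0, 0, 0)), 0)
})

test_that("tail probabilities hit their degenerate limits", {
  coh <- build_cohort(720, 6)
  w <- build_weights(null_summary(coh, 168, 1000, seed = 7))
  lo <- tail_probability(0, coh, 168, w, iterations = 1000, seed = 8)
  expect_equal(lo$tail_probability, 1, tolerance = 2 / 1001)
  hi <- tail_probability(Inf, coh, 168, w, iterations = 1000, seed = 8)
  expect_equal(hi$tail_probability, 1 / 1001)
})

test_that("tail probability decreases in the empirical score and in cohort size", {
  coh <- build_cohort(1500, 6)
  w <- build_weights(null_summary(coh, 168, 2000, seed = 9))
  ps <- vapply(c(0, 5, 20, 100),
               function(sc) tail_probability(sc, coh, 168, w, 2000, seed = 10)$tail_probability,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  # larger pools make the empirical clumping rarer
  emp <- empirical_composition()
  p_by_trc <- vapply(c(720, 1500, 5910), function(TRC) {
    co <- build_cohort(TRC, 6)
    ns <- null_summary(co, 168, 2000, seed = 11)
    ww <- build_weights(ns)
    tail_probability(score_composition(emp, ww), co, 168, ww, 2000,
                     seed = 12)$tail_probability
  }, numeric(1))
  expect_true(all(diff(p_by_trc) < 0))
})

test_that("confidence search brackets an interval and respects its bounds", {
  emp <- empirical_composition()
  cs <- confidence_trc_search(emp, 168, 6, alpha = 0.05, iterations = 1000,
                              seed = 13, t_max = 4e4)
  expect_equal(cs$boundary, "none")
  expect_equal(cs$T_star %% 6, 0)
  expect_gt(cs$T_star, 168)
  expect_lt(cs$T_star, 19440)          # far below the 25 km cohort
  # acceptance is monotone at the searched boundary: every accepted candidate
  # on the path is below every rejected one near T*
  path <- cs$path[-1, ]                # drop the degenerate lower-bound probe
  acc <- path$TRC[path$p >= 0.05]
  rej <- path$TRC[path$p < 0.05]
  expect_lt(max(acc), min(rej))
  # an all-singleton composition is compatible with any cohort: upper boundary
  flat <- sibship_composition(c(168, 0, 0, 0, 0, 0), 168)
  cs2 <- confidence_trc_search(flat, 168, 6, iterations = 300, seed = 14,
                               t_max = 5000)
  expect_equal(cs2$boundary, "above")
})

test_that("raising the acceptance level shrinks the compatible cohort", {
  emp <- empirical_composition()
  lo <- confidence_trc_search(emp, 168, 6, alpha = 0.05, iterations = 1000,
                              seed = 15, t_max = 4e4)
  hi <- confidence_trc_search(emp, 168, 6, alpha = 0.5, iterations = 1000,
                              seed = 15, t_max = 4e4)
  expect_lte(hi$T_star, lo$T_star)
})
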