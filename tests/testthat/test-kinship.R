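test_that("the packaged assignment table matches every published count", {
  pairs <- rcs_sibship_pairs()
  expect_equal(nrow(pairs), 129)
  expect_equal(sum(pairs$relation == "half_sib"), 126)
  expect_equal(sum(pairs$relation == "full_sib"), 3)
  expect_true(all(pairs$posterior[pairs$relation == "full_sib"] == 1))
  acc <- accept_pairs(pairs, 0.75)
  expect_equal(nrow(acc), 48)
  expect_equal(sum(acc$relation == "half_sib"), 45)
  expect_equal(sum(acc$relation == "half_sib" & acc$posterior >= 0.95), 18)
})

test_that("thresholding is strict and threshold zero keeps everything above zero", {
  pairs <- rcs_sibship_pairs()
  expect_equal(nrow(accept_pairs(pairs, 0)), nrow(pairs))
  # a posterior exactly at the threshold is rejected
  at_thr <- data.frame(i = "a", j = "b", relation = "half_sib", posterior = 0.75)
  expect_equal(nrow(accept_pairs(at_thr, 0.75)), 0)
  expect_error(accept_pairs(pairs, 1.5))
})

test_that("families are connected components over the full universe", {
  # transitive chain merges into one family
  chain <- data.frame(i = c("a", "b"), j = c("b", "c"),
                      relation = "half_sib", posterior = c(0.9, 0.9))
  part <- families_from_pairs(chain, c("a", "b", "c", "d", "e"))
  expect_equal(sort(vapply(part$families, length, 1L), decreasing = TRUE),
               c(3L, 1L, 1L))
  expect_setequal(part$families[[1]], c("a", "b", "c"))
  # no pairs: all singletons
  none <- data.frame(i = character(0), j = character(0),
                     relation = character(0), posterior = numeric(0))
  solo <- families_from_pairs(none, letters[1:5])
  expect_equal(vapply(solo$families, length, 1L), rep(1L, 5))
  # endpoints outside the universe are an error
  expect_error(families_from_pairs(chain, c("a", "b")), "universe")
})

test_that("partitions are disjoint and exhaustive for arbitrary pair sets", {
  set.seed(31)
  ids <- sprintf("x%02d", 1:40)
  for (rep in 1:10) {
    m <- matrix(sample(ids, 24, replace = TRUE), ncol = 2)
    m <- m[m[, 1] != m[, 2], , drop = FALSE]
    pairs <- data.frame(i = m[, 1], j = m[, 2], relation = "half_sib",
                        posterior = 0.9)
    part <- families_from_pairs(pairs, ids)
    members <- unlist(part$families)
    expect_setequal(members, ids)
    expect_equal(anyDuplicated(members), 0L)
  }
})

test_that("the empirical sibship summary reproduces the published arithmetic", {
  part <- families_from_pairs(accept_pairs(rcs_sibship_pairs()),
                              sprintf("R%03d", 1:168))
  ks <- kin_summary(part, 168)
  expect_equal(ks$n_families, 32)
  expect_equal(as.vector(table(ks$family_sizes)), c(20L, 10L, 1L, 1L))
  expect_equal(ks$recruits_with_kin, 79)
  expect_equal(round(100 * ks$pct_with_kin), 47)
  expect_equal(ks$Cmax, 120)
  # collapsing families counts merges, one fewer than the redundant pair count
  expect_equal(ks$Cmax_collapsed, 121)
  expect_equal(ks$recruits_with_kin + ks$singletons, 168)
})

test_that("sibship summaries hit their degenerate limits", {
  none <- data.frame(i = character(0), j = character(0),
                     relation = character(0), posterior = numeric(0))
  solo <- kin_summary(families_from_pairs(none, letters[1:6]), 6, n_pairs = 0)
  expect_equal(solo$recruits_with_kin, 0)
  expect_equal(solo$pct_with_kin, 0)
  expect_equal(solo$Cmax, 6)
  full <- data.frame(i = letters[1:5], j = letters[2:6],
                     relation = "half_sib", posterior = 0.9)
  one <- kin_summary(families_from_pairs(full, letters[1:6]), 6, n_pairs = 5)
  expect_equal(one$recruits_with_kin, 6)
})

test_that("a family partition converts to a valid sibship composition", {
  part <- families_from_pairs(accept_pairs(rcs_sibship_pairs()),
                              sprintf("R%03d", 1:168))
  comp <- composition_from_partition(part, 6)
  expect_equal(as.integer(comp), c(89, 20, 10, 1, 1, 0))
  expect_equal(sum(1:6 * as.integer(comp)), 168)
  expect_error(composition_from_partition(part, 3), "family of")
})

test_that("malformed assignment files are rejected", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), f, row.names = FALSE)
  expect_error(read_pair_assignments(f), "columns")
  write.csv(data.frame(i = "a", j = "a", relation = "half_sib",
                       posterior = 0.9), f, row.names = FALSE)
  expect_error(read_pair_assignments(f), "self-pairs")
  write.csv(data.frame(i = "a", j = "b", relation = "cousin",
                       posterior = 0.9), f, row.names = FALSE)
  expect_error(read_pair_assignments(f), "relation")
})
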