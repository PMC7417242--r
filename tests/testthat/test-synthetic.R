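test_that("locus panels respect the minor-allele-frequency floor", {
  set.seed(71)
  panel <- sample_panel(300, 0.33)
  expect_length(panel, 300)
  maf <- pmin(as.numeric(panel), 1 - as.numeric(panel))
  expect_true(all(maf >= 0.33))
  # degenerate band collapses to p = 0.5
  tight <- sample_panel(50, 0.4999)
  expect_true(all(abs(as.numeric(tight) - 0.5) < 2e-4))
  expect_length(sample_panel(0, 0.33), 0)
  expect_error(sample_panel(10, 0.5), "maf_min")
})

test_that("pedigree specifications validate their bounds", {
  expect_error(pedigree_spec(sires_per_colony = 3), "1 or 2")
  expect_error(pedigree_spec(missing_rate = 0.2), "missing_rate")
  expect_error(pedigree_spec(error_rate = 0.5), "error_rate")
})

test_that("error-free offspring are Mendelian-consistent with their parents", {
  set.seed(72)
  panel <- sample_panel(120, 0.33)
  spec <- pedigree_spec(sires_per_colony = 2, dams_per_colony = 3,
                        offspring_per_colony = 6, missing_rate = 0,
                        error_rate = 0)
  for (rep in 1:5) {
    col <- simulate_colony(panel, spec)
    for (i in seq_len(nrow(col$offspring))) {
      sire <- col$sires[col$pedigree$sire[i], ]
      dam <- col$dams[col$pedigree$dam[i], ]
      ok <- vapply(seq_along(panel), function(l) {
        mendel_compatible(col$offspring[i, l], sire[l], dam[l])
      }, logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("single-pair crosses give full sibs and split dams give half sibs", {
  set.seed(73)
  panel <- sample_panel(20, 0.33)
  fs <- simulate_colony(panel, pedigree_spec(sires_per_colony = 1,
                                             dams_per_colony = 1,
                                             offspring_per_colony = 2,
                                             missing_rate = 0, error_rate = 0))
  expect_equal(fs$pedigree$sire, c(1L, 1L))
  expect_equal(fs$pedigree$dam, c(1L, 1L))
  ped <- data.frame(id = c("a", "b", "c"),
                    sire = c("s1", "s1", "s2"), dam = c("d1", "d2", "d1"))
  expect_equal(true_relationship(ped, "a", "b"), "HS")
  expect_equal(true_relationship(ped, "a", "c"), "HS")
  expect_equal(true_relationship(ped, "b", "c"), "U")
})

test_that("heterozygote-by-heterozygote crosses segregate 1:2:1", {
  set.seed(74)
  panel <- sample_panel(200, 0.33)
  spec <- pedigree_spec(sires_per_colony = 1, dams_per_colony = 1,
                        offspring_per_colony = 6, missing_rate = 0,
                        error_rate = 0)
  counts <- c(0, 0, 0)
  for (rep in 1:30) {
    col <- simulate_colony(panel, spec)
    het <- col$sires[1, ] == 1L & col$dams[1, ] == 1L
    for (g in 0:2) counts[g + 1] <- counts[g + 1] + sum(col$offspring[, het] == g)
  }
  expect_gt(sum(counts), 1000)
  expect_gt(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.001)
})

test_that("pooled offspring allele frequencies converge to the panel", {
  set.seed(75)
  panel <- sample_panel(25, 0.33)
  sim <- generate_trc_genotyped(6000, 6, panel,
                                pedigree_spec(missing_rate = 0, error_rate = 0))
  expect_lt(max(abs(allele_freqs(sim$G) - as.numeric(panel))), 0.025)
})

test_that("genotyped cohorts align their pedigree with the positional families", {
  set.seed(76)
  panel <- sample_panel(30, 0.33)
  sim <- generate_trc_genotyped(720, 6, panel)
  expect_equal(nrow(sim$G), 720)
  expect_equal(sim$cohort$n_families, 120)
  expect_equal(sim$pedigree$colony, family_labels(sim$cohort))
  # per-call missingness stays near its nominal rate
  expect_lt(abs(mean(is.na(sim$G)) - 0.05), 0.01)
  # family size one means no relatives at all
  solo <- generate_trc_genotyped(12, 1, panel)
  expect_equal(true_relationship(solo$pedigree, "R0001", "R0002"), "U")
})

test_that("sampling a genotyped cohort and reclassifying recovers the expected pair count", {
  set.seed(77)
  panel <- sample_panel(300, 0.33)
  sim <- generate_trc_genotyped(720, 6, panel)
  idx <- sample(nrow(sim$G), 168)
  rel <- pairwise_relatedness(sim$G[idx, ], eps = 0.01, freqs = as.numeric(panel))
  # ~14,000 pairwise tests at this sample size: a stricter acceptance
  # threshold keeps spurious edges from over-merging families
  pa <- accept_pairs(as_pair_assignments(rel), 0.99)
  part <- families_from_pairs(pa, rownames(sim$G)[idx])
  sizes <- vapply(part$families, length, 1L)
  e2 <- expected_composition(720, 120, 6, 168)[["c2"]]
  # one random draw scatters roughly Poisson around the expectation, and
  # imperfect half-sib detection biases the recovered count downward; three
  # root-mean deviations absorb both
  expect_lt(abs(sum(sizes == 2) - e2), 3 * sqrt(e2))
})
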