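test_that("daily per-colony recruit output multiplies fecundity through survival", {
  expect_equal(recruits_per_colony_day(colony_biology(803, 0.5, 0.5, 0.03)),
               6.0225)
  # the published rounded value of 6 is within 1% of the derived product
  expect_lt(abs(recruits_per_colony_day(colony_biology(803, 0.5, 0.5, 0.03)) - 6) / 6,
            0.01)
  expect_equal(recruits_per_colony_day(colony_biology(0, 0.5, 0.5, 0.03)), 0)
  expect_equal(recruits_per_colony_day(colony_biology(100, 1, 1, 1)), 100)
  # a supplied R_Cd overrides the derived product
  expect_equal(recruits_per_colony_day(colony_biology(803, 0.5, 0.5, 0.03,
                                                      recruits_per_colony_day = 6)),
               6)
  expect_error(colony_biology(803, 1.2, 0.5, 0.03), "\\[0, 1\\]")
  expect_error(colony_biology(803, 0.5, 0.5, -0.1), "\\[0, 1\\]")
})

test_that("pelagic survival swept over its published range brackets the central value", {
  out <- vapply(c(0.01, 0.03, 0.05),
                function(S) recruits_per_colony_day(colony_biology(803, 0.5, 0.5, S)),
                numeric(1))
  expect_lt(abs(out[1] - 2) / 2, 0.01)
  expect_lt(abs(out[3] - 10) / 10, 0.01)
  expect_lt(abs(out[2] - 6) / 6, 0.01)
})

test_that("habitat area follows the declared geometry", {
  expect_equal(habitat_area(hab_r25()), 192)
  expect_equal(habitat_area(hab_r50()), 464.4)
  expect_equal(habitat_area(habitat_model(radius = 1, area_mode = "disc")), pi)
  expect_error(habitat_area(habitat_model(area_mode = "strip")), "strip mode")
  expect_error(habitat_area(habitat_model(area_mode = "disc")), "disc mode")
})

test_that("cohort size reproduces the published 25 km and 50 km values", {
  expect_equal(trc_size(bio6(), hab_r25()), 19445)
  expect_equal(trc_size(bio6(), hab_r50()), 47033)
  expect_equal(trc_size(bio6(), hab_r25(), area = 0), 0)
})

test_that("cohort size is linear in area and each multiplicative parameter", {
  base <- trc_size(bio6(), hab_r25(), round = FALSE)
  expect_equal(trc_size(bio6(), hab_r25(), area = 2 * 192, round = FALSE), 2 * base)
  expect_equal(trc_size(colony_biology(recruits_per_colony_day = 12), hab_r25(),
                        round = FALSE), 2 * base)
  hab2 <- habitat_model(colonies_per_transect = 2 * 10.23,
                        habitat_length = 160, habitat_width = 1.2)
  expect_equal(trc_size(bio6(), hab2, round = FALSE), 2 * base)
  hab3 <- habitat_model(habitat_length = 160, habitat_width = 1.2, daily_factor = 1)
  expect_equal(trc_size(bio6(), hab3, round = FALSE), 2 * base)
})

test_that("cohorts partition into complete families with remainders discarded", {
  co <- build_cohort(720, 6)
  expect_equal(co$n_families, 120)
  expect_equal(co$size, 720)
  co2 <- build_cohort(19445, 6)
  expect_equal(co2$n_families, 3240)
  expect_equal(co2$size, 19440)
  expect_equal(build_cohort(6, 6)$n_families, 1)
  expect_error(build_cohort(5, 6), "smaller than one family")
})

test_that("family labels cover every recruit exactly once", {
  co <- build_cohort(40, 6)
  lab <- family_labels(co)
  expect_length(lab, co$size)
  expect_equal(as.vector(table(lab)), rep(6L, co$n_families))
  expect_equal(sum(table(lab)), co$size)
})
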