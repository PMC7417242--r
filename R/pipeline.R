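#' Run the full kin-structured recruitment analysis
#'
#' Chains every stage on one parameter set: demographic cohort sizes for the
#' 25 km and 50 km source radii; Monte Carlo sibship nulls for both; the
#' radius-halving rate and the radius/cohort compatible with the empirical
#' sibling-pair count; the empirical sibship summary from a pair-assignment
#' table; the colony-count back-calculations; and the score test with the
#' confidence search for the largest compatible cohort. Every reported number
#' carries the stage, seed and convention flags that produced it.
#'
#' @param params Parameter list from [default_params()] or [read_params()].
#' @param pairs Pair-assignment data frame (default: the packaged
#'   reconstruction, [rcs_sibship_pairs()]).
#' @param seed Integer seed governing all Monte Carlo stages.
#' @param iterations Draws per Monte Carlo null.
#' @param score_iterations Draws for the score tail test.
#' @param search_iterations Draws per candidate in the confidence search.
#' @param out_dir Optional directory: writes `report.json` and `report.txt`
#'   there.
#' @return The report as a nested list (invisibly if written to disk).
#' @export
run_full_pipeline <- function(params = default_params(),
                              pairs = rcs_sibship_pairs(),
                              seed = 1L,
                              iterations = 1e5,
                              score_iterations = 1e4,
                              search_iterations = 2000,
                              out_dir = NULL) {
  s <- as.integer(params$family_size)
  n <- as.integer(params$n_sample)

  # --- demography ---------------------------------------------------------
  bio <- colony_biology(params$E, params$H, params$Hd, params$S,
                        recruits_per_colony_day = params$R_Cd)
  hab25 <- habitat_model(params$Da, params$At, params$F_R,
                         habitat_length = params$L_r25, habitat_width = params$W,
                         daily_factor = params$daily_factor)
  hab50 <- habitat_model(params$Da, params$At, params$F_R,
                         habitat_length = params$L_r50, habitat_width = params$W,
                         daily_factor = params$daily_factor)
  TRC_r25 <- trc_size(bio, hab25)
  TRC_r50 <- trc_size(bio, hab50)

  # --- sampling nulls -----------------------------------------------------
  null25 <- null_summary(build_cohort(TRC_r25, s), n, iterations, seed = seed)
  null50 <- null_summary(build_cohort(TRC_r50, s), n, iterations, seed = seed + 1L)

  # --- empirical sibship --------------------------------------------------
  acc <- accept_pairs(pairs, 0.75)
  recruits <- sprintf("R%03d", seq_len(n))
  part <- families_from_pairs(acc, recruits)
  ksum <- kin_summary(part, n = n)
  emp <- composition_from_partition(part, s)

  # --- radius inference ---------------------------------------------------
  rp <- rp_rate(null25$mean[2L], null50$mean[2L])
  sol <- solve_radius(params$sp_emp, rp, r25 = params$r25)
  TRC_rRp <- trc_from_disc_radius(sol$r_Rp, bio, hab25)
  cmax <- radius_from_colonies(params$R_Cd * ksum$Cmax, R_Cd = params$R_Cd,
                               C_A = params$C_A_rounded, F_R = params$F_R)

  # --- scoring ------------------------------------------------------------
  null_rp <- null_summary(build_cohort(TRC_rRp, s), n, iterations, seed = seed + 2L)
  weights <- build_weights(null_rp)
  emp_score <- score_composition(emp, weights)
  tail <- tail_probability(emp_score, build_cohort(TRC_rRp, s), n, weights,
                           iterations = score_iterations, seed = seed + 3L)
  search <- confidence_trc_search(emp, n = n, s = s, alpha = 0.05,
                                  iterations = search_iterations,
                                  seed = seed + 4L, t_max = 4 * TRC_rRp)
  riRCS <- radius_from_colonies(search$T_star, R_Cd = params$R_Cd,
                                C_A = params$C_A_rounded, F_R = params$F_R)

  report <- list(
    settings = list(params = params, seed = seed, iterations = iterations,
                    score_iterations = score_iterations,
                    search_iterations = search_iterations,
                    conventions = list(
                      forward_C_A = hab25$C_A,
                      inverse_C_A = params$C_A_rounded,
                      daily_factor = params$daily_factor,
                      radius_halving = "linear")),
    demography = list(R_Cd = recruits_per_colony_day(bio),
                      C_A = hab25$C_A,
                      A_r25 = habitat_area(hab25), A_r50 = habitat_area(hab50),
                      TRC_r25 = TRC_r25, TRC_r50 = TRC_r50),
    nulls = list(
      r25 = list(mean = null25$mean, se = null25$se, seed = null25$seed),
      r50 = list(mean = null50$mean, se = null50$se, seed = null50$seed)),
    sibship = ksum[c("n", "n_families", "recruits_with_kin", "pct_with_kin",
                     "singletons", "Cmax", "Cmax_collapsed")],
    sibship_composition = as.integer(emp),
    radius = list(Rp = rp$Rp, n_halve = sol$n_halve, r_Rp = sol$r_Rp,
                  A_Rp = pi * sol$r_Rp^2, TRC_rRp = TRC_rRp,
                  TRC_Cmax = params$R_Cd * ksum$Cmax,
                  A_Cmax = cmax$area, r_Cmax = cmax$radius),
    score_test = list(weights = as.numeric(weights),
                      null_mean = null_rp$mean,
                      empirical_score = emp_score,
                      tail_probability = tail$tail_probability,
                      iterations = tail$iterations, seed = tail$seed),
    confidence_search = list(TRC_riRCS = search$T_star,
                             A_riRCS = riRCS$area, r_iRCS = riRCS$radius,
                             alpha = search$alpha, boundary = search$boundary,
                             seed = search$seed)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
    return(invisible(report))
  }
  report
}

#' Human-readable rendering of a pipeline report
#'
#' @param report Output of [run_full_pipeline()].
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  d <- report$demography; r <- report$radius; sb <- report$sibship
  st <- report$score_test; cs <- report$confidence_search
  c("Kin-structured recruitment analysis",
    "===================================",
    sprintf("seed %d | %d null draws | daily_factor %.2f | forward C_A %.1f | inverse C_A %d",
            report$settings$seed, report$settings$iterations,
            report$settings$conventions$daily_factor,
            report$settings$conventions$forward_C_A,
            as.integer(report$settings$conventions$inverse_C_A)),
    "",
    sprintf("TRC_r25 = %d (area %.1f km^2) ; TRC_r50 = %d (area %.1f km^2)",
            d$TRC_r25, d$A_r25, d$TRC_r50, d$A_r50),
    sprintf("null mean pairs: r25 %.3f ; r50 %.3f",
            report$nulls$r25$mean[2], report$nulls$r50$mean[2]),
    sprintf("Rp = %.3f ; n_halve = %.3f ; r_Rp = %.3f km ; TRC_rRp = %d",
            r$Rp, r$n_halve, r$r_Rp, r$TRC_rRp),
    sprintf("sibship: %d families, %d of %d recruits with kin (%.0f%%), Cmax = %d (collapsed %d)",
            sb$n_families, sb$recruits_with_kin, sb$n, 100 * sb$pct_with_kin,
            sb$Cmax, sb$Cmax_collapsed),
    sprintf("TRC_Cmax = %d ; A_Cmax = %.3f km^2 ; r_Cmax = %.3f km",
            r$TRC_Cmax, r$A_Cmax, r$r_Cmax),
    sprintf("empirical score %.0f ; tail probability %.2e (%d draws)",
            st$empirical_score, st$tail_probability, st$iterations),
    sprintf("TRC_riRCS = %s ; r_iRCS = %.3f km (alpha %.2f)",
            format(cs$TRC_riRCS), cs$r_iRCS, cs$alpha))
}
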