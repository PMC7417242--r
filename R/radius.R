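#' Radius-halving rate of sibling-pair enrichment
#'
#' The rate `Rp` at which the mean sibling-pair count in a fixed-size sample
#' grows as the source radius is halved: `Rp = SP_r25 / SP_r50`, estimated
#' from the Monte Carlo nulls at 25 km and 50 km.
#'
#' @param sp_r25 Mean sibling-pair count per draw for the 25 km cohort.
#' @param sp_r50 Mean sibling-pair count per draw for the 50 km cohort.
#' @return An object of class `rp_estimate`: list with `sp_r25`, `sp_r50`,
#'   `Rp`.
#' @examples
#' rp_rate(3.49, 1.47)$Rp # 2.37
#' @export
rp_rate <- function(sp_r25, sp_r50) {
  stopifnot(is.numeric(sp_r25), is.numeric(sp_r50))
  if (sp_r50 <= 0) stop("sp_r50 must be > 0", call. = FALSE)
  structure(list(sp_r25 = sp_r25, sp_r50 = sp_r50, Rp = sp_r25 / sp_r50),
            class = "rp_estimate")
}

#' Source radius compatible with an empirical sibling-pair count
#'
#' How many times must the 25 km radius shrink for random sampling to yield as
#' many sibling pairs as observed? `n_halve = sp_emp / (Rp * sp_r25)`, and the
#' implied radius is the linear division `r_Rp = r25 / n_halve` (matching the
#' published arithmetic `25/5.8 = 4.31`). Set `geometric = TRUE` for the
#' alternative reading `r_Rp = r25 / 2^n_halve`, which treats `n_halve` as a
#' number of successive halvings; it is off by default.
#'
#' @param sp_emp Empirical sibling-pair count (48 in the study).
#' @param rp An [rp_rate()] object.
#' @param r25 Reference radius in km (default 25).
#' @param geometric Interpret `n_halve` as successive halvings (default
#'   `FALSE`, linear division).
#' @return List with `n_halve`, `r_Rp` (km) and the inputs.
#' @examples
#' solve_radius(48, rp_rate(3.49, 1.47))$r_Rp # ~4.3 km
#' @export
solve_radius <- function(sp_emp, rp, r25 = 25, geometric = FALSE) {
  stopifnot(inherits(rp, "rp_estimate"), sp_emp > 0, r25 > 0)
  n_halve <- sp_emp / (rp$Rp * rp$sp_r25)
  r_Rp <- if (geometric) r25 / 2^n_halve else r25 / n_halve
  list(sp_emp = sp_emp, Rp = rp$Rp, n_halve = n_halve, r25 = r25, r_Rp = r_Rp,
       geometric = geometric)
}

#' Cohort size from a disc-shaped source region
#'
#' Converts a radius (or a directly supplied area, e.g. a published rounded
#' value) into a cohort size via the forward demographic formula with the
#' module's `C_A` and `daily_factor` conventions.
#'
#' @param r Radius in km; ignored if `area` is supplied.
#' @param bio A [colony_biology()] object.
#' @param hab A [habitat_model()] object.
#' @param area Optional area in km^2 overriding `pi * r^2`.
#' @param C_A Optional colony density override.
#' @return Cohort size (count, rounded half-up).
#' @examples
#' bio <- colony_biology(recruits_per_colony_day = 6)
#' hab <- habitat_model()
#' trc_from_disc_radius(4.31, bio, hab)
#' @export
trc_from_disc_radius <- function(r = NULL, bio, hab, area = NULL, C_A = NULL) {
  if (is.null(area)) {
    stopifnot(!is.null(r), r >= 0)
    area <- pi * r^2
  }
  trc_size(bio, hab, area = area, C_A = C_A)
}

#' Habitat area and radius backing a given cohort size
#'
#' The inverse calculation used for the colony-count scenarios: the area of
#' habitat whose colonies produce a cohort of `TRC` recruits,
#' `A = TRC / (R_Cd * C_A * F_R)`, and the disc radius `r = sqrt(A / pi)`.
#' Following the published arithmetic, this inverse uses the rounded colony
#' density (102 per km^2 by default) and no daily factor; both choices are
#' explicit arguments, never silent.
#'
#' @param TRC Cohort size.
#' @param R_Cd Daily recruit output per colony (default 6).
#' @param C_A Colony density per km^2 (default the rounded 102).
#' @param F_R Reproductive female fraction (default 0.33).
#' @return List with `area` (km^2) and `radius` (km).
#' @examples
#' radius_from_colonies(720)$radius # ~1.066 km
#' @export
radius_from_colonies <- function(TRC, R_Cd = 6, C_A = 102, F_R = 0.33) {
  stopifnot(TRC >= 0, R_Cd > 0, C_A > 0, F_R > 0)
  A <- TRC / (R_Cd * C_A * F_R)
  list(TRC = TRC, area = A, radius = sqrt(A / pi), R_Cd = R_Cd, C_A = C_A,
       F_R = F_R)
}
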