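#' Colony reproductive biology parameters
#'
#' Bundles the per-colony fecundity and survival parameters that determine how
#' many settlement-competent larvae an average colony contributes to a reef's
#' recruiting pool on a given day.
#'
#' @param eggs_per_colony Average number of eggs per colony (`E`).
#' @param hatch_rate Fraction of a clutch that hatches (`H`), in `[0, 1]`.
#' @param daily_hatch_fraction Fraction of eggs hatching on a given day
#'   (`Hd`), in `[0, 1]`.
#' @param pld_survival Probability that a hatched larva survives the pelagic
#'   larval duration and recruits (`S`), in `[0, 1]`.
#' @param recruits_per_colony_day Optional: supply the daily per-colony
#'   recruit output directly instead of deriving it as `E * H * Hd * S`.
#'   Published demographic tables typically round this to an integer, so a
#'   supplied value overrides the derived one throughout.
#'
#' @return An object of class `colony_biology`.
#' @seealso [recruits_per_colony_day()], [trc_size()]
#' @export
colony_biology <- function(eggs_per_colony = 803,
                           hatch_rate = 0.5,
                           daily_hatch_fraction = 0.5,
                           pld_survival = 0.03,
                           recruits_per_colony_day = NULL) {
  stopifnot(is.numeric(eggs_per_colony), length(eggs_per_colony) == 1L,
            eggs_per_colony >= 0)
  for (f in list(hatch_rate = hatch_rate,
                 daily_hatch_fraction = daily_hatch_fraction,
                 pld_survival = pld_survival)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
      stop("hatch_rate, daily_hatch_fraction and pld_survival must be single values in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.null(recruits_per_colony_day) &&
      (!is.numeric(recruits_per_colony_day) || recruits_per_colony_day < 0)) {
    stop("recruits_per_colony_day must be >= 0", call. = FALSE)
  }
  structure(
    list(E = eggs_per_colony, H = hatch_rate, Hd = daily_hatch_fraction,
         S = pld_survival, R_Cd = recruits_per_colony_day),
    class = "colony_biology"
  )
}

#' Daily recruit output of an average colony
#'
#' The expected number of larvae produced per colony per day that survive the
#' pelagic phase and recruit: `R_Cd = E * H * Hd * S`. If the
#' [colony_biology()] object carries a supplied `R_Cd`, that value is returned
#' unchanged.
#'
#' @param bio A [colony_biology()] object.
#' @return A single nonnegative number (recruits per colony per day).
#' @examples
#' recruits_per_colony_day(colony_biology(803, 0.5, 0.5, 0.03)) # ~6
#' @export
recruits_per_colony_day <- function(bio) {
  stopifnot(inherits(bio, "colony_biology"))
  if (!is.null(bio$R_Cd)) return(bio$R_Cd)
  bio$E * bio$H * bio$Hd * bio$S
}

#' Habitat geometry and colony density
#'
#' Describes the reef habitat that supplies recruits: colony density measured
#' on belt transects (`C_A = Da / At`), the fraction of simultaneously
#' reproductive females, and the geometry used to convert a source radius into
#' habitat area. Two geometries are supported: `"strip"` (a coastal band of
#' length `L` and width `W`, how the fringing-reef habitat is measured from
#' imagery) and `"disc"` (`pi * r^2`, used for the inverse radius
#' calculations).
#'
#' @param colonies_per_transect Mean colony count per belt transect (`Da`).
#' @param transect_area Belt transect area in km^2 (`At`).
#' @param reproductive_female_fraction Fraction of females spawning
#'   simultaneously (`F_R`), in `[0, 1]`.
#' @param habitat_length,habitat_width Strip geometry, km.
#' @param radius Disc geometry radius, km.
#' @param area_mode `"strip"` or `"disc"`.
#' @param daily_factor Multiplier applied in [trc_size()] converting the
#'   standing reproductive output into a single night's cohort; defaults to
#'   0.5, the fraction of ripe clutches hatching on any one day. See the
#'   package vignette for why this factor is exposed explicitly.
#'
#' @return An object of class `habitat_model` with derived density `C_A`
#'   (colonies per km^2).
#' @export
habitat_model <- function(colonies_per_transect = 10.23,
                          transect_area = 0.1,
                          reproductive_female_fraction = 0.33,
                          habitat_length = NULL,
                          habitat_width = NULL,
                          radius = NULL,
                          area_mode = c("strip", "disc"),
                          daily_factor = 0.5) {
  area_mode <- match.arg(area_mode)
  stopifnot(transect_area > 0, colonies_per_transect >= 0)
  if (reproductive_female_fraction < 0 || reproductive_female_fraction > 1) {
    stop("reproductive_female_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(Da = colonies_per_transect, At = transect_area,
         C_A = colonies_per_transect / transect_area,
         F_R = reproductive_female_fraction,
         L = habitat_length, W = habitat_width, r = radius,
         area_mode = area_mode, daily_factor = daily_factor),
    class = "habitat_model"
  )
}

#' Habitat area for a source region
#'
#' Strip mode returns `L * W`; disc mode returns `pi * r^2`.
#'
#' @param hab A [habitat_model()] object.
#' @return Area in km^2.
#' @examples
#' habitat_area(habitat_model(habitat_length = 160, habitat_width = 1.2)) # 192
#' @export
habitat_area <- function(hab) {
  stopifnot(inherits(hab, "habitat_model"))
  if (hab$area_mode == "strip") {
    if (is.null(hab$L) || is.null(hab$W)) {
      stop("strip mode requires habitat_length and habitat_width", call. = FALSE)
    }
    hab$L * hab$W
  } else {
    if (is.null(hab$r)) stop("disc mode requires radius", call. = FALSE)
    pi * hab$r^2
  }
}

# Round half away from zero; base round() is round-half-even, which would
# report 19444 for 19444.5-type boundaries in published tables.
round_half_up <- function(x) floor(x + 0.5)

#' Size of the theoretical total recruiting cohort
#'
#' The number of larvae theoretically arriving at the focal reef on the
#' sampling night from habitat of a given area:
#' `TRC = R_Cd * C_A * F_R * daily_factor * area`, rounded half-up to an
#' integer.
#'
#' @param bio A [colony_biology()] object.
#' @param hab A [habitat_model()] object (supplies `C_A`, `F_R` and
#'   `daily_factor`).
#' @param area Habitat area in km^2; defaults to [habitat_area()] of `hab`.
#' @param C_A Override for the colony density, e.g. the rounded 102 colonies
#'   per km^2 used in some published back-calculations rather than the exact
#'   `Da/At`.
#' @param round Return an integer count (default) or the full-precision value.
#' @return Cohort size (count).
#' @examples
#' bio <- colony_biology(recruits_per_colony_day = 6)
#' hab <- habitat_model(habitat_length = 160, habitat_width = 1.2)
#' trc_size(bio, hab) # 19445
#' @export
trc_size <- function(bio, hab, area = habitat_area(hab), C_A = NULL,
                     round = TRUE) {
  stopifnot(inherits(bio, "colony_biology"), inherits(hab, "habitat_model"))
  if (area < 0) stop("area must be >= 0", call. = FALSE)
  dens <- if (is.null(C_A)) hab$C_A else C_A
  x <- recruits_per_colony_day(bio) * dens * hab$F_R * hab$daily_factor * area
  if (round) round_half_up(x) else x
}

#' Partition a recruiting cohort into sibling families
#'
#' Realizes the family structure the sampling null assumes: `K = floor(N_T/s)`
#' families of exactly `s` siblings each. A remainder of fewer than `s`
#' recruits is discarded, so the realized cohort size is `K * s`. Family
#' membership is positional: recruit `i` belongs to family
#' `floor((i-1)/s) + 1`.
#'
#' @param N_T Nominal cohort size.
#' @param s Family size (default 6, the average per-colony daily recruit
#'   output).
#' @return An object of class `recruit_cohort` with elements `n_families`,
#'   `family_size`, `size` (realized `K * s`) and `nominal_size`.
#' @examples
#' build_cohort(720, 6)$n_families # 120
#' @export
build_cohort <- function(N_T, s = 6L) {
  stopifnot(is.numeric(N_T), is.numeric(s), length(N_T) == 1L, length(s) == 1L)
  s <- as.integer(s)
  if (s < 1L) stop("family size s must be >= 1", call. = FALSE)
  if (N_T < s) stop("cohort smaller than one family (N_T < s)", call. = FALSE)
  K <- as.integer(N_T %/% s)
  structure(
    list(n_families = K, family_size = s, size = K * s,
         nominal_size = as.integer(round_half_up(N_T))),
    class = "recruit_cohort"
  )
}

#' Family label of each recruit in a cohort
#'
#' @param cohort A [build_cohort()] object.
#' @return Integer vector of length `cohort$size` assigning each recruit
#'   index to a family in `1..n_families`.
#' @export
family_labels <- function(cohort) {
  stopifnot(inherits(cohort, "recruit_cohort"))
  rep(seq_len(cohort$n_families), each = cohort$family_size)
}

#' @export
print.recruit_cohort <- function(x, ...) {
  cat(sprintf("Recruit cohort: %d recruits in %d families of %d (nominal %d)\n",
              x$size, x$n_families, x$family_size, x$nominal_size))
  invisible(x)
}
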