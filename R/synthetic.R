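# Synthetic colony pedigrees and biallelic SNP genotypes with the statistical
# structure the kinship analysis assumes: a panel of independent loci with a
# minor-allele-frequency floor, haremic colonies of ~6 same-cohort offspring
# sired by one or two males with multiple dams, Mendelian transmission,
# symmetric allele-level genotyping error, and uniform missingness.

#' Sample a biallelic locus panel
#'
#' Allele frequencies drawn uniformly on the band `[maf_min, 1 - maf_min]`,
#' emulating a panel selected for a minor allele frequency above `maf_min`.
#'
#' @param n_loci Number of loci (default 300).
#' @param maf_min Minor-allele-frequency floor in `[0, 0.5)` (default 0.33).
#' @return An object of class `locus_panel`: numeric frequency vector with
#'   attribute `maf_min`.
#' @export
sample_panel <- function(n_loci = 300, maf_min = 0.33) {
  stopifnot(n_loci >= 0)
  if (maf_min < 0 || maf_min >= 0.5) {
    stop("maf_min must be in [0, 0.5)", call. = FALSE)
  }
  p <- stats::runif(n_loci, maf_min, 1 - maf_min)
  structure(p, maf_min = maf_min, class = "locus_panel")
}

#' Colony pedigree specification
#'
#' @param n_colonies Number of colonies to simulate.
#' @param sires_per_colony 1 (the typical haremic structure) or 2 (the
#'   multi-sire deviation seen in the larger empirical sibling groups).
#' @param dams_per_colony Number of dams (default 3).
#' @param offspring_per_colony Recruits per colony entering the cohort
#'   (default 6).
#' @param missing_rate Per-genotype-call missingness in `[0, 0.15]`
#'   (default 0.05).
#' @param error_rate Allele-level genotyping error in `[0, 0.1]`
#'   (default 0.01).
#' @return An object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(n_colonies = 1, sires_per_colony = 1,
                          dams_per_colony = 3, offspring_per_colony = 6,
                          missing_rate = 0.05, error_rate = 0.01) {
  stopifnot(n_colonies >= 1, dams_per_colony >= 1, offspring_per_colony >= 1)
  if (!sires_per_colony %in% c(1L, 2L)) {
    stop("sires_per_colony must be 1 or 2", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 0.15) {
    stop("missing_rate must be in [0, 0.15]", call. = FALSE)
  }
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must be in [0, 0.1]", call. = FALSE)
  }
  structure(list(n_colonies = as.integer(n_colonies),
                 sires_per_colony = as.integer(sires_per_colony),
                 dams_per_colony = as.integer(dams_per_colony),
                 offspring_per_colony = as.integer(offspring_per_colony),
                 missing_rate = missing_rate, error_rate = error_rate),
            class = "pedigree_spec")
}

hwe_parent <- function(p) stats::rbinom(length(p), 2L, p)

# one gamete from a 0/1/2 parent genotype: transmitted allele count
gamete <- function(g) stats::rbinom(length(g), 1L, g / 2)

# flip a 0/1 allele vector symmetrically with probability error_rate
flip_alleles <- function(a, error_rate) {
  if (error_rate <= 0) return(a)
  flip <- stats::runif(length(a)) < error_rate
  ifelse(flip, 1L - a, a)
}

#' Simulate one colony's parents and offspring
#'
#' Parents are drawn in Hardy-Weinberg proportions from the panel
#' frequencies; each offspring receives one Mendelian allele per parent per
#' locus from a sire and a dam drawn at random from the colony's parents.
#' Genotyping error flips transmitted alleles symmetrically at
#' `spec$error_rate`; missingness masks calls at `spec$missing_rate`. With two
#' sires, offspring of different sires but the same dam are half sibs through
#' the dam, so mixed full-/half-sib patterns arise within one colony.
#'
#' @param panel A [sample_panel()].
#' @param spec A [pedigree_spec()] (its `n_colonies` is ignored here).
#' @return List with `offspring` (matrix, offspring x loci), `sires`, `dams`
#'   (true parental genotypes, error-free), and `pedigree` (data frame:
#'   offspring, sire, dam).
#' @export
simulate_colony <- function(panel, spec = pedigree_spec()) {
  stopifnot(inherits(panel, "locus_panel"), inherits(spec, "pedigree_spec"))
  p <- as.numeric(panel)
  sires <- lapply(seq_len(spec$sires_per_colony), function(i) hwe_parent(p))
  dams <- lapply(seq_len(spec$dams_per_colony), function(i) hwe_parent(p))
  n_off <- spec$offspring_per_colony
  off <- matrix(NA_integer_, n_off, length(p))
  sid <- sample.int(spec$sires_per_colony, n_off, replace = TRUE)
  did <- sample.int(spec$dams_per_colony, n_off, replace = TRUE)
  for (i in seq_len(n_off)) {
    g <- flip_alleles(gamete(sires[[sid[i]]]), spec$error_rate) +
      flip_alleles(gamete(dams[[did[i]]]), spec$error_rate)
    if (spec$missing_rate > 0) g[stats::runif(length(g)) < spec$missing_rate] <- NA
    off[i, ] <- g
  }
  rownames(off) <- paste0("off", seq_len(n_off))
  list(offspring = off,
       sires = do.call(rbind, sires), dams = do.call(rbind, dams),
       pedigree = data.frame(offspring = rownames(off), sire = sid, dam = did))
}

#' Generate a genotyped, family-structured recruiting cohort
#'
#' Simulates `K = N_T %/% s` colonies of `s` offspring each and stacks their
#' genotypes into the cohort the sampling machinery draws from, with true
#' pedigree labels aligned to the positional family structure of
#' [build_cohort()].
#'
#' @param N_T Nominal cohort size.
#' @param s Offspring (family size) per colony; overrides
#'   `spec$offspring_per_colony`.
#' @param panel A [sample_panel()] (a fresh default panel if missing).
#' @param spec A [pedigree_spec()] supplying the sire/dam structure, error
#'   and missingness.
#' @return List with `G` (recruits x loci genotype matrix), `cohort` (the
#'   matching [build_cohort()]), `pedigree` (data frame: id, colony, sire,
#'   dam — sire/dam ids are globally unique), and `panel`.
#' @export
generate_trc_genotyped <- function(N_T, s = 6, panel = sample_panel(),
                                   spec = pedigree_spec()) {
  cohort <- build_cohort(N_T, s)
  spec$offspring_per_colony <- cohort$family_size
  K <- cohort$n_families
  Gs <- vector("list", K)
  ped <- vector("list", K)
  for (k in seq_len(K)) {
    col <- simulate_colony(panel, spec)
    Gs[[k]] <- col$offspring
    ped[[k]] <- data.frame(
      colony = k,
      sire = sprintf("c%d_s%d", k, col$pedigree$sire),
      dam = sprintf("c%d_d%d", k, col$pedigree$dam))
  }
  G <- do.call(rbind, Gs)
  rownames(G) <- sprintf("R%04d", seq_len(nrow(G)))
  colnames(G) <- sprintf("L%03d", seq_len(ncol(G)))
  ped <- do.call(rbind, ped)
  ped <- data.frame(id = rownames(G), ped, stringsAsFactors = FALSE)
  list(G = G, cohort = cohort, pedigree = ped, panel = panel)
}

#' True relationship class of a pair from a pedigree
#'
#' @param ped Pedigree data frame with columns `id`, `sire`, `dam`.
#' @param i,j Individual ids.
#' @return `"FS"`, `"HS"` or `"U"` by the number of shared parents (2, 1, 0).
#' @export
true_relationship <- function(ped, i, j) {
  a <- ped[match(i, ped$id), ]
  b <- ped[match(j, ped$id), ]
  shared <- (a$sire == b$sire) + (a$dam == b$dam)
  c("U", "HS", "FS")[shared + 1L]
}
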