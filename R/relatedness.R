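# Pairwise relatedness classification from biallelic SNP genotypes.
#
# Genotypes are coded 0/1/2 (count of one arbitrary reference allele per
# locus, NA = missing). Relationship classes are parameterized by IBD-sharing
# coefficients (k0, k1, k2) = P(pair shares 0, 1, 2 alleles identical by
# descent): unrelated U = (1, 0, 0), half sibs HS = (1/2, 1/2, 0), full sibs
# FS = (1/4, 1/2, 1/4). Loci are treated as independent (the study panel was
# selected in linkage equilibrium).

# Per-locus 3 x 3 x L log-likelihood tables of observed genotype pairs under
# each class. HWE genotype frequencies; IBD1 conditionals share one allele
# drawn at random from the first genotype, the other drawn from the
# population. Genotyping error enters as a contamination mixture: with
# probability eps the observed pair is an independent draw from the unrelated
# distribution, keeping every log-likelihood finite.
pair_class_tables <- function(p, eps = 0.01) {
  stopifnot(all(p > 0), all(p < 1), eps > 0, eps <= 0.1)
  q <- 1 - p
  G <- rbind(q^2, 2 * p * q, p^2)          # genotype 0,1,2 frequencies
  L <- length(p)
  C1 <- array(0, c(3, 3, L))               # P(g2 | g1, one allele IBD)
  C1[1, 1, ] <- q;     C1[1, 2, ] <- p
  C1[2, 1, ] <- q / 2; C1[2, 2, ] <- 0.5; C1[2, 3, ] <- p / 2
  C1[3, 2, ] <- q;     C1[3, 3, ] <- p
  PU <- P1 <- P2 <- array(0, c(3, 3, L))
  for (a in 1:3) {
    for (b in 1:3) {
      PU[a, b, ] <- G[a, ] * G[b, ]
      P1[a, b, ] <- G[a, ] * C1[a, b, ]
      P2[a, b, ] <- G[a, ] * (a == b)
    }
  }
  mix <- function(P) log((1 - eps) * P + eps * PU)
  list(U = mix(PU),
       HS = mix(0.5 * PU + 0.5 * P1),
       FS = mix(0.25 * PU + 0.5 * P1 + 0.25 * P2))
}

#' Sample allele frequencies of a genotype matrix
#'
#' @param G Individuals x loci matrix of 0/1/2 codes with `NA` for missing.
#' @return Numeric vector: per-locus frequency of the allele counted by the
#'   codes.
#' @export
allele_freqs <- function(G) {
  colMeans(G, na.rm = TRUE) / 2
}

#' Classify all pairs of individuals by IBD relationship class
#'
#' For every pair of rows of `G`, computes multilocus log-likelihoods under
#' the unrelated (U), half-sib (HS) and full-sib (FS) IBD classes, calls the
#' maximum-likelihood class (ties go to U), and reports a sib posterior
#' `(L_HS + L_FS) / (L_U + L_HS + L_FS)` under a uniform class prior. Loci
#' missing in either member of a pair are skipped for that pair; monomorphic
#' loci are excluded up front with a warning (they carry no pairwise
#' information).
#'
#' @param G Individuals x loci genotype matrix (0/1/2/`NA`); rownames are
#'   used as individual identifiers.
#' @param eps Genotyping error rate mixed into the likelihood, in `(0, 0.1]`
#'   (default 0.01).
#' @param freqs Optional per-locus allele frequencies; estimated from `G` by
#'   default. Supply the adult-population frequencies when available.
#' @return A data frame with one row per pair: `i`, `j`, `logl_U`, `logl_HS`,
#'   `logl_FS`, `call` (factor U/HS/FS) and `posterior_sib`.
#' @export
pairwise_relatedness <- function(G, eps = 0.01, freqs = NULL) {
  G <- as.matrix(G)
  if (is.null(rownames(G))) rownames(G) <- paste0("ind", seq_len(nrow(G)))
  if (is.null(freqs)) freqs <- allele_freqs(G)
  poly <- freqs > 0 & freqs < 1 & !is.na(freqs)
  if (!all(poly)) {
    warning(sprintf("excluding %d monomorphic or all-missing loci",
                    sum(!poly)), call. = FALSE)
    G <- G[, poly, drop = FALSE]
    freqs <- freqs[poly]
  }
  if (ncol(G) == 0L) stop("no polymorphic loci left", call. = FALSE)
  tabs <- pair_class_tables(freqs, eps)
  n <- nrow(G)
  np <- n * (n - 1L) / 2L
  out_i <- out_j <- character(np)
  lu <- lh <- lf <- numeric(np)
  locs <- seq_len(ncol(G))
  r <- 0L
  for (i in seq_len(n - 1L)) {
    gi <- G[i, ]
    for (j in (i + 1L):n) {
      gj <- G[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      idx <- cbind(gi[ok] + 1L, gj[ok] + 1L, locs[ok])
      r <- r + 1L
      out_i[r] <- rownames(G)[i]; out_j[r] <- rownames(G)[j]
      lu[r] <- sum(tabs$U[idx]); lh[r] <- sum(tabs$HS[idx])
      lf[r] <- sum(tabs$FS[idx])
    }
  }
  ll <- cbind(U = lu, HS = lh, FS = lf)
  # argmax with ties to U: U wins at >=, then HS over FS
  call <- rep("U", np)
  call[lh > lu & lh >= lf] <- "HS"
  call[lf > lu & lf > lh] <- "FS"
  m <- pmax(lu, lh, lf)
  pu <- exp(lu - m); ph <- exp(lh - m); pf <- exp(lf - m)
  data.frame(i = out_i, j = out_j,
             logl_U = lu, logl_HS = lh, logl_FS = lf,
             call = factor(call, levels = c("U", "HS", "FS")),
             posterior_sib = (ph + pf) / (pu + ph + pf),
             stringsAsFactors = FALSE)
}

#' Convert relatedness calls to pair assignments
#'
#' Maps classifier output onto the pair-assignment form consumed by
#' [accept_pairs()] and [families_from_pairs()]: pairs called HS or FS, with
#' `posterior` set to the sib posterior. Pairwise likelihood posteriors are
#' less conservative than joint sibship-reconstruction posteriors, so the
#' downstream acceptance threshold for these is typically stricter (0.95
#' rather than 0.75; see the package vignette).
#'
#' @param rel Output of [pairwise_relatedness()].
#' @return A data frame with columns `i`, `j`, `relation`, `posterior`.
#' @export
as_pair_assignments <- function(rel) {
  sib <- rel[rel$call != "U", , drop = FALSE]
  data.frame(i = sib$i, j = sib$j,
             relation = ifelse(sib$call == "FS", "full_sib", "half_sib"),
             posterior = sib$posterior_sib,
             stringsAsFactors = FALSE)
}
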