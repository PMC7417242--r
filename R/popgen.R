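# Standard single- and two-sample population-genetic summaries for biallelic
# SNP matrices (0/1/2/NA codes), matching the usual GenAlEx-style definitions.

# per-locus expected heterozygosity and effective allele number from the
# allele frequency of the counted allele
he_from_p <- function(p) 1 - (p^2 + (1 - p)^2)

#' Multilocus probability of identity
#'
#' The probability that two unrelated individuals drawn from the same
#' population share a multilocus genotype. Per locus with allele frequencies
#' `p_i`: `PI = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`; across loci the product
#' of per-locus values (returned on the log10 scale as well, since with
#' hundreds of informative loci the product underflows any printable scale).
#'
#' @param p Per-locus frequency of the counted allele (biallelic loci).
#' @return List with `per_locus` (vector), `product` and `log10`.
#' @examples
#' prob_identity(0.5)$per_locus # 0.375
#' @export
prob_identity <- function(p) {
  q <- 1 - p
  per <- p^4 + q^4 + (2 * p * q)^2
  list(per_locus = per, product = prod(per), log10 = sum(log10(per)))
}

sample_stats <- function(G) {
  p <- allele_freqs(G)
  he <- he_from_p(p)
  ho <- colMeans(G == 1L, na.rm = TRUE)
  ne <- 1 / (1 - he)
  mHe <- mean(he, na.rm = TRUE)
  mHo <- mean(ho, na.rm = TRUE)
  list(n = nrow(G), p = p,
       Ne = mean(ne, na.rm = TRUE), Ho = mHo, He = mHe,
       F_IS = (mHe - mHo) / mHe,
       PI = prob_identity(p[p > 0 & p < 1]))
}

#' Population-genetic summary of two samples
#'
#' Per-sample effective allele number (`Ne = 1/sum(p_i^2)` per locus,
#' averaged), observed and expected heterozygosity, inbreeding coefficient
#' `F_IS = (He - Ho)/He`, and multilocus probability of identity; plus the
#' between-sample fixation index `F_ST = (Ht - Hs)/Ht` (Nei's G_ST over the
#' two samples, from sums of per-locus heterozygosities) and its Hedrick
#' standardization `F'_ST = F_ST / F_ST_max` with
#' `F_ST_max = (k - 1)(1 - Hs) / (k - 1 + Hs)` for `k = 2` samples. Loci
#' missing entirely in one sample are dropped pairwise from the between-sample
#' statistics, with a message.
#'
#' @param G_A,G_B Genotype matrices (individuals x loci, same locus order)
#'   for the two samples.
#' @return An object of class `popgen_stats`: list with per-sample summaries
#'   `A` and `B` and between-sample `F_ST`, `F_ST_max`, `Fp_ST`, `Hs`, `Ht`.
#' @export
popgen_stats <- function(G_A, G_B) {
  G_A <- as.matrix(G_A); G_B <- as.matrix(G_B)
  if (ncol(G_A) != ncol(G_B)) {
    stop("the two samples must be genotyped at the same loci", call. = FALSE)
  }
  A <- sample_stats(G_A)
  B <- sample_stats(G_B)
  ok <- !is.na(A$p) & !is.na(B$p)
  if (!all(ok)) {
    message(sprintf("dropping %d loci missing in one sample from F_ST",
                    sum(!ok)))
  }
  pA <- A$p[ok]; pB <- B$p[ok]
  hs <- (he_from_p(pA) + he_from_p(pB)) / 2
  ht <- he_from_p((pA + pB) / 2)
  Hs <- mean(hs); Ht <- mean(ht)
  F_ST <- if (Ht > 0) (Ht - Hs) / Ht else 0
  F_ST_max <- (2 - 1) * (1 - Hs) / (2 - 1 + Hs)
  structure(
    list(A = A[c("n", "Ne", "Ho", "He", "F_IS", "PI")],
         B = B[c("n", "Ne", "Ho", "He", "F_IS", "PI")],
         Hs = Hs, Ht = Ht, F_ST = F_ST, F_ST_max = F_ST_max,
         Fp_ST = F_ST / F_ST_max),
    class = "popgen_stats"
  )
}

#' @export
print.popgen_stats <- function(x, ...) {
  f <- function(s, nm) sprintf("%s: n=%d Ne=%.3f Ho=%.3f He=%.3f FIS=%.3f log10(PI)=%.1f",
                               nm, s$n, s$Ne, s$Ho, s$He, s$F_IS, s$PI$log10)
  cat(f(x$A, "A"), "\n", f(x$B, "B"), "\n", sep = "")
  cat(sprintf("F_ST=%.4f  F'_ST=%.4f\n", x$F_ST, x$Fp_ST))
  invisible(x)
}
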