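# Exhaustive-enumeration oracle for the expected sibship composition on
# cohorts small enough to list every possible draw.
enum_expected_composition <- function(N, s, n) {
  draws <- utils::combn(N, n)
  acc <- numeric(s)
  for (col in seq_len(ncol(draws))) {
    fam <- (draws[, col] - 1L) %/% s
    sz <- rle(sort(fam))$lengths
    acc <- acc + tabulate(sz, nbins = s)
  }
  stats::setNames(acc / ncol(draws), paste0("c", seq_len(s)))
}

# Table-of-record parameter objects used across tests
bio6 <- function() colony_biology(recruits_per_colony_day = 6)
hab_r25 <- function() habitat_model(habitat_length = 160, habitat_width = 1.2)
hab_r50 <- function() habitat_model(habitat_length = 387, habitat_width = 1.2)

# The empirical sibship composition: 89 singletons, 20 pairs, 10 triplets,
# 1 quadruplet, 1 quintuplet over the 168-recruit sample
empirical_composition <- function() sibship_composition(c(89, 20, 10, 1, 1, 0), 168)

# Offspring-vs-parents Mendelian compatibility at one biallelic locus:
# each parent must be able to donate one of the child's two alleles.
mendel_compatible <- function(child, sire, dam) {
  if (is.na(child)) return(TRUE)
  can_give <- function(par) switch(par + 1L, c(0L), c(0L, 1L), c(1L))
  for (a in can_give(sire)) {
    if ((child - a) %in% can_give(dam)) return(TRUE)
  }
  FALSE
}
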