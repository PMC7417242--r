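---
title: "Kin-structured recruitment: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin-structured recruitment: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinrecruit)
```

`kinrecruit` asks a single question of a single night's larval recruitment
pulse: is the amount of sibship inside a light-trap sample compatible with
random settlement out of a well-mixed larval pool? This vignette is the
package's own account of the models behind that question, the conventions and
numerical choices they required, and what the validation machinery does and
does not establish.

## The demographic null population

The sample is 168 settlement-stage damselfish larvae caught in one light
trap. The null hypothesis needs a population for that sample: the
*theoretical total recruiting cohort* (TRC), the complete larval pool
arriving at the reef that night. Its size follows from colony-level biology
and habitat geometry:

* `E` — eggs per colony (default 803);
* `H` — hatch rate per clutch (0.5, a consensus central value; anything in
  (0,1) is biologically possible);
* `Hd` — fraction of ripe eggs hatching on any one day (0.5);
* `S` — survival through the ~23-day pelagic larval phase (0.01–0.05;
  central value 0.03);
* `C_A` — colony density, 10.23 colonies per 0.1 km² belt transect =
  102.3 km⁻²;
* `F_R` — fraction of colonies with a simultaneously reproductive female
  (0.33);
* `A_r` — habitat area within a candidate source radius, measured as a
  coastal strip `L × W` (length along the coast × 1.2 km habitable width)
  for the 25 and 50 km radii, or as a disc `πr²` for the inverse
  calculations.

The per-colony daily output is `R_Cd = E·H·Hd·S = 6.02`, used as the rounded
6 throughout. The cohort is `TRC = R_Cd · C_A · F_R · d · A_r`.

**The daily factor `d`.** The product `R_Cd · C_A · F_R · A_r` alone does
not reproduce the tabulated cohort sizes this analysis is built around
(19,445 and 47,033 recruits for the 25 and 50 km scenarios); an additional
factor of 0.5 does, exactly, with `C_A = 102.3`. We therefore expose a
`daily_factor` defaulting to 0.5 — interpretable as the daily hatch fraction
applied at the cohort level — rather than bury the reconciliation. Setting
`daily_factor = 1` recovers the bare product.

**Two density conventions.** Forward cohort calculations use the exact
`C_A = Da/At = 102.3`; the inverse colony-count calculations
(`radius_from_colonies()`) use the rounded 102 km⁻² and no daily factor,
mirroring how such back-of-envelope arithmetic is conventionally printed.
Both are explicit arguments; neither is ever applied silently.

**Family structure.** Each contributing colony places `s = 6` siblings in
the cohort, so a TRC of nominal size `N` becomes `K = ⌊N/6⌋` complete
families; the remainder (at most 5 recruits out of 10³–10⁴) is discarded.
Family membership is positional, which makes sampling cheap and the
structure exactly exchangeable.

## The sampling null and its oracle

`draw_sample()` draws `n = 168` recruits uniformly without replacement and
tallies the *sibship composition* `c_k` — the number of families with
exactly `k` sampled members. A "sibling pair" is a family with exactly two
sampled members, not a count of dyads; this is the reading under which the
published per-draw means are recovered, and it makes `Σ k·c_k = n` an exact
per-draw invariant.

The number of sampled members of one family is hypergeometric, so the
expected composition has the closed form implemented in
`expected_composition()` (computed in log space;
`lchoose` keeps cohorts of 10⁵ exact). Every Monte Carlo mean is tested
against this oracle within three standard errors; for events too rare for
the simulation to observe, the Poisson standard error implied by the exact
expectation replaces the degenerate empirical one.

Monte Carlo summaries default to 10⁵ draws: the per-draw means then carry
standard errors of ~0.01 pairs, well below the two-decimal precision at
which such means are conventionally reported, at about ten seconds per
cohort on one core. Sensitivity beyond that is sampling-noise, not model.

## Radius inference

Halving the source radius roughly multiplies the mean pair count by a
constant `Rp` (≈ 2.37 between the 50 and 25 km scenarios; the mechanism is
the strict monotone decrease of `E[c_2]` in cohort size). The number of
halvings needed to reach the empirical 48 accepted sibling pairs is
`n = 48/(Rp·SP_r25)` and the compatible radius is the **linear** division
`r_Rp = 25/n ≈ 4.3 km`. A geometric reading (`25/2ⁿ`) is arguably the more
literal interpretation of "halved n times"; it is implemented behind
`geometric = TRUE` but off by default because the linear form is what the
published arithmetic this package reproduces actually computes. Printed
intermediates carry two-decimal rounding; all internal chaining is at full
precision, and tests allow the resulting ±1–2 recruit discrepancies.

## The score test

The published analysis scored compositions against the null with weights
"indirectly proportional" to event frequency, but the weight definition
itself was never printed — the literal score (142) and tail frequency
(0.015%) are reproducible only from the authors' deposited script, which
this package deliberately does not transcribe. We therefore define the
scheme explicitly and treat the literal numbers as non-reproducible
descriptors:

* weight of event size `k`: `w_k = round(1/max(mean_c_k, 1/iterations))`,
  capped at 1000, with `w_1 = 0` — rarer events weigh more, unseen events
  get a large finite weight;
* score of a composition: `Σ_k≥2 c_k·w_k` — zero iff no family has two or
  more sampled members, additive over disjoint compositions;
* tail probability: fraction of fresh null draws scoring at least the
  empirical score, with add-one smoothing so the estimate is never exactly
  zero. Ties count toward the tail (the conservative direction).

What replaces the unprintable constants is a percentile claim the test suite
computes: under these weights the empirical composition scores above the
99.9th percentile of the null of even the small radius-compatible cohort
(~5,900 recruits), i.e. the kinship in the sample is extreme against any
plausibly sized mixed pool.

**The confidence search.** `confidence_trc_search()` finds the largest
cohort size whose null still reaches the empirical score with probability
`alpha = 0.05`. Each candidate cohort defines its own null and its own
weights, so candidates are compared on their own terms. Two structural
points: tail probability *decreases* with cohort size (smaller pools make
kin-clumping likelier), which is what makes "largest compatible" the right
question; and the acceptance region is an *interval* — a cohort barely
larger than the sample forces near-complete families into every draw and
rejects the empirical composition just as surely as a huge one does. The
search therefore climbs from its lower bound to an accepted candidate,
doubles until rejection, and bisects the upper boundary to a granularity of
one family (6 recruits). On self-consistency runs (the empirical input
being the typical composition of a known cohort's null), the returned
boundary sits within one doubling step above the true size.

## Empirical sibship arithmetic

Pairwise sibship assignments enter as `(i, j, relation, posterior)` rows;
acceptance is *strict* (`posterior > 0.75`, so exactly 0.75 is rejected).
Families are connected components of the accepted-pair graph — sibship
treated as transitive — with singletons retained. The packaged table
`rcs_sibship_pairs()` is a *reconstruction*: the published record gives only
the assignment summary (3 full-sib pairs at posterior 1.0, 45 of 126
half-sib candidates above 0.75, 18 of those at or above 0.95, 32 families of
sizes 2×20, 3×10, 4, 5), so pair identities and exact posterior values are
synthetic, constrained to reproduce every one of those counts. One
consequence is preserved faithfully rather than resolved: the 48 accepted
pair assignments induce only 47 family merges (the quintuplet carries a
redundant edge), so the maximum-source-colony count is 120 by the
conventional pair arithmetic (`n − pairs`) but 121 by family collapse.
`kin_summary()` reports both.

## The relatedness classifier

As a desk-scale stand-in for full-likelihood sibship reconstruction, pairs
of genotypes are classified by multilocus likelihood under three IBD-sharing
classes — unrelated (1, 0, 0), half-sib (½, ½, 0), full-sib (¼, ½, ¼) —
with loci independent (the panel is selected in linkage equilibrium),
Hardy–Weinberg genotype frequencies, and genotyping error folded in as a
contamination mixture `(1−ε)·P_class + ε·P_U` (ε = 0.01 by default), which
keeps every log-likelihood finite. Ties go to unrelated. The reported
`posterior_sib` is the uniform-prior posterior of {HS, FS}.

Operating characteristics measured on synthetic colonies (300 loci, minor
allele frequency > 0.33): full-sib versus unrelated is essentially perfect;
half-sib versus unrelated is the hard margin, with ~1% of unrelated pairs
miscalled at the maximum-likelihood boundary. Pairwise posteriors are less
conservative than joint-reconstruction posteriors, so the validation
pipeline accepts pairs at `posterior_sib > 0.95` (recovering ≥ 90% of true
sibling pairs with false pairs a few percent of the true count on cohorts of
~15 colonies), and at 0.99 for light-trap-scale samples where ~14,000
pairwise tests would otherwise over-merge families through occasional false
edges. These thresholds are deliberate operating points, set from the
classifier's measured ROC on synthetic data, and are arguments, not
constants.

## Population-genetic summaries

Per-sample: `He = 1 − Σp²` and `Ne = 1/Σp²` per locus (averaged), observed
heterozygote fraction, `F_IS = (He − Ho)/He`; between two samples: Nei's
`F_ST = (Ht − Hs)/Ht` and the Hedrick standardization
`F'_ST = F_ST·(k−1+Hs)/((k−1)(1−Hs))` for `k = 2`. The multilocus
probability of identity is `Π_loci [Σp⁴ + Σ_{i<j}(2p_i p_j)²]`, reported on
the log10 scale since it underflows at 300 informative loci. These formulas
are verified on closed-form cases (at `p = 0.5`: `He = 0.5`, `Ne = 2`,
per-locus PI `= 0.375`); the study's own tabulated values depend on its
archived genotypes and are not asserted. Loci missing in one sample are
dropped pairwise from between-sample statistics, with a message.

## The synthetic generator

`sample_panel()` draws allele frequencies uniformly on the band
`[maf, 1−maf]` with `maf = 0.33` — the empirical record states only the
band, so the uniform spectrum is this package's choice, with a degenerate
spike at 0.5 available through a near-0.5 `maf_min` for worst-case
probability-of-identity checks. `simulate_colony()` draws parents in
Hardy–Weinberg proportions, transmits one Mendelian allele per parent per
locus, flips transmitted alleles symmetrically at rate ε, and masks calls
uniformly at the missingness rate (defaults: 6 offspring, 1 sire — the
haremic norm — or 2 for the multi-sire deviation, 3 dams, 5% missingness,
ε = 0.01). With ε = 0 every offspring is Mendelian-consistent with its
parents at every non-missing locus, heterozygote crosses segregate 1:2:1,
and pooled offspring frequencies converge to the panel.

What the generator deliberately does not model: linkage and LD (the real
panel was filtered to equilibrium), selection, mutation, clutch timing and
age structure within colonies, unequal family sizes, spatially explicit
sampling, and sequence-level artefacts. Passing validation on this generator
therefore shows the *statistical* machinery is correct under the analysis's
own assumptions; it does not show those assumptions hold on a reef.

## Known limitations

* The demographic parameters are order-of-magnitude biology; the cohort
  sizes inherit their uncertainty linearly, though the *contrast* between
  empirical kinship and any plausibly sized null is far larger than that
  uncertainty.
* Family size is a constant 6; real colonies vary, which would overdisperse
  the null slightly.
* The half-sib/unrelated likelihood margin at 300 moderately informative
  loci is intrinsically narrow; joint (multi-individual) reconstruction
  would sharpen it and is out of scope here.
* The score weights are one defensible realization of "indirectly
  proportional to frequency"; conclusions are stated as percentiles, which
  are insensitive to monotone reweighting, rather than as raw score units.
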