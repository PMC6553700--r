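---
title: "Models and methods behind famcoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famcoseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcoseg)
```

## The problem

Multiple sclerosis is overwhelmingly a complex trait, but a small number of
multi-incident families -- three or four generations with four or more
diagnosed members -- behave as if a single dominant variant of major effect
were being transmitted. In such families the observable signature is
*co-segregation*: the candidate allele travels with the diagnosis down the
pedigree, imperfectly, because penetrance is reduced (healthy carriers
exist, including healthy parents who demonstrably transmitted the allele)
and because phenocopies exist (patients whose disease has nothing to do
with the family's variant).

famcoseg implements the desk side of that study design: starting from
exome variant calls for the affected members of each family, narrow the
candidates to rare coding variants, test each against a tolerant
segregation rule, and follow up interesting genes in case/control cohorts
with carrier-frequency and odds-ratio statistics, plus a
haplotype-sharing check when the same variant surfaces in several
families.

## The disease model and the segregation rule

All inference assumes an **autosomal dominant, single-founder-introduction
model with zero de novo rate**: exactly one founder brings the variant
into the family, every carrier is heterozygous, and every non-founder
carrier has a carrier parent. Homozygous-alternate genotype calls are
collapsed to "carrier" with a warning, since the dominant model makes no
dosage distinction and a rare allele practically never appears twice in
one family.

A variant *segregates* in a family when both of the following hold:

* at least **75%** of the affected blood relatives with an informative
  (observed or inferred) genotype carry it -- the threshold is inclusive,
  so 3 of 4 passes; and
* at most **one** unaffected family member carries it, where *obligate
  carriers* are excluded from that count.

The affected-side denominator counts only informative individuals:
patients without DNA and without a forced genotype drop out rather than
being assumed wildtype, which would penalize missing DNA. Members whose
affection status is "possible" are excluded from both tallies by default
(`include_possible = TRUE` restores them); married-in members -- those
with no blood path to the proband -- never enter either tally. Both
thresholds are arguments (`min_affected_fraction`,
`max_unaffected_carriers`) with the defaults above.

## Obligate carriers and genotype inference

An individual is *forced* to carry the variant when every
Mendelian-consistent carrier assignment -- one founder introduction, no de
novo events, no observed call contradicted -- includes them.
`infer_genotypes()` computes forced carriers with a dominator argument on
the descent graph: for each founder that could have introduced the
variant, an untyped individual is forced exactly when removing them
disconnects some observed carrier from that founder (through vertices not
observed wildtype), and forced overall when this holds for every
candidate founder. Forced *wildtype* status is the dual: an untyped
individual that no candidate founder can reach at all (the everyday case
being a child of two wildtype parents). Everything else stays missing --
an untyped sibling of a carrier is a coin flip, never inferred.

The obligate-carrier set used by the segregation rule is the union of
(a) unaffected parents of affected carriers who are carriers in every
consistent assignment (whether observed or forced), and (b) all untyped
forced carriers along the connecting transmission paths. Rule (b) extends
the classical "unaffected parent" definition to connecting grandparents
and siblings-in-line; it is default-on (`extended = FALSE` restricts to
parents). An observed unaffected carrier who is *not* a parent of a
patient is deliberately not obligate -- those are exactly the carriers the
"at most one" budget is spent on.

Two failure modes are kept distinct: observed carriers that cannot all
descend from any single founder raise a model-violation *warning* and
inference abstains, while a directly inconsistent trio (carrier child,
both parents observed wildtype) is a hard *error* naming the trio.

The test suite checks the dominator implementation against an independent
oracle that exhaustively enumerates all `2^k` assignments of the untyped
individuals and intersects the consistent ones; the two agree on every
fixture family with at most 14 members, and inferred calls always match
the simulator's hidden truth.

## The rare-variant filter

`apply_filter()` retains variants that are simultaneously autosomal
(chromosomes 1-22, `chr` prefixes normalized), missense or nonsense, and
strictly below the MAF threshold (default 1%) in **every** configured
frequency database. "Below 1%" is read literally: a variant at exactly
0.01 is removed. A variant with no entry in a database counts as absent
(frequency 0) there, matching how novel variants are treated. The filter
is idempotent and monotone in the threshold.

`shared_by_affected()` implements the two-stage discovery rule: first
variants carried by *all* sequenced affected members; if that set is
empty, the fallback accepts variants carried by all but one (n-1 of n),
tagging the result so downstream reporting can distinguish the modes.
The n-1 fallback reflects the reality that a large family can harbor one
phenocopy among its sequenced patients.

## Association statistics

Carrier counts convert to allele frequencies as `carriers / (2n)`
(heterozygote assumption), and percent strings round half away from zero
to two decimals -- the convention that renders 13/5,004 alleles as
"0.26%" and 1/2,150 as "0.05%".

`odds_ratio()` builds a 2x2 table and returns the Woolf (log-normal)
95% interval `exp(ln OR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`. The
default table counts carrier versus non-carrier *individuals* per group;
this is the arithmetic that reproduces the published benchmark exactly
(5/6,252 cases vs 1/3,877 controls: OR 3.10, CI 0.36-26.56). An
allele-unit table (`unit = "allele"`, b = 2n - carriers) is provided for
comparisons against allele-frequency references, and is what
`frequency_vs_reference()` uses, reconstructing the reference side as
`c = round(maf · alleles)`. When any cell is zero the Haldane-Anscombe
correction (+0.5 everywhere) is applied and flagged explicitly, never
silently.

```{r ncoa3}
odds_ratio(carrier_counts(5, 6252, 1, 3877))
```

## Haplotype sharing

When the same substitution appears in several families, identical
microsatellite allele sizes (CEPH-normalized, hence integer-comparable)
at every co-genotyped flanking marker indicate a shared founder; any
mismatch indicates independent mutational origin, i.e. a hotspot. Fewer
than three co-genotyped markers is inconclusive, signalled as a condition
distinct from either verdict. Matching is exact by default -- no ±1 bp
stutter tolerance -- because CEPH normalization is assumed upstream.
Phasing uses a deliberately simple transmission rule: the allele
compatible with every carrier-parent-to-carrier-child meiosis, requiring
at least two informative meioses per marker, else the marker stays
unphased.

## The synthetic-data generator

`simulate_family()` generates the study conditions end to end: a founder
couple, Poisson-sized sibships (mean 3), married-in partners who are
always non-carriers, fair-coin transmission, affection sampled at the
configured penetrance/phenocopy rates, and genotype masking at the
configured missingness. Defaults are penetrance 0.7, phenocopy rate 0.05
and missingness 0.1 -- values a family study of a reduced-penetrance
dominant trait would consider realistic, chosen once and not tuned (the
source material gives no numeric penetrance estimate). Families are
ascertained the way multi-incident families are in practice: structures
are resampled until at least four affected members have DNA
(`min_affected_dna`, set 0 to disable). Ascertainment inflates
within-family penetrance, so the Monte-Carlo check that recovers the
penetrance parameter (0.6 recovered within ±0.03 over 1,000 families)
runs unascertained.

Each family also receives background variants (default 25) with
population frequencies log-uniform on [1e-4, 0.05] -- deliberately
spanning the 1% threshold so the filter is exercised -- and four
microsatellite markers transmitted in full linkage with the causal
variant. `simulate_cohort()` draws binomial carrier counts at configured
case/control frequencies. `write_fixture_bundle()` emits PED, VCFs,
frequency/marker/count TSVs and a JSON manifest, byte-identical for
identical seeds.

What the generator does *not* emulate: linkage disequilibrium and
recombination (markers are fully linked; no recombinant haplotypes),
age-dependent penetrance, genotyping error, and population stratification
in the cohort. Passing tests therefore demonstrate correctness of the
combinatorial and statistical machinery under the stated model, not
robustness to those real-data complications.

## Numerical and design choices

* **Verdict tie-breaking** in `nominate_candidates()` is affected
  fraction descending, then CADD descending, then lexicographic variant
  key -- fully deterministic; missing CADD sorts last.
* **Multi-family variants**: `mine_cohort()` evaluates each carrier's
  family separately; a variant must satisfy the criterion in every family
  to survive, since an aggregate fraction above 75% can hide individual
  families that clearly fail.
* **Degenerate inputs**: zero observed carriers, fewer than two sequenced
  affected, and all-zero 2x2 tables raise typed conditions
  (`famcoseg_insufficient`, `famcoseg_inconclusive`) so pipelines can
  distinguish "no data" from "negative result".
* **Problem sizes** used by the shipped validation runs: 500 simulated
  families for the full-penetrance sensitivity check, 1,000 random 2x2
  tables for the odds-ratio cross-check (agreement to 1e-9 relative),
  1,000 masked families for inference soundness, and an exhaustive-
  enumeration cross-check on families of at most 14 members. These sizes
  make each property estimate stable at the asserted tolerance while a
  full run stays comfortably interactive.

## Known limitations

* The single-founder assumption means bilineal families (two independent
  introductions) are flagged as model violations rather than analysed.
* X-linked and recessive models, kinship estimation from genotypes, and
  formal linkage statistics are out of scope.
* The published odds ratios whose denominators were not printed alongside
  them cannot be recomputed from first principles; the package reports
  its own arithmetic instead of imitating those figures.
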