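---
title: "Models and methods behind the forensic STR workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the forensic STR workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopgen)
```

`strpopgen` implements the statistical pipeline of a wildlife forensic STR
study: summarizing polymorphism of a candidate marker panel in two
differentiated reference groups (a wild wolf-like population and a managed
dog-like population), screening loci for artefacts, quantifying
differentiation, assigning individuals to their group of origin, and
converting a multi-locus genotype into a defensible match probability.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the simulation-based validation does and does not show.

## Data model

A `genotype_table` couples a locus panel with per-sample metadata and one
unordered allele pair per sample and locus. Allele labels are opaque text
tokens — digits giving a size class, optionally followed by a letter suffix
that separates same-sized sequence variants (e.g. `10in` vs `10` for an
insertion-bearing allele). Labels compare by string equality; the numeric
part is used only for size ordering and for the size-class binning of the
error scan. This accommodates panels that mix repeat counts, fragment sizes
and microvariants without committing to any one convention.

Missing data follow the standard codominant convention: `0` or an empty
cell is a missing allele, and a genotype with either allele missing is
treated as wholly missing by every statistic (`validate_table()` flags
half-missing records as errors rather than guessing). Sex markers
(`marker_class = "sex"`) are carried as presence/absence pseudo-genotypes
and excluded from all statistics — they inform sexing only.

## Per-locus summaries

Allele frequencies are counts over `2 * n_typed`. Expected heterozygosity
defaults to the unbiased small-sample form `2n/(2n-1) * (1 - sum(p^2))`,
matching the convention of the reference tools forensic labs use for these
tables; the plain gene diversity is available with `unbiased = FALSE`. The
effective allele number is `1/sum(p^2)` per population, averaged
arithmetically across loci in reports. PIC follows Botstein's definition
and is always bounded by the gene diversity.

The major-allele dominance flag defaults to a threshold of 0.5: a locus
whose most frequent allele reaches half of all copies in every analyzed
population contributes little identification power, whatever its allele
count. The threshold is deliberately configurable because no universal
value exists; 0.5 reproduces the qualitative behaviour expected of
dominated loci in panels like this one.

## Hardy–Weinberg testing

`hwe_exact_test()` is a Monte-Carlo exact test conditional on allele
counts: the observed `2n` alleles are re-paired into `n` genotypes many
times, and each array is scored by its conditional probability, which up to
a constant is `h*log(2) - sum(lgamma(n_ij + 1))` with `h` the heterozygote
count. The p-value is the fraction of shuffles no more probable than the
observed array, with the `(x+1)/(B+1)` correction, so it is valid (never
anti-conservative) at any shuffle count. Probability ordering makes the
test two-sided and well-defined for any number of alleles; a monomorphic
locus returns p = 1 because only one array exists. Ties in the statistic
are counted as "no more probable" with a 1e-9 guard against floating-point
noise in the `lgamma` sums.

Calibration is checked on a five-allele, n = 100 design, where the
conditional distribution has rich support: the rejection rate at
`alpha = 0.05` over 2000 null replicates is within one point of nominal and
the p-values pass a Kolmogorov–Smirnov uniformity check. With two alleles
and small samples the exact test is inherently discrete and conservative —
that is a property of exact HWE tests generally, not of this
implementation — which is why the calibration design is multi-allelic.

Bonferroni correction (`bonferroni_adjust()`) divides `alpha` by the number
of tests in the family; the family is chosen by the caller and defaults to
the set of tested loci within each population in the triage cascade, the
standard reading for panel screening. A locus that is raw-significant at
p = 0.005 in a 15-locus family sits above 0.05/15 = 0.0033 and is retained.

## Null alleles and the error scan

Null-allele burden is estimated from the heterozygote deficit by the
Chakraborty (`(HE-HO)/(HE+HO)`) and Brookfield (`(HE-HO)/(1+HE)`)
estimators; negative values (heterozygote excess) are reported as-is, and
the screening flag requires both estimators to exceed the threshold
(default 0.05, the level at which a locus's deficit begins to matter in
match-probability practice).

The homozygote-excess scan is a deliberately simplified surrogate for a
full stutter diagnostic: alleles are binned into equal-width size classes
(default 4), each class's observed homozygote count is compared with its
Monte-Carlo HWE expectation (one-sided), and the locus is flagged when a
majority of occupied classes are significant at `alpha = 0.05`. The
majority rule makes the scan specific (null rate well below alpha, since
several classes must fire jointly) but gives it power only where stutter
mis-calls touch most size classes — in practice, loci with few common size
classes, which is exactly the dinucleotide regime where stutter is
dangerous. Validation shows a 20 % adjacent-heterozygote corruption rate is
flagged in over 90 % of seeds at three size classes and n = 1000, while
highly polymorphic tetranucleotide loci dilute the signal below detection;
users screening such loci should rely on the dedicated fragment-analysis
tools this scan stands in for.

## F-statistics and AMOVA

`wc_fstats()` implements the Weir–Cockerham variance components: for every
allele, `a` (among populations), `b` (among individuals within populations)
and `c` (within individuals) are estimated with the standard finite-sample
corrections and summed over alleles and loci; FST = a/(a+b+c),
FIS = b/(b+c), FIT = (a+b)/(a+b+c). Summing components before taking
ratios (ratio-of-sums) is the classical weighting that keeps the estimator
nearly unbiased under unbalanced sampling. Negative components are retained
in every sum — truncation would bias multi-locus estimates — and only the
forensic θ table clamps per-locus FST at zero, since a negative subdivision
coefficient has no forensic meaning. The identity
`(1 - FIT) = (1 - FIS)(1 - FST)` holds exactly per locus by construction
and is enforced by tests at 1e-12. Loci with zero total variance are
reported as undefined and excluded from multi-locus sums.

AMOVA is one-level (among vs within populations) with allele copies as
units and the 0/1 allele-mismatch distance. With that metric all sums of
squares reduce to allele counts, and the method-of-moments components make
`Phi_ST` an FST-type quantity: on Balding–Nichols simulations it tracks the
multi-locus Weir–Cockerham estimate to the third decimal. We chose the
allele-copy formulation deliberately: a one-level decomposition over
*individuals* with pairwise genotype distances estimates `2θ/(1+θ)` rather
than θ and would disagree with the F-statistics it is meant to complement.
The permutation test moves whole individuals (both allele copies together),
preserving within-individual correlation (FIS) under the null of no
subdivision; `p_perm` uses the `(x+1)/(B+1)` correction. Rejection at
`alpha = 0.05` under the null is within 1.5 points of nominal over 1000
replicates.

## Assignment test

For each individual, the expected frequency of its multi-locus genotype is
computed in each reference population as the product over typed loci of
`p^2` (homozygote) or `2pq` (heterozygote); the individual is assigned
where `-ln f` is smallest, and `delta = |(-ln f_own) - (-ln f_other)|`
summarizes separation. Scoring an individual against a reference that
contains it biases the comparison toward self-assignment, so the own-group
frequency is computed leave-one-out: the individual's two alleles are
removed from the counts first. Alleles unobserved in a reference (possibly
after removal) receive the rare-allele frequency `1/(2n+1)`, the standard
frequentist convention that keeps every profile possible in every
population; `n` is the count of typed reference individuals actually
entering the frequency denominator. Loci where the query is untyped are
skipped; ties in `-ln f` resolve to the individual's own population (they
have probability zero in continuous settings).

## Match probabilities with subdivision correction

Single-locus match probabilities follow the NRC-II subdivision formulas
given in the README; θ = 0 reduces exactly to the product rule. The
homozygote correction is conservative — never below `p²` for any
θ ∈ [0, 1), verified on a 10⁴-point grid — while the heterozygote
correction is *not* uniformly conservative (p = q = 0.5, θ = 0.2 gives
3/7 < 0.5); both facts are documented and tested, since conservativeness
claims in casework should rest on the homozygote bound and on empirical
cohort comparisons, not on a blanket statement.

Multi-locus reports order loci by ascending θ (ties by locus name) and
accumulate running products, the standard layout of a forensic match
table. θ defaults to per-locus truncated Weir–Cockerham FST; a fixed scalar
(e.g. the NRC recommendation 0.03) may be supplied instead. Cohort averages
over fully typed samples default to the geometric mean (mean of log₁₀
frequencies, exponentiated), the natural average for strictly positive
quantities spanning orders of magnitude; the arithmetic mode is provided
for sensitivity analysis because either reading of "averaged over animals"
is defensible. On the default simulated cohort the θ-corrected average
exceeds the uncorrected one by several orders of magnitude, the qualitative
behaviour that motivates the correction.

## Panel triage

`apply_locus_filters()` applies four exclusion rules in a fixed order but
independently (any rule firing excludes the locus): genotyping-error
evidence in at least one population; null-allele burden above threshold in
at least `null_min_pops` populations (default 2); major-allele dominance in
every population; and HWE deviation surviving Bonferroni correction in at
least one population. Defaults (0.05 / 0.05 in ≥ 2 populations / 0.5 /
0.05) are configurable and surfaced in the audit report, since published
panel designs rarely state their numeric cutoffs. Every Monte-Carlo
sub-test is seeded from the single `seed` argument, making the report
deterministic; decisions are monotone in the thresholds. Note that heavy
corruption of one kind usually leaves secondary fingerprints of another
(strong stutter also depresses HO and hence raises the null-allele
estimators), so excluded loci often carry more than one reason — the
report keeps all of them.

## The synthetic-data generator

`simulate_study()` emulates the study design the package validates
against: two populations (wolf-like n = 103, dog-like n = 198) typed at 15
autosomal STR loci with 5–26 alleles each. Ancestral allele frequencies are
symmetric-Dirichlet draws (concentration 1, which yields the observed mix
of balanced and skewed spectra; the resulting mean expected heterozygosity
of 0.72–0.80 and mean allele number near 9–11 per locus sit inside the
envelope such panels report). Population frequencies follow the
Balding–Nichols model — Dirichlet with parameters `p_i (1-θ)/θ` around the
ancestral spectrum, θ = 0.08 by default — the same model family that
justifies the θ-corrected match formulas, so parameter recovery closes the
loop: the multi-locus Weir–Cockerham FST recovers θ within ±0.02 (mean of
100 replicates), FIS recovers an inbreeding coefficient of 0.2 within
±0.03, and the Chakraborty estimator recovers injected null-allele rates of
0.05–0.2 within ±0.03. Genotypes are drawn with
`P(AA) = p² + fis·p(1-p)`, `P(AB) = 2pq(1-fis)`; the dog-like group
defaults to fis = 0.05, reflecting breed management, the wolf-like group to
panmixia. Optional breed substructure adds a second-level Balding–Nichols
draw inside one population.

Corruption operators mirror the screening targets. Null alleles: each
allele copy of each genotype at the chosen locus independently becomes
null with probability r, so visible/null heterozygotes appear as
homozygotes and null/null genotypes go missing (missing rate ≈ r²); r = 0
is an exact identity. Stutter: with the given rate, a heterozygote whose
alleles occupy adjacent ranks in the locus's sorted size classes is
rewritten as a homozygote for the larger allele — only such pairs are ever
touched.

What the simulations do *not* emulate: mutation processes (no stepwise
mutation model), linkage between loci, allele-size-dependent stutter
intensity, allelic dropout of large fragments, and real breed pedigree
structure. Passing recovery and calibration tests therefore demonstrates
internal consistency of estimator and generator under the stated model,
not performance on every pathology of real electrophoretic data.

## Problem sizes and numerical choices

The validation suite uses the study-scale designs above (hundreds of
individuals, 15 loci) with 100–200 replicates for recovery means, 2000
replicates for HWE calibration and 1000 for AMOVA calibration with 199
permutations each — sizes at which the binomial error of a rejection-rate
estimate is well below the tolerance being asserted. Monte-Carlo p-values
always use the `(x+1)/(B+1)` form. Seeds: every stochastic function takes
an explicit seed, restores the caller's RNG state, and derives
deterministic sub-seeds when it fans out over loci and populations, so any
stage of `run_pipeline()` can be reproduced in isolation from the logged
parameters.

## Known limitations

The error scan is a surrogate, not a replacement, for fragment-level
stutter diagnostics (see above). The assignment test supports exactly two
reference populations, the design of the motivating casework. AMOVA is
one-level; hierarchical designs (breeds within dogs) are summarized instead
by pairwise FST. The θ-corrected likelihood-ratio machinery for kinship or
mixtures is out of scope.
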