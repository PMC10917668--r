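# strpopgen

Population genetics and forensic match statistics for codominant
microsatellite (STR) panels, built for wildlife forensic casework in which
samples must be attributed to one of two strongly differentiated groups —
the motivating application is distinguishing the Grey wolf from the domestic
dog and quantifying the evidential weight of a multi-locus genotype match.

## What it computes

For a genotype table (samples × loci, two allele columns per locus):

* **Polymorphism summaries** per locus and population: allele frequencies,
  number of alleles *Na*, effective allele number *Ne* = 1/Σp²,
  observed heterozygosity *HO*, unbiased expected heterozygosity
  *HE* = 2n/(2n−1)·(1 − Σp²), and Botstein's polymorphism information
  content PIC = 1 − Σpᵢ² − ΣΣ_{j>i} 2pᵢ²pⱼ².
* **Hardy–Weinberg screening**: a Monte-Carlo exact test conditional on
  allele counts (valid for any number of alleles), with Bonferroni
  correction over the locus family of each population.
* **Null-allele screening**: the Chakraborty estimator
  r = (HE − HO)/(HE + HO) and Brookfield estimator r = (HE − HO)/(1 + HE),
  plus a homozygote-excess scan across allele size classes as a
  genotyping-error (stutter) surrogate.
* **Differentiation**: Weir–Cockerham (1984) variance components per allele
  and locus, giving FIS, FST, FIT per locus and multi-locus by
  ratio-of-sums; one-level AMOVA over allele copies with a
  whole-individual permutation test; pairwise FST matrices.
* **Assignment test**: the expected frequency of each individual's
  multi-locus genotype in each reference population (p² / 2pq product over
  loci), leave-one-out corrected against its own population; individuals
  are assigned where −ln f is smallest.
* **Forensic match probabilities**: per-locus genotype frequencies with the
  NRC-II subdivision correction
  P(AA) = [2θ + (1−θ)p][3θ + (1−θ)p] / [(1+θ)(1+2θ)],
  P(AB) = 2[θ + (1−θ)p][θ + (1−θ)q] / [(1+θ)(1+2θ)],
  cumulated over loci in increasing-FST order, with per-locus θ taken as
  truncated Weir–Cockerham FST; cohort-averaged match probabilities with
  and without θ.
* **Panel triage**: the exclusion cascade used when designing a forensic
  panel — genotyping-error evidence → null-allele burden → major-allele
  dominance → post-Bonferroni HWE deviation — with an auditable per-locus
  report.
* **Synthetic studies**: a Balding–Nichols generator (population allele
  frequencies ~ Dirichlet(p·(1−θ)/θ) around an ancestral spectrum) with
  optional inbreeding, breed-like substructure, null-allele and stutter
  corruption, so the entire workflow can be validated by parameter
  recovery.

## Worked example

```r
library(strpopgen)

tab <- simulate_study(sim_config(seed = 1))   # wolf-like 103 + dog-like 198
tab
#> genotype_table: 301 samples, 15 loci (15 autosomal), 2 populations
#>   populations: dog (n=198), wolf (n=103)

wc_fstats(tab)$multilocus
#>        FIS        FST        FIT
#> 0.03384337 0.07656743 0.10781950

amova(tab, n_perm = 999, seed = 2)
#> AMOVA (populations: wolf, dog )
#>   among populations: sigma^2 = 0.4783  (7.67 %)
#>   within populations: sigma^2 = 5.7591  (92.33 %)
#>   Phi_ST = 0.0767, permutation p = 0.001 (999 permutations)

assignment_test(tab, populations = c("wolf", "dog"))
#> Leave-one-out assignment test (wolf vs dog)
#>  population   n pct_self_assigned mean_delta
#>        wolf 103               100   19.44988
#>         dog 198               100   20.69262

thetas <- per_locus_theta(wc_fstats(tab))
cohort_average_match_probability(tab, thetas)
#> Cohort-averaged match probability (geometric mean over 301 fully typed samples)
#>   without theta: 8.28e-22
#>   with theta:    9.02e-17
```

Reading: the two simulated populations sit at FST ≈ 0.077 (the generator's
subdivision parameter is 0.08), AMOVA attributes 7.7 % of allelic variation
to the between-population level (significant at p = 0.001), every
individual is assigned back to its population of origin by the
leave-one-out test, and ignoring population subdivision (θ) understates the
average multi-locus genotype frequency by about five orders of magnitude —
i.e. overstates the strength of a match. `run_pipeline()` chains all stages
and writes per-stage CSV reports plus a JSON summary.

The genotype CSV dialect is GenAlEx-like: columns
`sample_id,population[,sex]`, then two adjacent columns per locus named
`<locus>` and `<locus>.2`; alleles are text tokens such as `12` or the
insertion-tagged `10in`; `0` or an empty cell is missing. See
`read_genotypes()`.

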