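# disswarm

Divergence-island SNP (DIS) classification and swarm-association analysis
for hybridizing *Anopheles coluzzii* / *Anopheles gambiae* s.s.
populations.

## The problem

The sibling malaria vectors *An. coluzzii* and *An. gambiae* s.s. are
undergoing speciation with gene flow. Their genomes differ sharply only
inside three pericentromeric "islands of speciation" — on chromosomes X,
2L and 3L — that are protected from introgression by recombination
suppression. A panel of divergence-island SNPs (7 on X, 5 on 2L, 3 on
3L), each fixed for alternative alleles between the species, reads
ancestry directly: a non-hybrid is homospecific at every locus, an F1 is
heterozygous at every locus (with a single-species hemizygous X in
males), and an F1+n backcross shows a recombinant mixture. Because males
mate in species-segregated swarms, comparing each individual's
island genotypes with the type of swarm it was captured in measures how
tightly each island is tied to the assortative-mating machinery.

`disswarm` implements that analysis end to end for field entomologists
and population geneticists working with this panel (or any panel with
the same island structure):

* sex-aware classification into non-hybrid / F1 / F1+n, species
  assignment by an allele majority rule, per-island states and X/rDNA
  discordance (`classify_genotypes()`);
* swarm typing (monospecific vs mixed, `swarm_types()`) and
  island-by-swarm match tables with Wilson intervals
  (`build_match_table()`, `match_proportions()`);
* the statistical kernel: likelihood-ratio G-tests
  (`G = 2 Σ O ln(O/E)`), Fisher–Irwin exact tests, N−1 chi-square
  (`χ²·(n−1)/n`), pairwise odds-ratio LR comparisons, and logistic
  regressions with per-term likelihood-ratio tests
  (`logistic_lr_fit()`, `temporal_trend()`, `life_stage_comparison()`);
* kdr insecticide-resistance genotype trajectories and the recovery of
  coluzzii-like 2L islands carrying the resistant allele
  (`kdr_frequencies()`, `classify_2l_recovery()`, `recovery_trend()`);
* a forward population simulator of the two-species system — island
  recombination suppression, kdr viability selection, X-driven swarm
  assembly — with parameter recovery (`simulate_swarms()`,
  `recover_parameters()`);
* deterministic fixtures that replay published composition tables
  through the pipeline (`fixture_from_counts()`,
  `table1_male_counts()`, `table2_female_counts()`).

Everything takes and returns tibbles, chains with the pipe, and fitted
objects support `tidy()` / `glance()`.

## Worked example

Replay the published male swarm composition (2063 males, 106 swarms)
through the classifier and the association test:

```r
library(disswarm)
library(dplyr)

geno <- fixture_from_counts(table1_male_counts())
cl   <- classify_genotypes(geno)
count(cl, category, sort = TRUE)
#>   category      n
#> 1 BACKCROSS  1285     # 62.3% F1+n backcrosses
#> 2 PURE_GAM    696
#> 3 PURE_COL     80     # 37.6% non-hybrid in total
#> 4 F1            2     # 0.1%

swarm_types(cl) |> count(swarm_type)
#>   swarm_type  n
#> 1 COL        59
#> 2 GAM        44        # 103/106 = 97.2% monospecific
#> 3 MIXED       3

build_match_table(cl) |> match_proportions()
#>   species sex island    n n_match prop_match
#> 1 COL     M   X      1297    1297      1.000   # perfect X association
#> 2 COL     M   2L     1297      67      0.052   # broken by introgression
#> 3 COL     M   3L     1297    1297      1.000
#> 4 GAM     M   X       724     724      1.000
#> 5 GAM     M   2L      724     724      1.000
#> 6 GAM     M   3L      724     691      0.954

g_test(matrix(c(67, 691, 1230, 33), 2))
#> Likelihood-ratio G-test
#>   chi2 = 1878, df = 1, n = 2021, p = 0
```

The X island matches the swarm of capture in every individual, while
the coluzzii 2L association collapses: the 2L island of *An. gambiae*
swept into *An. coluzzii* on the back of the kdr resistance allele, so
most coluzzii backcrosses carry an entirely heterozygous 2L. The
G-statistic of 1878.3 (df = 1, n = 2021) quantifies how strongly
backcrossed genotypes concentrate in coluzzii-type swarms.

The same mechanism can be generated rather than replayed:

```r
sim <- simulate_swarms(sim_params(h = 0.01, s = 0.2), seed = 1)
cl  <- classify_genotypes(sim$individuals)
build_match_table(cl) |> match_proportions()
recover_parameters(sim)
```

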