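---
title: "Methods: DIS classification, swarm association and the forward simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIS classification, swarm association and the forward simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disswarm)
```

## The model

*An. coluzzii* and *An. gambiae* s.s. hybridize without intrinsic
post-zygotic barriers, yet remain distinct. Their genomes are nearly
undifferentiated except in three pericentromeric islands of speciation
(X, 2L, 3L) where recombination suppression protects clusters of
species-defining loci from gene flow. The divergence-island SNP (DIS)
panel — by default 7 X, 5 2L and 3 3L loci, each fixed for alternative
alleles between the species — turns an individual's genotype into an
ancestry mosaic at island resolution.

Calls are species-coded: `CC`/`GG` homozygous coluzzii/gambiae, `CG`
heterozygous, and `C`/`G` for the hemizygous male X. The hemizygosity
rules are structural: a diploid call on a male X locus is a genotyping
error and is rejected at the door, and a male X island can never be
entirely heterozygous.

### Hybrid categories

For a complete record (no missing DIS call — incomplete records are
excluded, except from kdr-sweep analyses, with logged counts):

* **non-hybrid** (`PURE_COL`, `PURE_GAM`): homospecific at every locus,
  hemizygous X calls included;
* **F1**: heterozygous at all 15 loci (females), or heterozygous at all
  8 autosomal loci with a uniform single-species hemizygous X (males).
  A male F1's X identifies his maternal species, since sons receive
  their X from their mother;
* **F1+n backcross** (`BACKCROSS`): everything else — any recombinant
  genotype.

These four categories partition the space of complete genotypes, and
the partition is label-symmetric: relabelling coluzzii as gambiae at
every call swaps the two pure categories, flips species assignments,
and leaves F1 and backcross membership unchanged. Both properties are
enforced by large-scale fuzz tests.

### Species by majority rule

Each individual is assigned to the species contributing the majority of
its species-specific allele copies: 2 per homozygous call, 1 to each
species per heterozygous call, 1 per hemizygous call. A complete male
carries 23 copies, so males can never tie. Females can (15 vs 15); the
tie is broken by the species of the X island, the island that never
recombined in field data, drives swarm membership, and carries the
classical rDNA diagnostic that field protocols themselves fall back on.
A tied female whose X is itself heterozygous (an all-heterozygous F1
female — never observed in the field data) has no majority in any
defensible sense: her species is `NA`, the event is flagged in
`species_tie`, and swarm typing simply ignores members without a
species. This is the one point where the classification refuses to
guess.

### Island states and discordance

Within each island: `HOM_COL`/`HOM_GAM` (all calls homospecific;
hemizygous counts as homospecific), `HET_ENTIRE` (heterozygous at every
locus — the signature of an entirely introgressed heterospecific
island), `RECOMBINED` (any other mixture — within-island crossover),
`MISSING`. `RECOMBINED` deliberately covers both hom/het mixtures and
mixtures of the two homozygous states: the latter is logically possible
in advanced backcrosses and must classify somewhere.

When an rDNA ITS call is available and the X island is homospecific,
disagreement between the two is flagged: the rDNA locus sits closer to
the X centromere than the DIS loci, so discordance indicates a rare
recombination event inside the X island rather than a scoring error.

## Swarm typing and the match analysis

A swarm is monospecific (`COL` or `GAM`) only if *every* member —
backcrosses included, through their majority species — is assigned to
that species; any proportion of both species makes it `MIXED`. Members
of mixed swarms are excluded from the match analysis (in the source
data they were dominated by homozygous coluzzii males and carried
little information).

The match predicate is: *an island matches a monospecific swarm iff it
is homospecific for the swarm's species.* Entirely heterozygous,
recombined, and homospecific-for-the-other-species islands all count as
mismatches — the last case matters, because the one X mismatch in the
field data was a fully homozygous male carrying a coluzzii X into a
gambiae-typical swarm.

Three nested analysis sets mirror the source analysis:
`"nonrecombinant"` (individuals homozygous at every locus),
`"entire_islands"` (adds individuals whose heterospecific islands are
all entirely heterozygous), `"all"` (adds within-island recombinants).
F1 hybrids are excluded throughout: the analysis contrasts non-hybrids
with F1+n recombinants, and an all-heterozygous genotype has no
own-species swarm to match. Proportions carry Wilson score intervals
(95% by default), which behave sensibly at the 0 and 1 boundaries where
the interesting values live; the interval method is isolated in one
function and swappable.

## The statistical kernel

* **G-test**: `G = 2 Σ O ln(O/E)` over cells with `O > 0` (empty cells
  contribute zero, the standard convention), `df = (r−1)(c−1)`,
  upper-tail chi-square p-value. Zero marginals are an error.
* **N−1 chi-square**: Pearson × (n−1)/n, the small-sample-robust 2×2
  variant. The Pearson statistic comes from `stats::chisq.test`
  (uncorrected); its small-count warning is suppressed because the
  (n−1) correction is the point.
* **Fisher–Irwin**: two-sided exact p by summing hypergeometric
  probabilities not exceeding the observed table's probability, with
  the usual `1 + 1e-7` relative tolerance for ties. Verified against
  exhaustive enumeration of every 2×2 table with total at most 30.
* **Pairwise island comparisons** build the island × match 2×2 from the
  match table and report the LR test plus the odds ratio
  (Haldane-corrected when a cell is zero); Fisher and N−1 variants are
  available behind a method flag. Per-island rows from the same
  individuals are treated as independent, exactly as in the source
  analysis — a documented caveat, not a bug to fix silently: with
  within-individual correlation the nominal p-values are optimistic.
  No multiple-testing correction is applied; raw pairwise p-values are
  reported.
* **Logistic LR tests**: binomial-logit fits where each term's
  chi-square is the deviance difference from deleting that term's
  columns from the model matrix, with sum-to-zero contrasts so that
  deleting a main effect under its interaction gives a type-III-style
  effect test (the behaviour of the commercial package used for the
  original analyses). Complete separation — deviance at its zero
  boundary — is flagged on the returned object and warned about, never
  fatal: the LR statistics remain well defined when coefficient
  estimates diverge. Year enters the temporal-trend model as a
  continuous covariate (df = 1, matching the reported degrees of
  freedom across three or more sampling years); a categorical option
  exists behind a flag. The life-stage model expands individuals to one
  observation per chromosome with response "island entirely
  heterozygous" and tests chromosome (df 2), life stage (df 2) and
  their interaction.

## kdr and 2L recovery

The resistant kdr allele sits inside the 2L island and drove its
adaptive introgression from gambiae into coluzzii. Genotypes are
unphased, so "recovered haplotype" is operationalised at the individual
level: `COL_RECOVERED_2L` requires the resistant allele (RR or RS) plus
homozygous-coluzzii calls at the `k` centromere-proximal 2L loci
(default: all 5 — the conservative choice, since the source analysis
does not state how many loci define the coluzzii-like pericentromeric
region; `k` is a parameter). `GAM_LIKE_2L` is an entirely heterozygous
or homozygous-gambiae 2L; everything else — including
susceptible-allele coluzzii-typical islands of the pre-introgression
type — is `OTHER`. The recovery trend is a G-test of year against
{recovered, gambiae-like}. Where the resistant allele was scored at
both the L1014F (West African) and L1014S (East African) mutations,
`combine_kdr_calls()` merges the two locus calls; the default counts an
R at either locus, and a mode restricts to L1014F only.

## The forward simulator

The simulator generates the study system's data-generating mechanism,
not its demography:

* **Discrete, non-overlapping generations.** Two pools founded fixed
  for opposite alleles at all DIS loci (defaults 1000 + 1000);
  gambiae founders carry the resistant kdr allele at frequency 0.8,
  coluzzii at 0 — the resistant allele reaches coluzzii only by
  introgression.
* **Mating pools are X-island pools.** A male belongs to his hemizygous
  X's species; a female to her X species, flipping a coin over her two
  X haplotypes (per mating) when heterozygous. A fraction `h` of
  matings (default 0.01 — hybridization is rare) are cross-species.
* **Meiosis**: at most one breakpoint per island, uniform over adjacent
  marker gaps (the kdr interval, between 2L ranks 1 and 2, counts as a
  gap). Defaults `r_x = 0` (within-X recombination was never observed),
  `r_3l = 0.005 << r_2l = 0.05` (recombined 3L chromosomes were nearly
  two orders of magnitude rarer than recombined 2L). Sons receive the
  maternal X intact.
* **Selection**: offspring viability proportional to `(1+s)` per
  resistant allele (default `s = 0.2`, strong enough to sweep within
  the simulated six-to-ten-generation horizon), implemented as
  weighted sampling of the surviving cohort *within each species
  pool*. Within-pool density regulation reflects the species' separate
  larval niches and holds both pools at their founding sizes; without
  it, the resistant-rich gambiae pool would numerically displace
  coluzzii instead of the resistance allele sweeping through coluzzii,
  which is the opposite of the observed system.
* **Sampling**: recorded generations (default: the final three, so
  that trend analyses see multiple years) sample each adult with
  probability 0.5 into swarming / indoor-resting / larval collections
  (weights 0.5/0.3/0.2). Swarming individuals join a swarm of their
  X-island species — mis-assembled with probability `eps` (default 0)
  — in near-equal swarms of about 19, the field average.
  **X-heterozygous females reproduce but never appear in swarm
  samples.** This mirrors the data (zero X-heterozygous females among
  266 swarm females despite 72.9% backcrosses) and encodes the study's
  central premise that swarm-site behaviour is X-driven: an individual
  with no defined X species has no defined swarm. It is also what
  makes "X match proportion exactly 1.0 at `eps = 0`, `r_x = 0`" a
  structural property the pipeline must detect, rather than a
  statistical accident.

`recover_parameters()` estimates `h` as the realized fraction of
cross-species matings among surviving offspring and `eps` as the
frequency of swarm members whose X species mismatches their swarm's
intended type, both from the truth sidecar; both are exactly zero when
the parameter is zero.

**What the simulator does not emulate**: seasonality, migration,
density dependence, unequal or fluctuating species abundances, spatial
structure beyond swarm assembly, genotyping error, non-random
missingness, and selection against recombinants other than the kdr
advantage. Tests passing on simulated data therefore show that the
pipeline detects the mechanisms it encodes — perfect X association,
kdr-driven 2L introgression, parameter recovery — not that field data
will be as clean.

## Fixtures from published counts

`fixture_from_counts()` rebuilds datasets from per-stratum category
counts using one canonical pattern per category (backcrosses: one
entirely heterozygous heterospecific island — 2L for coluzzii, 3L for
gambiae, matching the dominant observed introgression directions — on
a homospecific background, which always preserves the requested
majority). Every emitted record classifies back to exactly the
requested category, so published composition tables replay through the
pipeline losslessly. One caveat is inherent: swarms whose mixed status
came from the other sex's members (the five females from mixed swarms)
cannot be re-derived from a single-sex fixture; their strata are
marked in the swarm id and excluded where the published analysis
excluded them.

## Numerical choices and problem sizes

* Tie-break: X-island species; `NA` on a heterozygous-X tie.
* Odds ratios: Haldane–Anscombe 0.5 correction only when a cell is 0.
* Fisher two-sided rule: probability ≤ observed × (1 + 1e-7).
* Separation: flagged when the full-model deviance is below 1e-6, or
  when the fitter warns of fitted probabilities at 0/1.
* Test problem sizes: classifier fuzzing at 10^5 random records;
  exact-test enumeration over all 46,376 2×2 tables with n ≤ 30;
  simulation studies at 2000 individuals × 10 generations with 20
  seeds (mechanism checks) and 100 seeds (error-rate recovery). These
  are the package's reference scales: large enough for the stochastic
  assertions' tolerances, small enough to run routinely.

## Known limitations

* The per-island observations in pairwise comparisons are correlated
  within individuals; reported p-values are anti-conservative.
* The 2L recovery classes are an unphased individual-level proxy for a
  haplotype-level statement; phase-aware estimation (e.g. EM over
  haplotype frequencies) is out of scope.
* The panel is id/rank-based: no physical coordinates, so nothing can
  be said about breakpoint positions beyond marker intervals.
* Published summary statistics that depend on unpublished
  per-individual data (the per-species logistic LR values, the exact
  temporal-trend and recovery chi-squares) are covered by qualitative
  and property-based tests, not numeric reproduction.
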