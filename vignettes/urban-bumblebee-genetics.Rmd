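---
title: "Methods: microsatellite conservation genetics of bumble bees along an urban gradient"
author: "bombusgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite conservation genetics along an urban gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bombusgen)
```

This vignette documents the models, assumptions, parameter choices and known
limitations behind `bombusgen`. The package addresses a recurring design in
pollinator conservation genetics: several bumble bee species are sampled at a
handful of sites along an environmental gradient, genotyped at 10–18
microsatellite loci, and asked (i) how many colonies each site supports,
(ii) whether subpopulations are differentiated or inbred, and (iii) whether
worker body size is spatially structured.

## The data model

A `genotype_dataset` stores integer allele calls (fragment lengths, bp) in
two individual-by-locus matrices plus a metadata frame (species, site, sex,
caste, recorded ploidy, optional thorax width). Missing calls are `NA` in
both slots — never allele 0, even though the GenePop encoding writes `000`.
Males deserve care in a haplodiploid system: a true haploid male scored by a
fragment analyzer shows one peak per locus and is recorded either as a
single allele (ploidy 1) or as an apparent homozygote (ploidy 2, the
"diploid candidate" form the diploid-male classifier needs). GenePop has no
haploid encoding for diploid-coded loci, so `write_genepop()` exports
haploids as homozygotes and restores them through a metadata sidecar,
keeping write/read round-trips lossless (a property the test suite checks on
randomly generated datasets). Allele codes are taken as scored; no binning
or rounding happens at read time, because binning belongs to the upstream
scoring software. The four study sites (CC, CW, ED, SNR) are defaults in
examples only — site and species are free categorical labels.

## The synthetic-data generator

Every statistical claim in the test suite is checked against data with known
truth, produced by a simulator that mirrors the biology the analyses assume:

* **Colony structure.** One queen per colony, mated once (monogyny,
  monoandry). The queen carries two alleles per locus drawn from her site's
  frequencies; the drone carries one. Every sampled worker inherits the
  drone allele plus one random queen allele, so full sisters share the
  paternal allele at every locus and have relatedness 0.75.
* **Differentiation.** Site allele frequencies derive from a common
  Dirichlet base by `t` generations of multinomial drift of `2*Ne` gene
  copies, with `t` solved from `1 - (1 - 1/(2Ne))^t = target_fst` at
  `Ne = 1000`. Drift — not island-model migration — is used so the same
  mechanism serves the power simulation. `realized_theta()` reports the
  large-sample Weir–Cockerham limit of the generated frequencies, which is
  what estimator-recovery tests compare against.
* **Sex determination.** A single csd locus (default 20 equifrequent
  alleles) is transmitted like any other locus; fertilized eggs homozygous
  at csd develop as diploid males. A `related_mating` knob makes the drone
  the queen's brother with the given probability, raising csd homozygosity
  the way inbreeding does. The data do not license a quantitative map from
  F_IS to diploid-male rates, so relatedness is exposed as a knob rather
  than asserted as a mapping.
* **Observation model.** Three independent error layers, applied in the
  order gene pool → scoring → amplification: hidden null alleles (one null
  per locus at a configured frequency: null homozygotes come out missing,
  null heterozygotes appear homozygous — the standard single-null model,
  chosen because only the downstream filter, not the mechanism, is
  specified); per-allele mistyping with probability ε (replacement by a
  frequency-weighted random allele); and whole-locus failure. Defaults are
  ε = 0.05 (the error rate the sibship stage also assumes), failure 0.05,
  nulls 0.
* **Body size.** Thorax width = cell mean (grand mean 4.5 mm plus planted
  site/species/interaction effects) + a colony effect shared by sisters
  (Normal, sd 0.25 mm) + residual (Normal, sd 0.3 mm), truncated at zero.
  Only site/species means are reported in the literature this emulates, so
  effect sizes are configuration, not constants.

The generator is seeded once; each stage derives a fixed offset sub-seed, so
a run is bit-reproducible. What the simulator does **not** emulate: spatial
foraging structure, colony demography over time, allele-size homoplasy,
locus-specific error profiles, and allelic dropout as a separate mechanism
(a single ε stands in for all scoring error). Tests passing on simulated
data therefore validate the estimators under the stated model, not the
field realism of that model.

## Quality control

Filters run in the order the analyses require: missingness → null-allele
screen → sibship → sister dedup → LD prune → HWE report. Within the
missingness filter, loci are filtered before individuals (an individual's
failure rate depends on the panel in use); both use the inclusive ≥ 20%
rule, per species. The null screen drops loci per species when the
heterozygote-deficit estimator r = (He − Ho)/(He + Ho) (unbiased He) reaches
0.25, and runs before sibship reconstruction only. HWE uses the exact-test
statistic — the conditional probability of the genotype array given its
allele counts — with a Monte-Carlo null from re-pairing the allele multiset;
microsatellite tables are too sparse for chi-square asymptotics. LD uses a
G-statistic on the joint genotype table with a permutation null; connected
components of significant pairs (raw p < 0.05, as is conventional for this
screen) collapse to the least-missing locus, ties broken by name, making the
pruned panel deterministic. Whether the original analyses pooled sites for
HWE/LD or stratified by site is not stated; the default here pools sites
within species (per-site strata can be passed explicitly via `rows`), and
the null screen likewise defaults to per-species strata. All p-values carry
the add-one correction and never return exactly 0.

## Sibship inference and colony density

The reference workflow reconstructs sibships with a third-party MCMC
pedigree sampler. `bombusgen` instead uses deterministic agglomerative
maximum-likelihood clustering: families start as singletons; the merge that
most increases the total partition log-likelihood is applied, but only if
the best linking pair between the two families has full-sib posterior
(uniform prior over full-sib vs unrelated) at or above 0.95; ties break
toward the smallest family index. Family likelihoods integrate all members'
genotypes over one shared queen (diploid, HWE at the reference frequencies)
and one drone (haploid), with each observed allele independently mistyped
with probability ε = 0.05. The published "95% probability of females being
full siblings" setting is interpreted here as that posterior admission
threshold — an interpretation, flagged as such. This trades the MCMC's
global search for reproducibility and testability: the greedy partition is
verified against brute-force enumeration over all set partitions on small
cases, and against truth at study scale (20 colonies × 3 workers, 10 loci ×
8 alleles, ε = 0.02), where the adjusted Rand index exceeds 0.90 in well
over 90% of replicates. Reference allele frequencies are plug-in estimates
from the same site's females, computed once, not iterated (pooled-species
frequencies can be supplied via `freqs`). Mistyping is class-I error only;
allelic dropout is not modelled separately because a single error rate is
all the reference setting specifies.

The density chain then runs on counts: `N_ns = (N_nr/N_g) × N_i`, `N_c =
4.5·N·n·m/(1+2m)` with n = m = 1 hence 1.5 × N_ns. All chain values are
computed unrounded and rounded to one decimal only for reporting — required
to reproduce printed values such as 19.6 (from (11/16) × 19 × 1.5 =
19.59375, which would round differently if intermediate rounding were
applied). Sites with `N_g ≤ 15` are skipped (reported as dashes).

## F-statistics and allelic richness

Weir–Cockerham components a, b, c are computed per allele with the standard
n_c correction and summed over alleles and loci: θ = Σa/Σ(a+b+c), f = 1 −
Σc/Σ(b+c). Only diploid females (post sister-dedup) enter; negative
estimates are reported as computed. Confidence intervals bootstrap loci —
the statistic is a ratio of per-locus sums, making the locus the natural
resampling unit; the reference software supports both jackknife and
bootstrap without stating which was used, and the bootstrap was chosen here
(`n_boot` configurable). Percentile intervals over ~10–20 loci are known to
be slightly anti-conservative in small panels, which is why the calibration
test asserts coverage of zero under panmixia at ≥ 0.85 rather than exactly
0.95.

Allelic richness uses the hypergeometric rarefaction expectation per locus.
Depth defaults follow the smallest-sample convention — twice the smallest
retained subpopulation (site AR) and twice the smallest species total
(global AR) — but are additionally capped at the smallest typed gene-copy
count across loci, because with any missingness a depth of exactly 2n would
exclude every locus; this mirrors how the standard rarefaction tools pick
attainable depths. The SE reported over loci is the simple standard error
of per-locus AR values (the aggregation is not stated in the reference
setting; this is the plain reading). Sites with fewer than 25 genotyped
females after QC are excluded from F-statistics and site AR but retained in
global AR.

## Male ploidy

A male is classified diploid when ≥ 3 scored loci are heterozygous. The rule
is exact and hard: males scored at fewer than 3 loci can never classify as
diploid; they are counted haploid for the percentage (which matches the
printed convention) and flagged `indeterminate` in the table. At ε = 0 a
true haploid can never appear heterozygous; at ε > 0 the false-diploid rate
is the binomial tail P(≥ 3 loci mistyped-to-heterozygous), which the tests
check in closed form. Whether males failing the missingness filter belong in
N_g is not stated in the reference setting; here N_g counts males with at
least one scored locus in the dataset handed to the summary (so the
pipeline's missingness filter determines membership).

## Power simulation

Study-like power for detecting differentiation: subpopulation frequencies
drift from near-uniform bases to the target F_ST (Ne = 1000, t solved from
the drift expectation; if both t and a target are supplied they must agree
to 1e-9), 2n gene copies are sampled per subpopulation per locus
(multinomial sampling under within-population HWE — no HWE departure is
injected), and the null of homogeneity is tested by per-locus Pearson
chi-square summed over loci, or by per-locus Monte-Carlo Fisher exact tests
combined via −2Σlog p. The Fisher test is Monte-Carlo rather than the
network algorithm — unbiased p with controllable error on sparse r×k
tables. The exact per-species settings of the reference power analysis live
in supplementary material not available here, so the defaults (10 loci × 8
near-uniform alleles, 4 subpopulations, 40 diploids each, 500 replicates)
are a reconstruction of the stated design, not a replication; at F_ST =
0.05 this design yields power ≥ 0.99 for the chi-square test and holds its
type-I error at the nominal 0.05 when t = 0.

## Body size

After sister dedup and exclusion of cells with ≤ 15 measured workers,
thorax width is modelled by OLS with species, site and their interaction
under sum-to-zero coding. With every retained cell observed, F tests are
partial (Type-III-style, via `car::Anova`); with missing cells partial
tests are not well defined, and the implementation falls back to
nested-model (Type-II) comparisons, flagged in the output — the reference
setting names the ANOVA but not the sum-of-squares type or coding, so these
defaults are documented choices, not assertions about the original. LS
means and intraspecific site contrasts come from `emmeans` on the fitted
model, with t tests on the residual degrees of freedom (no Satterthwaite)
and a Bonferroni threshold of α divided by the number of contrasts produced
(0.05/18 = 0.00278 for the canonical retained-cell pattern of five species
by four sites minus four excluded cells); comparisons use the exact value,
display rounds to five decimals. Colony random effects are deliberately
absent: after one-sister-per-colony dedup each colony contributes one
worker, which is what justifies the fixed-effects ANOVA.

## Numerical and design notes

* Partition likelihoods are accumulated per locus in scaled product tables
  with log offsets; the merge loop asserts the partition log-likelihood is
  non-decreasing at every accepted step.
* Family-pair scores use BLAS cross-products over parent-configuration
  tables, so a 60-female site partitions in well under a second.
* Monomorphic loci return (0,0,0) components, AR equal to 1, HWE p = 1, and
  a flagged null-allele estimate of 0 — all excluded from ratios rather
  than propagating NaN.
* Rounding policy everywhere: compute unrounded, round at the reporting
  layer (one decimal for the density chain, two for diploid-male
  percentages, five for the displayed Bonferroni threshold).
* Problem sizes in the test suite (e.g. 100 sibship-recovery replicates at
  20 colonies × 3 workers; 500 null loci for HWE size; 3 replicates per
  differentiation target) were chosen as the smallest designs whose
  Monte-Carlo error is comfortably inside the asserted tolerances.

## Limitations

Polyandrous or polygynous colonies are handled only through the general
Crozier formula, not by the sibship model, which assumes strict full-sib
families. Exact numerical replication of the third-party MCMC sampler's
partitions is out of scope by design — on real data the density chain takes
its detected-colony counts wherever they came from. The F_IS ↔ diploid-male
link is qualitative; the package measures both but does not fit a joint
model. Geographic covariates (human population density, floral richness)
and map rendering are outside the package's scope.
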