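---
title: "Detecting and simulating an inversion supergene: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and simulating an inversion supergene: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supergene)
```

## The problem

A chromosomal inversion that captures several co-adapted loci is
inherited as a single Mendelian unit: recombination is suppressed in
inversion heterozygotes, so the two arrangements (here called A and B)
accumulate divergence while the rest of the genome is homogenised by
gene flow. In diploid genotype data this leaves a characteristic
signature:

* a single genomic region of high differentiation (FST, dXY) between
  carriers of alternative arrangements, against a near-zero genome-wide
  background;
* three clusters on PC1 of the region's genotypes, corresponding to
  the AA, AB and BB karyotypes, with the middle cluster roughly
  doubling in observed heterozygosity;
* elevated linkage disequilibrium across the region relative to the
  rest of its chromosome and to other chromosomes;
* if the arrangement affects a phenotype additively, a monotone
  AA < AB < BB ordering of phenotype means, and possibly a spatial
  (e.g. latitudinal) cline in arrangement frequency.

The package implements the full desk-scale workflow around that
signature: a synthetic-cohort generator with a planted inversion; the
windowed scan and LD statistics that localise it; PCA-plus-
heterozygosity karyotyping; a cline test and a surrogate association
scan; ABBA-BABA introgression tests and gene-tree topology weighting
for the question of where the B arrangement came from; and two
spatially explicit forward-time models of how the polymorphism is
maintained.

## Statistics

Per-site nucleotide diversity for variant sites uses the unbiased
pairwise estimator $\pi = \frac{n}{n-1} 2 p (1-p)$ over the $n$
non-missing chromosomes of a group; between groups,
$d_{XY} = p_1(1-p_2) + p_2(1-p_1)$. Windowed FST is the Hudson
ratio-of-averages $1 - \overline{H_W} / \overline{H_B}$ with
$H_W$ the mean of the two groups' per-site $\pi$ and $H_B = d_{XY}$,
computed over sites usable in both groups (at least two chromosomes
each). Hudson's estimator was chosen for its robustness to unequal
sample sizes; the choice is recorded in the scan output header, and
negative estimates are reported rather than clipped so that the
estimator's sampling behaviour stays visible. All of these equal
brute-force enumeration of differing chromosome pairs, which is how
the tests verify them.

LD is composite genotype $r^2$ — the squared Pearson correlation of
dosage vectors over pairwise-complete samples — because the data model
is unphased diploid calls. Decay curves bin all within-region pairs by
inter-site distance; the default 100 kb range with 20 kb bins is an
arbitrary reporting choice, exposed as parameters. Under linkage
equilibrium the finite-sample expectation of $r^2$ is about $1/n$,
which the tests use as the null reference.

The D statistic is the symmetric frequency form
$D = \sum (\mathrm{ABBA} - \mathrm{BABA}) / \sum (\mathrm{ABBA} +
\mathrm{BABA})$ with both allele polarisations counted
(ABBA $= (1-p_1)p_2p_3(1-p_4) + p_1(1-p_2)(1-p_3)p_4$), so the result
does not depend on which allele is labelled alternate; when the
outgroup is fixed ancestral this reduces to the familiar polarised
form. Significance comes from a delete-one-block jackknife over
contiguous site blocks (default 100 sites at synthetic scale) with the
weighted variance formula for unequal blocks, $Z = D/SE$ and a normal
two-sided p.

Topology weighting follows the taxon-subsampling logic: for a gene
tree with several tips per group, the weight of each taxon-level
topology is the fraction of one-tip-per-group subsamples whose induced
unrooted topology matches it. Topologies are enumerated recursively
(the catalog size is $(2g-5)!!$) and matched by canonical split sets;
exact enumeration is used up to 10,000 combinations, Monte-Carlo
subsampling beyond. Matching is unrooted even though empirical trees
are usually outgroup-rooted: the outgroup is simply another group, so
a rooted sister relationship is recoverable as an unrooted cherry.

## The synthetic cohort

`cohort_config()` defaults define the study conditions: 72 samples
with karyotype counts 37 AA : 7 AB : 28 BB and ecotype counts
26 common / 32 hoary / 14 lesser (the sample whose exclusion brings a
73-sample design to 72 is debited from the hoary count; the choice is
arbitrary and only affects a label), 27 samples labelled non-breeding.
Background sites (2,000 across a 10 Mb and a 5 Mb chromosome) draw one
Beta(0.8, 0.8) frequency per site shared by all samples — a
gene-flow-homogenised genome with realistically U-shaped frequencies
and no population structure. Inversion sites (500 in chr1:3–7 Mb) have
pool frequencies $p_A$ and $p_B$ differing by exactly `d`
(default 0.8); each individual draws two haplotypes from the pools its
karyotype dictates. Sites are independent within pools: recombination
suppression is *implicit* here, which is sufficient for the PCA, FST
and LD signatures; explicit linkage lives in the forward simulator.
Twenty modifier sites on chr2 differentiate the lesser ecotype with a
fixed pool-frequency difference of 0.8; their phenotype effect
(default 0.3 in total) is arbitrary, as no quantitative value exists
for it. Phenotype is `dosage(B) * beta_inv + modifier score + N(0,
0.25)`; latitude is Gaussian (`sd` 3°) around `55 + 4 * dosage(B)` —
a location-shift cline, since only the shift direction is knowable.

What the generator deliberately does not emulate: kinship and
population structure (so the association scan needs no mixed model),
coalescent linkage in the background, sequencing error, and
depth-dependent artefacts. Pipeline tests passing on these cohorts
therefore validate the statistical machinery, not robustness to those
real-data complications.

## Karyotyping

`call_inversion_genotypes()` runs PCA on the region's dosages after a
40% MAF cut (which enriches for sites segregating *between*
arrangements), mean-imputing missing dosages, then clusters PC1 with
deterministic 1-D k-means initialised at the 1/6, 3/6, 5/6 quantiles.
Because a PC's sign is arbitrary, PC1 is oriented so the larger outer
cluster sits leftmost before applying the AA/AB/BB labels left to
right; the applied orientation is recorded. The middle cluster must
out-heterozygose both outer clusters, otherwise the call set is
flagged (`het_check_passed = FALSE`) rather than rejected — with no
planted divergence the clusters are noise partitions and the flag is
the caller's warning. The latitude cline test is Kendall tau-b of
B dosage against latitude with a seeded permutation p (10,000
permutations by default).

The association scan is a per-site linear trend test (t on the slope
of phenotype against dosage). It is deliberately *not* a mixed model:
the synthetic cohorts carry no kinship, so a relatedness-corrected
model would be fitting structure that does not exist. On real,
structured data a mixed model is required, and the function's
documentation says so.

## The two maintenance models

Both models are non-overlapping-generation, individual-based forward
simulations of `N` diploids carrying one inversion locus (alleles A/B)
plus neutral biallelic loci on a 100 kb chromosome with a 50 kb
inversion. Phenotype is additive, $\phi = g/2$ for B dosage $g$, and
is matched against a selection gradient along the y-axis of the unit
square: fitness is $\max(0, 1 - s\,|y - \phi|)$, i.e. linear in
mismatch and truncated — the simplest interpretable form, isolated
behind `sim_fitness()` so alternatives are pluggable. Mothers are
sampled in proportion to fitness; each picks a mate weighted by
fitness times the assortment kernel $(1-a)^{|\Delta g|}$, a
dimensionless geometric-in-dosage choice with $a = 0$ random mating
and $a \to 1$ forbidding cross-karyotype pairs. Mating is
hermaphroditic (the models have no sexes). Offspring disperse from
the mother with a reflected Gaussian kernel (SD 0.05). Gametes
receive Poisson crossovers (rate per bp times 100 kb) at uniform
positions; crossovers inside the inversion are rejected when the
parent is inversion-heterozygous, so inside-loci stay linked to their
arrangement — the mechanism whose consequences the scan modules then
detect (`init_neutral_from_inversion = TRUE` starts the neutral loci
fully diverged between pools to make that linkage signature visible
on short runs).

Model 1 adds local competition: fitness is divided by
$1 + c \cdot n_{\text{neighbours}}$ within a 0.1 radius
($c = 0.02$), so sparse neighbourhoods are rewarded. Model 2 has two
unit squares spanning the *same* gradient, initialised fixed for
alternative arrangements (the two populations represent the two
homozygote ecotypes); each offspring migrates with probability `m`,
keeping its coordinates and switching squares, and each square is
regulated to its own half of `N`.

Two geometry decisions deserve justification because both were
genuinely open and both were settled by the behaviour of the model
family rather than by taste:

* **Mate choice is population-wide by default** (the default search
  radius exceeds the habitat diameter). With a small radius,
  spatially local mating creates de-facto assortative mating — near
  neighbours are mostly same-karyotype once the gradient sorts
  individuals — and the polymorphism then survives as a cline even
  with `a` near zero, erasing the distinction the assortment
  parameter is supposed to control. With population-wide mate choice,
  space acts only through selection, competition and dispersal, and
  the regimes separate cleanly: weak assortment loses an arrangement
  to drift, strong assortment maintains both with almost no
  heterozygotes.
* **Model 2's squares share one gradient rather than continuing it
  across populations.** A continued gradient makes the heterozygote
  the interface generalist: its expected mismatch under migration
  mixing is half that of the homozygotes, so high migration *creates*
  a heterotic balanced polymorphism instead of destroying one — the
  opposite of the documented behaviour of this model family. With
  replicate habitats on one (latitudinal) gradient, high migration
  merges the gene pools and drift removes an arrangement, while low
  migration keeps the two squares fixed for alternative arrangements
  with rare migrant-descended heterozygotes.

Simulation conditions: the historical-scale configuration is
`N = 1000`, 10,000 generations, 50 iterations. The package's tests
and acceptance script run the scaled regime `N = 200`, 2,000
generations, 20 iterations per cell on 3x3 grids
(`s` in 0.25/0.5/1.0 crossed with `a` in 0.05/0.5/0.95 or `m` in
0.25/0.005/0.0005), which preserves the drift-to-selection scaling
`generations / N = 10` of the full design; an iteration stops early
once an arrangement fixes, because fixation is absorbing. The
sweep reports, per cell: the stable fraction (both arrangements
segregating at the end), mean karyotype counts over stable
iterations, the signed heterozygote-ratio difference from the
observed 37:7:28 sample, and gradient stratification. For
stratification the per-class mean positions are computed over classes
with at least five members — the mean position of a one-individual
class is noise, and stable strong-assortment runs hold heterozygotes
at a handful of copies.

Numerical conventions: coordinates are folded back into the unit
square by reflection; the neutral mutation rate (default $10^{-3}$
per locus per gamete) and crossover rate (default $10^{-6}$ per bp)
are declared stand-ins chosen so that 40 loci acquire polymorphism
within scaled run lengths; all randomness flows through R's RNG, so a
seed makes runs bit-reproducible, including inside the compiled step
function.

## Degenerate inputs and tie-breaks

Sites with fewer than two non-missing chromosomes are skipped (not
errors) in diversity statistics; windows with no usable site carry
`NA`. Monomorphic sites have undefined $r^2$ and are skipped. A
zero jackknife SE (identical blocks) yields a floored p with a
warning. 1-D k-means breaks exact quantile ties by an infinitesimal
perturbation and errors when fewer than k distinct scores exist.
The MAF filter computes frequencies over non-missing alleles across
the whole dataset (per-dataset, not per-group — the convention had to
be fixed one way) and half-calls are conservatively treated as
missing.

## Known limitations

The association surrogate will be anticonservative on structured real
data. The cohort generator's implicit-linkage design cannot produce
LD *decay* within the inversion (all inversion pairs are equally
correlated), only the inside/outside contrast. Topology weighting
assumes binary input trees. The forward models are deliberately
minimal: no mutation to new inversions, no load accumulation or
degeneration dynamics inside the arrangement, no sexes, and habitat
boundaries are reflecting; conclusions about real systems should rest
on the regime structure, not on absolute parameter values.

## A worked run

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config())
inv <- variants_in_region(co$genotypes, "chr1", 3e6, 7e6)
calls <- call_inversion_genotypes(co$genotypes, region = inv)
attr(calls, "cluster_het")
table(calls$genotype)

cfg <- sim_config(model = 1, N = 200, generations = 2000,
                  iterations = 20, n_neutral_loci = 0, seed = 1)
sweep_simulations(cfg, s_values = c(0.25, 0.5, 1),
                  axis_values = c(0.05, 0.5, 0.95))
```

The package-level reproduction of all headline quantities is
`scripts/acceptance.R` in the source repository, runnable as
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.
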