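---
title: "Inferring genome exchange in mixed-ploidy unisexual Ambystoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring genome exchange in mixed-ploidy unisexual Ambystoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kleptopop)
```

## The inference problem

Unisexual salamanders of the *Ambystoma laterale–jeffersonianum* complex
reproduce by kleptogenesis: females need sperm from a sympatric sexual
species to trigger egg development, but may or may not incorporate the
sperm genome.  Each individual carries one haploid chromosome set (a
*haplome*) per ancestral species — here J (*A. jeffersonianum*) and L
(*A. laterale*) — in combinations LJ, LLJ or LLLJ, alongside pure LL
sexuals.  A reproductive event can be clonal, elevate ploidy (sperm
haplome added), reduce ploidy (one haplome dropped), or replace one L
haplome with a sperm-derived one.

The package infers which of these regimes shaped a sampled population
from co-dominant microsatellite genotypes.  The logic rests on an
asymmetry: where no *A. jeffersonianum* occurs, the J haplome can only be
transmitted clonally, so J variation measures the mutational background,
while any *excess* L variation — host-typical alleles many mutation steps
from the unisexual cluster, within-site rather than among-site
dispersion, surplus allelic richness — is the footprint of genome
exchange with local LL populations.

## Data model

`MsatDataset` stores, per individual and locus, the *distinct* allele
sizes observed (bp).  Multiplicity is deliberately unrepresented: a
triploid that is AAB or ABB at a locus is typed AB either way (a
*partial heterozygote*), so copy number must be inferred rather than
read.  Missing data is an empty cell.  A locus table carries the repeat
motif length and the species-diagnostic allele-size ranges; because J
and L ranges never overlap where both amplify, each allele can be routed
to a J or L *isolocus* (`splitIsoloci()`).  Alleles outside both ranges
are quarantined in a `-U` column with a warning rather than guessed.

Biotype calling (`callBiotypes()`) takes, per haplome, the maximum
number of distinct alleles over that haplome's isoloci: a partial
heterozygote can under-report copy number but never over-report it, so
the maximum is the tightest defensible lower bound.  The (L, J) copy
pair maps onto LL, LJ, LLJ or LLLJ; combinations outside that ladder
(e.g. three distinct J alleles) are left UNCALLED and excluded from
downstream distance analyses.  A consequence worth knowing: an
individual whose L haplomes happen to be identical at *every* L isolocus
is indistinguishable from a lower-ploidy one, and is called at the lower
ploidy.  On simulated clonal populations with heterozygous founders the
calls are exact; under heavy exchange a few percent of individuals are
genuinely information-free in this sense and are under-called — never
over-called.

Genetic groups are assigned from a small set of multimodal J loci whose
allele clusters sit at least eight mutation steps apart.  The rule table
names the consensus genotype and each group's diagnostic allele(s);
`assignGroups()` matches alleles up to a step tolerance (default 2,
i.e. under half the smallest gap), so that the one- or two-step
mutational wobble expected within a clonal lineage does not eject
individuals from their cluster, while the 8+-step gaps keep clusters
unconfusable.  Individuals whose deviations from the consensus are not
explained by exactly one group's diagnostics get `X`; missing data at a
diagnostic locus gives `UNASSIGNED`.

## Genotype distance

The allele-level dissimilarity is the stepwise-mutation-model transform
$d(a,b) = 1 - 2^{-x}$ with $x = |a-b|/\ell$ mutation steps for motif
length $\ell$: one step gives 0.5, and $d$ saturates toward 1 as alleles
diverge, which is what makes "highly divergent" host alleles so visible.
Size differences that are not whole repeat units are rounded to the
nearest step with a warning (fragment-size jitter is assumed binned
upstream).

For equal ploidy $k$, the genotype distance is the minimum over all
one-to-one allele assignments of the mean allele distance — enumerated
exhaustively, since $k \le 4$ gives at most $4! = 24$ assignments; an
exact minimum is cheaper and more transparent than an assignment solver
at this size.  For unequal ploidy the smaller genotype is completed with
virtual alleles under two models: *genome addition* draws them from the
smaller genotype's own alleles, *genome loss* from the larger genotype's.
All completions are enumerated, each scored as an equal-ploidy distance,
and averaged; with both models requested (the default) the final value
is the mean of the two model averages.  Completions are averaged, not
minimized, so the distance reflects the expectation over the unobserved
resolution rather than the most favorable one.

Partial heterozygotes are expanded the same way before comparison: a
genotype showing $k$ distinct alleles at an isolocus with biotype-implied
copy number $c > k$ has its $c - k$ unresolved copies drawn from the
observed alleles, and each completion is weighted by the product of
reference allele frequencies of the duplicated alleles, renormalized.
Frequencies come from `estimateAlleleFrequencies()`, where each
individual contributes its copy number split uniformly over its observed
alleles.  The default weighting scope is per site — imputation should
reflect the population the individual actually lives in — with global
and per-group scopes available.  Two conventions are worth stating
because either choice would be defensible: unresolved copies are treated
as drawn *independently* (ordered draws, giving multinomial weights to
multisets), and an allele absent from the frequency table is floored at
the minimum observed frequency with a warning instead of zeroing out its
completions.

`bruvoDistanceMatrix()` averages per-isolocus distances over the loci
where both individuals are scored (pairs sharing no locus are an error),
for the J, L, or combined LJ isolocus sets.  Origin-unresolved `U`
isoloci are never included.

## Trees, consensus and spatial structure

Neighbor joining is delegated to `ape::nj`, with negative branch lengths
clamped to zero; on additive distances it provably recovers the
generating tree, which the tests exercise.  Locus bootstrapping
resamples isoloci with replacement, rebuilds the matrix from
precomputed per-locus distances, and scores each bipartition of the
full-data tree by its replicate frequency; nodes under the collapse
threshold (default 50%) are contracted into polytomies.  The
majority-rule consensus implements the *extended* rule: splits in more
than half the trees are kept, then remaining splits are added greedily
by frequency (ties broken by the lexicographically smallest bipartition
encoding) whenever compatible.  AFLP data enter through the
simple-matching distance (share of mismatching bands).

Spatial structure uses Hellinger distances between site composition
profiles (square-rooted relative abundances, Euclidean), haversine
great-circle site distances in km, and permutation Mantel tests with the
+1 convention (the observed statistic counts in numerator and
denominator, so p is never 0).  The Mantel correlogram uses equal-width
distance classes over the observed range (20 by default) with
progressive Holm correction; the first-class upper bound is reported so
short-range autocorrelation claims can be checked against it.

## Exchange diagnostics

*Divergent alleles* (`detectDivergentAlleles()`): per isolocus, alleles
are clustered by single-linkage with gaps under the threshold (default
8 steps, matching the empirical gap between unisexual and host-typical
allele classes); everything outside the largest cluster is flagged with
its gap.  Two equal-sized largest clusters raise an error demanding
manual designation rather than an arbitrary choice.  Carrier frequencies
count haplome copy *slots* (unresolved multiplicities split uniformly) by
default, with a per-individual denominator available, and
`probNoCarrier()` gives the probability $(1-p)^n$ of never sampling a
carrier — the quantity that turns "group A shows no divergent alleles"
into evidence rather than absence of evidence.

*Alternative alleles* (`alternativeAlleles()`): rarefied allelic
richness (exact hypergeometric rarefaction) minus the number of distinct
alleles strict clonality would show, floored at zero and averaged over
an isolocus set.  The clonal baseline is the distinct-allele count of
the unit's modal (consensus) genotype — the count that clonal
propagation alone would produce, which makes a perfect clone score
exactly zero; a minimum-over-individuals baseline is available by flag.
Rarefaction sizes are weighted haplome counts (a group of three LLJ and
one LJ has $n = 7$ L copies but $n = 4$ J copies), and
`alternativeAlleleReport()` rarefies all compared units to the smallest
such count so J and L sets of different ploidy are compared on equal
copies; a fixed size can be passed instead.

*Dispersion partition* (`dispersionPartition()`): the distance matrix is
embedded by principal coordinates with negative-eigenvalue axes retained
(squared distances to centroids are positive-axis minus negative-axis
contributions, floored at zero — the standard treatment for semi-metric
distances, computed via `vegan::betadisper` with centroid distances).
Per group, `total` is the mean distance to the group centroid, `intra`
the mean distance to the (group × site) centroid, and
`inter = total - intra` (floored at zero with a warning in the rare
non-Euclidean case), with percentages of total.  One-way ANOVA plus
Tukey HSD on the per-individual centroid distances yields compact letter
codes for group comparison.

The two regimes then read directly off the outputs: mutation-only
lineages show similar J and L alternative alleles, zero divergent-allele
carriers, and among-site-dominated dispersion (new mutations are
site-local); exchanging lineages show L ≫ J alternative alleles,
host-level carrier frequencies, and within-site-dominated dispersion
(exchange keeps injecting host diversity inside each site while drawing
from similar pools everywhere).

## The simulator

`simulateKleptogenesis()` is a forward-time model whose purpose is to
produce datasets with known truth for every pipeline stage, not to fit
parameters.  Demes (one per group per site) evolve in discrete
non-overlapping generations; each daughter's mother is drawn uniformly
from the previous generation at constant deme size.  This Wright–Fisher
resampling is deliberate: if every female left exactly one daughter,
all lineages would have independent ancestries, within-site diversity
would match among-site diversity, and the clonal among-site signature
could not exist.  Coalescence within demes plus independent founding of
sites is the minimal structure that produces it.

Events per daughter follow the kleptogenesis menu: clonal (default),
replacement of a uniformly chosen L haplome by a host gamete, elevation
(gamete appended, no-op at LLLJ), reduction (uniform L haplome dropped,
no-op at LJ).  J haplomes are never exchanged (no *A. jeffersonianum*
in the modeled area).  Host pools are stationary per-site allele
frequency tables — hosts are a boundary condition, not a co-evolving
population.  Every haplome-locus then mutates by one repeat unit
(direction 50/50) with probability `mu`, reflecting at the configured
range bounds so alleles stay inside their diagnostic windows.

Preset defaults are chosen once as plausible study conditions:
tetranucleotide motifs; eight J and four L isoloci; `mu = 5e-4` per
haplome-locus per generation (mid-range for tetranucleotide
microsatellites); demes of 40 females; 400 generations (salamander
lineage ages far exceed local coalescent times, and this ratio of
divergence time to deme size lets among-site divergence dominate
within-site drift under clonality); four sites for the single-group
presets (a partition estimated from a single between-site contrast is
an unstable quantity, as in any field design); host pools of 5–6 alleles
per locus (expected heterozygosity ≈ 0.8) including a divergent class
~9 steps away at frequency 0.29 on two of the four L loci.  Event rates
for exchanging presets are 0.10 replacement, 0.02 elevation, 0.01
reduction per female-generation — invented order-of-magnitude values
(no empirical estimates exist) with elevation above reduction because
the complex is triploid-dominated.  Sampling is without replacement at
the final generation; 15 unisexuals per site plus 10 LL hosts where a
pool exists.

What the simulator does *not* emulate, and therefore what passing tests
cannot certify about real data: allele-size homoplasy across lineages,
non-stepwise mutations and null alleles, genotyping error, migration
between sites, host populations that drift or differ among sites, and
the LLJJ pathway.  The tests demonstrate that the statistics separate
the regimes when the model's assumptions hold; on real data the same
statistics inherit those assumptions.

## Numerical and design notes

* Test and validation problem sizes: distance-matrix and tree operations
  are exercised at 40–80 individuals and 8–12 isoloci; regime-recovery
  checks run 8 replicates per preset at the default conditions;
  calibration checks use 500 replicates (999 permutations each) for the
  Mantel type-I error and 500 replicates for dispersion-comparison
  power.
* Consensus genotype ties break toward the lexicographically smallest
  allele vector; consensus-tree split ties toward the smallest
  bipartition encoding; NJ inherits `ape::nj`'s deterministic
  tie-breaking.  All stochastic steps take explicit seeds and are
  bit-reproducible.
* Degenerate inputs have defined behavior rather than NA surprises:
  empty genotypes propagate as missing and are dropped from locus means;
  a pair sharing no locus, a constant Mantel matrix, a zero-band AFLP
  matrix, an all-zero abundance row, and a single-locus bootstrap are
  errors; an all-zero distance matrix yields a zero dispersion
  partition; singleton groups report NA.
* `(1,0)` copy pairs (a single distinct L allele and no J anywhere) are
  left UNCALLED rather than presumed homozygous LL.

## Limitations

The package deliberately stops short of estimating exchange *rates* or
distinguishing one-generation replacement from elevation-then-reduction
chains — the data cannot separate them.  Diagnostic ranges and rule
tables must be supplied (or taken from the simulator presets); no
empirical *Ambystoma* genotypes ship with the package.
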