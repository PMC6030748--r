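---
title: "Models and methods: population structure across watershed boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: population structure across watershed boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the estimators, the simulation engine, the design decisions
taken where the design was genuinely open, and the limits of what the
synthetic data can demonstrate.

## The data model

Microsatellite genotypes are diploid, unordered pairs of allele sizes in
base pairs, with whole-genotype missingness only (the Genepop interchange
format cannot represent half-calls, so a genotype with one unreadable
allele is recorded missing). Each locus carries a repeat-motif length;
statistics that live on the repeat-count scale (R~ST~, the stepwise
mutation model, allele-size variance) convert through
`(size − offset) / motif`, with the minimum observed allele as the
per-locus offset. The offset choice is immaterial for every statistic we
compute: R~ST~ and (δμ)² are invariant to adding a constant to all sizes
at a locus, which is also verified by test.

Populations map to higher-level groups — watersheds — through a grouping
scheme that carries coordinates and a pairwise distance matrix in km.
Distances are great-circle by default and can be replaced by hydrographic
(river-km) matrices; the matrix is tagged with its provenance because the
two supports answer slightly different isolation-by-distance questions.
Both are supported; the packaged workflow uses whichever matrix the
grouping scheme carries.

## The coalescent engine

Every simulated dataset comes from one engine: an exact discrete-event,
continuous-time coalescent over a set of populations with
piecewise-constant diploid sizes. Backward in time, lineages within a
population coalesce at rate k(k−1)/(4N~e~); `origin` events move all
lineages of a population into its source (a forward-time founding),
`admix` events route each lineage independently to one of two sources
with probability r, and `ne_change` events switch a population's size —
successive changes build founding bottlenecks. Loci are unlinked: one
independent genealogy per locus, no recombination within a locus (a
microsatellite is a point locus), no selection. Generation time is fixed
at one year, so times in years and generations coincide throughout.

Mutation follows the generalized stepwise model: mutations are Poisson on
branches, each changes the repeat count by a geometrically distributed
number of units (parameter `p_geom`; 0 gives the strict one-step model),
and states reflect into a bounded range of 40 contiguous states by
default — a standard convention for bounded microsatellite state spaces.
Per-locus rates are Gamma-distributed around the mean rate (shape 2 by
default, mean 5×10⁻⁴/generation), reflecting the usual across-locus rate
heterogeneity; both are configurable and documented rather than asserted
as any study's true values. The engine's one strong validation is the
closed form for strict-SMM equilibrium gene diversity,
E[H~e~] = 1 − 1/√(1+8Nμ): the test simulates 500 loci at N = 1000,
μ = 5×10⁻⁴ with a widened state range (80 states), because the closed
form assumes an unbounded ladder and reflecting boundaries at the default
range depress diversity by about one Monte-Carlo standard error.

## Estimators

**Heterozygosity.** H~e~ is Nei's unbiased estimator
2n/(2n−1)·(1 − Σp²). The bias correction matters at the fixture's
smallest sample (9 individuals); unbiasedness is verified by simulation
against 1 − Σp² at known frequencies.

**Allelic richness** uses hypergeometric rarefaction to g = 18 gene
copies (9 diploids — the smallest sample in the design), the FSTAT
convention. AR is undefined, not extrapolated, where 2n < g.

**Hardy–Weinberg tests** use the exact probability test: the p-value sums
Levene-conditional probabilities of all genotype configurations no more
probable than the observed one. Enumeration is exact for ≤3 alleles and
n ≤ 100; beyond that a Metropolis chain over configurations estimates the
p-value with a batch-means standard error. The chain's proposal swaps one
allele copy between two random individuals; because selecting a given
allele from a heterozygote has probability ½ but from a homozygote 1, the
Hastings correction exactly cancels the 2^H factor of the target, so
acceptance depends only on the factorial part — a classical but easy to
miss detail.

**Null alleles** are estimated by EM under HWE with one non-amplifying
allele: apparent homozygotes split into true homozygotes and
visible/null heterozygotes in the E-step. Missing genotypes can be
counted as null homozygotes (off by default; when off, the unseen
null/null class is augmented with its conditional expectation, the EM for
a truncated multinomial). When the maximum sits on the boundary p~N~ = 0
the EM approaches it sublinearly, so an iterate below the tolerance is
declared converged to the boundary rather than iterating forever.

**Weir–Cockerham θ** is computed from the 1984 a/b/c variance components,
summed over alleles and loci before taking the ratio. Negative estimates
are reported as-is — truncation would bias averages of weakly
differentiated pairs. Permutation tests shuffle individuals between the
two populations and use the add-one convention
p = (1+#{θ* ≥ θ})/(B+1), so p is never exactly zero.

**R~ST~** is the two-level variance-component ANOVA on repeat counts with
gene copies as units, components summed across loci before the ratio
(the SPAGeDi pooling). The allele-size permutation test shuffles which
size belongs to which allelic state within each locus — allele identities
and frequencies are untouched, so drift-driven differentiation is
preserved under the null while size information is destroyed. R~ST~ above
the permutation distribution indicates stepwise mutations contribute,
i.e. divergence old enough for mutation to matter.

**AMOVA** is three-level (group / population within group / within
population) on allele copies with the different-allele (0/1) metric,
under which sums of squared distances reduce to allele-count identities:
SSD of a set with copy counts c~a~ and total N is (N² − Σc²)/(2N).
Components use the standard unequal-size coefficients per locus and sum
across loci. The phrase "10,000 bootstraps" attached to F~CT~ testing in
this literature is operationally a permutation of whole populations among
groups, and that is what we implement; bootstrap resampling is not a
significance test for F~CT~.

**Isolation by distance** regresses F~ST~/(1−F~ST~) on ln distance;
pairs at F~ST~ = 1 are excluded with a warning because the transform is
undefined. The Mantel test is delegated to `vegan::mantel` (population
labels of one matrix permuted), seeded for determinism.

## Clustering

The admixture sampler follows the standard correlated-allele-frequencies
model: ancestral frequencies P~A~ with a Dirichlet(λ = 1) prior, cluster
frequencies Dirichlet(P~A~(1−F~k~)/F~k~) with drift parameters F~k~ under
a truncated N(0.01, 0.05²) prior, per-copy cluster labels Z, memberships
Q with a symmetric Dirichlet(α) prior, and a single α for all clusters
moving by a Metropolis walk (step 0.025) under a uniform(0, 10) prior —
the cited program's defaults where the literature is silent. Missing
copies are dropped from the likelihood, not imputed. ln Pr(X|K) is the
usual mean(logL) − var(logL)/2 over post-burn-in sweeps. Desk-scale
defaults (20 000 sweeps, 5 000 burn-in; the packaged analyses use
2 000/500) are deliberate: the fixture's clusters are strongly separated
and chains equilibrate within hundreds of sweeps, which the
two-seed-agreement test monitors.

ΔK is Evanno's criterion,
|mean lnP(K+1) − 2 mean lnP(K) + mean lnP(K−1)| / sd(lnP(K)), undefined
at the end points and reported infinite (flagged) when the replicate
spread is zero. Replicate runs are aligned greedily against the running
average with the similarity G = 1 − ‖Q₁−Q₂‖~F~/√(2n), exhaustively over
column permutations for K ≤ 7 and by greedy column matching above; the
exhaustive-vs-greedy agreement is tested for small K. Factorial
correspondence analysis codes individuals as 0/1/2 allele counts
(missing mean-imputed per column) and takes the chi-square-metric SVD;
coordinates are verified against an independent dense decomposition to
10⁻⁸ up to axis sign.

## Haplotype networks

Alignment columns containing N or a gap in any sequence are excluded
alignment-wide before comparison — the simplest defensible ambiguity
rule, applied identically to every sequence so haplotype collapsing is
order-independent. The median-joining construction iterates: build the
ε-relaxed minimum spanning network on Hamming distances (an edge of
weight d is kept iff its endpoints are not connected using edges of
weight < d − ε; ε = 0, the default, yields the union of all minimum
spanning trees); for every triple of nodes connected by at least two
network links, add the sitewise majority-consensus (median) vector when
it shortens the triple's connection; stop when no median is added, then
prune inferred medians of degree < 3. Ties in median construction take
the state of the lexicographically smallest sequence, which makes the
network independent of input order. With ε = 0 and homoplasy-free data
the output equals the minimum spanning tree (tested).

## Approximate Bayesian computation

Summary statistics are the classical microsatellite set: per group, mean
allele number, mean unbiased gene diversity and mean allele-size variance
(repeat units); per group pair, Weir–Cockerham F~ST~, the shared-allele
distance DAS (1 − mean proportion of shared alleles between cross-group
individuals) and the (δμ)² distance (squared difference of mean allele
size, averaged over loci). The vector order is fixed and documented, so
observed and simulated vectors always align.

Reference tables draw parameters from uniform priors (event-order
constraints enforced by rejection), simulate with the shared engine, and
record statistics; tables are seed-deterministic. Statistics are
standardized by their reference-table median absolute deviation — a
robustness choice over the standard deviation, since several statistics
are heavy-tailed under wide priors; statistics with zero MAD are dropped.
Model choice retains the closest 1% (configurable) in Euclidean distance
and fits an Epanechnikov-weighted multinomial logistic regression of the
scenario indicator on statistic deviations, evaluated at the observed
point; direct rejection frequencies are always reported alongside as a
cross-check, and a scenario absent from the retained set is floored at
zero with a warning. Parameter estimation logit-transforms each parameter
to its prior bounds (so adjusted draws cannot leave the prior support),
applies the weighted local-linear adjustment, back-transforms, and
reports weighted quantiles; a singular design falls back to the
unadjusted rejection sample with a warning. Model checking simulates from
posterior draws and reports two-sided tail probabilities for a held-out
statistic set that is required to be disjoint from the fitting set; the
packaged default fits on the one-sample statistics and holds out the
pairwise ones.

The two packaged scenario families mirror the study design: the Sazava
family (admixture between the Elbe and western-Morava groups vs either
pure origin) and the Czech Oder family (pure Morava origin — the
translocation hypothesis — vs pure Baltic origin vs admixture), each with
a founding bottleneck. Prior bounds ship as editable YAML files; they are
package choices selected to bracket plausible values for small lowland
fish populations (and to contain the posterior intervals such analyses
report), not a transcription of any study's prior table. Desk-scale
defaults are 10 000 simulations per scenario at 1% tolerance for the
operating-characteristics checks and 1 000 per scenario inside the
packaged pipeline; ABC accuracy improves monotonically with table size,
and the full-scale 10⁶ tables remain available through the same
arguments.

## The synthetic study fixture

`make_study_fixture()` encodes a deliberately structured history: two
deep stems (western and eastern refugia, split 9 000 generations ago),
the Danube stem and its Morava/Dyje/Tisza sub-stems, a North-Sea stem
founded by 50/50 admixture of the two refugia 1 500 generations ago, a
Baltic stem, and 27 sampled populations splitting from their stems
150–1500 generations ago at effective sizes of 120–3000 — values chosen
once to produce the diversity (H~e~ ≈ 0.35–0.8) and differentiation
(F~ST~ ≈ 0.05–0.5) ranges typical of such datasets. Two histories carry
the anthropogenic signal: the Czech Oder stem is founded from the Morava
stem 130 generations ago through a 20-generation bottleneck of N~e~ = 50,
and the Sazava population is founded 229 generations ago by admixture
(61.3% western-Morava) through a 6-generation bottleneck of N~e~ = 69.
Sample sizes follow the 27-population design (688 genotyped individuals;
pooled inference groups of 26/86/56 and 85/175/75). The nuisance overlay
puts null alleles at 6.9% and 7.9% on the two designated loci and 3.5%
random missingness (≈ 3.9% missing overall including null/null
genotypes); the two hyper-variable loci get an 8-fold higher mutation
rate. The mtDNA fixture is built by infinite-sites mutations on a
two-clade topology — a star-like western haplogroup (a frequent core plus
1–2-step derivatives) and a small eastern haplogroup 30 substitutions
away, carried by the Polish Baltic populations and two sequences of one
Rhine population — because CYTB is sequence data and the microsatellite
engine would be the wrong generative model.

What passing tests on this fixture do show: the estimators detect
exactly the structure that was built in — the translocated group clusters
with its source watershed at K = 2, F~CT~ rises when mismatched
populations are removed, the admixture scenario wins the Sazava model
choice, parameter recovery covers the truth at its nominal rate. What
they cannot show: robustness to the messiness of real genotypes (allele
scoring error, stutter, dropout beyond simple nulls), to unmodelled gene
flow after founding, or to mutation-model misspecification; the fixture's
history is far simpler than any real riverscape. Real-data behaviour of
the upstream tools this package reimplements is the appropriate external
benchmark.

## Numerical conventions

Permutation p-values use the add-one convention everywhere. Negative
variance-component ratios (θ, ρ, F~CT~) are reported as-is. All Monte
Carlo procedures take explicit integer seeds and are bitwise reproducible
given them; functions only touch the RNG when they actually randomize
(a point estimate with `n_perm = 0` leaves the caller's RNG state
alone). Probability computations that could underflow (Levene
probabilities, Dirichlet densities) run in log space; rarefaction uses
`lchoose`. The problem sizes used by the packaged tests — 500-locus
closed-form checks, 500-replicate calibration studies at 99 permutations,
10 000-simulation reference tables, 2 000-sweep Gibbs runs — were chosen
as the smallest sizes at which the corresponding statistical property is
sharp, and each is stated in the test that uses it.

## Known limitations

No recombination or selection in the simulator; no linkage or LOCPRIOR
clustering models; no standardized F′~ST~ or Jost's D; no
stutter/dropout diagnostics; the median-joining implementation omits the
maximum-parsimony post-processing step of the original software; ABC
uses neither linear-discriminant projections nor random forests. These
are scope decisions, not oversights.
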