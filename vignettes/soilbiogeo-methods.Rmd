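---
title: "Methods: biogeography and co-occurrence analysis of soil microbiome surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biogeography and co-occurrence analysis of soil microbiome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilbiogeo)
```

`soilbiogeo` implements the downstream statistics of a continental-scale
soil microbiome survey: what happens after reads have been clustered into
OTUs and a samples-by-OTUs count table exists. The pipeline covers
rarefaction, alpha and beta diversity, the geographic distance-decay of
community similarity, permutation tests linking community structure to
environment, core-microbiome analysis with a partitioned Bray-Curtis
statistic, and thresholded Spearman co-occurrence networks judged against
Erdős–Rényi null ensembles. A synthetic community generator with planted
ground truth makes every stage testable without sequencing data.

## The data model

An `otu_table` is a samples x OTUs matrix of non-negative integer counts
with optional greengenes/SILVA-style lineages. Counts are mandatory:
relative-abundance input is rejected because rarefaction — random
subsampling without replacement to a common depth — is only defined on
counts, and normalisation is an explicit step
(`relative_abundance()` is total-sum scaling). Site metadata carries
decimal-degree coordinates and environmental covariates (pH unitless; AK,
AN, AP in mg/kg; OC, TN in mg/kg; PRE in mm/yr; TEM in °C); a bundled
21-site table from Chinese maize fields (`inst/extdata/maize_sites.tsv`)
serves as the reference landscape. Distance matrices are symmetric with a
zero diagonal and a units tag (`km`, `dissimilarity`, or unbounded `raw`).

## Diversity

Richness is the count of detected OTUs and the Shannon-Wiener index is
computed in natural log, the convention of QIIME-era pipelines. Bray-Curtis
dissimilarity is `sum |x_ij - x_ik| / sum (x_ij + x_ik)`; the pipeline
default computes it on relative abundances, with a counts mode retained for
the partitioned core statistic on rarefied tables.

Weighted UniFrac weights every branch of a rooted phylogeny by its length
times the difference in the fraction of each sample's abundance descending
from it. The normalized variant divides each pair's raw value by its
maximum attainable value, `sum_i d_i (p_i + q_i)` with `d_i` the
root-to-tip distance, and is the pipeline default because the
distance-decay stage works on `1 - dissimilarity` and needs a `[0, 1]`
scale; the raw variant remains available since the choice is rarely stated
in survey papers. The implementation accumulates descendant abundance
fractions in one postorder pass and is cross-checked in the test suite
against an independent implementation and against the star-topology closed
form `l * sum_i |p_i - q_i|`.

## Distance decay

Geographic distances are haversine great-circle distances on a sphere of
radius 6,371 km — at continental scales this is within 0.2% of ellipsoidal
geodesics, and it reproduces the bundled landscape's 87–4,130 km pairwise
span. The distance-decay relationship (DDR) is the ordinary least-squares
regression of pairwise similarity (`1 - dissimilarity`) on pairwise
distance; its slope `w` is the spatial turnover rate. The default p-value
is the OLS slope t-test, as DDR figures conventionally report, but because
the 210 pairs from 21 sites are not independent a Mantel-style permutation
p-value is available (`p_method = "permutation"`). Per-phylum DDRs subset
the phylum's OTUs, renormalise within the subset, and use Bray-Curtis
similarity; sites where a phylum is absent are dropped and counted. The
per-phylum dissimilarity metric is a genuine open choice — per-phylum
subtrees for weighted UniFrac would be required otherwise — and Bray-Curtis
was chosen for it.

One property of window-limited linear DDR fits is worth stating because it
is counter-intuitive: the fitted slope is *not* monotone in the underlying
spatial correlation length. A community whose correlation length is far
below the smallest sampled distance is equally dissimilar everywhere
(plateau, slope near zero), one far above the window barely decays, and the
slope is steepest when turnover happens inside the sampled range. The
generator's per-phylum range overrides let tests plant this contrast
deliberately.

## Permutation statistics

`mantel()`, `permanova()`, `anosim()` and `cap()` are implemented as
explicit permutation engines sharing conventions: simultaneous row/column
permutation of the distance matrix (or rows of the score matrix for CAP),
the +1-corrected p-value `(1 + #{stat* >= stat}) / (1 + n_perm)` so p is
never 0, seed control, a default of 999 permutations, and an
`exhaustive = TRUE` mode that enumerates all `n!` relabelings for n <= 8 —
the mode the test suite compares against brute-force oracles. PERMANOVA
uses the trace forms of the Gower-centered matrix `G`: for hat matrix `H`,
`pseudo-F = [tr(HGH)/df_model] / [tr((I-H)G(I-H))/df_resid]` and
`R^2 = tr(HGH)/tr(G)`, with sequential (Type I) term addition in formula
order by default and `by = "margin"` available; on Euclidean distances of
univariate data it reproduces the classical one-way ANOVA F exactly. CAP
(db-RDA) regresses the positive-eigenvalue PCoA axes on the centered
constraint matrix; the eigen-analysis of the fitted values gives the
constrained axes, and constrained plus residual inertia reconstruct the
total by construction. Negative PCoA eigenvalues are reported but dropped
(no Lingoes/Cailliez correction), mirroring default `capscale` behaviour
on semi-metric dissimilarities. `vegan`'s `mantel`, `adonis2`, `anosim`
and `capscale` serve as independent cross-checks in the tests, never as
the implementation.

Type-I calibration is verified by simulation: with independent null data
(20 samples, 50 taxa, Bray-Curtis distances, an unrelated Gaussian
covariate), each engine rejects at α = 0.05 at a rate of 0.05 ± 0.01.
The acceptance suite runs 4,000 null simulations per engine at 99
permutations each; 99 permutations make the 5% level exactly attainable
(p ≤ 0.05 occurs exactly when at most 4 permuted statistics reach the
observed one), and 4,000 simulations put the Monte Carlo standard error
(~0.0034) well inside the ±0.01 band.

## Core microbiome

The core is defined at 100% prevalence: OTUs detected in every sample
(`find_core()`, threshold configurable, monotone in the threshold). Its
share of beta diversity is quantified by the partitioned Bray-Curtis
statistic: the numerator sum restricted to core taxa, the denominator over
all taxa. The per-pair contribution fraction is `BC_core / BC_all`; this
normalisation was chosen because it is additive — numerators over any
disjoint partition of taxa reconstruct the full numerator, so contribution
fractions sum to 1 for every pair — and therefore reads as "share of
community dissimilarity". It is computed on rarefied counts by default
(relative-abundance mode available), since even depths make the numerator
comparable across pairs. Core genera are screened against environmental
covariates by Spearman correlation with Benjamini-Hochberg FDR across the
whole genus-by-covariate family; only cells that are simultaneously strong
(|r| > 0.6) and significant (q < 0.05) are retained, everything else is
masked — the heatmap contract `autoplot()` renders.

## Co-occurrence networks

Spearman correlations are computed between all taxon pairs on relative
abundances (rank-then-Pearson, tie-corrected), with two-sided p-values
from the t approximation on n - 2 degrees of freedom. BH-FDR is applied
over the flattened upper triangle, and an edge is drawn when r > 0.6 and
q < 0.01. The threshold is deliberately one-sided: the criterion is
strictly positive co-occurrence, and negative correlations are excluded
(an `use_absolute` switch exists for sensitivity analysis). Taxa with zero
variance are dropped, and `min_prevalence` optionally removes sparse taxa
first: profiles dominated by zeros produce heavy rank ties whose
correlations and approximate p-values are unreliable, and prevalence
filtering before correlation is standard practice.

Topology reports average path length and diameter over connected node
pairs (the disconnected fraction is reported), graph density
`2m/(n(n-1))`, and the clustering coefficient as mean local clustering
over nodes of degree >= 2 — the convention under which the Erdős–Rényi
expectation equals the density, which is what makes the null comparison
interpretable. The null ensemble draws uniform G(n,m) graphs at the
observed size; for a 5,312-node, 181,157-edge network the expected
clustering is 0.0128 and the modal diameter across replicates is 3.
Betweenness centrality is unweighted Brandes counting, endpoints excluded;
keystone taxa are the top-k nodes by betweenness (k defaults to 7, ties
broken by degree then id) on the genus-level network, where genus
aggregation sums counts over OTUs with an assigned genus and drops
unassigned ones with a reported tally. Core versus non-core sub-networks
are compared on induced-subgraph topology and by a two-sided Wilcoxon
rank-sum test on the full-network betweenness distributions.

## The synthetic community generator

The generator emulates the post-clustering state of a 21-site continental
survey. Sites are placed uniformly in a bounding box spanning roughly
18–47°N, 77–127°E; precipitation and temperature decline linearly with
latitude plus noise (Spearman correlation with latitude is exactly -1 at
zero noise); pH is uniform on 5.2–8.9 and the edaphic covariates are drawn
within field-realistic ranges. Per-OTU expected log-abundance is a sum of:

* a log-normal baseline (`base_sd`, default 1.5) — community dominance
  structure;
* a spatial Gaussian random field per OTU with exponential correlation
  `exp(-d/range)` (`spatial_range_km`, default 1,500 km; `spatial_sd` 1),
  which is what produces an approximately linear distance decay of
  Bray-Curtis similarity over the sampled 87–4,130 km window;
* a shared standard-normal latent factor per guild (`guild_sd`, default
  2; 5 guilds of 6 members), inducing positive cross-sample correlation
  among members, with `guild_mu_offset` shifting guild members off the
  dominant community mass;
* a linear response to one environmental covariate for a configurable set
  of responder OTUs (`env_effect`, default 1, random sign); and
* i.i.d. log-scale noise (`noise_sd`, default 0.5).

Counts are multinomial per site at a log-normal library size clamped to
18,000–37,000 reads — depths uneven enough to justify the rarefaction
stage. Each core OTU (8% of OTUs by default, baseline boosted by 1.5 log
units so the core is abundant as well as ubiquitous) receives one
guaranteed read per sample, fixing its prevalence at exactly 1 while
keeping row sums equal to the drawn library size. The phylogeny is a
random coalescent over the OTU ids; taxonomy assigns phyla at realistic
continental-soil frequencies and genera from per-phylum pools with a
configurable unassigned fraction.

The planted distance-decay slope recorded in `SyntheticTruth` is defined
as the OLS slope of Bray-Curtis similarity against distance computed on
the noiseless expected relative-abundance profiles — the generative model
before multinomial sampling. This is the only definition that is both
planted (fixed before any counts are drawn) and on the same
similarity-per-km scale the DDR stage estimates; recovery tests require
the fit on sampled counts to land within 2 standard errors of it.

### What the generator does not emulate

Sequencing error, chimeras and OTU-clustering artefacts; mechanistic
dispersal or niche dynamics (decay is planted directly through the field
correlation, not simulated); phylogenetic signal in abundance (the tree is
independent of the abundance model, so weighted UniFrac on synthetic data
is a weaker mirror of Bray-Curtis); and true interaction networks —
guilds are latent-factor correlations, which is exactly what co-occurrence
analysis can at best detect. Passing tests therefore demonstrate that the
statistics recover the structure their estimands describe, not that
co-occurrence edges imply ecological interaction in real data.

### The guild-recovery experiment

The acceptance check that network edges recover planted guilds with
precision >= 0.9 runs under a configuration that isolates the latent-factor
signal: spatial field replaced by i.i.d. site effects (`spatial_range_km =
0`, `spatial_sd = 0.3`), thinner dominance tail (`base_sd = 1`), guild
factor sd 1.5 (three times the noise sd), guilds shifted off the dominant
mass (`guild_mu_offset = -1.5`), and the 50%-prevalence filter. Each
departure from the defaults removes a documented confound that otherwise
creates *genuine* strong non-guild correlations which the truth set cannot
credit: smooth spatial fields align by chance across OTUs at 21 sites; a
dominant co-moving guild drags every other taxon's relative abundance
through the total-sum denominator (compositional closure); and sparse
profiles correlate through shared zero ranks. These are well-known
pathologies of correlation-based co-occurrence inference — the reason the
field has moved toward compositionality-aware methods — and the default
generator deliberately retains them so that whole-pipeline runs look like
real data; the recovery experiment measures the network stage, not the
confounds.

## Numerical choices and degenerate inputs

Distance matrices are validated to symmetry within 1e-12 and exact-zero
diagonals, and symmetrised exactly on construction. PCoA retains
eigenvalues above 1e-10. Permutation p-values use the +1 correction
everywhere; exhaustive enumeration includes the identity permutation and
omits the correction. Keystone ranking breaks ties by degree, then node
id. Rarefaction refuses depths above any library size, naming the
offending sample; pairs with zero Bray-Curtis dissimilarity are excluded
from contribution fractions with a warning; constant covariates are
dropped from correlation screens with a warning and rejected in permutation
designs; an all-unassigned taxonomy is an error for genus aggregation.
Every stochastic stage of `run_pipeline()` consumes a stage-specific child
seed derived from the master seed (`child_seed()`), so any stage can be
re-run in isolation and the whole bundle is byte-identical under a fixed
config.

## Problem sizes used in the test suite

Module tests run at 21 sites and 50–400 OTUs; the calibration study uses
20 samples x 50 taxa with 99 permutations and 4,000 null simulations per
engine; the null-ensemble check simulates five G(5312, 181157) graphs;
exhaustive-enumeration oracles run at n = 4–8. These sizes were chosen so
the full suite completes in well under two minutes on a single CPU while
leaving every statistic's sampling distribution visibly exercised.

## Known limitations

Spearman-threshold networks inherit the compositional and sparsity biases
discussed above; SparCC-style inference is out of scope. APL and diameter
on disconnected graphs are computed within connected pairs, which can
flatter fragmented networks (the disconnected-pair fraction is reported
alongside). The Mantel test's method (Pearson vs Spearman) is exposed
because survey papers rarely state it; Spearman is the default. The
per-phylum DDR metric and the UniFrac normalisation are package choices
where the literature is silent, as noted in their sections.
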