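---
title: "Trait and lineage filtering across space: the five-matrix RLQ workflow"
author: "RLQspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait and lineage filtering across space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RLQspace)
```

## The question and the data

Environmental filtering admits into a local community only those species
whose traits suit the local conditions.  On a mapped forest plot this
leaves two fingerprints: community-mean traits track environmental
gradients, and co-occurring species are more similar — functionally and,
when traits carry phylogenetic signal, phylogenetically — than a random
draw from the plot-wide pool.  `RLQspace` implements a complete workflow
for detecting both fingerprints at several spatial grains from four data
objects:

* a **stem map** (tagged individuals with coordinates and species
  identity),
* a **species-by-trait table** of quantitative traits,
* a set of **environmental surfaces** at quadrat resolution,
* an ultrametric **phylogeny** of the species pool.

From these the package builds, at each quadrat scale, the five linked
matrices of the extended RLQ construction: the abundance table
$L$ (sites $\times$ species), the environmental table $E$ and the spatial
eigenvector table $S$ on the site side, and trait ($T$) and phylogenetic
($P$) distance matrices on the species side.  `alignBundle()` validates
and co-orders all five; the `FiveMatrixBundle` class carries them through
every downstream stage.

## Ordinations feeding the co-inertia

Each table is first summarized by the ordination suited to its type.
$L$ is decomposed by correspondence analysis (CA): the eigendecomposition
of the $\chi^2$-standardized table $(p_{ij} - r_i c_j)/\sqrt{r_i c_j}$,
whose marginal frequencies $r$ and $c$ become the site and species
weights used everywhere else.  $E$ (and $S$) are treated by weighted PCA
on variables standardized under $r$.  The distance matrices $T$ and $P$
are embedded by principal coordinate analysis; Gower trait distances need
not be Euclidean, so a Cailliez constant is added when negative
eigenvalues appear (the smallest constant making the configuration
embeddable, computed from the standard companion eigenproblem, and
flagged in the result).  The spatial table $S$ itself is the set of
Moran eigenvector maps: eigenvectors of the doubly-centred queen
adjacency of the quadrat lattice with positive eigenvalues, i.e. the
orthogonal spatial patterns with positive autocorrelation, ordered from
broadest to finest.

## The RLQ core and its five-matrix extension

Classic RLQ finds the pair of linear combinations — one of site
attributes, one of species attributes — maximizing their covariance
through $L$.  Numerically it is the SVD of

$$ C \;=\; R^\top D_r \,\tilde L\, D_c\, Q, \qquad
   \tilde L_{ij} = \frac{p_{ij}}{r_i c_j} - 1 , $$

with $R$ and $Q$ centred (and scaled) under $D_r = \mathrm{diag}(r)$ and
$D_c = \mathrm{diag}(c)$.  Squared singular values are the co-inertia per
axis; `rlqCore()` returns them with site scores $R u$ and species scores
$Q v$.  The extension concatenates blocks:
$R = [\,E^{std} \mid S\,]$ and $Q = [\,T^{PCoA} \mid P^{PCoA}\,]$.

Three numerical choices were genuinely open and are fixed as follows:

* **Block weighting.**  Each of the four blocks is rescaled to unit total
  inertia before concatenation, so environment and space (and traits and
  phylogeny) enter with equal a-priori influence; raw variances would
  otherwise let the larger block dominate.  The rescaling is a scalar per
  block, so axis directions inside a block are untouched.
* **PCoA axis retention.**  The smallest number of leading axes reaching
  95% of the (corrected) positive inertia per distance block — bounded
  dimensionality with an explicit criterion.
* **Sign convention.**  Every decomposition fixes eigenvector signs so
  the largest-magnitude loading is positive, making seeded runs
  bit-reproducible.

Site scores decompose exactly into their environmental and spatial parts
(`details$siteScoresEnv`, `details$siteScoresSpace`), and
`axisSummary()` reports weighted Pearson correlations of every original
variable with an axis — the standard axis-interpretation surface.

## Fourth-corner tests and the two null models

For one site variable $x$ and one species variable $y$ the fourth-corner
statistic is the Pearson correlation on the individual-inflated table
(every stem carries its site's $x$ and its species' $y$), computed in
closed form as $\tilde x^\top P \tilde y$ with both variables
standardized under the marginal weights.  The sum of its squares over all
variable pairs equals the RLQ total co-inertia — an identity the test
suite checks to $10^{-9}$.

Significance uses two permutation schemes: **model 2** permutes the rows
of $L$ (breaking the site–species link while preserving the
trait–species link) and **model 4** permutes its columns (the converse).
Each gives a two-sided p-value with the plus-one rule; the **combined**
p-value is their maximum, which is significant only when *both* links
hold and is known to be conservative — under neutral assembly its
realized size is nearer 0.03 than 0.05, which the acceptance suite
verifies stays within [0.02, 0.08].  Global matrix-pair tests
(`globalAssociation()`) use the total co-inertia of a block pair as the
observed value; the standardized effect size is computed against the
pooled model-2 and model-4 null draws, and $P = \max(p_2, p_4)$.

## Dispersion: NRI and S.E.S. PW

Within each quadrat the abundance-weighted mean pairwise distance is

$$ MPD = \frac{\sum_{i \ne j} f_i f_j D_{ij}}{\sum_{i \ne j} f_i f_j}, $$

conspecific pairs excluded (note that some popular implementations
include the zero $i{=}j$ pairs in the weighting; the two conventions
agree only at equal frequencies).  $D$ is the patristic distance matrix
for the phylogenetic index and the cophenetic distance of the UPGMA
trait dendrogram for the functional one — the dendrogram, not raw Gower
distances, because the functional index is defined on the trait
dendrogram.  The null model shuffles species names across the tips once
per iteration, pool-wide, leaving abundance, frequency and occurrence
untouched; permutations are drawn over the *sorted* label set so the
null is invariant to column storage order under a fixed seed.  The
indices are the sign-flipped standardized effect sizes

$$ NRI = -1 \times \frac{MPD_{obs} - \mathrm{mean}(MPD_{null})}
        {\mathrm{sd}(MPD_{null})} $$

(and identically for the dendrogram-based index), so positive values
mean clustering.  A zero null standard deviation (e.g. a star phylogeny)
yields index 0 with a degeneracy flag; quadrats with fewer than two
species are excluded and counted — frequent at the 10 m grain by
construction.

`axisSideSummary()` splits quadrats by the sign of their first RLQ axis
score and reports the mean index per side with a one-sample Student
t-test of mean zero and, optionally, a spatially corrected p-value from
an intercept-only simultaneous autoregressive (SAR) error model fitted
by maximum likelihood, with the log-determinant evaluated through the
eigenvalues of the row-standardized queen weight matrix.  Two caveats
are worth stating plainly.  First, quadrat indices within one plot share
the species pool, the tree and the null draws, so the t-test treats
correlated quadrats as replicates; it is the field's standard reporting
device, and the SAR correction absorbs the *spatial* part of that
dependence, but neither test is calibrated against resampling whole
plots.  What is calibrated — and what the acceptance suite checks — is
the index itself: under its own tip-shuffle null it is standard normal
across independent worlds to within $\pm 0.15$ in mean and sd.  Second,
the SAR spatial parameter is weakly identified on small lattices (its ML
estimator has sd $\approx 0.2$ under independent noise at $n = 100$);
its estimates are reported, not tested, below a few hundred quadrats.

## The synthetic generator: what it emulates and what it does not

No census of the motivating system is publicly deposited, so the package
ships a generator whose defaults emulate that study system once, as a
realism choice, and are then left alone:

* a rectangular 20-ha plot (500 m $\times$ 400 m);
* a pure-birth (Yule) phylogeny scaled to unit depth for
  `nSpecies = 300` — a few hundred taxa, as in species-rich tropical
  plots;
* 11 traits simulated by Brownian motion on a Pagel-$\lambda$
  transformed tree ($\lambda$ applied to the off-diagonal of the
  Brownian covariance; columns standardized), default
  $\lambda = 0.5$;
* 10 environmental surfaces as Gaussian random fields with exponential
  covariance and a 50 m autocorrelation range on the 10 m grid — the
  mesoscale patchiness of mapped soil variables; coarser grains are
  means of the constituent fine quadrats;
* regional abundances from a Fisher log-series (series parameter
  $x = 0.999$), giving the strong dominance typical of tropical plots,
  which deliberately stresses the abundance-weighted statistics;
* assembly that places each stem of species $s$ in quadrat $q$ with
  probability $\propto \exp(-c\,(t_s - e_q)^2)$ for exactly one
  designated trait–environment pair, all other variables being nuisance
  dimensions; $c = 0$ is uniform neutral placement.

The generator does **not** emulate dispersal limitation, conspecific
point clustering, trait–trait correlation structure, measurement error,
or interactions among multiple niche axes.  Passing recovery tests
therefore shows that the statistics detect trait-matching filtering
against spatially structured environments — not that they would behave
identically on real censuses with those additional features.

## Problem sizes and reproducibility

The test suite runs its statistical calibrations at deliberately chosen
sizes: type-I error of the combined fourth-corner test over 500 neutral
worlds of 50 twenty-metre quadrats (60 species, 2000 stems, 199
permutations); NRI self-calibration over 500 worlds; parameter recovery
over 40 worlds of 200 ten-metre quadrats at the default richness of 300
species with $\lambda = 1$ and filtering strength 10.  Every stage takes
a seed and is a pure function of (inputs, configuration, seed);
`runPipeline()` writes CSV tables with a JSON manifest of MD5 hashes,
and reruns under the same seed are byte-identical.

```{r example, eval = FALSE}
cfg <- simConfig(filteringStrength = 10, signalLambda = 1, seed = 1)
ds  <- simulateDataset(cfg)
res <- runPipeline(ds, scales = c(10, 20, 50, 100),
                   nPerm = 199, nIter = 199, seed = 1,
                   outDir = "results")
res$scale20$global          # Obs / SES / P per matrix pair
res$scale20$dispersion      # mean NRI and S.E.S. PW per axis side
```

## Known limitations

Only quantitative traits are supported (the Gower distance and the
fourth-corner statistic are their quantitative forms).  Single-census
data only.  The t-test/SAR caveats above apply to any axis-side summary.
The "canonical analysis" of the abundance table is implemented as
correspondence analysis — the decomposition classic RLQ is built on —
which we flag as an interpretation rather than leave implicit.
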