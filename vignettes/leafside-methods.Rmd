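---
title: "Methods: dispersal versus host filtering between leaf sides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersal versus host filtering between leaf sides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Leaves expose two very different habitats to bacteria. The upper
(adaxial) surface intercepts most airborne immigrants and most UV and
desiccation stress; the lower (abaxial) surface carries almost all
stomata, traps humidity, and leaches more plant-derived resources
through its thinner cuticle. If immigration dominates on top while
plant-driven selection ("host filtering") dominates underneath, the two
sides of one leaf should assemble their microbiomes by different rules:
the upper side should look more *neutral* (well described by dispersal
plus drift from a shared source pool) while the lower side should carry
more host-specific, more endemic, more concentrated communities.

`leafside` implements the statistical machinery to test that contrast on
an ASV (amplicon sequence variant) count table from a multi-species,
two-sides-per-leaf sampling design — together with a ground-truthed
synthetic generator of such studies, so every pipeline component can be
validated against data whose true assembly rules are known.

## The neutral occupancy-abundance model

The core model is Sloan's neutral community model for detection
(occupancy) versus mean relative abundance. A taxon whose relative
abundance in the source metacommunity is $p$ has, in a local community
of $N$ individuals receiving a fraction $m$ of immigrants per birth,
a stationary local relative abundance approximately distributed

$$x \sim \mathrm{Beta}\big(Nmp,\; Nm(1-p)\big).$$

Small $Nm$ (weak migration relative to drift) inflates the variance of
$x$; taxa then drop below detection more often and occupancy falls. The
model's predicted occupancy at detection limit $d$ is the Beta survival
function $P(x > d)$, and `fit_neutral()` estimates $m$ by least squares
of observed occupancies on predicted ones over all taxa, with a
50-point log-grid multistart before bounded refinement (the SSE surface
flattens at large $Nm$, so a single local search can stall on the
plateau). $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ measures how well the
neutral curve describes the cloud; per-taxon Wilson score envelopes at
the realized sample count classify taxa as above, within, or below the
neutral expectation.

### The detection limit

Sequencing observes $N$ reads, not the latent $x$; a taxon is "detected"
when it receives at least one read, which happens with probability
$1-(1-x)^N$. That soft threshold has its half-detection point at
$x = \ln 2 / N$, and we use $d = \ln 2/N$ as the default detection
limit. The cruder convention $d = 1/N$ is available via the `d`
argument, but against the package's own generator (latent Beta then
multinomial reads — exactly the model being fitted) it inflates
$\hat m$ by 20–40% across $m \in [0.05, 0.3]$, while $d = \ln 2/N$
recovers $m$ within a few percent. The acceptance tests require
recovery within ±20% at $m \in \{0.02, 0.05, 0.1, 0.3\}$ (100 samples,
300 taxa, $N = 4000$).

$N$ defaults to the rarefaction depth when the table is rarefied
(columns of equal sum), otherwise to the mean sample depth; the choice
is logged.

### Comparing fits between sides

The headline neutral-model result is a comparison of $R^2$ between two
fits. We attach uncertainty with a taxon-level bootstrap
(`compare_fit_r2()`): ASVs are resampled with replacement within each
side, $R^2$ is recomputed around the *fixed* fitted curves, and the
one-sided p-value is the bootstrap share of $\Delta R^2 \le 0$. Holding
the curves fixed makes this a residual bootstrap, cheap enough for
null-calibration studies; it slightly understates the variability of a
full refit, which is acceptable because the planted effects it is used
on are large.

## Core microbiome selection

Core taxa are selected from the abundance-occupancy distribution: taxa
are ranked by decreasing occupancy (ties: decreasing mean relative
abundance, then taxon id — the ranking is deterministic), and each
prefix of the ranking is scored by the share of between-sample
Bray-Curtis structure it carries,

$$\mathrm{contribution}(k) \;=\; \mathrm{mean}_{\,\text{pairs}(a,b)}
\frac{\sum_{i \le k} |a_i - b_i|}{\sum_{\text{all } i} |a_i - b_i|},$$

which is non-decreasing in $k$ and reaches exactly 1. The core is cut by
the "last 2% increase" rule: the smallest prefix beyond which every
relative gain $\mathrm{contribution}(k+1)/\mathrm{contribution}(k) - 1$
stays below the threshold (default 0.02). Note that a single taxon's
share is capped at 1/2: compositions sum to one, so per sample pair one
taxon's difference cannot exceed the summed differences of the rest.

Per-side core summaries (summed core relative abundance, fraction of
core detected) are contrasted between sides with one-sided paired
Wilcoxon tests, paired by plant individual.

## Weighted endemism

The degree of endemism of taxon $i$ is the proportion of host plant
species on which it was never detected,
$e_i = (S - S_i^{\mathrm{det}})/S$; taxa occurring in at most one sample
are excluded first. A sample's weighted endemism is
$W_s = \sum_i r_{is}\, e_i$ with $r_{is}$ the within-sample relative
abundance. Detection is evaluated on the filtered, unrarefied counts by
default (switchable), since presence/absence across a species' samples
is what the degree measures. $\log W$ feeds an OLS regression on pH,
leaf side and stomatal density with backward elimination at
$\alpha = 0.05$ (the full pre-elimination model is always retained);
zero-$W$ samples are floored at half the smallest positive $W$ before
the log. The side contrast is a paired Wilcoxon on $W$ by plant.

## PERMANOVA and Mantel

`permanova()` implements sequential (Type I) sums of squares on a
Gower-centred distance matrix: $G = C(-\tfrac12 D^{\circ 2})C$ with
$C = I - \mathbf{1}\mathbf{1}'/n$, per-term SS as increments of
$\operatorname{tr}(H_k G)$ over cumulative hat matrices, pseudo-$F$
against the residual mean square, and p-values from free permutation of
sample identities with the observed statistic included in the null set,
$p = (\#\{F^\ast \ge F\} + 1)/(n_{\mathrm{perm}} + 1)$. Earlier terms
absorb shared variation, so covariates enter most-specific-first (pH,
stomatal density, leaf side, host species, individual, side x species),
and the nested plant individual is encoded simply by its globally
unique labels entering after the species term. Supplying an explicit
permutation matrix switches to exact enumeration
($p = \#\{F^\ast \ge F\}/n!$), which the tests exploit at $n = 4$; on
univariate Euclidean input the pseudo-$F$ equals the classical one-way
ANOVA $F$ to numerical precision, and a 500-replicate null simulation
checks the 5% type-I error within [0.03, 0.07]. Permutations are free
(unrestricted) by default, matching common practice when no structure is
declared; a `strata` argument restricts shuffling within levels for
sensitivity analysis. The Mantel distance-decay test (Spearman by
default) and the Wilcoxon/Kendall wrappers delegate to the vetted
`vegan` and `stats` routines.

## The synthetic study generator

`simulate_study()` is the generative dual of the Sloan fit. Per sample,
the effective source pool is $q \propto p \cdot \mathrm{boost}$, the
latent abundance of each taxon is an independent
$\mathrm{Beta}(Nmq_i, Nm(1-q_i))$ draw (renormalized across taxa — kept
taxon-wise rather than Dirichlet so the generator matches the taxon-wise
model being fitted), and reads are multinomial at depth $N$. Defaults
encode the emulated study frame:

* 24 host species x 3 individuals x 2 leaf sides = 144 samples,
  $N = 14{,}000$ reads per sample before rarefaction to 4,000;
* migration $m_{\mathrm{upper}} = 0.15$ versus
  $m_{\mathrm{lower}} = 0.05$ — more airborne immigration on top;
* host filtering as multiplicative boosts on the source pool, stronger
  below (x10) than above (x3): a weaker-not-absent upper-side filter
  keeps the host-species main effect dominant over the side-by-species
  interaction, the structure observed in the emulated study's variance
  partition;
* filtered taxa per species: 20 shared "plant-associated" taxa (drawn
  from abundance ranks 21–120 so the planted core is distinct from the
  taxa that already dominate the pool) plus 5% of taxa chosen per
  species, plus 2 strictly endemic taxa per species — drawn from the
  rare half of the pool, down-scaled x100 in the source so they are
  effectively undetectable off-host, boosted x3000 on their host's
  lower side and excluded (boost 0) elsewhere;
* a lognormal metacommunity with $\sigma_{\log} = 1.2$ over 500 taxa.
  The shape matters: at $\sigma_{\log} = 2$ the source pool is already
  so uneven that lower-side filtering cannot further concentrate
  abundance, and the evenness (inverse Simpson) side contrast vanishes
  by construction; at 1.2 filtering demonstrably reduces evenness, as
  the emulated system shows;
* covariates: pH per leaf with the lower surface 0.21 units more acidic
  (leaf-level Gaussian noise sd 0.15, clipped to the observed range
  4.89–7.16), stomata essentially absent above and ~150/mm² below,
  coordinates jittered inside a ~0.14 km² garden frame, plus leaf
  hardness, pubescence and area.

The exported `TruthRecord` carries the design, metacommunity, filter
profiles and per-sample expected compositions, so recovery can always be
scored against ground truth. A single master seed drives a hierarchical
seed stream (one derived seed per sample and per stage), making every
run byte-reproducible.

### What the generator does not emulate

Real phyllosphere data add mechanisms the generator deliberately omits:
taxon-taxon interactions (including phage), temporal succession and
arrival-order effects, UV/desiccation mortality as an explicit process,
sequencing error and chimeras, compositional biases of PCR, and
contamination. Passing the planted-effect tests therefore shows the
*statistical pipeline* detects the designed contrasts at realistic
sizes — not that real leaves behave like the generator.

## Numerical and design choices

* **Low-count filter**: counts ≤ 2 are zeroed per entry (per sample),
  the conventional reading of singleton/doubleton denoising; a
  `max_anywhere` switch drops whole taxa instead. The filter is
  idempotent.
* **Rarefaction**: multivariate hypergeometric (without replacement) via
  `vegan::rrarefy`, exact target depth, one draw per sample, explicit
  seed required; shallow samples are dropped with a warning.
* **0.1% abundance floor**: strict less-than; taxa exactly at the floor
  are retained.
* **Bray-Curtis**: computed on within-sample relative abundances;
  equals half the L1 distance for normalized columns.
* **Haversine distances**: fixed Earth radius 6,371 km; at a ~0.14 km²
  extent the projection choice is immaterial.
* **Optimizer determinism**: the neutral fit has no random component;
  taxon order never changes the result.
* **Degenerate inputs**: all-zero samples are refused by
  normalization; tables with fewer than 10 usable taxa refuse to fit;
  fewer than 6 complete leaf pairs refuse the paired tests; saturated
  PERMANOVA designs (no residual df) error.

## Problem sizes

The validation suite runs entirely on synthetic data generated at test
time: the full design (144 samples x 500 taxa) for the planted-effect
checks, 100-sample x 300-taxon sweeps for migration recovery, 500
small-n null datasets at 199 permutations for PERMANOVA calibration,
and 50 replicates of the no-effect design for specificity of the four
directional findings. The analysis scripts and the acceptance run use
9,999 permutations for PERMANOVA and Mantel, as in the emulated study.

## Known limitations

* Least-squares (not likelihood) fitting of $m$, as in the standard
  implementations; no confidence interval on $\hat m$ itself.
* The $R^2$ bootstrap holds fitted curves fixed (see above).
* The migration estimate from a rarefied table reflects the compound
  sampling chain (generation at 14,000 reads, rarefaction to 4,000), so
  $\hat m$ is comparable *between* groups fit at the same depth but is
  not the generator's $m$ in absolute terms; the recovery tests
  therefore fit at the generation depth.
* Free permutations ignore the repeated-measures structure (two sides
  per plant); `strata` exists for sensitivity checks, and the paired
  side contrasts use explicitly paired tests instead.
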