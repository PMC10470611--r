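# leafside

Community-assembly analysis for the two sides of a leaf.

Phyllosphere bacterial communities are shaped by a tug-of-war between
**dispersal** (airborne immigrants landing mostly on the upper leaf
surface) and **host filtering** (plant-driven selection, strongest on
the stomata-rich, resource-leaching lower surface). `leafside`
implements the statistical pipeline to quantify that contrast on an
ASV-by-sample count table from a multi-species, upper/lower-paired leaf
swab design, plus a ground-truthed synthetic study generator to
validate every step.

What it computes:

* **Sloan neutral community model** fits to occupancy-abundance clouds,
  per leaf side: a taxon at source abundance *p* has local relative
  abundance Beta(*Nmp*, *Nm*(1−*p*)); predicted occupancy is the Beta
  survival at the detection limit; *m* is fit by least squares and fit
  quality by *R²*, with Wilson envelopes classifying taxa as
  above/neutral/below.
* **Core microbiome** from abundance-occupancy distributions:
  occupancy-first ranking, cumulative Bray-Curtis contribution curve,
  "last 2% increase" cutoff, and paired per-side core summaries.
* **Weighted endemism**: per-taxon degree of endemism (share of host
  species where never detected), per-sample weighted endemism
  W = Σᵢ rᵢ eᵢ, its regression on pH/leaf side/stomatal density with
  backward elimination, and the paired side contrast.
* **Inference machinery**: sequential-term PERMANOVA on Bray-Curtis
  (Gower-centred trace decomposition, free permutations, exact
  enumeration mode), Mantel distance-decay, Wilcoxon/Kendall wrappers,
  rarefaction and the study's read filters.
* **`simulate_study()`**: the generative dual of the neutral fit —
  shared lognormal metacommunity, per-side migration parameters,
  multiplicative host-filter boosts (shared plant-associated taxa,
  species-specific sets, strict endemics), realistic covariates, and a
  full ground-truth record.

## Worked example

```r
library(leafside)

cfg <- pipeline_config(design = study_design(), seed = 1, n_perm = 9999)
report <- run_pipeline(cfg)
print(report)
```

```
Leaf-side community assembly report
  samples: 144, taxa after filtering: 500
  neutral fit R^2: upper 0.947 vs lower 0.904 (boot p = 0.001)
  richness higher on upper: TRUE (p = 8.35e-14)
  core abundance higher on lower: TRUE (p = 8.47e-14)
  weighted endemism higher on lower: TRUE (p = 2.36e-11)
  core size: 53 taxa
```

Reading the output: the default design plants more immigration on the
upper surface (m = 0.15 vs 0.05) and stronger host filtering on the
lower (boosts ×10 vs ×3, plus per-species endemics). The pipeline
detects all four designed signatures — the upper side hews closer to
the neutral occupancy-abundance curve (higher *R²*, taxon-bootstrap
p = 0.001), alpha diversity is higher on top (paired one-sided
Wilcoxon), core taxa are more abundant underneath, and weighted
endemism is higher underneath. The 53-taxon core is the smallest
occupancy-ranked prefix whose further Bray-Curtis gains stay below 2%.

The same analysis as a stepwise narrative, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study + ground truth
Rscript analysis/02_filter_rarefy.R   # <=2-read filter, rarefy to 4,000
Rscript analysis/03_alpha_beta.R      # diversity, PERMANOVA, Mantel
Rscript analysis/04_neutral_fits.R    # per-side Sloan fits
Rscript analysis/05_core_microbiome.R # core selection + side contrasts
Rscript analysis/06_endemism.R        # weighted endemism + regression
Rscript analysis/07_report.R          # consolidated report.json
```

Real data drop in via `pipeline_config(table_path = ..., metadata_path
= ...)`: a dense TSV feature table (taxa as rows, `#TaxonID` header) or
BIOM-JSON, and a metadata TSV with `sample_id`, `plant_species`,
`plant_individual`, `leaf_side` (+ optional pH, stomatal density,
coordinates).

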