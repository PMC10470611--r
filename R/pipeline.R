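#' Configuration for a full leaf-side analysis run
#'
#' Either point `table_path`/`metadata_path` at an existing feature table
#' + sample sheet, or supply a [study_design()] to simulate one. All
#' thresholds default to the study's published choices: low-count filter
#' at <= 2 reads per sample, 0.1% total relative-abundance floor for the
#' differential-abundance pre-filter, rarefaction to 4,000 reads, core
#' threshold 2% relative gain, PERMANOVA with 9,999 permutations.
#'
#' @param design A [study_design()] (ignored when paths are given).
#' @param table_path,metadata_path Optional input files (dense TSV).
#' @param rarefaction_depth Reads per sample after rarefaction.
#' @param low_count_max Per-sample low-count cutoff.
#' @param min_total_relabund Total relative-abundance floor (applied only
#'   for the reported filter census; the main pipeline works from the
#'   low-count-filtered table as the study did).
#' @param core_threshold Relative-gain cutoff for core selection.
#' @param permanova_terms Ordered PERMANOVA terms.
#' @param n_perm Permutations for PERMANOVA and Mantel.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for tables and report.json.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(design = study_design(),
                            table_path = NULL, metadata_path = NULL,
                            rarefaction_depth = 4000,
                            low_count_max = 2,
                            min_total_relabund = 0.001,
                            core_threshold = 0.02,
                            permanova_terms = c("ph", "stomatal_density",
                                                "leaf_side", "plant_species",
                                                "plant_individual",
                                                "leaf_side:plant_species"),
                            n_perm = 9999,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(rarefaction_depth >= 1, low_count_max >= 0,
            min_total_relabund >= 0, min_total_relabund < 1,
            core_threshold >= 0)
  cfg <- list(design = design, table_path = table_path,
              metadata_path = metadata_path,
              rarefaction_depth = rarefaction_depth,
              low_count_max = low_count_max,
              min_total_relabund = min_total_relabund,
              core_threshold = core_threshold,
              permanova_terms = permanova_terms,
              n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full leaf-side community-assembly analysis
#'
#' Stages: simulate or read inputs; low-count filter; rarefaction; alpha
#' diversity with paired side contrasts; Bray-Curtis + PERMANOVA + Mantel
#' distance-decay; per-side neutral-model fits with the bootstrap R^2
#' contrast; core-microbiome selection and per-side core summaries;
#' weighted endemism with its regression and paired side test. All
#' randomness derives from `cfg$seed` via [seed_stream()], so reruns with
#' the same config are identical.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `"leafside_report"` with elements `inputs`,
#'   `alpha`, `beta`, `neutral`, `core`, `endemism`, `findings` (the four
#'   directional leaf-side findings with p-values), and `seeds`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- seed_stream(cfg$seed, 8)
  names(seeds) <- c("simulate", "rarefy", "permanova", "mantel",
                    "boot_r2", "spare1", "spare2", "spare3")

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$table_path)) {
    table_raw <- read_feature_table(cfg$table_path)
    sheet <- read_sample_sheet(cfg$metadata_path)
  } else {
    design <- cfg$design
    design$seed <- seeds[["simulate"]]
    sim <- simulate_study(design)
    table_raw <- sim$table
    sheet <- sim$sheet
    truth <- sim$truth
  }

  # --- filtering + rarefaction -------------------------------------------
  filtered <- filter_low_counts(table_raw, cfg$low_count_max)
  da_table <- filter_total_relabund(table_raw, cfg$min_total_relabund)
  rarefied <- rarefy_table(filtered, cfg$rarefaction_depth,
                           seed = seeds[["rarefy"]])
  sheet_r <- align_samples(rarefied, sheet)

  # --- alpha diversity ----------------------------------------------------
  alpha <- alpha_diversity(rarefied)
  alpha$plant_individual <- sheet_r$plant_individual
  alpha$leaf_side <- sheet_r$leaf_side
  ap <- pair_by_individual(alpha, c("richness", "inverse_simpson"))
  richness_test <- rank_tests(ap$upper$richness, ap$lower$richness,
                              "wilcoxon_paired", alternative = "greater")
  simpson_test <- rank_tests(ap$upper$inverse_simpson,
                             ap$lower$inverse_simpson,
                             "wilcoxon_paired", alternative = "greater")

  # --- beta diversity: PERMANOVA + Mantel --------------------------------
  comp <- to_relative_abundance(rarefied)
  bc <- bray_curtis_matrix(comp)
  terms <- cfg$permanova_terms
  have <- vapply(unique(unlist(strsplit(terms, ":"))), function(cl) {
    cl %in% names(sheet_r) && !anyNA(sheet_r[[cl]])
  }, logical(1))
  terms <- terms[vapply(strsplit(terms, ":"),
                        function(cls) all(have[cls]), logical(1))]
  perm <- permanova(bc, sheet_r, terms, n_perm = cfg$n_perm,
                    seed = seeds[["permanova"]])
  mantel_res <- NULL
  if (all(c("latitude", "longitude") %in% names(sheet_r))) {
    geo <- geo_distance_matrix(sheet_r, collapse = "per_individual")
    bc_plant <- collapse_distance(
      bc, stats::setNames(sheet_r$plant_individual, sheet_r$sample_id))
    mantel_res <- mantel_test(geo, bc_plant[rownames(geo), rownames(geo)],
                              n_perm = cfg$n_perm, seed = seeds[["mantel"]])
  }

  # --- neutral fits per side ---------------------------------------------
  fits <- compare_group_fits(rarefied, sheet_r, "leaf_side",
                             N = cfg$rarefaction_depth)
  r2_contrast <- compare_fit_r2(fits$upper, fits$lower,
                                seed = seeds[["boot_r2"]])

  # --- core microbiome ----------------------------------------------------
  ranked <- rank_taxa(rarefied)
  curve <- bc_contribution_curve(rarefied, ranked)
  core <- select_core(curve, cfg$core_threshold)
  core_sides <- core_side_summary(core, rarefied, sheet_r)

  # --- weighted endemism (on filtered, unrarefied counts) ----------------
  sheet_f <- align_samples(filtered, sheet)
  e <- endemism_degrees(filtered, sheet_f)
  W <- weighted_endemism(filtered, e)
  regression <- NULL
  if (all(c("ph", "stomatal_density") %in% names(sheet_f))) {
    regression <- endemism_regression(W, sheet_f)
  }
  endemism_test <- side_comparison(W, sheet_f)

  findings <- list(
    neutral_fit_closer_on_upper = list(
      observed = fits$upper$r_squared > fits$lower$r_squared,
      r2_upper = fits$upper$r_squared, r2_lower = fits$lower$r_squared,
      p_value = r2_contrast$p_value),
    richness_higher_on_upper = list(
      observed = stats::median(ap$upper$richness - ap$lower$richness) > 0,
      p_value = richness_test$p_value),
    core_more_abundant_on_lower = list(
      observed = stats::median(
        core_sides$per_sample$core_abundance[
          core_sides$per_sample$leaf_side == "lower"]) >
        stats::median(core_sides$per_sample$core_abundance[
          core_sides$per_sample$leaf_side == "upper"]),
      p_value = core_sides$abundance_test$p_value),
    endemism_higher_on_lower = list(
      observed = endemism_test$median_lower > endemism_test$median_upper,
      p_value = endemism_test$p_value))

  report <- list(
    inputs = list(n_taxa_raw = nrow(table_raw),
                  n_samples = ncol(table_raw),
                  n_taxa_filtered = nrow(filtered),
                  n_taxa_da_filter = nrow(da_table),
                  n_samples_rarefied = ncol(rarefied),
                  mean_reads_per_sample = mean(colSums(ct_matrix(table_raw))),
                  config = cfg[setdiff(names(cfg), "design")]),
    alpha = list(per_sample = alpha, richness_test = richness_test,
                 inverse_simpson_test = simpson_test),
    beta = list(permanova = perm, mantel = mantel_res),
    neutral = list(fits = fits, r2_contrast = r2_contrast),
    core = list(selection = core, side_summary = core_sides),
    endemism = list(degrees = e, W = W, regression = regression,
                    side_test = endemism_test),
    findings = findings,
    truth = truth,
    seeds = seeds)
  class(report) <- "leafside_report"
  if (!is.null(cfg$out_dir)) write_report(report, rarefied, cfg$out_dir)
  report
}

#' @export
print.leafside_report <- function(x, ...) {
  f <- x$findings
  cat("Leaf-side community assembly report\n")
  cat(sprintf("  samples: %d, taxa after filtering: %d\n",
              x$inputs$n_samples, x$inputs$n_taxa_filtered))
  cat(sprintf("  neutral fit R^2: upper %.3f vs lower %.3f (boot p = %.3g)\n",
              f$neutral_fit_closer_on_upper$r2_upper,
              f$neutral_fit_closer_on_upper$r2_lower,
              f$neutral_fit_closer_on_upper$p_value))
  cat(sprintf("  richness higher on upper: %s (p = %.3g)\n",
              f$richness_higher_on_upper$observed,
              f$richness_higher_on_upper$p_value))
  cat(sprintf("  core abundance higher on lower: %s (p = %.3g)\n",
              f$core_more_abundant_on_lower$observed,
              f$core_more_abundant_on_lower$p_value))
  cat(sprintf("  weighted endemism higher on lower: %s (p = %.3g)\n",
              f$endemism_higher_on_lower$observed,
              f$endemism_higher_on_lower$p_value))
  cat(sprintf("  core size: %d taxa\n", x$core$selection$core_size))
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (summary statistics, no bulky matrices) plus
#' per-taxon/per-sample TSVs into `out_dir`.
#'
#' @param report A `leafside_report`.
#' @param rarefied The rarefied count table (for the per-taxon outputs).
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, rarefied = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- report_summary(report)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  utils::write.table(report$alpha$per_sample,
                     file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$beta$permanova$table,
                     file.path(out_dir, "permanova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fits <- report$neutral$fits
  for (nm in names(fits)) {
    utils::write.table(fits[[nm]]$taxa,
                       file.path(out_dir, sprintf("neutral_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  core <- report$core$selection
  core_tab <- data.frame(taxon_id = core$ranked_taxa,
                         rank = seq_along(core$ranked_taxa),
                         cumulative_contribution = unname(core$contribution),
                         is_core = core$ranked_taxa %in% core$core_ids)
  utils::write.table(core_tab, file.path(out_dir, "core.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(taxon_id = names(report$endemism$degrees$e),
               endemism = unname(report$endemism$degrees$e)),
    file.path(out_dir, "endemism_taxa.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$endemism$W,
                     file.path(out_dir, "endemism_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

# flatten a report into JSON-friendly summary form (stable key order,
# no timestamps, so identical runs serialize identically)
report_summary <- function(report) {
  fits <- report$neutral$fits
  perm <- report$beta$permanova$table
  list(
    schema = "leafside-report/1",
    inputs = report$inputs[c("n_taxa_raw", "n_samples", "n_taxa_filtered",
                             "n_samples_rarefied", "mean_reads_per_sample")],
    alpha = list(
      mean_richness_upper = mean(report$alpha$per_sample$richness[
        report$alpha$per_sample$leaf_side == "upper"]),
      mean_richness_lower = mean(report$alpha$per_sample$richness[
        report$alpha$per_sample$leaf_side == "lower"]),
      richness_p = report$alpha$richness_test$p_value,
      inverse_simpson_p = report$alpha$inverse_simpson_test$p_value),
    permanova = stats::setNames(
      lapply(seq_len(nrow(perm)), function(i) {
        list(df = perm$df[i], SS = perm$sum_of_squares[i],
             R2 = perm$r_squared[i], F = perm$pseudo_F[i],
             p = perm$p_value[i])
      }), perm$term),
    mantel = report$beta$mantel[c("rho", "p_value")],
    neutral = stats::setNames(
      lapply(fits, function(f) list(m = f$m, N = f$N, d = f$d,
                                    r_squared = f$r_squared,
                                    n_taxa = f$n_taxa)),
      names(fits)),
    r2_contrast = report$neutral$r2_contrast,
    core = list(size = report$core$selection$core_size,
                abundance_p = report$core$side_summary$abundance_test$p_value,
                occupancy_p = report$core$side_summary$occupancy_test$p_value),
    endemism = list(n_taxa = length(report$endemism$degrees$e),
                    n_excluded = length(report$endemism$degrees$excluded_taxa),
                    side_p = report$endemism$side_test$p_value,
                    median_W_lower = report$endemism$side_test$median_lower,
                    median_W_upper = report$endemism$side_test$median_upper),
    findings = report$findings,
    seeds = as.list(report$seeds))
}
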