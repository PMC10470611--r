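#' Degree of endemism per taxon
#'
#' A taxon's degree of endemism is the proportion of host plant species
#' on which it was never detected:
#' e_i = (n_species - n_species_detected_i) / n_species. Taxa detected in
#' at most one sample are excluded first (they carry no usable
#' distributional signal). Detection means count > 0 in the supplied
#' table — by convention the filtered, unrarefied table.
#'
#' @param t A count table.
#' @param sheet Sample metadata with `plant_species` (>= 2 species).
#' @return A list with `e` (named numeric vector over retained taxa),
#'   `excluded_taxa`, and `n_species`.
#' @export
endemism_degrees <- function(t, sheet) {
  sheet <- align_samples(t, sheet)
  species <- unique(sheet$plant_species)
  if (length(species) < 2) stop("need at least two plant species")
  m <- ct_matrix(t)
  n_samples_detected <- rowSums(m > 0)
  excluded <- rownames(m)[n_samples_detected <= 1]
  keep <- n_samples_detected > 1
  detected <- m[keep, , drop = FALSE] > 0
  # species x taxon detection: any sample of the species with a read
  by_sp <- vapply(species, function(sp) {
    cols <- sheet$plant_species == sp
    rowSums(detected[, cols, drop = FALSE]) > 0
  }, logical(sum(keep)))
  n_sp_detected <- rowSums(by_sp)
  e <- (length(species) - n_sp_detected) / length(species)
  names(e) <- rownames(m)[keep]
  list(e = e, excluded_taxa = excluded, n_species = length(species))
}

#' Weighted endemism per sample
#'
#' W_s = sum_i relabund_{i,s} * e_i over the taxa retained by
#' [endemism_degrees()] (relative abundances from the full sample
#' composition). Also returns the natural log, with zero-W samples
#' floored at half the smallest positive W so they stay usable in the
#' regression.
#'
#' @param t The count table used for `e`.
#' @param e The result of [endemism_degrees()] (or a named numeric
#'   vector of degrees).
#' @param zero_floor Optional explicit floor for W = 0 before the log.
#' @return A data.frame with `sample_id`, `W`, `log_W` and a logical
#'   `flagged` for samples with no retained-taxon reads.
#' @export
weighted_endemism <- function(t, e, zero_floor = NULL) {
  if (is.list(e)) e <- e$e
  m <- ct_matrix(t)
  missing <- setdiff(names(e), rownames(m))
  if (length(missing)) stop("degrees refer to taxa absent from table: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  comp <- sweep(m, 2, colSums(m), "/")
  W <- as.numeric(crossprod(comp[names(e), , drop = FALSE], e))
  flagged <- colSums(m[names(e), , drop = FALSE]) == 0
  if (any(flagged)) {
    warning("sample(s) with no reads among retained taxa: ",
            paste(colnames(m)[flagged], collapse = ", "))
  }
  floor_val <- zero_floor %||%
    (if (any(W > 0)) min(W[W > 0]) / 2 else 1)
  log_W <- log(ifelse(W > 0, W, floor_val))
  data.frame(sample_id = colnames(m), W = W, log_W = log_W,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple regression of log weighted endemism on leaf covariates
#'
#' Ordinary least squares of `log_W` on pH, leaf side and stomatal
#' density, then backward elimination: the term with the largest p-value
#' is dropped until every remaining term has p < `alpha` ("optimizing"
#' the model). The full pre-elimination model is always reported.
#'
#' @param W Output of [weighted_endemism()].
#' @param sheet Sample metadata with `ph`, `leaf_side`,
#'   `stomatal_density`.
#' @param covariates Covariate columns (defaults above).
#' @param alpha Retention threshold (default 0.05).
#' @return A list with `full_model`, `final_model` (both `lm`),
#'   `coefficients` (final), `elimination` (character trace of dropped
#'   terms), `adj_r_squared`.
#' @export
endemism_regression <- function(W, sheet,
                                covariates = c("ph", "leaf_side",
                                               "stomatal_density"),
                                alpha = 0.05) {
  sheet <- read_sample_sheet(sheet)
  df <- merge(W, sheet, by = "sample_id")
  missing <- setdiff(covariates, names(df))
  if (length(missing)) stop("missing covariate(s): ",
                            paste(missing, collapse = ", "))
  if (!all(is.finite(df$log_W))) stop("non-finite log_W values")
  fml <- stats::reformulate(covariates, response = "log_W")
  full <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; aliased terms: ",
         paste(bad, collapse = ", "))
  }
  terms_left <- covariates
  model <- full
  trace <- character(0)
  repeat {
    if (length(terms_left) == 0) break
    # term-level p-values (F-test per term, handles factor terms cleanly)
    dr <- stats::drop1(model, test = "F")
    pv <- dr[["Pr(>F)"]][-1]
    names(pv) <- rownames(dr)[-1]
    if (all(pv < alpha)) break
    worst <- names(pv)[which.max(pv)]
    trace <- c(trace, sprintf("%s (p = %.3g)", worst, max(pv)))
    terms_left <- setdiff(terms_left, worst)
    model <- if (length(terms_left)) {
      stats::lm(stats::reformulate(terms_left, response = "log_W"),
                data = df)
    } else {
      stats::lm(log_W ~ 1, data = df)
    }
  }
  list(full_model = full, final_model = model,
       coefficients = summary(model)$coefficients,
       elimination = trace,
       adj_r_squared = summary(model)$adj.r.squared)
}

#' Paired comparison of weighted endemism between leaf sides
#'
#' Wilcoxon signed-rank on W_lower - W_upper paired by plant individual.
#' Default alternative `"greater"`: endemism is expected higher on the
#' lower (host-filtered) surface.
#'
#' @param W Output of [weighted_endemism()].
#' @param sheet Sample metadata.
#' @param alternative Passed to [stats::wilcox.test()]; refers to
#'   lower minus upper.
#' @return A list with `statistic`, `p_value`, `n_pairs`,
#'   `median_lower`, `median_upper`, `alternative`.
#' @export
side_comparison <- function(W, sheet, alternative = "greater") {
  sheet <- read_sample_sheet(sheet)
  df <- merge(W, sheet[, c("sample_id", "plant_individual", "leaf_side")],
              by = "sample_id")
  paired <- pair_by_individual(df, "W")
  if (nrow(paired$lower) < 6) stop("fewer than 6 complete upper/lower pairs")
  lo <- paired$lower$W
  up <- paired$upper$W
  if (all(lo == up)) {
    return(list(statistic = NA_real_, p_value = 1, n_pairs = length(lo),
                median_lower = stats::median(lo),
                median_upper = stats::median(up),
                alternative = alternative))
  }
  ht <- stats::wilcox.test(lo, up, paired = TRUE, alternative = alternative,
                           exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_pairs = length(lo), median_lower = stats::median(lo),
       median_upper = stats::median(up), alternative = alternative)
}
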