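#' Rank taxa for core-microbiome selection
#'
#' Abundance-occupancy ranking ("spatial" variant: this design has no
#' time series): taxa ordered by decreasing occupancy, ties broken by
#' decreasing mean relative abundance, then lexically by taxon id, so the
#' ranking is deterministic.
#'
#' @param t A (rarefied) count table.
#' @return A character vector of taxon ids, most core-like first.
#' @export
rank_taxa <- function(t) {
  prof <- occupancy_abundance(t)
  ord <- order(-prof$occupancy, -prof$p, prof$taxon_id)
  prof$taxon_id[ord]
}

#' Cumulative Bray-Curtis contribution of ranked taxa
#'
#' For each prefix of the ranking, the fraction of between-sample
#' Bray-Curtis structure carried by those taxa: for a sample pair the
#' top-k subset dissimilarity is the cumulative |a_i - b_i| over ranked
#' taxa divided by the pair's full denominator, so
#' contribution(k) = mean over pairs of
#' (sum_{i<=k} |a_i - b_i|) / (sum_all |a_i - b_i|).
#' The curve starts at 0 (k = 0 is implicit), is non-decreasing and ends
#' at exactly 1. Pairs with zero full dissimilarity are skipped.
#'
#' @param t A (rarefied) count table.
#' @param ranked Taxon ranking covering all taxa (from [rank_taxa()]).
#' @return A numeric vector `contribution` of length `nrow(t)`, named by
#'   ranked taxon ids.
#' @export
bc_contribution_curve <- function(t, ranked) {
  m <- ct_matrix(t)
  if (!setequal(ranked, rownames(m)) || length(ranked) != nrow(m)) {
    stop("ranking must cover all taxa exactly once")
  }
  comp <- sweep(m, 2, colSums(m), "/")[ranked, , drop = FALSE]
  n <- ncol(comp)
  if (n < 2) stop("need at least two samples")
  # accumulate sum over pairs of |a - b| / (pair's total |a - b|):
  # the cumulative-over-taxa operator is linear, so row sums suffice
  acc <- numeric(nrow(comp))
  n_pairs <- 0
  for (j in seq_len(n - 1)) {
    diffs <- abs(comp[, (j + 1):n, drop = FALSE] - comp[, j])
    tot <- colSums(diffs)
    keep <- tot > 0
    if (any(keep)) {
      acc <- acc + rowSums(sweep(diffs[, keep, drop = FALSE], 2, tot[keep],
                                 "/"))
      n_pairs <- n_pairs + sum(keep)
    }
  }
  if (n_pairs == 0) stop("all sample pairs identical; no beta diversity")
  curve <- cumsum(acc) / n_pairs
  names(curve) <- ranked
  curve
}

#' Select the core microbiome from a contribution curve
#'
#' "Last 2% increase" stopping rule on the cumulative Bray-Curtis
#' contribution: the core is the smallest prefix k* past which every
#' relative gain contribution(k+1)/contribution(k) - 1 stays below
#' `threshold`. A flat curve degenerates to the minimal prefix with
#' nonzero contribution.
#'
#' @param curve Output of [bc_contribution_curve()].
#' @param threshold Relative-gain cutoff (default 0.02).
#' @return A list of class `"core_selection"`: `ranked_taxa`,
#'   `contribution`, `threshold`, `core_ids`, `core_size`.
#' @export
select_core <- function(curve, threshold = 0.02) {
  stopifnot(threshold >= 0)
  if (any(diff(curve) < -1e-12)) stop("contribution curve must be ",
                                      "non-decreasing")
  K <- length(curve)
  first_pos <- match(TRUE, curve > 0)
  if (is.na(first_pos)) stop("flat zero curve: no beta diversity to explain")
  gains <- curve[-1] / pmax(curve[-K], .Machine$double.xmin) - 1
  big <- which(gains > threshold)       # gain from k to k+1
  k_star <- if (length(big)) max(big) + 1 else first_pos
  k_star <- max(k_star, first_pos)
  structure(list(ranked_taxa = names(curve),
                 contribution = curve,
                 threshold = threshold,
                 core_ids = names(curve)[seq_len(k_star)],
                 core_size = k_star),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf(paste0("core_selection: %d core taxa of %d ",
                     "(threshold %.3g, contribution at cut %.3f)\n"),
              x$core_size, length(x$ranked_taxa), x$threshold,
              x$contribution[x$core_size]))
  invisible(x)
}

#' Per-sample core summaries and the paired side contrast
#'
#' For every sample: the summed relative abundance of core taxa and the
#' fraction of core taxa detected. Sides are then contrasted with paired
#' one-sided Wilcoxon signed-rank tests (paired by plant individual):
#' core relative abundance is tested for being higher on the lower
#' surface, core detection (occupancy) for being higher on the upper
#' surface — the two directions host filtering is expected to produce.
#' Set `alternative = "two.sided"` for direction-free tests.
#'
#' @param core A [select_core()] result (or character vector of core ids).
#' @param t A (rarefied) count table.
#' @param sheet Sample metadata with `leaf_side` and `plant_individual`.
#' @param alternative `"directional"` (default, see above) or
#'   `"two.sided"`.
#' @return A list with `per_sample` (data.frame), `abundance_test` and
#'   `occupancy_test` (each: statistic, p_value, alternative, n_pairs).
#' @export
core_side_summary <- function(core, t, sheet, alternative = c("directional",
                                                              "two.sided")) {
  alternative <- match.arg(alternative)
  core_ids <- if (inherits(core, "core_selection")) core$core_ids else core
  if (length(core_ids) == 0) stop("empty core set")
  m <- ct_matrix(t)
  missing <- setdiff(core_ids, rownames(m))
  if (length(missing)) stop("core taxa absent from table: ",
                            paste(missing, collapse = ", "))
  sheet <- align_samples(t, sheet)
  comp <- sweep(m, 2, colSums(m), "/")
  per_sample <- data.frame(
    sample_id = colnames(m),
    plant_individual = sheet$plant_individual,
    leaf_side = sheet$leaf_side,
    core_abundance = colSums(comp[core_ids, , drop = FALSE]),
    core_detected = colMeans(m[core_ids, , drop = FALSE] > 0),
    row.names = NULL, stringsAsFactors = FALSE)
  paired <- pair_by_individual(per_sample, c("core_abundance",
                                             "core_detected"))
  test <- function(lower, upper, alt) {
    ht <- stats::wilcox.test(lower, upper, paired = TRUE, alternative = alt,
                             exact = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         alternative = alt, n_pairs = length(lower))
  }
  alt_ab <- if (alternative == "directional") "greater" else "two.sided"
  alt_oc <- if (alternative == "directional") "less" else "two.sided"
  list(per_sample = per_sample,
       abundance_test = test(paired$lower$core_abundance,
                             paired$upper$core_abundance, alt_ab),
       occupancy_test = test(paired$lower$core_detected,
                             paired$upper$core_detected, alt_oc),
       n_pairs = nrow(paired$lower))
}

# split a per-sample table into aligned lower/upper halves by plant;
# unpaired plants dropped with a warning
pair_by_individual <- function(df, value_cols) {
  wide <- split(df, df$plant_individual)
  complete <- vapply(wide, function(x) {
    all(c("upper", "lower") %in% x$leaf_side) && nrow(x) == 2
  }, logical(1))
  if (any(!complete)) {
    warning("dropping unpaired plant individual(s): ",
            paste(names(wide)[!complete], collapse = ", "))
  }
  wide <- wide[complete]
  lower <- do.call(rbind, lapply(wide, function(x) x[x$leaf_side == "lower",
                                                     value_cols,
                                                     drop = FALSE]))
  upper <- do.call(rbind, lapply(wide, function(x) x[x$leaf_side == "upper",
                                                     value_cols,
                                                     drop = FALSE]))
  list(lower = lower, upper = upper, plants = names(wide))
}
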