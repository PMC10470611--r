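#' Zero out low-count observations
#'
#' Denoising filter applied before any analysis: read counts of
#' `per_sample_max` or fewer in a given sample are treated as sequencing
#' noise. The default interpretation (`mode = "per_entry"`) zeroes each
#' offending cell sample-by-sample, the conventional reading of
#' singleton/doubleton removal; `mode = "max_anywhere"` instead drops a
#' taxon outright when its largest count across all samples is at or below
#' the cutoff. Taxa whose rows become all-zero are dropped either way.
#'
#' @param t A count table.
#' @param per_sample_max Counts less than or equal to this are removed
#'   (default 2, i.e. singletons and doubletons).
#' @param mode `"per_entry"` (default) or `"max_anywhere"`; see Details.
#' @return A filtered count table with attribute `filter_report`, a list
#'   with `entries_zeroed` and `taxa_dropped`.
#' @export
filter_low_counts <- function(t, per_sample_max = 2,
                              mode = c("per_entry", "max_anywhere")) {
  mode <- match.arg(mode)
  stopifnot(per_sample_max >= 0)
  m <- ct_matrix(t)
  if (mode == "per_entry") {
    low <- m > 0 & m <= per_sample_max
    zeroed <- sum(low)
    m[low] <- 0L
  } else {
    gone <- apply(m, 1, max) <= per_sample_max
    zeroed <- sum(m[gone, , drop = FALSE] > 0)
    m[gone, ] <- 0L
  }
  empty <- rowSums(m) == 0
  out <- as_count_table(m[!empty, , drop = FALSE])
  attr(out, "filter_report") <- list(entries_zeroed = zeroed,
                                     taxa_dropped = rownames(m)[empty])
  out
}

#' Drop taxa below a total relative-abundance floor
#'
#' Removes taxa whose summed reads account for strictly less than
#' `min_frac` of the grand total (the 0.1% pre-filter used ahead of
#' differential-abundance testing). Taxa exactly at the floor are kept.
#'
#' @param t A count table.
#' @param min_frac Minimum total relative abundance, in `[0, 1)`.
#' @return A filtered count table.
#' @export
filter_total_relabund <- function(t, min_frac = 0.001) {
  stopifnot(min_frac >= 0, min_frac < 1)
  m <- ct_matrix(t)
  total <- sum(as.numeric(m))
  if (total == 0) stop("cannot filter an empty (all-zero) table")
  keep <- rowSums(m) / total >= min_frac
  as_count_table(m[keep, , drop = FALSE])
}

#' Rarefy samples to equal depth
#'
#' Uniform random subsampling without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) of each sample's reads to
#' exactly `depth`. Samples with fewer than `depth` total reads are
#' dropped with a warning; subsampling without replacement cannot reach
#' the target for them.
#'
#' @param t A count table.
#' @param depth Target reads per sample (default 4000).
#' @param seed Integer seed; required so every rarefaction is logged and
#'   reproducible.
#' @return A rarefied count table whose column sums all equal `depth`,
#'   with attribute `dropped_samples`.
#' @export
rarefy_table <- function(t, depth = 4000, seed) {
  stopifnot(depth >= 1)
  if (missing(seed)) stop("rarefy_table() requires an explicit seed")
  m <- ct_matrix(t)
  totals <- colSums(m)
  shallow <- totals < depth
  if (all(shallow)) stop("all samples have fewer than ", depth, " reads")
  if (any(shallow)) {
    warning(sum(shallow), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(m)[shallow], collapse = ", "))
    m <- m[, !shallow, drop = FALSE]
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # rrarefy warns when the smallest nonzero count exceeds 1, which is the
  # normal state of a low-count-filtered table; silence just that warning
  rare <- withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  out <- as_count_table(rare)
  attr(out, "dropped_samples") <- colnames(ct_matrix(t))[shallow]
  out
}

#' Convert counts to within-sample relative abundances
#'
#' @param t A count table with no all-zero samples.
#' @return A numeric matrix (taxa x samples) whose columns each sum to 1,
#'   with class `"composition_table"`.
#' @export
to_relative_abundance <- function(t) {
  m <- ct_matrix(t)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  }
  comp <- sweep(m, 2, totals, "/")
  class(comp) <- c("composition_table", class(comp))
  comp
}
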