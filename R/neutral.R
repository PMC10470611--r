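#' Occupancy-abundance profiles per taxon
#'
#' For each taxon: mean within-sample relative abundance p (averaged over
#' samples) and occupancy (fraction of samples where the taxon has at
#' least one read).
#'
#' @param t A count table with at least two samples.
#' @return A data.frame with `taxon_id`, `p`, `occupancy`, `n_samples`.
#' @export
occupancy_abundance <- function(t) {
  m <- ct_matrix(t)
  if (ncol(m) < 2) stop("need at least two samples")
  if (nrow(m) == 0) stop("empty table")
  comp <- sweep(m, 2, pmax(colSums(m), 1), "/")
  data.frame(taxon_id = rownames(m),
             p = rowMeans(comp),
             occupancy = rowMeans(m > 0),
             n_samples = ncol(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Neutral-model predicted occupancy
#'
#' Under the Sloan neutral community model a taxon with source-pool mean
#' relative abundance p has local relative abundance distributed
#' Beta(N m p, N m (1 - p)), where N is the community (read) size and m
#' the migration parameter. Its predicted occupancy is the probability of
#' exceeding the detection limit d:
#' `1 - pbeta(d, N m p, N m (1 - p))`. The boundary cases p = 0 and p = 1
#' return 0 and 1.
#'
#' @param p Mean relative abundance(s) in `[0, 1]` (vectorized).
#' @param m Migration parameter, > 0.
#' @param N Community size (reads per sample), > 0.
#' @param d Detection limit in (0, 1). The default `log(2)/N` is the
#'   relative abundance at which a taxon sampled as N reads is detected
#'   (>= 1 read) with probability one half: 1 - (1 - x)^N = 1/2 at
#'   x = ln2/N. The cruder one-read convention `1/N` overstates the
#'   threshold and biases the migration estimate upward; pass `d = 1/N`
#'   to reproduce it.
#' @return Predicted occupancy in `[0, 1]`.
#' @export
predict_occupancy <- function(p, m, N, d) {
  stopifnot(m > 0, N > 0, d > 0, d < 1, all(p >= 0), all(p <= 1))
  out <- numeric(length(p))
  interior <- p > 0 & p < 1
  out[interior] <- stats::pbeta(d, N * m * p[interior],
                                N * m * (1 - p[interior]),
                                lower.tail = FALSE)
  out[p == 1] <- 1
  out
}

#' Fit the Sloan neutral model to occupancy-abundance data
#'
#' Least-squares fit of the migration parameter m: minimizes
#' sum_i (occupancy_i - predicted(p_i; m, N, d))^2 over m in (1e-6, 1],
#' using a 50-point log-spaced grid multistart followed by bounded
#' refinement (the SSE surface is flat for large N m, so a single local
#' search can stall). R^2 = 1 - SSE/SST with SST around the mean observed
#' occupancy. Each taxon gets a Wilson score envelope on its predicted
#' occupancy at the realized sample count and a class:
#' `above` / `neutral` / `below` the envelope.
#'
#' Taxa with p = 0 or occupancy = 0 are excluded from the fit but kept in
#' the per-taxon report with class `NA`.
#'
#' @param profiles Output of [occupancy_abundance()].
#' @param N Community size; defaults to the rarefaction depth when known.
#' @param d Detection limit; default `log(2)/N`, the half-detection
#'   abundance under read sampling (see [predict_occupancy()]). Pass
#'   `1/N` for the plain one-read convention.
#' @param conf Envelope confidence level (default 0.95).
#' @return An object of class `"neutral_fit"`: list with `m`, `N`, `d`,
#'   `r_squared`, `n_taxa`, `n_samples`, `boundary` (logical: optimizer
#'   at the m range edge), and `taxa` (per-taxon data.frame with
#'   predicted occupancy, envelope `lower`/`upper`, `class`).
#' @export
fit_neutral <- function(profiles, N, d = log(2) / N, conf = 0.95) {
  stopifnot(is.data.frame(profiles),
            all(c("taxon_id", "p", "occupancy") %in% names(profiles)))
  usable <- profiles$p > 0 & profiles$p < 1 & profiles$occupancy > 0
  if (sum(usable) < 10) {
    stop("need at least 10 taxa with interior mean abundance and nonzero ",
         "occupancy to fit")
  }
  fp <- profiles[usable, , drop = FALSE]
  sse <- function(m) {
    sum((fp$occupancy - predict_occupancy(fp$p, m, N, d))^2)
  }
  grid <- exp(seq(log(1e-6), log(1), length.out = 50))
  grid_sse <- vapply(grid, sse, numeric(1))
  i0 <- which.min(grid_sse)
  lo <- grid[max(i0 - 1, 1)]
  hi <- grid[min(i0 + 1, length(grid))]
  opt <- stats::optimize(sse, lower = lo, upper = hi, tol = 1e-10)
  m_hat <- opt$minimum
  boundary <- m_hat <= 1e-6 * 1.05 || m_hat >= 1 - 1e-8
  if (boundary) {
    warning("neutral fit: migration estimate at the boundary of (1e-6, 1]")
  }
  sse_hat <- opt$objective
  sst <- sum((fp$occupancy - mean(fp$occupancy))^2)
  r2 <- 1 - sse_hat / sst
  n_samp <- if ("n_samples" %in% names(profiles)) profiles$n_samples[1]
            else NA_integer_
  pred <- predict_occupancy(profiles$p, m_hat, N, d)
  env <- wilson_interval(pred, n_samp, conf)
  cls <- rep(NA_character_, nrow(profiles))
  cls[usable] <- ifelse(fp$occupancy > env$upper[usable], "above",
                 ifelse(fp$occupancy < env$lower[usable], "below", "neutral"))
  taxa <- data.frame(profiles,
                     predicted = pred, lower = env$lower, upper = env$upper,
                     class = cls, stringsAsFactors = FALSE)
  structure(list(m = m_hat, N = N, d = d, r_squared = r2,
                 n_taxa = sum(usable), n_samples = n_samp,
                 boundary = boundary, conf = conf, taxa = taxa),
            class = "neutral_fit")
}

# Wilson score interval for a proportion (well-behaved near 0/1)
wilson_interval <- function(p, n, conf = 0.95) {
  if (is.na(n)) return(list(lower = rep(NA_real_, length(p)),
                            upper = rep(NA_real_, length(p))))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf(paste0("Sloan neutral model fit: m = %.4g, N = %g, d = %.3g\n",
                     "  R^2 = %.3f over %d taxa (%s samples)%s\n"),
              x$m, x$N, x$d, x$r_squared, x$n_taxa,
              ifelse(is.na(x$n_samples), "?", x$n_samples),
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Fit the neutral model per sample group
#'
#' Splits samples by a metadata column (e.g. `leaf_side`), fits each
#' group independently, and also returns the pooled fit.
#'
#' @param t A (rarefied) count table.
#' @param sheet Sample metadata.
#' @param group_col Metadata column to split on.
#' @param N Community size passed to [fit_neutral()]; defaults to the
#'   common column sum when the table is rarefied, else the mean column
#'   sum (a message records the choice).
#' @param ... Passed to [fit_neutral()].
#' @return A named list of `neutral_fit` objects (one per group plus
#'   `"pooled"`).
#' @export
compare_group_fits <- function(t, sheet, group_col = "leaf_side", N = NULL,
                               ...) {
  sheet <- align_samples(t, sheet)
  if (!group_col %in% names(sheet)) stop("unknown column: ", group_col)
  m <- ct_matrix(t)
  depths <- colSums(m)
  if (is.null(N)) {
    N <- if (length(unique(depths)) == 1) depths[1] else mean(depths)
    message("compare_group_fits: using N = ", round(N, 1),
            if (length(unique(depths)) == 1) " (rarefied depth)"
            else " (mean sample depth)")
  }
  groups <- split(sheet$sample_id, sheet[[group_col]])
  small <- names(groups)[lengths(groups) < 10]
  if (length(small)) {
    stop("group(s) with fewer than 10 samples: ",
         paste(small, collapse = ", "))
  }
  fits <- lapply(groups, function(ids) {
    fit_neutral(occupancy_abundance(as_count_table(m[, ids, drop = FALSE])),
                N = N, ...)
  })
  fits$pooled <- fit_neutral(occupancy_abundance(t), N = N, ...)
  fits
}

#' Bootstrap contrast of two neutral-fit R^2 values
#'
#' Tests whether fit A describes its occupancy-abundance cloud better
#' than fit B (H1: R^2_A > R^2_B) by resampling taxa with replacement
#' within each fit and recomputing R^2 around the fitted curves (the
#' curves themselves are held fixed; this is a residual bootstrap over
#' ASVs, not a refit).
#'
#' @param fit_a,fit_b `neutral_fit` objects.
#' @param n_boot Bootstrap replicates (default 999).
#' @param seed Integer seed.
#' @return A list with `delta` (observed R^2_A - R^2_B), `p_value`
#'   (one-sided, +1-corrected), and `n_boot`.
#' @export
compare_fit_r2 <- function(fit_a, fit_b, n_boot = 999, seed = 1L) {
  set.seed(seed)
  boot_r2 <- function(fit) {
    tx <- fit$taxa
    tx <- tx[!is.na(tx$class), , drop = FALSE]
    res <- tx$occupancy - tx$predicted
    function() {
      i <- sample.int(nrow(tx), replace = TRUE)
      occ <- tx$occupancy[i]
      1 - sum(res[i]^2) / sum((occ - mean(occ))^2)
    }
  }
  ra <- boot_r2(fit_a); rb <- boot_r2(fit_b)
  delta_star <- vapply(seq_len(n_boot), function(...) ra() - rb(),
                       numeric(1))
  delta <- fit_a$r_squared - fit_b$r_squared
  list(delta = delta,
       p_value = (sum(delta_star <= 0) + 1) / (n_boot + 1),
       n_boot = n_boot)
}
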