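#' Sequential-term PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA with sequential (Type I) sums of
#' squares: the distance matrix is Gower-centred
#' (G = C (-D^2/2) C, C = I - 11'/n), each term's SS is the increment in
#' tr(H_k G) as its columns join the cumulative design matrix, and
#' pseudo-F_k = (SS_k / df_k) / (SS_res / df_res). Significance comes
#' from free permutation of sample identities (rows/columns of D), with
#' the observed statistic included in the null set:
#' p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1). Term order matters —
#' earlier terms absorb shared variation — and a nested factor (plant
#' individual within species) is expressed simply by entering its
#' globally-unique labels after the species term. Interactions are
#' written `"a:b"`.
#'
#' Alternatively `permutations` may be a matrix with one permutation of
#' `1:n` per row; it is then treated as a complete enumeration and the
#' exact p-value `#\{F_perm >= F_obs\} / nrow` is returned (the identity
#' row should be included).
#'
#' @param D Square distance matrix (or `dist`) with sample ids.
#' @param sheet Sample metadata.
#' @param terms Ordered character vector of term labels (columns of
#'   `sheet`, or `"a:b"` interactions).
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional explicit permutation matrix (overrides
#'   `n_perm`/`seed`).
#' @param strata Optional metadata column restricting permutations to
#'   shuffle only within its levels (sensitivity analysis; default free).
#' @return An object of class `"permanova"`: data.frame `table` with
#'   per-term df, SS, R2, F and p plus Residual and Total rows, and the
#'   call parameters.
#' @export
permanova <- function(D, sheet, terms, n_perm = 9999, seed = NULL,
                      permutations = NULL, strata = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  n <- nrow(D)
  sheet <- read_sample_sheet(sheet)
  if (!is.null(rownames(D)) && all(rownames(D) %in% sheet$sample_id)) {
    sheet <- sheet[rownames(D), , drop = FALSE]
  } else if (nrow(sheet) != n) {
    stop("distance matrix and metadata sample sets do not match")
  }
  base_cols <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing <- setdiff(base_cols, names(sheet))
  if (length(missing)) stop("unknown term column(s): ",
                            paste(missing, collapse = ", "))
  for (cl in base_cols) {
    if (is.character(sheet[[cl]]) || is.logical(sheet[[cl]])) {
      sheet[[cl]] <- factor(sheet[[cl]])
    }
    if (is.factor(sheet[[cl]]) && nlevels(droplevels(sheet[[cl]])) < 2) {
      stop("term '", cl, "' has a single level")
    }
  }
  if (is.null(permutations) && n_perm < 99) {
    warning("fewer than 99 permutations gives a very coarse p-value")
  }

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # cumulative hat matrices H_0 (intercept) .. H_K
  X <- matrix(1, n, 1)
  hats <- list(tcrossprod(X) / n)
  ranks <- 1L
  for (k in seq_along(terms)) {
    Xk <- stats::model.matrix(stats::reformulate(terms[seq_len(k)]),
                              data = sheet)
    qrk <- qr(Xk)
    Q <- qr.Q(qrk)[, seq_len(qrk$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
    ranks[k + 1] <- qrk$rank
  }
  df <- diff(ranks)
  if (any(df == 0)) {
    warning("term(s) fully aliased by earlier terms: ",
            paste(terms[df == 0], collapse = ", "))
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) stop("saturated model: no residual degrees of freedom")

  K <- length(terms)
  # rows of A are vec(H_k); traces for any permuted G come from A %*% vec(Gp)
  A <- do.call(rbind, lapply(hats, as.vector))
  tr <- drop(A %*% as.vector(G))
  ss <- diff(tr)
  ss_res <- ss_total - tr[K + 1]
  Fobs <- (ss / df) / (ss_res / df_res)

  if (is.null(permutations)) {
    if (!is.null(seed)) set.seed(seed)
    idx <- seq_len(n)
    if (!is.null(strata)) {
      s <- as.character(sheet[[strata]])
      permutations <- t(vapply(seq_len(n_perm), function(...) {
        pm <- idx
        for (lv in unique(s)) pm[s == lv] <- sample(idx[s == lv])
        pm
      }, integer(n)))
    } else {
      permutations <- t(vapply(seq_len(n_perm), function(...) sample(idx),
                               integer(n)))
    }
    exact <- FALSE
  } else {
    permutations <- as.matrix(permutations)
    stopifnot(ncol(permutations) == n)
    exact <- TRUE
  }

  count <- numeric(K)
  chunk <- max(1L, floor(2e7 / (n * n)))
  nperm_eff <- nrow(permutations)
  for (start in seq(1, nperm_eff, by = chunk)) {
    rows <- start:min(start + chunk - 1, nperm_eff)
    Gv <- vapply(rows, function(r) {
      pm <- permutations[r, ]
      as.vector(G[pm, pm])
    }, numeric(n * n))
    trp <- A %*% Gv                       # (K+1) x chunk of traces
    ssp <- trp[-1, , drop = FALSE] - trp[-nrow(trp), , drop = FALSE]
    ssres_p <- ss_total - trp[nrow(trp), ]
    Fp <- sweep(ssp, 1, df, "/") /
      matrix(rep(ssres_p / df_res, each = K), nrow = K)
    count <- count + rowSums(Fp >= Fobs - 1e-12)
  }
  p <- if (exact) count / nperm_eff else (count + 1) / (nperm_eff + 1)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    sum_of_squares = c(ss, ss_res, ss_total),
    r_squared = c(ss, ss_res, ss_total) / ss_total,
    pseudo_F = c(Fobs, NA, NA),
    p_value = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n_permutations = nperm_eff, exact = exact,
                 n = n, terms = terms),
            class = "permanova")
}

gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d %spermutations)\n",
              x$n_permutations, if (x$exact) "enumerated " else ""))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Rank (Spearman, default) or Pearson correlation of the lower-triangle
#' entries, significance by simultaneous row/column permutation of the
#' second matrix. Delegates to [vegan::mantel()].
#'
#' @param D1,D2 Square distance matrices over the same samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Permutations (default 9999).
#' @param seed Integer seed.
#' @return A list with `rho`, `p_value`, `method`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, method = c("spearman", "pearson"),
                        n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  if (inherits(D1, "dist")) D1 <- as.matrix(D1)
  if (inherits(D2, "dist")) D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2))) {
      stop("distance matrices cover different sample sets")
    }
    D2 <- D2[rownames(D1), rownames(D1)]
  }
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                       method = method, permutations = n_perm)
  list(rho = unname(res$statistic), p_value = res$signif,
       method = method, n_perm = n_perm)
}

#' Classical rank tests used throughout the analysis
#'
#' Thin, uniform wrappers over [stats::wilcox.test()] (paired and
#' unpaired) and [stats::cor.test()] (Kendall tau-b).
#'
#' @param x,y Numeric vectors (equal length for paired/kendall kinds).
#' @param kind One of `"wilcoxon_paired"`, `"wilcoxon_unpaired"`,
#'   `"kendall"`.
#' @param ... Passed to the underlying test (e.g. `alternative`).
#' @return A list with `statistic` and `p_value` (plus `estimate` for
#'   Kendall).
#' @export
rank_tests <- function(x, y, kind = c("wilcoxon_paired", "wilcoxon_unpaired",
                                      "kendall"), ...) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  if (kind == "wilcoxon_paired") {
    stopifnot(length(x) == length(y))
    if (all(x == y)) {
      return(list(statistic = NA_real_, p_value = 1,
                  note = "all paired differences zero"))
    }
    ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, ...)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else if (kind == "wilcoxon_unpaired") {
    ht <- stats::wilcox.test(x, y, exact = FALSE, ...)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    stopifnot(length(x) == length(y))
    ht <- stats::cor.test(x, y, method = "kendall", exact = FALSE, ...)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         estimate = unname(ht$estimate))
  }
}
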