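#' Per-sample alpha diversity
#'
#' Observed richness (taxa with count > 0) and the inverse Simpson index
#' (1 / sum p_i^2 on within-sample proportions, via [vegan::diversity()]).
#' Both are meant to be computed on the rarefied table; unequal column
#' sums indicate unrarefied input and trigger a warning unless
#' `force = TRUE` suppresses the check.
#'
#' @param t A count table (rarefied).
#' @param force Skip the equal-depth check.
#' @return A data.frame with `sample_id`, `richness`, `inverse_simpson`.
#' @export
alpha_diversity <- function(t, force = FALSE) {
  m <- ct_matrix(t)
  depths <- colSums(m)
  if (!force && length(unique(depths)) > 1) {
    warning("unequal sample depths: alpha diversity expects rarefied input")
  }
  if (any(depths == 0)) stop("all-zero sample(s): ",
                             paste(colnames(m)[depths == 0], collapse = ", "))
  data.frame(sample_id = colnames(m),
             richness = richness(m),
             inverse_simpson = inverse_simpson(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname alpha_diversity
#' @details `richness()` and `inverse_simpson()` also accept a single
#'   count vector.
#' @export
richness <- function(t) {
  if (is.matrix(t)) return(colSums(ct_matrix(t) > 0))
  sum(t > 0)
}

#' @rdname alpha_diversity
#' @export
inverse_simpson <- function(t) {
  if (is.matrix(t)) {
    m <- ct_matrix(t)
    if (any(colSums(m) == 0)) stop("all-zero sample in inverse_simpson()")
    return(unname(vegan::diversity(t(m), index = "invsimpson")))
  }
  if (sum(t) == 0) stop("inverse_simpson() needs at least one positive count")
  unname(vegan::diversity(t, index = "invsimpson"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i) on within-sample relative
#' abundances (equal to half the L1 distance for normalized columns).
#' Computed with [vegan::vegdist()].
#'
#' @param comp A composition table from [to_relative_abundance()] (or any
#'   taxa x samples matrix of relative abundances).
#' @return A symmetric sample x sample matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(comp) {
  m <- unclass(comp)
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("columns must be normalized relative abundances (use ",
         "to_relative_abundance())")
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  d
}

#' Great-circle distance matrix between samples or plants
#'
#' Haversine distances in meters with Earth radius 6,371,000 m. With
#' `collapse = "per_individual"` duplicate sample coordinates are averaged
#' per plant individual and the matrix is between plants.
#'
#' @param sheet A sample sheet with `latitude`/`longitude`.
#' @param collapse `"per_sample"` or `"per_individual"`.
#' @return A symmetric distance matrix (meters).
#' @export
geo_distance_matrix <- function(sheet,
                                collapse = c("per_sample", "per_individual")) {
  collapse <- match.arg(collapse)
  sheet <- read_sample_sheet(sheet)
  if (!all(c("latitude", "longitude") %in% names(sheet))) {
    stop("sample sheet has no coordinates")
  }
  bad <- is.na(sheet$latitude) | is.na(sheet$longitude)
  if (any(bad)) {
    stop("missing coordinates for: ",
         paste(sheet$sample_id[bad], collapse = ", "))
  }
  if (collapse == "per_individual") {
    lat <- tapply(sheet$latitude, sheet$plant_individual, mean)
    lon <- tapply(sheet$longitude, sheet$plant_individual, mean)
    ids <- names(lat)
    pts <- cbind(as.numeric(lon), as.numeric(lat))
  } else {
    ids <- sheet$sample_id
    pts <- cbind(sheet$longitude, sheet$latitude)
  }
  n <- nrow(pts)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000)
  }
  d <- (d + t(d)) / 2  # enforce exact symmetry
  diag(d) <- 0
  d
}

#' Collapse a sample-level distance matrix by group
#'
#' Averages all between-group entries, giving a group-level matrix (used
#' to compare community dissimilarity between plants with their
#' geographic distance).
#'
#' @param d A square distance matrix with sample ids as dimnames.
#' @param groups A named vector (names = sample ids) or a vector aligned
#'   with `rownames(d)` giving each sample's group.
#' @return A group x group matrix of mean between-group distances, zero
#'   diagonal.
#' @export
collapse_distance <- function(d, groups) {
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  g <- sort(unique(as.character(groups)))
  out <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (i < j) {
        block <- d[groups == g[i], groups == g[j], drop = FALSE]
        out[i, j] <- out[j, i] <- mean(block)
      }
    }
  }
  out
}

#' Write / read a square distance matrix as TSV
#'
#' mothur/QIIME-compatible square dialect: header row of sample ids,
#' first column sample ids.
#'
#' @param d A square distance matrix.
#' @param path File path.
#' @export
write_distance_matrix <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("", colnames(d)), collapse = "\t"), con)
  writeLines(paste(rownames(d),
                   apply(d, 1, function(r) paste(format(r, digits = 10,
                                                        trim = TRUE),
                                                 collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
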