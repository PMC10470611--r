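#' Derive a stream of stage seeds from a master seed
#'
#' Hierarchical seeding: every stochastic stage of a simulation or
#' pipeline run draws its own seed from this stream so stages are
#' reproducible independently of one another.
#'
#' @param master Master integer seed.
#' @param n Number of seeds to draw.
#' @return An integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Describe a two-leaf-side phyllosphere study design
#'
#' Bundles every knob of the synthetic community generator. The defaults
#' encode the study frame the analysis targets: 24 host plant species,
#' three individuals each, both leaf sides swabbed (144 samples before
#' any dropout), about 14,000 reads per sample before rarefaction, a
#' lower leaf surface that receives fewer immigrants (smaller migration
#' parameter m) but stronger species-specific host filtering, and a lower
#' surface 0.21 pH units more acidic than the upper.
#'
#' Host filtering is expressed as multiplicative boosts on the shared
#' metacommunity: a small set of plant-associated taxa boosted on every
#' species' lower surface (these seed the cross-species core), a random
#' species-specific set boosted only on that host's lower surface, and a
#' couple of strictly endemic taxa per species (vanishingly rare in the
#' source pool, strongly boosted on their host's lower side, excluded
#' everywhere else). Setting `filter_strength_lower = 0` switches all
#' filtering off; equal `m_upper`/`m_lower` plus no filtering is the null
#' design in which the two sides are statistically exchangeable.
#'
#' @param n_species Number of host plant species.
#' @param n_individuals Individual plants per species.
#' @param n_taxa Metacommunity richness S.
#' @param sigma_log Lognormal shape of the metacommunity rank-abundance
#'   distribution.
#' @param reads_per_sample Sequencing depth N per sample (pre-rarefaction).
#' @param m_upper,m_lower Migration parameter per leaf side, in (0, 1].
#' @param filter_strength_upper,filter_strength_lower Multiplicative
#'   boost applied to filtered taxa on each side; 0 disables filtering on
#'   that side. Must satisfy `lower >= upper >= 0`.
#' @param frac_boosted Fraction of taxa boosted per species (species-
#'   specific host filtering).
#' @param n_plant_associated Number of shared plant-associated taxa
#'   boosted on all lower surfaces.
#' @param n_endemic_per_species Strictly endemic taxa per species.
#' @param endemic_p_scale Factor shrinking endemic taxa's source-pool
#'   abundance (they are effectively absent without their host's boost).
#' @param endemic_boost Boost endemic taxa receive on their host's
#'   filtered side.
#' @param ph_offset Mean pH difference upper minus lower (pH units).
#' @param ph_upper_mean,ph_noise_sd Mean upper-surface pH and leaf-level
#'   Gaussian noise sd.
#' @param ph_range Observed pH range to clip to, or NULL for no clipping.
#' @param dropout_rate Probability a sample is lost (the field study kept
#'   132 of 144).
#' @param seed Master seed for the whole simulated study.
#' @return A list of class `"study_design"`.
#' @export
study_design <- function(n_species = 24,
                         n_individuals = 3,
                         n_taxa = 500,
                         sigma_log = 1.2,
                         reads_per_sample = 14000,
                         m_upper = 0.15,
                         m_lower = 0.05,
                         filter_strength_upper = 3,
                         filter_strength_lower = 10,
                         frac_boosted = 0.05,
                         n_plant_associated = 20,
                         n_endemic_per_species = 2,
                         endemic_p_scale = 1e-2,
                         endemic_boost = 3000,
                         ph_offset = 0.21,
                         ph_upper_mean = 6.35,
                         ph_noise_sd = 0.15,
                         ph_range = c(4.89, 7.16),
                         dropout_rate = 0,
                         seed = 1L) {
  stopifnot(n_species >= 2, n_individuals >= 1,
            m_upper > 0, m_upper <= 1, m_lower > 0, m_lower <= 1,
            filter_strength_lower >= filter_strength_upper,
            filter_strength_upper >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  design <- list(n_species = n_species, n_individuals = n_individuals,
                 n_taxa = n_taxa, sigma_log = sigma_log,
                 reads_per_sample = reads_per_sample,
                 m_upper = m_upper, m_lower = m_lower,
                 filter_strength_upper = filter_strength_upper,
                 filter_strength_lower = filter_strength_lower,
                 frac_boosted = frac_boosted,
                 n_plant_associated = n_plant_associated,
                 n_endemic_per_species = n_endemic_per_species,
                 endemic_p_scale = endemic_p_scale,
                 endemic_boost = endemic_boost,
                 ph_offset = ph_offset, ph_upper_mean = ph_upper_mean,
                 ph_noise_sd = ph_noise_sd, ph_range = ph_range,
                 dropout_rate = dropout_rate, seed = as.integer(seed))
  class(design) <- "study_design"
  design
}

#' Draw a lognormal metacommunity
#'
#' Source-pool relative abundances p are i.i.d. lognormal(0, sigma_log^2),
#' normalized to sum to one. `sigma_log = 0` gives the perfectly even pool
#' p_i = 1/S.
#'
#' @param S Number of taxa (>= 2).
#' @param sigma_log Lognormal shape parameter (>= 0).
#' @param seed Integer seed.
#' @return A list with `taxon_ids`, `p` (named, sums to 1) and
#'   `sigma_log`.
#' @export
build_metacommunity <- function(S, sigma_log, seed) {
  stopifnot(S >= 2, sigma_log >= 0)
  set.seed(seed)
  raw <- stats::rlnorm(S, meanlog = 0, sdlog = sigma_log)
  p <- raw / sum(raw)
  ids <- sprintf("asv%04d", seq_len(S))
  names(p) <- ids
  list(taxon_ids = ids, p = p, sigma_log = sigma_log)
}

#' Construct per-species host-filter profiles
#'
#' See [study_design()] for the filtering structure. Returns one profile
#' per species: a named boost vector over all taxa (1 = neutral,
#' 0 = excluded) plus the species' endemic taxa.
#'
#' @param meta A metacommunity from [build_metacommunity()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A list with `profiles` (per-species list of `boost` and
#'   `endemic_set`), `plant_associated` ids, and `endemic` ids per
#'   species.
#' @export
host_filter_profiles <- function(meta, design, seed) {
  set.seed(seed)
  S <- length(meta$p)
  ids <- meta$taxon_ids
  strength <- design$filter_strength_lower
  if (strength == 0) {
    profiles <- stats::setNames(vector("list", design$n_species),
                                sprintf("sp%02d", seq_len(design$n_species)))
    return(list(profiles = profiles, plant_associated = character(0),
                endemic = lapply(profiles, function(x) character(0))))
  }
  # shared plant-associated taxa: moderately common source-pool members
  ord <- order(meta$p, decreasing = TRUE)
  window <- ord[seq(21, min(120, S))]
  plant_assoc <- ids[sample(window, min(design$n_plant_associated,
                                        length(window)))]
  pool <- setdiff(ids, plant_assoc)
  n_end <- design$n_endemic_per_species * design$n_species
  # endemics come from the rare tail of the pool so that, once scaled by
  # endemic_p_scale, they are effectively undetectable off their host
  rare_pool <- intersect(pool, ids[meta$p <= stats::median(meta$p)])
  endemic_all <- if (n_end > 0) sample(rare_pool,
                                       min(n_end, length(rare_pool)))
                 else character(0)
  endemic_by_sp <- split(endemic_all,
                         rep(seq_len(design$n_species),
                             length.out = length(endemic_all)))
  pool <- setdiff(pool, endemic_all)
  n_boost <- ceiling(design$frac_boosted * S)
  species <- sprintf("sp%02d", seq_len(design$n_species))
  profiles <- vector("list", design$n_species)
  names(profiles) <- species
  for (s in seq_len(design$n_species)) {
    boost <- stats::setNames(rep(1, S), ids)
    boost[plant_assoc] <- strength
    boost[sample(pool, min(n_boost, length(pool)))] <- strength
    boost[endemic_all] <- 0            # excluded everywhere ...
    own <- endemic_by_sp[[as.character(s)]]
    if (!is.null(own)) boost[own] <- design$endemic_boost  # ... except home
    profiles[[s]] <- list(species = species[s], boost = boost,
                          endemic_set = own %||% character(0))
  }
  list(profiles = profiles, plant_associated = plant_assoc,
       endemic = lapply(profiles, `[[`, "endemic_set"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one sample under the neutral kernel with optional filtering
#'
#' The generative dual of the Sloan occupancy-abundance model: the
#' effective source pool is `q = normalize(p * boost)` (q = p with no
#' profile); each taxon's latent local relative abundance is drawn
#' independently as Beta(N m q_i, N m (1 - q_i)), the latent vector is
#' renormalized, and reads are drawn multinomially. Taxa with
#' `N m q_i = 0` are deterministically absent.
#'
#' @param meta Metacommunity (or any list with a `p` vector).
#' @param profile A host-filter profile (list with `boost`) or NULL for
#'   pure neutral assembly.
#' @param m Migration parameter in (0, 1].
#' @param N_reads Reads to draw.
#' @param seed Optional integer seed.
#' @return A named integer count vector over taxa.
#' @export
simulate_sample <- function(meta, profile = NULL, m, N_reads, seed = NULL) {
  stopifnot(m > 0, m <= 1, N_reads >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- meta$p
  q <- if (is.null(profile)) p else p * profile$boost[names(p)]
  q <- q / sum(q)
  a <- N_reads * m * q
  b <- N_reads * m * (1 - q)
  x <- numeric(length(q))
  pos <- a > 0
  x[pos] <- stats::rbeta(sum(pos), a[pos], b[pos])
  x[!is.finite(x)] <- 0
  if (sum(x) == 0) x[which.max(q)] <- 1  # pathological draw; keep sample valid
  x <- x / sum(x)
  counts <- stats::rmultinom(1, N_reads, x)[, 1]
  names(counts) <- names(p)
  counts
}

#' Simulate a full two-leaf-side study
#'
#' One sample per (species, individual, leaf side). Upper surfaces use
#' `m_upper` and the upper filter strength (none by default); lower
#' surfaces use `m_lower` and the species' host-filter profile. Covariates
#' (pH with its per-side offset, stomatal density concentrated on the
#' lower surface, jittered coordinates inside a ~0.14 km^2 garden,
#' hardness, pubescence, leaf area) are drawn per plant.
#'
#' @param design A [study_design()].
#' @return A list with `table` (count table), `sheet` (sample metadata)
#'   and `truth` (ground-truth record: design, metacommunity, profiles,
#'   per-sample expected source compositions and side parameters).
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  seeds <- seed_stream(design$seed, 6 +
                       design$n_species * design$n_individuals * 2)
  meta <- build_metacommunity(design$n_taxa, design$sigma_log, seeds[1])
  # endemic taxa are scaled down in the source pool before profiles are
  # drawn, so they are effectively invisible unless boosted by their host
  filt <- host_filter_profiles(meta, design, seeds[2])
  endemic_all <- unlist(filt$endemic, use.names = FALSE)
  if (length(endemic_all)) {
    meta$p[endemic_all] <- meta$p[endemic_all] * design$endemic_p_scale
    meta$p <- meta$p / sum(meta$p)
  }
  species <- sprintf("sp%02d", seq_len(design$n_species))
  set.seed(seeds[3])
  # per-plant covariates
  plants <- expand.grid(individual = seq_len(design$n_individuals),
                        species = species, stringsAsFactors = FALSE)
  plants$plant_id <- sprintf("%s_i%d", plants$species, plants$individual)
  n_pl <- nrow(plants)
  # ~0.14 km^2 frame centred on a botanical-garden-like coordinate
  lat0 <- 37.875; lon0 <- -122.2375
  plants$latitude <- lat0 + stats::runif(n_pl, -0.00168, 0.00168)
  plants$longitude <- lon0 + stats::runif(n_pl, -0.00213, 0.00213)
  plants$leaf_area <- stats::runif(n_pl, 94, 276)
  hard <- stats::setNames(sample(0:3, design$n_species, replace = TRUE),
                          species)
  pub <- stats::setNames(stats::runif(design$n_species) < 0.3, species)
  ph_up <- stats::rnorm(n_pl, design$ph_upper_mean, 0.35)
  ph_lo <- ph_up - design$ph_offset + stats::rnorm(n_pl, 0, design$ph_noise_sd)
  if (!is.null(design$ph_range)) {
    ph_up <- pmin(pmax(ph_up, design$ph_range[1]), design$ph_range[2])
    ph_lo <- pmin(pmax(ph_lo, design$ph_range[1]), design$ph_range[2])
  }
  stom_up <- stats::runif(n_pl, 0, 5)
  stom_lo <- stats::rlnorm(n_pl, log(150), 0.3)

  sides <- c("upper", "lower")
  n_samp <- n_pl * 2
  counts <- matrix(0L, nrow = design$n_taxa, ncol = n_samp,
                   dimnames = list(meta$taxon_ids, rep("", n_samp)))
  rows <- vector("list", n_samp)
  q_expect <- matrix(NA_real_, nrow = design$n_taxa, ncol = n_samp)
  samp_seeds <- seeds[-(1:6)]
  k <- 0
  for (i in seq_len(n_pl)) {
    for (side in sides) {
      k <- k + 1
      sp <- plants$species[i]
      sid <- sprintf("%s_%s", plants$plant_id[i], substr(side, 1, 2))
      m_side <- if (side == "upper") design$m_upper else design$m_lower
      prof <- NULL
      if (side == "lower" && design$filter_strength_lower > 0) {
        prof <- filt$profiles[[sp]]
      } else if (side == "upper" && design$filter_strength_upper > 0) {
        prof <- filt$profiles[[sp]]
        fu <- design$filter_strength_upper
        b <- prof$boost
        b[b > 1] <- b[b > 1] * fu / design$filter_strength_lower
        prof$boost <- b
      }
      counts[, k] <- simulate_sample(meta, prof, m_side,
                                     design$reads_per_sample,
                                     seed = samp_seeds[k])
      q <- if (is.null(prof)) meta$p else meta$p * prof$boost[meta$taxon_ids]
      q_expect[, k] <- q / sum(q)
      rows[[k]] <- data.frame(
        sample_id = sid, plant_species = sp,
        plant_individual = plants$plant_id[i], leaf_side = side,
        ph = if (side == "upper") ph_up[i] else ph_lo[i],
        stomatal_density = if (side == "upper") stom_up[i] else stom_lo[i],
        leaf_hardness = hard[[sp]], pubescence = pub[[sp]],
        latitude = plants$latitude[i], longitude = plants$longitude[i],
        leaf_area = plants$leaf_area[i], stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, rows)
  colnames(counts) <- sheet$sample_id
  dimnames(q_expect) <- list(meta$taxon_ids, sheet$sample_id)
  if (design$dropout_rate > 0) {
    set.seed(seeds[4])
    keep <- stats::runif(n_samp) >= design$dropout_rate
    counts <- counts[, keep, drop = FALSE]
    sheet <- sheet[keep, , drop = FALSE]
    q_expect <- q_expect[, keep, drop = FALSE]
  }
  truth <- list(design = design, metacommunity = meta,
                profiles = filt$profiles,
                plant_associated = filt$plant_associated,
                endemic = filt$endemic,
                expected_composition = q_expect,
                side_m = c(upper = design$m_upper, lower = design$m_lower))
  list(table = as_count_table(counts),
       sheet = read_sample_sheet(sheet),
       truth = truth)
}

#' Serialize a ground-truth record as JSON
#'
#' Writes the design, the metacommunity, filter-set membership and side
#' parameters. The full expected-composition matrix is included only when
#' `include_expected = TRUE` (it is bulky and recomputable from the rest).
#'
#' @param truth The `truth` element of [simulate_study()]'s result.
#' @param path Output path.
#' @param include_expected Include the expected composition matrix.
#' @export
write_truth_json <- function(truth, path, include_expected = FALSE) {
  out <- list(
    design = unclass(truth$design),
    metacommunity = list(taxon_ids = truth$metacommunity$taxon_ids,
                         p = unname(truth$metacommunity$p),
                         sigma_log = truth$metacommunity$sigma_log),
    plant_associated = truth$plant_associated,
    endemic = truth$endemic,
    boosted = lapply(truth$profiles, function(pr) {
      if (is.null(pr)) return(character(0))
      names(pr$boost)[pr$boost > 1]
    }),
    side_m = as.list(truth$side_m))
  if (include_expected) out$expected_composition <- truth$expected_composition
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
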