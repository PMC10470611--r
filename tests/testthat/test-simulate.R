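test_that("metacommunity draws are normalized, shaped, and deterministic", {
  even <- build_metacommunity(10, 0, seed = 1)
  expect_equal(unname(even$p), rep(0.1, 10))
  m1 <- build_metacommunity(200, 2, seed = 5)
  m2 <- build_metacommunity(200, 2, seed = 5)
  expect_identical(m1$p, m2$p)
  expect_equal(sum(m1$p), 1, tolerance = 1e-12)
  big <- build_metacommunity(500, 2, seed = 9)
  expect_gte(log10(max(big$p) / min(big$p)), 3)  # >= 3 orders of magnitude
})

test_that("neutral sampling kernel matches its Beta mean and variance
           ordering", {
  meta <- build_metacommunity(50, 1, seed = 2)
  # m = 1, large N: per-taxon mean relabund approaches p
  reps <- vapply(1:200, function(s)
    simulate_sample(meta, NULL, m = 1, N_reads = 20000, seed = s) / 20000,
    numeric(50))
  mc_mean <- rowMeans(reps)
  mc_se <- apply(reps, 1, sd) / sqrt(200)
  z <- abs(mc_mean - meta$p) / (mc_se + 1e-12)
  # 50 simultaneous 3-sigma checks: allow the expected handful of grazes
  expect_gte(mean(z <= 3), 0.9)
  expect_true(all(z <= 4.5))

  # smaller m inflates across-sample variance at equal source composition
  v_small <- apply(vapply(1:500, function(s)
    simulate_sample(meta, NULL, 0.01, 2000, seed = 1000 + s) / 2000,
    numeric(50)), 1, var)
  v_large <- apply(vapply(1:500, function(s)
    simulate_sample(meta, NULL, 0.5, 2000, seed = 2000 + s) / 2000,
    numeric(50)), 1, var)
  expect_gt(mean(v_small / (v_large + 1e-12) > 1), 0.9)
})

test_that("zero-boost taxa never appear", {
  meta <- build_metacommunity(20, 1, seed = 3)
  profile <- list(boost = stats::setNames(rep(1, 20), meta$taxon_ids))
  profile$boost[5] <- 0
  draws <- vapply(1:50, function(s)
    simulate_sample(meta, profile, 0.3, 5000, seed = s), numeric(20))
  expect_true(all(draws[5, ] == 0))
})

test_that("simulated study has the full design frame and covariate
           structure", {
  sim <- default_sim()
  d <- sim$truth$design
  expect_equal(ncol(sim$table), d$n_species * d$n_individuals * 2)
  expect_equal(nrow(sim$sheet), ncol(sim$table))
  expect_setequal(unique(sim$sheet$leaf_side), c("upper", "lower"))
  expect_true(all(sim$sheet$ph >= 4.89 & sim$sheet$ph <= 7.16))
  up <- sim$sheet$leaf_side == "upper"
  # lower surfaces more acidic by roughly the designed offset
  ph_by_plant <- split(sim$sheet, sim$sheet$plant_individual)
  offs <- vapply(ph_by_plant, function(x)
    x$ph[x$leaf_side == "upper"] - x$ph[x$leaf_side == "lower"], numeric(1))
  expect_equal(mean(offs), d$ph_offset, tolerance = 0.06)
  # stomata essentially absent on upper surfaces
  expect_lt(max(sim$sheet$stomatal_density[up]), 10)
  expect_gt(min(sim$sheet$stomatal_density[!up]), 10)
  # coordinates inside a ~0.14 km^2 frame
  expect_lt(diff(range(sim$sheet$latitude)) * 111195, 400)
})

test_that("study simulation is fully deterministic under its master seed", {
  s1 <- simulate_study(study_design(n_species = 4, n_individuals = 2,
                                    n_taxa = 60, seed = 77))
  s2 <- simulate_study(study_design(n_species = 4, n_individuals = 2,
                                    n_taxa = 60, seed = 77))
  expect_identical(unclass(s1$table), unclass(s2$table))
  expect_identical(s1$sheet, s2$sheet)
  s3 <- simulate_study(study_design(n_species = 4, n_individuals = 2,
                                    n_taxa = 60, seed = 78))
  expect_false(identical(unclass(s1$table), unclass(s3$table)))
})

test_that("planted endemic taxa recover a near-maximal endemism degree", {
  sim <- default_sim()
  filtered <- filter_low_counts(sim$table, 2)
  e <- endemism_degrees(filtered, sim$sheet)
  endemic <- intersect(unlist(sim$truth$endemic), names(e$e))
  expect_gt(length(endemic), 20)
  n_sp <- sim$truth$design$n_species
  # drift occasionally lands a stray off-host detection; degrees stay
  # near the (S-1)/S maximum
  expect_gte(mean(e$e[endemic]), (n_sp - 2) / n_sp)
  expect_true(all(e$e[endemic] >= 0.8))
})

test_that("migration recovery from the generative dual is within 20%", {
  meta <- build_metacommunity(300, 2, seed = 11)
  m_true <- 0.1
  counts <- vapply(1:100, function(s)
    simulate_sample(meta, NULL, m_true, 4000, seed = 5000 + s),
    numeric(300))
  dimnames(counts) <- list(meta$taxon_ids, sprintf("s%03d", 1:100))
  fit <- fit_neutral(occupancy_abundance(as_count_table(counts)), N = 4000)
  expect_lt(abs(fit$m - m_true) / m_true, 0.2)
})
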