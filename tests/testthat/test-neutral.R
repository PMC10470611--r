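test_that("occupancy-abundance profiles are exact on small tables", {
  t <- as_count_table(matrix(c(10L, 0L, 5L, 5L), 2, byrow = TRUE,
                             dimnames = list(c("patchy", "even"),
                                             c("s1", "s2"))))
  prof <- occupancy_abundance(t)
  expect_equal(prof$p[prof$taxon_id == "patchy"], mean(c(10 / 15, 0)))
  expect_equal(prof$occupancy[prof$taxon_id == "patchy"], 0.5)
  expect_equal(prof$occupancy[prof$taxon_id == "even"], 1)
  # occupancy invariant under per-sample rescaling
  t2 <- as_count_table(matrix(c(20L, 0L, 10L, 5L), 2, byrow = TRUE,
                              dimnames = list(c("patchy", "even"),
                                              c("s1", "s2"))))
  expect_equal(occupancy_abundance(t2)$occupancy, prof$occupancy)
  expect_error(occupancy_abundance(as_count_table(
    matrix(1L, 1, 1, dimnames = list("a", "s")))), "two samples")
})

test_that("predicted occupancy has the right limits, closed form and
           monotonicity", {
  expect_equal(predict_occupancy(0, 0.1, 1000, 0.001), 0)
  expect_equal(predict_occupancy(1, 0.1, 1000, 0.001), 1)
  expect_lt(predict_occupancy(1e-9, 0.1, 1000, 0.001), 1e-4)
  # alpha = N m p = 1: survival of Beta(1, beta) is (1 - d)^beta
  expect_equal(predict_occupancy(0.01, 0.1, 1000, 0.001),
               (1 - 0.001)^99, tolerance = 1e-9)
  grid <- seq(1e-4, 0.5, length.out = 40)
  occ <- predict_occupancy(grid, 0.05, 4000, 1 / 4000)
  expect_true(all(diff(occ) >= -1e-12))
})

test_that("predicted occupancy agrees with a Monte-Carlo Beta oracle", {
  set.seed(21)
  for (p in c(0.001, 0.01, 0.1)) {
    for (m in c(0.02, 0.2)) {
      draws <- rbeta(2e4, 4000 * m * p, 4000 * m * (1 - p))
      d <- log(2) / 4000
      mc <- mean(draws > d)
      se <- sqrt(mc * (1 - mc) / 2e4)
      expect_equal(predict_occupancy(p, m, 4000, d), mc,
                   tolerance = max(3 * se, 1e-4) / max(mc, 1e-4))
    }
  }
})

test_that("self-consistent occupancies are refit exactly with R^2 = 1", {
  set.seed(8)
  p <- sort(runif(80, 1e-4, 0.2))
  N <- 4000
  profiles <- data.frame(taxon_id = sprintf("t%02d", seq_along(p)), p = p,
                         occupancy = predict_occupancy(p, 0.2, N,
                                                       log(2) / N),
                         n_samples = 100)
  fit <- fit_neutral(profiles, N = N)
  expect_equal(fit$m, 0.2, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  # fit is deterministic and invariant to taxon order
  fit2 <- fit_neutral(profiles[sample(nrow(profiles)), ], N = N)
  expect_equal(fit2$m, fit$m, tolerance = 1e-10)
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-10)
})

test_that("occupancies shuffled against abundance give R^2 near or below
           zero", {
  set.seed(13)
  meta <- build_metacommunity(200, 2, seed = 31)
  counts <- vapply(1:60, function(s)
    simulate_sample(meta, NULL, 0.1, 4000, seed = 900 + s), numeric(200))
  dimnames(counts) <- list(meta$taxon_ids, sprintf("s%02d", 1:60))
  prof <- occupancy_abundance(as_count_table(counts))
  prof <- prof[prof$occupancy > 0 & prof$p > 0, ]
  r2s <- vapply(1:10, function(i) {
    shuffled <- prof
    shuffled$occupancy <- sample(shuffled$occupancy)
    fit_neutral(shuffled, N = 4000)$r_squared
  }, numeric(1))
  expect_lt(mean(r2s), 0.15)
})

test_that("per-taxon envelopes bracket predictions and classes are
           assigned", {
  sim <- default_sim()
  r <- rarefy_table(filter_low_counts(sim$table), 4000, seed = 5)
  fit <- fit_neutral(occupancy_abundance(r), N = 4000)
  tx <- fit$taxa
  ok <- !is.na(tx$class)
  expect_true(all(tx$lower[ok] <= tx$predicted[ok] + 1e-12))
  expect_true(all(tx$upper[ok] >= tx$predicted[ok] - 1e-12))
  expect_setequal(setdiff(unique(tx$class), NA), c("above", "neutral",
                                                   "below"))
  expect_true(all(tx$predicted >= 0 & tx$predicted <= 1))
})

test_that("group fits split, pool, and validate group sizes", {
  sim <- default_sim()
  r <- rarefy_table(filter_low_counts(sim$table), 4000, seed = 6)
  fits <- suppressMessages(compare_group_fits(r, sim$sheet, "leaf_side"))
  expect_named(fits, c("lower", "upper", "pooled"))
  # identical group compositions give identical fits
  t <- random_table(60, 24, seed = 2, lambda = 100)
  sheet <- toy_sheet(colnames(t), "sp1",
                     sides = rep(c("upper", "lower"), each = 12),
                     individuals = paste0("sp1_i", rep(1:12, 2)))
  m <- unclass(t)
  m[, 13:24] <- m[, 1:12]  # lower duplicates upper
  dup <- as_count_table(m)
  fits2 <- suppressMessages(compare_group_fits(dup, sheet, "leaf_side"))
  expect_equal(fits2$upper$m, fits2$lower$m, tolerance = 1e-8)
  small_sheet <- sheet
  small_sheet$leaf_side <- c("upper", rep("lower", 23))
  expect_error(suppressMessages(compare_group_fits(dup, small_sheet,
                                                   "leaf_side")),
               "fewer than 10")
  expect_error(suppressMessages(compare_group_fits(dup, sheet, "nope")),
               "unknown column")
})

test_that("bootstrap R^2 contrast detects a planted fit-quality gap and
           stays calibrated under exchange", {
  rep_ <- default_report()
  rc <- rep_$neutral$r2_contrast
  expect_gt(rc$delta, 0)
  expect_lt(rc$p_value, 0.05)
  # same fit against itself: p should be well away from significance
  self <- compare_fit_r2(rep_$neutral$fits$upper, rep_$neutral$fits$upper,
                         n_boot = 499, seed = 3)
  expect_gt(self$p_value, 0.2)
})
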