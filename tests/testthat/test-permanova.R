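test_that("perfect group separation puts all variance on the group term", {
  ids <- sprintf("s%d", 1:4)
  D <- matrix(1, 4, 4, dimnames = list(ids, ids))
  D[1:2, 1:2] <- 0
  D[3:4, 3:4] <- 0
  diag(D) <- 0
  sheet <- toy_sheet(ids, "sp1", sides = rep(c("upper", "lower"), each = 2),
                     individuals = paste0("p", 1:4))
  res <- suppressWarnings(permanova(D, sheet, "leaf_side", n_perm = 199,
                                    seed = 1))
  tab <- res$table
  expect_equal(tab$r_squared[tab$term == "leaf_side"], 1, tolerance = 1e-9)
  expect_equal(tab$sum_of_squares[tab$term == "Residual"], 0,
               tolerance = 1e-9)
})

test_that("univariate Euclidean input reproduces classical ANOVA exactly", {
  set.seed(5)
  y <- rnorm(30)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  ids <- sprintf("s%02d", 1:30)
  sheet <- toy_sheet(ids, "sp1", sides = "upper",
                     individuals = paste0("p", 1:30))
  sheet$grp <- as.character(g)
  sheet$leaf_side <- rep(c("upper", "lower"), 15)
  D <- as.matrix(dist(y))
  dimnames(D) <- list(ids, ids)
  res <- permanova(D, sheet, "grp", n_perm = 99, seed = 2)
  aov_tab <- anova(lm(y ~ g))
  tab <- res$table
  expect_equal(tab$pseudo_F[1], aov_tab$`F value`[1], tolerance = 1e-9)
  expect_equal(tab$sum_of_squares[1], aov_tab$`Sum Sq`[1],
               tolerance = 1e-9)
  expect_equal(tab$sum_of_squares[tab$term == "Residual"],
               aov_tab$`Sum Sq`[2], tolerance = 1e-9)
})

test_that("enumerated permutations give the exact p-value at n = 4", {
  set.seed(7)
  x <- matrix(rnorm(8), 4)
  ids <- sprintf("s%d", 1:4)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(ids, ids)
  sheet <- toy_sheet(ids, "sp1", sides = c("upper", "upper", "lower",
                                           "lower"),
                     individuals = paste0("p", 1:4))
  perms <- all_perms(4)
  res <- permanova(D, sheet, "leaf_side", permutations = perms)
  # oracle: per-relabeling F from vegan::adonis2 (independent SS path)
  side <- sheet$leaf_side
  F_null <- apply(perms, 1, function(pm) {
    a2 <- suppressMessages(vegan::adonis2(
      as.dist(D) ~ g, data = data.frame(g = side[order(pm)]),
      permutations = 1))
    a2$F[1]
  })
  F_obs <- suppressMessages(vegan::adonis2(
    as.dist(D) ~ g, data = data.frame(g = side), permutations = 1))$F[1]
  p_exact <- mean(F_null >= F_obs - 1e-12)
  expect_equal(res$table$p_value[1], p_exact, tolerance = 1e-12)
  expect_equal(res$table$pseudo_F[1], F_obs, tolerance = 1e-9)
})

test_that("sequential SS, R2 and F agree with vegan::adonis2 by terms", {
  sim <- simulate_study(study_design(n_species = 4, n_individuals = 3,
                                     n_taxa = 80, seed = 33))
  r <- rarefy_table(filter_low_counts(sim$table), 4000, seed = 3)
  bc <- bray_curtis_matrix(to_relative_abundance(r))
  sheet <- sim$sheet[colnames(r), ]
  terms <- c("ph", "leaf_side", "plant_species", "leaf_side:plant_species")
  mine <- permanova(bc, sheet, terms, n_perm = 199, seed = 4)
  ref <- vegan::adonis2(as.dist(bc) ~ ph + leaf_side + plant_species +
                          leaf_side:plant_species,
                        data = sheet, permutations = 199, by = "terms")
  k <- length(terms)
  expect_equal(mine$table$sum_of_squares[1:k], ref$SumOfSqs[1:k],
               tolerance = 1e-8)
  expect_equal(mine$table$r_squared[1:k], ref$R2[1:k], tolerance = 1e-8)
  expect_equal(mine$table$pseudo_F[1:k], ref$F[1:k], tolerance = 1e-8)
  expect_equal(mine$table$df[1:k], ref$Df[1:k])
})

test_that("term reordering changes the split but never the total SS", {
  sim <- simulate_study(study_design(n_species = 3, n_individuals = 2,
                                     n_taxa = 50, seed = 44))
  r <- rarefy_table(filter_low_counts(sim$table), 4000, seed = 3)
  bc <- bray_curtis_matrix(to_relative_abundance(r))
  sheet <- sim$sheet[colnames(r), ]
  a <- permanova(bc, sheet, c("leaf_side", "plant_species"), n_perm = 99,
                 seed = 5)
  b <- permanova(bc, sheet, c("plant_species", "leaf_side"), n_perm = 99,
                 seed = 5)
  tot <- function(x) x$table$sum_of_squares[x$table$term == "Total"]
  expect_equal(tot(a), tot(b), tolerance = 1e-10)
  expect_equal(sum(a$table$sum_of_squares[1:3]), tot(a), tolerance = 1e-9)
  expect_equal(sum(a$table$r_squared[1:3]), 1, tolerance = 1e-9)
})

test_that("permutation p-values are seed-reproducible and conventions
           validated", {
  set.seed(9)
  x <- matrix(rnorm(40), 20)
  ids <- sprintf("s%02d", 1:20)
  D <- as.matrix(dist(x)); dimnames(D) <- list(ids, ids)
  sheet <- toy_sheet(ids, "sp1", sides = rep(c("upper", "lower"), 10),
                     individuals = paste0("p", 1:20))
  r1 <- permanova(D, sheet, "leaf_side", n_perm = 199, seed = 42)
  r2 <- permanova(D, sheet, "leaf_side", n_perm = 199, seed = 42)
  expect_identical(r1$table$p_value, r2$table$p_value)
  expect_gte(r1$table$p_value[1], 1 / 200)
  expect_warning(permanova(D, sheet, "leaf_side", n_perm = 49, seed = 1),
                 "99")
  sheet$constant <- "x"
  expect_error(permanova(D, sheet, "constant", n_perm = 99), "single level")
})

test_that("mantel test: identity, monotone invariance, and size checks", {
  set.seed(10)
  x <- matrix(rnorm(30), 15)
  D1 <- as.matrix(dist(x))
  ids <- sprintf("s%02d", 1:15)
  dimnames(D1) <- list(ids, ids)
  res <- mantel_test(D1, D1, n_perm = 99, seed = 1)
  expect_equal(res$rho, 1, tolerance = 1e-12)
  # monotone transform leaves the spearman statistic at 1
  res2 <- mantel_test(D1, sqrt(D1), n_perm = 99, seed = 1)
  expect_equal(res2$rho, 1, tolerance = 1e-12)
  expect_error(mantel_test(D1, D1[1:10, 1:10]), "size")
})

test_that("rank test wrappers match their classical limits", {
  k1 <- rank_tests(c(1, 2, 3), c(1, 2, 3), "kendall")
  expect_equal(k1$estimate, 1)
  k2 <- rank_tests(c(1, 2, 3), c(3, 2, 1), "kendall")
  expect_equal(k2$estimate, -1)
  w <- rank_tests(c(1.5, 2.5, 3.5), c(1.5, 2.5, 3.5), "wilcoxon_paired")
  expect_equal(w$p_value, 1)
  expect_error(rank_tests(c(1, NA), c(1, 2), "kendall"))
})
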