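test_that("low-count filter zeroes per-sample entries and drops empty taxa", {
  t <- as_count_table(matrix(c(3L, 1L, 2L, 5L), 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  out <- filter_low_counts(t, 2)
  expect_equal(unclass(out)[, "s1"], c(a = 3L, b = 0L))
  expect_equal(unclass(out)[, "s2"], c(a = 0L, b = 5L))
  expect_equal(attr(out, "filter_report")$entries_zeroed, 2)

  hi <- as_count_table(matrix(c(3L, 4L, 5L, 6L), 2,
                              dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(unclass(filter_low_counts(hi, 2)), unclass(hi),
               ignore_attr = TRUE)

  doomed <- as_count_table(matrix(c(1L, 2L, 9L, 9L), 2, byrow = TRUE,
                                  dimnames = list(c("gone", "kept"),
                                                  c("s1", "s2"))))
  out <- filter_low_counts(doomed, 2)
  expect_identical(rownames(out), "kept")
  expect_identical(attr(out, "filter_report")$taxa_dropped, "gone")
})

test_that("low-count filter is idempotent and max_anywhere mode differs", {
  t <- random_table(40, 8, seed = 5, lambda = 3)
  once <- filter_low_counts(t, 2)
  twice <- filter_low_counts(once, 2)
  strip <- function(x) {
    attr(x, "filter_report") <- NULL
    unclass(x)
  }
  expect_identical(strip(once), strip(twice))
  expect_equal(attr(twice, "filter_report")$entries_zeroed, 0)
  # a taxon with max count 2 survives per_entry if some count is > 2
  t2 <- as_count_table(matrix(c(2L, 3L, 2L, 2L), 2, byrow = TRUE,
                              dimnames = list(c("mixed", "low"),
                                              c("s1", "s2"))))
  per_entry <- filter_low_counts(t2, 2)
  expect_equal(unclass(per_entry)["mixed", ], c(s1 = 0L, s2 = 3L))
  expect_false("low" %in% rownames(per_entry))
  # max_anywhere keeps the whole row (including the 2) when any count > 2
  anywhere <- filter_low_counts(t2, 2, mode = "max_anywhere")
  expect_equal(unclass(anywhere)["mixed", ], c(s1 = 2L, s2 = 3L))
  expect_false("low" %in% rownames(anywhere))
})

test_that("total relative-abundance filter uses a strict less-than", {
  m <- matrix(c(1L, rep(0L, 3), 9999L, rep(0L, 3)), nrow = 2, byrow = TRUE,
              dimnames = list(c("rare", "common"), sprintf("s%d", 1:4)))
  t <- as_count_table(m)
  expect_false("rare" %in% rownames(filter_total_relabund(t, 0.001)))
  expect_equal(rownames(filter_total_relabund(t, 0)), c("rare", "common"))
  # exactly at the floor: 10 of 10000 = 0.1% is retained
  m2 <- matrix(c(10L, 9990L), ncol = 1,
               dimnames = list(c("edge", "bulk"), "s1"))
  expect_true("edge" %in% rownames(filter_total_relabund(
    as_count_table(m2), 0.001)))
  empty <- as_count_table(matrix(0L, 1, 1, dimnames = list("a", "s")))
  expect_error(filter_total_relabund(empty), "empty")
})

test_that("rarefaction hits the exact depth, drops shallow samples, and is
           seed-reproducible", {
  t <- random_table(30, 6, seed = 7, lambda = 300)
  r <- rarefy_table(t, depth = 4000, seed = 11)
  expect_true(all(colSums(unclass(r)) == 4000))
  expect_true(all(unclass(r) <= unclass(t)[, colnames(r)]))
  expect_identical(unclass(rarefy_table(t, 4000, seed = 11)), unclass(r))
  expect_false(identical(unclass(rarefy_table(t, 4000, seed = 12)),
                         unclass(r)))
  # sample exactly at depth passes through unchanged
  tot <- colSums(unclass(t))
  r2 <- rarefy_table(t, depth = min(tot), seed = 1)
  at_depth <- names(tot)[tot == min(tot)]
  expect_identical(unclass(r2)[, at_depth], unclass(t)[, at_depth])
  # shallow samples are dropped with a warning; all-shallow errors
  expect_warning(r3 <- rarefy_table(t, depth = max(tot), seed = 1),
                 "dropped")
  expect_false(any(names(tot)[tot < max(tot)] %in% colnames(r3)))
  expect_error(rarefy_table(t, depth = sum(tot) + 1, seed = 1), "fewer")
  expect_error(rarefy_table(t, 4000), "seed")
})

test_that("mean rarefied counts converge to depth x relative abundance", {
  counts <- c(a = 50L, b = 30L, c = 20L)
  t <- as_count_table(matrix(counts, ncol = 1,
                             dimnames = list(names(counts), "s1")))
  depth <- 20
  draws <- vapply(seq_len(1000),
                  function(s) unclass(rarefy_table(t, depth, seed = s))[, 1],
                  numeric(3))
  p <- counts / sum(counts)
  expected <- depth * p
  # hypergeometric variance with finite-population correction
  se <- sqrt(depth * p * (1 - p) * (100 - depth) / (100 - 1) / 1000)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se))
})

test_that("relative abundances normalize columns and flag zero samples", {
  t <- as_count_table(matrix(c(2L, 2L, 4L, 0L), 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))))
  comp <- to_relative_abundance(t)
  expect_equal(unclass(comp)[, "s1"], c(a = 0.5, b = 0.5))
  expect_equal(unclass(comp)[, "s2"], c(a = 1, b = 0))
  expect_equal(unname(colSums(unclass(comp))), c(1, 1))
  z <- as_count_table(matrix(c(1L, 0L), 1, 2,
                             dimnames = list("a", c("ok", "empty"))))
  expect_error(to_relative_abundance(z), "empty")
})
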