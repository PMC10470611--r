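# shared fixtures, all generated in code

tiny_table <- function() {
  as_count_table(matrix(c(3L, 1L, 0L, 2L), nrow = 2,
                        dimnames = list(c("asvA", "asvB"), c("s1", "s2"))))
}

random_table <- function(n_taxa, n_samples, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), nrow = n_taxa,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                              sprintf("s%03d", seq_len(n_samples))))
  # avoid all-zero rows/columns
  m[1, ] <- m[1, ] + 1L
  m[, colSums(m) == 0] <- 1L
  as_count_table(m)
}

# one shared default-design simulation + pipeline run, cached per session
.fixture_env <- new.env()

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_study(study_design(seed = 20260926))
  }
  .fixture_env$sim
}

default_report <- function() {
  if (is.null(.fixture_env$report)) {
    cfg <- pipeline_config(design = study_design(), seed = 20260926,
                           n_perm = 199)
    .fixture_env$report <- suppressMessages(suppressWarnings(
      run_pipeline(cfg)))
  }
  .fixture_env$report
}

# minimal metadata sheet for a table whose samples alternate sides
toy_sheet <- function(sample_ids, species, sides = NULL,
                      individuals = NULL) {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids,
    plant_species = rep_len(species, n),
    plant_individual = individuals %||%
      paste0(rep_len(species, n), "_i", rep_len(1:3, n)),
    leaf_side = sides %||% rep_len(c("upper", "lower"), n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
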