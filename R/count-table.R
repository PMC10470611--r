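#' Validate and construct an ASV-by-sample count table
#'
#' The package represents feature tables the way `vegan` does: a plain
#' numeric matrix, here with taxa as rows and samples as columns, carrying
#' taxon and sample identifiers as dimnames. `as_count_table()` checks the
#' contract every downstream operation relies on: integer counts >= 0,
#' unique identifiers on both margins, dimensions matching the identifier
#' lists.
#'
#' @param counts A matrix (or object coercible to one) of read counts,
#'   taxa in rows, samples in columns.
#' @param taxon_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#' @return An integer matrix with class `"count_table"` prepended.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), nrow = 2,
#'             dimnames = list(c("asv1", "asv2"), c("s1", "s2")))
#' as_count_table(m)
#' @export
as_count_table <- function(counts, taxon_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(taxon_ids)) rownames(counts) <- taxon_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table needs taxon (row) and sample (column) identifiers")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (non-integer cell found)")
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# strip the class so matrix math never dispatches back here
ct_matrix <- function(t) {
  m <- unclass(t)
  class(m) <- NULL
  m
}

#' Read a feature table from disk
#'
#' Two dialects are supported: `tsv_dense`, a dense tab-separated table
#' with taxa as rows (first header cell `#TaxonID`, remaining header cells
#' sample identifiers), and `biom_json`, a BIOM-format file parsed by the
#' \pkg{biomformat} package (read-only; tables are always written back as
#' dense TSV).
#'
#' @param path Path to the file.
#' @param dialect `"tsv_dense"` (default) or `"biom_json"`.
#' @return A validated [as_count_table()] matrix.
#' @export
read_feature_table <- function(path, dialect = c("tsv_dense", "biom_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "biom_json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(as_count_table(m))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("feature table has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != nfield[1])) {
    stop("ragged rows in feature table (expected ", nfield[1],
         " fields, got ", paste(unique(nfield[nfield != nfield[1]]),
                                collapse = "/"), ")")
  }
  header <- fields[[1]]
  sample_ids <- header[-1]
  taxon_ids <- vapply(fields[-1], `[[`, character(1), 1)
  cells <- do.call(rbind, lapply(fields[-1], `[`, -1))
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at taxon '", taxon_ids[bad[1]], "', sample '",
         sample_ids[bad[2]], "'")
  }
  if (any(abs(num - round(num)) > 1e-8)) {
    bad <- which(abs(num - round(num)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count '", cells[bad[1], bad[2]], "' at taxon '",
         taxon_ids[bad[1]], "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(num) <- list(taxon_ids, sample_ids)
  as_count_table(num)
}

#' Write a feature table as dense TSV
#'
#' Canonical on-disk dialect: taxa as rows, header row
#' `#TaxonID<TAB>sample...`, UTF-8, newline-terminated.
#'
#' @param t A count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path) {
  m <- ct_matrix(t)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("#TaxonID", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read or validate a sample metadata sheet
#'
#' Required columns: `sample_id`, `plant_species`, `plant_individual`,
#' `leaf_side` (values `upper`/`lower`). Optional covariates: `ph` (pH
#' units, plausibility-checked against 3-12), `stomatal_density`
#' (stomata/mm^2), `latitude`/`longitude` (decimal degrees),
#' `leaf_hardness` (ordinal 0-3), `pubescence` (logical), `leaf_area`
#' (cm^2). Each plant individual must map to exactly one species.
#'
#' @param x A path to a TSV file, or a data.frame to validate in place.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(x) {
  sheet <- if (is.data.frame(x)) {
    x
  } else {
    utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = "")
  }
  required <- c("sample_id", "plant_species", "plant_individual", "leaf_side")
  missing <- setdiff(required, names(sheet))
  if (length(missing)) {
    stop("sample sheet missing required columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  bad_side <- setdiff(unique(sheet$leaf_side), c("upper", "lower"))
  if (length(bad_side)) {
    stop("leaf_side must be 'upper' or 'lower'; found: ",
         paste(bad_side, collapse = ", "))
  }
  sp_per_ind <- tapply(sheet$plant_species, sheet$plant_individual,
                       function(s) length(unique(s)))
  if (any(sp_per_ind > 1)) {
    stop("plant individual(s) mapped to more than one species: ",
         paste(names(sp_per_ind)[sp_per_ind > 1], collapse = ", "))
  }
  if ("ph" %in% names(sheet)) {
    ph <- sheet$ph[!is.na(sheet$ph)]
    if (any(ph < 3 | ph > 12)) {
      stop("pH values outside the plausible range 3-12")
    }
  }
  rownames(sheet) <- sheet$sample_id
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet A validated sample sheet.
#' @param path Output path for the TSV.
#' @export
write_sample_sheet <- function(sheet, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(sheet, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# align a count table's samples with a sheet, erroring on mismatch
align_samples <- function(t, sheet) {
  sheet <- read_sample_sheet(sheet)
  missing <- setdiff(colnames(t), sheet$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  sheet[colnames(t), , drop = FALSE]
}
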