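# File I/O: study tables, omics layers, result tables, run configuration.
#
# Study tables and layers are delimited text (comma for .csv, tab
# otherwise; .gz accepted transparently). Result TSVs use 6 significant
# digits so diffs stay readable; full precision lives in companion JSON.

.read_delim_auto <- function(path) {
  base <- sub("\\.gz$", "", path)
  sep <- if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a study table into a study frame
#'
#' Reads a delimited file with a header row and maps its columns onto the
#' study-frame roles via `mapping`. Rows with missing mapped values are
#' dropped (complete-case) with a message.
#'
#' @param path CSV/TSV file (optionally gzipped).
#' @param mapping list with entries `sample_id`, `exposure`, `outcome`,
#'   optional `covariates` (character vector) and `cohort`, each naming a
#'   column of the file.
#' @return a [study_frame()].
#' @export
read_study <- function(path, mapping) {
  df <- .read_delim_auto(path)
  need <- c(mapping$sample_id, mapping$exposure, mapping$outcome,
            mapping$covariates, mapping$cohort)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("mapped column(s) not in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  study_frame(sample_id = df[[mapping$sample_id]],
              exposure = df[[mapping$exposure]],
              outcome = df[[mapping$outcome]],
              covariates = if (length(mapping$covariates))
                df[mapping$covariates] else NULL,
              cohort = if (!is.null(mapping$cohort))
                df[[mapping$cohort]] else NULL)
}

#' Read one omics layer
#'
#' Expects a delimited file whose first column holds sample IDs and whose
#' remaining columns are numeric features (header row = feature IDs).
#'
#' @param path CSV/TSV file (optionally gzipped).
#' @return numeric matrix samples x features with dimnames.
#' @export
read_layer <- function(path) {
  df <- .read_delim_auto(path)
  if (ncol(df) < 2 || nrow(df) == 0)
    stop("layer file ", path, " has no feature data")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at row ", bad[1] + 1L,
         ", column ", bad[2] + 1L)
  }
  rownames(m) <- ids
  m
}

#' Write one omics layer
#' @param m numeric matrix samples x features (rownames = sample IDs).
#' @param path output CSV/TSV path (dialect chosen by extension).
#' @return `path`, invisibly.
#' @export
write_layer <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table (readable TSV + full-precision JSON)
#'
#' Numeric columns are written with 6 significant digits in the TSV; when
#' `json = TRUE` a companion `.json` file preserves full precision.
#'
#' @param tab data.frame.
#' @param path output TSV path.
#' @param json also write `sub(".tsv", ".json", path)` (default TRUE).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path, json = TRUE) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json)
    jsonlite::write_json(as.data.frame(tab),
                         sub("\\.tsv$", ".json", path),
                         digits = NA, na = "null")
  invisible(path)
}

#' Read a run configuration
#'
#' YAML file describing a full run: `study:` (path + column mapping with
#' `exposure:`, `outcome:`, `covariates: []`, `cohort:`), `layers:` (named
#' paths), and optional stage parameters (`seed`, `budget`, `bootstrap_B`,
#' `K`, `var_threshold`, `n_perm`, `mode`, `out`). Referenced files must
#' exist.
#'
#' @param path YAML file.
#' @return named list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$study$path)) stop("config needs study: path:")
  files <- c(cfg$study$path, unlist(cfg$layers))
  missing_files <- files[!file.exists(files)]
  if (length(missing_files))
    stop("configured file(s) not found: ",
         paste(missing_files, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Write a provenance record for a run
#'
#' Machine-readable JSON with the configuration, package version and seed,
#' so any output directory documents how it was produced.
#'
#' @param config the run configuration (list).
#' @param seed the seed used.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, seed, path) {
  rec <- list(package = "mediomics",
              version = as.character(utils::packageVersion("mediomics")),
              seed = seed,
              config = unclass(config),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
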