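#' Study frame: the epidemiologic backbone of a multi-omic mediation study
#'
#' Bundles, per sample, the exposure, the outcome, covariates and a cohort
#' label. All downstream stages consume this container. Rows with missing
#' exposure, outcome, covariate or cohort values are dropped (complete-case
#' analysis) with a message.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param exposure numeric exposure vector (e.g. blood mercury; typically in
#'   SD units after [scale_within_groups()]).
#' @param outcome numeric (continuous biomarker, e.g. CK-18 in SD units) or
#'   binary outcome vector.
#' @param covariates data.frame of covariate columns (numeric or
#'   factor/character), or `NULL` for none.
#' @param cohort cohort labels (factor or character), or `NULL` for a
#'   single-cohort study.
#'
#' @return An object of class `"study_frame"`: a data.frame with columns
#'   `sample_id`, `exposure`, `outcome`, `cohort` and one column per
#'   covariate, plus attribute `covariate_names`.
#' @export
study_frame <- function(sample_id, exposure, outcome, covariates = NULL,
                        cohort = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id values: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (length(exposure) != n || length(outcome) != n)
    stop("exposure and outcome must have one value per sample")
  if (is.null(cohort)) cohort <- rep("cohort1", n)
  cohort <- factor(cohort)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(n))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per sample")
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
  }
  df <- data.frame(sample_id = sample_id,
                   exposure = as.numeric(exposure),
                   outcome = as.numeric(outcome),
                   cohort = cohort,
                   stringsAsFactors = FALSE)
  df <- cbind(df, covariates)
  keep <- complete.cases(df)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) dropped (incomplete exposure/outcome/",
            "covariate/cohort data)")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "covariate_names") <- names(covariates)
  class(df) <- c("study_frame", "data.frame")
  df
}

#' @export
print.study_frame <- function(x, ...) {
  cat("study_frame: ", nrow(x), " samples, ",
      length(covariate_names(x)), " covariate(s), ",
      nlevels(x$cohort), " cohort(s)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Covariate column names of a study frame
#' @param study a [study_frame()].
#' @return character vector (possibly empty).
#' @export
covariate_names <- function(study) attr(study, "covariate_names") %||% character(0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-omics container: ordered named layers over one sample index
#'
#' Holds one or more samples-x-features numeric matrices that share a single
#' sample ordering. Feature IDs must be unique within each layer.
#'
#' @param layers named list of numeric matrices (samples x features) with
#'   rownames = sample IDs and colnames = feature IDs.
#' @param sample_ids optional character vector fixing the shared sample
#'   order; defaults to the rownames of the first layer.
#'
#' @return An object of class `"multi_omics"`: a named list of matrices with
#'   identical row order, plus attribute `sample_ids`.
#' @export
multi_omics <- function(layers, sample_ids = NULL) {
  if (!is.list(layers) || length(layers) == 0)
    stop("layers must be a non-empty named list of matrices")
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("every layer must be named")
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(sample_ids)) sample_ids <- rownames(layers[[1]])
  if (is.null(sample_ids))
    stop("layers must carry sample IDs as rownames (or pass sample_ids)")
  sample_ids <- as.character(sample_ids)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (is.null(rownames(m))) {
      if (nrow(m) != length(sample_ids))
        stop("layer '", nm, "' has ", nrow(m), " rows; expected ",
             length(sample_ids))
      rownames(m) <- sample_ids
    }
    missing_ids <- setdiff(sample_ids, rownames(m))
    if (length(missing_ids))
      stop("layer '", nm, "' is missing samples: ",
           paste(head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) ", ...")
    if (anyDuplicated(colnames(m)))
      stop("layer '", nm, "' has duplicated feature IDs")
    layers[[nm]] <- m[sample_ids, , drop = FALSE]
  }
  structure(layers, sample_ids = sample_ids, class = "multi_omics")
}

#' @export
print.multi_omics <- function(x, ...) {
  cat("multi_omics: ", length(x), " layer(s), ",
      length(attr(x, "sample_ids")), " samples\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-14s %5d features\n", nm, ncol(x[[nm]])))
  invisible(x)
}

#' Align a study frame and a multi-omics container on shared samples
#'
#' Verifies that every study sample is present in every layer and reorders
#' the layers to the study's sample order.
#'
#' @param study a [study_frame()].
#' @param omics a [multi_omics()].
#' @return the reordered `multi_omics`.
#' @export
align_samples <- function(study, omics) {
  ids <- study$sample_id
  for (nm in names(omics)) {
    missing_ids <- setdiff(ids, rownames(omics[[nm]]))
    if (length(missing_ids))
      stop("sample IDs absent from layer '", nm, "': ",
           paste(head(missing_ids, 10), collapse = ", "),
           if (length(missing_ids) > 10) ", ...")
  }
  multi_omics(lapply(omics, function(m) m[ids, , drop = FALSE]),
              sample_ids = ids)
}

#' Column-concatenate the layers of a multi-omics container
#'
#' Feature IDs are prefixed with `layer.` when `prefix = TRUE` so that the
#' origin layer of every column stays recoverable after early integration.
#'
#' @param omics a [multi_omics()].
#' @param prefix prefix feature IDs with their layer name (default TRUE).
#' @return a numeric matrix samples x (sum of features), with attribute
#'   `layer_of` mapping each column to its layer.
#' @export
concat_layers <- function(omics, prefix = TRUE) {
  mats <- lapply(names(omics), function(nm) {
    m <- omics[[nm]]
    if (prefix) colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  })
  out <- do.call(cbind, mats)
  attr(out, "layer_of") <- rep(names(omics),
                               vapply(omics, ncol, integer(1)))
  out
}
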