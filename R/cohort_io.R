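# Domain containers and delimited-table I/O for expression, protein and
# clinical data. Convention everywhere: features (genes/proteins) in rows,
# samples in columns.

#' Construct an expression matrix
#'
#' A genes x samples numeric matrix of RNA-seq counts. Values must be
#' nonnegative and complete; the `normalized` flag records whether
#' median-of-ratios size-factor normalization has been applied
#' (see [size_factor_normalize()]).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param normalized logical; `TRUE` if the values are normalized counts.
#' @return A numeric matrix of class `"expression_matrix"` with attribute
#'   `normalized`.
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  values <- validate_feature_matrix(values, kind = "gene")
  if (any(values < 0)) {
    ga_stop("NegativeValue", "expression values must be nonnegative")
  }
  structure(values,
            normalized = isTRUE(normalized),
            class = c("expression_matrix", "ga_matrix"))
}

#' Construct a serum protein panel
#'
#' A proteins x samples numeric matrix of relative protein abundances on the
#' NPX (normalized protein expression) scale. NPX is a log-scale relative
#' unit, so values may be negative.
#'
#' @param values numeric matrix, proteins in rows, samples in columns, with
#'   unique row and column names.
#' @return A numeric matrix of class `"protein_panel"`.
#' @export
protein_panel <- function(values) {
  values <- validate_feature_matrix(values, kind = "protein")
  structure(values, class = c("protein_panel", "ga_matrix"))
}

# Shared invariants: unique ids, no missing cells, at least 2 x 2.
validate_feature_matrix <- function(values, kind) {
  if (!is.matrix(values) || !is.numeric(values)) {
    ga_stop("NonNumericCell", "%s matrix must be a numeric matrix", kind)
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    ga_stop("EmptyMatrix", "need at least 2 %ss and 2 samples, got %d x %d",
            kind, nrow(values), ncol(values))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ga_stop("MissingIdentifiers", "%s matrix needs row and column names", kind)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    ga_stop("DuplicateIdentifier", "duplicate %s identifier: %s", kind, dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    ga_stop("DuplicateIdentifier", "duplicate sample identifier: %s", dup)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    ga_stop("MissingValue", "missing value at row '%s', column '%s'",
            rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  values
}

#' Construct a clinical covariate table
#'
#' One row per sample. Recognised variables: `days_posttransplant` (days),
#' `creatinine` (mg/dL at biopsy), `creatinine_increase` (mg/dL over
#' baseline), `egfr` (mL/min, CKD-EPI), `proteinuria` (mg/g), `diagnosis`
#' (`"nonrejection"`/`"rejection"`), and optional `creatinine_pred_2mo`,
#' `creatinine_pred_12mo` (mg/dL). Missing values are permitted and are
#' excluded pairwise by the correlation machinery downstream.
#'
#' @param df data.frame with a `sample_id` column (or sample ids as row
#'   names) and any subset of the recognised variables.
#' @return A data.frame of class `"clinical_table"` with sample ids as row
#'   names.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  if ("sample_id" %in% names(df)) {
    rownames(df) <- as.character(df$sample_id)
    df$sample_id <- NULL
  }
  if (is.null(rownames(df)) || anyDuplicated(rownames(df))) {
    ga_stop("DuplicateIdentifier", "clinical table needs unique sample ids")
  }
  if ("egfr" %in% names(df)) {
    bad <- !is.na(df$egfr) & df$egfr <= 0
    if (any(bad)) {
      ga_stop("InvalidClinicalValue", "egfr must be positive (sample '%s')",
              rownames(df)[bad][1L])
    }
  }
  if ("diagnosis" %in% names(df)) {
    df$diagnosis <- as.character(df$diagnosis)
    ok <- is.na(df$diagnosis) | df$diagnosis %in% c("nonrejection", "rejection")
    if (!all(ok)) {
      ga_stop("InvalidClinicalValue", "diagnosis must be nonrejection/rejection")
    }
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Bundle time-matched expression, protein and clinical data
#'
#' All three components must cover an identical, ordered sample set (the
#' time-matched contract: serum was drawn at the time of the biopsy). Use
#' [align_samples()] to build a bundle from partially overlapping inputs.
#'
#' @param expression an [expression_matrix()].
#' @param proteins a [protein_panel()].
#' @param clinical a [clinical_table()] or `NULL`.
#' @param provenance free-text source tag.
#' @return A list of class `"cohort_bundle"`.
#' @export
cohort_bundle <- function(expression, proteins, clinical = NULL,
                          provenance = "unspecified") {
  s <- colnames(expression)
  if (!identical(s, colnames(proteins))) {
    ga_stop("SampleMismatch", "expression and protein sample ids differ")
  }
  if (!is.null(clinical) && !identical(s, rownames(clinical))) {
    ga_stop("SampleMismatch", "clinical sample ids differ from expression")
  }
  structure(list(expression = expression, proteins = proteins,
                 clinical = clinical, provenance = provenance),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle '%s': %d genes x %d samples, %d proteins%s\n",
              x$provenance, nrow(x$expression), ncol(x$expression),
              nrow(x$proteins),
              if (is.null(x$clinical)) "" else
                sprintf(", %d clinical variables", ncol(x$clinical))))
  invisible(x)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature x sample matrix from delimited text
#'
#' TSV or CSV (detected from the file extension); the first row holds sample
#' identifiers and the first column feature identifiers. The transposed
#' layout is accepted via `orientation = "features_in_cols"`.
#'
#' @param path file path.
#' @param orientation `"features_in_rows"` (default) or `"features_in_cols"`.
#' @param type `"expression"` or `"protein"`: which container to return.
#' @return An [expression_matrix()] or [protein_panel()].
#' @export
read_matrix <- function(path,
                        orientation = c("features_in_rows", "features_in_cols"),
                        type = c("expression", "protein")) {
  orientation <- match.arg(orientation)
  type <- match.arg(type)
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          row.names = NULL, quote = "\"")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    ga_stop("EmptyMatrix", "no data cells in '%s'", path)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    ga_stop("DuplicateIdentifier", "duplicate identifier '%s' in '%s'",
            ids[duplicated(ids)][1L], path)
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      ga_stop("NonNumericCell", "non-numeric cell '%s' at row %d, column %d",
              cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L])
    }
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    ga_stop("MissingValue", "missing value at row %d, column %d",
            bad[1L], bad[2L])
  }
  rownames(num) <- ids
  colnames(num) <- colnames(df)[-1L]
  if (orientation == "features_in_cols") num <- t(num)
  if (type == "expression") expression_matrix(num) else protein_panel(num)
}

#' Write a feature x sample matrix as TSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round trip reproduces every cell exactly.
#'
#' @param x a matrix-like container from this package.
#' @param path output path (TSV).
#' @param id_header header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_header = "feature_id") {
  m <- unclass(x)
  out <- data.frame(rownames(m),
                    apply(m, 2L, function(col) sprintf("%.17g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(id_header, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Expects a `sample_id` column plus any of the recognised clinical
#' variables (see [clinical_table()]); empty cells and `NA` become missing.
#'
#' @param path file path (TSV or CSV).
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  clinical_table(df)
}

#' Write a clinical table as TSV
#'
#' @param x a [clinical_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  out <- cbind(sample_id = rownames(x), as.data.frame(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a cohort on the common sample set
#'
#' Restricts and reorders expression, protein and clinical data to their
#' common samples, sorted lexicographically for determinism. Dropped samples
#' are reported per component via `message()` and recorded in the bundle
#' attribute `"dropped"`.
#'
#' @param expression an [expression_matrix()].
#' @param proteins a [protein_panel()].
#' @param clinical optional [clinical_table()].
#' @param provenance source tag for the bundle.
#' @return A [cohort_bundle()] over the sorted common samples.
#' @export
align_samples <- function(expression, proteins, clinical = NULL,
                          provenance = "aligned") {
  sets <- list(expression = colnames(expression),
               proteins = colnames(proteins))
  if (!is.null(clinical)) sets$clinical <- rownames(clinical)
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0L) {
    ga_stop("NoCommonSamples", "no sample id occurs in every component")
  }
  dropped <- lapply(sets, function(s) setdiff(s, common))
  for (comp in names(dropped)) {
    if (length(dropped[[comp]]) > 0L) {
      message(sprintf("align_samples: dropped %d sample(s) from %s: %s",
                      length(dropped[[comp]]), comp,
                      paste(dropped[[comp]], collapse = ", ")))
    }
  }
  expr <- expression_matrix(unclass(expression)[, common, drop = FALSE],
                            normalized = attr(expression, "normalized"))
  prot <- protein_panel(unclass(proteins)[, common, drop = FALSE])
  clin <- if (is.null(clinical)) NULL else {
    cl <- clinical[common, , drop = FALSE]
    rownames(cl) <- common
    class(cl) <- c("clinical_table", "data.frame")
    cl
  }
  out <- cohort_bundle(expr, prot, clin, provenance = provenance)
  attr(out, "dropped") <- dropped
  out
}

#' Drop low-variance proteins from a panel
#'
#' Proteins whose sample standard deviation is at or below `min_sd` are
#' removed, emulating the panel-side removal of proteins with low variance
#' or below the detection threshold. With the default `min_sd = 0` exactly
#' the constant proteins are removed.
#'
#' @param panel a [protein_panel()].
#' @param min_sd nonnegative removal threshold on the per-protein sd.
#' @return The filtered [protein_panel()]; removed ids in attribute
#'   `"removed"`.
#' @export
filter_low_variance_proteins <- function(panel, min_sd = 0) {
  stopifnot(min_sd >= 0)
  sds <- apply(unclass(panel), 1L, stats::sd)
  keep <- sds > min_sd
  if (!any(keep)) {
    ga_stop("AllProteinsRemoved",
            "no protein exceeds the variance threshold %g", min_sd)
  }
  removed <- rownames(panel)[!keep]
  if (length(removed) > 0L) {
    message(sprintf("filter_low_variance_proteins: removed %d protein(s): %s",
                    length(removed), paste(removed, collapse = ", ")))
  }
  out <- protein_panel(unclass(panel)[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}
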