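# Signature validation: intrasignature correlation against a random-set
# null, signature scores, and association with clinical kidney function.

#' Mean pairwise Spearman correlation within a protein set
#'
#' The off-diagonal mean of the Spearman similarity matrix of the member
#' proteins (all unordered pairs, pairwise-complete samples).
#'
#' @param panel a [protein_panel()].
#' @param members character vector of at least 2 member protein ids.
#' @return A single correlation in [-1, 1].
#' @export
intrasignature_correlation <- function(panel, members) {
  pm <- unclass(panel)
  unknown <- setdiff(members, rownames(pm))
  if (length(unknown) > 0L) {
    ga_stop("UnknownProtein", "protein '%s' not in panel", unknown[1L])
  }
  if (length(members) < 2L) {
    ga_stop("TooFewMembers", "need at least 2 member proteins")
  }
  sub <- pm[members, , drop = FALSE]
  rho <- spearman_matrix(sub, sub)$rho
  mean(rho[upper.tri(rho)], na.rm = TRUE)
}

#' Random-set null for the intrasignature correlation
#'
#' Draws `n_sets` random protein sets (without replacement within each set)
#' and returns their intrasignature correlations. The default 10 sets of 10
#' proteins mirror the control construction used for signature validation.
#' Sets are drawn from the full measured panel by default; pass `exclude`
#' to hold out e.g. the signature members.
#'
#' @param panel a [protein_panel()].
#' @param set_size proteins per random set.
#' @param n_sets number of random sets.
#' @param seed RNG seed.
#' @param exclude protein ids never drawn.
#' @return Numeric vector of length `n_sets`.
#' @export
random_set_null <- function(panel, set_size = 10L, n_sets = 10L, seed = 1L,
                            exclude = character()) {
  pool <- setdiff(rownames(panel), exclude)
  if (set_size > length(pool)) {
    ga_stop("InsufficientProteins",
            "set_size %d exceeds the %d available proteins",
            set_size, length(pool))
  }
  set.seed(as.integer(seed))
  vapply(seq_len(n_sets), function(i) {
    intrasignature_correlation(panel, sample(pool, set_size))
  }, numeric(1L))
}

#' Per-sample signature score
#'
#' The arithmetic mean of the member proteins' NPX values in each sample.
#'
#' @param panel a [protein_panel()].
#' @param members member protein ids (at least 1).
#' @return Named numeric vector over the panel's samples.
#' @export
signature_score <- function(panel, members) {
  pm <- unclass(panel)
  unknown <- setdiff(members, rownames(pm))
  if (length(unknown) > 0L) {
    ga_stop("UnknownProtein", "protein '%s' not in panel", unknown[1L])
  }
  stopifnot(length(members) >= 1L)
  colMeans(pm[members, , drop = FALSE])
}

#' Associate a score with clinical variables
#'
#' Spearman correlation of the score against each clinical variable with
#' pairwise deletion of missing values, plus the least-squares regression
#' line (slope, intercept) for XY plotting. A variable with too few
#' complete pairs is reported with `NA` statistics and status
#' `"too_few_pairs"` rather than failing.
#'
#' @param score named per-sample numeric vector (e.g. from
#'   [signature_score()]).
#' @param clinical a [clinical_table()] covering the same samples.
#' @param variables clinical variable names to test.
#' @return Data.frame: `variable`, `rho`, `p`, `n_used`, `slope`,
#'   `intercept`, `status`.
#' @export
clinical_association <- function(score, clinical,
                                 variables = c("egfr", "creatinine",
                                               "proteinuria",
                                               "days_posttransplant")) {
  missing_var <- setdiff(variables, colnames(clinical))
  if (length(missing_var) > 0L) {
    ga_stop("UnknownClinicalVariable", "variable '%s' not in clinical table",
            missing_var[1L])
  }
  samples <- intersect(names(score), rownames(clinical))
  if (length(samples) < 3L) {
    ga_stop("TooFewPairs", "fewer than 3 samples shared with clinical table")
  }
  rows <- lapply(variables, function(v) {
    x <- score[samples]
    y <- as.numeric(clinical[samples, v])
    res <- tryCatch(spearman(x, y), graftaxis_error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_,
                        n_used = sum(stats::complete.cases(x, y)),
                        slope = NA_real_, intercept = NA_real_,
                        status = "too_few_pairs", stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ x)
    data.frame(variable = v, rho = res$rho, p = res$p, n_used = res$n_used,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validate a signature against the random-set null and clinical function
#'
#' For each requested truncation (top-3 / top-6 / top-10 by default,
#' capped at the signature size) the intrasignature correlation is compared
#' to `n_sets` random protein sets; `exceeds_null` is `TRUE` when it is
#' strictly greater than every null draw (`null_rule = "max"`) or than the
#' 95th percentile (`"percentile_95"`). The truncated signature score is
#' also correlated with the clinical variables. An optional
#' leave-one-protein-out recomputation of the intrasignature correlation is
#' reported alongside (never silently applied).
#'
#' @param panel a [protein_panel()].
#' @param signature a [extract_signature()] result or a character vector of
#'   ordered member protein ids (strongest first).
#' @param clinical optional [clinical_table()].
#' @param n_sets,set_size null configuration (defaults 10 and the
#'   truncation size).
#' @param truncations integer truncation sizes.
#' @param null_rule `"max"` or `"percentile_95"`.
#' @param seed RNG seed for the null draws.
#' @param variables clinical variables to test.
#' @param leave_one_out also report, per truncation, the intrasignature
#'   correlation with each member dropped in turn.
#' @return List of class `"validation_report"` with one entry per
#'   truncation: `members`, `intra_rho`, `null_rhos`, `null_mean`,
#'   `null_sd`, `exceeds_null`, `clinical_assocs`, optional
#'   `leave_one_out`.
#' @export
validate_signature <- function(panel, signature, clinical = NULL,
                               n_sets = 10L, set_size = NULL,
                               truncations = c(3L, 6L, 10L),
                               null_rule = c("max", "percentile_95"),
                               seed = 1L,
                               variables = c("egfr", "creatinine",
                                             "proteinuria",
                                             "days_posttransplant"),
                               leave_one_out = FALSE) {
  null_rule <- match.arg(null_rule)
  members_all <- if (is.data.frame(signature)) signature$protein else signature
  stopifnot(length(members_all) >= 2L)
  truncations <- sort(unique(pmin(as.integer(truncations),
                                  length(members_all))))
  truncations <- truncations[truncations >= 2L]
  per_trunc <- lapply(truncations, function(tk) {
    members <- members_all[seq_len(tk)]
    intra <- intrasignature_correlation(panel, members)
    nulls <- random_set_null(panel,
                             set_size = if (is.null(set_size)) tk else set_size,
                             n_sets = n_sets,
                             seed = substream_seed(seed, 500L + tk))
    exceeds <- switch(null_rule,
                      max = intra > max(nulls),
                      percentile_95 = intra > stats::quantile(nulls, 0.95,
                                                              names = FALSE))
    out <- list(members = members, intra_rho = intra, null_rhos = nulls,
                null_mean = mean(nulls), null_sd = stats::sd(nulls),
                exceeds_null = exceeds)
    if (!is.null(clinical)) {
      out$clinical_assocs <- clinical_association(
        signature_score(panel, members), clinical, variables)
    }
    if (isTRUE(leave_one_out) && tk > 2L) {
      out$leave_one_out <- vapply(seq_along(members), function(i) {
        intrasignature_correlation(panel, members[-i])
      }, numeric(1L))
      names(out$leave_one_out) <- members
    }
    out
  })
  names(per_trunc) <- sprintf("top_%d", truncations)
  structure(list(truncations = per_trunc, null_rule = null_rule,
                 n_sets = as.integer(n_sets), seed = as.integer(seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report (%s rule, %d null sets)\n",
              x$null_rule, x$n_sets))
  for (nm in names(x$truncations)) {
    tr <- x$truncations[[nm]]
    cat(sprintf("  %s: intra rho %.3f vs null %.3f +- %.3f -> exceeds: %s\n",
                nm, tr$intra_rho, tr$null_mean, tr$null_sd,
                tr$exceeds_null))
  }
  invisible(x)
}

#' Serialize / reload a validation report (JSON)
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path` (write) or the reloaded `validation_report` (read).
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$truncations <- lapply(obj$truncations, function(tr) {
    if (!is.null(tr$clinical_assocs)) {
      tr$clinical_assocs <- as.data.frame(tr$clinical_assocs,
                                          stringsAsFactors = FALSE)
    }
    tr
  })
  obj$n_sets <- as.integer(obj$n_sets)
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "validation_report")
}
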