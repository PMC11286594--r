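# Serum-axis analysis: Spearman correlation of network/axis activity with
# the serum protein panel, similarity ordering by hierarchical clustering
# (complete linkage on 1 - Spearman rho), axis aggregation, and extraction
# of the HEALTH / INJURY protein signatures.

#' Spearman correlation with t-approximation p-value
#'
#' Computes rho as Pearson correlation of average ranks (ties averaged)
#' after pairwise deletion of missing entries, and a two-sided p-value from
#' the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`. For |rho| = 1 the
#' smallest representable positive p is returned so that p stays in (0, 1].
#'
#' @param x,y numeric vectors of equal length; `NA`s deleted pairwise.
#' @return List with `rho`, `p`, `n_used`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) {
    ga_stop("TooFewPairs", "need at least 3 complete pairs, have %d", n)
  }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    ga_stop("TooFewPairs", "a variable is constant on the complete pairs")
  }
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) {
    .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  list(rho = rho, p = p, n_used = n)
}

# Spearman rho/p/n between every row of a and every row of b; cells with
# too few complete pairs become NA with a warning.
spearman_matrix <- function(a, b) {
  rho <- matrix(NA_real_, nrow(a), nrow(b),
                dimnames = list(rownames(a), rownames(b)))
  pval <- rho
  nmat <- matrix(NA_integer_, nrow(a), nrow(b), dimnames = dimnames(rho))
  failed <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      res <- tryCatch(spearman(a[i, ], b[j, ]), graftaxis_error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      rho[i, j] <- res$rho; pval[i, j] <- res$p; nmat[i, j] <- res$n_used
    }
  }
  if (failed > 0L) {
    ga_warn("TooFewPairs", "%d correlation cell(s) had too few pairs", failed)
  }
  list(rho = rho, p = pval, n = nmat)
}

# Complete-linkage leaf order on 1 - Spearman rho between the rows of m.
spearman_leaf_order <- function(m) {
  if (nrow(m) < 3L) return(seq_len(nrow(m)))
  rho <- spearman_matrix(m, m)$rho
  rho[is.na(rho)] <- 0
  stats::hclust(stats::as.dist(1 - rho), method = "complete")$order
}

#' Correlate network activity with the protein panel
#'
#' Full Spearman rho / p / n matrices between network activity rows and
#' protein rows (samples matched by name), with dendrogram leaf orders for
#' display: rows and columns are each ordered by complete-linkage
#' hierarchical clustering on the distance 1 - Spearman rho between their
#' per-sample profiles.
#'
#' @param activity networks x samples matrix from [network_activity()].
#' @param panel a [protein_panel()] over the same samples.
#' @return List of class `"axis_correlation"`: `rho`, `p`, `n`, `row_order`,
#'   `col_order`.
#' @export
correlate_activity_proteins <- function(activity, panel) {
  pm <- unclass(panel)
  if (!setequal(colnames(activity), colnames(pm))) {
    ga_stop("SampleMismatch", "activity and panel sample ids differ")
  }
  pm <- pm[, colnames(activity), drop = FALSE]
  res <- spearman_matrix(activity, pm)
  structure(list(rho = res$rho, p = res$p, n = res$n,
                 row_order = spearman_leaf_order(activity),
                 col_order = spearman_leaf_order(pm)),
            class = "axis_correlation")
}

#' @export
print.axis_correlation <- function(x, ...) {
  cat(sprintf("axis_correlation: %d networks/axes x %d proteins, rho range [%.2f, %.2f]\n",
              nrow(x$rho), ncol(x$rho), min(x$rho, na.rm = TRUE),
              max(x$rho, na.rm = TRUE)))
  invisible(x)
}

#' Aggregate networks into axis activity
#'
#' Axis activity in a sample is the mean z-scored expression over all genes
#' belonging to any member network of the axis (gene-weighted: a network
#' with more genes contributes proportionally more).
#'
#' @param axes named list mapping axis name (e.g. `"MB"`, `"INF"`) to an
#'   integer vector of network ids.
#' @param z z-scored [expression_matrix()] over the clustered genes.
#' @param labels named network labels covering the rows of `z`.
#' @return axes x samples numeric matrix.
#' @export
axis_activity <- function(axes, z, labels) {
  stopifnot(is.list(axes), !is.null(names(axes)), length(axes) >= 1L)
  ids <- sort(unique(unlist(axes)))
  known <- sort(unique(labels))
  if (!all(ids %in% known)) {
    ga_stop("UnknownNetworkId", "network id(s) %s not present",
            paste(setdiff(ids, known), collapse = ", "))
  }
  if (anyDuplicated(unlist(axes))) {
    ga_stop("UnknownNetworkId", "axes must reference disjoint network sets")
  }
  m <- unclass(z)
  lab <- labels[rownames(m)]
  out <- t(vapply(axes, function(members) {
    colMeans(m[lab %in% members, , drop = FALSE])
  }, numeric(ncol(m))))
  rownames(out) <- names(axes)
  out
}

#' Per-protein correlation table against each axis
#'
#' @param axis_act axes x samples matrix from [axis_activity()] (rows named
#'   by axis, e.g. MB and INF).
#' @param panel a [protein_panel()] over the same samples.
#' @return Data.frame of class `"protein_axis_table"` with one row per
#'   protein and columns `rho_<axis>`, `p_<axis>`, `n_<axis>`.
#' @export
protein_axis_table <- function(axis_act, panel) {
  pm <- unclass(panel)
  if (!setequal(colnames(axis_act), colnames(pm))) {
    ga_stop("SampleMismatch", "axis activity and panel sample ids differ")
  }
  pm <- pm[, colnames(axis_act), drop = FALSE]
  res <- spearman_matrix(axis_act, pm)
  out <- data.frame(protein = colnames(res$rho), stringsAsFactors = FALSE)
  for (ax in rownames(axis_act)) {
    out[[paste0("rho_", ax)]] <- res$rho[ax, ]
    out[[paste0("p_", ax)]] <- res$p[ax, ]
    out[[paste0("n_", ax)]] <- res$n[ax, ]
  }
  rownames(out) <- NULL
  class(out) <- c("protein_axis_table", "data.frame")
  out
}

#' Extract a serum protein signature
#'
#' Category filters on the per-protein axis correlations (raw p-values by
#' default, the paper-style `|rho| > 0.6 & p < 0.05` screen):
#' `MB_up`: `rho_MB > rho_min & p_MB < p_max`; `MB_down`:
#' `rho_MB <= -rho_min & p_MB < p_max`; `INF_up` / `INF_down` analogously;
#' `HEALTH = MB_up | INF_down`; `INJURY = MB_down | INF_up` (union
#' semantics: a protein qualifies through either axis or both). Proteins
#' are ranked by the largest |rho| among their qualifying axis conditions,
#' descending, ties by protein id, and the top `k` are returned.
#'
#' @param table a [protein_axis_table()] with MB and INF columns.
#' @param category one of `"HEALTH"`, `"INJURY"`, `"MB_up"`, `"MB_down"`,
#'   `"INF_up"`, `"INF_down"`.
#' @param rho_min correlation threshold in (0, 1].
#' @param p_max p-value threshold in (0, 1).
#' @param k signature size cap (fewer if the filter yields fewer).
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method
#'   applied per axis before filtering.
#' @return Data.frame of class `"signature"` (possibly 0 rows) with
#'   columns `protein`, `rho_MB`, `p_MB`, `rho_INF`, `p_INF`, `rank_stat`,
#'   plus attributes `category` and `k`.
#' @export
extract_signature <- function(table, category = c("HEALTH", "INJURY",
                                                  "MB_up", "MB_down",
                                                  "INF_up", "INF_down"),
                              rho_min = 0.6, p_max = 0.05, k = 10L,
                              p_adjust = "none") {
  category <- match.arg(category)
  stopifnot(rho_min > 0, rho_min <= 1, p_max > 0, p_max < 1, k >= 1L)
  p_mb <- stats::p.adjust(table$p_MB, method = p_adjust)
  p_inf <- stats::p.adjust(table$p_INF, method = p_adjust)
  cond <- list(
    MB_up = table$rho_MB > rho_min & p_mb < p_max,
    MB_down = table$rho_MB <= -rho_min & p_mb < p_max,
    INF_up = table$rho_INF > rho_min & p_inf < p_max,
    INF_down = table$rho_INF <= -rho_min & p_inf < p_max)
  cond <- lapply(cond, function(v) !is.na(v) & v)
  parts <- switch(category,
                  HEALTH = c("MB_up", "INF_down"),
                  INJURY = c("MB_down", "INF_up"),
                  category)
  qual <- Reduce(`|`, cond[parts])
  rho_cols <- list(MB_up = abs(table$rho_MB), MB_down = abs(table$rho_MB),
                   INF_up = abs(table$rho_INF), INF_down = abs(table$rho_INF))
  stat <- rep(-Inf, nrow(table))
  for (part in parts) {
    cand <- ifelse(cond[[part]], rho_cols[[part]], -Inf)
    stat <- pmax(stat, cand)
  }
  sel <- which(qual)
  sel <- sel[order(-stat[sel], table$protein[sel])]
  sel <- sel[seq_len(min(k, length(sel)))]
  out <- data.frame(protein = table$protein[sel],
                    rho_MB = table$rho_MB[sel], p_MB = table$p_MB[sel],
                    rho_INF = table$rho_INF[sel], p_INF = table$p_INF[sel],
                    rank_stat = stat[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, category = category, k = as.integer(k),
            class = c("signature", "data.frame"))
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("%s signature: %d protein(s)\n", attr(x, "category"), nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x, digits = 3)
  invisible(x)
}

#' Write a signature as TSV
#'
#' @param x a `signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(x, path) {
  out <- as.data.frame(x)
  out$category <- rep(attr(x, "category"), nrow(out))
  out$rank <- seq_len(nrow(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map recovered networks to axes by ground-truth majority vote
#'
#' Utility for synthetic-cohort experiments: each recovered network is
#' assigned the axis carried by the majority of its genes' planted modules
#' (ties and majority-`none` networks stay unassigned).
#'
#' @param labels named recovered network labels.
#' @param truth ground-truth list from [generate_cohort()].
#' @return Named list mapping `"MB"`/`"INF"`/`"ECM"` to network id vectors.
#' @export
map_networks_to_axes <- function(labels, truth) {
  gene_axis <- truth$module_axis[truth$gene_module[names(labels)]]
  gene_axis[is.na(gene_axis)] <- "none"
  axes <- list()
  for (net in sort(unique(labels))) {
    tab <- sort(table(gene_axis[labels == net]), decreasing = TRUE)
    top <- names(tab)[1L]
    if (top != "none") axes[[top]] <- c(axes[[top]], net)
  }
  axes
}
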