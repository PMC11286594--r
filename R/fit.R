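# Central fitting interface: one call from a matched cohort to gene
# networks, serum-axis correlations and HEALTH/INJURY signatures, returned
# as a classed object with the usual modelling methods.

#' Fit the serum-allograft axis model
#'
#' Runs the full discovery chain on a time-matched cohort: size-factor
#' normalization (if the expression is raw counts), variable-gene selection
#' by CV, z-scoring, t-SNE embedding, k-means network calling, per-sample
#' network activity, Spearman correlation of activity against the serum
#' panel, aggregation of user-assigned networks into MB / INF axis
#' activity, and extraction of the four axis categories plus the HEALTH and
#' INJURY signatures. Axis membership (which networks are metabolic, which
#' inflammatory) is biological annotation and therefore an input, not an
#' inference.
#'
#' @param expression an [expression_matrix()].
#' @param proteins a [protein_panel()].
#' @param clinical optional [clinical_table()].
#' @param axes named list mapping axis names (`MB`, `INF`) to network ids,
#'   or `NULL` to stop after the network-protein correlation stage.
#' @param target_count variable genes to keep.
#' @param k number of networks, or `NULL` to select by silhouette over
#'   `k_grid`.
#' @param k_grid candidate k values.
#' @param perplexity,seed,n_restarts,max_iter embedding / clustering tuning.
#' @param rho_min,p_max,top_k signature filter: |rho| threshold, p-value
#'   threshold, signature size.
#' @param min_protein_sd variance filter applied to the panel.
#' @param log1p_scale CV scale option.
#' @return An object of class `"graft_axes"` with components `bundle`,
#'   `networks` (a `"gene_networks"`), `correlation`
#'   (an `"axis_correlation"`), and when `axes` is given: `axes`,
#'   `axis_act`, `protein_table`, `signatures` (list by category),
#'   `clinical_assocs` (per signature, when clinical data are present).
#' @export
graft_axes <- function(expression, proteins, clinical = NULL, axes = NULL,
                       target_count = 2000L, k = NULL, k_grid = 2:20,
                       perplexity = 30, seed = 0L, n_restarts = 25L,
                       max_iter = 500L, rho_min = 0.6, p_max = 0.05,
                       top_k = 10L, min_protein_sd = 0,
                       log1p_scale = FALSE) {
  proteins <- filter_low_variance_proteins(proteins, min_protein_sd)
  bundle <- align_samples(expression, proteins, clinical)
  networks <- fit_gene_networks(bundle$expression,
                                target_count = target_count, k = k,
                                k_grid = k_grid, perplexity = perplexity,
                                seed = seed, n_restarts = n_restarts,
                                max_iter = max_iter,
                                log1p_scale = log1p_scale)
  correlation <- correlate_activity_proteins(networks$activity,
                                             bundle$proteins)
  fit <- list(bundle = bundle, networks = networks,
              correlation = correlation,
              params = list(target_count = target_count, k = networks$k,
                            perplexity = perplexity, seed = seed,
                            rho_min = rho_min, p_max = p_max,
                            top_k = top_k))
  if (!is.null(axes)) {
    fit$axes <- axes
    fit$axis_act <- axis_activity(axes, networks$z, networks$labels)
    fit$protein_table <- protein_axis_table(fit$axis_act, bundle$proteins)
    cats <- c("HEALTH", "INJURY", "MB_up", "MB_down", "INF_up", "INF_down")
    fit$signatures <- lapply(stats::setNames(cats, cats), function(cat) {
      extract_signature(fit$protein_table, cat, rho_min = rho_min,
                        p_max = p_max, k = top_k)
    })
    if (!is.null(bundle$clinical)) {
      fit$clinical_assocs <- lapply(fit$signatures, function(sig) {
        if (nrow(sig) == 0L) return(NULL)
        clinical_association(signature_score(bundle$proteins, sig$protein),
                             bundle$clinical)
      })
    }
  }
  class(fit) <- "graft_axes"
  fit
}

#' @export
print.graft_axes <- function(x, ...) {
  cat("Serum-allograft axis fit\n")
  cat(sprintf("  cohort: %d samples, %d genes (%d variable), %d proteins\n",
              ncol(x$bundle$expression), nrow(x$bundle$expression),
              length(x$networks$selected_genes), nrow(x$bundle$proteins)))
  cat(sprintf("  gene networks: k = %d (CV threshold %.4f)\n",
              x$networks$k, x$networks$cv_threshold))
  if (!is.null(x$signatures)) {
    for (cat_name in c("HEALTH", "INJURY")) {
      sig <- x$signatures[[cat_name]]
      cat(sprintf("  %s signature (%d): %s\n", cat_name, nrow(sig),
                  paste(sig$protein, collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
summary.graft_axes <- function(object, ...) {
  print(object)
  cat("\nNetwork sizes:\n")
  print(table(object$networks$labels))
  if (!is.null(object$axis_act)) {
    cat("\nAxis activity correlation (Spearman):\n")
    ax <- object$axis_act
    if (nrow(ax) >= 2L) {
      cat(sprintf("  rho(%s, %s) = %.3f\n", rownames(ax)[1L],
                  rownames(ax)[2L], spearman(ax[1L, ], ax[2L, ])$rho))
    }
  }
  if (!is.null(object$clinical_assocs)) {
    for (cat_name in c("HEALTH", "INJURY")) {
      ca <- object$clinical_assocs[[cat_name]]
      if (is.null(ca)) next
      cat(sprintf("\n%s signature vs clinical:\n", cat_name))
      print(ca, digits = 3, row.names = FALSE)
    }
  }
  invisible(object)
}

#' Per-protein axis correlations of a fit
#'
#' @param object a `"graft_axes"` fit with axes assigned.
#' @param ... unused.
#' @return The [protein_axis_table()] of the fit.
#' @export
coef.graft_axes <- function(object, ...) {
  if (is.null(object$protein_table)) {
    ga_stop("NoAxes", "fit has no axis assignment; rerun with `axes`")
  }
  object$protein_table
}

#' Score a (new) protein panel with a fitted signature
#'
#' Applies a signature frozen from the training fit to a new serum panel —
#' the external-validation use: member proteins must be measured in the new
#' panel, nothing is re-derived.
#'
#' @param object a `"graft_axes"` fit with signatures.
#' @param newdata a [protein_panel()]; defaults to the training panel.
#' @param category signature to apply.
#' @param top truncation (e.g. 3 for the top-3 sub-signature).
#' @param ... unused.
#' @return Named per-sample score vector.
#' @export
predict.graft_axes <- function(object, newdata = NULL,
                               category = "INJURY", top = NULL, ...) {
  if (is.null(object$signatures)) {
    ga_stop("NoAxes", "fit has no signatures; rerun with `axes`")
  }
  sig <- object$signatures[[category]]
  if (is.null(sig) || nrow(sig) == 0L) {
    ga_stop("EmptySignature", "signature '%s' is empty", category)
  }
  members <- sig$protein
  if (!is.null(top)) members <- members[seq_len(min(top, length(members)))]
  panel <- if (is.null(newdata)) object$bundle$proteins else newdata
  signature_score(panel, members)
}

#' Plot the ordered network-protein correlation matrix
#'
#' Heatmap of Spearman rho between network activity and serum proteins,
#' rows and columns in dendrogram leaf order (blue negative, red positive).
#'
#' @param x a `"graft_axes"` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.graft_axes <- function(x, ...) {
  co <- x$correlation
  m <- co$rho[co$row_order, co$col_order, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101L)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(-1, 1), col = pal, xlab = "proteins (ordered)",
                  ylab = "gene networks (ordered)", axes = FALSE,
                  main = "Network activity vs serum proteins (Spearman rho)",
                  ...)
  graphics::axis(2L, at = seq_len(nrow(m)), labels = rownames(m), las = 1,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
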