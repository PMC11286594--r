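# Coregulated gene-network calling: size-factor normalization, variable-gene
# selection by coefficient of variation, per-gene z-scoring, 2-D t-SNE
# embedding of the genes, k-means network calling on the embedding, and
# per-sample network activity (mean expression of member genes).

#' Median-of-ratios size-factor normalization
#'
#' Each sample is divided by its size factor, the median over reference
#' genes of the ratio count / geometric-mean-count. A gene enters the
#' reference set only if its count is positive in every sample; genes with
#' zeros are still rescaled, they just do not vote on the size factors.
#'
#' @param counts an [expression_matrix()] of raw nonnegative counts.
#' @return The normalized [expression_matrix()] (`normalized` flag set);
#'   size factors in attribute `"size_factors"`.
#' @export
size_factor_normalize <- function(counts) {
  m <- unclass(counts)
  log_geo <- rowMeans(log(m))             # -Inf for any gene with a zero
  ref <- is.finite(log_geo)
  if (!any(ref)) {
    ga_stop("NoReferenceGenes", "no gene has a positive count in every sample")
  }
  sf <- apply(m[ref, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_geo[ref]))
  })
  out <- sweep(m, 2L, sf, "/")
  res <- expression_matrix(out, normalized = TRUE)
  attr(res, "size_factors") <- sf
  res
}

# CV = sample sd / mean per gene; mean-zero genes get CV 0.
gene_cv <- function(m, log1p_scale = FALSE) {
  if (log1p_scale) m <- log1p(m)
  mu <- rowMeans(m)
  sds <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu == 0, 0, sds / mu)
  stats::setNames(cv, rownames(m))
}

#' Select highly variable genes by coefficient of variation
#'
#' Genes are ranked by CV = sample sd / mean, descending; exactly
#' `target_count` genes are returned (the paper-style "about 2,000 genes"
#' prefilter is expressed as a count, and the implied CV threshold is
#' reported back). Boundary ties break lexicographically by gene id.
#'
#' @param expr a normalized [expression_matrix()].
#' @param target_count number of genes to keep.
#' @param log1p_scale compute the CV on `log1p` counts instead of the
#'   linear scale.
#' @return List with `genes` (ids, CV-descending) and `cv_threshold`
#'   (CV of the last included gene).
#' @export
select_variable_genes <- function(expr, target_count, log1p_scale = FALSE) {
  m <- unclass(expr)
  if (target_count < 1L || target_count > nrow(m)) {
    ga_stop("TargetExceedsGenes", "target_count %d outside 1..%d",
            target_count, nrow(m))
  }
  cv <- gene_cv(m, log1p_scale)
  ord <- order(-cv, names(cv))
  sel <- ord[seq_len(target_count)]
  list(genes = rownames(m)[sel], cv_threshold = unname(cv[sel[target_count]]))
}

#' Z-score each gene across samples
#'
#' @param expr an [expression_matrix()] (typically restricted to the
#'   selected variable genes).
#' @return An [expression_matrix()] whose rows have mean 0 and sample sd 1.
#' @export
zscore_genes <- function(expr) {
  m <- unclass(expr)
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    ga_stop("ConstantRow", "constant gene row '%s' cannot be z-scored",
            rownames(m)[sds == 0][1L])
  }
  z <- (m - rowMeans(m)) / sds
  # allow negatives: bypass the nonnegativity check of expression_matrix()
  structure(z, normalized = TRUE, class = c("expression_matrix", "ga_matrix"))
}

#' Embed genes in two dimensions with t-SNE
#'
#' Runs exact t-SNE on the gene rows of the z-scored expression matrix
#' (samples are the feature dimensions), with deterministic seeded random
#' initialisation, early exaggeration, and an adaptive-gain gradient
#' descent. At the scale this package targets (a few thousand genes) the
#' exact O(n^2) gradient is used throughout.
#'
#' @param z z-scored [expression_matrix()] (genes x samples).
#' @param perplexity t-SNE perplexity; requires `nrow(z) > 3 * perplexity`.
#' @param seed integer seed for the initial layout.
#' @param max_iter gradient-descent iterations.
#' @param eta learning rate.
#' @param exaggeration,exag_iter early-exaggeration factor and duration.
#' @return A genes x 2 numeric matrix of embedding coordinates.
#' @export
embed_genes <- function(z, perplexity = 30, seed = 0L, max_iter = 500L,
                        eta = 200, exaggeration = 12, exag_iter = 100L) {
  m <- unclass(z)
  n <- nrow(m)
  if (n <= 3 * perplexity) {
    ga_stop("PerplexityTooLarge",
            "perplexity %g needs more than %d genes (have %d)",
            perplexity, ceiling(3 * perplexity), n)
  }
  set.seed(as.integer(seed))
  y0 <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
  y <- .tsne_exact(m, y0, perplexity, as.integer(max_iter), eta,
                   exaggeration, as.integer(exag_iter))
  if (!all(is.finite(y))) {
    ga_stop("EmbeddingDiverged", "t-SNE produced non-finite coordinates")
  }
  dimnames(y) <- list(rownames(m), c("tsne1", "tsne2"))
  y
}

#' Call gene networks by k-means on the embedding
#'
#' Seeded k-means with restarts on the 2-D t-SNE coordinates; the best
#' inertia solution is kept. Labels are renumbered canonically: network 1
#' is the largest, descending by size, size ties broken by the smallest
#' member gene id.
#'
#' @param embedding genes x 2 matrix from [embed_genes()].
#' @param k number of networks.
#' @param seed RNG seed for the restarts.
#' @param n_restarts number of k-means starts.
#' @return Named integer vector of network labels in `1..k`.
#' @export
cluster_genes <- function(embedding, k, seed = 0L, n_restarts = 25L) {
  if (k < 1L || k > nrow(embedding)) {
    ga_stop("KExceedsPoints", "k = %d outside 1..%d", k, nrow(embedding))
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(embedding, centers = k, nstart = n_restarts,
                      iter.max = 200L)
  canonical_labels(stats::setNames(km$cluster, rownames(embedding)), k)
}

# Renumber labels: 1 = largest network, descending; ties by smallest gene id.
canonical_labels <- function(labels, k) {
  sizes <- tabulate(labels, nbins = k)
  first_id <- vapply(seq_len(k), function(j) {
    ids <- names(labels)[labels == j]
    if (length(ids) == 0L) "\uFFFF" else min(ids)
  }, character(1L))
  ord <- order(-sizes, first_id)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  stats::setNames(remap[labels], names(labels))
}

#' Per-sample network activity
#'
#' Activity of a network in a sample is the mean (z-scored) expression of
#' its member genes.
#'
#' @param z z-scored [expression_matrix()] over the clustered genes.
#' @param labels named integer network labels covering every row of `z`.
#' @return networks x samples numeric matrix, rows named `N<id>`.
#' @export
network_activity <- function(z, labels) {
  m <- unclass(z)
  if (is.null(names(labels))) {
    if (length(labels) != nrow(m)) {
      ga_stop("UnlabeledGene", "labels must cover every gene row")
    }
    labels <- stats::setNames(labels, rownames(m))
  }
  if (!all(rownames(m) %in% names(labels))) {
    ga_stop("UnlabeledGene", "gene '%s' has no network label",
            setdiff(rownames(m), names(labels))[1L])
  }
  lab <- labels[rownames(m)]
  ks <- sort(unique(lab))
  if (length(ks) == 0L) ga_stop("EmptyNetwork", "no labels supplied")
  act <- rowsum(m, group = lab) / as.vector(table(lab)[as.character(ks)])
  rownames(act) <- sprintf("N%d", ks)
  act
}

#' Choose k by mean silhouette over a grid
#'
#' Runs [cluster_genes()] for each candidate k and returns the k with the
#' highest mean silhouette width on the embedding (Euclidean distance);
#' ties resolve to the smallest such k. A fixed-k analysis simply bypasses
#' this helper.
#'
#' @param embedding genes x 2 matrix.
#' @param k_grid integer candidates (values < 2 are ignored; a length-1
#'   grid is returned as-is).
#' @param seed RNG seed shared by the k-means runs.
#' @param n_restarts restarts per k.
#' @return The selected integer k.
#' @export
choose_k <- function(embedding, k_grid, seed = 0L, n_restarts = 25L) {
  stopifnot(length(k_grid) >= 1L)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 1L) return(k_grid)
  k_grid <- k_grid[k_grid >= 2L & k_grid <= nrow(embedding) - 1L]
  d <- stats::dist(embedding)
  scores <- vapply(k_grid, function(k) {
    lab <- cluster_genes(embedding, k, seed = seed, n_restarts = n_restarts)
    mean(cluster::silhouette(as.integer(lab), d)[, "sil_width"])
  }, numeric(1L))
  k_grid[which.max(scores)]
}

#' Fit the full gene-network model
#'
#' Convenience wrapper running normalization (if needed), variable-gene
#' selection, z-scoring, embedding, network calling and activity in one
#' call.
#'
#' @param expr an [expression_matrix()]; raw counts are size-factor
#'   normalized first.
#' @param target_count number of variable genes to keep.
#' @param k fixed number of networks, or `NULL` to scan `k_grid`.
#' @param k_grid candidate k values when `k` is `NULL`.
#' @param perplexity,seed,n_restarts,max_iter tuning passed through.
#' @param log1p_scale CV scale option of [select_variable_genes()].
#' @return List of class `"gene_networks"`: `selected_genes`, `cv_threshold`,
#'   `embedding`, `labels`, `activity`, `k`, `z`.
#' @export
fit_gene_networks <- function(expr, target_count = 2000L, k = NULL,
                              k_grid = 2:20, perplexity = 30, seed = 0L,
                              n_restarts = 25L, max_iter = 500L,
                              log1p_scale = FALSE) {
  if (!isTRUE(attr(expr, "normalized"))) {
    expr <- size_factor_normalize(expr)
  }
  sel <- select_variable_genes(expr, target_count, log1p_scale)
  sub <- structure(unclass(expr)[sel$genes, , drop = FALSE],
                   normalized = TRUE,
                   class = c("expression_matrix", "ga_matrix"))
  z <- zscore_genes(sub)
  emb <- embed_genes(z, perplexity = perplexity, seed = seed,
                     max_iter = max_iter)
  if (is.null(k)) k <- choose_k(emb, k_grid, seed = seed,
                                n_restarts = n_restarts)
  labels <- cluster_genes(emb, k, seed = seed, n_restarts = n_restarts)
  act <- network_activity(z, labels)
  structure(list(selected_genes = sel$genes,
                 cv_threshold = sel$cv_threshold,
                 embedding = emb, labels = labels, activity = act,
                 k = as.integer(k), z = z),
            class = "gene_networks")
}

#' @export
print.gene_networks <- function(x, ...) {
  cat(sprintf("gene_networks: %d variable genes (CV threshold %.4f), k = %d\n",
              length(x$selected_genes), x$cv_threshold, x$k))
  cat("network sizes:", paste(table(x$labels), collapse = " "), "\n")
  invisible(x)
}
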