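# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

named_matrix <- function(values, nrow, prefix_r = "g", prefix_c = "s") {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- sprintf("%s%d", prefix_r, seq_len(nrow(m)))
  colnames(m) <- sprintf("%s%d", prefix_c, seq_len(ncol(m)))
  m
}

random_panel <- function(n_proteins, n_samples, seed = 1) {
  set.seed(seed)
  protein_panel(named_matrix(rnorm(n_proteins * n_samples), n_proteins,
                             prefix_r = "P"))
}

# A compact two-axis scenario used by several module tests.
small_scenario <- function(seed = 1, n_samples = 40, loading = 0.85,
                           noise_sd = 0.3, n_modules = 4L,
                           genes_per_module = 30L, n_background = 40L,
                           n_proteins = 30L) {
  strength <- seq(0.9, 0.7, length.out = 5L)
  couplings <- rbind(
    data.frame(protein = 1:5, axis = "MB", rho = -strength),
    data.frame(protein = 1:5, axis = "INF", rho = strength),
    data.frame(protein = 6:10, axis = "MB", rho = strength),
    data.frame(protein = 6:10, axis = "INF", rho = -strength))
  synthetic_config(
    n_samples = n_samples, n_modules = n_modules,
    genes_per_module = genes_per_module, n_background_genes = n_background,
    module_loading = loading,
    axis_map = rep(c("MB", "INF"), length.out = n_modules),
    n_proteins = n_proteins, protein_couplings = couplings,
    clinical_couplings = c(MB = 0.6, INF = -0.6),
    noise_sd = noise_sd, seed = seed)
}

# Independent Spearman oracle: explicit average ranks, explicit Pearson
# moment formula, explicit two-sided t-approximation.
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = n - 2), n_used = n)
}

# Adjusted Rand index over the genes present in both labelings.
ari_vs_truth <- function(labels, truth) {
  gm <- truth$gene_module[names(labels)]
  keep <- !is.na(gm)
  mclust::adjustedRandIndex(gm[keep], labels[keep])
}

# Axis activity computed from the planted module assignments (isolates the
# serum-axis machinery from network recovery, which is tested separately).
truth_axis_table <- function(co) {
  z <- zscore_genes(co$bundle$expression)
  gm <- co$truth$gene_module
  lab <- gm[!is.na(gm)]
  zm <- structure(unclass(z)[names(lab), , drop = FALSE],
                  class = c("expression_matrix", "ga_matrix"))
  axes <- list(MB = unname(which(co$truth$module_axis == "MB")),
               INF = unname(which(co$truth$module_axis == "INF")))
  protein_axis_table(axis_activity(axes, zm, lab), co$bundle$proteins)
}
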