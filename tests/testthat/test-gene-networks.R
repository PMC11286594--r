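test_that("median-of-ratios size factors match the hand-derived toy case", {
  m <- named_matrix(c(2, 4, 8, 16), 2)   # samples (2,4) and (8,16)
  norm <- size_factor_normalize(expression_matrix(m))
  expect_equal(unname(attr(norm, "size_factors")), c(0.5, 2))
  expect_equal(unclass(norm)[, "s1"], c(g1 = 4, g2 = 8))
  expect_equal(unclass(norm)[, "s2"], c(g1 = 4, g2 = 8))
  expect_true(attr(norm, "normalized"))
})

test_that("identical samples give unit size factors and an unchanged matrix", {
  m <- named_matrix(rep(c(3, 7, 11), 2), 3)
  norm <- size_factor_normalize(expression_matrix(m))
  expect_equal(unname(attr(norm, "size_factors")), c(1, 1))
  expect_equal(unclass(norm)[, ], m)
})

test_that("a gene with a zero is dropped from the reference set but rescaled", {
  m <- named_matrix(c(2, 4, 0, 8, 16, 5), 3)  # g3 has a zero in sample 1
  norm <- size_factor_normalize(expression_matrix(m))
  # size factors from g1, g2 only: geometric means (4, 8), medians (0.5, 2)
  expect_equal(unname(attr(norm, "size_factors")), c(0.5, 2))
  expect_equal(unclass(norm)["g3", ], c(s1 = 0, s2 = 2.5))
  # all-zero reference set errors
  z <- named_matrix(c(0, 1, 2, 0), 2)
  expect_error(size_factor_normalize(expression_matrix(z)),
               class = "NoReferenceGenes")
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  set.seed(77)
  m <- named_matrix(rpois(200, lambda = 50) + 1, 20)
  sf <- attr(size_factor_normalize(expression_matrix(m)), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("CV gene selection ranks, thresholds and tie-breaks as documented", {
  m <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3), g3 = c(0, 10, 20))
  colnames(m) <- c("s1", "s2", "s3")
  em <- expression_matrix(m, normalized = TRUE)
  sel <- select_variable_genes(em, 2L)
  expect_identical(sel$genes, c("g3", "g2"))   # CVs 1.0, 0.5, 0
  expect_equal(sel$cv_threshold, 0.5)
  # a constant gene is never selected while a varying one is available
  expect_false("g1" %in% select_variable_genes(em, 2L)$genes)
  expect_error(select_variable_genes(em, 4L), class = "TargetExceedsGenes")
  # invariance to sample column order
  perm <- expression_matrix(m[, c(3, 1, 2)], normalized = TRUE)
  expect_identical(select_variable_genes(perm, 2L), sel)
  # boundary ties resolve lexicographically by gene id
  tie <- expression_matrix(rbind(b = c(1, 2, 3), a = c(2, 4, 6),
                                 c = c(5, 5, 5)) |>
                             (\(x) { colnames(x) <- c("s1", "s2", "s3"); x })(),
                           normalized = TRUE)
  expect_identical(select_variable_genes(tie, 1L)$genes, "a")
})

test_that("z-scoring centers, scales, idempotes, and rejects constant rows", {
  m <- named_matrix(c(1, 4, 2, 4, 3, 4), 2)
  expect_error(zscore_genes(expression_matrix(m, normalized = TRUE)),
               class = "ConstantRow")
  m2 <- named_matrix(c(1, 5, 2, 7, 3, 9), 2)
  z <- zscore_genes(expression_matrix(m2, normalized = TRUE))
  expect_equal(unclass(z)["g1", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unname(rowMeans(unclass(z))), c(0, 0))
  expect_equal(unname(apply(unclass(z), 1, sd)), c(1, 1))
  expect_equal(unclass(zscore_genes(z))[, ], unclass(z)[, ],
               tolerance = 1e-10)
})

test_that("t-SNE embedding is finite, deterministic, and separates planted modules", {
  cfg <- synthetic_config(n_samples = 25, n_modules = 2,
                          genes_per_module = 40, module_loading = 0.95,
                          axis_map = c("MB", "INF"), noise_sd = 0.1,
                          n_proteins = 0L, seed = 3)
  co <- generate_cohort(cfg)
  z <- zscore_genes(co$bundle$expression)
  emb <- embed_genes(z, perplexity = 10, seed = 0, max_iter = 300)
  expect_identical(dim(emb), c(80L, 2L))
  expect_true(all(is.finite(emb)))
  expect_identical(embed_genes(z, perplexity = 10, seed = 0,
                               max_iter = 300), emb)
  truth_lab <- co$truth$gene_module[rownames(emb)]
  sil <- cluster::silhouette(truth_lab, dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0)
  expect_error(embed_genes(z, perplexity = 30), class = "PerplexityTooLarge")
})

test_that("k-means network calling recovers planted blobs with canonical numbering", {
  set.seed(1)
  blob1 <- cbind(rnorm(30, 0, 0.2), rnorm(30, 0, 0.2))
  blob2 <- cbind(rnorm(10, 8, 0.2), rnorm(10, 8, 0.2))
  emb <- rbind(blob1, blob2)
  rownames(emb) <- sprintf("g%02d", seq_len(40))
  lab <- cluster_genes(emb, k = 2, seed = 0)
  # canonical: network 1 is the larger blob
  expect_identical(unname(lab[1:30]), rep(1L, 30))
  expect_identical(unname(lab[31:40]), rep(2L, 10))
  expect_identical(unname(cluster_genes(emb, k = 1, seed = 0)), rep(1L, 40))
  expect_error(cluster_genes(emb, k = 41, seed = 0),
               class = "KExceedsPoints")
})

test_that("network activity is the member mean and merges size-weightedly", {
  z <- rbind(a = c(1, -1, 0), b = c(-1, 1, 0), c = c(2, 2, 2),
             d = c(0, 4, 2))
  colnames(z) <- c("s1", "s2", "s3")
  zx <- structure(z, class = c("expression_matrix", "ga_matrix"))
  lab <- c(a = 1L, b = 1L, c = 2L, d = 3L)
  act <- network_activity(zx, lab)
  expect_equal(act["N1", ], c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(act["N2", ], c(s1 = 2, s2 = 2, s3 = 2))   # single-gene row
  # permutation invariance
  zp <- structure(z[c(3, 1, 4, 2), ],
                  class = c("expression_matrix", "ga_matrix"))
  expect_equal(network_activity(zp, lab), act)
  # merging networks 1 and 2 gives the size-weighted mean of activities
  lab_m <- c(a = 1L, b = 1L, c = 1L, d = 3L)
  merged <- network_activity(zx, lab_m)
  expect_equal(merged["N1", ], (2 * act["N1", ] + 1 * act["N2", ]) / 3)
  expect_error(network_activity(zx, c(a = 1L, b = 1L, c = 2L)),
               class = "UnlabeledGene")
})

test_that("silhouette scan recovers the planted number of blobs", {
  set.seed(7)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  emb <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(25, centers[i, 1], 0.3), rnorm(25, centers[i, 2], 0.3))
  }))
  rownames(emb) <- sprintf("g%02d", seq_len(75))
  expect_identical(choose_k(emb, 2:6, seed = 0), 3L)
  expect_identical(choose_k(emb, 2L, seed = 0), 2L)
})

test_that("full network fit recovers planted modules on a two-axis cohort", {
  aris <- vapply(1:3, function(s) {
    co <- generate_cohort(small_scenario(seed = 20 + s, loading = 0.85,
                                         noise_sd = 0.3))
    nets <- fit_gene_networks(co$bundle$expression, target_count = 130L,
                              k = 4L, perplexity = 10, max_iter = 300L)
    ari_vs_truth(nets$labels, co$truth)
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})
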