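test_that("spearman matches hand-derived values and handles the edge cases", {
  # ranks of y are (1,2,3,5,4): sum d^2 = 2, rho = 1 - 12/120 = 0.9
  res <- spearman(1:5, c(5, 6, 7, 9, 8))
  expect_equal(res$rho, 0.9)
  expect_identical(res$n_used, 5L)
  expect_equal(spearman(1:6, (1:6)^3)$rho, 1)            # monotone, no ties
  expect_equal(spearman(1:6, rev(1:6))$rho, -1)          # antisymmetry
  expect_gt(spearman(1:6, (1:6)^3)$p, 0)                 # p stays positive
  # pairwise deletion of missing values
  res_na <- spearman(c(1, 2, NA, 4, 5), c(2, 4, 9, 8, 10))
  expect_identical(res_na$n_used, 4L)
  expect_equal(res_na$rho, 1)
  expect_error(spearman(c(1, 2, NA, NA), c(1, NA, 2, 3)),
               class = "TooFewPairs")
  expect_error(spearman(rep(1, 5), 1:5), class = "TooFewPairs")
})

test_that("spearman agrees with the t-approximation of cor.test, with ties", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, sd = 0.01)
    y <- sample(1:6, n, replace = TRUE)
    mine <- spearman(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("activity-protein correlation matrices and leaf orders are reproducible", {
  set.seed(21)
  act <- named_matrix(rnorm(40), 4, prefix_r = "N")
  pm <- named_matrix(rnorm(60), 6, prefix_r = "P")
  pm["P1", ] <- act["N2", ]                  # protein equal to an activity row
  co <- correlate_activity_proteins(act, protein_panel(pm))
  expect_equal(co$rho["N2", "P1"], 1)
  expect_identical(dim(co$rho), c(4L, 6L))
  expect_true(all(co$rho >= -1 & co$rho <= 1))
  expect_true(all(co$p > 0 & co$p <= 1))
  expect_true(all(co$n == 10L))
  co2 <- correlate_activity_proteins(act, protein_panel(pm))
  expect_identical(co$row_order, co2$row_order)
  expect_identical(co$col_order, co2$col_order)
})

test_that("complete-linkage merge order on three proteins matches the hand-derived dendrogram", {
  pm <- rbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(1, 3, 2, 4))
  colnames(pm) <- sprintf("s%d", 1:4)
  # pairwise Spearman: AB = -1, AC = 0.8, BC = -0.8 -> distances 2, 0.2, 1.8
  rho <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    spearman(pm[ij[1], ], pm[ij[2], ])$rho
  })
  expect_equal(rho, c(-1, 0.8, -0.8))
  hc <- hclust(as.dist(1 - cor(apply(pm, 1, rank))), method = "complete")
  # A and C merge first (distance 0.2), B joins last at height 2
  expect_identical(sort(hc$merge[1, ]), c(-3L, -1L))
  expect_identical(hc$merge[2, ], c(-2L, 1L))
  expect_equal(hc$height, c(0.2, 2))
  # the package's leaf order keeps A and C adjacent
  act <- named_matrix(rnorm(8), 2, prefix_r = "N")
  co <- correlate_activity_proteins(act, protein_panel(pm))
  ord <- rownames(pm)[co$col_order]
  expect_equal(abs(diff(match(c("A", "C"), ord))), 1)
})

test_that("axis activity is the gene-weighted mean over member networks", {
  z <- rbind(g1 = c(2, 0, -2), g2 = c(1, 1, 1), g3 = c(0, 3, 0),
             g4 = c(-1, 2, 5))
  colnames(z) <- c("s1", "s2", "s3")
  zx <- structure(z, class = c("expression_matrix", "ga_matrix"))
  lab <- c(g1 = 1L, g2 = 2L, g3 = 2L, g4 = 2L)
  act <- network_activity(zx, lab)
  ax <- axis_activity(list(MB = c(1L, 2L)), zx, lab)
  # gene-weighted: (1/4) g1 + (3/4) mean(g2..g4), not the network mean
  expect_equal(ax["MB", ], colMeans(z))
  expect_false(isTRUE(all.equal(ax["MB", ],
                                colMeans(act[c("N1", "N2"), ]))))
  # a one-network axis equals that network's activity row
  expect_equal(axis_activity(list(INF = 2L), zx, lab)["INF", ], act["N2", ])
  # two disjoint axes give two rows; unknown ids and overlaps error
  both <- axis_activity(list(MB = 1L, INF = 2L), zx, lab)
  expect_identical(rownames(both), c("MB", "INF"))
  expect_error(axis_activity(list(MB = 7L), zx, lab),
               class = "UnknownNetworkId")
  expect_error(axis_activity(list(MB = 1L, INF = c(1L, 2L)), zx, lab),
               class = "UnknownNetworkId")
})

test_that("signature extraction filters, ranks and unions as documented", {
  tbl <- data.frame(
    protein = c("P1", "P2", "P3", "P4"),
    rho_MB = c(-0.9, -0.2, 0.9, 0.1),
    p_MB = c(0.01, 0.5, 0.01, 0.5),
    rho_INF = c(0.8, 0.7, -0.85, 0.1),
    p_INF = c(0.01, 0.01, 0.01, 0.5))
  class(tbl) <- c("protein_axis_table", "data.frame")
  inj <- extract_signature(tbl, "INJURY", rho_min = 0.6, p_max = 0.05, k = 2)
  expect_identical(inj$protein, c("P1", "P2"))
  expect_equal(inj$rank_stat, c(0.9, 0.7))
  hea <- extract_signature(tbl, "HEALTH", rho_min = 0.6, p_max = 0.05, k = 2)
  expect_identical(hea$protein, "P3")
  # single-axis categories
  expect_identical(extract_signature(tbl, "MB_down")$protein, "P1")
  expect_identical(extract_signature(tbl, "INF_up")$protein, c("P1", "P2"))
  # no protein passes -> empty signature
  none <- extract_signature(tbl, "INJURY", rho_min = 0.95)
  expect_identical(nrow(none), 0L)
  # HEALTH and INJURY membership is disjoint here
  expect_length(intersect(inj$protein, hea$protein), 0L)
})

test_that("mutually exclusive up/down categories never share a protein", {
  set.seed(33)
  for (i in 1:10) {
    act <- named_matrix(rnorm(30), 2, prefix_r = "X")
    rownames(act) <- c("MB", "INF")
    pm <- random_panel(12, 15, seed = 100 + i)
    tbl <- protein_axis_table(act, pm)
    up <- extract_signature(tbl, "MB_up", rho_min = 0.1, p_max = 0.9, k = 12)
    dn <- extract_signature(tbl, "MB_down", rho_min = 0.1, p_max = 0.9, k = 12)
    expect_length(intersect(up$protein, dn$protein), 0L)
  }
})

test_that("a planted protein recovers its coupling against true-axis activity", {
  cfg <- small_scenario(seed = 12, n_samples = 500)
  co <- generate_cohort(cfg)
  z <- zscore_genes(co$bundle$expression)
  gm <- co$truth$gene_module
  lab <- gm[!is.na(gm)]
  axes <- list(MB = which(co$truth$module_axis == "MB"),
               INF = which(co$truth$module_axis == "INF"))
  zm <- structure(unclass(z)[names(lab), ],
                  class = c("expression_matrix", "ga_matrix"))
  ax <- axis_activity(axes, zm, lab)
  tbl <- protein_axis_table(ax, co$bundle$proteins)
  # PRT001 planted at Spearman +0.9 to INF (attenuated by activity noise)
  expect_gt(tbl$rho_INF[tbl$protein == "PRT001"], 0.7)
  expect_lt(tbl$rho_MB[tbl$protein == "PRT001"], -0.6)
  # an uncoupled protein stays quiet
  expect_lt(abs(tbl$rho_INF[tbl$protein == "PRT020"]), 0.25)
})

test_that("planted INJURY proteins dominate the extracted top signature", {
  hits <- vapply(1:3, function(s) {
    co <- generate_cohort(small_scenario(seed = 40 + s, n_samples = 200))
    z <- zscore_genes(co$bundle$expression)
    gm <- co$truth$gene_module
    lab <- gm[!is.na(gm)]
    zm <- structure(unclass(z)[names(lab), ],
                    class = c("expression_matrix", "ga_matrix"))
    axes <- list(MB = unname(which(co$truth$module_axis == "MB")),
                 INF = unname(which(co$truth$module_axis == "INF")))
    ax <- axis_activity(axes, zm, lab)
    tbl <- protein_axis_table(ax, co$bundle$proteins)
    sig <- extract_signature(tbl, "INJURY", k = 5)
    length(intersect(sig$protein, sprintf("PRT%03d", 1:5)))
  }, numeric(1))
  expect_gte(median(hits), 4)
})
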