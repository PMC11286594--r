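test_that("intrasignature correlation is the off-diagonal mean of pairwise rho", {
  pm <- rbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(1, 3, 2, 4))
  colnames(pm) <- sprintf("s%d", 1:4)
  panel <- protein_panel(pm)
  # pairwise rhos: AB = -1, AC = 0.8, BC = -0.8 -> mean -1/3
  expect_equal(intrasignature_correlation(panel, c("A", "B", "C")), -1 / 3)
  expect_equal(intrasignature_correlation(panel, c("C", "A", "B")), -1 / 3)
  # two identical profiles
  pm2 <- rbind(pm, D = c(2, 4, 6, 8))
  panel2 <- protein_panel(pm2)
  expect_equal(intrasignature_correlation(panel2, c("A", "D")), 1)
  expect_error(intrasignature_correlation(panel, c("A", "Z")),
               class = "UnknownProtein")
  expect_error(intrasignature_correlation(panel, "A"),
               class = "TooFewMembers")
})

test_that("random-set null is seeded, sized, and degenerates without sampling freedom", {
  panel <- random_panel(20, 12, seed = 5)
  a <- random_set_null(panel, set_size = 5, n_sets = 10, seed = 3)
  b <- random_set_null(panel, set_size = 5, n_sets = 10, seed = 3)
  expect_identical(a, b)
  expect_length(a, 10L)
  expect_false(identical(a, random_set_null(panel, 5, 10, seed = 4)))
  # full panel, one set: no sampling freedom, equals the panel-wide mean
  full <- random_set_null(panel, set_size = 20, n_sets = 1, seed = 1)
  expect_equal(full, intrasignature_correlation(panel, rownames(panel)))
  expect_error(random_set_null(panel, set_size = 21, n_sets = 1, seed = 1),
               class = "InsufficientProteins")
  expect_error(random_set_null(panel, set_size = 20, n_sets = 1, seed = 1,
                               exclude = "P1"),
               class = "InsufficientProteins")
})

test_that("null distribution mean tracks the panel-wide mean pairwise correlation", {
  panel <- random_panel(30, 40, seed = 8)
  nulls <- random_set_null(panel, set_size = 10, n_sets = 100, seed = 2)
  expect_lt(abs(mean(nulls) -
                  intrasignature_correlation(panel, rownames(panel))), 0.05)
  expect_true(all(nulls >= -1 & nulls <= 1))
})

test_that("signature scores average member proteins and ignore the rest", {
  pm <- rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(100, 100, 100))
  colnames(pm) <- sprintf("s%d", 1:3)
  panel <- protein_panel(pm)
  expect_equal(signature_score(panel, c("A", "B")),
               c(s1 = 2, s2 = 2, s3 = 2))
  expect_equal(signature_score(panel, "A"), c(s1 = 1, s2 = 2, s3 = 3))
  expect_error(signature_score(panel, c("A", "nope")),
               class = "UnknownProtein")
})

test_that("clinical association reports rho, regression line and missing-data status", {
  set.seed(6)
  clin <- clinical_table(data.frame(
    sample_id = sprintf("s%d", 1:10),
    egfr = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
    creatinine = rnorm(10, 2), proteinuria = rep(NA_real_, 10),
    days_posttransplant = c(1:5, NA, 7:10)))
  score <- setNames(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100) / 10,
                    sprintf("s%d", 1:10))
  ca <- clinical_association(score, clin)
  expect_equal(ca$rho[ca$variable == "egfr"], 1)
  expect_equal(ca$slope[ca$variable == "egfr"], 10)
  expect_equal(ca$intercept[ca$variable == "egfr"], 0)
  expect_identical(ca$status[ca$variable == "proteinuria"], "too_few_pairs")
  expect_identical(ca$n_used[ca$variable == "days_posttransplant"], 9L)
  expect_error(clinical_association(score, clin, "missing_var"),
               class = "UnknownClinicalVariable")
})

test_that("injury score tracks kidney function with the planted sign", {
  signs <- vapply(1:10, function(s) {
    co <- generate_cohort(small_scenario(seed = 300 + s, n_samples = 200))
    score <- signature_score(co$bundle$proteins, sprintf("PRT%03d", 1:5))
    ca <- clinical_association(score, co$bundle$clinical, "egfr")
    ca$rho[1]
  }, numeric(1))
  expect_gte(sum(signs < 0), 9)
})

test_that("validation report assembles truncations, null rule and serialization", {
  co <- generate_cohort(small_scenario(seed = 77, n_samples = 40))
  planted <- sprintf("PRT%03d", 1:5)
  rep_ <- validate_signature(co$bundle$proteins, planted,
                             clinical = co$bundle$clinical,
                             n_sets = 10, truncations = c(3, 5, 10),
                             seed = 1, leave_one_out = TRUE)
  expect_named(rep_$truncations, c("top_3", "top_5"))
  tr <- rep_$truncations$top_5
  expect_length(tr$null_rhos, 10L)
  expect_true(tr$intra_rho >= -1 && tr$intra_rho <= 1)
  expect_identical(tr$exceeds_null, tr$intra_rho > max(tr$null_rhos))
  expect_identical(tr$members, planted)
  expect_length(tr$leave_one_out, 5L)
  expect_s3_class(tr$clinical_assocs, "data.frame")
  # percentile rule is the alternative comparison
  rep2 <- validate_signature(co$bundle$proteins, planted, n_sets = 20,
                             truncations = 5, null_rule = "percentile_95",
                             seed = 1)
  tr2 <- rep2$truncations$top_5
  expect_identical(tr2$exceeds_null,
                   tr2$intra_rho > quantile(tr2$null_rhos, 0.95,
                                            names = FALSE))
  # JSON round trip preserves the numbers
  f <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep_, f)
  back <- read_validation_report(f)
  expect_equal(back$truncations$top_5$intra_rho, tr$intra_rho)
  expect_equal(back$truncations$top_5$null_rhos, tr$null_rhos)
  expect_identical(back$truncations$top_5$exceeds_null, tr$exceeds_null)
})

test_that("truncation of a rank-decreasing planted signature is monotone in cohesion", {
  co <- generate_cohort(small_scenario(seed = 55, n_samples = 200))
  panel <- co$bundle$proteins
  planted <- sprintf("PRT%03d", 1:5)   # couplings 0.9 down to 0.7
  top2 <- intrasignature_correlation(panel, planted[1:2])
  top3 <- intrasignature_correlation(panel, planted[1:3])
  top5 <- intrasignature_correlation(panel, planted)
  expect_gte(top2, top3 - 0.02)
  expect_gte(top3, top5 - 0.02)
  expect_gt(top5, 0.3)
})
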