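# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: coregulated gene modules driven by latent axis factors
# (metabolism MB vs inflammation INF, anti-correlated; ECM and axis-free
# modules independent), serum proteins coupled to the axis factors with a
# configurable target Spearman correlation (Gaussian copula), and clinical
# kidney function coupled to the same factors.

#' Build and validate a synthetic cohort configuration
#'
#' @param n_samples number of patients.
#' @param n_modules number of coregulated gene modules.
#' @param genes_per_module member genes per module.
#' @param n_background_genes genes with no module (pure noise).
#' @param module_loading loading of member genes on their module factor,
#'   in (0, 1].
#' @param axis_map character vector of length `n_modules` over
#'   `{"MB","INF","ECM","none"}`, assigning each module to an axis.
#' @param axis_weight share of module-factor variance carried by the axis
#'   factor, in [0, 1); same-axis module factors correlate at this value.
#' @param factor_correlation correlation of the MB and INF latent factors,
#'   in [-1, 0] (the axes oppose each other).
#' @param n_proteins panel size.
#' @param protein_couplings data.frame with columns `protein` (index in
#'   1..n_proteins), `axis` (`"MB"`/`"INF"`/`"ECM"`), `rho` (target Spearman
#'   in [-1, 1]). A protein may appear once per axis (dual coupling).
#' @param clinical_couplings named numeric, target Spearman of egfr with the
#'   axis factors, e.g. `c(MB = 0.6, INF = -0.6)`.
#' @param noise_sd sd of the per-gene noise added to the loading-weighted
#'   module factor.
#' @param lognormal_scale scale applied to the latent gene value before
#'   exponentiation into count space.
#' @param seed integer master seed; sub-streams are derived per component so
#'   that e.g. changing `n_proteins` does not perturb the gene data.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_samples,
                             n_modules,
                             genes_per_module,
                             n_background_genes = 0L,
                             module_loading = 0.85,
                             axis_map = rep("none", n_modules),
                             axis_weight = 0.5,
                             factor_correlation = -0.7,
                             n_proteins = 0L,
                             protein_couplings = NULL,
                             clinical_couplings = c(MB = 0, INF = 0),
                             noise_sd = 0.3,
                             lognormal_scale = 0.7,
                             seed = 1L) {
  stopifnot(n_samples >= 2L, n_modules >= 1L, genes_per_module >= 1L,
            n_background_genes >= 0L,
            module_loading > 0, module_loading <= 1,
            length(axis_map) == n_modules,
            all(axis_map %in% c("MB", "INF", "ECM", "none")),
            axis_weight >= 0, axis_weight < 1,
            factor_correlation >= -1, factor_correlation <= 0,
            noise_sd > 0, lognormal_scale > 0)
  if (!is.null(protein_couplings)) {
    stopifnot(is.data.frame(protein_couplings),
              all(c("protein", "axis", "rho") %in% names(protein_couplings)),
              all(protein_couplings$protein >= 1L),
              all(protein_couplings$protein <= n_proteins),
              all(protein_couplings$axis %in% c("MB", "INF", "ECM")),
              all(abs(protein_couplings$rho) <= 1))
    if (anyDuplicated(protein_couplings[, c("protein", "axis")])) {
      ga_stop("InfeasibleCoupling",
              "a protein is coupled twice to the same axis")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 n_background_genes = as.integer(n_background_genes),
                 module_loading = module_loading,
                 axis_map = axis_map,
                 axis_weight = axis_weight,
                 factor_correlation = factor_correlation,
                 n_proteins = as.integer(n_proteins),
                 protein_couplings = protein_couplings,
                 clinical_couplings = clinical_couplings,
                 noise_sd = noise_sd,
                 lognormal_scale = lognormal_scale,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Spearman target -> Pearson parameter of the Gaussian copula.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Coefficients (a, b) so that z = a*MB + b*INF + resid has the requested
# Pearson correlations with the two axis factors (correlation c between
# them). Errors if the residual variance would be negative.
dual_coupling_coefs <- function(r_mb, r_inf, c, label = "variable") {
  denom <- 1 - c^2
  if (denom < .Machine$double.eps) {
    ga_stop("InfeasibleCoupling", "axis factors are perfectly correlated")
  }
  a <- (r_mb - c * r_inf) / denom
  b <- (r_inf - c * r_mb) / denom
  expl <- a * r_mb + b * r_inf
  if (expl > 1 + 1e-12) {
    ga_stop("InfeasibleCoupling",
            "joint coupling of %s (r_MB=%.3f, r_INF=%.3f at c=%.2f) is unsatisfiable",
            label, r_mb, r_inf, c)
  }
  c(a = a, b = b, resid_sd = sqrt(max(0, 1 - expl)))
}

# Derived sub-stream seeds keep the components independent of each other.
substream_seed <- function(seed, offset) (seed * 7L + offset) %% 2147483647L

#' Generate a synthetic cohort with ground truth
#'
#' Latent construction: `(MB, INF)` are standard bivariate normal with the
#' configured (negative) correlation; ECM is independent. Each module factor
#' is `sqrt(w) * axis + sqrt(1-w) * u_m` with a module-specific standard
#' normal `u_m` (`w = axis_weight`; axis-free modules use `u_m` alone).
#' Member-gene latents are `loading * factor + noise_sd * eps`; counts are
#' `exp(log_baseline + lognormal_scale * latent)` so that the matrix looks
#' like normalized RNA-seq counts and CV filtering behaves realistically.
#' Proteins and egfr reach their target Spearman correlation with the axis
#' factors through a Gaussian copula (Pearson parameter `2*sin(pi*rho/6)`).
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `bundle` (a [cohort_bundle()], expression
#'   flagged as normalized counts) and `truth` (gene->module, module->axis,
#'   protein couplings, latent factor matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  c_mbinf <- config$factor_correlation
  w <- config$axis_weight

  ## --- latent factors -----------------------------------------------------
  set.seed(substream_seed(config$seed, 101L))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
  mb <- z1
  inf <- c_mbinf * z1 + sqrt(1 - c_mbinf^2) * z2
  ecm <- z3
  axis_factors <- rbind(MB = mb, INF = inf, ECM = ecm)
  u <- matrix(stats::rnorm(config$n_modules * n), config$n_modules, n)
  module_factors <- matrix(0, config$n_modules, n)
  for (m in seq_len(config$n_modules)) {
    ax <- config$axis_map[m]
    module_factors[m, ] <- if (ax == "none") u[m, ] else
      sqrt(w) * axis_factors[ax, ] + sqrt(1 - w) * u[m, ]
  }
  rownames(module_factors) <- sprintf("M%02d", seq_len(config$n_modules))

  ## --- genes --------------------------------------------------------------
  set.seed(substream_seed(config$seed, 211L))
  n_member <- config$n_modules * config$genes_per_module
  n_genes <- n_member + config$n_background_genes
  gene_module <- c(rep(seq_len(config$n_modules),
                       each = config$genes_per_module),
                   rep(NA_integer_, config$n_background_genes))
  gene_ids <- c(sprintf("G%02d_%03d",
                        rep(seq_len(config$n_modules),
                            each = config$genes_per_module),
                        rep(seq_len(config$genes_per_module),
                            times = config$n_modules)),
                sprintf("BG%04d", seq_len(config$n_background_genes)))
  log_base <- stats::runif(n_genes, log(50), log(2000))
  latent <- matrix(stats::rnorm(n_genes * n, sd = config$noise_sd), n_genes, n)
  member <- !is.na(gene_module)
  latent[member, ] <- latent[member, ] +
    config$module_loading * module_factors[gene_module[member], , drop = FALSE]
  counts <- exp(log_base + config$lognormal_scale * latent)
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids

  ## --- proteins -----------------------------------------------------------
  panel <- NULL
  coupling_truth <- NULL
  if (config$n_proteins >= 2L) {
    set.seed(substream_seed(config$seed, 307L))
    prot_ids <- sprintf("PRT%03d", seq_len(config$n_proteins))
    pc <- config$protein_couplings
    z <- matrix(stats::rnorm(config$n_proteins * n), config$n_proteins, n)
    if (!is.null(pc) && nrow(pc) > 0L) {
      for (p in unique(pc$protein)) {
        rows <- pc[pc$protein == p, , drop = FALSE]
        r <- stats::setNames(rep(0, 3), c("MB", "INF", "ECM"))
        r[rows$axis] <- spearman_to_pearson(rows$rho)
        if (r[["ECM"]] != 0 && (r[["MB"]] != 0 || r[["INF"]] != 0)) {
          ga_stop("InfeasibleCoupling",
                  "protein %d couples ECM together with MB/INF", p)
        }
        if (r[["ECM"]] != 0) {
          z[p, ] <- r[["ECM"]] * ecm + sqrt(1 - r[["ECM"]]^2) * z[p, ]
        } else if (nrow(rows) == 1L) {
          # single-axis coupling: plain copula on that factor; the induced
          # correlation with the opposing axis (r * c) is left free
          g <- if (rows$axis == "MB") mb else inf
          rp <- spearman_to_pearson(rows$rho)
          z[p, ] <- rp * g + sqrt(1 - rp^2) * z[p, ]
        } else {
          cf <- dual_coupling_coefs(r[["MB"]], r[["INF"]], c_mbinf,
                                    label = sprintf("protein %d", p))
          z[p, ] <- cf["a"] * mb + cf["b"] * inf + cf["resid_sd"] * z[p, ]
        }
      }
      coupling_truth <- data.frame(protein = prot_ids[pc$protein],
                                   axis = pc$axis, rho = pc$rho,
                                   stringsAsFactors = FALSE)
    }
    npx <- z + 5  # NPX-like offset; relative log-scale units
    rownames(npx) <- prot_ids
    colnames(npx) <- sample_ids
    panel <- protein_panel(npx)
  }

  ## --- clinical -----------------------------------------------------------
  set.seed(substream_seed(config$seed, 401L))
  cc <- config$clinical_couplings
  r_e <- spearman_to_pearson(c(cc[["MB"]], cc[["INF"]]))
  cf_e <- dual_coupling_coefs(r_e[1L], r_e[2L], c_mbinf, label = "egfr")
  z_e <- cf_e["a"] * mb + cf_e["b"] * inf + cf_e["resid_sd"] * stats::rnorm(n)
  egfr <- 15 + 35 * exp(0.5 * z_e)           # monotone: Spearman preserved
  creat <- exp(0.3 - 0.35 * z_e + 0.25 * stats::rnorm(n))
  clin <- clinical_table(data.frame(
    sample_id = sample_ids,
    days_posttransplant = as.integer(round(exp(6 + stats::rnorm(n)))),
    creatinine = round(creat, 2),
    creatinine_increase = round(pmax(0, creat - 1 +
                                       0.2 * stats::rnorm(n)), 2),
    egfr = round(egfr, 1),
    proteinuria = round(exp(5 + stats::rnorm(n)), 0),
    diagnosis = ifelse(inf > 0, "rejection", "nonrejection"),
    stringsAsFactors = FALSE))

  expr <- expression_matrix(counts, normalized = TRUE)
  bundle <- if (is.null(panel)) {
    structure(list(expression = expr, proteins = NULL, clinical = clin,
                   provenance = "synthetic"), class = "cohort_bundle")
  } else {
    cohort_bundle(expr, panel, clin, provenance = "synthetic")
  }
  truth <- list(
    gene_module = stats::setNames(gene_module, gene_ids),
    module_axis = stats::setNames(config$axis_map,
                                  rownames(module_factors)),
    protein_coupling = coupling_truth,
    factors = rbind(axis_factors, module_factors))
  colnames(truth$factors) <- sample_ids
  list(bundle = bundle, truth = truth)
}

#' Reference synthetic scenario mirroring the study dimensions
#'
#' 15 samples; 15 modules of 130 genes (4 metabolic, 8 inflammatory, 2 ECM,
#' 1 axis-free) plus background noise genes up to 2,600 in total; 159 serum
#' proteins of which 10 are INJURY-like (coupled negatively to MB and
#' positively to INF, target |Spearman| decreasing 0.9 to 0.7 with rank) and
#' 10 HEALTH-like (mirrored signs); egfr coupled +0.6 to MB and -0.6 to INF.
#'
#' @param n_samples optional override of the cohort size (default 15).
#' @param seed master seed.
#' @return A [synthetic_config()].
#' @export
reference_scenario <- function(n_samples = 15L, seed = 1L) {
  axis_map <- c("MB", "MB", "MB", "MB",
                "INF", "INF", "INF", "INF", "INF", "INF", "INF", "INF",
                "ECM", "ECM", "none")
  strength <- seq(0.9, 0.7, length.out = 10L)
  injury <- data.frame(protein = 1:10,
                       mb = -strength, inf = strength)
  health <- data.frame(protein = 11:20,
                       mb = strength, inf = -strength)
  both <- rbind(injury, health)
  couplings <- rbind(
    data.frame(protein = both$protein, axis = "MB", rho = both$mb),
    data.frame(protein = both$protein, axis = "INF", rho = both$inf))
  synthetic_config(
    n_samples = n_samples,
    n_modules = 15L,
    genes_per_module = 130L,
    n_background_genes = 650L,
    module_loading = 0.85,
    axis_map = axis_map,
    axis_weight = 0.5,
    factor_correlation = -0.7,
    n_proteins = 159L,
    protein_couplings = couplings,
    clinical_couplings = c(MB = 0.6, INF = -0.6),
    noise_sd = 0.3,
    lognormal_scale = 0.7,
    seed = seed)
}

#' Planted signature protein ids of the reference scenario
#'
#' @param category `"INJURY"` or `"HEALTH"`.
#' @return Character vector of 10 protein ids, strongest coupling first.
#' @export
reference_planted <- function(category = c("INJURY", "HEALTH")) {
  category <- match.arg(category)
  idx <- if (category == "INJURY") 1:10 else 11:20
  sprintf("PRT%03d", idx)
}

#' Write a generated cohort (and its ground truth) as TSV files
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             proteins = file.path(dir, "proteins.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth_genes = file.path(dir, "truth_gene_module.tsv"),
             truth_proteins = file.path(dir, "truth_protein_coupling.tsv"))
  write_matrix(cohort$bundle$expression, paths["expression"], "gene_id")
  if (!is.null(cohort$bundle$proteins)) {
    write_matrix(cohort$bundle$proteins, paths["proteins"], "protein_id")
  }
  write_clinical(cohort$bundle$clinical, paths["clinical"])
  gm <- cohort$truth$gene_module
  utils::write.table(
    data.frame(gene_id = names(gm), module = unname(gm),
               axis = ifelse(is.na(gm), NA,
                             unname(cohort$truth$module_axis[gm]))),
    paths["truth_genes"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth$protein_coupling)) {
    utils::write.table(cohort$truth$protein_coupling, paths["truth_proteins"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
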