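# End-to-end orchestration: simulate or load a cohort, fit the model,
# optionally compare against a second cohort, validate signatures, and
# write every artifact with a manifest.

#' Run the full serum-allograft analysis pipeline
#'
#' Stages, in order: cohort input (synthetic generation or delimited-file
#' loading), gene-network fit, optional cross-cohort correspondence,
#' axis/signature extraction, signature validation. All artifacts are
#' written to `out_dir` as TSV plus a JSON run report; a manifest records
#' the configuration, seeds and input hashes so a run can be reproduced
#' bit-identically.
#'
#' @param config list. Either `synthetic = TRUE` with an optional
#'   `scenario` ([synthetic_config()]; default [reference_scenario()]), or
#'   paths `expression_file`, `protein_file`, `clinical_file`. Optional
#'   analysis keys: `target_count`, `k`, `k_grid`, `perplexity`,
#'   `n_restarts`, `rho_min`, `p_max`, `top_k`, `min_protein_sd`,
#'   `n_sets`, `set_size`, `truncations`, `theta`, `axes` (named list of
#'   network ids; in synthetic mode defaults to the ground-truth majority
#'   mapping), and `second_cohort` (a list with `selected_genes` and
#'   `labels` from another run) to enable the correspondence stage.
#' @param out_dir output directory.
#' @param seed master seed for every random stage.
#' @return List of class `"run_report"`: artifact paths, stage summaries,
#'   and the fitted `"graft_axes"` object.
#' @export
run_pipeline <- function(config = list(synthetic = TRUE), out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(
    list(synthetic = FALSE, target_count = 2000L, k = NULL, k_grid = 2:20,
         perplexity = 30, n_restarts = 25L, max_iter = 500L, rho_min = 0.6,
         p_max = 0.05, top_k = 10L, min_protein_sd = 0, n_sets = 10L,
         set_size = NULL, truncations = c(3L, 6L, 10L), theta = 0.8,
         axes = NULL, second_cohort = NULL, scenario = NULL),
    config)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ga_stop("StageFailure", "stage '%s' failed: %s", name,
              conditionMessage(e))
    })
  }

  ## stage: input
  truth <- NULL
  inputs <- list()
  bundle <- stage("input", {
    if (isTRUE(cfg$synthetic)) {
      scen <- if (is.null(cfg$scenario)) reference_scenario(seed = seed)
              else cfg$scenario
      scen$seed <- as.integer(seed)
      cohort <- generate_cohort(scen)
      truth <- cohort$truth
      paths$cohort <- write_cohort(cohort, file.path(out_dir, "cohort"))
      cohort$bundle
    } else {
      expr <- read_matrix(cfg$expression_file, type = "expression")
      prot <- read_matrix(cfg$protein_file, type = "protein")
      clin <- if (!is.null(cfg$clinical_file)) read_clinical(cfg$clinical_file)
              else NULL
      inputs <- list(expression = cfg$expression_file,
                      proteins = cfg$protein_file,
                      clinical = cfg$clinical_file)
      align_samples(expr, filter_low_variance_proteins(prot,
                                                       cfg$min_protein_sd),
                    clin)
    }
  })

  ## stage: networks
  networks <- stage("networks", {
    fit_gene_networks(bundle$expression, target_count = cfg$target_count,
                      k = cfg$k, k_grid = cfg$k_grid,
                      perplexity = cfg$perplexity, seed = seed,
                      n_restarts = cfg$n_restarts, max_iter = cfg$max_iter)
  })
  paths$selected_genes <- file.path(out_dir, "selected_genes.tsv")
  utils::write.table(data.frame(gene_id = networks$selected_genes),
                     paths$selected_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$embedding <- file.path(out_dir, "embedding.tsv")
  utils::write.table(cbind(gene_id = rownames(networks$embedding),
                           as.data.frame(networks$embedding)),
                     paths$embedding, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$labels <- file.path(out_dir, "network_labels.tsv")
  utils::write.table(data.frame(gene_id = names(networks$labels),
                                network = unname(networks$labels)),
                     paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$activity <- file.path(out_dir, "network_activity.tsv")
  utils::write.table(cbind(network = rownames(networks$activity),
                           as.data.frame(networks$activity)),
                     paths$activity, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage: cross-cohort (optional)
  correspondence <- NULL
  if (!is.null(cfg$second_cohort)) {
    correspondence <- stage("cross_cohort", {
      common <- common_variable_genes(networks$selected_genes,
                                      cfg$second_cohort$selected_genes)
      cluster_correspondence(networks$labels, cfg$second_cohort$labels,
                             common, theta = cfg$theta)
    })
    paths$correspondence <- write_correspondence(
      correspondence, file.path(out_dir, "cross_cohort"))
  }

  ## stage: axes + signatures
  axes <- cfg$axes
  if (is.null(axes) && !is.null(truth)) {
    axes <- map_networks_to_axes(networks$labels, truth)
    axes <- axes[intersect(c("MB", "INF"), names(axes))]
  }
  fit <- stage("axes", {
    correlation <- correlate_activity_proteins(networks$activity,
                                               bundle$proteins)
    fit <- list(bundle = bundle, networks = networks,
                correlation = correlation,
                params = list(target_count = cfg$target_count,
                              k = networks$k, perplexity = cfg$perplexity,
                              seed = seed, rho_min = cfg$rho_min,
                              p_max = cfg$p_max, top_k = cfg$top_k))
    if (!is.null(axes) && length(axes) >= 2L) {
      fit$axes <- axes
      fit$axis_act <- axis_activity(axes, networks$z, networks$labels)
      fit$protein_table <- protein_axis_table(fit$axis_act, bundle$proteins)
      cats <- c("HEALTH", "INJURY", "MB_up", "MB_down", "INF_up", "INF_down")
      fit$signatures <- lapply(stats::setNames(cats, cats), function(cat) {
        extract_signature(fit$protein_table, cat, rho_min = cfg$rho_min,
                          p_max = cfg$p_max, k = cfg$top_k)
      })
      if (!is.null(bundle$clinical)) {
        fit$clinical_assocs <- lapply(fit$signatures, function(sig) {
          if (nrow(sig) == 0L) return(NULL)
          clinical_association(signature_score(bundle$proteins,
                                               sig$protein),
                               bundle$clinical)
        })
      }
    }
    class(fit) <- "graft_axes"
    fit
  })
  paths$rho_matrix <- file.path(out_dir, "network_protein_rho.tsv")
  utils::write.table(cbind(network = rownames(fit$correlation$rho),
                           as.data.frame(fit$correlation$rho)),
                     paths$rho_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fit$signatures)) {
    for (cat_name in names(fit$signatures)) {
      p <- file.path(out_dir, sprintf("signature_%s.tsv", cat_name))
      write_signature(fit$signatures[[cat_name]], p)
      paths[[paste0("signature_", cat_name)]] <- p
    }
  }

  ## stage: validation
  validation <- NULL
  if (!is.null(fit$signatures) && nrow(fit$signatures$INJURY) >= 2L) {
    validation <- stage("validation", {
      validate_signature(bundle$proteins, fit$signatures$INJURY,
                         clinical = bundle$clinical, n_sets = cfg$n_sets,
                         set_size = cfg$set_size,
                         truncations = cfg$truncations,
                         seed = substream_seed(seed, 911L))
    })
    paths$validation <- file.path(out_dir, "validation_report.json")
    write_validation_report(validation, paths$validation)
  }

  ## manifest
  manifest <- list(
    package_version = as.character(utils::packageVersion("graftaxis")),
    seed = as.integer(seed),
    config = cfg[setdiff(names(cfg), c("scenario", "second_cohort"))],
    synthetic = isTRUE(cfg$synthetic),
    input_md5 = if (length(inputs) > 0L)
      lapply(inputs, function(p) if (is.null(p)) NULL
             else unname(tools::md5sum(p)))
      else NULL)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)

  structure(list(paths = paths, fit = fit, correspondence = correspondence,
                 validation = validation, truth = truth, seed = seed),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d): %d artifact group(s)\n", x$seed,
              length(x$paths)))
  print(x$fit)
  invisible(x)
}
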