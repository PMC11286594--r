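# Cross-cohort reproducibility of gene networks: which fraction of each
# network in cohort A maps onto each network of an independently processed
# cohort B, computed over the genes that survived variable-gene filtering
# in both cohorts.

#' Common variable genes of two cohorts
#'
#' @param genesA,genesB character vectors of selected gene ids.
#' @return Sorted intersection.
#' @export
common_variable_genes <- function(genesA, genesB) {
  sort(intersect(genesA, genesB))
}

#' Network correspondence between two cohorts
#'
#' For each A-network, the fraction of its common genes falling into each
#' B-network. An A-network is flagged as reproduced when its largest
#' fraction reaches `theta` (default 0.8: at least 80% of its common genes
#' land in a single B-network). Fractions are computed over common
#' genes only; an A-network with no common genes yields an all-zero row,
#' a `FALSE` flag and a warning.
#'
#' @param labelsA,labelsB named integer network labels of the two cohorts.
#' @param common character vector of common genes (see
#'   [common_variable_genes()]); every common gene must be labeled in both.
#' @param theta predominance threshold in (0, 1].
#' @return List of class `"correspondence_table"`: `common_genes`,
#'   `fraction_matrix` (A-networks x B-networks, row-stochastic over
#'   covered rows), `predominant_flags`, `theta`.
#' @export
cluster_correspondence <- function(labelsA, labelsB, common, theta = 0.8) {
  stopifnot(theta > 0, theta <= 1)
  missing_a <- setdiff(common, names(labelsA))
  missing_b <- setdiff(common, names(labelsB))
  if (length(missing_a) || length(missing_b)) {
    ga_stop("UnlabeledCommonGene", "common gene '%s' is unlabeled",
            c(missing_a, missing_b)[1L])
  }
  ka <- sort(unique(labelsA))
  kb <- sort(unique(labelsB))
  la <- labelsA[common]
  lb <- labelsB[common]
  counts <- matrix(0L, length(ka), length(kb),
                   dimnames = list(sprintf("A%d", ka), sprintf("B%d", kb)))
  tab <- table(factor(la, levels = ka), factor(lb, levels = kb))
  counts[] <- as.integer(tab)
  denom <- rowSums(counts)
  frac <- counts / ifelse(denom == 0, 1, denom)
  if (any(denom == 0)) {
    ga_warn("EmptyCorrespondenceRow",
            "%d A-network(s) have no common genes", sum(denom == 0))
  }
  flags <- apply(frac, 1L, max) >= theta & denom > 0
  structure(list(common_genes = common, fraction_matrix = frac,
                 predominant_flags = flags, theta = theta),
            class = "correspondence_table")
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat(sprintf("correspondence_table: %d common genes, %d x %d networks, %d/%d flagged at theta = %.2f\n",
              length(x$common_genes), nrow(x$fraction_matrix),
              ncol(x$fraction_matrix), sum(x$predominant_flags),
              length(x$predominant_flags), x$theta))
  invisible(x)
}

#' Write correspondence results as TSV
#'
#' @param x a `correspondence_table`.
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_correspondence <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- file.path(dir, "fraction_matrix.tsv")
  fl <- file.path(dir, "predominant_flags.tsv")
  utils::write.table(cbind(network = rownames(x$fraction_matrix),
                           as.data.frame(x$fraction_matrix)),
                     fm, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(network = names(x$predominant_flags),
                                predominant = x$predominant_flags),
                     fl, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fm, fl))
}
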