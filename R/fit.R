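# Contribution tables for a set of compounds, computing each taxon's CMP
# matrix once instead of once per compound (what taxon_contribution() would
# cost in a loop).
contributions_for <- function(m, profile, compounds, cmp_community,
                              method = "pearson", threshold = 0.5) {
  taxon_cmp <- lapply(profile$taxa, function(t) {
    compute_cmp(m, single_taxon_g(profile, t), quiet = TRUE)
  })
  names(taxon_cmp) <- profile$taxa
  out <- lapply(compounds, function(cpd) {
    community <- cmp_community[cpd, ]
    if (sd(community) == 0) return(NULL)
    r <- vapply(profile$taxa, function(t) {
      own <- taxon_cmp[[t]][cpd, ]
      if (sd(own) == 0) return(NA_real_)
      cor(own, community, method = method)
    }, numeric(1))
    tab <- data.frame(taxon = profile$taxa, r = unname(r),
                      significant = !is.na(r) & r > threshold,
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$r, tab$taxon, na.last = TRUE), , drop = FALSE]
    rownames(tab) <- NULL
    key <- if (all(is.na(tab$r))) NA_character_ else tab$taxon[which.max(tab$r)]
    structure(tab, class = c("taxon_contribution", "data.frame"),
              key_contributor = key, compound = cpd)
  })
  names(out) <- compounds
  out[!vapply(out, is.null, logical(1))]
}

#' Fit a community metabolite potential model
#'
#' The full integration pipeline as one estimator: builds the normalized
#' stoichiometric matrix from the reaction network, computes community-wide
#' CMP scores from the gene-family abundance table (supplied directly or
#' assembled from a taxon profile), tests each measured metabolite's
#' concordance with its CMP scores by Mantel permutation test, estimates
#' q-values by permutation-null resampling, classifies well-predicted
#' metabolites (p and q both below `alpha`), and — when a taxon profile is
#' available — deconvolves each well-predicted compound's community scores
#' into per-taxon contributions and assembles the taxa-metabolite
#' association network.
#'
#' @param reactions A `reaction_table` data frame
#'   ([parse_reaction_table()], [generate_network()]) or a prebuilt
#'   `stoich_matrix`.
#' @param metabolites Compounds x samples measured metabolite abundance
#'   matrix; compound identifiers must be mapped to the reaction network's
#'   compound ids.
#' @param gene_abundance Optional gene families x samples abundance matrix
#'   (predicted-metagenome style). If omitted, `taxa` must be given and the
#'   community table is assembled as the sum of single-taxon tables.
#' @param taxa Optional [taxon_profile()]; enables contribution
#'   deconvolution and the association network.
#' @param n_perm Mantel permutations per test (default 999).
#' @param n_boot Null-resampling rounds for the FDR (default 50).
#' @param alpha Strict well-predicted threshold on both p and q (default
#'   0.01).
#' @param contribution_threshold Contribution correlation cutoff for a
#'   significant taxon-metabolite edge (default 0.5).
#' @param cor_method Correlation type for contributions, `"pearson"`
#'   (default) or `"spearman"`.
#' @param seed Optional integer seed covering the permutation stages.
#' @return An object of class `metapot`: a list with elements `m`, `cmp`,
#'   `results` (the `association_result` table), `contributions`,
#'   `network`, `aligned` (the aligned score/abundance matrices), `params`
#'   and `call`. Use [summary.metapot()], [plot.metapot()] and
#'   [predict.metapot()] to inspect it.
#' @examples
#' study <- generate_study(design = study_design(n_per_group = 3),
#'                         n_compounds = 20, n_families = 40, n_taxa = 5,
#'                         n_planted = 4, rho = 0.9, seed = 7, depth = 1000)
#' fit <- metapot(study$reactions, study$metabolites, taxa = study$profile,
#'                n_perm = 99, n_boot = 10, seed = 7)
#' summary(fit)
#' @export
metapot <- function(reactions, metabolites, gene_abundance = NULL, taxa = NULL,
                    n_perm = 999, n_boot = 50, alpha = 0.01,
                    contribution_threshold = 0.5,
                    cor_method = c("pearson", "spearman"), seed = NULL) {
  cor_method <- match.arg(cor_method)
  cl <- match.call()
  m <- if (inherits(reactions, "stoich_matrix")) {
    reactions
  } else {
    build_stoichiometric_matrix(reactions)
  }
  if (is.null(gene_abundance)) {
    if (is.null(taxa)) stop("supply gene_abundance or a taxon profile")
    gene_abundance <- community_g(taxa)
  }
  cmp <- compute_cmp(m, gene_abundance, quiet = TRUE)
  results <- associate_metabolites(cmp, metabolites, n_perm = n_perm,
                                   n_boot = n_boot, alpha = alpha, seed = seed)
  al <- align_layers(cmp, metabolites)
  contributions <- list()
  network <- NULL
  if (!is.null(taxa)) {
    wp <- results$compound[results$well_predicted]
    contributions <- contributions_for(m, taxa, wp, cmp,
                                       method = cor_method,
                                       threshold = contribution_threshold)
    network <- build_network(
      results, contributions,
      metabolite_abundance = rowMeans(al$met),
      taxon_abundance = rowMeans(taxa$abundances))
  }
  structure(list(m = m, cmp = cmp, results = results,
                 contributions = contributions, network = network,
                 aligned = al,
                 params = list(n_perm = n_perm, n_boot = n_boot, alpha = alpha,
                               contribution_threshold = contribution_threshold,
                               cor_method = cor_method, seed = seed),
                 call = cl),
            class = "metapot")
}

#' @export
print.metapot <- function(x, ...) {
  n_tested <- sum(!is.na(x$results$p_value))
  n_wp <- sum(x$results$well_predicted)
  cat("Community metabolite potential model\n")
  cat(sprintf("  %d compounds scored over %d samples; %d mapped metabolites tested\n",
              nrow(x$cmp), ncol(x$cmp), n_tested))
  cat(sprintf("  %d well-predicted (Mantel p < %g and FDR q < %g)\n",
              n_wp, x$params$alpha, x$params$alpha))
  if (!is.null(x$network)) {
    cat(sprintf("  association network: %d nodes, %d edges\n",
                igraph::vcount(x$network), igraph::ecount(x$network)))
  }
  invisible(x)
}

#' Summarize a fitted community metabolite potential model
#'
#' @param object A `metapot` fit.
#' @param ... Unused.
#' @return A `summary.metapot` list: testing counts, the well-predicted
#'   fraction among mapped (tested) metabolites and among all supplied
#'   metabolites, the top associations, and contributing-taxon counts.
#' @export
summary.metapot <- function(object, ...) {
  res <- object$results
  n_all <- nrow(res)
  n_tested <- sum(!is.na(res$p_value))
  n_wp <- sum(res$well_predicted)
  sig_taxa <- unique(unlist(lapply(object$contributions, function(ct) {
    ct$taxon[ct$significant]
  })))
  top <- res[res$well_predicted, , drop = FALSE]
  top <- top[order(top$p_value, -abs(top$mantel_r)), , drop = FALSE]
  out <- list(n_compounds = n_all, n_tested = n_tested,
              n_well_predicted = n_wp,
              pct_of_mapped = if (n_tested > 0) 100 * n_wp / n_tested else NA_real_,
              pct_of_all = if (n_all > 0) 100 * n_wp / n_all else NA_real_,
              n_contributing_taxa = length(sig_taxa),
              top_associations = head(top, 10L),
              params = object$params)
  class(out) <- "summary.metapot"
  out
}

#' @export
print.summary.metapot <- function(x, ...) {
  cat("Community metabolite potential model summary\n")
  cat(sprintf("  metabolites supplied: %d; mapped and tested: %d\n",
              x$n_compounds, x$n_tested))
  cat(sprintf("  well-predicted: %d (%.1f%% of mapped, %.1f%% of all)\n",
              x$n_well_predicted, x$pct_of_mapped, x$pct_of_all))
  cat(sprintf("  taxa contributing (r > %g) to at least one well-predicted metabolite: %d\n",
              x$params$contribution_threshold, x$n_contributing_taxa))
  if (nrow(x$top_associations) > 0L) {
    cat("  strongest associations:\n")
    print(x$top_associations[, c("compound", "mantel_r", "p_value", "q_value",
                                 "direction")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.metapot <- function(object, ...) {
  setNames(object$results$mantel_r, object$results$compound)
}

#' Predict CMP scores for new samples
#'
#' Applies the fitted model's normalized stoichiometric matrix to a new
#' gene-family abundance table, yielding metabolite-potential scores for
#' unseen samples. With `newdata = NULL`, returns the training CMP matrix.
#'
#' @param object A `metapot` fit.
#' @param newdata Gene families x samples abundance matrix, or `NULL`.
#' @param ... Unused.
#' @return A `cmp_matrix` (compounds x samples).
#' @export
predict.metapot <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$cmp)
  compute_cmp(object$m, newdata, quiet = TRUE)
}

#' Plot measured abundance against predicted metabolite potential
#'
#' Scatter of a compound's measured per-sample abundances against its CMP
#' scores, annotated with the Mantel statistic and p-value — the per-
#' metabolite view of how well the predicted metagenome explains the
#' measured metabolome.
#'
#' @param x A `metapot` fit.
#' @param compound Compound identifier; default the well-predicted compound
#'   with the smallest p-value (or the smallest p overall when none is well
#'   predicted).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.metapot <- function(x, compound = NULL, ...) {
  res <- x$results
  if (is.null(compound)) {
    pool <- if (any(res$well_predicted)) res[res$well_predicted, ] else res
    pool <- pool[!is.na(pool$p_value), , drop = FALSE]
    if (nrow(pool) == 0L) stop("no testable compound to plot")
    compound <- pool$compound[order(pool$p_value, -abs(pool$mantel_r))][1L]
  }
  if (!(compound %in% rownames(x$aligned$cmp))) {
    stop("compound not in the aligned layers: ", compound)
  }
  i <- match(compound, res$compound)
  graphics::plot(x$aligned$cmp[compound, ], x$aligned$met[compound, ],
                 xlab = "predicted metabolite potential (CMP score)",
                 ylab = "measured abundance",
                 main = sprintf("%s (Mantel r = %.2f, p = %.3g)",
                                compound, res$mantel_r[i], res$p_value[i]),
                 ...)
  invisible(x)
}
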