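#' Compute community metabolite potential (CMP) scores
#'
#' Multiplies the row-normalized stoichiometric matrix by a gene-family
#' abundance table: `scores[c, s] = sum_k m[c, k] * g[k, s]` over the gene
#' families shared between the two. A positive score means the community's
#' gene content favors net production of the compound in that sample, a
#' negative score net depletion.
#'
#' Gene families present in only one of the two inputs are dropped
#' symmetrically (KO coverage differs across database releases), with a
#' message reporting the counts. Compounds whose stoichiometric row becomes
#' all-zero after the intersection are flagged as unmapped in the
#' `"unmapped"` attribute.
#'
#' @param m Stoichiometric matrix from [build_stoichiometric_matrix()]
#'   (compounds x gene families).
#' @param g Gene-family abundance matrix (gene families x samples),
#'   non-negative; corrected relative abundances as produced by
#'   predicted-metagenome pipelines are accepted as-is.
#' @param quiet Suppress the intersection message.
#' @return Matrix of class `cmp_matrix` (compounds x samples) with
#'   attributes `unmapped` (character vector of compounds with no shared
#'   gene families) and `provenance` (`"community"`).
#' @export
compute_cmp <- function(m, g, quiet = FALSE) {
  stopifnot(is.matrix(m), is.matrix(g))
  if (any(!is.finite(g))) stop("gene-family abundance table contains non-finite values")
  if (any(g < 0)) stop("gene-family abundance table contains negative values")
  shared <- intersect(colnames(m), rownames(g))
  if (length(shared) == 0L) {
    stop("no gene-family overlap between the stoichiometric matrix (",
         ncol(m), " families, e.g. ", paste(head(colnames(m), 3), collapse = ", "),
         ") and the abundance table (", nrow(g), " families, e.g. ",
         paste(head(rownames(g), 3), collapse = ", "), ")")
  }
  if (!quiet && (length(shared) < ncol(m) || length(shared) < nrow(g))) {
    message(sprintf("compute_cmp: %d shared gene families (%d dropped from M, %d from G)",
                    length(shared), ncol(m) - length(shared), nrow(g) - length(shared)))
  }
  ms <- unclass(m)[, shared, drop = FALSE]
  scores <- ms %*% g[shared, , drop = FALSE]
  unmapped <- rownames(m)[rowSums(abs(ms)) == 0]
  structure(scores, class = c("cmp_matrix", class(matrix())),
            unmapped = unmapped, provenance = "community")
}

#' Assemble a taxon profile
#'
#' Bundles per-taxon gene content with per-sample taxon relative abundances,
#' the two ingredients of single-taxon metabolite-potential scoring.
#'
#' @param gene_content Non-negative matrix, taxa x gene families (gene copy
#'   numbers per taxon genome).
#' @param abundances Matrix, taxa x samples, per-sample relative abundances;
#'   each sample column must sum to at most 1 (small numerical excess is
#'   tolerated).
#' @return A list of class `taxon_profile` with elements `taxa`,
#'   `gene_content`, `abundances`.
#' @export
taxon_profile <- function(gene_content, abundances) {
  stopifnot(is.matrix(gene_content), is.matrix(abundances))
  if (!identical(rownames(gene_content), rownames(abundances))) {
    shared <- intersect(rownames(gene_content), rownames(abundances))
    if (length(shared) == 0L) stop("no taxa shared between gene content and abundances")
    gene_content <- gene_content[shared, , drop = FALSE]
    abundances <- abundances[shared, , drop = FALSE]
  }
  if (any(gene_content < 0)) stop("gene content must be non-negative")
  if (any(colSums(abundances) > 1 + 1e-9)) {
    stop("per-sample taxon abundances must sum to at most 1")
  }
  structure(list(taxa = rownames(gene_content),
                 gene_content = gene_content,
                 abundances = abundances),
            class = "taxon_profile")
}

#' Gene-family abundance table of a single taxon
#'
#' The taxon's genomic gene content scaled by its relative abundance in each
#' sample: `g_t[k, s] = gene_content[t, k] * abundance[t, s]`. Summing this
#' over all taxa reproduces the community table of [community_g()], which is
#' what makes community CMP scores decompose additively into per-taxon
#' scores.
#'
#' @param profile A [taxon_profile()].
#' @param taxon Taxon identifier present in the profile.
#' @return Gene families x samples matrix.
#' @export
single_taxon_g <- function(profile, taxon) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (!(taxon %in% profile$taxa)) stop("unknown taxon: ", taxon)
  outer(profile$gene_content[taxon, ], profile$abundances[taxon, ])
}

#' Community gene-family abundance table from a taxon profile
#'
#' Computed as the sum over taxa of [single_taxon_g()], so the additive
#' decomposition of CMP scores holds by construction.
#'
#' @param profile A [taxon_profile()].
#' @return Gene families x samples matrix.
#' @export
community_g <- function(profile) {
  stopifnot(inherits(profile, "taxon_profile"))
  out <- single_taxon_g(profile, profile$taxa[1L])
  for (t in profile$taxa[-1L]) out <- out + single_taxon_g(profile, t)
  out
}

#' Per-taxon contributions to a compound's community CMP scores
#'
#' For each taxon, computes CMP scores from that taxon's gene content alone
#' and correlates them, across samples, with the community-wide CMP scores
#' of the compound. Taxa whose correlation exceeds 0.5 are flagged as
#' significant contributors; the key contributor is the taxon with the
#' maximum correlation.
#'
#' @param m Stoichiometric matrix.
#' @param profile A [taxon_profile()].
#' @param compound Compound identifier (row of `m`).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @param threshold Contribution correlation cutoff for the significance
#'   flag; default 0.5.
#' @return Data frame of class `taxon_contribution` with columns `taxon`,
#'   `r`, `significant`, ordered by decreasing correlation (missing values
#'   last); attribute `key_contributor` holds the arg-max taxon (NA if all
#'   correlations are undefined).
#' @export
taxon_contribution <- function(m, profile, compound,
                               method = c("pearson", "spearman"),
                               threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "taxon_profile"))
  if (!(compound %in% rownames(m))) stop("compound not in stoichiometric matrix: ", compound)
  n_samples <- ncol(profile$abundances)
  if (n_samples < 3L) stop("need at least 3 samples for contribution correlations")
  community <- compute_cmp(m, community_g(profile), quiet = TRUE)[compound, ]
  if (sd(community) == 0) {
    stop("community CMP scores for ", compound, " are constant; contributions undefined")
  }
  r <- vapply(profile$taxa, function(t) {
    own <- compute_cmp(m, single_taxon_g(profile, t), quiet = TRUE)[compound, ]
    if (sd(own) == 0) return(NA_real_)
    cor(own, community, method = method)
  }, numeric(1))
  out <- data.frame(taxon = profile$taxa, r = unname(r),
                    significant = !is.na(r) & r > threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$taxon, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  key <- if (all(is.na(out$r))) NA_character_ else out$taxon[which.max(out$r)]
  structure(out, class = c("taxon_contribution", "data.frame"),
            key_contributor = key, compound = compound)
}
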