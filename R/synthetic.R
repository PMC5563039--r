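#' Factorial study design for synthetic experiments
#'
#' Emulates a dose-response time-course cohort: every combination of
#' radiation dose and sacrifice time receives `n_per_group` animals. The
#' defaults reproduce a 4-dose (0, 0.1, 0.25, 1 Gy) by 2-time (10, 30 d)
#' design with 10 mice per group, i.e. 80 samples.
#'
#' @param doses Numeric dose levels (Gy).
#' @param times Numeric sampling times (days).
#' @param n_per_group Animals per dose-by-time group, at least 2.
#' @return Data frame of class `study_design` with columns `sample_id`,
#'   `dose`, `time`.
#' @export
study_design <- function(doses = c(0, 0.1, 0.25, 1.0), times = c(10, 30),
                         n_per_group = 10) {
  stopifnot(n_per_group >= 2, length(doses) >= 1, length(times) >= 1)
  grid <- expand.grid(mouse = seq_len(n_per_group), dose = doses, time = times,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    sample_id = sprintf("d%s_t%g_m%02d", grid$dose, grid$time, grid$mouse),
    dose = grid$dose, time = grid$time, stringsAsFactors = FALSE)
  class(out) <- c("study_design", "data.frame")
  out
}

#' Generate a sparse irreversible reaction network
#'
#' Draws a random signed stoichiometry table: each (compound, gene family)
#' link is present with probability `density`, with integer coefficients of
#' magnitude 1-3 and a 60/40 produce/consume split. Every compound is
#' guaranteed at least one producing gene family.
#'
#' @param n_compounds,n_families Numbers of compounds and gene families.
#' @param density Link probability in (0, 1].
#' @param seed Integer seed.
#' @return A `reaction_table` data frame (one synthetic reaction per link,
#'   `reversible = FALSE` throughout) ready for
#'   [build_stoichiometric_matrix()] or [write_reaction_table()].
#' @export
generate_network <- function(n_compounds, n_families, density = 0.05, seed = NULL) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (n_families < 1L || n_compounds < 1L) {
    stop("infeasible network parameters: need at least one compound and one family")
  }
  if (!is.null(seed)) set.seed(seed)
  compounds <- sprintf("C%05d", seq_len(n_compounds))
  families  <- sprintf("K%05d", seq_len(n_families))
  rows <- vector("list", n_compounds)
  for (c in seq_len(n_compounds)) {
    link <- which(runif(n_families) < density)
    coef <- sample(1:3, length(link), replace = TRUE) *
      ifelse(runif(length(link)) < 0.6, 1, -1)
    if (!any(coef > 0)) {
      extra <- sample.int(n_families, 1L)
      if (extra %in% link) {
        coef[match(extra, link)] <- abs(coef[match(extra, link)])
      } else {
        link <- c(link, extra)
        coef <- c(coef, sample(1:3, 1L))
      }
    }
    rows[[c]] <- data.frame(gene_family = families[link],
                            compound = compounds[c],
                            coefficient = coef, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$compound, out$gene_family), , drop = FALSE]
  out <- data.frame(reaction_id = sprintf("R%05d", seq_len(nrow(out))),
                    out, reversible = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reaction_table", "data.frame")
  out
}

#' Write a reaction table TSV
#'
#' Inverse of [parse_reaction_table()]: emits the five-column header
#' (`reaction_id`, `gene_family`, `compound`, `coefficient`, `reversible`).
#'
#' @param reactions A `reaction_table` data frame.
#' @param path Output path.
#' @export
write_reaction_table <- function(reactions, path) {
  df <- reactions
  if (!("reversible" %in% names(df))) df$reversible <- FALSE
  df$reversible <- tolower(as.character(df$reversible))
  cols <- c("reaction_id", "gene_family", "compound", "coefficient", "reversible")
  write.table(df[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic microbial community
#'
#' Simulates taxon relative abundances over a [study_design()]: log-normal
#' baseline abundances per taxon, optional group-specific multiplicative
#' effects for responder taxa (an arbitrary dose-by-time map, so
#' threshold-like non-monotonic dose responses can be emulated), per-sample
#' renormalization, multinomial OTU counts at a configurable sequencing
#' depth, and presence/absence-with-copy-number gene content per taxon
#' genome.
#'
#' @param design A [study_design()] data frame.
#' @param n_taxa Number of taxa (>= 2).
#' @param n_families Number of gene families in the genomes.
#' @param responder_spec Optional data frame with columns `taxon` (id or
#'   index), `dose`, `time`, `log2fc`: the named taxon's abundance in the
#'   matching dose-by-time group is multiplied by `2^log2fc` before
#'   renormalization.
#' @param seed Integer seed.
#' @param depth Multinomial sequencing depth per sample for the OTU table.
#' @param gene_prob Probability a family is present in a genome.
#' @param copy_max Maximum gene copy number for present families.
#' @return List with elements `profile` (a [taxon_profile()]), `otu`
#'   (taxa x samples integer counts) and `design`.
#' @export
generate_community <- function(design, n_taxa = 30, n_families = 200,
                               responder_spec = NULL, seed = NULL,
                               depth = 60000, gene_prob = 0.3, copy_max = 3) {
  stopifnot(inherits(design, "data.frame"), n_taxa >= 2)
  if (!is.null(seed)) set.seed(seed)
  taxa <- sprintf("T%03d", seq_len(n_taxa))
  families <- sprintf("K%05d", seq_len(n_families))
  n_s <- nrow(design)
  base <- rnorm(n_taxa, mean = 0, sd = 1.5)
  raw <- exp(base + matrix(rnorm(n_taxa * n_s, sd = 0.5), n_taxa, n_s))
  dimnames(raw) <- list(taxa, design$sample_id)
  if (!is.null(responder_spec) && nrow(responder_spec) > 0L) {
    for (i in seq_len(nrow(responder_spec))) {
      t_id <- responder_spec$taxon[i]
      if (is.numeric(t_id)) t_id <- taxa[t_id]
      sel <- design$dose == responder_spec$dose[i] &
        design$time == responder_spec$time[i]
      raw[t_id, sel] <- raw[t_id, sel] * 2^responder_spec$log2fc[i]
    }
  }
  ab <- sweep(raw, 2, colSums(raw), "/")
  otu <- vapply(seq_len(n_s), function(s) rmultinom(1, depth, ab[, s])[, 1],
                integer(n_taxa))
  dimnames(otu) <- dimnames(ab)
  present <- matrix(rbinom(n_taxa * n_families, 1, gene_prob), n_taxa, n_families)
  copies <- matrix(sample.int(copy_max, n_taxa * n_families, replace = TRUE),
                   n_taxa, n_families)
  gc <- present * copies
  dimnames(gc) <- list(taxa, families)
  # a genome with no genes breaks nothing but is biologically silly
  empty <- rowSums(gc) == 0
  if (any(empty)) gc[empty, sample.int(n_families, 1L)] <- 1
  list(profile = taxon_profile(gc, ab), otu = otu, design = design)
}

#' Planted ground truth for a synthetic metabolome
#'
#' Records which compounds are coupled to their CMP scores, with what
#' affine coefficients and target correlation, and (optionally) which taxon
#' was engineered as the key contributor — the reference that recovery
#' experiments are scored against.
#'
#' @param compounds All compound identifiers of the study.
#' @param planted Identifiers of the compounds coupled to CMP scores.
#' @param rho Target score/abundance correlation for planted compounds (one
#'   value or one per planted compound), in (0, 1].
#' @param intercept,slope Affine coupling coefficients (recycled).
#' @param key_contributor Optional named character vector (per planted
#'   compound) of engineered key-contributor taxa.
#' @return List of class `planted_truth`.
#' @export
planted_truth <- function(compounds, planted, rho = 0.6, intercept = 0,
                          slope = 1, key_contributor = NULL) {
  stopifnot(all(planted %in% compounds), all(rho > 0), all(rho <= 1))
  coupling <- data.frame(compound = planted,
                         intercept = rep_len(intercept, length(planted)),
                         slope = rep_len(slope, length(planted)),
                         rho = rep_len(rho, length(planted)),
                         stringsAsFactors = FALSE)
  structure(list(compounds = compounds, well_predicted_set = planted,
                 coupling = coupling, key_contributor = key_contributor,
                 realized_r = NULL),
            class = "planted_truth")
}

#' Generate a synthetic metabolite abundance table
#'
#' For planted compounds, abundance is an affine image of the compound's
#' CMP row plus Gaussian noise scaled so the expected score/abundance
#' correlation equals the planted `rho` (noise sd =
#' `|slope| * sd(cmp) * sqrt(1/rho^2 - 1)`; `rho = 1` gives an exact affine
#' image). All other compounds are independent Gaussian noise. The realized
#' per-compound correlation is recorded in the returned table's `"truth"`
#' attribute.
#'
#' @param truth A [planted_truth()].
#' @param cmp CMP score matrix covering at least the truth's compounds.
#' @param seed Integer seed.
#' @param null_sd Standard deviation of the noise-only compounds.
#' @return Compounds x samples abundance matrix with attribute `truth` (the
#'   input truth with `realized_r` filled in).
#' @export
generate_metabolome <- function(truth, cmp, seed = NULL, null_sd = 1) {
  stopifnot(inherits(truth, "planted_truth"),
            all(truth$compounds %in% rownames(cmp)))
  if (!is.null(seed)) set.seed(seed)
  n_s <- ncol(cmp)
  met <- matrix(rnorm(length(truth$compounds) * n_s, sd = null_sd),
                nrow = length(truth$compounds),
                dimnames = list(truth$compounds, colnames(cmp)))
  for (i in seq_len(nrow(truth$coupling))) {
    cpd <- truth$coupling$compound[i]
    x <- cmp[cpd, ]
    slope <- truth$coupling$slope[i]
    rho <- truth$coupling$rho[i]
    noise_sd <- abs(slope) * sd(x) * sqrt(1 / rho^2 - 1)
    met[cpd, ] <- truth$coupling$intercept[i] + slope * x +
      rnorm(n_s, sd = noise_sd)
  }
  realized <- vapply(truth$compounds, function(cpd) {
    x <- cmp[cpd, ]
    if (sd(x) == 0 || sd(met[cpd, ]) == 0) return(NA_real_)
    cor(x, met[cpd, ])
  }, numeric(1))
  truth$realized_r <- realized
  attr(met, "truth") <- truth
  met
}

#' Generate a complete synthetic multi-omics study
#'
#' Chains the generators into one coherent study: reaction network,
#' community (taxon profile + OTU counts) over the study design, community
#' gene-family table, CMP scores, and a metabolome in which a planted subset
#' of compounds is coupled to its CMP scores at correlation `rho`. When
#' `exclusive_producers` is `TRUE`, each planted compound's producing gene
#' families are (where feasible without conflicts) confined to a single
#' randomly chosen taxon, which is then recorded as the compound's true key
#' contributor.
#'
#' @param design A [study_design()]; default the 4-dose x 2-time x 10-mouse
#'   layout (80 samples).
#' @param n_compounds,n_families,n_taxa,density Network and community sizes.
#' @param n_planted Number of compounds coupled to their CMP scores.
#' @param rho Planted coupling correlation.
#' @param responder_spec Passed to [generate_community()].
#' @param exclusive_producers Engineer taxon-exclusive producers for planted
#'   compounds (default `TRUE`).
#' @param seed Integer seed driving all stages.
#' @param depth OTU sequencing depth.
#' @return List of class `metapot_study`: `reactions`, `m` (stoichiometric
#'   matrix), `profile`, `otu`, `g` (community gene table), `cmp`,
#'   `metabolites`, `truth`, `design`, `params`.
#' @export
generate_study <- function(design = study_design(), n_compounds = 150,
                           n_families = 200, n_taxa = 30, density = 0.05,
                           n_planted = 30, rho = 0.6, responder_spec = NULL,
                           exclusive_producers = TRUE, seed = 1,
                           depth = 60000) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  reactions <- generate_network(n_compounds, n_families, density,
                                seed = sub_seeds[1L])
  m <- build_stoichiometric_matrix(reactions)
  comm <- generate_community(design, n_taxa = n_taxa, n_families = n_families,
                             responder_spec = responder_spec,
                             seed = sub_seeds[2L], depth = depth)
  profile <- comm$profile

  set.seed(sub_seeds[3L])
  planted <- sample(rownames(m), min(n_planted, nrow(m)))
  key <- NULL
  if (exclusive_producers) {
    # confine a planted compound's entire reaction row (producing and
    # depleting families) to one taxon, so that taxon's single-taxon CMP
    # profile is the community profile and it is the true key contributor
    key <- setNames(rep(NA_character_, length(planted)), planted)
    claimed <- character(0)  # families already reserved for another compound
    gc <- profile$gene_content
    for (cpd in planted) {
      fams <- colnames(m)[unclass(m)[cpd, ] != 0]
      fams <- intersect(fams, colnames(gc))
      if (length(fams) == 0L || any(fams %in% claimed)) next
      t_id <- sample(rownames(gc), 1L)
      gc[setdiff(rownames(gc), t_id), fams] <- 0
      gc[t_id, fams] <- pmax(gc[t_id, fams], 1)
      claimed <- c(claimed, fams)
      key[cpd] <- t_id
    }
    profile <- taxon_profile(gc, profile$abundances)
  }

  g <- community_g(profile)
  cmp <- compute_cmp(m, g, quiet = TRUE)
  # only compounds with sample variance in their scores can carry a coupling
  usable <- planted[apply(cmp[planted, , drop = FALSE], 1, sd) > 0]
  truth <- planted_truth(rownames(cmp), usable, rho = rho,
                         key_contributor = if (is.null(key)) NULL else key[usable])
  met <- generate_metabolome(truth, cmp, seed = sub_seeds[4L])
  structure(list(reactions = reactions, m = m, profile = profile,
                 otu = comm$otu, g = g, cmp = cmp, metabolites = met,
                 truth = attr(met, "truth"), design = design,
                 params = list(n_compounds = n_compounds,
                               n_families = n_families, n_taxa = n_taxa,
                               density = density, n_planted = n_planted,
                               rho = rho, depth = depth, seed = seed)),
            class = "metapot_study")
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `reactions.tsv`, `gene_content.tsv`, `taxa_abundance.tsv`,
#' `otu_table.tsv`, `ko_table.tsv`, `metabolites.tsv`, `truth.json` and
#' `manifest.json` (seeds and parameters; JSON files require jsonlite).
#'
#' @param study A `metapot_study` from [generate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "metapot_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_reaction_table(study$reactions, file.path(dir, "reactions.tsv"))
  write_matrix_tsv(study$profile$gene_content, file.path(dir, "gene_content.tsv"))
  write_matrix_tsv(study$profile$abundances, file.path(dir, "taxa_abundance.tsv"))
  write_matrix_tsv(study$otu, file.path(dir, "otu_table.tsv"))
  write_matrix_tsv(study$g, file.path(dir, "ko_table.tsv"))
  write_matrix_tsv(study$metabolites, file.path(dir, "metabolites.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- study$truth
    jsonlite::write_json(
      list(well_predicted_set = truth$well_predicted_set,
           coupling = truth$coupling,
           key_contributor = as.list(truth$key_contributor),
           realized_r = as.list(truth$realized_r)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(study$params, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
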