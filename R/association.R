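# Upper-triangle pairwise Euclidean distances of a 1-D sample vector.
dist_vec <- function(x) {
  d <- abs(outer(x, x, "-"))
  d[upper.tri(d)]
}

# All permutations of 1:n as rows, identity first (n <= 8 guard; 8! = 40320).
all_perms <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Mantel permutation test between two per-sample vectors
#'
#' Builds the sample-by-sample Euclidean distance matrix of each vector,
#' computes the Mantel statistic (Pearson correlation of the upper-triangle
#' distances), and obtains a one-tailed permutation p-value by relabeling
#' the samples of the first layer. A one-tailed test (high distance-matrix
#' concordance) matches the question asked of metabolite-potential scores:
#' does the predicted profile resemble the measured one?
#'
#' When the number of distinct relabelings `factorial(n)` does not exceed
#' `n_perm`, the test enumerates all of them and returns the exact p-value
#' `#\{stat >= observed\} / n!` (the identity relabeling counts, so p > 0).
#' Otherwise `n_perm` random relabelings are drawn and
#' `p = (1 + #\{stat >= observed\}) / (1 + n_perm)`.
#'
#' Euclidean distances are invariant to sign flip plus shift of a vector, so
#' the Mantel statistic cannot distinguish positive from negative coupling;
#' carry the sign separately (see the `direction` column of
#' [associate_metabolites()]).
#'
#' @param x,y Numeric vectors over the same samples, length >= 4, neither
#'   constant.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates exactly when `factorial(n) <= n_perm`.
#' @return List of class `mantel_test`: `statistic`, `p_value`, `n`,
#'   `method` (`"exact"` or `"permutation"`), `n_perm`.
#' @export
mantel_test <- function(x, y, n_perm = 999, seed = NULL, exact = NULL) {
  if (length(x) != length(y)) {
    stop("alignment error: vectors have lengths ", length(x), " and ", length(y))
  }
  n <- length(x)
  if (n < 4L) stop("need at least 4 samples for a Mantel test")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined test: constant input vector (zero variance)")
  }
  if (!is.null(seed)) set.seed(seed)
  dyv <- dist_vec(y)
  dyv <- dyv - mean(dyv)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ii <- ut[, 1L] - 1L
  jj <- ut[, 2L] - 1L
  if (is.null(exact)) exact <- n <= 8L && factorial(n) <= n_perm
  if (exact) {
    perm <- all_perms(n)
    stats <- mantel_stat_perms(x, dyv, ii, jj, perm)
    obs <- stats[1L]  # first enumerated permutation is the identity
    p <- mean(stats >= obs - 1e-12)
    res <- list(statistic = obs, p_value = p, n = n,
                method = "exact", n_perm = nrow(perm))
  } else {
    k <- mantel_perm_kernel(x, dyv, ii, jj, as.integer(n_perm))
    res <- list(statistic = k$r, p_value = (1 + k$count) / (1 + n_perm),
                n = n, method = "permutation", n_perm = n_perm)
  }
  class(res) <- "mantel_test"
  res
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d relabelings): r = %.4f, p = %.4g, n = %d\n",
              x$method, x$n_perm, x$statistic, x$p_value, x$n))
  invisible(x)
}

# Per-compound Mantel r and p for aligned score/abundance matrices
# (rows = compounds, columns = identical samples). Rows with zero variance
# in either layer get NA.
mantel_screen <- function(cmp, met, n_perm = 999) {
  stopifnot(identical(colnames(cmp), colnames(met)),
            identical(rownames(cmp), rownames(met)))
  n <- ncol(cmp)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ii <- ut[, 1L] - 1L
  jj <- ut[, 2L] - 1L
  r <- p <- rep(NA_real_, nrow(cmp))
  for (c in seq_len(nrow(cmp))) {
    x <- cmp[c, ]
    y <- met[c, ]
    if (sd(x) == 0 || sd(y) == 0) next
    dyv <- dist_vec(y)
    dyv <- dyv - mean(dyv)
    k <- mantel_perm_kernel(x, dyv, ii, jj, as.integer(n_perm))
    r[c] <- k$r
    p[c] <- (1 + k$count) / (1 + n_perm)
  }
  data.frame(compound = rownames(cmp), mantel_r = r, p_value = p,
             stringsAsFactors = FALSE)
}

#' Empirical FDR for Mantel p-values by permutation-null resampling
#'
#' Estimates a q-value for each compound's Mantel p-value by repeatedly
#' permuting the sample labels of the metabolite table, which breaks every
#' real score/abundance coupling while preserving the marginal structure of
#' both layers, and recomputing the full set of Mantel p-values. At each
#' candidate threshold t (the observed p-values), the false discovery rate
#' is estimated as the mean number of null p-values at or below t divided by
#' the observed count at or below t; each compound's q-value is the minimum
#' estimate over thresholds at or above its own p (step-up monotonicity),
#' capped at 1.
#'
#' @param observed_p Numeric vector of Mantel p-values, one per compound,
#'   computed from the aligned `cmp`/`met` pair.
#' @param cmp Compounds x samples CMP score matrix.
#' @param met Compounds x samples metabolite abundance matrix, aligned to
#'   `cmp` (same dimnames).
#' @param n_boot Number of label-permutation null rounds (default 50). Fewer
#'   than 10 triggers an instability warning.
#' @param n_perm Permutations per Mantel test inside each round.
#' @param seed Optional integer seed.
#' @return Numeric vector of q-values aligned with `observed_p` (NA where
#'   `observed_p` is NA).
#' @export
bootstrap_fdr <- function(observed_p, cmp, met, n_boot = 50, n_perm = 999,
                          seed = NULL) {
  stopifnot(length(observed_p) == nrow(cmp), identical(dim(cmp), dim(met)))
  if (n_boot < 10) warning("n_boot < 10 gives unstable FDR estimates")
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(observed_p)
  thr <- sort(unique(observed_p[ok]))
  null_counts <- matrix(0, nrow = n_boot, ncol = length(thr))
  n_s <- ncol(met)
  for (b in seq_len(n_boot)) {
    perm <- sample.int(n_s)
    met_b <- met[, perm, drop = FALSE]
    colnames(met_b) <- colnames(met)
    p_b <- mantel_screen(cmp, met_b, n_perm = n_perm)$p_value
    p_b <- p_b[!is.na(p_b)]
    null_counts[b, ] <- vapply(thr, function(t) sum(p_b <= t), numeric(1))
  }
  obs_counts <- vapply(thr, function(t) sum(observed_p[ok] <= t), numeric(1))
  fdr_at <- colMeans(null_counts) / pmax(1, obs_counts)
  # step-up: q at threshold t is the best (smallest) estimate at any t' >= t
  q_at <- rev(cummin(rev(pmin(fdr_at, 1))))
  q <- rep(NA_real_, length(observed_p))
  q[ok] <- q_at[match(observed_p[ok], thr)]
  q
}

#' Classify compounds as well predicted
#'
#' Applies the conjunction rule with strict inequalities: a compound is well
#' predicted when its Mantel p-value and its empirical FDR q-value are both
#' strictly below `alpha` (default 0.01). The `direction` column carries the
#' sign of the raw score/abundance correlation, which the Mantel statistic
#' itself cannot provide.
#'
#' @param results Data frame with columns `compound`, `mantel_r`, `p_value`,
#'   `q_value`, `direction` (as assembled by [associate_metabolites()]).
#' @param alpha Strict threshold applied to both p and q; default 0.01.
#' @return The input with a logical `well_predicted` column, class
#'   `association_result`.
#' @export
classify_well_predicted <- function(results, alpha = 0.01) {
  stopifnot(all(c("compound", "p_value", "q_value") %in% names(results)))
  results$well_predicted <- !is.na(results$p_value) & !is.na(results$q_value) &
    results$p_value < alpha & results$q_value < alpha
  class(results) <- unique(c("association_result", class(results)))
  results
}

# Align two compound x sample matrices on exact sample-identifier match;
# unmatched samples dropped with a warning, compounds intersected.
align_layers <- function(cmp, met) {
  shared_s <- intersect(colnames(cmp), colnames(met))
  if (length(shared_s) < 4L) stop("fewer than 4 shared samples between layers")
  dropped <- (ncol(cmp) - length(shared_s)) + (ncol(met) - length(shared_s))
  if (dropped > 0) warning(dropped, " unmatched sample column(s) dropped during alignment")
  shared_c <- intersect(rownames(cmp), rownames(met))
  if (length(shared_c) == 0L) stop("no compounds shared between CMP scores and metabolite table")
  list(cmp = cmp[shared_c, shared_s, drop = FALSE],
       met = met[shared_c, shared_s, drop = FALSE])
}

#' Mantel screening of all metabolites against their CMP scores
#'
#' Aligns the CMP score matrix with the measured metabolite table (exact
#' sample-identifier match, compound intersection), runs a Mantel
#' permutation test per compound, estimates q-values by permutation-null
#' resampling ([bootstrap_fdr()]), and classifies well-predicted compounds.
#'
#' @param cmp Compounds x samples CMP matrix ([compute_cmp()]).
#' @param met Compounds x samples measured metabolite abundances (compound
#'   identifiers mapped to the reaction network's compound ids).
#' @param n_perm Mantel permutations per test (default 999).
#' @param n_boot Null-resampling rounds for the FDR (default 50).
#' @param alpha Well-predicted threshold on p and q (default 0.01).
#' @param seed Optional integer seed covering both stages.
#' @return An `association_result` data frame: `compound`, `mantel_r`,
#'   `p_value`, `q_value`, `direction`, `well_predicted`. Compounds with a
#'   constant layer get NA statistics and are never well predicted.
#' @export
associate_metabolites <- function(cmp, met, n_perm = 999, n_boot = 50,
                                  alpha = 0.01, seed = NULL) {
  al <- align_layers(cmp, met)
  if (!is.null(seed)) set.seed(seed)
  res <- mantel_screen(al$cmp, al$met, n_perm = n_perm)
  res$q_value <- bootstrap_fdr(res$p_value, al$cmp, al$met,
                               n_boot = n_boot, n_perm = n_perm)
  res$direction <- vapply(seq_len(nrow(res)), function(i) {
    x <- al$cmp[i, ]; y <- al$met[i, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    sign(cor(x, y))
  }, numeric(1))
  classify_well_predicted(res, alpha = alpha)
}

#' Build the taxa-metabolite association network
#'
#' Connects each well-predicted metabolite to the taxa whose single-taxon
#' CMP profiles track the community profile (contribution correlation above
#' the threshold). Edge weight is the contribution correlation; node
#' attributes carry mean relative abundances for sizing.
#'
#' @param results An `association_result` data frame.
#' @param contributions Named list of [taxon_contribution()] tables, one per
#'   well-predicted compound.
#' @param metabolite_abundance Optional named vector of mean metabolite
#'   abundances (node attribute).
#' @param taxon_abundance Optional named vector of mean taxon relative
#'   abundances (node attribute).
#' @return An [igraph::graph] with vertex attributes `type`
#'   (`"metabolite"`/`"taxon"`) and `abundance`, and edge attribute
#'   `weight`. Empty graph if nothing is well predicted.
#' @export
build_network <- function(results, contributions,
                          metabolite_abundance = NULL, taxon_abundance = NULL) {
  wp <- results$compound[results$well_predicted]
  edges <- do.call(rbind, lapply(wp, function(cpd) {
    ct <- contributions[[cpd]]
    if (is.null(ct)) return(NULL)
    sig <- ct[!is.na(ct$r) & ct$significant, , drop = FALSE]
    if (nrow(sig) == 0L) return(NULL)
    data.frame(from = cpd, to = sig$taxon, weight = sig$r,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  type <- ifelse(igraph::V(g)$name %in% results$compound, "metabolite", "taxon")
  igraph::V(g)$type <- type
  ab <- rep(NA_real_, igraph::vcount(g))
  if (!is.null(metabolite_abundance)) {
    hit <- match(igraph::V(g)$name, names(metabolite_abundance))
    ab[!is.na(hit)] <- metabolite_abundance[hit[!is.na(hit)]]
  }
  if (!is.null(taxon_abundance)) {
    hit <- match(igraph::V(g)$name, names(taxon_abundance))
    ab[!is.na(hit)] <- taxon_abundance[hit[!is.na(hit)]]
  }
  igraph::V(g)$abundance <- ab
  g
}

#' Write an association network as edge-list and node-attribute TSVs
#'
#' @param g Graph from [build_network()].
#' @param edge_path,node_path Output TSV paths.
#' @export
write_network <- function(g, edge_path, node_path) {
  if (igraph::ecount(g) == 0L) {
    write.table(data.frame(from = character(), to = character(), weight = numeric()),
                edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(node = character(), type = character(), abundance = numeric()),
                node_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(NULL))
  }
  el <- igraph::as_data_frame(g, what = "edges")
  write.table(el, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(node = igraph::V(g)$name, type = igraph::V(g)$type,
                      abundance = igraph::V(g)$abundance)
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
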