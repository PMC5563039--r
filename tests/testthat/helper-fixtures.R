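# Shared fixture builders; everything is generated in code at test time.

# Strip score-matrix bookkeeping attributes for numeric comparison.
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

write_reaction_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("reaction_id\tgene_family\tcompound\tcoefficient\treversible", lines),
             path)
  path
}

# Random reaction set as a plain data.frame (not via generate_network, so
# property tests on the builder do not depend on the generator under test).
random_reactions <- function(n_compounds, n_families, n_records, seed) {
  set.seed(seed)
  data.frame(
    reaction_id = sprintf("R%03d", seq_len(n_records)),
    gene_family = sprintf("K%03d", sample.int(n_families, n_records, replace = TRUE)),
    compound = sprintf("C%03d", sample.int(n_compounds, n_records, replace = TRUE)),
    coefficient = sample(c(-3:-1, 1:3), n_records, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Two-taxon profile where taxon A exclusively carries compound C1's producing
# family (K1) while taxon B carries C1's consuming family (K2) and all of
# compound C2's families (K3, K4). Abundances are left unclosed (sums < 1,
# remainder = unmodeled taxa) so the two taxa vary independently and
# correlations can tell them apart.
two_taxon_fixture <- function(n_samples = 8, seed = 42) {
  set.seed(seed)
  gc <- rbind(A = c(K1 = 2, K2 = 0, K3 = 0, K4 = 0),
              B = c(K1 = 0, K2 = 1, K3 = 1, K4 = 2))
  ab <- rbind(A = runif(n_samples, 0.2, 0.5),
              B = runif(n_samples, 0.2, 0.5))
  colnames(ab) <- sprintf("s%02d", seq_len(n_samples))
  rx <- data.frame(
    gene_family = c("K1", "K2", "K3", "K4"),
    compound    = c("C1", "C1", "C2", "C2"),
    coefficient = c(2, -1, 1, 3),
    stringsAsFactors = FALSE)
  list(profile = taxon_profile(gc, ab), reactions = rx,
       m = build_stoichiometric_matrix(rx))
}

# Independent triple-loop CMP oracle (never calls compute_cmp internals).
cmp_oracle <- function(m, g) {
  shared <- intersect(colnames(m), rownames(g))
  out <- matrix(0, nrow(m), ncol(g), dimnames = list(rownames(m), colnames(g)))
  for (c in seq_len(nrow(m))) {
    for (s in seq_len(ncol(g))) {
      acc <- 0
      for (k in shared) acc <- acc + m[c, k] * g[k, s]
      out[c, s] <- acc
    }
  }
  out
}

# Independent exhaustive Mantel oracle: plain-R enumeration over all
# relabelings, statistic computed with stats::cor on full distance vectors.
mantel_enum_oracle <- function(x, y) {
  n <- length(x)
  perms <- gtools_style_perms(n)
  dvec <- function(v) {
    d <- abs(outer(v, v, "-"))
    d[upper.tri(d)]
  }
  dy <- dvec(y)
  obs <- cor(dvec(x), dy)
  stats <- apply(perms, 1, function(p) cor(dvec(x[p]), dy))
  list(statistic = obs, p_value = mean(stats >= obs - 1e-12))
}

# Heap-free recursive permutation enumeration, independent of the package's.
gtools_style_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_style_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1L))
  }))
}

# Tiny aligned CMP/metabolite pair with `n_coupled` perfectly coupled rows.
coupled_layers <- function(n_compounds = 12, n_samples = 12, n_coupled = 0,
                           seed = 1) {
  set.seed(seed)
  cmp <- matrix(rnorm(n_compounds * n_samples), n_compounds,
                dimnames = list(sprintf("C%02d", seq_len(n_compounds)),
                                sprintf("s%02d", seq_len(n_samples))))
  met <- matrix(rnorm(n_compounds * n_samples), n_compounds,
                dimnames = dimnames(cmp))
  if (n_coupled > 0) {
    for (i in seq_len(n_coupled)) met[i, ] <- 1.5 * cmp[i, ]
  }
  list(cmp = cmp, met = met)
}
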