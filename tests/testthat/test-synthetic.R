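test_that("the default design is 4 doses x 2 times x 10 mice", {
  d <- study_design()
  expect_equal(nrow(d), 80L)
  expect_setequal(unique(d$dose), c(0, 0.1, 0.25, 1.0))
  expect_setequal(unique(d$time), c(10, 30))
  expect_equal(anyDuplicated(d$sample_id), 0L)
  expect_error(study_design(n_per_group = 1), "n_per_group")
})

test_that("generated networks are reproducible, bounded and producer-complete", {
  n1 <- generate_network(25, 40, density = 0.1, seed = 5)
  n2 <- generate_network(25, 40, density = 0.1, seed = 5)
  expect_identical(n1, n2)
  has_producer <- tapply(n1$coefficient, n1$compound, function(x) any(x > 0))
  expect_true(all(has_producer))
  dense <- generate_network(6, 8, density = 1, seed = 1)
  expect_equal(nrow(dense), 6L * 8L)
  expect_error(generate_network(5, 5, density = 0), "density")
})

test_that("generated networks round-trip through the parser", {
  rx <- generate_network(12, 20, density = 0.15, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(rx, path)
  back <- parse_reaction_table(path, quiet = TRUE)
  expect_equal(back$gene_family, rx$gene_family)
  expect_equal(back$compound, rx$compound)
  expect_equal(back$coefficient, rx$coefficient)
})

test_that("community OTU counts hit the configured depth and abundances sum to 1", {
  d <- study_design(n_per_group = 3)
  comm <- generate_community(d, n_taxa = 10, n_families = 30, seed = 4,
                             depth = 2000)
  expect_true(all(colSums(comm$otu) == 2000))
  expect_equal(unname(colSums(comm$profile$abundances)), rep(1, nrow(d)),
               tolerance = 1e-12)
  expect_identical(colnames(comm$otu), d$sample_id)
})

test_that("a planted responder taxon is recovered by a two-group comparison", {
  d <- study_design(n_per_group = 10)
  spec <- data.frame(taxon = "T003", dose = 0.1, time = 10, log2fc = 2)
  comm <- generate_community(d, n_taxa = 12, n_families = 30,
                             responder_spec = spec, seed = 21, depth = 5000)
  ab <- comm$profile$abundances["T003", ]
  hit_group <- d$dose == 0.1 & d$time == 10
  ctrl_group <- d$dose == 0 & d$time == 10
  expect_gt(mean(ab[hit_group]), mean(ab[ctrl_group]))
  w <- stats::wilcox.test(ab[hit_group], ab[ctrl_group], alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("without responders the groups differ only by sampling noise", {
  d <- study_design(n_per_group = 10)
  comm <- generate_community(d, n_taxa = 8, n_families = 20, seed = 31,
                             depth = 5000)
  ab <- comm$profile$abundances
  p <- vapply(rownames(ab), function(t) {
    stats::kruskal.test(ab[t, ], interaction(d$dose, d$time))$p.value
  }, numeric(1))
  # 8 independent null tests: none should be extreme
  expect_gt(min(p), 0.001)
})

test_that("noise-free planted compounds are exact affine images of their scores", {
  st <- generate_study(design = study_design(n_per_group = 2),
                       n_compounds = 10, n_families = 30, n_taxa = 4,
                       n_planted = 3, rho = 1, seed = 3, depth = 1000)
  truth <- st$truth
  expect_gt(length(truth$well_predicted_set), 0L)
  cpd <- truth$well_predicted_set[1L]
  fitlm <- stats::lm(st$metabolites[cpd, ] ~ st$cmp[cpd, ])
  expect_lt(max(abs(stats::residuals(fitlm))), 1e-9)
  expect_equal(unname(truth$realized_r[cpd]), 1, tolerance = 1e-9)

  res <- mantel_test(st$cmp[cpd, ], st$metabolites[cpd, ], n_perm = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("unplanted compounds have correlations typical of noise", {
  st <- generate_study(n_compounds = 60, n_families = 100, n_taxa = 10,
                       n_planted = 10, rho = 0.8, seed = 13, depth = 2000)
  truth <- st$truth
  null_r <- truth$realized_r[setdiff(truth$compounds, truth$well_predicted_set)]
  null_r <- null_r[!is.na(null_r)]
  # |r| for independent noise at n = 80 has sd ~ 1/sqrt(79)
  expect_lt(median(abs(null_r)), 3 / sqrt(79))
  planted_r <- truth$realized_r[truth$well_predicted_set]
  expect_gt(min(planted_r), 0.5)
})

test_that("study generation is seed-reproducible end to end", {
  a <- generate_study(design = study_design(n_per_group = 2), n_compounds = 8,
                      n_families = 20, n_taxa = 4, n_planted = 2, seed = 77,
                      depth = 500)
  b <- generate_study(design = study_design(n_per_group = 2), n_compounds = 8,
                      n_families = 20, n_taxa = 4, n_planted = 2, seed = 77,
                      depth = 500)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$otu, b$otu)
  expect_identical(a$truth$well_predicted_set, b$truth$well_predicted_set)
})

test_that("written studies are complete and consistent on disk", {
  st <- generate_study(design = study_design(n_per_group = 2), n_compounds = 8,
                       n_families = 20, n_taxa = 4, n_planted = 2, seed = 15,
                       depth = 500)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "reactions.tsv", "gene_content.tsv", "taxa_abundance.tsv", "otu_table.tsv",
    "ko_table.tsv", "metabolites.tsv", "truth.json", "manifest.json")))))
  back <- parse_reaction_table(file.path(dir, "reactions.tsv"), quiet = TRUE)
  m_back <- build_stoichiometric_matrix(back)
  expect_equal(unclass(m_back), unclass(st$m))
  met_back <- read_matrix_tsv(file.path(dir, "metabolites.tsv"))
  met_orig <- st$metabolites
  attr(met_orig, "truth") <- NULL
  expect_equal(met_back, met_orig, tolerance = 1e-12)
})
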