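test_that("a perfect linear relation gives r = 1 at the smallest attainable p", {
  set.seed(2)
  x <- rnorm(12)
  res <- mantel_test(x, 2 * x, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1.0, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("the permutation p at n = 5 equals exhaustive enumeration", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(5)
    y <- 0.5 * x + rnorm(5)
    got <- mantel_test(x, y, n_perm = 999)
    expect_equal(got$method, "exact")
    expect_equal(got$n_perm, 120L)
    oracle <- mantel_enum_oracle(x, y)
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, oracle$p_value)
  }
})

test_that("the Mantel statistic agrees with vegan on the same distance matrices", {
  set.seed(13)
  x <- rnorm(15)
  y <- 0.7 * x + rnorm(15)
  ours <- mantel_test(x, y, n_perm = 999, seed = 3)
  ref <- vegan::mantel(stats::dist(x), stats::dist(y), permutations = 999)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.02)
})

test_that("Mantel p is invariant to positive affine rescaling of either vector", {
  set.seed(4)
  x <- rnorm(10)
  y <- rnorm(10)
  a <- mantel_test(x, y, n_perm = 499, seed = 11)
  b <- mantel_test(3 * x + 7, y, n_perm = 499, seed = 11)
  d <- mantel_test(x, 0.1 * y - 2, n_perm = 499, seed = 11)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, d$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, d$p_value)
})

test_that("the Mantel test is sign-blind and the direction field carries the sign", {
  set.seed(6)
  x <- rnorm(10)
  pos <- mantel_test(x, x, n_perm = 499, seed = 2)
  neg <- mantel_test(x, -x, n_perm = 499, seed = 2)
  expect_equal(pos$statistic, neg$statistic, tolerance = 1e-12)
  expect_equal(pos$p_value, neg$p_value)

  ly <- coupled_layers(n_compounds = 2, n_samples = 10, seed = 9)
  ly$met[1, ] <- ly$cmp[1, ]
  ly$met[2, ] <- -ly$cmp[2, ]
  res <- associate_metabolites(ly$cmp, ly$met, n_perm = 199, n_boot = 10, seed = 5)
  expect_equal(res$direction, c(1, -1))
})

test_that("degenerate inputs are rejected", {
  expect_error(mantel_test(rep(1, 6), rnorm(6)), "undefined")
  expect_error(mantel_test(rnorm(6), rnorm(5)), "alignment")
  expect_error(mantel_test(rnorm(3), rnorm(3)), "at least 4")
})

test_that("null p-values are close to uniform", {
  set.seed(21)
  p <- replicate(300, {
    mantel_test(rnorm(15), rnorm(15), n_perm = 199)$p_value
  })
  rej <- mean(p <= 0.05)
  ci <- qbinom(c(0.005, 0.995), 300, 0.05) / 300
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the empirical FDR is near 1 under the global null", {
  ly <- coupled_layers(n_compounds = 15, n_samples = 12, n_coupled = 0, seed = 3)
  res <- associate_metabolites(ly$cmp, ly$met, n_perm = 199, n_boot = 20, seed = 8)
  expect_gt(median(res$q_value), 0.5)
  expect_false(any(res$well_predicted))
})

test_that("perfect coupling drives q to the attainable floor", {
  ly <- coupled_layers(n_compounds = 15, n_samples = 12, n_coupled = 15, seed = 4)
  set.seed(10)
  p <- mantel_screen(ly$cmp, ly$met, n_perm = 199)$p_value
  expect_true(all(p == 1 / 200))
  q <- bootstrap_fdr(p, ly$cmp, ly$met, n_boot = 20, n_perm = 199, seed = 10)
  # numerator is the mean count of null p-values at the floor: small but >= 0
  expect_true(all(q < 0.2))
  expect_equal(length(unique(q)), 1L)
})

test_that("identical observed p-values get identical q-values", {
  ly <- coupled_layers(n_compounds = 6, n_samples = 10, n_coupled = 6, seed = 5)
  p <- rep(0.02, 6)
  q <- bootstrap_fdr(p, ly$cmp, ly$met, n_boot = 15, n_perm = 99, seed = 2)
  expect_equal(length(unique(q)), 1L)
})

test_that("q-values are monotone in the observed p-values", {
  ly <- coupled_layers(n_compounds = 20, n_samples = 12, n_coupled = 6, seed = 6)
  res <- associate_metabolites(ly$cmp, ly$met, n_perm = 199, n_boot = 15, seed = 3)
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
})

test_that("the well-predicted rule is a strict conjunction", {
  base <- data.frame(compound = c("a", "b", "c", "d"),
                     mantel_r = 0.5,
                     p_value = c(0.005, 0.005, 0.01, 0.02),
                     q_value = c(0.005, 0.02, 0.005, 0.005),
                     direction = 1)
  res <- classify_well_predicted(base)
  expect_equal(res$well_predicted, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("sub-threshold FDR rounds warn about instability", {
  ly <- coupled_layers(n_compounds = 4, n_samples = 10, seed = 7)
  set.seed(1)
  p <- mantel_screen(ly$cmp, ly$met, n_perm = 99)$p_value
  expect_warning(bootstrap_fdr(p, ly$cmp, ly$met, n_boot = 5, n_perm = 99),
                 "unstable")
})

test_that("network construction respects the edge invariants", {
  res <- data.frame(compound = c("C1", "C2"), mantel_r = c(0.8, 0.1),
                    p_value = c(0.001, 0.5), q_value = c(0.001, 0.9),
                    direction = 1, well_predicted = c(TRUE, FALSE))
  ct <- structure(
    data.frame(taxon = c("A", "B"), r = c(0.9, 0.2),
               significant = c(TRUE, FALSE)),
    class = c("taxon_contribution", "data.frame"), key_contributor = "A")
  g <- build_network(res, list(C1 = ct),
                     metabolite_abundance = c(C1 = 2),
                     taxon_abundance = c(A = 0.4, B = 0.6))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 0.9)
  expect_setequal(igraph::V(g)$name, c("C1", "A"))

  g0 <- build_network(res[2, , drop = FALSE], list())
  expect_equal(igraph::ecount(g0), 0L)

  paths <- c(withr::local_tempfile(fileext = ".tsv"),
             withr::local_tempfile(fileext = ".tsv"))
  write_network(g, paths[1], paths[2])
  edges <- read.delim(paths[1])
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$weight, 0.9)
})
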