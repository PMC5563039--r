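test_that("the low-abundance filter honors the strict inequality", {
  counts <- matrix(0L, 3, 2, dimnames = list(c("o_keep", "o_edge", "o_drop"),
                                             c("s1", "s2")))
  counts["o_keep", ] <- c(499995L, 499996L)  # grand total 1,000,000
  counts["o_edge", ] <- c(2L, 3L)            # exactly 5 = 0.0005%
  counts["o_drop", ] <- c(2L, 2L)            # 4 < 5, removed
  filtered <- filter_low_abundance(counts, quiet = TRUE)
  expect_setequal(rownames(filtered), c("o_keep", "o_edge"))
  expect_identical(filter_low_abundance(counts, fraction_threshold = 0,
                                        quiet = TRUE), counts)
})

test_that("the filter matches a brute-force per-OTU scan on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    counts <- matrix(rpois(40 * 6, lambda = 4), 40, 6,
                     dimnames = list(sprintf("o%02d", 1:40), sprintf("s%d", 1:6)))
    thr <- 0.004
    got <- filter_low_abundance(counts, thr, quiet = TRUE)
    keep <- vapply(seq_len(nrow(counts)),
                   function(i) sum(counts[i, ]) / sum(counts) >= thr, logical(1))
    expect_identical(got, counts[keep, , drop = FALSE])
  }
})

test_that("rarefaction yields exact depths and is seed-stable", {
  set.seed(3)
  counts <- matrix(rpois(30 * 5, lambda = 100), 30, 5,
                   dimnames = list(sprintf("o%02d", 1:30), sprintf("s%d", 1:5)))
  rar1 <- rarefy_table(counts, depth = 500, seed = 7)
  expect_true(all(colSums(rar1) == 500))
  expect_true(all(rar1 <= counts))
  rar2 <- rarefy_table(counts, depth = 500, seed = 7)
  expect_identical(rar1, rar2)
  rar3 <- rarefy_table(counts, depth = 500, seed = 8)
  expect_false(identical(rar1, rar3))
})

test_that("samples already at depth are returned unchanged", {
  counts <- matrix(c(100L, 200L, 300L), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  rar <- rarefy_table(counts, depth = 600, seed = 1)
  expect_identical(rar[, 1], counts[, 1])
})

test_that("shallow samples are removed, or everything fails loudly", {
  counts <- matrix(c(100L, 100L, 5L, 5L), 2, 2,
                   dimnames = list(c("a", "b"), c("deep", "shallow")))
  expect_warning(rar <- rarefy_table(counts, depth = 150, seed = 2), "shallow")
  expect_equal(colnames(rar), "deep")
  expect_error(suppressWarnings(rarefy_table(counts, depth = 10000, seed = 2)),
               "fewer than")
})

test_that("rarefied per-OTU means track the hypergeometric expectation", {
  set.seed(9)
  counts <- matrix(as.integer(c(600, 300, 100)), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  depth <- 200
  draws <- sapply(1:300, function(i) rarefy_table(counts, depth, seed = i)[, 1])
  expected <- depth * counts[, 1] / sum(counts)
  expect_equal(rowMeans(draws), expected, tolerance = 0.05)
})

test_that("filtering commutes with OTU relabeling", {
  set.seed(12)
  counts <- matrix(rpois(20 * 4, 10), 20, 4,
                   dimnames = list(sprintf("o%02d", 1:20), sprintf("s%d", 1:4)))
  perm <- sample.int(20)
  f1 <- filter_low_abundance(counts[perm, ], 0.01, quiet = TRUE)
  f2 <- filter_low_abundance(counts, 0.01, quiet = TRUE)[perm[perm %in%
    which(rowSums(counts) / sum(counts) >= 0.01)], , drop = FALSE]
  expect_setequal(rownames(f1), rownames(f2))
  expect_identical(f1[sort(rownames(f1)), ], f2[sort(rownames(f2)), ])
})

test_that("class enrichment reproduces the hand-computed fold ratio", {
  background <- sprintf("m%03d", 1:100)
  subset <- background[1:10]
  cls <- data.frame(id = background[c(1:5, 11:15)], class = "X")
  res <- class_enrichment(subset, background, cls)
  expect_equal(res$fold_ratio[res$class == "X"], (5 / 10) / (10 / 100))
  expect_equal(res$subset_hits, 5L)
  expect_equal(res$background_hits, 10L)
})

test_that("the over-representation p equals the term-by-term tail sum", {
  res <- class_enrichment(sprintf("m%03d", 1:10), sprintf("m%03d", 1:100),
                          data.frame(id = sprintf("m%03d", c(1:5, 11:15)),
                                     class = "X"))
  # P(X >= 5) with 10 class members, 90 others, 10 drawn
  oracle <- sum(vapply(5:10, function(k) dhyper(k, 10, 90, 10), numeric(1)))
  expect_equal(res$p_over, oracle, tolerance = 1e-12)
})

test_that("subset = background is the identity case", {
  ids <- sprintf("m%02d", 1:30)
  cls <- data.frame(id = ids, class = rep(c("X", "Y"), 15))
  res <- class_enrichment(ids, ids, cls)
  expect_true(all(res$fold_ratio == 1))
  expect_true(all(res$p_over == 1))
})

test_that("classes absent from the subset are reported with valid p-values", {
  background <- sprintf("m%02d", 1:40)
  cls <- data.frame(id = background, class = rep(c("X", "Y"), each = 20))
  res <- class_enrichment(background[1:20], background, cls)
  expect_setequal(res$class, c("X", "Y"))
  expect_equal(res$subset_hits[res$class == "Y"], 0L)
  expect_true(all(res$p_over > 0 & res$p_over <= 1))
  expect_true(all(res$p_under > 0 & res$p_under <= 1))
})

test_that("semicolon-delimited class labels are expanded", {
  background <- c("m1", "m2", "m3", "m4")
  cls <- data.frame(id = c("m1", "m2"), class = c("X;Y", "Y"))
  res <- class_enrichment(c("m1", "m2"), background, cls)
  expect_equal(res$background_hits[res$class == "Y"], 2L)
  expect_equal(res$background_hits[res$class == "X"], 1L)
})

test_that("OTU tables round-trip through the TSV reader", {
  set.seed(5)
  counts <- matrix(rpois(12, 50), 4, 3,
                   dimnames = list(sprintf("o%d", 1:4), sprintf("s%d", 1:3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(counts, path)
  expect_identical(read_otu_table(path), counts)
})
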