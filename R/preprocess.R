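#' Remove low-abundance OTUs from a count table
#'
#' Drops OTUs whose share of all reads in the dataset is strictly below
#' `fraction_threshold`. The default, 5e-6 (0.0005 %), is the independent
#' filter recommended for deeply sequenced amplicon tables; it discards
#' mostly-spurious rare OTUs and raises differential-abundance detection
#' sensitivity.
#'
#' @param counts Integer matrix, OTUs x samples.
#' @param fraction_threshold Strict lower bound on the dataset-wide count
#'   fraction; an OTU at exactly the threshold is kept.
#' @param quiet Suppress the removal-count message.
#' @return The filtered count matrix.
#' @export
filter_low_abundance <- function(counts, fraction_threshold = 5e-6, quiet = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("count table has no reads")
  frac <- rowSums(counts) / total
  keep <- frac >= fraction_threshold
  if (!quiet) {
    message(sprintf("filter_low_abundance: removed %d of %d OTUs below %.6g of total reads",
                    sum(!keep), nrow(counts), fraction_threshold))
  }
  counts[keep, , drop = FALSE]
}

#' Rarefy a count table to a fixed per-sample depth
#'
#' Randomly subsamples each sample's reads without replacement to exactly
#' `depth` reads. Samples with fewer classified reads than `depth` cannot be
#' rarefied and are removed with a warning, mirroring the usual
#' sample-exclusion rule. Deterministic given `seed`.
#'
#' @param counts Integer matrix, OTUs x samples.
#' @param depth Target reads per sample (default 60000).
#' @param seed Integer seed; required for reproducible pipelines.
#' @return Rarefied count matrix; every column sums to exactly `depth`.
#' @export
rarefy_table <- function(counts, depth = 60000, seed = NULL) {
  stopifnot(is.matrix(counts), depth > 0)
  totals <- colSums(counts)
  low <- totals < depth
  if (all(low)) stop("all samples have fewer than ", depth, " reads")
  if (any(low)) {
    warning(sum(low), " sample(s) with fewer than ", depth,
            " classified reads removed: ",
            paste(colnames(counts)[low], collapse = ", "))
    counts <- counts[, !low, drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  # vegan works on samples-as-rows community matrices; its advisory about
  # count magnitudes does not apply to already-integer OTU tables
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(rar) <- "integer"
  rar
}

#' Hypergeometric class enrichment of a compound subset
#'
#' For each class label, tests whether the subset (e.g. condition-specific
#' or well-predicted compounds) contains more (or fewer) members of the
#' class than expected from its background frequency. The fold ratio is the
#' subset class frequency over the background class frequency; p-values are
#' exact hypergeometric tail sums (over-representation and
#' under-representation), reported raw by default as is customary for these
#' screens; set `adjust` for a multiplicity correction.
#'
#' @param subset_ids Identifiers of the subset; must be contained in
#'   `background_ids`.
#' @param background_ids Identifiers of the full background set.
#' @param class_map Data frame with columns `id` and `class`; an id may
#'   appear with several classes (one row each, or semicolon-delimited in
#'   the `class` column).
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (e.g. `"BH"`); default `"none"`.
#' @return Data frame with one row per class occurring in the background:
#'   `class`, `subset_hits`, `subset_size`, `background_hits`,
#'   `background_size`, `fold_ratio`, `p_over`, `p_under`. Classes absent
#'   from the subset are still reported; `fold_ratio` is NA when a class has
#'   no background members.
#' @export
class_enrichment <- function(subset_ids, background_ids, class_map,
                             adjust = "none") {
  stopifnot(all(c("id", "class") %in% names(class_map)))
  subset_ids <- unique(subset_ids)
  background_ids <- unique(background_ids)
  if (!all(subset_ids %in% background_ids)) {
    stop("subset identifiers must be a subset of the background")
  }
  # expand semicolon-delimited multi-class labels
  split_classes <- strsplit(as.character(class_map$class), ";", fixed = TRUE)
  map <- data.frame(id = rep(class_map$id, lengths(split_classes)),
                    class = trimws(unlist(split_classes)),
                    stringsAsFactors = FALSE)
  map <- unique(map[map$id %in% background_ids & nzchar(map$class), , drop = FALSE])
  classes <- sort(unique(map$class))
  N <- length(background_ids)
  n <- length(subset_ids)
  out <- do.call(rbind, lapply(classes, function(cl) {
    members <- map$id[map$class == cl]
    K <- length(members)
    k <- sum(subset_ids %in% members)
    fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(class = cl, subset_hits = k, subset_size = n,
               background_hits = K, background_size = N,
               fold_ratio = fold,
               p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               p_under = phyper(k, K, N - K, n, lower.tail = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(class = character(), subset_hits = integer(),
                      subset_size = integer(), background_hits = integer(),
                      background_size = integer(), fold_ratio = numeric(),
                      p_over = numeric(), p_under = numeric()))
  }
  if (adjust != "none") {
    out$p_over_adj <- stats::p.adjust(out$p_over, method = adjust)
    out$p_under_adj <- stats::p.adjust(out$p_under, method = adjust)
  }
  rownames(out) <- NULL
  out
}

#' Read an OTU count table from TSV or BIOM (JSON) format
#'
#' @param path Path to a tab-delimited table (first column = OTU ids,
#'   remaining columns = integer sample counts) or a JSON-dialect `.biom`
#'   file (requires the biomformat package).
#' @return Integer matrix, OTUs x samples.
#' @export
read_otu_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading .biom files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
  } else {
    m <- read_matrix_tsv(path)
  }
  storage.mode(m) <- "integer"
  m
}
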