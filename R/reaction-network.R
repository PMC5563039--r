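#' Parse a reaction table linking gene families to compounds
#'
#' Reads a TSV describing enzymatic reactions: which gene family (KEGG
#' Orthology style identifier) produces (positive coefficient) or consumes
#' (negative coefficient) which compound, and whether the reaction is
#' reversible. Reversible reactions are dropped by default because the
#' stoichiometric scoring assumes a defined net direction; a reversible
#' record has no net sign, and expanding it into both directions cancels
#' to zero under aggregation.
#'
#' Duplicate (gene_family, compound) pairs are aggregated by summing their
#' coefficients (net contribution across reactions); pairs whose net
#' coefficient is exactly zero are removed.
#'
#' @param path Path to a TSV file with a header row and columns
#'   `reaction_id`, `gene_family`, `compound`, `coefficient`,
#'   `reversible` (`true`/`false`).
#' @param keep_reversible Keep records flagged reversible, using their
#'   stated direction as written. Default `FALSE`.
#' @param quiet Suppress the retained/dropped record counts message.
#' @return A `data.frame` of class `reaction_table` with columns
#'   `reaction_id`, `gene_family`, `compound`, `coefficient`. Aggregated
#'   records carry the contributing reaction ids joined with `";"`.
#' @seealso [build_stoichiometric_matrix()]
#' @export
parse_reaction_table <- function(path, keep_reversible = FALSE, quiet = FALSE) {
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("reaction_id", "gene_family", "compound", "coefficient", "reversible")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("reaction table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("empty network: ", path, " has no reaction records")

  coef <- suppressWarnings(as.numeric(raw$coefficient))
  bad <- which(is.na(coef) | !nzchar(raw$gene_family) | !nzchar(raw$compound))
  if (length(bad) > 0L) {
    # +1 for the header row so the number matches the file
    stop("malformed reaction record at line ", bad[1L] + 1L, " of ", path,
         " (non-numeric coefficient or empty identifier)")
  }
  rev_chr <- tolower(raw$reversible)
  if (!all(rev_chr %in% c("true", "false", "t", "f", "1", "0"))) {
    bad <- which(!(rev_chr %in% c("true", "false", "t", "f", "1", "0")))[1L]
    stop("malformed reversible flag at line ", bad + 1L, " of ", path)
  }
  reversible <- rev_chr %in% c("true", "t", "1")

  n_rev <- sum(reversible)
  keep <- if (keep_reversible) rep(TRUE, nrow(raw)) else !reversible
  rx <- data.frame(reaction_id = raw$reaction_id[keep],
                   gene_family = raw$gene_family[keep],
                   compound    = raw$compound[keep],
                   coefficient = coef[keep],
                   stringsAsFactors = FALSE)
  if (nrow(rx) == 0L) stop("empty network: all records in ", path, " are reversible")

  key <- paste(rx$gene_family, rx$compound, sep = "\r")
  agg_coef <- tapply(rx$coefficient, key, sum)
  agg_ids  <- tapply(rx$reaction_id, key, function(x) paste(unique(x), collapse = ";"))
  keys <- names(agg_coef)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(reaction_id = unname(agg_ids[keys]),
                    gene_family = vapply(parts, `[[`, "", 1L),
                    compound    = vapply(parts, `[[`, "", 2L),
                    coefficient = unname(as.numeric(agg_coef)),
                    stringsAsFactors = FALSE)
  cancelled <- abs(out$coefficient) == 0
  out <- out[!cancelled, , drop = FALSE]
  if (nrow(out) == 0L) stop("empty network: all coefficients cancel to zero")
  out <- out[order(out$compound, out$gene_family), , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet) {
    message(sprintf(
      "parse_reaction_table: %d records read, %d reversible %s, %d cancelled, %d retained",
      nrow(raw), n_rev, if (keep_reversible) "kept" else "dropped",
      sum(cancelled), nrow(out)))
  }
  class(out) <- c("reaction_table", "data.frame")
  out
}

#' Build the normalized compound-by-gene-family stoichiometric matrix
#'
#' Assembles the raw stoichiometric matrix by summing coefficients per
#' (compound, gene family) cell, then normalizes each compound row so that
#' its positive entries sum to 1 and its negative entries to -1. Each entry
#' is then the relative contribution of a gene family to the production
#' (positive) or depletion (negative) of the compound, the form required by
#' metabolite-potential scoring.
#'
#' @param reactions A `reaction_table` from [parse_reaction_table()], or any
#'   data.frame with `gene_family`, `compound` and `coefficient` columns.
#' @return A numeric matrix of class `stoich_matrix` (rows = compounds,
#'   columns = gene families). All-zero compound rows are dropped with a
#'   warning.
#' @examples
#' rx <- data.frame(gene_family = c("K1", "K2", "K4"),
#'                  compound = "C1", coefficient = c(2, 1, -1))
#' build_stoichiometric_matrix(rx)["C1", ]  # 2/3, 1/3, -1
#' @export
build_stoichiometric_matrix <- function(reactions) {
  stopifnot(is.data.frame(reactions),
            all(c("gene_family", "compound", "coefficient") %in% names(reactions)))
  if (nrow(reactions) == 0L) stop("empty network: no reactions to assemble")
  compounds <- sort(unique(reactions$compound))
  families  <- sort(unique(reactions$gene_family))
  m <- matrix(0, nrow = length(compounds), ncol = length(families),
              dimnames = list(compounds, families))
  i <- match(reactions$compound, compounds)
  j <- match(reactions$gene_family, families)
  for (k in seq_len(nrow(reactions))) {
    m[i[k], j[k]] <- m[i[k], j[k]] + reactions$coefficient[k]
  }
  zero_rows <- rowSums(abs(m)) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " compound row(s) are all-zero after aggregation; dropped")
    m <- m[!zero_rows, , drop = FALSE]
  }
  normalize_stoichiometry(m)
}

#' Row-normalize a stoichiometric matrix
#'
#' Per compound row, divides positive entries by their sum and negative
#' entries by the absolute value of their sum, so positives sum to 1 and
#' negatives to -1 (rows lacking one sign keep only the other). The
#' operation is idempotent.
#'
#' @param m Numeric matrix, rows = compounds, columns = gene families.
#' @return The normalized matrix, class `stoich_matrix`.
#' @export
normalize_stoichiometry <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  pos <- pmax(m, 0)
  neg <- pmin(m, 0)
  pos_sum <- rowSums(pos)
  neg_sum <- rowSums(neg)  # <= 0
  pos_scaled <- pos / ifelse(pos_sum > 0, pos_sum, 1)
  neg_scaled <- neg / ifelse(neg_sum < 0, -neg_sum, 1)
  out <- pos_scaled + neg_scaled
  class(out) <- c("stoich_matrix", class(matrix()))
  out
}

#' Write a stoichiometric (or any labeled) matrix as TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output path. Rows become lines; the first column holds the
#'   row identifier under the header `id`.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' First column (any name) is taken as row identifiers; remaining columns
#' must be numeric.
#'
#' @param path TSV path with header.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix file ", path)
  rownames(m) <- df[[1L]]
  m
}
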