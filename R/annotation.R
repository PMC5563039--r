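# Proton mass in Da; electron-mass refinement is below the 1 ppm floor at
# the masses handled here.
PROTON_MASS <- 1.007276

#' Neutral monoisotopic mass from an observed m/z
#'
#' Inverts the singly protonated adducts: `[M+H]+` in positive mode
#' (subtract a proton) and `[M-H]-` in negative mode (add a proton). These
#' are the only adducts currently implemented.
#'
#' @param mz Observed mass-to-charge ratio(s), Da.
#' @param mode `"positive"` or `"negative"` (recycled over `mz`).
#' @return Neutral mass(es) in Da.
#' @examples
#' neutral_mass(556.2771, "positive")  # 555.2698
#' neutral_mass(554.2615, "negative")  # 555.2688
#' @export
neutral_mass <- function(mz, mode) {
  mode <- match.arg(mode, c("positive", "negative"), several.ok = FALSE)
  out <- if (mode == "positive") mz - PROTON_MASS else mz + PROTON_MASS
  if (any(out <= 0)) stop("non-positive neutral mass; check m/z and ionization mode")
  out
}

#' Relative mass error in parts per million
#'
#' @param observed Observed neutral mass, Da.
#' @param reference Reference monoisotopic mass, Da.
#' @return `|observed - reference| / reference * 1e6`.
#' @export
ppm_error <- function(observed, reference) {
  abs(observed - reference) / reference * 1e6
}

#' Accurate-mass annotation of LC-MS features
#'
#' Matches each feature's neutral mass (from [neutral_mass()]) against a
#' compound database by relative mass error. Candidates within the ppm
#' tolerance are ranked ascending by ppm error, the criterion used for
#' putative identification; exact ties are broken lexicographically by
#' compound id, so the output is deterministic and order-invariant in both
#' inputs.
#'
#' @param features Data frame with columns `feature_id`, `mz`, `mode`
#'   (`"positive"`/`"negative"`); other columns (e.g. retention time) are
#'   carried along unused.
#' @param compound_db Data frame with columns `compound_id`,
#'   `monoisotopic_mass`, and optionally `name` and `classes`.
#' @param ppm_tol Mass tolerance in ppm; the customary accurate-mass search
#'   range is 1 to 7.5 ppm, and values outside it trigger a warning but are
#'   honored. Default 7.5.
#' @return Data frame with one row per (feature, candidate):
#'   `feature_id`, `compound_id`, `ppm_error`, `rank` (1 = best). Features
#'   with no candidate are absent.
#' @export
annotate_features <- function(features, compound_db, ppm_tol = 7.5) {
  stopifnot(all(c("feature_id", "mz", "mode") %in% names(features)),
            all(c("compound_id", "monoisotopic_mass") %in% names(compound_db)))
  if (ppm_tol < 1 || ppm_tol > 7.5) {
    warning("ppm_tol ", ppm_tol, " outside the usual 1-7.5 ppm accurate-mass range")
  }
  if (nrow(compound_db) == 0L || nrow(features) == 0L) {
    return(data.frame(feature_id = character(), compound_id = character(),
                      ppm_error = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(features)), function(i) {
    nm <- neutral_mass(features$mz[i], features$mode[i])
    err <- ppm_error(nm, compound_db$monoisotopic_mass)
    hit <- which(err <= ppm_tol)
    if (length(hit) == 0L) return(NULL)
    ord <- hit[order(err[hit], compound_db$compound_id[hit])]
    data.frame(feature_id = features$feature_id[i],
               compound_id = compound_db$compound_id[ord],
               ppm_error = err[ord],
               rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(), compound_id = character(),
                      ppm_error = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$feature_id, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a raw LC-MS intensity
#'
#' Divides a raw ion intensity by the intensity of the mode-matched internal
#' standard (debrisoquine for positive mode, 4-nitrobenzoic acid for
#' negative mode) and by the fecal pellet weight, yielding abundances
#' comparable across samples and sample amounts.
#'
#' @param raw Raw intensity (vector allowed).
#' @param standard_intensity Internal-standard intensity per sample; must be
#'   strictly positive.
#' @param pellet_weight_mg Sample pellet weight in mg; strictly positive.
#' @return `raw / standard_intensity / pellet_weight_mg`.
#' @export
normalize_intensity <- function(raw, standard_intensity, pellet_weight_mg) {
  bad <- which(standard_intensity <= 0)
  if (length(bad) > 0L) {
    stop("non-positive internal-standard intensity for sample index(es): ",
         paste(bad, collapse = ", "))
  }
  bad <- which(pellet_weight_mg <= 0)
  if (length(bad) > 0L) {
    stop("non-positive pellet weight for sample index(es): ",
         paste(bad, collapse = ", "))
  }
  raw / standard_intensity / pellet_weight_mg
}
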