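#' Read an MRM peak-area table
#'
#' Expects a CSV/TSV file with columns `sample_id`, `peptide`, `channel`
#' (`light` or `heavy`) and `area`. Unknown columns are preserved.
#'
#' @param path Path to the table; the delimiter is inferred from the file
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @return Tibble of validated peak measurements.
#' @export
read_peak_table <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  validate_peak_table(x)
}

#' @keywords internal
validate_peak_table <- function(x) {
  required <- c("sample_id", "peptide", "channel", "area")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(x$channel %in% c("light", "heavy"))) {
    stop("channel must be 'light' or 'heavy'")
  }
  if (any(x$area < 0)) stop("negative peak area")
  key <- paste(x$sample_id, x$peptide, x$channel)
  if (anyDuplicated(key)) {
    stop("duplicated (sample_id, peptide, channel): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  tibble::as_tibble(x)
}

#' Read sample metadata
#'
#' Accepts CSV or JSON with fields `sample_id`, `spiked_pmol`,
#' `total_protein_ug`, `cells_in_digest` and `is_negative_control`.
#'
#' @param path Path to the metadata file.
#' @return Tibble of validated sample metadata.
#' @export
read_sample_meta <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("sample_id", "spiked_pmol", "total_protein_ug",
                "cells_in_digest", "is_negative_control")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(x$spiked_pmol <= 0)) stop("spiked_pmol must be positive")
  if (any(x$cells_in_digest <= 0 & !x$is_negative_control)) {
    stop("cells_in_digest must be positive for quantified samples")
  }
  tibble::as_tibble(x)
}

#' Cells represented in a digest aliquot
#'
#' Helper converting a harvest expressed in OD600 x volume units into the
#' number of cells represented by the protein aliquot that was digested.
#' Uses a cells-per-(OD600 x mL) factor (default 8e8, a standard E. coli
#' value) scaled by the fraction of extracted protein that was digested.
#'
#' @param od_ml Harvested OD600 x mL (e.g. 50).
#' @param aliquot_ug Protein digested (e.g. 50).
#' @param extracted_ug Total protein extracted from the harvest.
#' @param cells_per_od_ml Cell density conversion factor.
#' @return Number of cells represented in the digest.
#' @export
cells_in_digest <- function(od_ml, aliquot_ug, extracted_ug,
                            cells_per_od_ml = 8e8) {
  stopifnot(od_ml > 0, aliquot_ug > 0, extracted_ug >= aliquot_ug)
  od_ml * cells_per_od_ml * aliquot_ug / extracted_ug
}

#' Subtract a negative-control background from light-channel areas
#'
#' Light areas are reduced by the matched control light area and clamped at
#' zero; heavy (standard) areas are untouched. Peptides absent from the
#' control are left unsubtracted with a warning.
#'
#' @param samples,control Peak tables (see [read_peak_table()]).
#' @return Corrected peak table.
#' @export
subtract_negative_control <- function(samples, control) {
  samples <- validate_peak_table(samples)
  control <- validate_peak_table(control)
  ctl <- control[control$channel == "light", ]
  bg <- stats::setNames(ctl$area, ctl$peptide)
  unmatched <- setdiff(unique(samples$peptide[samples$channel == "light"]),
                       names(bg))
  if (length(unmatched) > 0L) {
    warning("peptide(s) absent from negative control, not subtracted: ",
            paste(unmatched, collapse = ", "))
  }
  is_light <- samples$channel == "light" & samples$peptide %in% names(bg)
  samples$area[is_light] <-
    pmax(0, samples$area[is_light] - bg[samples$peptide[is_light]])
  samples
}

#' Quantify a peptide from its light/heavy peak-area ratio
#'
#' The analyte amount is the light/heavy area ratio times the spiked
#' standard amount. When the heavy standard is quantified on its
#' monoisotopic (fully-labeled) peak only, the heavy area represents just
#' the `p^nC` fully-labeled fraction of the spike; passing that fraction as
#' `deficit_correction` rescales accordingly.
#'
#' @param light_area,heavy_area Peak areas (same arbitrary units).
#' @param spiked_pmol Standard amount spiked into the digest (pmol).
#' @param deficit_correction Fully-labeled fraction `p^nC` of the standard
#'   peptide, or `NULL` for no correction.
#' @return Amount in pmol, or `NA` (with a warning) if `heavy_area` is 0.
#' @export
quantify_peptide <- function(light_area, heavy_area, spiked_pmol = 100.9,
                             deficit_correction = NULL) {
  stopifnot(light_area >= 0, heavy_area >= 0, spiked_pmol > 0)
  if (heavy_area == 0) {
    warning("heavy area is zero; quantification failed")
    return(NA_real_)
  }
  corr <- if (is.null(deficit_correction)) 1 else deficit_correction
  stopifnot(corr > 0, corr <= 1)
  (light_area / heavy_area) * spiked_pmol * corr
}

#' Convert a molar amount to protein copies per cell
#'
#' @param amount_pmol Amount in pmol.
#' @param cells Number of cells represented in the digest.
#' @return Copies per cell.
#' @export
copies_per_cell <- function(amount_pmol, cells) {
  if (any(cells <= 0)) stop("cells must be positive")
  amount_pmol * 1e-12 * AVOGADRO / cells
}

#' Protein abundance from peptide-level values
#'
#' Averages the non-excluded peptide values; excluded peptides are
#' recorded with their reason and do not contribute.
#'
#' @param protein_id Protein identifier.
#' @param peptide_values Named numeric vector of per-peptide copies per
#'   cell (or pmol), names are peptide sequences.
#' @param exclusions Named character vector: names are excluded peptide
#'   sequences, values the reasons.
#' @return A list of class `protein_abundance` with elements `protein_id`,
#'   `copies_per_cell` (mean of used peptides, `NA` if all excluded),
#'   `peptides_used`, `peptides_excluded`, `per_peptide`.
#' @export
protein_abundance <- function(protein_id, peptide_values,
                              exclusions = character(0)) {
  used <- peptide_values[!names(peptide_values) %in% names(exclusions)]
  if (length(used) == 0L) {
    warning("all peptides excluded for ", protein_id, "; abundance undefined")
    value <- NA_real_
  } else {
    value <- mean(used)
  }
  structure(list(protein_id = protein_id, copies_per_cell = value,
                 peptides_used = names(used),
                 peptides_excluded = exclusions,
                 per_peptide = peptide_values),
            class = "protein_abundance")
}

#' Quantify protein abundances from a peak table
#'
#' End-to-end quantification: optional negative-control subtraction,
#' light/heavy ratio quantification with labeling-deficit correction,
#' conversion to copies per cell, peptide exclusion and per-protein
#' averaging, then averaging across replicate samples.
#'
#' @param peaks Peak table (see [read_peak_table()]); replicate samples are
#'   separate `sample_id`s.
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param peptide_map Tibble with columns `peptide` and `protein_id`
#'   mapping quantification peptides to their targets.
#' @param control Optional negative-control peak table.
#' @param enrichment 13C enrichment of the standard, used for the deficit
#'   correction.
#' @param deficit_correction Apply the `p^nC` correction (default TRUE).
#' @param exclusions Named character vector of excluded peptides (names)
#'   and reasons (values), e.g. from [audit_junctions()].
#' @return Tibble with one row per protein: `protein_id`,
#'   `copies_per_cell` (mean over replicates), `sd` (across replicates),
#'   `n_replicates`, `peptides_used`, `peptides_excluded`.
#' @export
quantify_samples <- function(peaks, meta, peptide_map, control = NULL,
                             enrichment = 0.99, deficit_correction = TRUE,
                             exclusions = character(0)) {
  peaks <- validate_peak_table(peaks)
  if (!is.null(control)) peaks <- subtract_negative_control(peaks, control)
  meta <- meta[!meta$is_negative_control, , drop = FALSE]

  corr <- NULL
  if (deficit_correction) {
    nc <- vapply(peptide_map$peptide, function(p)
      as.integer(elemental_composition(p))[1], integer(1))
    corr <- stats::setNames(enrichment^nc, peptide_map$peptide)
  }

  per_rep <- lapply(meta$sample_id, function(sid) {
    sm <- meta[meta$sample_id == sid, ]
    sub <- peaks[peaks$sample_id == sid, ]
    light <- stats::setNames(sub$area[sub$channel == "light"],
                             sub$peptide[sub$channel == "light"])
    heavy <- stats::setNames(sub$area[sub$channel == "heavy"],
                             sub$peptide[sub$channel == "heavy"])
    vapply(seq_len(nrow(peptide_map)), function(i) {
      pep <- peptide_map$peptide[i]
      if (!pep %in% names(light) || !pep %in% names(heavy)) return(NA_real_)
      amt <- quantify_peptide(light[[pep]], heavy[[pep]],
                              spiked_pmol = sm$spiked_pmol,
                              deficit_correction =
                                if (is.null(corr)) NULL else corr[[pep]])
      copies_per_cell(amt, sm$cells_in_digest)
    }, numeric(1))
  })
  pep_mat <- do.call(cbind, per_rep)  # peptides x replicates
  rownames(pep_mat) <- peptide_map$peptide

  proteins <- unique(peptide_map$protein_id)
  rows <- lapply(proteins, function(pid) {
    peps <- peptide_map$peptide[peptide_map$protein_id == pid]
    rep_values <- vapply(seq_len(ncol(pep_mat)), function(j) {
      pa <- suppressWarnings(
        protein_abundance(pid, pep_mat[peps, j, drop = TRUE],
                          exclusions[names(exclusions) %in% peps]))
      pa$copies_per_cell
    }, numeric(1))
    used <- setdiff(peps, names(exclusions))
    tibble::tibble(
      protein_id = pid,
      copies_per_cell = mean(rep_values),
      sd = if (length(rep_values) > 1L) stats::sd(rep_values) else NA_real_,
      n_replicates = length(rep_values),
      peptides_used = paste(used, collapse = ";"),
      peptides_excluded = paste(intersect(peps, names(exclusions)),
                                collapse = ";")
    )
  })
  do.call(rbind, rows)
}

#' Fit a calibration curve for a standard peptide
#'
#' Ordinary or 1/x-weighted least squares of response ratio against spiked
#' amount. The validated range is the span of points whose relative
#' residual from the fit is below `resid_tol`.
#'
#' @param amount_pmol Spiked amounts (pmol), at least 2 points (3 and more
#'   than one order of magnitude for range validation).
#' @param ratio Measured response ratios.
#' @param weighting `"none"` or `"inverse_amount"`.
#' @param resid_tol Relative residual tolerance for range validation.
#' @return List of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (validated `c(low, high)` in pmol), `points`.
#' @export
fit_calibration <- function(amount_pmol, ratio,
                            weighting = c("none", "inverse_amount"),
                            resid_tol = 0.2) {
  weighting <- match.arg(weighting)
  if (length(amount_pmol) < 2L) stop("need at least 2 calibration points")
  stopifnot(length(amount_pmol) == length(ratio))
  w <- if (weighting == "inverse_amount") 1 / amount_pmol else NULL
  fit <- stats::lm(ratio ~ amount_pmol, weights = w)
  pred <- stats::fitted(fit)
  ss_res <- sum((ratio - pred)^2)
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  ok <- abs(ratio - pred) <= resid_tol * pmax(abs(pred), .Machine$double.eps)
  rng <- if (any(ok)) range(amount_pmol[ok]) else c(NA_real_, NA_real_)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = min(max(r2, 0), 1),
                 range = rng,
                 points = tibble::tibble(amount_pmol = amount_pmol,
                                         ratio = ratio, in_range = ok)),
            class = "calibration_curve")
}

#' Recommend a trypsin digestion time from a release time course
#'
#' Returns the earliest time point at which the relative increase in
#' released signal from the previous point drops below `rel_tol`. If the
#' signal never plateaus, the last time is returned with a `no_plateau`
#' flag (some peptides never reach a digestion plateau, a recognized
#' source of quantification error).
#'
#' @param time_h Strictly increasing digestion times (h), at least 3.
#' @param signal Released peptide signal at each time.
#' @param rel_tol Relative-increase threshold (default 0.05).
#' @return List with `time_h` (recommended time) and `plateau` (logical).
#' @export
digestion_plateau <- function(time_h, signal, rel_tol = 0.05) {
  if (length(time_h) < 3L) stop("need at least 3 time points")
  stopifnot(length(signal) == length(time_h), all(diff(time_h) > 0))
  rel <- abs(diff(signal)) / pmax(abs(signal[-length(signal)]),
                                  .Machine$double.eps)
  hit <- which(rel < rel_tol)
  if (length(hit) == 0L) {
    list(time_h = time_h[length(time_h)], plateau = FALSE)
  } else {
    list(time_h = time_h[hit[1] + 1L], plateau = TRUE)
  }
}

#' Molar mass implied by a mass and molar amount
#'
#' @param mass_ug Mass in micrograms.
#' @param amount_pmol Molar amount in picomoles.
#' @return Molar mass in kDa.
#' @export
implied_molar_mass <- function(mass_ug, amount_pmol) {
  if (mass_ug <= 0 || amount_pmol <= 0) stop("inputs must be positive")
  (mass_ug * 1e-6) / (amount_pmol * 1e-12) / 1000
}
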