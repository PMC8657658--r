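#' Control-well summary statistics
#'
#' Bundles the positive/negative control means and standard deviations that
#' the Z-factor is computed from. Positive controls are the strong-effect
#' wells (cysteamine for the cystine assay, non-induced wells for the
#' apoptosis assay); negative controls are vehicle-only (or induced-untreated)
#' wells.
#'
#' @param mu_p,mu_n Control means, in assay units.
#' @param sigma_p,sigma_n Control standard deviations (sample, n-1
#'   denominator); must be non-negative.
#' @param n_p,n_n Number of control wells summarized; at least 2 each so the
#'   SDs are estimable.
#' @return An object of class `control_summary`.
#' @seealso [summarize_controls()] to build one from raw well values.
#' @export
control_summary <- function(mu_p, sigma_p, n_p, mu_n, sigma_n, n_n) {
  assert_number(mu_p, "mu_p")
  assert_number(mu_n, "mu_n")
  assert_number(sigma_p, "sigma_p")
  assert_number(sigma_n, "sigma_n")
  if (sigma_p < 0 || sigma_n < 0) stopf("control SDs must be non-negative")
  n_p <- assert_count(n_p, "n_p", lower = 2)
  n_n <- assert_count(n_n, "n_n", lower = 2)
  structure(
    list(mu_p = mu_p, sigma_p = sigma_p, n_p = n_p,
         mu_n = mu_n, sigma_n = sigma_n, n_n = n_n),
    class = "control_summary"
  )
}

#' Summarize raw control wells
#'
#' @param positive,negative Numeric vectors of raw control readouts (length
#'   >= 2 each).
#' @return A [control_summary()].
#' @export
summarize_controls <- function(positive, negative) {
  if (length(positive) < 2L || length(negative) < 2L) {
    stopf("need at least 2 wells per control group to estimate SDs (got %d positive, %d negative)",
          length(positive), length(negative))
  }
  if (anyNA(positive) || anyNA(negative)) stopf("control readouts contain NA")
  control_summary(
    mu_p = mean(positive), sigma_p = stats::sd(positive), n_p = length(positive),
    mu_n = mean(negative), sigma_n = stats::sd(negative), n_n = length(negative)
  )
}

#' Z-factor assay-quality statistic
#'
#' `z = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|`. A perfect assay (zero
#' control variance) scores 1; the statistic is unbounded below. Symmetric in
#' the two control groups and strictly decreasing in each SD.
#'
#' @param summary A [control_summary()].
#' @return The Z-factor (a number <= 1).
#' @export
z_factor <- function(summary) {
  if (!inherits(summary, "control_summary")) {
    stopf("'summary' must be a control_summary object")
  }
  sep <- abs(summary$mu_p - summary$mu_n)
  if (sep == 0) {
    stopf("control means are equal; Z-factor separation is undefined")
  }
  1 - 3 * (summary$sigma_p + summary$sigma_n) / sep
}

#' Replicate-adjusted Z-factor
#'
#' For assays read in r replicates the control spread shrinks by sqrt(r).
#' The default (`mode = "spread"`) divides the spread term by sqrt(r):
#' `z = 1 - [3 (sigma_p + sigma_n) / |mu_p - mu_n|] / sqrt(r)`,
#' which is the standard error of replicate-averaged wells and keeps z <= 1
#' with a perfect assay still scoring 1. `mode = "whole"` divides the whole
#' plain statistic by sqrt(r) instead (an alternative literal reading; under
#' it a perfect assay scores 1/sqrt(r)).
#'
#' @param summary A [control_summary()].
#' @param r Replicate count, >= 1.
#' @param mode `"spread"` (default) or `"whole"`; see Details.
#' @return The adjusted Z-factor. Equals [z_factor()] at `r = 1` in both
#'   modes.
#' @export
z_factor_replicate_adjusted <- function(summary, r, mode = c("spread", "whole")) {
  mode <- match.arg(mode)
  if (!is_count(r) || r < 1) stopf("replicate count 'r' must be an integer >= 1")
  z <- z_factor(summary)
  if (mode == "spread") {
    1 - (1 - z) / sqrt(r)
  } else {
    z / sqrt(r)
  }
}

#' Per-plate Z-factor quality control
#'
#' Computes the control summary for one plate, the chosen Z-factor variant,
#' and a pass/fail verdict against a threshold.
#'
#' @param wells A data frame of wells from a single plate with at least a
#'   `role` column and the readout column named by `readout`.
#' @param readout Name of the numeric readout column.
#' @param positive_role,negative_role Values of `role` marking the
#'   positive/negative control wells.
#' @param threshold Pass threshold: the plate passes when `z >= threshold`.
#'   Default 0.5, the conventional "excellent assay" bound.
#' @param replicates Replicate count used when `adjusted = TRUE`.
#' @param adjusted Use the replicate-adjusted statistic?
#' @param mode Adjustment mode, see [z_factor_replicate_adjusted()].
#' @return An object of class `z_factor_report`: a list with elements
#'   `summary`, `z`, `replicates`, `adjusted`, `pass_threshold`, `passed`,
#'   and `plate_id` (if present in `wells`).
#' @export
plate_qc <- function(wells, readout, positive_role = "positive",
                     negative_role = "vehicle", threshold = 0.5,
                     replicates = 1L, adjusted = FALSE,
                     mode = c("spread", "whole")) {
  mode <- match.arg(mode)
  if (!is.data.frame(wells) || !"role" %in% names(wells)) {
    stopf("'wells' must be a data frame with a 'role' column")
  }
  if (!readout %in% names(wells)) stopf("readout column '%s' not found", readout)
  plate_id <- if ("plate_id" %in% names(wells)) {
    ids <- unique(wells$plate_id)
    if (length(ids) > 1L) stopf("plate_qc() expects wells from a single plate, got %d", length(ids))
    as.character(ids)
  } else NA_character_
  pos <- wells[[readout]][wells$role == positive_role]
  neg <- wells[[readout]][wells$role == negative_role]
  plate_lbl <- if (is.na(plate_id)) "<plate>" else plate_id
  if (length(pos) < 2L) {
    stopf("plate %s has %d '%s' control wells; at least 2 required",
          plate_lbl, length(pos), positive_role)
  }
  if (length(neg) < 2L) {
    stopf("plate %s has %d '%s' control wells; at least 2 required",
          plate_lbl, length(neg), negative_role)
  }
  smry <- summarize_controls(pos, neg)
  z <- if (adjusted) {
    z_factor_replicate_adjusted(smry, replicates, mode)
  } else {
    z_factor(smry)
  }
  structure(
    list(plate_id = plate_id, summary = smry, z = z,
         replicates = as.integer(replicates), adjusted = adjusted,
         pass_threshold = threshold, passed = z >= threshold),
    class = "z_factor_report"
  )
}

#' @export
print.z_factor_report <- function(x, ...) {
  cat(sprintf("Z-factor report%s\n",
              if (!is.na(x$plate_id)) paste0(" [plate ", x$plate_id, "]") else ""))
  cat(sprintf("  z = %.4f%s  (threshold %.2f: %s)\n", x$z,
              if (x$adjusted) sprintf(" (replicate-adjusted, r=%d)", x$replicates) else "",
              x$pass_threshold, if (x$passed) "PASS" else "FAIL"))
  s <- x$summary
  cat(sprintf("  positive: mean %.4g sd %.4g (n=%d); negative: mean %.4g sd %.4g (n=%d)\n",
              s$mu_p, s$sigma_p, s$n_p, s$mu_n, s$sigma_n, s$n_n))
  invisible(x)
}

#' Quality control across all plates of a screen
#'
#' Runs [plate_qc()] on every plate in a multi-plate well table and returns a
#' per-plate summary table.
#'
#' @inheritParams plate_qc
#' @param wells Data frame with `plate_id`, `role`, and the readout column.
#' @return A data frame with one row per plate: `plate_id`, `z`, `passed`,
#'   control means/SDs and well counts.
#' @export
qc_plates <- function(wells, readout, positive_role = "positive",
                      negative_role = "vehicle", threshold = 0.5,
                      replicates = 1L, adjusted = FALSE,
                      mode = c("spread", "whole")) {
  mode <- match.arg(mode)
  if (!"plate_id" %in% names(wells)) stopf("'wells' must have a 'plate_id' column")
  plates <- split(wells, wells$plate_id)
  rows <- lapply(plates, function(pw) {
    rep <- plate_qc(pw, readout, positive_role, negative_role, threshold,
                    replicates, adjusted, mode)
    s <- rep$summary
    data.frame(plate_id = rep$plate_id, z = rep$z, passed = rep$passed,
               mu_p = s$mu_p, sigma_p = s$sigma_p, n_p = s$n_p,
               mu_n = s$mu_n, sigma_n = s$sigma_n, n_n = s$n_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assay-level Z-factor from pooled controls
#'
#' Pools the control wells of every plate and computes a single screen-level
#' Z-factor, the number usually quoted as "the Z-factor of the assay".
#'
#' @inheritParams qc_plates
#' @return A `z_factor_report` (with `plate_id = NA`).
#' @export
assay_z <- function(wells, readout, positive_role = "positive",
                    negative_role = "vehicle", threshold = 0.5,
                    replicates = 1L, adjusted = FALSE,
                    mode = c("spread", "whole")) {
  mode <- match.arg(mode)
  w <- wells[, setdiff(names(wells), "plate_id"), drop = FALSE]
  plate_qc(w, readout, positive_role, negative_role, threshold,
           replicates, adjusted, mode)
}
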