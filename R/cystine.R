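#' Normalize cystine content to protein
#'
#' Cystine is measured per well (nmol) and divided by the well's protein
#' content (mg) so wells with different cell numbers are comparable.
#'
#' @param cystine Cystine amounts in nmol (vectorized).
#' @param protein Protein amounts in mg; must be strictly positive.
#' @return Cystine in nmol/mg protein.
#' @export
normalize_cystine <- function(cystine, protein) {
  if (!is.numeric(cystine) || !is.numeric(protein)) {
    stopf("'cystine' and 'protein' must be numeric")
  }
  if (length(cystine) != length(protein) && length(protein) != 1L) {
    stopf("'cystine' and 'protein' lengths differ")
  }
  if (any(!is.finite(protein)) || any(protein <= 0)) {
    stopf("protein content must be > 0 mg")
  }
  cystine / protein
}

#' Express a value as percent of the plate's vehicle mean
#'
#' @param value Normalized readout(s) (e.g. nmol/mg) for treated wells.
#' @param vehicle Normalized readouts of the vehicle (negative-control) wells
#'   on the same plate; at least one value.
#' @return `100 * value / mean(vehicle)`.
#' @export
percent_of_vehicle <- function(value, vehicle) {
  if (length(vehicle) < 1L || anyNA(vehicle)) {
    stopf("need at least one valid vehicle well")
  }
  m <- mean(vehicle)
  if (!is.finite(m) || m <= 0) {
    stopf("vehicle mean is %s; cannot normalize", format(m))
  }
  100 * value / m
}

#' Per-compound cystine activity from plate tables
#'
#' Normalizes each well's cystine to protein, expresses it as percent of the
#' same plate's vehicle mean, and aggregates replicate wells per compound.
#' Normalization is plate-wise: controls live on every plate and each well is
#' referenced to its own plate.
#'
#' @param wells Data frame with columns `plate_id`, `compound_id`, `role`,
#'   `cystine_nmol`, `protein_mg`.
#' @param vehicle_role,compound_role `role` values marking vehicle control
#'   and library-compound wells.
#' @param replicate_policy How replicate wells of one compound are combined
#'   on the percent scale: `"mean"` (default), `"min"`, or `"max"`.
#' @return Data frame with `compound_id`, `activity` (percent of vehicle) and
#'   `n_wells`.
#' @export
screen_cystine <- function(wells, vehicle_role = "vehicle",
                           compound_role = "compound",
                           replicate_policy = c("mean", "min", "max")) {
  replicate_policy <- match.arg(replicate_policy)
  need <- c("plate_id", "compound_id", "role", "cystine_nmol", "protein_mg")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("wells table lacks column(s): %s", paste(miss, collapse = ", "))
  wells$normalized <- normalize_cystine(wells$cystine_nmol, wells$protein_mg)
  aggregate_percent(wells, value_col = "normalized",
                    reference_role = vehicle_role,
                    compound_role = compound_role,
                    replicate_policy = replicate_policy)
}

# shared plate-wise percent-of-reference + per-compound aggregation
aggregate_percent <- function(wells, value_col, reference_role, compound_role,
                              replicate_policy) {
  pct <- rep(NA_real_, nrow(wells))
  for (pid in unique(wells$plate_id)) {
    on_plate <- wells$plate_id == pid
    ref <- wells[[value_col]][on_plate & wells$role == reference_role]
    if (length(ref) < 1L) {
      stopf("plate %s has no '%s' reference wells", pid, reference_role)
    }
    pct[on_plate] <- percent_of_vehicle(wells[[value_col]][on_plate], ref)
  }
  cmp <- wells$role == compound_role
  if (!any(cmp)) stopf("no '%s' wells in the input", compound_role)
  agg_fun <- switch(replicate_policy, mean = mean, min = min, max = max)
  by_cpd <- split(pct[cmp], wells$compound_id[cmp])
  data.frame(
    compound_id = names(by_cpd),
    activity = vapply(by_cpd, agg_fun, numeric(1)),
    n_wells = vapply(by_cpd, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call cystine-depletion hits
#'
#' A compound is a hit when it reduces cystine by at least
#' `threshold_reduction` percent of the vehicle level; the boundary is
#' inclusive (a compound at exactly 50% residual activity is a hit at the
#' default threshold).
#'
#' @param results Data frame with one row per compound (`compound_id`,
#'   `activity` as percent of vehicle), or a named numeric vector of
#'   activities.
#' @param threshold_reduction Minimum percent reduction; default 50.
#' @return Data frame with `compound_id`, `phenotype`, `activity`,
#'   `reduction`, `hit`.
#' @export
call_cystine_hits <- function(results, threshold_reduction = 50) {
  call_screen_hits(results, threshold_reduction, phenotype = "cystine")
}

call_screen_hits <- function(results, threshold_reduction, phenotype) {
  assert_number(threshold_reduction, "threshold_reduction", lower = 0, upper = 100)
  if (is.numeric(results) && !is.null(names(results))) {
    results <- data.frame(compound_id = names(results), activity = unname(results),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(results) || !all(c("compound_id", "activity") %in% names(results))) {
    stopf("'results' must have columns 'compound_id' and 'activity'")
  }
  dup <- unique(results$compound_id[duplicated(results$compound_id)])
  if (length(dup)) {
    stopf("duplicate compound id(s): %s (average replicates first)",
          paste(utils::head(dup, 5), collapse = ", "))
  }
  reduction <- 100 - results$activity
  data.frame(
    compound_id = results$compound_id,
    phenotype = phenotype,
    activity = results$activity,
    reduction = reduction,
    hit = reduction >= threshold_reduction,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
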