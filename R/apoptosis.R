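#' Caspase-3/7 positivity fraction
#'
#' Apoptosis is quantified per well as caspase-positive nuclei over total
#' nuclei.
#'
#' @param positive Count of caspase-positive nuclei (vectorized).
#' @param total Total nucleus count; must be > 0 and >= `positive`.
#' @return Proportion in \[0, 1\].
#' @export
apoptosis_fraction <- function(positive, total) {
  if (!is.numeric(positive) || !is.numeric(total)) {
    stopf("'positive' and 'total' must be numeric counts")
  }
  if (any(!is.finite(total)) || any(total <= 0)) stopf("total nucleus count must be > 0")
  if (any(positive < 0)) stopf("positive nucleus count must be >= 0")
  if (any(positive > total)) stopf("positive nuclei exceed total nuclei")
  positive / total
}

#' Normalize an apoptosis fraction to the plate's induced-untreated mean
#'
#' Each plate carries untreated wells exposed to the apoptosis stimulus; the
#' per-well caspase positivity is expressed as percent of their mean, so 100
#' means "as apoptotic as untreated induced cells".
#'
#' @param fraction Caspase-positive fraction(s) for treated wells.
#' @param induced Fractions of the induced-untreated wells on the same plate
#'   (>= 1 value).
#' @return Percent of the induced-untreated mean.
#' @export
normalize_to_induced <- function(fraction, induced) {
  if (length(induced) < 1L || anyNA(induced)) {
    stopf("need at least one induced-untreated well")
  }
  m <- mean(induced)
  if (m == 0) stopf("induced-untreated mean is 0; cannot normalize")
  100 * fraction / m
}

#' Per-compound apoptosis activity from plate tables
#'
#' Computes the caspase positivity fraction per well, normalizes it within
#' each plate to that plate's induced-untreated mean, and averages replicate
#' wells per compound (replicates are normalized within their own plate
#' first, then averaged across plates). Non-induced vehicle wells are left
#' untouched here; they serve as Z-factor controls.
#'
#' @param wells Data frame with columns `plate_id`, `compound_id`, `role`,
#'   `positive_nuclei`, `total_nuclei`.
#' @param induced_role `role` value of the induced-untreated reference wells.
#' @param compound_role `role` value of library-compound wells.
#' @param replicate_policy `"mean"` (default), `"min"`, or `"max"`.
#' @return Data frame with `compound_id`, `activity` (percent of the induced
#'   reference) and `n_wells`.
#' @export
screen_apoptosis <- function(wells, induced_role = "induced_untreated",
                             compound_role = "compound",
                             replicate_policy = c("mean", "min", "max")) {
  replicate_policy <- match.arg(replicate_policy)
  need <- c("plate_id", "compound_id", "role", "positive_nuclei", "total_nuclei")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("wells table lacks column(s): %s", paste(miss, collapse = ", "))
  wells$fraction <- apoptosis_fraction(wells$positive_nuclei, wells$total_nuclei)
  aggregate_percent(wells, value_col = "fraction",
                    reference_role = induced_role,
                    compound_role = compound_role,
                    replicate_policy = replicate_policy)
}

#' Call apoptosis-protection hits
#'
#' A compound is a hit when it reduces the normalized apoptosis rate by at
#' least `threshold_reduction` percent of the induced-untreated level;
#' boundary inclusive.
#'
#' @param results Data frame (`compound_id`, `activity`) or named numeric
#'   vector of normalized activities.
#' @param threshold_reduction Minimum percent reduction; default 40.
#' @return Data frame with `compound_id`, `phenotype`, `activity`,
#'   `reduction`, `hit`.
#' @export
call_apoptosis_hits <- function(results, threshold_reduction = 40) {
  call_screen_hits(results, threshold_reduction, phenotype = "apoptosis")
}
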