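#' Intersect the hit sets of the two screens
#'
#' Compounds active in both the cystine-depletion and the
#' apoptosis-protection screen are the lead candidates. Commutative and
#' idempotent; empty inputs are allowed.
#'
#' @param cystine_hits,apoptosis_hits Character vectors of compound ids, or
#'   hit tables as returned by [call_cystine_hits()] /
#'   [call_apoptosis_hits()] (their `hit == TRUE` rows are used).
#' @return Sorted character vector of compounds present in both sets.
#' @export
cross_screens <- function(cystine_hits, apoptosis_hits) {
  as_ids <- function(x) {
    if (is.data.frame(x)) {
      if (!all(c("compound_id", "hit") %in% names(x))) {
        stopf("hit table must have 'compound_id' and 'hit' columns")
      }
      x <- x$compound_id[x$hit]
    }
    unique(as.character(x))
  }
  sort(intersect(as_ids(cystine_hits), as_ids(apoptosis_hits)))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x / c)^b)` where `a` is the
#' zero-dose asymptote (top), `d` the infinite-dose asymptote (bottom), `c`
#' the EC50 (same units as `dose`) and `b` the Hill slope. At `x = c` the
#' fitted value is `(a + d) / 2`. Initialization takes `a`/`d` from the
#' responses at the extreme doses, `c` from the geometric mid-dose, `b = 1`,
#' with a bounded multi-start on failure; the optimizer is
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with `c` constrained positive.
#'
#' @param dose Doses (e.g. in uM); at least 4 distinct positive values.
#' @param response Responses (e.g. percent of vehicle), same length.
#' @param n_restarts Extra restarts from perturbed starts when the first fit
#'   fails (default 5).
#' @return An object of class `dose_response_fit`: list with `a` (top), `d`
#'   (bottom), `c` (ec50), `b` (hill), `rss`, `converged`, `n`. When the fit
#'   is degenerate or does not converge, `converged` is `FALSE` and the
#'   parameters are `NA`.
#' @export
fit_4pl <- function(dose, response, n_restarts = 5L) {
  if (length(dose) != length(response)) stopf("'dose' and 'response' lengths differ")
  if (anyNA(dose) || anyNA(response) || any(!is.finite(response))) {
    stopf("doses and responses must be finite")
  }
  if (any(dose <= 0)) stopf("doses must be positive")
  ud <- sort(unique(dose))
  if (length(ud) < 4L) stopf("need at least 4 distinct doses, got %d", length(ud))

  no_fit <- structure(
    list(a = NA_real_, d = NA_real_, c = NA_real_, b = NA_real_,
         rss = NA_real_, converged = FALSE, n = length(dose)),
    class = "dose_response_fit"
  )
  if (diff(range(response)) < 1e-8 * max(1, abs(mean(response)))) {
    return(no_fit)  # flat data: a ~ d, EC50 unidentifiable
  }

  lo <- mean(response[dose == ud[1]])
  hi <- mean(response[dose == ud[length(ud)]])
  c0 <- exp(mean(log(range(ud))))
  starts <- list(
    list(a = lo, d = hi, c = c0, b = 1),
    list(a = lo, d = hi, c = ud[2], b = 1),
    list(a = lo, d = hi, c = ud[length(ud) - 1], b = 2),
    list(a = lo, d = hi, c = c0, b = 0.5),
    list(a = max(response), d = min(response), c = c0, b = 4),
    list(a = min(response), d = max(response), c = c0, b = 1)
  )
  starts <- starts[seq_len(min(length(starts), 1L + n_restarts))]

  best <- NULL
  dat <- data.frame(x = dose, y = response)
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ d + (a - d) / (1 + (x / c)^b),
        data = dat, start = st,
        lower = c(a = -Inf, d = -Inf, c = 1e-9, b = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(a = unname(cf["a"]), d = unname(cf["d"]),
                   c = unname(cf["c"]), b = unname(cf["b"]), rss = rss)
    }
  }
  if (is.null(best) || !is.finite(best$rss) || best$c <= 0) return(no_fit)
  if (abs(best$a - best$d) < 1e-6 * max(1, abs(best$a))) return(no_fit)
  structure(
    c(best[c("a", "d", "c", "b", "rss")],
      list(converged = TRUE, n = length(dose))),
    class = "dose_response_fit"
  )
}

#' Evaluate a fitted 4PL curve
#'
#' @param fit A `dose_response_fit` (converged) or a list with elements
#'   `a`, `d`, `c`, `b`.
#' @param dose Doses to predict at.
#' @return Predicted responses.
#' @export
predict_4pl <- function(fit, dose) {
  if (inherits(fit, "dose_response_fit") && !isTRUE(fit$converged)) {
    stopf("cannot predict from a non-converged fit")
  }
  with(fit, d + (a - d) / (1 + (dose / c)^b))
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: not converged / degenerate\n")
  } else {
    cat(sprintf("4PL fit: top %.3f, bottom %.3f, EC50 %.4g, hill %.3f (RSS %.4g, n=%d)\n",
                x$a, x$d, x$c, x$b, x$rss, x$n))
  }
  invisible(x)
}

#' Confirmation statistics: one-way ANOVA with Bonferroni pairwise follow-up
#'
#' Compares replicate responses across conditions by one-way ANOVA; when the
#' overall p is below `alpha`, all pairwise comparisons are evaluated with
#' pooled-variance t tests and Bonferroni adjustment (raw p multiplied by the
#' number of comparisons, capped at 1). Pairwise results are withheld when
#' the overall test is not significant.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 replicates
#'   each).
#' @param alpha Significance level gating the pairwise step (default 0.05).
#' @return List with `f`, `p`, `df_between`, `df_within`, and `pairwise`
#'   (data frame `group1`, `group2`, `p_raw`, `p_adjusted`, or `NULL` when
#'   the overall test is not significant). If every observation is identical
#'   the F statistic is undefined: `f` and `p` are `NA` and a warning is
#'   raised.
#' @export
confirm_by_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stopf("every group needs at least 2 replicates")
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), sizes), levels = names(groups))
  if (anyNA(value)) stopf("groups contain NA")

  if (stats::var(value) == 0) {
    warnf("all observations identical; F statistic undefined, no evidence of differences")
    return(list(f = NA_real_, p = NA_real_,
                df_between = length(groups) - 1L,
                df_within = length(value) - length(groups),
                pairwise = NULL, alpha = alpha))
  }

  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]

  pairwise <- NULL
  if (is.finite(p) && p < alpha) {
    pt <- stats::pairwise.t.test(value, group, p.adjust.method = "none",
                                 pool.sd = TRUE)
    m <- pt$p.value
    pairs <- which(!is.na(m), arr.ind = TRUE)
    n_comp <- nrow(pairs)
    pairwise <- data.frame(
      group1 = rownames(m)[pairs[, 1]],
      group2 = colnames(m)[pairs[, 2]],
      p_raw = m[pairs],
      p_adjusted = pmin(1, m[pairs] * n_comp),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  list(f = f, p = p,
       df_between = length(groups) - 1L,
       df_within = length(value) - length(groups),
       pairwise = pairwise, alpha = alpha)
}

#' Fit dose-response curves for a table of lead compounds
#'
#' @param dr Data frame with columns `compound_id`, `dose_uM`,
#'   `response_percent` (replicate rows allowed).
#' @param n_restarts Passed to [fit_4pl()].
#' @return Named list of `dose_response_fit` objects, one per compound.
#' @export
fit_dose_response <- function(dr, n_restarts = 5L) {
  need <- c("compound_id", "dose_uM", "response_percent")
  miss <- setdiff(need, names(dr))
  if (length(miss)) stopf("dose-response table lacks column(s): %s", paste(miss, collapse = ", "))
  lapply(split(dr, dr$compound_id), function(d) {
    fit_4pl(d$dose_uM, d$response_percent, n_restarts = n_restarts)
  })
}
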