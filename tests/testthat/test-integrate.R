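test_that("cross_screens is the set intersection, commutative and idempotent", {
  expect_equal(cross_screens(c("A", "B", "C"), c("B", "C", "D")), c("B", "C"))
  expect_equal(cross_screens(c("A", "B"), character()), character())
  expect_equal(cross_screens(c("X", "Y"), c("Y", "X")),
               cross_screens(c("Y", "X"), c("X", "Y")))
  expect_equal(cross_screens(c("A", "B"), c("A", "B")), c("A", "B"))

  # screen-sized sets constructed with exactly 6 common members
  common <- sprintf("CPD%04d", 1:6)
  cys <- c(common, sprintf("CYS%02d", 1:18))   # 24 cystine hits
  apo <- c(common, sprintf("APO%02d", 1:21))   # 27 apoptosis hits
  expect_setequal(cross_screens(cys, apo), common)
  expect_length(cross_screens(cys, apo), 6)
})

test_that("cross_screens accepts hit tables and uses only flagged rows", {
  cys <- data.frame(compound_id = c("A", "B", "C"), hit = c(TRUE, TRUE, FALSE))
  apo <- data.frame(compound_id = c("B", "C", "D"), hit = c(TRUE, TRUE, TRUE))
  expect_equal(cross_screens(cys, apo), "B")
})

test_that("fit_4pl recovers noiseless parameters to high precision", {
  truth <- list(a = 100, d = 0, c = 2.5, b = 1.5)
  doses <- c(0.1, 1, 2.5, 5, 10, 100)  # tested grid plus asymptote anchors
  y <- truth$d + (truth$a - truth$d) / (1 + (doses / truth$c)^truth$b)
  fit <- fit_4pl(doses, y)
  expect_true(fit$converged)
  for (par in c("a", "d", "c", "b")) {
    expect_equal(fit[[par]], truth[[par]], tolerance = 1e-6)
  }
  # midpoint property: the fitted curve at x = EC50 is (top + bottom) / 2
  expect_equal(predict_4pl(fit, fit$c), (fit$a + fit$d) / 2, tolerance = 1e-8)
})

test_that("degenerate dose-response inputs are flagged, not fitted", {
  doses <- c(1, 2.5, 5, 10)
  flat <- fit_4pl(doses, rep(50, 4))
  expect_false(flat$converged)
  expect_true(is.na(flat$c))
  expect_error(fit_4pl(c(1, 1, 2, 2), c(90, 91, 50, 49)), "4 distinct doses")
  expect_error(fit_4pl(c(-1, 1, 2, 5), c(90, 80, 50, 20)), "positive")
  expect_error(predict_4pl(flat, 1), "non-converged")
})

test_that("EC50 is recovered within 10% median relative error under noise", {
  truth <- list(a = 100, d = 5, c = 2.5, b = 1.5)
  doses <- rep(c(0.1, 1, 2.5, 5, 10, 100), each = 3)
  mu <- truth$d + (truth$a - truth$d) / (1 + (doses / truth$c)^truth$b)
  set.seed(123)
  rel_err <- replicate(50, {
    fit <- fit_4pl(doses, mu + rnorm(length(doses), 0, 2))
    if (fit$converged) abs(fit$c - truth$c) / truth$c else NA
  })
  expect_true(all(!is.na(rel_err)))
  expect_lt(median(rel_err), 0.10)
})

test_that("one-way ANOVA confirmation gates pairwise Bonferroni comparisons", {
  # identical groups: F = 0, p = 1, no pairwise step
  out <- confirm_by_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(out$f, 0)
  expect_equal(out$p, 1)
  expect_null(out$pairwise)

  # clearly separated groups: pairwise p values are raw x m, capped at 1
  groups <- list(ctrl = c(10.1, 9.9, 10.0), lo = c(8.0, 8.2, 7.9),
                 hi = c(5.1, 5.0, 4.8))
  out <- confirm_by_anova(groups)
  expect_lt(out$p, 0.05)
  expect_equal(nrow(out$pairwise), 3)
  expect_equal(out$pairwise$p_adjusted,
               pmin(1, out$pairwise$p_raw * 3))

  # Bonferroni multiplication rule on the raw scale
  expect_equal(pmin(1, 0.02 * 3), 0.06)
})

test_that("degenerate ANOVA inputs are rejected or warned about", {
  expect_error(confirm_by_anova(list(a = c(1, 2, 3))), "at least 2 groups")
  expect_error(confirm_by_anova(list(a = 1, b = c(1, 2))), "at least 2 replicates")
  expect_warning(out <- confirm_by_anova(list(a = c(2, 2), b = c(2, 2))),
                 "identical")
  expect_true(is.na(out$f))
})

test_that("fit_dose_response fits every compound in a long table", {
  sim <- simulate_dose_response(c("D1", "D2"), doses = c(0.1, 1, 2.5, 5, 10, 100),
                                noise_sd = 0.5, seed = 31)
  fits <- fit_dose_response(sim$data)
  expect_named(fits, c("D1", "D2"))
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  for (id in names(fits)) {
    tr <- sim$truth[sim$truth$compound_id == id, ]
    expect_equal(fits[[id]]$c, tr$c, tolerance = 0.15)
  }
})
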