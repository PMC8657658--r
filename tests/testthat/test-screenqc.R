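test_that("z_factor matches hand-evaluated control summaries", {
  expect_equal(z_factor(control_summary(100, 0, 4, 0, 0, 4)), 1.0)
  expect_equal(z_factor(control_summary(0, 5, 8, 100, 5, 8)), 0.7)
  # large spread can push z below zero, never above one
  expect_lt(z_factor(control_summary(0, 40, 4, 100, 40, 4)), 0)
})

test_that("degenerate or invalid control summaries are rejected", {
  expect_error(z_factor(control_summary(50, 10, 4, 50, 1, 4)), "separation")
  expect_error(control_summary(0, -1, 4, 100, 5, 4), "non-negative")
  expect_error(control_summary(0, 5, 1, 100, 5, 4), ">= 2")
  expect_error(summarize_controls(5, c(1, 2, 3)), "at least 2")
})

test_that("replicate adjustment divides the spread term by sqrt(r)", {
  s <- control_summary(0, 5, 8, 100, 5, 8)
  expect_equal(z_factor_replicate_adjusted(s, 1), 0.7)
  expect_equal(z_factor_replicate_adjusted(s, 4), 0.85)  # 1 - 0.30 / 2
  perfect <- control_summary(0, 0, 8, 100, 0, 8)
  for (r in c(1, 3, 9)) {
    expect_equal(z_factor_replicate_adjusted(perfect, r), 1.0)
  }
  # the whole-expression variant scales the full statistic instead
  expect_equal(z_factor_replicate_adjusted(s, 4, mode = "whole"), 0.35)
  expect_error(z_factor_replicate_adjusted(s, 0), ">= 1")
})

test_that("z_factor is symmetric, bounded, and monotone in the SDs", {
  set.seed(42)
  for (i in 1:200) {
    mu <- sort(runif(2, -50, 150))
    if (diff(mu) < 1e-6) next
    sd1 <- runif(1, 0, 20); sd2 <- runif(1, 0, 20)
    z12 <- z_factor(control_summary(mu[1], sd1, 4, mu[2], sd2, 4))
    z21 <- z_factor(control_summary(mu[2], sd2, 4, mu[1], sd1, 4))
    expect_identical(z12, z21)
    expect_lte(z12, 1)
    # strictly decreasing in each SD
    z_worse <- z_factor(control_summary(mu[1], sd1 + 1, 4, mu[2], sd2, 4))
    expect_lt(z_worse, z12)
  }
})

test_that("plate_qc summarizes a plate's controls and applies the threshold", {
  plate <- data.frame(
    plate_id = "P01",
    role = c(rep("positive", 3), rep("vehicle", 3), rep("compound", 4)),
    value = c(0, 0, 0, 100, 100, 100, 50, 60, 70, 80)
  )
  rep <- plate_qc(plate, "value", positive_role = "positive", threshold = 0.5)
  expect_s3_class(rep, "z_factor_report")
  expect_equal(rep$z, 1.0)
  expect_true(rep$passed)

  noisy <- data.frame(
    plate_id = "P02",
    role = c(rep("positive", 4), rep("vehicle", 4)),
    value = c(rnorm_fixed(4, 0, 5), rnorm_fixed(4, 100, 5))
  )
  rep2 <- plate_qc(noisy, "value", positive_role = "positive", threshold = 0.8)
  expect_equal(rep2$z, 0.7, tolerance = 1e-12)
  expect_false(rep2$passed)

  lone <- data.frame(plate_id = "P03",
                     role = c("positive", "vehicle", "vehicle"),
                     value = c(0, 99, 101))
  expect_error(plate_qc(lone, "value", positive_role = "positive"), "at least 2")
  two_plates <- rbind(plate, transform(plate, plate_id = "P99"))
  expect_error(plate_qc(two_plates, "value", positive_role = "positive"),
               "single plate")
})

test_that("qc_plates reports one verdict per plate", {
  plates <- rbind(
    data.frame(plate_id = "A", role = c("p", "p", "n", "n"), v = c(0, 0, 10, 10)),
    data.frame(plate_id = "B", role = c("p", "p", "n", "n"), v = c(0, 4, 6, 10))
  )
  out <- qc_plates(plates, "v", positive_role = "p", negative_role = "n",
                   threshold = 0.5)
  expect_equal(out$plate_id, c("A", "B"))
  expect_equal(out$passed, c(TRUE, FALSE))
  expect_equal(out$z[1], 1.0)
})
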