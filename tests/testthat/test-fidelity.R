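test_that("min-max normalization and median imputation follow the reference", {
  ref <- data.frame(x = c(0, 2, 3, 4, 10), y = rep(7, 5))
  tab <- data.frame(x = c(5, NA), y = c(7, 7))
  m <- impute_and_normalize(tab, ref)
  expect_equal(unname(m[1, "x"]), 0.5)
  expect_equal(unname(m[2, "x"]), 0.3)  # median 3 then scaled
  expect_equal(unname(m[, "y"]), c(0.5, 0.5))  # constant reference column
  sup <- data.frame(x = c(NA_real_, NA_real_), y = c(7, 7))
  ms <- impute_and_normalize(sup, ref)
  expect_equal(unname(ms[, "x"]), c(0.3, 0.3))  # suppressed column = median
  expect_error(impute_and_normalize(data.frame(z = 1), ref, "x"), "absent")
})

test_that("normalized prevalence uses within-group relative distributions", {
  orig <- data.frame(g = rep(c("A", "B"), each = 50),
                     f1 = rep(c(1, 0), c(10, 90)),
                     f2 = rep(c(1, 0, 1, 0), c(5, 45, 5, 45)))
  self <- normalized_prevalence(orig, orig, "g")
  expect_true(all(self$table$normalized[self$table$status == "ok"] == 100))
  expect_equal(unname(self$mean_deviation), c(0, 0))

  # original p = 0.10, protected p = 0.12 -> 120
  o <- data.frame(g = "A", f = rep(c(1, 0), c(10, 90)))
  p <- data.frame(g = "A", f = rep(c(1, 0), c(12, 88)))
  r <- normalized_prevalence(o, p, "g", flags = "f")
  expect_equal(r$table$normalized, 120)

  # ratios {1.0, 0.5, 1.5} -> mean deviation 1/3
  o3 <- data.frame(g = "A", a = rep(c(1, 0), c(20, 80)),
                   b = rep(c(1, 0), c(20, 80)), c = rep(c(1, 0), c(20, 80)))
  p3 <- data.frame(g = "A", a = rep(c(1, 0), c(20, 80)),
                   b = rep(c(1, 0), c(10, 90)), c = rep(c(1, 0), c(30, 70)))
  r3 <- normalized_prevalence(o3, p3, "g", flags = c("a", "b", "c"))
  expect_equal(unname(r3$mean_deviation), (0 + 0.5 + 0.5) / 3)

  # zero original prevalence is undefined; suppressed columns are flagged
  o0 <- data.frame(g = "A", f = rep(0, 10), s = rep(c(1, 0), 5))
  p0 <- data.frame(g = "A", f = rep(0, 10), s = rep(NA_real_, 10))
  r0 <- normalized_prevalence(o0, p0, "g", flags = c("f", "s"))
  expect_equal(r0$table$status, c("undefined", "suppressed"))
  expect_true(is.na(r0$mean_deviation[["A"]]))
})

test_that("correlation distance averages absolute pairwise differences", {
  d <- correlated_pair(200, 0.5, seed = 3)
  expect_equal(correlation_distance(d, d)$distance, 0)
  d2 <- correlated_pair(200, 0.3, seed = 4)
  r <- correlation_distance(d, d2)
  expect_equal(r$distance, 0.2, tolerance = 1e-9)
  # zero-variance protected column: its pairs are undefined and excluded
  d3 <- d2
  d3$b <- 0
  r3 <- correlation_distance(d, d3, columns = c("a", "b"))
  expect_true(is.na(r3$distance) || r3$undefined_pairs == 1)
  expect_equal(r3$undefined_pairs, 1)
  expect_error(correlation_distance(d["a"], d2["a"]), "at least two")
})

test_that("support metrics behave at their identity and disjoint extremes", {
  set.seed(6)
  X <- as.data.frame(matrix(stats::rnorm(500 * 4), 500))
  copy <- X
  pra <- precision_recall_authenticity(X, copy)
  expect_equal(pra$authenticity, 0)
  expect_gte(pra$ip_alpha, 0.95)
  expect_gte(pra$ir_beta, 0.95)
  shifted <- X + 100
  far <- precision_recall_authenticity(X, shifted)
  expect_lte(far$ip_alpha, 0.05)
  expect_lte(far$ir_beta, 0.05)
  expect_equal(far$authenticity, 1)
  expect_error(precision_recall_authenticity(X[1:5, ], X), "at least 10")
  const <- as.data.frame(matrix(1, 50, 3))
  expect_error(precision_recall_authenticity(const, const), "all-constant")
})

test_that("same-distribution samples score high on both support metrics", {
  set.seed(7)
  A <- as.data.frame(matrix(stats::rnorm(2000 * 5), 2000))
  B <- as.data.frame(matrix(stats::rnorm(2000 * 5), 2000))
  pra <- precision_recall_authenticity(A, B)
  expect_gte(pra$ip_alpha, 0.9)
  expect_gte(pra$ir_beta, 0.9)
  # swapping the datasets swaps the two curves' roles
  swapped <- precision_recall_authenticity(B, A)
  expect_gt(pra$authenticity, 0.3)   # independent draws are mostly authentic
  expect_equal(pra$ip_alpha, swapped$ir_beta, tolerance = 0.05)
})

test_that("fidelity report bundles self-comparison identities", {
  coh <- harmonize_cohort(quick_cohort(120, seed = 17))
  fr <- fidelity_report(coh, coh, "treatment_group")
  expect_equal(fr$correlation_distance, 0)
  expect_equal(fr$authenticity, 0)
  dev <- fr$normalized_prevalence$mean_deviation
  expect_true(all(dev[!is.na(dev)] == 0))
})
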