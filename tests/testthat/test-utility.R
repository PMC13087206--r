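test_that("stabilized weights are 1 when covariates carry no information", {
  set.seed(2)
  n <- 2000
  d <- data.frame(t = sample(c("A", "B"), n, replace = TRUE, prob = c(.6, .4)),
                  x = rep(1, n))  # constant covariate -> marginal propensity
  pw <- propensity_weights(d, "x", "t", c("A", "B"))
  expect_true(all(abs(pw$weights - 1) < 1e-9))
  d$x2 <- stats::rnorm(n)  # independent covariate -> weights near 1
  pw2 <- propensity_weights(d, "x2", "t", c("A", "B"))
  expect_lt(max(abs(pw2$weights - 1)), 0.25)
  # per-arm weight sums approximately recover arm sizes
  for (g in c("A", "B")) {
    idx <- d$t == g
    expect_lt(abs(sum(pw2$weights[idx]) - sum(idx)) / sum(idx), 0.01)
  }
})

test_that("weighting balances a covariate that differs between arms", {
  coh <- harmonize_cohort(quick_cohort(4000, seed = 15))
  covs <- c(schema_attributes(default_schema(), role = "comorbidity"),
            "age", "gender")
  pw <- propensity_weights(coh, covs, "treatment_group", c("DOAC", "VKA"))
  bal <- smd_balance(coh, pw$weights, covs, "treatment_group",
                     c("DOAC", "VKA"))
  ok <- !is.na(bal$smd_before) & !is.na(bal$smd_after)
  expect_lt(mean(abs(bal$smd_after[ok])), mean(abs(bal$smd_before[ok])))
  # atrial fibrillation is planted with a large group difference
  af <- bal[bal$covariate == "atrial_fibrillation", ]
  expect_lt(abs(af$smd_after), abs(af$smd_before))
})

test_that("standardized mean differences follow the pooled-SD formula", {
  d <- data.frame(t = rep(c("A", "B"), each = 2),
                  x = c(0.1, 1.1, -0.1, 0.9))  # means .6/.4, pooled SD .5
  bal <- smd_balance(d, rep(1, 4), "x", "t", c("A", "B"))
  expect_equal(bal$smd_before, 0.4, tolerance = 1e-9)
  same <- data.frame(t = rep(c("A", "B"), each = 3), x = rep(1:3, 2))
  b2 <- smd_balance(same, rep(1, 6), "x", "t", c("A", "B"))
  expect_equal(b2$smd_before, 0)
  const <- data.frame(t = rep(c("A", "B"), each = 3), x = rep(1, 6))
  expect_true(is.na(smd_balance(const, rep(1, 6), "x", "t",
                                c("A", "B"))$smd_before))
})

test_that("a zero-event arm is reported not estimable", {
  d <- data.frame(t = rep(c("A", "B"), each = 50),
                  flag = c(rep(c(1, 0), c(5, 45)), rep(0, 50)),
                  time = rexp(100, 1 / 300))
  r <- weighted_cox_hr(d, rep(1, 100), "flag", "time", "t", c("A", "B"))
  expect_false(r$estimable)
  expect_true(is.na(r$hr) && is.na(r$ci_low) && is.na(r$ci_high))
  expect_equal(unname(r$events), c(5, 0))
})

test_that("the weighted Cox fit recovers a known hazard ratio", {
  set.seed(8)
  n <- 4000
  tr <- sample(c("A", "B"), n, replace = TRUE)
  rate <- ifelse(tr == "A", 1.25, 1) / 1000
  time <- pmin(rexp(n, rate), 365)
  flag <- as.integer(time < 365)
  d <- data.frame(t = tr, flag = flag, time = time)
  r <- weighted_cox_hr(d, rep(1, n), "flag", "time", "t", c("A", "B"))
  expect_true(r$estimable)
  expect_true(r$ci_low <= 1.25 && 1.25 <= r$ci_high)
  expect_true(r$ci_low <= r$hr && r$hr <= r$ci_high)
  expect_gt(r$ci_low, 0)
})

test_that("the utility report reproduces the study layout on a cohort", {
  coh <- quick_cohort(1200, seed = 23)
  u <- suppressWarnings(run_utility(coh))  # rare flags may separate the arms
  expect_equal(u$outcomes$outcome, c("all_cause_mortality", "major_bleeding"))
  expect_true(all(c("events_exposed", "events_comparator", "hr", "ci_low",
                    "ci_high", "estimable") %in% names(u$outcomes)))
  expect_equal(nrow(u$balance), 22)  # 20 flags + age + gender
  for (i in which(u$outcomes$estimable)) {
    expect_true(u$outcomes$ci_low[i] <= u$outcomes$hr[i])
    expect_true(u$outcomes$hr[i] <= u$outcomes$ci_high[i])
  }
})

test_that("a cohort and its anonymized version give compatible hazard ratios", {
  coh <- quick_cohort(1500, seed = 29)
  u0 <- run_utility(coh)
  cl <- default_classification()
  anon <- anonymize(coh, scenario_anon_config(cl, "context-dependent"),
                    default_hierarchies())
  u1 <- run_utility(anon$table)
  for (i in seq_len(nrow(u1$outcomes))) {
    if (!u1$outcomes$estimable[i] || !u0$outcomes$estimable[i]) next
    expect_true(u1$outcomes$hr[i] >= u0$outcomes$ci_low[i] &&
                  u1$outcomes$hr[i] <= u0$outcomes$ci_high[i],
                label = u1$outcomes$outcome[i])
  }
})

test_that("an unusable treatment column degrades to NA weights", {
  d <- data.frame(t = rep(NA_character_, 20), x = rnorm(20))
  expect_warning(pw <- propensity_weights(d, "x", "t", c("A", "B")),
                 "no usable")
  expect_true(all(is.na(pw$weights)))
})
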