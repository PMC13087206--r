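test_that("default schema has the published shape", {
  s <- default_schema()
  expect_s3_class(s, "cohort_schema")
  expect_equal(nrow(s$attributes), 39)
  expect_equal(sum(s$attributes$role == "demographic"), 3)
  expect_equal(sum(s$attributes$role == "comorbidity"), 20)
  expect_equal(sum(s$attributes$role == "study-info"), 9)
  expect_equal(sum(s$attributes$role == "outcome"), 7)
  expect_false(anyDuplicated(s$attributes$name) > 0)
  # every outcome event flag has a paired event-time attribute
  for (fl in names(s$event_pairs)) {
    expect_true(s$event_pairs[[fl]] %in% s$attributes$name)
  }
})

test_that("schema constructor rejects malformed inputs", {
  a <- default_schema()$attributes
  expect_error(cohort_schema(rbind(a, a[1, ]), "treatment_group",
                             c("DOAC", "VKA")), "unique")
  expect_error(cohort_schema(a, "nope", c("DOAC", "VKA")), "treatment")
  expect_error(cohort_schema(a, "treatment_group", "DOAC"), "two group")
})

test_that("cohort generation is deterministic and schema-conformant", {
  c1 <- quick_cohort(400, seed = 9)
  c2 <- quick_cohort(400, seed = 9)
  expect_identical(c1, c2)
  expect_true(validate_cohort(c1, default_schema()))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(c1, f1)
  write_cohort_csv(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_cohort_csv(f1, default_schema())
  expect_equal(back$age, c1$age)
  expect_s3_class(back$first_vte_date, "Date")
  expect_equal(back$first_vte_date, c1$first_vte_date)
})

test_that("exposed-group share matches the configured split", {
  coh <- generate_cohort(cohort_config(seed = 11))
  share <- mean(coh$treatment_group == "DOAC")
  expect_lt(abs(share - 0.715), 0.03)
})

test_that("degenerate prevalences yield all-zero flags", {
  prev <- default_prevalences()
  prev[, ] <- 0
  coh <- generate_cohort(cohort_config(n_records = 200,
                                       comorbidity_prevalences = prev,
                                       seed = 2))
  flags <- schema_attributes(default_schema(), role = "comorbidity")
  expect_true(all(as.matrix(coh[, flags]) == 0))
})

test_that("identity latent correlation produces uncorrelated flags", {
  cfg <- cohort_config(n_records = 50000,
                       flag_correlation = diag(20),
                       comorbidity_prevalences = {
                         p <- default_prevalences()
                         p[, ] <- 0.3  # common flags so correlations are estimable
                         p
                       },
                       seed = 4)
  coh <- generate_cohort(cfg)
  flags <- schema_attributes(default_schema(), role = "comorbidity")
  r <- stats::cor(as.matrix(coh[, flags]))
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)
})

test_that("generator recovers configured prevalences and hazards", {
  cfg <- cohort_config(n_records = 20000, seed = 6)
  coh <- generate_cohort(cfg)
  prev <- cfg$comorbidity_prevalences
  for (g in 1:2) {
    grp <- coh$treatment_group == cfg$schema$group_labels[g]
    ng <- sum(grp)
    for (fl in rownames(prev)) {
      p <- prev[fl, g]
      se <- sqrt(max(p * (1 - p), 1e-6) / ng)
      expect_lt(abs(mean(coh[[fl]][grp]) - p), 3 * se + 1e-9)
    }
    # exponential hazard MLE: events / person-days
    lam_hat <- sum(coh$death_flag[grp]) / sum(coh$death_time_days[grp])
    lam <- cfg$outcome_hazards$death[g]
    expect_lt(abs(lam_hat - lam) / lam, 0.10)
  }
})

test_that("default config yields rare outcome events at realistic magnitude", {
  coh <- generate_cohort(cohort_config(seed = 1))
  deaths <- tapply(coh$death_flag, coh$treatment_group, sum)
  bleeds <- tapply(coh$major_bleeding_flag, coh$treatment_group, sum)
  expect_true(deaths["DOAC"] >= 25 && deaths["DOAC"] <= 90)
  expect_true(deaths["VKA"] >= 4 && deaths["VKA"] <= 45)
  expect_true(bleeds["DOAC"] >= 15 && bleeds["DOAC"] <= 70)
  expect_true(bleeds["VKA"] >= 2 && bleeds["VKA"] <= 35)
  expect_lt(deaths["VKA"], deaths["DOAC"])
  expect_lt(bleeds["VKA"], bleeds["DOAC"])
})

test_that("invalid generator configs are rejected", {
  R <- default_flag_correlation()
  R[1, 2] <- R[2, 1] <- 0.999
  R[1, 3] <- R[3, 1] <- 0.999
  R[2, 3] <- R[3, 2] <- -0.999  # not PSD
  expect_error(cohort_config(flag_correlation = R), "positive semi-definite")
  expect_error(cohort_config(n_records = 1), "at least 2")
  expect_error(cohort_config(group_probability = 1.5), "\\[0,1\\]")
})

test_that("generator configs round-trip through YAML", {
  cfg <- cohort_config(n_records = 300, seed = 5)
  f <- tempfile(fileext = ".yaml")
  write_cohort_config_yaml(cfg, f)
  back <- read_cohort_config_yaml(f)
  expect_identical(generate_cohort(cfg), generate_cohort(back))
})

test_that("split_cohort partitions exactly, reproducibly and disjointly", {
  coh <- quick_cohort(1000, seed = 3)
  s1 <- split_cohort(coh, c(0.5, 0.25, 0.25), seed = 21)
  expect_equal(vapply(s1, nrow, 0L), c(train = 500L, control = 250L,
                                       pool = 250L))
  s2 <- split_cohort(coh, c(0.5, 0.25, 0.25), seed = 21)
  expect_identical(s1, s2)
  idx <- unlist(lapply(s1, attr, "row_indices"))
  expect_false(anyDuplicated(idx) > 0)
  expect_error(split_cohort(coh, c(0.9999, 0.00001, 0.00001)), "empty")
})
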