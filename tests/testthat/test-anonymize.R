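test_that("k-anonymity checker counts equivalence classes", {
  t4 <- data.frame(qi = c("A", "A", "B", "B"), y = 1:4)
  expect_true(check_k_anonymity(t4, "qi", 2)$satisfied)
  expect_false(check_k_anonymity(t4, "qi", 3)$satisfied)
  t6 <- data.frame(qi = c("A", "A", "A", "B", "B", "C"))
  r <- check_k_anonymity(t6, "qi", 2)
  expect_false(r$satisfied)
  expect_equal(r$min_class_size, 1)
  expect_equal(sort(unname(r$class_sizes)), c(1L, 2L, 3L))
  expect_warning(v <- check_k_anonymity(t4, character(), 2), "vacuously")
  expect_true(v$satisfied)
})

test_that("equal-distance t-closeness is the total-variation distance", {
  # class distribution identical to the table distribution
  t1 <- data.frame(qi = rep(c("A", "B"), each = 4),
                   s = rep(c(0, 1), 4))
  r <- check_t_closeness(t1, "qi", "s", 0.1)
  expect_true(r$satisfied)
  expect_equal(r$max_distance, 0)
  # table 50/50, one class entirely value 1 -> TV distance 0.5
  t2 <- data.frame(qi = rep(c("A", "B"), each = 2), s = c(0, 0, 1, 1))
  r2 <- check_t_closeness(t2, "qi", "s", 0.5)
  expect_true(r2$satisfied)
  expect_equal(r2$max_distance, 0.5)
  expect_false(check_t_closeness(t2, "qi", "s", 0.4)$satisfied)
  # a single class equal to the whole table always passes
  t3 <- data.frame(qi = rep("A", 6), s = c(1, 1, 1, 0, 0, 1))
  expect_true(check_t_closeness(t3, "qi", "s", 1e-9)$satisfied)
  expect_error(check_t_closeness(t3, "qi", "nope", 0.5), "absent")
})

test_that("granularity loss follows the interval-width / domain formula", {
  h <- list(age = hierarchy_numeric("age", c(5, 10), domain = c(18, 108)))
  orig <- data.frame(age = c(30, 35, 39))
  expect_equal(granularity_loss(orig, orig, h), 0)
  sup <- data.frame(age = c(NA_real_, NA_real_, NA_real_))
  expect_equal(granularity_loss(orig, sup, h), 1)
  gen <- apply_hierarchy(h$age, orig$age, 2, domain = c(18, 108))
  trans <- data.frame(age = gen$values)
  expect_equal(granularity_loss(orig, trans, h), 10 / 90)
})

test_that("date microaggregation replaces classes by rounded mean dates", {
  t <- data.frame(d = as.Date(c("2020-01-01", "2020-01-03", "2021-05-05")))
  out <- microaggregate_dates(t, "d", c("x", "x", "y"))
  expect_equal(out$d, as.Date(c("2020-01-02", "2020-01-02", "2021-05-05")))
  t2 <- data.frame(d = as.Date("1970-01-01") + c(0, 10, 11))
  out2 <- microaggregate_dates(t2, "d", rep("x", 3))
  expect_equal(unique(out2$d), as.Date("1970-01-08"))  # mean 7 rounded
  t3 <- data.frame(d = as.Date(c(NA, NA)))
  expect_true(all(is.na(microaggregate_dates(t3, "d", c("x", "x"))$d)))
})

test_that("date/offset conversion round-trips and honors midpoints", {
  t <- data.frame(anchor = as.Date("2020-03-01"),
                  ev = as.Date("2020-03-31"))
  off <- dates_to_offsets(t, "anchor", "ev")
  expect_equal(off$ev, 30)
  back <- offsets_to_dates(off, "anchor", "ev")
  expect_equal(back$ev, t$ev)
  # offset generalized to [0, 30) with midpoint 15
  mid <- off
  mid$ev <- 15
  rec <- offsets_to_dates(mid, "anchor", "ev")
  expect_equal(rec$ev, as.Date("2020-03-16"))
  t$anchor <- as.Date(NA)
  expect_true(is.na(dates_to_offsets(t, "anchor", "ev")$ev))
})

test_that("vacuous constraints return the identity transformation", {
  tab <- data.frame(age = c(21, 34, 55, 71), flag = c(0, 1, 0, 1))
  h <- list(age = hierarchy_numeric("age", c(5, 10)),
            flag = hierarchy_categorical("flag", categories = c("0", "1")))
  cfg <- anon_config(k = 1, t = 1, protected_attributes = c("age", "flag"))
  r <- anonymize(tab, cfg, h)
  expect_equal(r$loss, 0)
  expect_equal(r$suppressed_records, 0)
  expect_equal(r$table$age, tab$age)
  expect_true(check_k_anonymity(r$table, r$quasi_identifiers, 1)$satisfied)
})

test_that("the toy age table is 2-anonymized with the outlier handled", {
  tab <- data.frame(age = c(21, 22, 23, 41, 42, 80),
                    s = c(0, 1, 0, 1, 0, 1))
  h <- list(age = hierarchy_numeric("age", c(5, 10)))
  cfg <- anon_config(k = 2, t = 1, protected_attributes = "age",
                     sensitive_attributes = character())
  r <- anonymize(tab, cfg, h)
  expect_true(check_k_anonymity(r$table, "age", 2)$satisfied)
  # the age-80 record is suppressed or the attribute fully generalized
  expect_true(r$suppressed_records >= 1 ||
                r$chosen_levels[["age"]] == h$age$n_levels - 1L ||
                length(unique(r$table$age)) == 1L)
  # search matches the independent brute-force optimum
  oracle <- brute_force_anon_loss(tab, "age", h, k = 2)
  expect_equal(r$loss, oracle, tolerance = 1e-12)
})

test_that("lattice search equals exhaustive enumeration on tiny instances", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    p <- sample(1:3, 1)
    tab <- as.data.frame(lapply(seq_len(p), function(j)
      sample(0:60, n, replace = TRUE)))
    names(tab) <- paste0("q", seq_len(p))
    tab$s <- sample(0:1, n, replace = TRUE)
    h <- lapply(names(tab)[seq_len(p)], function(nm)
      hierarchy_numeric(nm, c(10, 25)))
    names(h) <- names(tab)[seq_len(p)]
    with_sens <- i %% 2 == 0
    cfg <- anon_config(k = 2, t = 0.5,
                       protected_attributes = names(h),
                       sensitive_attributes = if (with_sens) "s"
                                              else character())
    r <- anonymize(tab, cfg, h)
    oracle <- brute_force_anon_loss(tab, names(h), h, k = 2,
                                    t = if (with_sens) 0.5,
                                    sensitive = if (with_sens) "s")
    expect_equal(r$loss, oracle, tolerance = 1e-12,
                 label = sprintf("instance %d (n=%d, p=%d)", i, n, p))
  }
})

test_that("achieved loss is monotone in k", {
  set.seed(5)
  tab <- data.frame(q1 = sample(0:40, 12, replace = TRUE),
                    q2 = sample(0:40, 12, replace = TRUE))
  h <- list(q1 = hierarchy_numeric("q1", c(10, 20)),
            q2 = hierarchy_numeric("q2", c(10, 20)))
  losses <- vapply(c(1, 2, 3, 4), function(k) {
    anonymize(tab, anon_config(k = k, t = 1,
                               protected_attributes = names(h)), h)$loss
  }, 0)
  expect_true(all(diff(losses) >= -1e-12))
})

test_that("anonymization satisfies its own checkers on a simulated cohort", {
  coh <- quick_cohort(250, seed = 31)
  sp <- split_cohort(coh, c(0.6, 0.2, 0.2), seed = 1)
  cl <- default_classification()
  h <- default_hierarchies()
  for (scen in c("context-dependent", "context-independent")) {
    cfg <- scenario_anon_config(cl, scen)
    r <- anonymize(sp$train, cfg, h)
    expect_true(check_k_anonymity(r$table, r$quasi_identifiers,
                                  2)$satisfied, label = scen)
    for (sa in r$sensitive_attributes) {
      expect_true(check_t_closeness(r$table, r$quasi_identifiers, sa,
                                    0.5)$satisfied,
                  label = paste(scen, sa))
    }
    expect_true(r$loss >= 0 && r$loss <= 1)
  }
})

test_that("protecting everything suppresses at least as much as the threat-modeled setup", {
  coh <- quick_cohort(500, seed = 12)
  sp <- split_cohort(coh, c(0.6, 0.2, 0.2), seed = 2)
  cl <- default_classification()
  h <- default_hierarchies()
  r_ci <- anonymize(sp$train, scenario_anon_config(cl, "context-independent"),
                    h)
  r_cd <- anonymize(sp$train, scenario_anon_config(cl, "context-dependent"),
                    h)
  expect_gt(r_ci$suppressed_records, r_cd$suppressed_records)
  expect_gte(length(r_ci$suppressed_attributes),
             length(r_cd$suppressed_attributes))
})

test_that("hierarchy specifications round-trip through YAML", {
  h <- list(age = hierarchy_numeric("age", c(5, 10), domain = c(18, 108)),
            flag = hierarchy_categorical("flag", categories = c("0", "1")))
  f <- tempfile(fileext = ".yaml")
  write_hierarchies_yaml(h, f)
  back <- read_hierarchies_yaml(f)
  v <- c(23, 61, 88)
  for (lev in 0:2) {
    expect_equal(apply_hierarchy(back$age, v, lev),
                 apply_hierarchy(h$age, v, lev))
  }
  expect_equal(back$flag$n_levels, h$flag$n_levels)
})

test_that("missing hierarchies and infeasible configs fail loudly", {
  tab <- data.frame(a = 1:6)
  expect_error(anonymize(tab, anon_config(k = 2,
                                          protected_attributes = "a"),
                         hierarchies = list()), "no hierarchy")
  h <- list(a = hierarchy_numeric("a", 2))
  cfg <- anon_config(k = 5, t = 0.5, protected_attributes = "a",
                     record_suppression_limit = 0,
                     allow_attribute_suppression = FALSE)
  expect_error(anonymize(data.frame(a = 1:6), cfg, h), "infeasible")
})
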