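test_that("risk normalization matches its closed form", {
  expect_equal(round(risk_score(0.960, 0.926), 2), 0.46)
  expect_equal(risk_score(0.3, 0.3), 0)
  expect_equal(risk_score(1.0, 0.4), 1.0)
  expect_error(risk_score(0.5, 1), "undefined")
  expect_error(risk_score(1.2, 0.5))
})

test_that("nearest-neighbor ties break deterministically by record order", {
  pool <- data.frame(x = c(1, 1, 1), y = c("a", "a", "b"))
  tgt <- data.frame(x = 1, y = "a")
  nn <- privcohort:::knn_indices(tgt, pool, c("x", "y"), 1)
  expect_equal(nn[[1]], 1L)
  nn2 <- privcohort:::knn_indices(tgt, pool, c("x", "y"), 2)
  expect_equal(nn2[[1]], c(1L, 2L))
})

make_attack_sets <- function(n = 300, seed = 1) {
  coh <- generate_cohort(cohort_config(n_records = 3 * n, seed = seed))
  sp <- split_cohort(coh, c(1 / 3, 1 / 3, 1 / 3), seed = seed)
  list(train = harmonize_cohort(sp$train),
       control = harmonize_cohort(sp$control))
}

aux_all <- function() setdiff(default_schema()$attributes$name, "insured_id")

test_that("identity release leaks through linkage and singling-out", {
  s <- make_attack_sets(250, seed = 2)
  cfg <- attack_config(aux_attributes = aux_all(), repetitions = 3, seed = 5)
  lk <- linkage(s$train, s$train, s$control, config = cfg)
  expect_gt(lk$risk, 0.8)
  expect_true(lk$valid)
  so <- singling_out(s$train, s$train, s$control, "multivariate", cfg)
  expect_gt(so$risk, 0.8)
  su <- singling_out(s$train, s$train, s$control, "univariate", cfg)
  expect_gt(su$risk, 0.8)
})

test_that("a release independent of the attacked sets carries no risk", {
  s <- make_attack_sets(250, seed = 3)
  ind <- harmonize_cohort(generate_cohort(cohort_config(n_records = 250,
                                                        seed = 404)))
  cfg <- attack_config(aux_attributes = aux_all(), repetitions = 5, seed = 6)
  for (att in list(
    linkage(ind, s$train, s$control, config = cfg),
    singling_out(ind, s$train, s$control, "multivariate", cfg),
    attribute_inference(ind, s$train, s$control, "arterial_hypertension",
                        cfg))) {
    tol <- 3 * max(att$risk_sd, 0.02, na.rm = TRUE) + 0.05
    expect_lt(abs(att$risk), tol)
  }
})

test_that("attribute inference succeeds on an identity release", {
  s <- make_attack_sets(250, seed = 4)
  cfg <- attack_config(aux_attributes = aux_all(), repetitions = 3, seed = 7)
  ai <- attribute_inference(s$train, s$train, s$control, "age", cfg)
  expect_gt(ai$risk, 0.8)
  expect_true(ai$valid)
  # validity flag is exactly "main beats baseline"
  expect_equal(ai$valid, ai$r_main > ai$r_baseline)
})

test_that("singling-out warns when candidate predicates run short", {
  dup <- data.frame(a = rep(c("x", "y"), 10), b = rep(1, 20))
  atk <- data.frame(a = rep(c("x", "y"), 5), b = rep(1, 10))
  cfg <- attack_config(aux_attributes = c("a", "b"), n_targets = 50,
                       repetitions = 2, seed = 8)
  expect_warning(r <- singling_out(dup, atk, atk, "univariate", cfg),
                 "fewer candidate predicates")
  expect_s3_class(r, "risk_report")
})

test_that("linkage rejects malformed attribute splits", {
  s <- make_attack_sets(120, seed = 9)
  cfg <- attack_config(aux_attributes = aux_all(), repetitions = 2, seed = 1)
  expect_error(linkage(s$train, s$train, s$control,
                       aux_split = list("age", "age"), config = cfg),
               "disjoint")
  expect_error(linkage(s$train, s$train, s$control,
                       aux_split = list(character(), "age"), config = cfg),
               "non-empty")
  expect_error(attribute_inference(s$train, s$train, s$control, "age",
                                   attack_config(aux_attributes = "age",
                                                 seed = 1)),
               "no auxiliary")
})
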