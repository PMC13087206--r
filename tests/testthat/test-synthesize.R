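test_that("rare categories are pooled and clip bounds match quantiles", {
  set.seed(1)
  d <- data.frame(cat = c(rep("common", 95), rep("rare", 3), rep("mid", 2)),
                  num = stats::rnorm(100))
  cfg <- synth_config(rare_category_min_count = 5, seed = 2)
  m <- synth_fit(d, cfg)
  cats <- m$models$cat$cpt$cats
  expect_false("rare" %in% cats)
  expect_false("mid" %in% cats)
  expect_true("_other_" %in% cats)
  expect_true("common" %in% cats)
  expect_equal(m$encoders$num$clip,
               unname(stats::quantile(d$num, c(0.01, 0.99))),
               tolerance = 1e-12)
})

test_that("constant columns are modeled as constants with a warning", {
  d <- data.frame(k = rep("x", 60), v = rep(c("a", "b"), 30))
  expect_warning(m <- synth_fit(d, synth_config(seed = 1)), "constant")
  out <- synth_sample(m, 40, seed = 3)
  expect_true(all(out$k == "x"))
})

test_that("sampling preserves the requested row count and is deterministic", {
  d <- quick_cohort(200, seed = 8)
  m <- suppressWarnings(synth_fit(d, synth_config(seed = 5),
                                  default_schema()))
  s1 <- synth_sample(m, nrow(d), seed = 9)
  expect_equal(nrow(s1), 200)
  expect_identical(s1, synth_sample(m, 200, seed = 9))
  expect_false(identical(s1, synth_sample(m, 200, seed = 10)))
  expect_equal(names(s1), names(d))
  expect_error(synth_sample(m, 0), "positive")
})

test_that("early stopping rejects spurious parents on independent data", {
  set.seed(42)
  n <- 10000
  d <- as.data.frame(lapply(1:10, function(j)
    sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))))
  names(d) <- paste0("f", 1:10)
  m <- synth_fit(d, synth_config(seed = 3))
  n_parents <- vapply(m$models, function(mm) length(mm$parents), 0L)
  expect_gte(mean(n_parents == 0), 0.8)
})

test_that("sampled marginals stay within sampling error of training data", {
  train <- quick_cohort(2000, seed = 21)
  m <- suppressWarnings(synth_fit(train, synth_config(seed = 4),
                                  default_schema()))
  syn <- synth_sample(m, 20000, seed = 22)
  flags <- schema_attributes(default_schema(), role = "comorbidity")
  for (g in c("DOAC", "VKA")) {
    tr_g <- train[train$treatment_group == g, ]
    sy_g <- syn[syn$treatment_group == g, ]
    for (fl in setdiff(flags, "obesity")) {
      if (sum(tr_g[[fl]]) < m$config$rare_category_min_count) next
      p <- mean(tr_g[[fl]])
      se <- sqrt(p * (1 - p) * (1 / nrow(tr_g) + 1 / nrow(sy_g)))
      expect_lt(abs(mean(sy_g[[fl]]) - p), 3 * se + 0.005,
                label = paste(g, fl))
    }
  }
})

test_that("sampled numerics respect clip bounds and pooled rarities vanish", {
  train <- quick_cohort(400, seed = 13)
  m <- suppressWarnings(synth_fit(train, synth_config(seed = 6),
                                  default_schema()))
  syn <- synth_sample(m, 5000, seed = 14)
  for (nm in c("age", "index_offset", "death_time_days")) {
    e <- m$encoders[[nm]]
    expect_true(all(syn[[nm]] >= e$clip[1] - 1e-9 &
                      syn[[nm]] <= e$clip[2] + 1e-9), label = nm)
  }
  # categories rarer than the threshold never appear (pooled label excepted;
  # binary flags decode the pooled label to the majority value)
  for (nm in c("gender", "treatment_group")) {
    cnt <- table(as.character(train[[nm]]))
    sampled <- setdiff(unique(as.character(syn[[nm]])), "_other_")
    expect_true(all(cnt[sampled] >= m$config$rare_category_min_count),
                label = nm)
  }
  if (sum(train$obesity) < m$config$rare_category_min_count) {
    expect_equal(sum(syn$obesity), 0)
  }
})

test_that("synthetic rows collide with training rows no more than chance", {
  set.seed(99)
  n <- 400
  d <- as.data.frame(lapply(1:8, function(j)
    sample(letters[1:4], n, replace = TRUE)))
  names(d) <- paste0("c", 1:8)
  m <- synth_fit(d, synth_config(seed = 7))
  syn <- synth_sample(m, n, seed = 8)
  key <- function(x) do.call(paste, c(x, sep = "|"))
  hits <- sum(key(syn) %in% key(d))
  # expected collision rate under the model's marginals
  p_row <- vapply(unique(key(d)), function(kk) {
    vals <- strsplit(kk, "\\|")[[1]]
    prod(vapply(seq_along(vals), function(j) {
      pm <- m$models[[j]]$cpt$p_marg
      unname(pm[vals[j]] %||% min(pm))
    }, 0))
  }, 0)
  expected <- n * sum(p_row)
  expect_lte(hits, expected + 4 * sqrt(expected) + 2)
})

test_that("fitted models round-trip through JSON", {
  d <- quick_cohort(150, seed = 2)[, c("age", "gender",
                                       "arterial_hypertension",
                                       "treatment_group",
                                       "death_time_days")]
  m <- synth_fit(d, synth_config(seed = 11))
  f <- tempfile(fileext = ".json")
  write_synth_model(m, f)
  m2 <- read_synth_model(f)
  s1 <- synth_sample(m, 100, seed = 5)
  s2 <- synth_sample(m2, 100, seed = 5)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("fitting demands a minimal sample", {
  expect_error(synth_fit(data.frame(a = 1:10), synth_config()), "at least 50")
})
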