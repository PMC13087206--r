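test_that("threat scores are the sum of the three ratings", {
  expect_equal(score_attribute(attribute_profile("x", replicability = 1,
                                                 availability = 1,
                                                 distinguishability = 1)), 3)
  expect_equal(score_attribute(attribute_profile("x", replicability = 3,
                                                 availability = 3,
                                                 distinguishability = 3)), 9)
  expect_equal(score_attribute(attribute_profile("x", replicability = 2,
                                                 availability = 3,
                                                 distinguishability = 1)), 6)
  expect_error(score_attribute(attribute_profile("id", direct = TRUE)),
               "bypass")
  expect_error(attribute_profile("x", replicability = 4, availability = 1,
                                 distinguishability = 1), "1..3")
})

test_that("direct identifiers are classed direct regardless of ratings", {
  p <- list(attribute_profile("id", direct = TRUE),
            attribute_profile("a", replicability = 3, availability = 3,
                              distinguishability = 3))
  cl <- classify_attributes(p, threshold = 6)
  expect_equal(cl$table$class, c("direct", "indirect"))
})

test_that("bundled default profiles reproduce the published category counts", {
  cl <- default_classification()
  counts <- table(cl$table$class)
  expect_equal(unname(counts["direct"]), 1L)
  expect_equal(unname(counts["indirect"]), 10L)
  expect_equal(unname(counts["sensitive"]), 5L)
  expect_equal(sum(counts), 39L)  # exhaustive and mutually exclusive
})

test_that("a threshold above 9 leaves only direct and sensitive classes", {
  cl <- classify_attributes(default_profiles(), threshold = 10,
                            default_schema())
  expect_equal(sum(cl$table$class == "indirect"), 0L)
  expect_true(all(cl$table$class %in% c("direct", "sensitive",
                                        "insensitive")))
})

test_that("raising a single rating never demotes an indirect attribute", {
  base <- attribute_profile("x", replicability = 2, availability = 2,
                            distinguishability = 2)
  for (thr in 3:9) {
    cls0 <- classify_attributes(list(base), thr)$table$class
    for (dim in c("replicability", "availability", "distinguishability")) {
      p <- base
      p[[dim]] <- 3L
      cls1 <- classify_attributes(list(p), thr)$table$class
      rank <- c(insensitive = 0, sensitive = 0, indirect = 1)
      expect_gte(rank[cls1], rank[cls0])
    }
  }
})

test_that("classification demands a profile for every schema attribute", {
  p <- default_profiles()
  expect_error(classify_attributes(p[-5], default_threshold(),
                                   default_schema()), "missing profile")
})

test_that("threat profiles round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  write_profiles_yaml(default_profiles(), f)
  back <- read_profiles_yaml(f)
  cl1 <- classify_attributes(default_profiles(), 6, default_schema())
  cl2 <- classify_attributes(back, 6, default_schema())
  expect_equal(cl1$table, cl2$table)
})
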