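#' Membership-inference configuration
#'
#' Defaults follow a coverage-based design: reference samples of 500 records
#' with 10 training and 10 test replicates per label and 30 independent runs
#' give every attacker-pool record at least a 95% chance of appearing in at
#' least one reference draw.
#'
#' @param n_average_targets,n_outlier_targets how many average / outlier
#'   targets to attack.
#' @param sample_size reference-sample size per shadow dataset.
#' @param train_replicates,test_replicates labeled shadow datasets per label
#'   per run.
#' @param n_runs independent runs.
#' @param n_bins histogram bins per numeric attribute for the marginal
#'   feature set.
#' @param coverage_probability required probability that each pool record is
#'   drawn at least once.
#' @param seed integer.
#' @return an `mia_config` list.
#' @export
mia_config <- function(n_average_targets = 10L, n_outlier_targets = 10L,
                       sample_size = 500L, train_replicates = 10L,
                       test_replicates = 10L, n_runs = 30L, n_bins = 10L,
                       coverage_probability = 0.95, seed = 1L) {
  stopifnot(sample_size > 0, train_replicates > 0, test_replicates > 0,
            n_runs > 0)
  structure(list(n_average_targets = as.integer(n_average_targets),
                 n_outlier_targets = as.integer(n_outlier_targets),
                 sample_size = as.integer(sample_size),
                 train_replicates = as.integer(train_replicates),
                 test_replicates = as.integer(test_replicates),
                 n_runs = as.integer(n_runs), n_bins = as.integer(n_bins),
                 coverage_probability = coverage_probability,
                 seed = as.integer(seed)),
            class = "mia_config")
}

#' Select average and outlier target records
#'
#' Records are ranked by the mean distance to their 5 nearest neighbors in
#' min-max normalized space: the top `n_outlier` are the outlier targets and
#' the `n_average` records closest to the median of that distance
#' distribution (excluding the outliers) are the average targets. Ties break
#' by record index, so the ranking is invariant to record order.
#'
#' @param cohort data.frame with at least `n_average + n_outlier` rows.
#' @param n_average,n_outlier target counts.
#' @param k neighbors entering the mean distance.
#' @return list with integer vectors `average` and `outlier` (row indices)
#'   and the distance `scores`.
#' @export
select_targets <- function(cohort, n_average = 10L, n_outlier = 10L, k = 5L) {
  n <- nrow(cohort)
  if (n < n_average + n_outlier) stop("cohort too small for target counts")
  X <- impute_and_normalize(cohort, cohort)
  D <- cross_dist(X, X)
  diag(D) <- Inf
  k <- min(k, n - 1L)
  scores <- apply(D, 1, function(d) mean(sort(d)[seq_len(k)]))
  ord <- order(-scores, seq_len(n))
  outlier <- ord[seq_len(n_outlier)]          # most outlying first
  rest <- setdiff(seq_len(n), outlier)
  med <- stats::median(scores[rest])
  average <- rest[order(abs(scores[rest] - med), rest)][seq_len(n_average)]
  list(average = average, outlier = outlier, scores = scores)
}

#' Fit marginal-feature bins on the attacker pool
#'
#' Numeric attributes get `n_bins` equal-width bins over the pool range
#' (values outside are clipped to the end bins); categorical attributes keep
#' the pool's category set plus an overflow slot for unseen values.
#'
#' @param pool attacker reference data.frame.
#' @param n_bins histogram bins per numeric attribute.
#' @return a `marginal_bins` object for [marginal_features()].
#' @export
fit_marginal_bins <- function(pool, n_bins = 10L) {
  spec <- lapply(names(pool), function(nm) {
    v <- pool[[nm]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    if (is.numeric(v) && length(unique(stats::na.omit(v))) > 2) {
      rng <- range(v, na.rm = TRUE)
      if (!all(is.finite(rng)) || rng[1] == rng[2]) {
        rng <- c(rng[1] - 0.5, rng[1] + 0.5)
      }
      list(name = nm, kind = "numeric",
           edges = seq(rng[1], rng[2], length.out = n_bins + 1L))
    } else {
      list(name = nm, kind = "categorical",
           categories = sort(unique(as.character(stats::na.omit(v)))))
    }
  })
  structure(list(spec = spec), class = "marginal_bins")
}

#' Attribute-wise marginal feature vector of a table
#'
#' Concatenates, per attribute, binned counts (numeric) or category relative
#' frequencies (categorical) using bins fitted on the attacker pool; the
#' feature length is independent of the table size and invariant to row
#' order.
#'
#' @param table data.frame.
#' @param bins a [fit_marginal_bins()] object.
#' @return named numeric vector.
#' @export
marginal_features <- function(table, bins) {
  feats <- lapply(bins$spec, function(sp) {
    v <- table[[sp$name]]
    if (sp$kind == "numeric") {
      if (inherits(v, "Date")) v <- as.numeric(v)
      v <- v[!is.na(v)]
      v <- pmin(pmax(v, sp$edges[1]), sp$edges[length(sp$edges)])
      idx <- findInterval(v, sp$edges, all.inside = TRUE)
      cnt <- tabulate(idx, nbins = length(sp$edges) - 1L)
      stats::setNames(cnt, paste0(sp$name, "_b", seq_along(cnt)))
    } else {
      s <- as.character(v[!is.na(v)])
      cnt <- c(vapply(sp$categories, function(cc) sum(s == cc), 0),
               other = sum(!s %in% sp$categories))
      tot <- max(length(s), 1L)
      stats::setNames(cnt / tot,
                      paste0(sp$name, "_", c(sp$categories, "other")))
    }
  })
  unlist(feats)
}

#' Protection procedures for shadow-model attacks
#'
#' A protector is a function mapping a training data.frame to a released
#' data.frame. `protector_identity` releases the input unchanged (maximal
#' leakage); `protector_constant` releases a fixed dataset regardless of
#' input (no leakage); `protector_anonymizer` wraps [anonymize()];
#' `protector_synthesizer` fits [synth_fit()] and releases a same-size
#' [synth_sample()].
#'
#' @param fixed data.frame released by the constant protector.
#' @param config,hierarchies arguments for the wrapped procedure.
#' @param synth_cfg a [synth_config()].
#' @return a function `(data.frame) -> data.frame`.
#' @export
protector_identity <- function() function(d) d

#' @rdname protector_identity
#' @export
protector_constant <- function(fixed) function(d) fixed

#' @rdname protector_identity
#' @export
protector_anonymizer <- function(config, hierarchies = default_hierarchies()) {
  function(d) anonymize(d, config, hierarchies)$table
}

#' @rdname protector_identity
#' @export
protector_synthesizer <- function(synth_cfg = synth_config(), schema = NULL) {
  function(d) synth_sample(synth_fit(d, synth_cfg, schema), nrow(d),
                           seed = sample.int(.Machine$integer.max, 1))
}

#' Shadow-model membership inference against a protection procedure
#'
#' Per run, reference samples are drawn from the attacker pool and protected
#' with and without the target record; a random-forest classifier trained on
#' the marginal features of the labeled shadow releases is evaluated on
#' fresh labeled releases. The risk is the attacker advantage
#' `TPR - FPR`, aggregated over runs; negative values indicate no effective
#' advantage and are reported as-is.
#'
#' @param target single-row data.frame (the attacked record).
#' @param protector a protection function (see [protector_identity()]).
#' @param attacker_pool reference data.frame from the same population; the
#'   target is never drawn into reference samples.
#' @param config an [mia_config()].
#' @param bins optional pre-fitted [fit_marginal_bins()].
#' @return an `mia_result` with `tpr`, `fpr`, `risk`, per-run rates,
#'   `coverage_ok` and the number of discarded runs.
#' @export
membership_inference <- function(target, protector, attacker_pool, config,
                                 bins = NULL) {
  stopifnot(nrow(target) == 1)
  if (config$sample_size > nrow(attacker_pool)) {
    stop("sample_size exceeds attacker pool size")
  }
  set.seed(config$seed)
  if (is.null(bins)) bins <- fit_marginal_bins(attacker_pool, config$n_bins)

  draws_per_record <- config$n_runs *
    (config$train_replicates + config$test_replicates) * 2
  p_incl <- 1 - (1 - config$sample_size / nrow(attacker_pool))^draws_per_record
  coverage_ok <- p_incl >= config$coverage_probability
  if (!coverage_ok) {
    warning(sprintf(
      "coverage criterion not met: inclusion probability %.3f < %.2f",
      p_incl, config$coverage_probability))
  }

  shadow <- function(label_in) {
    base_n <- if (label_in) config$sample_size - 1L else config$sample_size
    ref <- attacker_pool[sample.int(nrow(attacker_pool), base_n), ,
                         drop = FALSE]
    if (label_in) ref <- rbind(ref, target)
    protector(ref[sample.int(nrow(ref)), , drop = FALSE])
  }

  runs <- list()
  discarded <- 0L
  for (run in seq_len(config$n_runs)) {
    res <- tryCatch({
      make_set <- function(n_rep) {
        labs <- rep(c(TRUE, FALSE), each = n_rep)
        feats <- t(vapply(labs, function(l) marginal_features(shadow(l), bins),
                          numeric(length(marginal_features(attacker_pool[1, ,
                            drop = FALSE], bins)))))
        list(x = feats, y = factor(labs, levels = c(FALSE, TRUE)))
      }
      tr <- make_set(config$train_replicates)
      te <- make_set(config$test_replicates)
      varying <- apply(tr$x, 2, function(col) stats::var(col) > 0)
      if (!any(varying)) {
        # the release carries no signal about the input: no advantage
        pred <- factor(rep(FALSE, length(te$y)), levels = c(FALSE, TRUE))
      } else {
        rf <- randomForest::randomForest(tr$x[, varying, drop = FALSE],
                                         tr$y, ntree = 100)
        pred <- stats::predict(rf, te$x[, varying, drop = FALSE])
      }
      tpr <- mean(pred[te$y == "TRUE"] == "TRUE")
      fpr <- mean(pred[te$y == "FALSE"] == "TRUE")
      data.frame(run = run, tpr = tpr, fpr = fpr)
    }, error = function(e) {
      warning("shadow run discarded: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) discarded <- discarded + 1L else {
      runs[[length(runs) + 1L]] <- res
    }
  }
  if (!length(runs)) stop("all shadow runs failed")
  runs <- do.call(rbind, runs)
  tpr <- mean(runs$tpr)
  fpr <- mean(runs$fpr)
  structure(list(tpr = tpr, fpr = fpr, risk = tpr - fpr,
                 runs = runs, coverage_ok = coverage_ok,
                 discarded_runs = discarded),
            class = "mia_result")
}

#' @export
print.mia_result <- function(x, ...) {
  cat(sprintf("mia_result: risk=%.3f (TPR %.3f, FPR %.3f) over %d runs%s\n",
              x$risk, x$tpr, x$fpr, nrow(x$runs),
              if (x$coverage_ok) "" else " [coverage not met]"))
  invisible(x)
}
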