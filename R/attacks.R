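#' Normalized privacy risk score
#'
#' Excess success of the main attack over the control attack, normalized by
#' the remaining headroom to perfect success:
#' `R = (r_main - r_control) / (1 - r_control)`.
#'
#' @param r_main success rate of the attack on training records, in `[0, 1]`.
#' @param r_control success rate of the same attack evaluated on an
#'   independent control set, in `[0, 1)`.
#' @return the normalized risk (negative values indicate no effective
#'   advantage and are returned as-is).
#' @export
risk_score <- function(r_main, r_control) {
  stopifnot(r_main >= 0, r_main <= 1, r_control >= 0, r_control <= 1)
  if (any(r_control >= 1)) {
    stop("risk undefined: control attack success rate is 1")
  }
  (r_main - r_control) / (1 - r_control)
}

#' Attack configuration
#'
#' @param aux_attributes attribute names available to the adversary
#'   (scenario-dependent: the classified indirect identifiers in the
#'   context-dependent scenario, every attribute in the context-independent
#'   one).
#' @param n_targets number of targets / queries per repetition (default: 20%
#'   of the attacked records).
#' @param n_multivariate_queries cap for multivariate singling-out queries.
#' @param repetitions number of attack repetitions.
#' @param knn_k neighbors for linkage matching.
#' @param numeric_tolerance fraction of an attribute's range within which a
#'   numeric inference counts as correct.
#' @param seed integer.
#' @return an `attack_config` list.
#' @export
attack_config <- function(aux_attributes,
                          n_targets = NULL,
                          n_multivariate_queries = 100L,
                          repetitions = 10L,
                          knn_k = 1L,
                          numeric_tolerance = 0.05,
                          seed = 1L) {
  structure(list(aux_attributes = aux_attributes,
                 n_targets = n_targets,
                 n_multivariate_queries = as.integer(n_multivariate_queries),
                 repetitions = as.integer(repetitions),
                 knn_k = as.integer(knn_k),
                 numeric_tolerance = numeric_tolerance,
                 seed = as.integer(seed)),
            class = "attack_config")
}

# mixed-type Gower-style distance between rows of A and rows of B:
# range-normalized absolute difference for numerics, 0/1 mismatch for
# categoricals, averaged over attributes; a missing value mismatches (1)
# unless both sides are missing (0)
gower_dist <- function(A, B, columns, ranges = NULL) {
  nA <- nrow(A)
  nB <- nrow(B)
  acc <- matrix(0, nA, nB)
  for (nm in columns) {
    a <- A[[nm]]
    b <- B[[nm]]
    if (inherits(a, "Date")) a <- as.numeric(a)
    if (inherits(b, "Date")) b <- as.numeric(b)
    if (is.numeric(a) && is.numeric(b)) {
      rng <- ranges[[nm]] %||% {
        r <- range(c(a, b), na.rm = TRUE)
        if (!all(is.finite(r))) c(0, 1) else r
      }
      span <- max(rng[2] - rng[1], 1e-12)
      d <- abs(outer(a, b, "-")) / span
      d <- pmin(d, 1)
    } else {
      d <- outer(as.character(a), as.character(b), "!=") * 1
    }
    na_a <- is.na(a)
    na_b <- is.na(b)
    d[na_a, ] <- 1
    d[, na_b] <- 1
    if (any(na_a) && any(na_b)) d[na_a, na_b] <- 0
    d[is.na(d)] <- 1
    acc <- acc + d
  }
  acc / length(columns)
}

# k nearest rows of pool for each row of targets; deterministic tie-break by
# record order
knn_indices <- function(targets, pool, columns, k, ranges = NULL) {
  d <- gower_dist(targets, pool, columns, ranges)
  lapply(seq_len(nrow(d)), function(i) order(d[i, ])[seq_len(k)])
}

risk_report <- function(reps) {
  risk <- mean(reps$risk, na.rm = TRUE)
  structure(list(r_main = mean(reps$r_main),
                 r_baseline = mean(reps$r_baseline),
                 r_control = mean(reps$r_control),
                 risk = risk,
                 risk_sd = stats::sd(reps$risk),
                 valid = mean(reps$r_main) > mean(reps$r_baseline),
                 n_valid_reps = sum(reps$r_main > reps$r_baseline),
                 repetitions = reps),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("risk_report: risk=%.2f (SD %.2f)%s | main=%.3f baseline=%.3f control=%.3f\n",
              x$risk, x$risk_sd, if (x$valid) "" else " [invalid]",
              x$r_main, x$r_baseline, x$r_control))
  invisible(x)
}

#' Linkage attack
#'
#' Splits the auxiliary attributes into two disjoint sets; a target is linked
#' when its k-nearest protected neighbors under set A and under set B
#' overlap. The main attack draws targets from the training records, the
#' control attack from the control set, and the baseline picks random
#' neighbor sets. The per-repetition risks are normalized with
#' [risk_score()] and averaged.
#'
#' @param protected released data.frame.
#' @param attacked_original training records used to build the release.
#' @param attacked_control independent control records.
#' @param aux_split list of two disjoint attribute-name vectors; default
#'   splits `aux_attributes` in half.
#' @param config an [attack_config()].
#' @return a `risk_report`.
#' @export
linkage <- function(protected, attacked_original, attacked_control,
                    aux_split = NULL, config) {
  aux <- intersect(config$aux_attributes, names(protected))
  if (is.null(aux_split)) {
    half <- seq_len(ceiling(length(aux) / 2))
    aux_split <- list(aux[half], aux[-half])
  }
  if (!length(aux_split[[1]]) || !length(aux_split[[2]])) {
    stop("both linkage attribute sets must be non-empty")
  }
  if (length(intersect(aux_split[[1]], aux_split[[2]]))) {
    stop("linkage attribute sets must be disjoint")
  }
  set.seed(config$seed)
  m <- config$n_targets %||% ceiling(0.2 * min(nrow(attacked_original),
                                               nrow(attacked_control)))
  ranges <- numeric_ranges(protected, aux)
  link_rate <- function(targets) {
    nnA <- knn_indices(targets, protected, aux_split[[1]], config$knn_k,
                       ranges)
    nnB <- knn_indices(targets, protected, aux_split[[2]], config$knn_k,
                       ranges)
    mean(mapply(function(a, b) length(intersect(a, b)) > 0, nnA, nnB))
  }
  reps <- do.call(rbind, lapply(seq_len(config$repetitions), function(r) {
    tm <- attacked_original[sample.int(nrow(attacked_original),
                                       min(m, nrow(attacked_original))), ,
                            drop = FALSE]
    tc <- attacked_control[sample.int(nrow(attacked_control),
                                      min(m, nrow(attacked_control))), ,
                           drop = FALSE]
    r_main <- link_rate(tm)
    r_control <- link_rate(tc)
    r_base <- mean(replicate(m, {
      length(intersect(sample.int(nrow(protected), config$knn_k),
                       sample.int(nrow(protected), config$knn_k))) > 0
    }))
    data.frame(r_main = r_main, r_baseline = r_base, r_control = r_control,
               risk = if (r_control >= 1) NA_real_ else
                 risk_score(r_main, r_control))
  }))
  risk_report(reps)
}

numeric_ranges <- function(d, columns) {
  out <- list()
  for (nm in columns) {
    v <- d[[nm]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    if (is.numeric(v) && any(!is.na(v))) out[[nm]] <- range(v, na.rm = TRUE)
  }
  out
}

# predicate helpers for singling-out -------------------------------------

match_predicate <- function(data, pred) {
  ok <- rep(TRUE, nrow(data))
  for (p in pred) {
    v <- data[[p$attr]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    val <- p$value
    if (inherits(val, "Date")) val <- as.numeric(val)
    hit <- switch(p$op,
                  "==" = as.character(v) == as.character(val),
                  "<=" = suppressWarnings(as.numeric(v) <= as.numeric(val)),
                  ">=" = suppressWarnings(as.numeric(v) >= as.numeric(val)))
    hit[is.na(hit)] <- FALSE
    ok <- ok & hit
  }
  ok
}

singles_out <- function(data, pred) sum(match_predicate(data, pred)) == 1L

random_predicate <- function(data, columns, width = 1L) {
  attrs <- sample(columns, width)
  lapply(attrs, function(nm) {
    v <- data[[nm]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    if (is.numeric(v) && length(unique(stats::na.omit(v))) > 2) {
      rng <- range(v, na.rm = TRUE)
      list(attr = nm, op = sample(c("<=", ">="), 1),
           value = stats::runif(1, rng[1], rng[2]))
    } else {
      vals <- unique(stats::na.omit(as.character(v)))
      if (!length(vals)) vals <- "<NA>"
      list(attr = nm, op = "==", value = sample(vals, 1))
    }
  })
}

#' Singling-out attack
#'
#' Predicates are generated from the released (protected) data only:
#' univariate predicates use values unique within the release plus min/max
#' thresholds; multivariate predicates are conjunctions over 2-4 attributes
#' of a randomly drawn released record. Candidates are screened to isolate
#' exactly one record in the release; a guess then succeeds when the
#' predicate also isolates exactly one record in the attacked dataset.
#' Main/baseline/control as in [linkage()]; the baseline draws uniform
#' random predicates over the observed value ranges. Because isolation
#' probability depends on the attacked set's size, pass comparably sized
#' training and control sets for an unbiased main/control comparison.
#'
#' @param protected released data.frame.
#' @param attacked_original,attacked_control attacked record sets (disjoint).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param config an [attack_config()].
#' @return a `risk_report`.
#' @export
singling_out <- function(protected, attacked_original, attacked_control,
                         mode = c("univariate", "multivariate"), config) {
  mode <- match.arg(mode)
  aux <- intersect(config$aux_attributes, names(protected))
  set.seed(config$seed)
  n_q <- if (mode == "multivariate") {
    config$n_multivariate_queries
  } else {
    config$n_targets %||%
      ceiling(0.2 * min(nrow(attacked_original), nrow(attacked_control)))
  }

  # candidate predicates single out exactly one record in the RELEASE;
  # success is then isolating exactly one record in the attacked set
  uni_pool <- list()
  if (mode == "univariate") {
    for (nm in aux) {
      v <- protected[[nm]]
      if (inherits(v, "Date")) v <- as.numeric(v)
      cnt <- table(as.character(v))
      uniq <- names(cnt)[cnt == 1L]
      for (u in uniq) {
        uni_pool[[length(uni_pool) + 1L]] <-
          list(list(attr = nm, op = "==", value = u))
      }
      if (is.numeric(v) && any(!is.na(v))) {
        for (cand in list(
          list(attr = nm, op = "<=", value = min(v, na.rm = TRUE)),
          list(attr = nm, op = ">=", value = max(v, na.rm = TRUE)))) {
          if (singles_out(protected, list(cand))) {
            uni_pool[[length(uni_pool) + 1L]] <- list(cand)
          }
        }
      }
    }
    if (length(uni_pool) < n_q) {
      warning("fewer candidate predicates (", length(uni_pool),
              ") than requested (", n_q, "); using all")
    }
  }

  multivariate_predicate <- function() {
    rec <- protected[sample.int(nrow(protected), 1), , drop = FALSE]
    width <- sample(2:4, 1)
    attrs <- sample(aux, min(width, length(aux)))
    lapply(attrs, function(nm) {
      v <- rec[[nm]]
      if (inherits(v, "Date")) v <- as.numeric(v)
      if (is.numeric(v) && !is.na(v) &&
          length(unique(stats::na.omit(as.numeric(protected[[nm]])))) > 2) {
        list(attr = nm, op = sample(c("<=", ">="), 1), value = v)
      } else {
        list(attr = nm, op = "==",
             value = if (is.na(v)) "<NA>" else as.character(v))
      }
    })
  }

  draw_predicates <- function() {
    if (mode == "univariate") {
      if (!length(uni_pool)) return(list())
      uni_pool[sample.int(length(uni_pool), min(n_q, length(uni_pool)))]
    } else {
      preds <- list()
      attempts <- 0L
      while (length(preds) < n_q && attempts < 50L * n_q) {
        attempts <- attempts + 1L
        p <- multivariate_predicate()
        if (singles_out(protected, p)) preds[[length(preds) + 1L]] <- p
      }
      preds
    }
  }

  reps <- do.call(rbind, lapply(seq_len(config$repetitions), function(r) {
    preds <- draw_predicates()
    if (!length(preds)) {
      return(data.frame(r_main = 0, r_baseline = 0, r_control = 0, risk = 0))
    }
    base_preds <- lapply(seq_along(preds), function(q)
      random_predicate(protected, aux,
                       width = if (mode == "multivariate") sample(2:4, 1)
                               else 1L))
    r_main <- mean(vapply(preds, singles_out, TRUE,
                          data = attacked_original))
    r_control <- mean(vapply(preds, singles_out, TRUE,
                             data = attacked_control))
    r_base <- mean(vapply(base_preds, singles_out, TRUE,
                          data = attacked_original))
    data.frame(r_main = r_main, r_baseline = r_base, r_control = r_control,
               risk = if (r_control >= 1) NA_real_ else
                 risk_score(r_main, r_control))
  }))
  risk_report(reps)
}

#' Attribute-inference attack
#'
#' Predicts a secret attribute of each target as the secret value of the
#' target's nearest released record on the auxiliary attributes; a
#' categorical prediction must match exactly, a numeric one within
#' `numeric_tolerance` of the attribute's range. The baseline guesses from
#' the released data's marginal distribution of the secret. The report is
#' flagged invalid when the main attack does not beat the baseline.
#'
#' @param protected released data.frame.
#' @param attacked_original,attacked_control attacked record sets.
#' @param secret_attribute the attribute to infer (must not be auxiliary).
#' @param config an [attack_config()]; `aux_attributes` minus the secret are
#'   used for matching.
#' @return a `risk_report`.
#' @export
attribute_inference <- function(protected, attacked_original,
                                attacked_control, secret_attribute, config) {
  aux <- setdiff(intersect(config$aux_attributes, names(protected)),
                 secret_attribute)
  if (!length(aux)) stop("no auxiliary attributes left for matching")
  set.seed(config$seed)
  m <- min(nrow(attacked_original), nrow(attacked_control))
  m <- min(config$n_targets %||% ceiling(0.2 * m), m)
  ranges <- numeric_ranges(protected, c(aux, secret_attribute))
  sv <- protected[[secret_attribute]]
  if (inherits(sv, "Date")) sv <- as.numeric(sv)
  numeric_secret <- is.numeric(sv) &&
    length(unique(stats::na.omit(sv))) > 2
  tol <- if (numeric_secret) {
    rng <- ranges[[secret_attribute]] %||% c(0, 1)
    config$numeric_tolerance * max(rng[2] - rng[1], 1e-12)
  } else {
    NA_real_
  }
  correct <- function(pred, truth) {
    if (inherits(truth, "Date")) truth <- as.numeric(truth)
    if (numeric_secret) {
      ok <- abs(as.numeric(pred) - as.numeric(truth)) <= tol
    } else {
      ok <- as.character(pred) == as.character(truth)
    }
    ok[is.na(ok)] <- FALSE
    ok
  }
  infer_rate <- function(targets) {
    nn <- knn_indices(targets, protected, aux, 1L, ranges)
    pred <- sv[unlist(nn)]
    truth <- targets[[secret_attribute]]
    mean(correct(pred, truth))
  }
  reps <- do.call(rbind, lapply(seq_len(config$repetitions), function(r) {
    tm <- attacked_original[sample.int(nrow(attacked_original), m), ,
                            drop = FALSE]
    tc <- attacked_control[sample.int(nrow(attacked_control), m), ,
                           drop = FALSE]
    r_main <- infer_rate(tm)
    r_control <- infer_rate(tc)
    guess <- sv[sample.int(length(sv), m, replace = TRUE)]
    r_base <- mean(correct(guess, tm[[secret_attribute]]))
    data.frame(r_main = r_main, r_baseline = r_base, r_control = r_control,
               risk = if (r_control >= 1) NA_real_ else
                 risk_score(r_main, r_control))
  }))
  risk_report(reps)
}
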