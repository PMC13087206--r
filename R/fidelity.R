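#' Min-max normalize a table against a reference
#'
#' All numeric-codable columns (binary flags included, dates as days) are
#' scaled with the reference min/max; missing values are imputed with the
#' reference column median before scaling, so a fully suppressed column in
#' the protected data becomes a constant at the scaled reference median.
#' Constant reference columns map to 0.5.
#'
#' @param table data.frame to normalize.
#' @param reference data.frame defining per-column min / max / median.
#' @param columns columns to use; defaults to all columns of `reference`
#'   that are numeric, logical, binary or dates.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
impute_and_normalize <- function(table, reference, columns = NULL) {
  as_num <- function(v) {
    if (inherits(v, "Date")) return(as.numeric(v))
    if (is.logical(v)) return(as.numeric(v))
    if (is.numeric(v)) return(as.numeric(v))
    NULL
  }
  if (is.null(columns)) {
    columns <- names(reference)[!vapply(lapply(reference, as_num), is.null,
                                        TRUE)]
  }
  missing <- setdiff(columns, names(table))
  if (length(missing)) stop("column absent from table: ",
                            paste(missing, collapse = ", "))
  out <- matrix(NA_real_, nrow(table), length(columns),
                dimnames = list(NULL, columns))
  for (nm in columns) {
    ref <- as_num(reference[[nm]])
    if (is.null(ref)) stop("column ", nm, " is not numeric-codable")
    v <- as_num(table[[nm]])
    if (is.null(v)) v <- rep(NA_real_, nrow(table))
    med <- stats::median(ref, na.rm = TRUE)
    if (is.na(med)) med <- 0
    v[is.na(v)] <- med
    lo <- suppressWarnings(min(ref, na.rm = TRUE))
    hi <- suppressWarnings(max(ref, na.rm = TRUE))
    out[, nm] <- if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
      rep(0.5, nrow(table))
    } else {
      pmin(pmax((v - lo) / (hi - lo), 0), 1)
    }
  }
  out
}

#' Normalized prevalence of binary flags by treatment group
#'
#' Within each treatment group, the prevalence of every binary flag is
#' computed on the within-dataset relative distribution; the protected value
#' is expressed as a percentage of the original value (baseline 100). Flags
#' suppressed in the protected data (all missing) are flagged and excluded
#' from the group-level mean absolute deviation, as are flags with original
#' prevalence 0.
#'
#' @param original,protected data.frames sharing the flag and group columns.
#' @param group_column treatment-group column name.
#' @param flags binary flag columns (default: all shared 0/1 columns).
#' @return list with `table` (per flag and group: original and protected
#'   prevalence, normalized value, status) and `mean_deviation` per group
#'   (mean of `|normalized - 100| / 100` over usable flags).
#' @export
normalized_prevalence <- function(original, protected, group_column,
                                  flags = NULL) {
  if (is.null(flags)) {
    is_flag <- function(v) (is.numeric(v) || is.logical(v)) &&
      all(is.na(v) | v %in% c(0, 1))
    flags <- intersect(names(original)[vapply(original, is_flag, TRUE)],
                       names(protected))
  }
  groups <- sort(unique(stats::na.omit(original[[group_column]])))
  rows <- list()
  for (g in groups) {
    og <- original[original[[group_column]] %in% g, , drop = FALSE]
    pg <- protected[protected[[group_column]] %in% g, , drop = FALSE]
    for (f in flags) {
      p_orig <- mean(og[[f]], na.rm = TRUE)
      pv <- pg[[f]]
      suppressed <- all(is.na(pv)) || nrow(pg) == 0
      p_prot <- if (suppressed) NA_real_ else mean(pv, na.rm = TRUE)
      status <- if (suppressed) "suppressed"
                else if (is.nan(p_orig) || p_orig == 0) "undefined"
                else "ok"
      norm <- if (status == "ok") 100 * (p_prot / p_orig) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, flag = f, p_original = p_orig, p_protected = p_prot,
        normalized = norm, status = status, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  dev <- vapply(groups, function(g) {
    ok <- tab$group == g & tab$status == "ok"
    if (!any(ok)) return(NA_real_)
    mean(abs(tab$normalized[ok] - 100) / 100)
  }, 0)
  list(table = tab, mean_deviation = stats::setNames(dev, groups))
}

#' Correlation distance between two datasets
#'
#' Pairwise Pearson correlations over all numeric-codable attributes (binary
#' flags enter as 0/1, equivalent to point-biserial correlation); the scalar
#' distance is the mean over defined off-diagonal pairs of the absolute
#' difference between the two correlation matrices. Pairs undefined in either
#' dataset (zero variance or suppressed columns) are excluded and reported.
#'
#' @param original,protected data.frames.
#' @param columns columns to correlate; defaults to shared numeric-codable
#'   columns.
#' @return list with `distance`, correlation matrices `rho_original` /
#'   `rho_protected`, and `undefined_pairs` (count excluded).
#' @export
correlation_distance <- function(original, protected, columns = NULL) {
  num_cols <- function(d) {
    names(d)[vapply(d, function(v)
      is.numeric(v) || is.logical(v) || inherits(v, "Date"), TRUE)]
  }
  if (is.null(columns)) {
    columns <- intersect(num_cols(original), num_cols(protected))
  }
  if (length(columns) < 2) stop("need at least two usable attributes")
  to_mat <- function(d) {
    m <- sapply(columns, function(nm) as.numeric(d[[nm]]))
    matrix(m, ncol = length(columns), dimnames = list(NULL, columns))
  }
  r1 <- suppressWarnings(stats::cor(to_mat(original),
                                    use = "pairwise.complete.obs"))
  r2 <- suppressWarnings(stats::cor(to_mat(protected),
                                    use = "pairwise.complete.obs"))
  diff <- abs(r1 - r2)
  off <- upper.tri(diff)
  defined <- off & !is.na(diff)
  list(distance = mean(diff[defined]),
       rho_original = r1, rho_protected = r2,
       undefined_pairs = sum(off & is.na(diff)))
}

#' Integrated alpha-precision, beta-recall and authenticity
#'
#' Multivariate similarity in min-max normalized space (reference = the
#' original data; missing values imputed with the original column medians).
#' The alpha-support of a dataset is estimated by distance-from-center
#' quantile balls: the alpha-precision curve is the fraction of protected
#' records within the original's alpha-ball, the beta-recall curve swaps the
#' roles. Both curves are integrated against the identity on a 20-point
#' level grid (trapezoid rule), `1 - 2 * integral(|curve - level|)`, so a
#' distribution-matched release scores near 1 and a disjoint release near 0.
#' Authenticity is the fraction of protected records whose nearest original
#' neighbor is farther away than that original record's own nearest neighbor
#' within the original data; an exact copy scores 0.
#'
#' @param original,protected data.frames with at least 10 records each.
#' @param columns numeric-codable columns (defaults as in
#'   [impute_and_normalize()]).
#' @param grid_points number of integration levels.
#' @return list with `ip_alpha`, `ir_beta`, `authenticity` and the two
#'   curves.
#' @export
precision_recall_authenticity <- function(original, protected,
                                          columns = NULL, grid_points = 20L) {
  if (nrow(original) < 10 || nrow(protected) < 10) {
    stop("need at least 10 records in each dataset")
  }
  X <- impute_and_normalize(original, original, columns)
  Y <- impute_and_normalize(protected, original, colnames(X))
  if (all(apply(X, 2, stats::var) == 0)) {
    stop("all-constant data: support metrics undefined")
  }
  levels <- seq(0, 1, length.out = grid_points + 1L)[-1]

  curve <- function(A, B) {
    # fraction of B inside the level-ball of A (center = mean of A)
    ctr <- colMeans(A)
    dA <- sqrt(rowSums(sweep(A, 2, ctr)^2))
    dB <- sqrt(rowSums(sweep(B, 2, ctr)^2))
    vapply(levels, function(a)
      mean(dB <= stats::quantile(dA, a, names = FALSE) + 1e-12), 0)
  }
  integrate_dev <- function(cv) {
    xs <- c(0, levels)
    ys <- abs(c(0, cv) - xs)
    area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
    max(0, min(1, 1 - 2 * area))
  }
  p_curve <- curve(X, Y)
  r_curve <- curve(Y, X)

  # authenticity via exact nearest neighbors
  dXY <- cross_dist(Y, X)            # protected x original
  nn_idx <- apply(dXY, 1, which.min)
  d1 <- dXY[cbind(seq_len(nrow(Y)), nn_idx)]
  dXX <- cross_dist(X, X)
  diag(dXX) <- Inf
  d_self <- apply(dXX, 1, min)
  authentic <- d1 > d_self[nn_idx]

  list(ip_alpha = integrate_dev(p_curve),
       ir_beta = integrate_dev(r_curve),
       authenticity = mean(authentic),
       precision_curve = p_curve, recall_curve = r_curve, levels = levels)
}

# Euclidean cross-distance matrix (rows of A x rows of B)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Full fidelity report for a protected dataset
#'
#' Bundles [normalized_prevalence()], [correlation_distance()] and
#' [precision_recall_authenticity()] against the original.
#'
#' @param original,protected data.frames.
#' @param group_column treatment-group column.
#' @return a `fidelity_report` list.
#' @export
fidelity_report <- function(original, protected, group_column) {
  np <- normalized_prevalence(original, protected, group_column)
  cd <- correlation_distance(original, protected)
  pra <- precision_recall_authenticity(original, protected)
  structure(list(normalized_prevalence = np,
                 correlation_distance = cd$distance,
                 undefined_correlation_pairs = cd$undefined_pairs,
                 ip_alpha = pra$ip_alpha, ir_beta = pra$ir_beta,
                 authenticity = pra$authenticity),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("fidelity_report: corr distance=", round(x$correlation_distance, 4),
      " IPa=", round(x$ip_alpha, 4), " IRb=", round(x$ir_beta, 4),
      " authenticity=", round(x$authenticity, 4), "\n", sep = "")
  invisible(x)
}
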