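#' Unit-weighted composite scores for each construct
#'
#' Reverse-keyed items are un-reversed (`6 - response`) before averaging.
#'
#' @param survey a `survey_dataset`.
#' @param constructs which constructs to score (default: all in the map).
#' @return numeric matrix, one column per construct.
#' @export
composite_scores <- function(survey, constructs = NULL) {
  map <- survey$construct_map
  constructs <- constructs %||% unique(map$construct)
  out <- vapply(constructs, function(cnm) {
    rows <- map[map$construct == cnm, , drop = FALSE]
    if (nrow(rows) == 0) stop2("no items mapped to construct ", cnm)
    X <- as.matrix(survey$responses[rows$item])
    X[, rows$reverse] <- 6 - X[, rows$reverse, drop = FALSE]
    rowMeans(X)
  }, numeric(nrow(survey$responses)))
  colnames(out) <- constructs
  out
}

#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_T^2} is
#' the variance of the row sums. Computed on raw covariances by default; set
#' `standardized = TRUE` to compute it on the item correlation matrix.
#'
#' @param items n x k numeric matrix or data.frame (k >= 2 items, n >= 3).
#' @param standardized use the standardized (correlation-based) form.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items, standardized = FALSE) {
  X <- as.matrix(items)
  k <- ncol(X)
  if (k < 2) stop2("alpha needs at least 2 items")
  if (nrow(X) < 3) stop2("alpha needs at least 3 observations")
  if (standardized) X <- scale(X)
  vtot <- stats::var(rowSums(X))
  if (vtot <= .Machine$double.eps) stop2("zero total variance")
  (k / (k - 1)) * (1 - sum(apply(X, 2, stats::var)) / vtot)
}

#' Composite reliability and average variance extracted
#'
#' From standardized loadings \eqn{\lambda}: \eqn{AVE = mean(\lambda^2)} and
#' \eqn{CR = (\sum\lambda)^2 / ((\sum\lambda)^2 + \sum(1-\lambda^2))}.
#'
#' @param loadings vector of standardized loadings in (0, 1].
#' @return list with `CR` and `AVE`.
#' @export
composite_stats <- function(loadings) {
  if (length(loadings) == 0) stop2("empty loading vector")
  if (any(loadings <= 0 | loadings > 1)) stop2("loadings must lie in (0, 1]")
  s <- sum(loadings)
  list(CR = s^2 / (s^2 + sum(1 - loadings^2)), AVE = mean(loadings^2))
}

#' Fornell-Larcker discriminant-validity report
#'
#' Replaces the diagonal of the construct correlation matrix with
#' \eqn{\sqrt{AVE}}; a construct pair passes when both diagonal entries
#' exceed the absolute off-diagonal correlation.
#'
#' @param R construct correlation matrix (named).
#' @param ave named vector of AVE values, one per construct in `R`.
#' @return object of class `discriminant_report`: list with `matrix` (the
#'   Fornell-Larcker matrix), `pairs` (data.frame of pairwise verdicts) and
#'   `pass` (overall flag).
#' @export
fornell_larcker <- function(R, ave) {
  R <- as.matrix(R)
  if (nrow(R) != length(ave)) stop2("dimension mismatch between R and ave")
  cn <- colnames(R) %||% names(ave) %||% paste0("C", seq_along(ave))
  if (!is.null(names(ave))) ave <- ave[cn]
  M <- R
  diag(M) <- sqrt(ave)
  dimnames(M) <- list(cn, cn)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  pairs <- data.frame(
    a = cn[idx[, 1]], b = cn[idx[, 2]],
    correlation = R[idx],
    sqrt_ave_a = sqrt(ave)[idx[, 1]], sqrt_ave_b = sqrt(ave)[idx[, 2]]
  )
  pairs$pass <- pairs$sqrt_ave_a > abs(pairs$correlation) &
    pairs$sqrt_ave_b > abs(pairs$correlation)
  structure(list(matrix = M, pairs = pairs, pass = all(pairs$pass)),
            class = "discriminant_report")
}

#' @export
print.discriminant_report <- function(x, ...) {
  cat("Fornell-Larcker criterion:", if (x$pass) "all pairs pass"
      else paste(sum(!x$pairs$pass), "pair(s) fail"), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Harman's single-factor test
#'
#' Share of total variance captured by the first principal component of the
#' item correlation matrix (the largest eigenvalue over the number of items,
#' as a percentage). Reverse-keyed items are un-reversed first.
#'
#' @param survey a `survey_dataset` or a numeric item matrix.
#' @return variance share in percent.
#' @export
harman_single_factor <- function(survey) {
  X <- if (inherits(survey, "survey_dataset")) {
    map <- survey$construct_map
    M <- as.matrix(survey$responses[map$item])
    M[, map$reverse] <- 6 - M[, map$reverse, drop = FALSE]
    M
  } else as.matrix(survey)
  if (ncol(X) < 2) stop2("need at least 2 items")
  R <- suppressWarnings(stats::cor(X))
  if (anyNA(R)) stop2("singular input: constant item(s)")
  max(eigen(R, symmetric = TRUE, only.values = TRUE)$values) / ncol(X) * 100
}

#' Marker-variable check for common method bias
#'
#' Maximum absolute correlation between the marker construct's composite and
#' each focal construct's composite, with a pass/fail verdict against a
#' conventional cutoff.
#'
#' @param survey a `survey_dataset`.
#' @param marker name of the marker construct (default `"MK"`).
#' @param cutoff verdict threshold (default 0.15).
#' @return list with `correlations`, `max_abs_r`, `cutoff`, `pass`.
#' @export
marker_check <- function(survey, marker = "MK", cutoff = 0.15) {
  map <- survey$construct_map
  if (!marker %in% map$construct) stop2("marker construct not present: ", marker)
  comp <- composite_scores(survey)
  focal <- setdiff(colnames(comp), marker)
  r <- drop(stats::cor(comp[, marker], comp[, focal]))
  names(r) <- focal
  list(correlations = r, max_abs_r = max(abs(r)), cutoff = cutoff,
       pass = max(abs(r)) < cutoff)
}

#' Reliability and convergent-validity report
#'
#' Per construct: Cronbach's alpha, composite reliability (CR), average
#' variance extracted (AVE) and the item count. CR and AVE are computed from
#' estimated standardized loadings; by default these are estimated from the
#' item correlation matrix as the loading vector of a one-factor model
#' (square root of the mean inter-item correlation under essential
#' tau-equivalence, per-item refined by the centroid ratio).
#'
#' @param survey a `survey_dataset`.
#' @param constructs constructs to report on (default: all non-marker).
#' @return data.frame with one row per construct.
#' @export
reliability_report <- function(survey, constructs = NULL) {
  map <- survey$construct_map
  constructs <- constructs %||% unique(map$construct)
  rows <- lapply(constructs, function(cnm) {
    its <- map[map$construct == cnm, , drop = FALSE]
    X <- as.matrix(survey$responses[its$item])
    X[, its$reverse] <- 6 - X[, its$reverse, drop = FALSE]
    lam <- estimate_loadings(X)
    cs <- composite_stats(pmin(lam, 1))
    data.frame(construct = cnm, items = ncol(X),
               alpha = cronbach_alpha(X), CR = cs$CR, AVE = cs$AVE)
  })
  do.call(rbind, rows)
}

# One-factor standardized loadings from an item correlation matrix via the
# centroid method: lambda_i = cov(x_i, total-minus-i) scaled consistently;
# exact for a single common factor, robust for k = 2.
estimate_loadings <- function(X) {
  R <- stats::cor(X)
  k <- ncol(R)
  if (k == 2) return(rep(sqrt(abs(R[1, 2])), 2))
  lam <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    ro <- R[others, others]
    # lambda_i^2 = r_ij * r_il / r_jl averaged over pairs (j, l) != i
    pr <- which(upper.tri(ro), arr.ind = TRUE)
    vals <- R[i, others[pr[, 1]]] * R[i, others[pr[, 2]]] /
      ro[upper.tri(ro)]
    sqrt(max(mean(vals), 0))
  }, 0)
  pmin(lam, 0.999)
}

#' Full measurement-model assessment
#'
#' Bundles the reliability report, the Fornell-Larcker analysis on composite
#' correlations, Harman's single-factor share, and (when a marker construct
#' is present) the marker-variable check. The discriminant matrix is labelled
#' as computed on unit-weighted composite correlations.
#'
#' @param survey a `survey_dataset`.
#' @param marker marker construct name, or `NULL` to skip.
#' @return list with `reliability`, `discriminant`, `harman_share`,
#'   `marker`, `correlation_kind`.
#' @export
assess_measurement <- function(survey, marker = if ("MK" %in%
                               survey$construct_map$construct) "MK" else NULL) {
  focal <- setdiff(unique(survey$construct_map$construct), marker)
  rel <- reliability_report(survey, focal)
  comp <- composite_scores(survey, focal)
  R <- stats::cor(comp)
  disc <- fornell_larcker(R, stats::setNames(rel$AVE, rel$construct))
  list(reliability = rel,
       discriminant = disc,
       harman_share = harman_single_factor(survey),
       marker = if (!is.null(marker)) marker_check(survey, marker),
       correlation_kind = "unit-weighted composite correlations")
}
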