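#' R-squared of a predictor subset from a correlation matrix
#'
#' \eqn{R^2(S) = r_{yS}' R_{SS}^{-1} r_{yS}}, the explained variance of a
#' standardized least-squares regression; the empty subset gives 0.
#'
#' @param R correlation matrix including the outcome.
#' @param outcome outcome name (or index).
#' @param subset character vector of predictor names (possibly empty).
#' @param ridge diagonal loading used only if `R_SS` is singular (a warning
#'   is raised).
#' @return scalar R-squared.
#' @export
r2_from_corr <- function(R, outcome, subset, ridge = 1e-10) {
  if (length(subset) == 0) return(0)
  Rss <- R[subset, subset, drop = FALSE]
  rys <- R[subset, outcome]
  b <- tryCatch(solve(Rss, rys), error = function(e) {
    warning("singular predictor block; applying ridge fallback", call. = FALSE)
    solve(Rss + diag(ridge, nrow(Rss)), rys)
  })
  drop(crossprod(rys, b))
}

#' LMG (Shapley) decomposition of explained variance
#'
#' Decomposes the full-model \eqn{R^2} over predictors by averaging each
#' predictor's incremental \eqn{R^2} over all orderings, computed exactly by
#' the subset-weight formula
#' \deqn{LMG(x) = \sum_{S \subseteq P \setminus x} \frac{|S|!\,(k-|S|-1)!}{k!}
#'   (R^2(S \cup x) - R^2(S)).}
#'
#' @param x either a correlation matrix (with named rows/columns) or a
#'   numeric data matrix / data.frame of raw scores (columns = variables),
#'   or a `survey_dataset` (composites are used).
#' @param outcome outcome variable name.
#' @param predictors character vector of predictor names (at most 12 for
#'   exact enumeration).
#' @return object of class `importance_decomposition`: data.frame with the
#'   per-predictor LMG value (R-squared units) and percentage share, plus
#'   attributes `r_squared` (total) and `outcome`.
#' @export
lmg <- function(x, outcome, predictors) {
  if (inherits(x, "survey_dataset")) x <- composite_scores(x)
  x <- as.matrix(x)
  R <- if (nrow(x) == ncol(x) &&
           isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-8)) &&
           all(abs(diag(x) - 1) < 1e-8)) x else stats::cor(x)
  k <- length(predictors)
  if (k < 1) stop2("need at least one predictor")
  if (k > 12) stop2("exact LMG enumeration supports at most 12 predictors")
  if (!all(c(outcome, predictors) %in% colnames(R)))
    stop2("outcome/predictors missing from the correlation matrix")

  # R^2 for every subset of predictors, indexed by bitmask
  nsub <- 2^k
  r2 <- numeric(nsub)
  for (m in seq_len(nsub - 1)) {
    S <- predictors[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    r2[m + 1] <- r2_from_corr(R, outcome, S)
  }
  wts <- factorial(0:(k - 1)) * factorial(k - 1 - 0:(k - 1)) / factorial(k)
  vals <- vapply(seq_len(k), function(i) {
    bit <- 2^(i - 1)
    others <- seq_len(nsub) - 1
    others <- others[bitwAnd(others, bit) == 0]
    sizes <- vapply(others, function(m) sum(bitwAnd(m, 2^(seq_len(k) - 1)) > 0), 0)
    sum(wts[sizes + 1] * (r2[others + bit + 1] - r2[others + 1]))
  }, 0)
  total <- r2[nsub]
  out <- data.frame(predictor = predictors, lmg = vals,
                    share = if (total > 0) vals / total * 100 else NA_real_)
  attr(out, "r_squared") <- total
  attr(out, "outcome") <- outcome
  class(out) <- c("importance_decomposition", "data.frame")
  out
}

#' @export
print.importance_decomposition <- function(x, ...) {
  cat("LMG decomposition of R^2 =", round(attr(x, "r_squared"), 4),
      "for outcome", attr(x, "outcome"), "\n")
  print.data.frame(cbind(x[1], lmg = round(x$lmg, 4),
                         share = round(x$share, 1)), row.names = FALSE)
  invisible(x)
}
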