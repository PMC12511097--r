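# Maximum-likelihood estimation for covariance-structure models.
#
# Discrepancy: F_ML = log|Sigma(theta)| - log|S| + tr(S Sigma^-1) - p
#              (+ (xbar - mu)' Sigma^-1 (xbar - mu) with mean structure),
# chi-square = (n - 1) * F_ML. Variances are log-parameterized during
# optimization so they stay positive by construction; gradients are analytic.

# Assemble the model matrices at a named natural-scale parameter vector.
fill_matrices <- function(mod, est) {
  L <- mod$Lambda$value; Bm <- mod$B$value; P <- mod$Psi$value
  Tv <- mod$Theta$value[, 1]
  for (r in seq_len(nrow(mod$params))) {
    pr <- mod$params[r, ]
    v <- est[[pr$label]]
    switch(pr$matrix,
      Lambda = { L[pr$row, pr$col] <- v },
      B      = { Bm[pr$row, pr$col] <- v },
      Psi    = { P[pr$row, pr$col] <- v; P[pr$col, pr$row] <- v },
      Theta  = { Tv[pr$row] <- v })
  }
  out <- list(Lambda = L, B = Bm, Psi = P, Theta = Tv)
  if (mod$meanstructure) {
    nu <- mod$nu$value; al <- mod$alpha$value
    for (r in which(mod$params$matrix == "nu"))
      nu[mod$params$row[r]] <- est[[mod$params$label[r]]]
    for (r in which(mod$params$matrix == "alpha"))
      al[mod$params$row[r]] <- est[[mod$params$label[r]]]
    out$nu <- nu; out$alpha <- al
  }
  out
}

#' Model-implied moments
#'
#' Assembles \eqn{\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T}
#' \Lambda' + \Theta} (and \eqn{\mu(\theta) = \nu + \Lambda (I-B)^{-1}
#' \alpha} when the model carries a mean structure).
#'
#' @param mod a compiled `sem_model`.
#' @param est named vector/list of natural-scale parameter values, one per
#'   free-parameter label.
#' @return list with `Sigma`, `mu` (or NULL), and the latent covariance `V`.
#' @export
implied_moments <- function(mod, est) {
  M <- fill_matrices(mod, est)
  m <- length(mod$latents)
  IB <- diag(m) - M$B
  C <- tryCatch(solve(IB), error = function(e)
    stop2("singular (I - B): structural system not invertible"))
  V <- C %*% M$Psi %*% t(C)
  Sigma <- M$Lambda %*% V %*% t(M$Lambda) + diag(M$Theta, length(M$Theta))
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(mod$indicators, mod$indicators)
  mu <- NULL
  if (mod$meanstructure) {
    mu <- as.vector(M$nu + M$Lambda %*% (C %*% M$alpha))
    names(mu) <- mod$indicators
  }
  list(Sigma = Sigma, mu = mu, V = V, mats = M, C = C)
}

# natural <-> optimizer scale (variances on the log scale)
to_opt <- function(mod, est) {
  lab <- free_params(mod)
  isv <- vapply(lab, function(l)
    mod$params$variance[match(l, mod$params$label)], NA)
  x <- unlist(est[lab])
  x[isv] <- log(pmax(x[isv], 1e-10))
  stats::setNames(x, lab)
}
from_opt <- function(mod, x) {
  lab <- free_params(mod)
  isv <- vapply(lab, function(l)
    mod$params$variance[match(l, mod$params$label)], NA)
  est <- x
  est[isv] <- exp(x[isv])
  as.list(stats::setNames(est, lab))
}

# F_ML and its analytic natural-scale gradient at `est`.
sem_objective <- function(mod, est, S, xbar = NULL, logdetS, gradient = TRUE) {
  im <- tryCatch(implied_moments(mod, est), error = function(e) NULL)
  p <- length(mod$indicators)
  bad <- list(F = 1e12, grad = NULL)
  if (is.null(im)) return(bad)
  ch <- tryCatch(chol(im$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(bad)
  Sinv <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  Fv <- logdet - logdetS + sum(Sinv * S) - p
  r <- NULL
  if (mod$meanstructure) {
    r <- xbar - im$mu
    Fv <- Fv + drop(crossprod(r, Sinv %*% r))
  }
  if (!gradient) return(list(F = Fv, grad = NULL, im = im))

  M <- im$mats; C <- im$C; V <- im$V; L <- M$Lambda
  SS <- if (is.null(r)) S else S + tcrossprod(r)
  G <- Sinv - Sinv %*% SS %*% Sinv
  GL <- G %*% L
  Mm <- crossprod(L, GL)            # Lambda' G Lambda
  H <- crossprod(C, Mm %*% C)       # C' M C
  GLV <- GL %*% V
  VMC <- V %*% Mm %*% C
  gm <- if (is.null(r)) NULL else -2 * (Sinv %*% r)
  Ca <- if (mod$meanstructure) drop(C %*% M$alpha) else NULL
  gLC <- if (is.null(gm)) NULL else drop(crossprod(gm, L %*% C))

  gr <- numeric(nrow(mod$params))
  for (k in seq_len(nrow(mod$params))) {
    pr <- mod$params[k, ]
    i <- pr$row; j <- pr$col
    gr[k] <- switch(pr$matrix,
      Lambda = 2 * GLV[i, j] +
        if (mod$meanstructure) gm[i] * Ca[j] else 0,
      B = 2 * VMC[j, i] +
        if (mod$meanstructure) gLC[i] * Ca[j] else 0,
      Psi = if (i == j) H[i, i] else H[i, j] + H[j, i],
      Theta = G[i, i],
      nu = gm[i],
      alpha = gLC[i])
    gr[k]
  }
  lab <- free_params(mod)
  grad <- vapply(lab, function(l) sum(gr[mod$params$label == l]), 0)
  list(F = Fv, grad = grad, im = im)
}

default_start <- function(mod, S) {
  est <- list()
  sdS <- sqrt(diag(S))
  scale_ind <- vapply(mod$latents, function(l) {
    terms <- vapply(mod$measurement[[l]], function(t) parse_term(t)$var, "")
    fx <- mod$Lambda$value[terms, l]
    free <- mod$Lambda$free[terms, l]
    sc <- terms[!free & fx != 0]
    if (length(sc)) sc[1] else terms[1]
  }, "")
  for (r in seq_len(nrow(mod$params))) {
    pr <- mod$params[r, ]
    est[[pr$label]] <- switch(pr$matrix,
      Lambda = {
        ind <- mod$indicators[pr$row]; lat <- mod$latents[pr$col]
        sdS[ind] / sdS[scale_ind[lat]]
      },
      B = 0,
      Psi = if (pr$row == pr$col) {
        lat <- mod$latents[pr$row]
        if (mod$Lambda$free[scale_ind[lat], lat]) 1  # std_lv-style free scale
        else 0.5 * S[scale_ind[lat], scale_ind[lat]]
      } else 0,
      Theta = 0.5 * S[pr$row, pr$row],
      nu = 0, alpha = 0)
  }
  est
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance matrix (and
#' mean vector, when the model has a mean structure) and the model-implied
#' moments, using quasi-Newton optimization with analytic gradients and
#' log-parameterized variances. Optional random multi-starts guard against
#' local minima.
#'
#' @param data numeric matrix/data.frame of indicator scores (used to form
#'   `S`, `xbar` and `n`), or NULL if `S` and `n` are given.
#' @param model a `sem_model` or model-description text.
#' @param S sample covariance matrix (ignored when `data` given).
#' @param n sample size.
#' @param xbar sample means (needed with mean structure when `data` absent).
#' @param start optional named list of natural-scale starting values.
#' @param n_starts number of optimization starts (first from `start`/
#'   defaults, the rest randomly perturbed).
#' @param se compute standard errors from the numeric Hessian of the
#'   analytic gradient (set FALSE to save time in simulations).
#' @param control passed to [stats::nlminb()].
#' @return an object of class `sem_fit`.
#' @export
fit_ml <- function(data = NULL, model, S = NULL, n = NULL, xbar = NULL,
                   start = NULL, n_starts = 1, se = TRUE,
                   control = list(iter.max = 1000, eval.max = 2000)) {
  mod <- if (inherits(model, "sem_model")) model else compile_model(model)
  if (!is.null(data)) {
    X <- as.matrix(data[, mod$indicators, drop = FALSE])
    n <- nrow(X)
    S <- stats::cov(X)
    xbar <- colMeans(X)
  }
  if (is.null(S) || is.null(n)) stop2("supply either data or S and n")
  S <- (S + t(S)) / 2
  p <- length(mod$indicators)
  if (!all(mod$indicators %in% colnames(S)))
    stop2("S lacks indicators: ",
          paste(setdiff(mod$indicators, colnames(S)), collapse = ", "))
  S <- S[mod$indicators, mod$indicators]
  if (mod$meanstructure) {
    if (is.null(xbar)) stop2("mean structure requires xbar (or raw data)")
    xbar <- xbar[mod$indicators]
  } else xbar <- NULL
  chS <- tryCatch(chol(S), error = function(e)
    stop2("sample covariance matrix is not positive definite"))
  if (n <= p) stop2("n must exceed the number of indicators")
  logdetS <- 2 * sum(log(diag(chS)))
  if (model_df(mod) < 0) stop2("model has negative degrees of freedom")

  est0 <- start %||% default_start(mod, S)
  if (mod$meanstructure && !is.null(xbar))
    for (r in which(mod$params$matrix == "nu"))
      est0[[mod$params$label[r]]] <- xbar[mod$params$row[r]]
  x0 <- to_opt(mod, est0)

  obj <- function(x) sem_objective(mod, from_opt(mod, x), S, xbar, logdetS,
                                   gradient = FALSE)$F
  grd <- function(x) {
    est <- from_opt(mod, x)
    o <- sem_objective(mod, est, S, xbar, logdetS)
    if (is.null(o$grad)) return(rep(0, length(x)))
    g <- o$grad
    lab <- names(g)
    isv <- vapply(lab, function(l)
      mod$params$variance[match(l, mod$params$label)], NA)
    g[isv] <- g[isv] * unlist(est[lab[isv]])   # chain rule for log-variances
    g
  }

  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    xs <- if (s == 1) x0 else x0 + stats::rnorm(length(x0), 0, 0.3)
    res <- tryCatch(stats::nlminb(xs, obj, gradient = grd, control = control),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop2("optimization failed in all starts")
  est <- from_opt(mod, best$par)
  gnorm <- max(abs(grd(best$par)))
  conv <- best$convergence == 0 || gnorm < 1e-5
  Fv <- max(best$objective, 0)
  im <- implied_moments(mod, est)

  fit <- structure(list(
    model = mod, est = est, F_ml = Fv,
    chisq = (n - 1) * Fv, df = model_df(mod), n = n,
    S = S, xbar = xbar, Sigma = im$Sigma, mu = im$mu, V = im$V,
    converged = conv, grad_norm = gnorm, se = NULL
  ), class = "sem_fit")
  if (!conv)
    warning("fit did not converge (max |grad| = ",
            format(gnorm, digits = 3), ")", call. = FALSE)
  if (se) fit <- add_se(fit, S, xbar, logdetS)
  fit$standardized <- standardize(fit)
  fit
}

# Standard errors from the numeric Hessian (central differences of the
# analytic natural-scale gradient) of (n-1)/2 * F_ML.
add_se <- function(fit, S, xbar, logdetS) {
  mod <- fit$model
  lab <- free_params(mod)
  x <- unlist(fit$est[lab])
  k <- length(x)
  Hn <- matrix(0, k, k)
  h <- pmax(abs(x), 0.05) * 1e-4
  gfun <- function(xx) {
    o <- sem_objective(mod, as.list(stats::setNames(xx, lab)), S, xbar,
                       logdetS)
    o$grad %||% rep(NA_real_, k)
  }
  for (j in seq_len(k)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]; xm[j] <- x[j] - h[j]
    Hn[, j] <- (gfun(xp) - gfun(xm)) / (2 * h[j])
  }
  Hn <- (Hn + t(Hn)) / 2 * (fit$n - 1) / 2
  V <- tryCatch(solve(Hn), error = function(e) {
    warning("Hessian singular; SEs unavailable", call. = FALSE)
    NULL
  })
  if (!is.null(V)) {
    sev <- sqrt(pmax(diag(V), 0))
    fit$se <- stats::setNames(sev, lab)
    fit$vcov <- V
  }
  fit
}

#' Standardized solution and R-squared of a fitted model
#'
#' Rescales loadings and structural coefficients by the implied latent and
#' indicator standard deviations; reports \eqn{R^2 = 1 - \psi_{jj}/V_{jj}}
#' for every endogenous latent. Near-zero variance estimates are flagged as
#' Heywood-boundary cases.
#'
#' @param fit a `sem_fit`.
#' @return list with `loadings`, `paths` (data.frame with std estimates),
#'   `r_squared` (named vector), `heywood` (logical flag).
#' @export
standardize <- function(fit) {
  mod <- fit$model
  im <- implied_moments(mod, fit$est)
  d <- sqrt(pmax(diag(im$V), 1e-12))
  names(d) <- mod$latents
  sdx <- sqrt(diag(im$Sigma))
  M <- im$mats
  ld <- which(mod$Lambda$free | mod$Lambda$value != 0, arr.ind = TRUE)
  loadings <- data.frame(
    indicator = mod$indicators[ld[, 1]], latent = mod$latents[ld[, 2]],
    est = M$Lambda[ld], std = M$Lambda[ld] * d[ld[, 2]] / sdx[ld[, 1]])
  bd <- which(mod$B$free | mod$B$value != 0, arr.ind = TRUE)
  paths <- data.frame(
    to = mod$latents[bd[, 1]], from = mod$latents[bd[, 2]],
    est = M$B[bd], std = M$B[bd] * d[bd[, 2]] / d[bd[, 1]])
  if (!is.null(fit$se) && nrow(paths) > 0) {
    lb <- paste0(paths$to, "~", paths$from)
    paths$se <- unname(fit$se[lb])
    paths$t <- paths$est / paths$se
  }
  endo <- setdiff(mod$latents, mod$exogenous)
  r2 <- vapply(endo, function(l) 1 - M$Psi[l, l] / im$V[l, l], 0)
  heywood <- any(M$Theta < 1e-6 & mod$Theta$free[, 1]) ||
    any(diag(M$Psi)[mod$Psi$free[cbind(seq_along(d), seq_along(d))]] < 1e-6)
  list(loadings = loadings, paths = paths, r_squared = r2, heywood = heywood)
}

#' Fit indices against the independence baseline
#'
#' CFI, TLI, RMSEA and SRMR with the conventional definitions; the baseline
#' is the independence model (free variances, free means when applicable) on
#' the same sample moments.
#'
#' @param fit a `sem_fit` (or a list with `chisq`, `df`, `n`, `S`, `Sigma`).
#' @param baseline optional list with `chisq` and `df` overriding the
#'   independence baseline (e.g. from a pooled multi-group fit).
#' @return named list: `chisq`, `df`, `cfi`, `tli`, `rmsea`, `srmr`,
#'   `baseline_chisq`, `baseline_df`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  chi <- fit$chisq; df <- fit$df; n <- fit$n
  if (is.null(baseline)) {
    p <- nrow(fit$S)
    Fb <- sum(log(diag(fit$S))) - determinant(fit$S, logarithm = TRUE)$modulus
    baseline <- list(chisq = (n - 1) * as.numeric(Fb), df = p * (p - 1) / 2)
  }
  chib <- baseline$chisq; dfb <- baseline$df
  num <- max(chi - df, 0)
  den <- max(chib - dfb, chi - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (dfb == 0 || df == 0) NA_real_ else
    ((chib / dfb) - (chi / df)) / ((chib / dfb) - 1)
  if (df == 0) {
    if (chi > 1e-8)
      warning("df = 0: RMSEA undefined, reported as 0", call. = FALSE)
    rmsea <- 0
  } else rmsea <- sqrt(max(chi - df, 0) / (df * (n - 1)))
  sdx <- sqrt(diag(fit$S))
  res <- (fit$S - fit$Sigma) / tcrossprod(sdx)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  list(chisq = chi, df = df, cfi = cfi, tli = tli, rmsea = rmsea,
       srmr = srmr, baseline_chisq = chib, baseline_df = dfb)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> chi-square =", round(x$chisq, 2), "df =", x$df,
      " n =", x$n, if (!x$converged) "(NOT converged)" else "", "\n")
  s <- x$standardized
  if (nrow(s$paths)) {
    cat("Structural paths (standardized):\n")
    print(cbind(s$paths[c("to", "from")], round(s$paths[-(1:2)], 3)),
          row.names = FALSE)
    cat("R-squared:", paste(sprintf("%s=%.3f", names(s$r_squared),
                                    s$r_squared), collapse = ", "), "\n")
  }
  invisible(x)
}
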