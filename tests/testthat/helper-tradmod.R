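# Shared fixtures and independent oracles.

# Data matrix whose *sample* covariance equals R exactly (QR orthogonalized
# columns rescaled by sqrt(n-1), then rotated by chol(R)).
make_data_with_cov <- function(n, R, seed = 1) {
  set.seed(seed)
  k <- ncol(R)
  Z <- matrix(rnorm(n * k), n)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))                      # orthonormal columns
  X <- sqrt(n - 1) * Q %*% chol(R)
  colnames(X) <- colnames(R) %||% paste0("x", seq_len(k))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force LMG oracle: mean marginal contribution over all k! orderings,
# with its own inline R^2 (independent of the package's subset-weight path).
lmg_bruteforce <- function(R, outcome, predictors) {
  r2 <- function(S) {
    if (length(S) == 0) return(0)
    drop(crossprod(R[S, outcome],
                   solve(R[S, S, drop = FALSE], R[S, outcome])))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  ords <- perms(predictors)
  acc <- stats::setNames(numeric(length(predictors)), predictors)
  for (o in ords) {
    prev <- character(0)
    for (x in o) {
      acc[x] <- acc[x] + r2(c(prev, x)) - r2(prev)
      prev <- c(prev, x)
    }
  }
  acc / length(ords)
}

# Inter-construct correlations of the published discriminant-validity tables
# (off-diagonals only; diagonals there are sqrt(AVE), not correlations).
published_corr_matrix <- function() {
  cn <- c("CI", "MFSC", "ATT", "PP", "PI", "PB")
  R <- diag(6)
  dimnames(R) <- list(cn, cn)
  R["CI", "MFSC"] <- -0.451; R["CI", "ATT"] <- 0.652
  R["CI", "PP"] <- -0.315;   R["CI", "PI"] <- 0.689; R["CI", "PB"] <- 0.557
  R["MFSC", "ATT"] <- -0.510; R["MFSC", "PP"] <- 0.388
  R["MFSC", "PI"] <- -0.598;  R["MFSC", "PB"] <- -0.482
  R["ATT", "PP"] <- -0.421; R["ATT", "PI"] <- 0.753; R["ATT", "PB"] <- 0.612
  R["PP", "PI"] <- -0.499;  R["PP", "PB"] <- -0.380
  R["PI", "PB"] <- 0.701
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

# Small two-construct continuous-indicator generator for SEM group tests:
# PI = b * CI + disturbance, three indicators each with loading 0.9.
gen_two_construct <- function(n, b, seed = 1) {
  set.seed(seed)
  ci <- rnorm(n)
  pi_ <- b * ci + rnorm(n, 0, sqrt(1 - b^2))
  mk <- function(z, pre) {
    X <- sapply(1:3, function(i) 0.9 * z + rnorm(n, 0, sqrt(1 - 0.81)))
    colnames(X) <- paste0(pre, 1:3)
    X
  }
  cbind(mk(ci, "CI"), mk(pi_, "PI"))
}

two_construct_model <- "latent CI =~ CI1 + CI2 + CI3
latent PI =~ PI1 + PI2 + PI3
path PI <- CI"

# cached default spec (built once per test run)
default_spec_cached <- local({
  spec <- NULL
  function() {
    if (is.null(spec)) spec <<- build_population_spec()
    spec
  }
})

corr_spec_cached <- local({
  spec <- NULL
  function() {
    if (is.null(spec)) spec <<- build_population_spec(
      list(regime = "corr-matched"))
    spec
  }
})

# finite-difference gradient of the ML discrepancy, for gradient audits
numeric_gradient <- function(mod, est, S, xbar = NULL) {
  logdetS <- 2 * sum(log(diag(chol(S))))
  labs <- free_params(mod)
  f <- function(e) tradmod:::sem_objective(mod, e, S, xbar, logdetS,
                                           gradient = FALSE)$F
  vapply(labs, function(l) {
    h <- max(abs(est[[l]]), 0.1) * 1e-6
    ep <- est; em <- est
    ep[[l]] <- ep[[l]] + h; em[[l]] <- em[[l]] - h
    (f(ep) - f(em)) / (2 * h)
  }, 0)
}
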