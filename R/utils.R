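# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo = 1, hi = 5) pmin(pmax(x, lo), hi)

stop2 <- function(...) stop(..., call. = FALSE)

#' Nearest positive-semi-definite repair of a correlation matrix
#'
#' Clips negative eigenvalues at a small floor and rescales the result back
#' to unit diagonal. The repair is order-independent and leaves an already
#' positive-semi-definite matrix unchanged (up to numerical noise).
#'
#' @param R symmetric correlation matrix.
#' @param eig_floor smallest admissible eigenvalue after repair.
#' @return list with elements `mat` (repaired matrix) and `max_delta`
#'   (largest absolute entry change).
#' @export
nearest_pd <- function(R, eig_floor = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop2("correlation matrix must be symmetric")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= eig_floor)
    return(list(mat = R, max_delta = 0))
  v <- pmax(e$values, eig_floor)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  list(mat = M, max_delta = max(abs(M - R)))
}

# Draw from MVN(0, Sigma) given a fixed RNG stream; uses eigen for PSD safety.
rmvnorm0 <- function(n, Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(Sigma))
  Z <- matrix(stats::rnorm(n * nrow(Sigma)), n)
  X <- Z %*% t(A)
  colnames(X) <- colnames(Sigma)
  X
}

# Restartable seed derivation: combine a base seed and an index into a
# reproducible child seed below 2^31.
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 9973) %% 2147483629 + 1
}
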