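test_that("model compilation assigns labels, scaling and df correctly", {
  m <- compile_model(default_sem_model())
  st <- unique(m$params$label[m$params$matrix == "B"])
  expect_length(st, 7)              # the seven structural paths
  expect_setequal(st, c("ATT~CI", "PI~CI", "PI~MFSC", "PI~ATT", "PI~PP",
                        "PB~PI", "MFSC~URB"))
  # single-indicator latent: loading fixed 1, zero measurement error
  expect_equal(m$Lambda$value["urban", "URB"], 1)
  expect_false(m$Lambda$free["urban", "URB"])
  expect_equal(m$Theta$value["urban", 1], 0)
  expect_false(m$Theta$free["urban", 1])

  # just-identified one-factor CFA: df = 0
  m1 <- compile_model("latent A =~ A1 + A2 + A3")
  expect_equal(model_df(m1), 0)
  expect_length(free_params(m1), 6)

  expect_error(compile_model("latent A =~ A1 + A2
latent B =~ B1 + B2
path A <- B
path B <- A"), "cyclic")
})

test_that("duplicate labels impose equality constraints", {
  set.seed(3)
  z <- rnorm(500)
  X <- cbind(A1 = z + rnorm(500, 0, 0.6), A2 = 0.8 * z + rnorm(500, 0, 0.6),
             A3 = 0.7 * z + rnorm(500, 0, 0.6))
  f <- fit_ml(X, "latent A =~ A1 + l*A2 + l*A3", se = FALSE)
  ld <- f$standardized$loadings
  expect_equal(ld$est[ld$indicator == "A2"], ld$est[ld$indicator == "A3"])
})

test_that("implied moments follow the path-tracing rules", {
  # no structural paths, orthogonal latents: block-diagonal covariance
  m <- compile_model("latent A =~ A1 + A2
latent B =~ B1 + B2
orthogonal A
orthogonal B")
  est <- list("A=~A2" = 0.8, "B=~B2" = 0.7, "A~~A" = 1, "B~~B" = 1,
              "A1~~A1" = 0.5, "A2~~A2" = 0.5, "B1~~B1" = 0.5, "B2~~B2" = 0.5)
  Sg <- implied_moments(m, est)$Sigma
  expect_equal(unname(Sg[c("A1", "A2"), c("B1", "B2")]),
               matrix(0, 2, 2))

  # single path x -> y, unit variances, identity loadings: cov(x, y) = b
  m2 <- compile_model("latent X =~ x
latent Y =~ y
path Y <- X")
  est2 <- list("Y~X" = 0.37, "X~~X" = 1, "Y~~Y" = 1)
  Sg2 <- implied_moments(m2, est2)$Sigma
  expect_equal(Sg2["x", "y"], 0.37)
  expect_equal(Sg2["y", "y"], 1 + 0.37^2)
})

test_that("zero-discrepancy data reproduce the generating parameters", {
  m <- compile_model("latent A =~ A1 + A2 + A3
latent B =~ B1 + B2 + B3
path B <- A")
  theta0 <- list("A=~A2" = 0.8, "A=~A3" = 1.1, "B=~B2" = 0.9,
                 "B=~B3" = 0.75, "B~A" = 0.5, "A~~A" = 1, "B~~B" = 0.75,
                 "A1~~A1" = 0.4, "A2~~A2" = 0.5, "A3~~A3" = 0.45,
                 "B1~~B1" = 0.35, "B2~~B2" = 0.6, "B3~~B3" = 0.4)
  S0 <- implied_moments(m, theta0)$Sigma
  f <- fit_ml(S = S0, n = 500, model = m, se = FALSE)
  expect_lt(f$F_ml, 1e-9)
  expect_lt(f$chisq, 1e-6)
  for (l in names(theta0))
    expect_equal(f$est[[l]], theta0[[l]], tolerance = 1e-3)
  # self-consistency: the implied moments at the optimum reproduce S
  expect_equal(implied_moments(m, f$est)$Sigma, S0, tolerance = 1e-6)
})

test_that("the analytic gradient matches finite differences", {
  m <- compile_model("latent A =~ A1 + A2 + A3
latent B =~ B1 + B2 + B3
path B <- A")
  set.seed(12)
  R <- cov2cor(crossprod(matrix(rnorm(36), 6))) + diag(0.5, 6)
  dimnames(R) <- list(c("A1", "A2", "A3", "B1", "B2", "B3"),
                      c("A1", "A2", "A3", "B1", "B2", "B3"))
  est <- tradmod:::default_start(m, R)
  est[["B~A"]] <- 0.3
  o <- tradmod:::sem_objective(m, est, R, NULL,
                               2 * sum(log(diag(chol(R)))))
  expect_equal(o$grad, numeric_gradient(m, est, R), tolerance = 1e-5)
})

test_that("gradient with mean structure matches finite differences", {
  m <- compile_model("latent A =~ A1 + A2 + A3", meanstructure = TRUE)
  m2 <- m
  m2$alpha$free["A"] <- TRUE
  m2$alpha$label["A"] <- "A~1"
  m2$params <- tradmod:::param_table(m2)
  # over-parameterized (alpha + all nu free) is fine for a gradient audit
  set.seed(13)
  R <- cov2cor(crossprod(matrix(rnorm(9), 3))) + diag(0.5, 3)
  dimnames(R) <- list(c("A1", "A2", "A3"), c("A1", "A2", "A3"))
  xbar <- c(A1 = 0.3, A2 = -0.2, A3 = 0.1)
  est <- tradmod:::default_start(m2, R)
  est[["A~1"]] <- 0.05
  est[["A1~1"]] <- 0.1; est[["A2~1"]] <- -0.1; est[["A3~1"]] <- 0
  o <- tradmod:::sem_objective(m2, est, R, xbar,
                               2 * sum(log(diag(chol(R)))))
  expect_equal(o$grad, numeric_gradient(m2, est, R, xbar), tolerance = 1e-5)
})

test_that("standardization rescales paths and reports R-squared", {
  # single-predictor latent regression with standardized beta 0.6: R^2 = 0.36
  X <- gen_two_construct(4000, b = 0.6, seed = 21)
  f <- fit_ml(X, two_construct_model, se = FALSE)
  expect_equal(unname(f$standardized$r_squared["PI"]),
               f$standardized$paths$std^2, tolerance = 1e-8)
  expect_equal(f$standardized$paths$std, 0.6, tolerance = 0.05)

  # scale invariance: rescaling an indicator leaves the standardized
  # solution unchanged
  X2 <- X; X2[, "CI2"] <- X2[, "CI2"] * 10
  f2 <- fit_ml(X2, two_construct_model, se = FALSE)
  expect_equal(f2$standardized$paths$std, f$standardized$paths$std,
               tolerance = 1e-5)
  expect_equal(f2$standardized$loadings$std, f$standardized$loadings$std,
               tolerance = 1e-5)
})

test_that("fit indices hit their definitional anchors", {
  m <- compile_model("latent A =~ A1 + A2 + A3
latent B =~ B1 + B2 + B3
path B <- A")
  theta0 <- list("A=~A2" = 0.8, "A=~A3" = 1.1, "B=~B2" = 0.9,
                 "B=~B3" = 0.75, "B~A" = 0.5, "A~~A" = 1, "B~~B" = 0.75,
                 "A1~~A1" = 0.4, "A2~~A2" = 0.5, "A3~~A3" = 0.45,
                 "B1~~B1" = 0.35, "B2~~B2" = 0.4, "B3~~B3" = 0.4)
  S0 <- implied_moments(m, theta0)$Sigma
  f <- fit_ml(S = S0, n = 500, model = m, se = FALSE)
  idx <- fit_indices(f)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  expect_lt(idx$srmr, 1e-5)

  # model equal to the baseline: CFI = 0 by definition
  idx0 <- fit_indices(list(chisq = idx$baseline_chisq,
                           df = idx$baseline_df, n = 500, S = S0,
                           Sigma = diag(diag(S0))),
                      baseline = list(chisq = idx$baseline_chisq,
                                      df = idx$baseline_df))
  expect_equal(idx0$cfi, 0)

  # omitting a true cross-loading worsens CFI
  set.seed(31)
  n <- 1076
  a <- rnorm(n); b <- 0.5 * a + rnorm(n, 0, sqrt(0.75))
  X <- cbind(A1 = a + rnorm(n, 0, 0.5), A2 = 0.9 * a + rnorm(n, 0, 0.5),
             A3 = 0.8 * a + 0.5 * b + rnorm(n, 0, 0.5),
             B1 = b + rnorm(n, 0, 0.5), B2 = 0.9 * b + rnorm(n, 0, 0.5),
             B3 = 0.8 * b + rnorm(n, 0, 0.5))
  good <- fit_ml(X, "latent A =~ A1 + A2 + A3
latent B =~ B1 + B2 + B3 + A3
path B <- A", se = FALSE)
  bad <- fit_ml(X, "latent A =~ A1 + A2 + A3
latent B =~ B1 + B2 + B3
path B <- A", se = FALSE)
  expect_lt(fit_indices(bad)$cfi, fit_indices(good)$cfi)
})

test_that("errors surface for unusable input", {
  m <- compile_model("latent A =~ A1 + A2 + A3")
  S <- diag(3); dimnames(S) <- list(paste0("A", 1:3), paste0("A", 1:3))
  expect_error(fit_ml(S = S, n = 2, model = m), "exceed")
  Sbad <- matrix(1, 3, 3, dimnames = dimnames(S))
  expect_error(fit_ml(S = Sbad, n = 100, model = m), "positive definite")
  expect_error(fit_ml(S = S[1:2, 1:2], n = 100, model = m), "lacks")
})

test_that("multi-group estimation recovers group-specific structural paths", {
  # two identical groups: configural estimates coincide
  X <- gen_two_construct(700, b = 0.5, seed = 41)
  mg0 <- fit_multigroup(list(g1 = X, g2 = X), two_construct_model,
                        level = "configural")
  e1 <- unlist(mg0$group_fits[[1]]$est)
  e2 <- unlist(mg0$group_fits[[2]]$est)
  names(e2) <- sub("\\|g2$", "|g1", names(e2))
  expect_equal(e1, e2[names(e1)], tolerance = 1e-5)

  # urban 0.30 vs rural 0.40 generating effects recovered within 0.05
  Xu <- gen_two_construct(2000, b = 0.30, seed = 42)
  Xr <- gen_two_construct(2000, b = 0.40, seed = 43)
  mg <- fit_multigroup(list(urban = Xu, rural = Xr), two_construct_model,
                       level = "configural")
  bu <- mg$group_fits$urban$standardized$paths$std
  br <- mg$group_fits$rural$standardized$paths$std
  expect_equal(bu, 0.30, tolerance = 0.05)
  expect_equal(br, 0.40, tolerance = 0.05)

  expect_error(fit_multigroup(list(g1 = X), two_construct_model),
               "at least 2")
  Xmiss <- X[, 1:5]
  expect_error(fit_multigroup(list(g1 = X, g2 = Xmiss),
                              two_construct_model), "incompatible|lacks")
})

test_that("the invariance sequence supports invariant groups and flags loading shifts", {
  cfa <- "latent A =~ A1 + A2 + A3"
  gen <- function(n, load, seed) {
    set.seed(seed)
    z <- rnorm(n)
    X <- sapply(load, function(l) l * z + rnorm(n, 0, 0.6))
    colnames(X) <- paste0("A", 1:3)
    X
  }
  inv <- invariance_sequence(list(a = gen(500, c(1, 0.8, 0.9), 1),
                                  b = gen(500, c(1, 0.8, 0.9), 2)), cfa)
  expect_true(all(inv$supported))
  expect_true(all(diff(inv$df) >= 0))
  expect_true(all(abs(inv$delta_cfi[-1]) <= 0.01))

  # a 0.3 loading perturbation in one group breaks metric invariance
  inv2 <- invariance_sequence(list(a = gen(500, c(1, 0.8, 0.9), 3),
                                   b = gen(500, c(1, 1.1, 0.6), 4)), cfa)
  expect_false(inv2$supported[inv2$level == "metric"])

  expect_error(invariance_sequence(list(a = gen(100, c(1, .8, .9), 5)), cfa),
               "at least 2")
})

test_that("the common-latent-factor check is null on clean data and inert at zero", {
  X <- gen_two_construct(1200, b = 0.5, seed = 51)
  cl <- fit_with_clf(X, two_construct_model, se = FALSE)
  expect_true(cl$converged)
  expect_lt(cl$max_change, 0.05)

  # CLF with loadings fixed to zero reproduces the base fit exactly
  zero_clf <- paste0(two_construct_model, "\nlatent CLF =~ ",
                     paste(paste0("0*", colnames(X)), collapse = " + "),
                     "\northogonal CLF")
  f0 <- fit_ml(X, zero_clf, se = FALSE)
  fb <- fit_ml(X, two_construct_model, se = FALSE)
  common <- intersect(names(fb$est), names(f0$est))
  expect_equal(unlist(f0$est[common]), unlist(fb$est[common]),
               tolerance = 1e-5)

  # an injected method factor is absorbed: the CLF path estimate is closer
  # to the generating value than the contaminated base estimate (trait
  # loadings are varied so method and trait variance stay distinguishable)
  set.seed(52)
  n <- 2500
  ci <- rnorm(n); pi_ <- 0.4 * ci + rnorm(n, 0, sqrt(0.84)); mth <- rnorm(n)
  lds <- c(0.85, 0.7, 0.5)
  mk <- function(z, pre) {
    X <- sapply(1:3, function(i)
      lds[i] * z + 0.45 * mth + rnorm(n, 0, sqrt(1 - lds[i]^2 - 0.2)))
    colnames(X) <- paste0(pre, 1:3); X
  }
  Xm <- cbind(mk(ci, "CI"), mk(pi_, "PI"))
  clm <- fit_with_clf(Xm, two_construct_model, se = FALSE, n_starts = 5)
  expect_true(clm$converged)
  base_b <- clm$base$standardized$paths$std
  clf_b <- clm$clf$standardized$paths$std
  expect_lt(abs(clf_b - 0.4), abs(base_b - 0.4))
  sl <- clm$clf$standardized$loadings
  expect_gt(mean(sl$std[sl$latent == "CLF"]), 0.3)
})
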