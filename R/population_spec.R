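#' Default population specification
#'
#' Returns the configuration the synthetic-survey generator treats as the
#' study conditions: eight focal constructs (CI, MFSC, ATT, PP, PI, PB, FN,
#' HL) plus a method-marker construct, the published inter-construct
#' correlations, per-construct reliabilities expressed as standardized
#' loadings, the urban/rural and age composition of the sample, and the
#' standardized urban-context effect on medicine-food separation cognition
#' (MFSC).
#'
#' Construct means are mostly unanchored in the source tables (only the
#' purchase-intention composite mean 3.73 and SD 1.07 are published); the
#' defaults below are plausible mid-scale values and are fully configurable.
#'
#' @return a list suitable as `config` for [build_population_spec()].
#' @export
default_population_config <- function() {
  list(
    constructs = list(
      list(name = "CI",   mean = 3.80, sd = 1.00, loadings = rep(sqrt(0.778), 3)),
      list(name = "MFSC", mean = 3.00, sd = 1.00, loadings = rep(sqrt(0.710), 3),
           reverse = 1:3),
      list(name = "ATT",  mean = 3.70, sd = 1.00, loadings = rep(sqrt(0.805), 3)),
      list(name = "PP",   mean = 3.20, sd = 1.00, loadings = rep(sqrt(0.757), 3)),
      list(name = "PI",   mean = 3.73, sd = 1.07, loadings = rep(sqrt(0.824), 3)),
      list(name = "PB",   mean = 3.10, sd = 1.00, loadings = rep(sqrt(0.748), 2)),
      list(name = "FN",   mean = 2.90, sd = 1.00, loadings = rep(0.866, 3),
           reverse = 1),
      list(name = "HL",   mean = 3.50, sd = 1.00, loadings = rep(0.849, 3)),
      list(name = "MK",   mean = 3.00, sd = 1.00, loadings = rep(0.80, 3),
           marker = TRUE)
    ),
    correlations = list(
      c("CI", "MFSC", -0.451), c("CI", "ATT", 0.652), c("CI", "PP", -0.315),
      c("CI", "PI", 0.689), c("CI", "PB", 0.557),
      c("MFSC", "ATT", -0.510), c("MFSC", "PP", 0.388), c("MFSC", "PI", -0.598),
      c("MFSC", "PB", -0.482), c("MFSC", "FN", 0.237), c("MFSC", "HL", -0.052),
      c("ATT", "PP", -0.421), c("ATT", "PI", 0.753), c("ATT", "PB", 0.612),
      c("PP", "PI", -0.499), c("PP", "PB", -0.380),
      c("PI", "PB", 0.701),
      c("FN", "HL", -0.345)
    ),
    structural = c(CI_ATT = 0.41, CI_PI = 0.34, MFSC_PI = -0.29,
                   ATT_PI = 0.44, PP_PI = -0.27, PI_PB = 0.59,
                   URBAN_MFSC = 0.26),
    urban_prop  = 0.546,
    age_props   = c("18-25" = 0.218, "26-40" = 0.451,
                    "41-55" = 0.249, "56+" = 0.082),
    urban_effect = 0.26,
    thresholds  = stats::qnorm(c(0.2, 0.4, 0.6, 0.8)),
    regime      = "model-generated",
    likert      = TRUE
  )
}

#' Build and validate a population specification
#'
#' Assembles the generator's full parameter set from a configuration list or
#' a YAML file, validates it, and derives the quantities the generator needs:
#' the latent (generating) correlation matrix, per-item generating loadings
#' calibrated so that the observed standardized loadings match the requested
#' values after Likert discretization, the composite attenuation factor per
#' construct, and the z-scale mean offsets that reproduce the requested
#' construct means on the 1-5 response scale.
#'
#' Two regimes are supported. `"corr-matched"` reproduces the published
#' composite correlations: the latent matrix is the requested matrix
#' disattenuated by the composite-latent attenuation factors, so that
#' unit-weighted composites of the generated items recover the requested
#' values. `"model-generated"` draws exogenous constructs with the requested
#' exogenous correlations and builds the endogenous constructs from the
#' structural coefficients plus Gaussian disturbances, so that a structural
#' equation model refitted to the generated items recovers the coefficients.
#'
#' If either derived matrix is not positive semi-definite it is repaired by
#' eigenvalue clipping and rescaling to unit diagonal; the maximum absolute
#' entry change is stored in the spec (`repair_delta`).
#'
#' @param config a configuration list (see [default_population_config()] for
#'   the schema) or path to a YAML file with the same structure. Supplied
#'   fields override the defaults.
#' @return an object of class `population_spec`.
#' @export
build_population_spec <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  def <- default_population_config()
  if (!is.null(config$constructs)) def$constructs <- config$constructs
  for (nm in setdiff(names(config), "constructs")) def[[nm]] <- config[[nm]]
  cfg <- def

  cons <- cfg$constructs
  names(cons) <- vapply(cons, function(x) x$name, "")
  cn <- names(cons)
  if (anyDuplicated(cn)) stop2("duplicate construct names")

  for (c in cons) {
    if (any(c$loadings <= 0 | c$loadings >= 1))
      stop2("loadings must lie in (0,1) for construct ", c$name)
    if (!is.null(c$sd) && c$sd <= 0) stop2("sd must be positive: ", c$name)
  }

  # assemble the target (requested, composite-scale) correlation matrix
  if (!is.null(cfg$correlation_matrix)) {
    R <- as.matrix(cfg$correlation_matrix)
    if (is.null(dimnames(R))) dimnames(R) <- list(cn, cn)
    R <- R[cn, cn]
  } else {
    R <- diag(length(cn))
    dimnames(R) <- list(cn, cn)
    for (tr in cfg$correlations) {
      a <- tr[[1]]; b <- tr[[2]]; r <- as.numeric(tr[[3]])
      if (!(a %in% cn) || !(b %in% cn)) next  # constructs not in play
      R[a, b] <- R[b, a] <- r
    }
  }
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop2("correlation matrix must be symmetric")
  if (any(abs(R) > 1)) stop2("correlation entries must lie in [-1, 1]")
  if (any(abs(diag(R) - 1) > 1e-12)) stop2("correlation diagonal must be 1")

  if (abs(sum(cfg$age_props) - 1) > 1e-6)
    stop2("age_props must sum to 1")
  if (cfg$urban_prop < 0 || cfg$urban_prop > 1)
    stop2("urban_prop must be a fraction in [0, 1]")
  th <- cfg$thresholds
  if (cfg$likert && (length(th) != 4 || any(diff(th) <= 0)))
    stop2("thresholds must be 4 strictly increasing z-scale cut points")
  regime <- match.arg(cfg$regime, c("model-generated", "corr-matched"))
  # urban_effect and the URBAN_MFSC structural coefficient describe the same
  # quantity; an explicit urban_effect override wins
  if (!is.null(config$urban_effect))
    cfg$structural[["URBAN_MFSC"]] <- config$urban_effect
  cfg$urban_effect <- cfg$structural[["URBAN_MFSC"]]

  means <- vapply(cons, function(x) x$mean, 0)
  sds   <- vapply(cons, function(x) x$sd %||% 1, 0)
  marker <- vapply(cons, function(x) isTRUE(x$marker), NA)

  spec <- structure(list(
    constructs = cons, names = cn, means = means, sds = sds,
    marker = marker, R_target = R,
    structural = cfg$structural, urban_prop = cfg$urban_prop,
    age_props = cfg$age_props, urban_effect = cfg$urban_effect,
    thresholds = th, regime = regime, likert = isTRUE(cfg$likert),
    repair_delta = 0
  ), class = "population_spec")

  spec$calib <- calibrate_items(spec)
  spec$R_latent <- generating_matrix(spec)
  spec$repair_delta <- attr(spec$R_latent, "repair_delta") %||% 0
  spec
}

# ---- Hermite machinery for the Likert discretization ---------------------
#
# An item is D(v) = 1 + sum_k 1[v > t_k] with v ~ N(mu, 1). In the Hermite
# basis (probabilists' polynomials He_n) the coefficients are
#   a_n = sum_k He_{n-1}(t_k - mu) * phi(t_k - mu),
# and for two items whose continuous parts correlate rho,
#   cov(D_i, D_j) = sum_{n>=1} a_n^i a_n^j rho^n / n!   (exact in the limit).
# Truncation at N_HERMITE terms is accurate to < 1e-6 for |rho| <= 0.99.
N_HERMITE <- 12L

hermite_he <- function(x, nmax) {
  H <- matrix(0, length(x), nmax + 1)
  H[, 1] <- 1
  if (nmax >= 1) H[, 2] <- x
  if (nmax >= 2) for (n in 2:nmax) H[, n + 1] <- x * H[, n] - (n - 1) * H[, n - 1]
  H
}

# Hermite coefficients a_1..a_N of a discretized item with cuts th, offset mu
item_hermite <- function(th, mu) {
  tau <- th - mu
  Hm <- hermite_he(tau, N_HERMITE - 1)          # He_0 .. He_{N-1}
  as.vector(crossprod(Hm, stats::dnorm(tau)))   # a_n = sum He_{n-1}(tau) phi(tau)
}

# cov(D_i, D_j) given Hermite coefficient vectors and continuous correlation
dcov <- function(a_i, a_j, rho) {
  n <- seq_along(a_i)
  sum(a_i * a_j * rho^n / factorial(n))
}

# Per-construct discretization calibration: the z-scale mean offset that
# yields the requested construct mean on the 1-5 scale; the generating
# loading per item chosen so that the *observed* inter-item correlations
# equal the products of the requested standardized loadings; the composite
# standard deviation; the composite-latent attenuation factor; and the
# construct-level Hermite coefficients used for cross-construct calibration.
calibrate_items <- function(spec) {
  th <- spec$thresholds
  out <- lapply(spec$names, function(cnm) {
    con <- spec$constructs[[cnm]]
    lam_t <- con$loadings
    k <- length(lam_t)
    if (!spec$likert) {
      # continuous mode: items are linear in the latent, no discretization
      sd_c <- sqrt((sum(outer(lam_t, lam_t)) + sum(1 - lam_t^2)) / k^2)
      A <- mean(lam_t) / sd_c
      return(list(mu_z = 0, lambda_gen = lam_t, attenuation = A,
                  sd_c = sd_c, gcoef = NULL, item_sd = rep(1, k)))
    }
    # mean offset: E[score] = 1 + sum_k Phi(mu - t_k) = target mean
    f <- function(mu) 1 + sum(stats::pnorm(mu - th)) - con$mean
    mu <- stats::uniroot(f, c(-6, 6), tol = 1e-10)$root
    pcat <- diff(c(0, stats::pnorm(th - mu), 1))
    m1 <- sum((1:5) * pcat)
    v_d <- sum((1:5)^2 * pcat) - m1^2
    a <- item_hermite(th, mu)
    # generating loadings lambda_g = c * lam_t with c solving
    #   mean_pairs cov(D_i, D_j) = mean_pairs lam_ti lam_tj * v_d
    if (k > 1) {
      pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      tgt <- mean(lam_t[pr[, 1]] * lam_t[pr[, 2]]) * v_d
      g <- function(cc) mean(apply(pr, 1, function(ij)
        dcov(a, a, cc^2 * lam_t[ij[1]] * lam_t[ij[2]]))) - tgt
      cmax <- 0.999 / max(lam_t)
      cc <- if (g(cmax) < 0) cmax else stats::uniroot(g, c(0.05, cmax),
                                                      tol = 1e-10)$root
    } else {
      # single item: match corr(D, z) to the requested loading
      cc <- min(lam_t * sqrt(v_d) / a[1] / lam_t, 0.999 / lam_t)
    }
    lam_g <- pmin(cc * lam_t, 0.999)
    # composite moments
    covd <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      if (i == j) v_d else dcov(a, a, lam_g[i] * lam_g[j])
    }))
    sd_c <- sqrt(mean(covd))
    cov_cz <- mean(lam_g) * a[1]           # only He_1 projects onto z
    # construct-level coefficients: cov(C1, C2) = sum_n g_n1 g_n2 r^n / n!
    nn <- seq_len(N_HERMITE)
    gcoef <- vapply(nn, function(n) mean(a[n] * lam_g^n), 0)
    list(mu_z = mu, lambda_gen = lam_g, attenuation = cov_cz / sd_c,
         sd_c = sd_c, gcoef = gcoef, item_sd = rep(sqrt(v_d), k),
         # requested observed loading in item-sd units, for the item-level
         # pairwise correlation calibration of the model-generated regime
         load_sd = mean(lam_t) * sqrt(v_d))
  })
  names(out) <- spec$names
  out
}

# The latent (z-scale, generating) correlation matrix for the spec's regime.
generating_matrix <- function(spec) {
  cn <- spec$names
  R <- spec$R_target
  if (spec$regime == "corr-matched") {
    # disattenuate so that unit-weighted composites of the generated items
    # reproduce the requested correlations: solve each latent pair
    # correlation from the exact discretized-composite covariance
    A <- vapply(spec$calib, function(x) x$attenuation, 0)
    Rl <- diag(length(cn))
    dimnames(Rl) <- list(cn, cn)
    nn <- seq_len(N_HERMITE)
    for (i in seq_along(cn)[-1]) for (j in seq_len(i - 1)) {
      tgt <- R[i, j]
      if (tgt == 0) next
      ci <- spec$calib[[cn[i]]]; cj <- spec$calib[[cn[j]]]
      if (is.null(ci$gcoef)) {         # continuous items: linear attenuation
        r <- tgt / (A[i] * A[j])
      } else {
        f <- function(r) sum(ci$gcoef * cj$gcoef * r^nn / factorial(nn)) -
          tgt * ci$sd_c * cj$sd_c
        r <- if (f(0.999) < 0) 0.999 else if (f(-0.999) > 0) -0.999 else
          stats::uniroot(f, c(-0.999, 0.999), tol = 1e-12)$root
      }
      Rl[i, j] <- Rl[j, i] <- max(min(r, 0.99), -0.99)
    }
    u_load <- numeric(length(cn))
    names(u_load) <- cn
    if ("MFSC" %in% cn)
      u_load["MFSC"] <- min(spec$urban_effect / A[["MFSC"]], 0.99)
  } else {
    Rl <- model_implied_latent(spec)
    u_load <- attr(Rl, "u_load")
    if (spec$likert) {
      # calibrate each generating pair correlation so that the correlation
      # recovered through the factor structure of the *discretized* items
      # equals the structurally implied value (undoes the higher-order
      # distortion of the Likert cut)
      nn <- seq_len(N_HERMITE)
      for (i in seq_along(cn)[-1]) for (j in seq_len(i - 1)) {
        tgt <- Rl[i, j]
        if (tgt == 0) next
        ci <- spec$calib[[cn[i]]]; cj <- spec$calib[[cn[j]]]
        f <- function(r) sum(ci$gcoef * cj$gcoef * r^nn / factorial(nn)) -
          tgt * ci$load_sd * cj$load_sd
        r <- if (f(0.999) < 0) 0.999 else if (f(-0.999) > 0) -0.999 else
          stats::uniroot(f, c(-0.999, 0.999), tol = 1e-12)$root
        Rl[i, j] <- Rl[j, i] <- r
      }
    }
  }
  rep <- nearest_pd(Rl)
  attr(rep$mat, "repair_delta") <- rep$max_delta
  attr(rep$mat, "u_load") <- u_load
  rep$mat
}

# Latent correlation matrix implied by the structural coefficients
# (model-generated regime), marginal over the urban dummy. The system is
# solved with the standardized urban dummy U as an explicit exogenous
# variable; disturbance variances are chosen so every construct has unit
# marginal variance.
model_implied_latent <- function(spec) {
  cn <- spec$names
  b <- spec$structural
  vars <- c(cn, "U")
  m <- length(vars)
  B <- matrix(0, m, m, dimnames = list(vars, vars))
  path <- function(to, from, val)
    if (all(c(to, from) %in% vars) && !is.null(val)) B[to, from] <<- val
  path("ATT", "CI", b[["CI_ATT"]])
  path("PI", "CI", b[["CI_PI"]]); path("PI", "MFSC", b[["MFSC_PI"]])
  path("PI", "ATT", b[["ATT_PI"]]); path("PI", "PP", b[["PP_PI"]])
  path("PB", "PI", b[["PI_PB"]])
  path("MFSC", "U", b[["URBAN_MFSC"]])
  # Psi: exogenous covariances and disturbance (co)variances on the z-scale.
  # cov(zeta_MFSC, X) carries the requested marginal correlation of MFSC
  # with each exogenous construct; U is independent of everything else.
  exog <- intersect(c("CI", "PP", "FN", "HL", "MK"), cn)
  Psi <- matrix(0, m, m, dimnames = list(vars, vars))
  Psi[exog, exog] <- spec$R_target[exog, exog]
  Psi["U", "U"] <- 1
  endo <- intersect(c("MFSC", "ATT", "PI", "PB"), cn)
  if ("MFSC" %in% cn)
    Psi["MFSC", exog] <- Psi[exog, "MFSC"] <- spec$R_target["MFSC", exog]
  IB <- solve(diag(m) - B)
  for (e in endo) {  # causal order; recursive system => IB[e, e] == 1
    Psi[e, e] <- 0
    V <- IB %*% Psi %*% t(IB)
    Psi[e, e] <- max(1 - V[e, e], 0.02)
  }
  V <- IB %*% Psi %*% t(IB)
  out <- stats::cov2cor(V[cn, cn, drop = FALSE])
  # total loading of each construct on the standardized urban dummy
  attr(out, "u_load") <- IB[cn, "U"] / sqrt(diag(V)[cn])
  out
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat("  constructs:", paste(x$names, collapse = ", "), "\n")
  cat("  regime:", x$regime, if (x$likert) "(likert)" else "(continuous)", "\n")
  cat("  urban proportion:", x$urban_prop,
      " urban->MFSC effect:", x$urban_effect, "\n")
  cat("  age groups:", paste(sprintf("%s=%.3f", names(x$age_props),
                                     x$age_props), collapse = ", "), "\n")
  rd <- attr(x$R_latent, "repair_delta") %||% 0
  if (rd > 0) cat("  latent matrix PD-repaired, max |delta| =",
                  format(rd, digits = 3), "\n")
  invisible(x)
}
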