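# Multi-group estimation, the measurement-invariance sequence, and the
# common-latent-factor (method bias) comparison.

# Clone a compiled model for group g, suffixing labels that are not
# constrained equal across groups. `shared` names the matrices whose labels
# stay common ("Lambda", "nu", ...).
relabel_group <- function(mod, g, shared = character(0)) {
  suf <- function(l) paste0(l, "|g", g)
  keep <- mod$params$matrix %in% shared
  mod$params$label[!keep] <- suf(mod$params$label[!keep])
  for (mn in c("Lambda", "B", "Psi")) {
    if (mn %in% shared) next
    sel <- !is.na(mod[[mn]]$label)
    mod[[mn]]$label[sel] <- suf(mod[[mn]]$label[sel])
  }
  if (!"Theta" %in% shared) {
    sel <- !is.na(mod$Theta$label)
    mod$Theta$label[sel] <- suf(mod$Theta$label[sel])
  }
  if (mod$meanstructure) {
    if (!"nu" %in% shared) {
      sel <- !is.na(mod$nu$label)
      mod$nu$label[sel] <- suf(mod$nu$label[sel])
    }
    sel <- mod$alpha$free
    if (any(sel)) mod$alpha$label[sel] <- suf(mod$alpha$label[sel])
  }
  mod
}

# Free the latent means of a non-reference group (scalar invariance level).
free_latent_means <- function(mod, g) {
  mod$alpha$free[] <- TRUE
  mod$alpha$label[] <- paste0(mod$latents, "~1|g", g)
  mod$params <- param_table(mod)
  mod
}

#' Fit a structural equation model in several groups simultaneously
#'
#' Minimizes the pooled discrepancy \eqn{\sum_g (n_g - 1)/(N - G) F_g};
#' the reported chi-square is \eqn{\sum_g (n_g - 1) F_g}. Constraint levels:
#' `configural` (all parameters group-specific), `metric` (factor loadings
#' equal), `scalar` (loadings and intercepts equal; mean structure enabled;
#' reference-group latent means fixed at 0, other groups' free).
#'
#' @param data_list named list of indicator data matrices, one per group.
#' @param model a `sem_model` or model text (recompiled per level).
#' @param level constraint level.
#' @param S_list,n_list,xbar_list summary-statistic interface used when
#'   `data_list` is NULL.
#' @param se compute standard errors (joint numeric Hessian); default FALSE.
#' @param control optimizer control passed to [stats::nlminb()].
#' @return object of class `sem_mgfit`.
#' @export
fit_multigroup <- function(data_list = NULL, model,
                           level = c("configural", "metric", "scalar"),
                           S_list = NULL, n_list = NULL, xbar_list = NULL,
                           se = FALSE,
                           control = list(iter.max = 2000, eval.max = 4000)) {
  level <- match.arg(level)
  text <- if (inherits(model, "sem_model")) model$text else model
  ms <- level == "scalar"
  base <- compile_model(text, meanstructure = ms,
                        std_lv = if (inherits(model, "sem_model"))
                          model$std_lv else FALSE)
  if (!is.null(data_list)) {
    G <- length(data_list)
    for (d in data_list)
      if (!all(base$indicators %in% colnames(d)))
        stop2("incompatible indicator sets across groups")
    S_list <- lapply(data_list, function(d)
      stats::cov(as.matrix(d[, base$indicators, drop = FALSE])))
    xbar_list <- lapply(data_list, function(d)
      colMeans(as.matrix(d[, base$indicators, drop = FALSE])))
    n_list <- lapply(data_list, nrow)
  }
  G <- length(S_list)
  if (G < 2) stop2("multi-group estimation needs at least 2 groups")
  for (S in S_list)
    if (!all(base$indicators %in% colnames(S)))
      stop2("incompatible indicator sets across groups")
  shared <- switch(level, configural = character(0),
                   metric = "Lambda", scalar = c("Lambda", "nu"))
  gname <- names(S_list) %||% paste0("group", seq_len(G))

  mods <- vector("list", G)
  for (g in seq_len(G)) {
    mg <- base
    if (ms && g > 1) mg <- free_latent_means(mg, g)
    mods[[g]] <- relabel_group(mg, g, shared)
  }
  n_vec <- unlist(n_list)
  N <- sum(n_vec)
  w <- (n_vec - 1) / (N - G)
  prep <- lapply(seq_len(G), function(g) {
    S <- (S_list[[g]] + t(S_list[[g]])) / 2
    S <- S[base$indicators, base$indicators]
    list(S = S, xbar = if (ms) xbar_list[[g]][base$indicators],
         logdetS = 2 * sum(log(diag(chol(S)))))
  })

  labs <- unique(unlist(lapply(mods, free_params)))
  isv <- stats::setNames(rep(FALSE, length(labs)), labs)
  x0 <- stats::setNames(numeric(length(labs)), labs)
  for (g in seq_len(G)) {
    st <- default_start(mods[[g]], prep[[g]]$S)
    if (ms) for (r in which(mods[[g]]$params$matrix == "nu"))
      st[[mods[[g]]$params$label[r]]] <-
        prep[[g]]$xbar[mods[[g]]$params$row[r]]
    xg <- to_opt(mods[[g]], st)
    x0[names(xg)] <- xg
    pv <- mods[[g]]$params
    isv[pv$label[pv$variance]] <- TRUE
  }

  split_est <- function(x) {
    xn <- x
    xn[isv] <- exp(pmin(x[isv], 50))
    lapply(mods, function(mg) as.list(xn[free_params(mg)]))
  }
  obj <- function(x) {
    ests <- split_est(x)
    sum(vapply(seq_len(G), function(g)
      w[g] * sem_objective(mods[[g]], ests[[g]], prep[[g]]$S,
                           prep[[g]]$xbar, prep[[g]]$logdetS,
                           gradient = FALSE)$F, 0))
  }
  grd <- function(x) {
    ests <- split_est(x)
    gtot <- stats::setNames(numeric(length(labs)), labs)
    for (g in seq_len(G)) {
      o <- sem_objective(mods[[g]], ests[[g]], prep[[g]]$S,
                         prep[[g]]$xbar, prep[[g]]$logdetS)
      if (is.null(o$grad)) return(gtot)
      gtot[names(o$grad)] <- gtot[names(o$grad)] + w[g] * o$grad
    }
    gtot[isv] <- gtot[isv] * xn_cache(x)
    gtot
  }
  xn_cache <- function(x) exp(pmin(x[isv], 50))

  res <- stats::nlminb(x0, obj, gradient = grd, control = control)
  ests <- split_est(res$par)
  F_g <- vapply(seq_len(G), function(g)
    sem_objective(mods[[g]], ests[[g]], prep[[g]]$S, prep[[g]]$xbar,
                  prep[[g]]$logdetS, gradient = FALSE)$F, 0)
  chisq <- sum((n_vec - 1) * F_g)
  p <- length(base$indicators)
  mom <- G * (p * (p + 1) / 2 + if (ms) p else 0)
  df <- mom - length(labs)

  group_fits <- lapply(seq_len(G), function(g) {
    im <- implied_moments(mods[[g]], ests[[g]])
    structure(list(model = mods[[g]], est = ests[[g]],
                   F_ml = F_g[g], chisq = (n_vec[g] - 1) * F_g[g],
                   df = NA, n = n_vec[g], S = prep[[g]]$S,
                   xbar = prep[[g]]$xbar, Sigma = im$Sigma, mu = im$mu,
                   V = im$V, converged = res$convergence == 0, se = NULL),
              class = "sem_fit")
  })
  for (g in seq_len(G))
    group_fits[[g]]$standardized <- standardize(group_fits[[g]])
  names(group_fits) <- gname

  # independence baseline pooled over groups (means saturated)
  Fb <- vapply(prep, function(pp)
    sum(log(diag(pp$S))) -
      as.numeric(determinant(pp$S, logarithm = TRUE)$modulus), 0)
  structure(list(
    level = level, group_fits = group_fits, chisq = chisq, df = df,
    n = N, n_groups = G, labels = labs,
    baseline = list(chisq = sum((n_vec - 1) * Fb), df = G * p * (p - 1) / 2),
    converged = res$convergence == 0 || max(abs(grd(res$par))) < 1e-4
  ), class = "sem_mgfit")
}

#' @export
print.sem_mgfit <- function(x, ...) {
  cat("<sem_mgfit>", x$level, "level,", x$n_groups, "groups, chi-square =",
      round(x$chisq, 2), "df =", x$df, "\n")
  invisible(x)
}

#' Fit indices for a multi-group fit
#' @param fit a `sem_mgfit`.
#' @return as [fit_indices()], using the pooled independence baseline.
#' @export
fit_indices_mg <- function(fit) {
  f1 <- fit$group_fits[[1]]
  agg <- list(chisq = fit$chisq, df = fit$df, n = fit$n,
              S = f1$S, Sigma = f1$Sigma)
  idx <- fit_indices(agg, baseline = fit$baseline)
  # SRMR pooled across groups
  srmr <- mean(vapply(fit$group_fits, function(f) {
    sdx <- sqrt(diag(f$S))
    res <- (f$S - f$Sigma) / tcrossprod(sdx)
    sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  }, 0))
  idx$srmr <- srmr
  idx
}

#' Sequential measurement-invariance test
#'
#' Fits the configural, metric and scalar models in order and applies the
#' conventional decision rules: the configural level is supported when its
#' CFI reaches `cfi_configural`; each subsequent level is supported when the
#' CFI drop from the previous level satisfies \eqn{|\Delta CFI| \le 0.01}.
#'
#' @param data_list named list of per-group indicator matrices (>= 2 groups),
#'   or a named list of `survey_dataset`s (converted via [sem_data()]).
#' @param model measurement (CFA) model text or `sem_model`.
#' @param delta_cutoff ΔCFI cutoff (default 0.01).
#' @param cfi_configural configural-fit cutoff (default 0.90).
#' @return object of class `invariance_report`: data.frame with chi-square,
#'   df, CFI, TLI, RMSEA, ΔCFI and verdict per level; fits attached as an
#'   attribute.
#' @export
invariance_sequence <- function(data_list, model, delta_cutoff = 0.01,
                                cfi_configural = 0.90) {
  if (length(data_list) < 2)
    stop2("invariance testing needs at least 2 groups")
  data_list <- lapply(data_list, function(d)
    if (inherits(d, "survey_dataset")) sem_data(d) else d)
  levels <- c("configural", "metric", "scalar")
  fits <- lapply(levels, function(lv)
    fit_multigroup(data_list, model, level = lv))
  idx <- lapply(fits, fit_indices_mg)
  cfi <- vapply(idx, `[[`, 0, "cfi")
  dcfi <- c(NA, diff(cfi))
  verdict <- c(cfi[1] >= cfi_configural, abs(dcfi[-1]) <= delta_cutoff)
  rep <- data.frame(
    level = levels,
    chisq = vapply(idx, `[[`, 0, "chisq"),
    df = vapply(fits, `[[`, 0, "df"),
    cfi = cfi,
    tli = vapply(idx, `[[`, 0, "tli"),
    rmsea = vapply(idx, `[[`, 0, "rmsea"),
    delta_cfi = dcfi,
    supported = verdict)
  if (any(diff(rep$df) < 0))
    warning("df not non-decreasing across levels", call. = FALSE)
  structure(rep, class = c("invariance_report", "data.frame"), fits = fits)
}

#' @export
print.invariance_report <- function(x, ...) {
  y <- x
  y$chisq <- round(y$chisq, 1)
  for (cn in c("cfi", "tli", "rmsea")) y[[cn]] <- round(y[[cn]], 3)
  y$delta_cfi <- round(y$delta_cfi, 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Common-latent-factor (CLF) comparison for method bias
#'
#' Refits the model with one orthogonal method factor loading equally on all
#' indicators (single shared loading, variance fixed at 1) and reports the
#' largest absolute change in the standardized structural paths relative to
#' the base fit.
#'
#' @param data indicator data matrix (or `survey_dataset`).
#' @param model model text or `sem_model`.
#' @param ... passed to [fit_ml()].
#' @return list with `base`, `clf` (fits), `path_deltas`, `max_change`,
#'   `converged`.
#' @export
fit_with_clf <- function(data, model, ...) {
  if (inherits(data, "survey_dataset")) data <- sem_data(data)
  text <- if (inherits(model, "sem_model")) model$text else
    paste(model, collapse = "\n")
  base <- fit_ml(data, model, ...)
  inds <- base$model$indicators
  clf_text <- paste0(text, "\nlatent CLF =~ ",
                     paste(paste0("clf*", inds), collapse = " + "),
                     "\northogonal CLF")
  clf <- tryCatch(fit_ml(data, clf_text, ...), error = function(e) NULL)
  if (is.null(clf) || !clf$converged) {
    warning("CLF model did not converge; returning base fit", call. = FALSE)
    return(list(base = base, clf = clf, path_deltas = NULL,
                max_change = NA_real_, converged = FALSE))
  }
  pb <- base$standardized$paths
  pc <- clf$standardized$paths
  key <- paste(pb$to, pb$from)
  dl <- pb$std - pc$std[match(key, paste(pc$to, pc$from))]
  deltas <- data.frame(to = pb$to, from = pb$from, base = pb$std,
                       clf = pc$std[match(key, paste(pc$to, pc$from))],
                       delta = dl)
  list(base = base, clf = clf, path_deltas = deltas,
       max_change = max(abs(dl)), converged = TRUE)
}

#' Indicator matrix for SEM from a survey
#'
#' Un-reverses reverse-keyed items and appends a 0/1 `urban` dummy column
#' (1 = urban) when the survey carries a `location` column.
#'
#' @param survey a `survey_dataset`.
#' @param constructs constructs whose items to include (default: all).
#' @return numeric matrix.
#' @export
sem_data <- function(survey, constructs = NULL) {
  map <- survey$construct_map
  if (!is.null(constructs)) map <- map[map$construct %in% constructs, ]
  X <- as.matrix(survey$responses[map$item])
  X[, map$reverse] <- 6 - X[, map$reverse, drop = FALSE]
  if ("location" %in% names(survey$responses))
    X <- cbind(X, urban = as.numeric(survey$responses$location == "urban"))
  X
}
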