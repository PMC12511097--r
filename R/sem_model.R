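#' Compile a structural equation model from a text description
#'
#' The model syntax has one statement per line:
#' \preformatted{
#'   latent CI =~ CI1 + CI2 + CI3     # measurement: latent and indicators
#'   path ATT <- CI                   # structural regression(s)
#'   path PI <- CI + MFSC + ATT + PP
#'   cov MFSC ~~ CI                   # free (disturbance) covariance
#' }
#' A term may be prefixed `value*` (fixed value) or `name*` (shared label,
#' i.e. an equality constraint). Defaults follow common covariance-structure
#' conventions: the first loading of every latent is fixed to 1 (or, with
#' `std_lv = TRUE`, all loadings are free and each latent's (disturbance)
#' variance is fixed to 1); exogenous latents covary freely; disturbances
#' are uncorrelated unless a `cov` line frees them; measurement errors are
#' uncorrelated; a single-indicator latent gets loading 1 and zero
#' measurement error. The structural matrix must be recursive (acyclic).
#'
#' @param text model description (single string or character vector of
#'   lines); lines starting with `#` are ignored.
#' @param std_lv scale latents by fixing their (disturbance) variance to 1
#'   instead of the first loading.
#' @param meanstructure add intercepts (`nu`, free) and latent means
#'   (`alpha`, fixed 0) to the parameter map.
#' @return an object of class `sem_model`.
#' @export
compile_model <- function(text, std_lv = FALSE, meanstructure = FALSE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]

  measurement <- list()   # latent -> character of indicator terms
  paths <- list()         # list(to, terms)
  covs <- list()          # list(a, b)
  ortho <- character(0)   # latents kept orthogonal to everything
  for (ln in lines) {
    if (grepl("^latent\\s+", ln)) {
      body <- sub("^latent\\s+", "", ln)
      parts <- strsplit(body, "=~", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop2("malformed latent statement: ", ln)
      lat <- trimws(parts[1])
      measurement[[lat]] <- c(measurement[[lat]], split_terms(parts[2]))
    } else if (grepl("^path\\s+", ln)) {
      body <- sub("^path\\s+", "", ln)
      parts <- strsplit(body, "<-|~(?!~)", perl = TRUE)[[1]]
      if (length(parts) != 2) stop2("malformed path statement: ", ln)
      paths[[length(paths) + 1]] <- list(to = trimws(parts[1]),
                                         terms = split_terms(parts[2]))
    } else if (grepl("^cov\\s+", ln)) {
      body <- sub("^cov\\s+", "", ln)
      parts <- trimws(strsplit(body, "~~", fixed = TRUE)[[1]])
      if (length(parts) != 2) stop2("malformed cov statement: ", ln)
      covs[[length(covs) + 1]] <- parts
    } else if (grepl("^orthogonal\\s+", ln)) {
      ortho <- c(ortho, trimws(sub("^orthogonal\\s+", "", ln)))
    } else stop2("unrecognized model statement: ", ln)
  }
  if (length(measurement) == 0) stop2("model declares no latent variables")

  latents <- names(measurement)
  indicators <- unique(unlist(lapply(measurement, function(tt)
    vapply(tt, function(t) parse_term(t)$var, ""))))
  m <- length(latents); p <- length(indicators)

  blank <- function(nr, nc, rn, cn) list(
    value = matrix(0, nr, nc, dimnames = list(rn, cn)),
    free  = matrix(FALSE, nr, nc, dimnames = list(rn, cn)),
    label = matrix(NA_character_, nr, nc, dimnames = list(rn, cn)))
  Lambda <- blank(p, m, indicators, latents)
  B      <- blank(m, m, latents, latents)
  Psi    <- blank(m, m, latents, latents)
  Theta  <- blank(p, 1, indicators, "theta")

  scaled_by_loading <- stats::setNames(logical(m), latents)
  for (lat in latents) {
    terms <- lapply(measurement[[lat]], parse_term)
    has_fixed <- any(vapply(terms, function(t)
      !is.null(t$fixed) && t$fixed != 0, NA))
    can_fix_first <- !has_fixed && !std_lv
    for (tm in terms) {
      i <- tm$var
      if (!is.null(tm$fixed)) {
        Lambda$value[i, lat] <- tm$fixed
      } else if (!is.null(tm$label)) {
        Lambda$free[i, lat] <- TRUE
        Lambda$label[i, lat] <- tm$label
        Lambda$value[i, lat] <- 1
      } else if (length(terms) == 1 || can_fix_first) {
        Lambda$value[i, lat] <- 1          # scale indicator
        can_fix_first <- FALSE
        scaled_by_loading[lat] <- TRUE
      } else {
        Lambda$free[i, lat] <- TRUE
        Lambda$label[i, lat] <- paste0(lat, "=~", i)
        Lambda$value[i, lat] <- 1
      }
    }
    if (has_fixed || length(terms) == 1) scaled_by_loading[lat] <- TRUE
  }
  for (ph in paths) {
    if (!ph$to %in% latents) stop2("path to unknown latent: ", ph$to)
    for (tm0 in ph$terms) {
      tm <- parse_term(tm0)
      if (!tm$var %in% latents) stop2("path from unknown latent: ", tm$var)
      if (!is.null(tm$fixed)) {
        B$value[ph$to, tm$var] <- tm$fixed
      } else {
        B$free[ph$to, tm$var] <- TRUE
        B$label[ph$to, tm$var] <- tm$label %||% paste0(ph$to, "~", tm$var)
      }
    }
  }
  # acyclicity check via topological elimination
  adj <- (B$free | B$value != 0)
  left <- latents
  repeat {
    srcs <- left[rowSums(adj[left, left, drop = FALSE]) == 0]
    if (length(srcs) == 0) break
    left <- setdiff(left, srcs)
  }
  if (length(left) > 0)
    stop2("structural model is cyclic (involves: ",
          paste(left, collapse = ", "), ")")

  exo <- latents[!latents %in% latents[rowSums(B$free | B$value != 0) > 0]]
  # variances: free (log-parameterized) unless the latent's scale is set by
  # fixing its variance (std_lv, or no fixed loading available)
  for (l in latents) {
    if (!scaled_by_loading[l]) {
      Psi$value[l, l] <- 1
    } else {
      Psi$free[l, l] <- TRUE
      Psi$label[l, l] <- paste0(l, "~~", l)
      Psi$value[l, l] <- 1
    }
  }
  # exogenous latents covary freely by default (orthogonal ones excepted)
  exo_cov <- setdiff(exo, ortho)
  if (length(exo_cov) > 1) {
    for (i in 2:length(exo_cov)) for (j in 1:(i - 1)) {
      a <- exo_cov[i]; b <- exo_cov[j]
      Psi$free[a, b] <- Psi$free[b, a] <- TRUE
      Psi$label[a, b] <- Psi$label[b, a] <- paste0(b, "~~", a)
    }
  }
  for (cv in covs) {
    a <- cv[1]; b <- cv[2]
    if (!all(c(a, b) %in% latents)) stop2("cov between unknown latents: ",
                                          a, " ~~ ", b)
    Psi$free[a, b] <- Psi$free[b, a] <- TRUE
    Psi$label[a, b] <- Psi$label[b, a] <- paste0(b, "~~", a)
  }
  # measurement error variances; zero (fixed) for single-indicator latents
  single <- unlist(lapply(latents, function(l)
    if (length(measurement[[l]]) == 1) parse_term(measurement[[l]][1])$var))
  for (i in indicators) {
    if (i %in% single) {
      Theta$value[i, 1] <- 0
    } else {
      Theta$free[i, 1] <- TRUE
      Theta$label[i, 1] <- paste0(i, "~~", i)
      Theta$value[i, 1] <- 0.5
    }
  }
  nu <- alpha <- NULL
  if (meanstructure) {
    nu <- list(value = stats::setNames(numeric(p), indicators),
               free = stats::setNames(rep(TRUE, p), indicators),
               label = stats::setNames(paste0(indicators, "~1"), indicators))
    alpha <- list(value = stats::setNames(numeric(m), latents),
                  free = stats::setNames(rep(FALSE, m), latents),
                  label = stats::setNames(rep(NA_character_, m), latents))
  }
  mod <- structure(list(
    latents = latents, indicators = indicators, exogenous = exo,
    Lambda = Lambda, B = B, Psi = Psi, Theta = Theta,
    nu = nu, alpha = alpha, meanstructure = meanstructure,
    measurement = measurement, orthogonal = ortho,
    text = paste(lines, collapse = "\n"), std_lv = std_lv
  ), class = "sem_model")
  mod$params <- param_table(mod)
  mod
}

split_terms <- function(x) {
  tt <- trimws(unlist(strsplit(x, "[+[:space:]]+")))
  tt[nzchar(tt)]
}

# A term is `var`, `3*var` (fixed) or `lab*var` (labelled/equality).
parse_term <- function(t) {
  if (grepl("*", t, fixed = TRUE)) {
    parts <- trimws(strsplit(t, "*", fixed = TRUE)[[1]])
    pre <- parts[1]; var <- parts[2]
    val <- suppressWarnings(as.numeric(pre))
    if (!is.na(val)) return(list(var = var, fixed = val, label = NULL))
    return(list(var = var, fixed = NULL, label = pre))
  }
  list(var = t, fixed = NULL, label = NULL)
}

# Free-parameter table: one row per location, grouped by label. Variance
# parameters (Psi diagonal, Theta) are flagged for log-parameterization.
param_table <- function(mod) {
  rows <- list()
  add <- function(mat, name, variance = FALSE) {
    idx <- which(mat$free, arr.ind = TRUE)
    if (length(idx) == 0) return()
    if (is.null(dim(idx))) idx <- matrix(idx, ncol = 2)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (name == "Psi" && j > i) next      # symmetric: keep lower triangle
      rows[[length(rows) + 1]] <<- data.frame(
        label = mat$label[i, j], matrix = name, row = i, col = j,
        variance = variance || (name == "Psi" && i == j),
        start = mat$value[i, j])
    }
  }
  add(mod$Lambda, "Lambda")
  add(mod$B, "B")
  add(mod$Psi, "Psi")
  add(mod$Theta, "Theta", variance = TRUE)
  if (mod$meanstructure) {
    for (i in which(mod$nu$free))
      rows[[length(rows) + 1]] <- data.frame(
        label = mod$nu$label[i], matrix = "nu", row = i, col = 1L,
        variance = FALSE, start = mod$nu$value[i])
    for (i in which(mod$alpha$free))
      rows[[length(rows) + 1]] <- data.frame(
        label = mod$alpha$label[i], matrix = "alpha", row = i, col = 1L,
        variance = FALSE, start = mod$alpha$value[i])
  }
  tab <- do.call(rbind, rows)
  tab$label <- as.character(tab$label)
  tab
}

#' Free parameters of a compiled model
#' @param mod a `sem_model`.
#' @return character vector of unique parameter labels.
#' @export
free_params <- function(mod) unique(mod$params$label)

#' Model degrees of freedom against a sample of size p indicators
#' @param mod a `sem_model`.
#' @return degrees of freedom (sample moments minus free parameters).
#' @export
model_df <- function(mod) {
  p <- length(mod$indicators)
  mom <- p * (p + 1) / 2 + if (mod$meanstructure) p else 0
  mom - length(free_params(mod))
}

#' @export
print.sem_model <- function(x, ...) {
  cat("<sem_model>", length(x$latents), "latents,",
      length(x$indicators), "indicators,",
      length(free_params(x)), "free parameters, df =", model_df(x), "\n")
  st <- x$params[x$params$matrix == "B", "label"]
  if (length(st)) cat("  structural:", paste(unique(st), collapse = ", "), "\n")
  invisible(x)
}
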