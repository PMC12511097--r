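#' Generate latent construct scores for synthetic respondents
#'
#' Draws `n` respondents with demographics (urban/rural location, age group)
#' and latent construct scores on the 1-5 scale. The latent scores follow
#' the spec's generating correlation matrix; the medicine-food separation
#' cognition (MFSC) score of urban respondents is shifted upward so that the
#' standardized urban-context effect equals the configured value, with the
#' shift applied mean-centred and the Gaussian residual variance reduced so
#' that the marginal latent moments match the generating matrix exactly.
#'
#' @param spec a [build_population_spec()] object.
#' @param n number of respondents (>= 2).
#' @param seed integer seed; output is deterministic given (spec, n, seed).
#' @return data.frame with columns `id`, `location`, `age_group` and one
#'   latent score column per construct (not clipped to the response range).
#' @export
generate_respondents <- function(spec, n, seed = 1) {
  if (!inherits(spec, "population_spec")) stop2("spec must be a population_spec")
  if (n < 2) stop2("n must be at least 2")
  set.seed(as.integer(seed %% 2147483647))
  p <- spec$urban_prop
  urban <- stats::rbinom(n, 1, p)
  age <- sample(names(spec$age_props), n, TRUE, spec$age_props)
  sdu <- sqrt(p * (1 - p))
  U <- if (sdu > 0) (urban - p) / sdu else rep(0, n)

  cn <- spec$names
  u_load <- attr(spec$R_latent, "u_load")
  if (is.null(u_load)) u_load <- stats::setNames(numeric(length(cn)), cn)
  Sig_g <- spec$R_latent - tcrossprod(u_load)  # Gaussian residual covariance
  Z <- rmvnorm0(n, Sig_g) + tcrossprod(U, u_load)
  colnames(Z) <- cn

  lat <- sweep(sweep(Z, 2, spec$sds, `*`), 2, spec$means, `+`)
  out <- data.frame(id = seq_len(n),
                    location = ifelse(urban == 1, "urban", "rural"),
                    age_group = age, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(lat))
}

#' Discretize latent construct scores into Likert item responses
#'
#' Each item is a linear combination of the construct's latent z-score and
#' independent Gaussian noise (weights `loading` and `sqrt(1 - loading^2)`),
#' shifted by the construct's calibrated mean offset and cut at the spec's
#' thresholds into the categories 1-5. Generating loadings are calibrated at
#' spec-build time so that the *observed* standardized loadings match the
#' requested values after discretization. Reverse-keyed items are recorded
#' flipped (`6 - score`). With `likert = FALSE` in the spec the items stay
#' continuous on the construct scale (a loading of 1 then reproduces the
#' latent score exactly).
#'
#' @param latent data.frame from [generate_respondents()] (or any data.frame
#'   containing the construct columns).
#' @param spec the population spec used to generate `latent`.
#' @param seed integer seed for the item noise.
#' @return a `survey_dataset`: list with `responses` (item columns plus
#'   `id`, `location`, `age_group` when present), `construct_map`
#'   (item/construct/reverse), `spec`, `seed`.
#' @export
latent_to_likert <- function(latent, spec, seed = 1) {
  if (!inherits(spec, "population_spec")) stop2("spec must be a population_spec")
  set.seed(as.integer(seed %% 2147483647))
  n <- nrow(latent)
  th <- spec$thresholds
  items <- list()
  map <- list()
  for (cnm in spec$names) {
    if (!cnm %in% names(latent)) stop2("latent table lacks construct ", cnm)
    con <- spec$constructs[[cnm]]
    cal <- spec$calib[[cnm]]
    k <- length(con$loadings)
    if (k < 1) stop2("no loadings defined for construct ", cnm)
    z <- (latent[[cnm]] - con$mean) / (con$sd %||% 1)
    rev_idx <- con$reverse %||% integer(0)
    for (i in seq_len(k)) {
      nm <- paste0(cnm, i)
      if (spec$likert) {
        lam <- cal$lambda_gen[i]
        if (is.na(lam)) stop2("missing loading for item ", nm)
        v <- cal$mu_z + lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
        score <- findInterval(v, th) + 1L
      } else {
        lam <- con$loadings[i]
        score <- con$mean + (con$sd %||% 1) *
          (lam * z + sqrt(1 - lam^2) * stats::rnorm(n))
      }
      rev <- i %in% rev_idx
      if (rev) score <- 6 - score
      items[[nm]] <- score
      map[[nm]] <- data.frame(item = nm, construct = cnm, reverse = rev,
                              stringsAsFactors = FALSE)
    }
  }
  responses <- as.data.frame(items)
  for (dcol in c("id", "location", "age_group"))
    if (dcol %in% names(latent)) responses[[dcol]] <- latent[[dcol]]
  structure(list(responses = responses,
                 construct_map = do.call(rbind, unname(map)),
                 spec = spec, seed = seed),
            class = "survey_dataset")
}

#' Generate a complete synthetic survey
#'
#' Composes [build_population_spec()], [generate_respondents()] and
#' [latent_to_likert()]. Deterministic given `(config, n, seed)`.
#'
#' @param n number of respondents; defaults to the study sample size 1076.
#' @param seed integer seed.
#' @param config configuration list or YAML path (see
#'   [default_population_config()]); ignored when `spec` is given.
#' @param spec optionally a prebuilt population spec (saves recalibration
#'   when generating many replicate surveys).
#' @return a `survey_dataset`; the latent table is attached as
#'   `$latent`.
#' @export
generate_survey <- function(n = 1076, seed = 1, config = list(), spec = NULL) {
  if (is.null(spec)) spec <- build_population_spec(config)
  lat <- generate_respondents(spec, n, seed = child_seed(seed, 1))
  sv <- latent_to_likert(lat, spec, seed = child_seed(seed, 2))
  sv$latent <- lat
  sv$seed <- seed
  sv
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>", nrow(x$responses), "respondents,",
      nrow(x$construct_map), "items,",
      length(unique(x$construct_map$construct)), "constructs\n")
  cat("  constructs:", paste(unique(x$construct_map$construct),
                             collapse = ", "), "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Write a survey to CSV with a JSON sidecar
#'
#' The CSV holds one row per respondent (item columns named
#' `<construct><index>`, plus `location` and `age_group`); the sidecar JSON
#' carries the construct map and generation metadata (seed, spec hash).
#'
#' @param survey a `survey_dataset`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey$responses, path, row.names = FALSE)
  meta <- list(construct_map = survey$construct_map,
               seed = survey$seed,
               spec_hash = spec_hash(survey$spec),
               generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a survey written by [write_survey()]
#' @param path CSV path (expects `<path>.meta.json` alongside).
#' @return a `survey_dataset` (without the generating spec).
#' @export
read_survey <- function(path) {
  responses <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(list(responses = responses,
                 construct_map = as.data.frame(meta$construct_map),
                 spec = NULL, seed = meta$seed),
            class = "survey_dataset")
}

# Stable content hash of the generating parameters (md5 of a canonical dump).
spec_hash <- function(spec) {
  if (is.null(spec)) return(NA_character_)
  key <- list(means = spec$means, sds = spec$sds, R = round(spec$R_target, 10),
              urban = spec$urban_prop, ages = spec$age_props,
              eff = spec$urban_effect, regime = spec$regime,
              likert = spec$likert,
              loadings = lapply(spec$constructs, function(x) x$loadings))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(key, digits = NA), tf)
  unname(tools::md5sum(tf))
}
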