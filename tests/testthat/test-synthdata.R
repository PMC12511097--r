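test_that("population spec holds the published targets and validates input", {
  spec <- default_spec_cached()
  expect_equal(spec$R_target["CI", "ATT"], 0.652)
  expect_equal(spec$R_target["MFSC", "FN"], 0.237)
  expect_equal(spec$urban_prop, 0.546)
  expect_equal(unname(spec$age_props["26-40"]), 0.451)
  expect_equal(spec$urban_effect, 0.26)

  expect_error(build_population_spec(list(age_props = c(a = 0.5, b = 0.4))),
               "sum to 1")
  expect_error(build_population_spec(list(urban_prop = 1.2)), "fraction")
  bad <- diag(9); bad[1, 2] <- 0.5   # asymmetric
  expect_error(build_population_spec(list(correlation_matrix = bad)),
               "symmetric")
  bad2 <- diag(9); bad2[1, 2] <- bad2[2, 1] <- 1.4
  expect_error(build_population_spec(list(correlation_matrix = bad2)),
               "\\[-1, 1\\]")
})

test_that("nearest-PD repair clips negative eigenvalues and is idempotent on PD input", {
  ok <- nearest_pd(diag(3))
  expect_equal(ok$max_delta, 0)
  expect_identical(ok$mat, diag(3))

  R <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3, 3)
  expect_lt(min(eigen(R)$values), 0)           # oracle: input is indefinite
  rep <- nearest_pd(R)
  expect_gte(min(eigen(rep$mat)$values), 0)
  expect_equal(diag(rep$mat), rep(1, 3))
  expect_gt(rep$max_delta, 0)
})

test_that("respondent generation reproduces demographics and the urban MFSC shift", {
  spec <- default_spec_cached()
  lat <- generate_respondents(spec, 1076, seed = 11)
  expect_equal(mean(lat$location == "urban"), 0.546,
               tolerance = 3 * sqrt(0.546 * 0.454 / 1076) / 0.546)
  expect_true(all(lat$age_group %in% names(spec$age_props)))

  # standardized urban effect: latent group difference = 0.26 / sd(dummy)
  big <- generate_respondents(spec, 60000, seed = 2)
  d <- mean(big$MFSC[big$location == "urban"]) -
    mean(big$MFSC[big$location == "rural"])
  expect_lt(abs(d - 0.26 / sqrt(0.546 * 0.454)), 0.03)

  # no-effect configuration: group means equal in expectation
  spec0 <- build_population_spec(list(urban_effect = 0))
  b0 <- generate_respondents(spec0, 60000, seed = 3)
  d0 <- mean(b0$MFSC[b0$location == "urban"]) -
    mean(b0$MFSC[b0$location == "rural"])
  expect_lt(abs(d0), 0.02)

  expect_error(generate_respondents(spec, 1), "at least 2")
})

test_that("large-sample latent correlations match the generating matrix", {
  spec <- default_spec_cached()
  lat <- generate_respondents(spec, 100000, seed = 5)
  Rhat <- cor(as.matrix(lat[spec$names]))
  expect_lt(max(abs(Rhat - spec$R_latent)), 0.01)
})

test_that("likert discretization is monotone, reversible and deterministic", {
  spec <- default_spec_cached()
  lat <- generate_respondents(spec, 400, seed = 7)
  sv1 <- latent_to_likert(lat, spec, seed = 9)
  sv2 <- latent_to_likert(lat, spec, seed = 9)
  expect_identical(sv1$responses, sv2$responses)
  expect_true(all(as.matrix(sv1$responses[sv1$construct_map$item]) %in% 1:5))
  # reverse-keyed items recorded flipped: at a latent high extreme the
  # recorded response is 1
  lat_hi <- lat
  lat_hi$MFSC <- 50       # far above any threshold
  hi <- latent_to_likert(lat_hi, spec, seed = 9)
  expect_true(all(hi$responses$MFSC1 == 1))
  # monotonicity: raising the latent never lowers a non-reversed response
  lat_up <- lat
  lat_up$PI <- lat$PI + 1
  up <- latent_to_likert(lat_up, spec, seed = 9)
  expect_true(all(up$responses$PI1 >= sv1$responses$PI1))
  expect_error(latent_to_likert(lat["id"], spec, seed = 1), "lacks construct")
})

test_that("continuous mode with unit loading reproduces the latent score", {
  cfg <- list(constructs = list(
    list(name = "CI", mean = 3.8, sd = 1, loadings = c(0.99999))),
    correlations = list(), likert = FALSE,
    structural = c(URBAN_MFSC = 0))
  spec <- build_population_spec(cfg)
  lat <- generate_respondents(spec, 200, seed = 1)
  sv <- latent_to_likert(lat, spec, seed = 2)
  expect_equal(sv$responses$CI1, lat$CI, tolerance = 0.005)
})

test_that("default survey reproduces the purchase-intention anchors and marker independence", {
  spec <- default_spec_cached()
  sv <- generate_survey(1076, seed = 21, spec = spec)
  pi_comp <- composite_scores(sv, "PI")
  expect_lt(abs(mean(pi_comp) - 3.73), 0.1)

  sv2 <- generate_survey(1076, seed = 21, spec = spec)
  expect_identical(sv$responses, sv2$responses)   # determinism contract

  mk <- marker_check(sv)
  expect_true(mk$pass)
  expect_lt(mk$max_abs_r, 0.15)
})

test_that("observed reliability structure matches the requested loadings", {
  # generating loadings are calibrated so lambda^2 ~ AVE survives the cut
  cfg <- default_population_config()
  cfg$constructs[[1]]$loadings <- rep(0.88, 3)   # CI: lambda^2 = 0.7744
  spec <- build_population_spec(cfg)
  sv <- generate_survey(5000, seed = 31, spec = spec)
  X <- as.matrix(sv$responses[paste0("CI", 1:3)])
  r <- cor(X)
  ave_hat <- mean(r[upper.tri(r)])    # equal loadings: AVE = mean inter-item r
  expect_lt(abs(ave_hat - 0.778), 0.05)
})

test_that("composite correlations recover the published matrix at scale (corr-matched)", {
  spec <- corr_spec_cached()
  sv <- generate_survey(100000, seed = 41, spec = spec)
  comp <- composite_scores(sv)
  Rhat <- cor(comp)
  err <- abs(Rhat - spec$R_target)
  diag(err) <- 0
  expect_lt(max(err), 0.02)
})

test_that("survey round-trips through CSV with its sidecar", {
  spec <- default_spec_cached()
  sv <- generate_survey(60, seed = 51, spec = spec)
  tf <- file.path(tempdir(), "survey_roundtrip.csv")
  write_survey(sv, tf)
  back <- read_survey(tf)
  expect_equal(back$responses$PI1, sv$responses$PI1)
  expect_equal(back$construct_map$construct, sv$construct_map$construct)
  expect_equal(back$seed, sv$seed)
  unlink(c(tf, paste0(tf, ".meta.json")))
})
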