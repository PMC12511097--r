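test_that("network construction is deterministic, connected and heavy-tailed", {
  net <- build_network(1000, m = 3, seed = 7)
  net2 <- build_network(1000, m = 3, seed = 7)
  expect_identical(net$edges, net2$edges)

  # scale-free degree distribution: hub degree far above the median
  expect_gt(max(net$degree), 10 * stats::median(net$degree))
  expect_true(all(net$degree >= 1))

  tiny <- build_network(2, m = 1, seed = 1)
  expect_equal(nrow(tiny$edges), 1)

  expect_error(build_network(3, m = 3), "n > m")

  tf <- file.path(tempdir(), "net.csv")
  write_network(net, tf)
  back <- read_network(tf)
  expect_equal(back$degree, net$degree)
  unlink(tf)
})

test_that("agent initialization matches the population spec and survey moments", {
  spec <- default_spec_cached()
  net <- build_network(2000, 3, seed = 1)
  pop <- init_agents(spec, net, seed = 2)
  expect_true(all(pop$states >= 1 & pop$states <= 5))
  # core 26-55 band: 45.1% + 24.9% of agents
  expect_equal(mean(pop$age_group %in% c("26-40", "41-55")), 0.451 + 0.249,
               tolerance = 0.05)
  expect_equal(unname(colMeans(pop$states)["ATT"]), 3.7, tolerance = 0.08)

  # degenerate spec: zero variance collapses all agents to the same state
  cfg <- default_population_config()
  for (i in seq_along(cfg$constructs)) cfg$constructs[[i]]$sd <- 1e-12
  pop0 <- init_agents(build_population_spec(cfg), net, seed = 3)
  expect_lt(max(apply(pop0$states, 2, stats::sd)), 1e-6)

  # survey-derived initialization matches the survey's composite means
  sv <- generate_survey(1076, seed = 4, spec = spec)
  popS <- init_agents(sv, net, seed = 5)
  comp <- composite_scores(sv, c("CI", "MFSC", "ATT", "PP"))
  expect_equal(unname(colMeans(popS$states)),
               unname(pmin(pmax(colMeans(comp), 1), 5)), tolerance = 0.05)
})

test_that("a single step follows the update rules exactly", {
  # two agents, one edge; tau = 0.05, mean mode: 3.0 with neighbour 4.0
  # moves to 3.05; the higher agent stays put
  net <- build_network(2, 1, seed = 1)
  pop <- structure(list(
    states = cbind(CI = c(3, 4), MFSC = c(3, 3), ATT = c(3.7, 3.7),
                   PP = c(3.2, 3.2)),
    location = c("urban", "rural"), age_group = c("26-40", "26-40"),
    pi = rep(NA_real_, 2), purchased = c(FALSE, FALSE), network = net,
    mu = c(CI = 3.8, MFSC = 3, ATT = 3.7, PP = 3.2),
    sd = c(CI = 1, MFSC = 1, ATT = 1, PP = 1)), class = "agent_population")
  par <- simulation_params(tau = 0.05, sigma = 0, threshold_sd = 0,
                           seed = 1)
  out <- step_population(pop, par)
  expect_equal(unname(out$states[, "CI"]), c(3.05, 4))

  # tau = 0, sigma = 0: states constant, PI a deterministic function
  par0 <- simulation_params(tau = 0, sigma = 0, threshold_sd = 0, seed = 1)
  out0 <- step_population(pop, par0)
  expect_equal(out0$states, pop$states)
  z <- (pop$states - matrix(pop$mu, 2, 4, byrow = TRUE))
  expected_pi <- pmin(pmax(3.73 + 1.07 * drop(z %*% par0$betas), 1), 5)
  expect_equal(out0$pi, expected_pi)

  # sum mode aggregates rather than averages
  par_s <- simulation_params(tau = 0.05, sigma = 0, threshold_sd = 0,
                             diffusion = "sum", seed = 1)
  out_s <- step_population(pop, par_s)
  expect_equal(unname(out_s$states[1, "CI"]), 3.05)  # degree-1 node: equal
})

test_that("simulation runs are deterministic, bounded and ratcheting", {
  spec <- default_spec_cached()
  par <- simulation_params(n_agents = 400, steps = 60, seed = 9)
  r1 <- run_simulation(par, spec = spec)
  r2 <- run_simulation(par, spec = spec)
  expect_identical(r1$series, r2$series)

  expect_true(all(r1$final$states >= 1 & r1$final$states <= 5))
  expect_true(all(r1$series$purchase_rate >= 0 &
                  r1$series$purchase_rate <= 1))
  # population-mean CI is non-decreasing (upward-gated diffusion)
  expect_true(all(diff(r1$series$mean_ci) >= -1e-12))

  # tau = 0: the CI field is a fixed point
  par0 <- simulation_params(tau = 0, n_agents = 400, steps = 40, seed = 9)
  r0 <- run_simulation(par0, spec = spec)
  expect_equal(diff(range(r0$series$mean_ci)), 0)

  # boundedness holds at the top of the admissible tau range
  parX <- simulation_params(tau = 0.2, n_agents = 300, steps = 50,
                            diffusion = "sum", seed = 5)
  rX <- run_simulation(parX, spec = spec)
  expect_true(all(rX$final$states >= 1 & rX$final$states <= 5))

  # per-agent ratchet in mean mode
  net <- build_network(300, 3, seed = 11)
  pop <- init_agents(spec, net, seed = 12)
  par_m <- simulation_params(tau = 0.1, sigma = 0, threshold_sd = 0, seed = 1)
  before <- pop$states[, "CI"]
  after <- step_population(pop, par_m)$states[, "CI"]
  expect_true(all(after - before >= -1e-12))
})

test_that("calibration reports the pattern table and a unique argmin", {
  spec <- default_spec_cached()
  par <- simulation_params(n_agents = 300, steps = 40, seed = 3)
  cal <- calibrate_tau(tau_grid = c(0.01, 0.05, 0.1), replicates = 2,
                       params = par, spec = spec)
  expect_equal(nrow(cal$table), 3)
  expect_true(cal$best_tau %in% cal$table$tau)
  expect_equal(sum(cal$table$distance == min(cal$table$distance)), 1)

  # pattern equal to the no-diffusion steady state: smallest tau wins
  p0 <- simulation_params(tau = 0, n_agents = 300, steps = 40, seed = 3)
  base <- tail_summary(run_simulation(p0, spec = spec))
  cal0 <- calibrate_tau(tau_grid = c(0.01, 0.05, 0.1),
                        targets = c(mean = base[["mean_pi"]],
                                    sd = base[["sd_pi"]]),
                        replicates = 2, params = par, spec = spec)
  expect_equal(cal0$best_tau, 0.01)

  expect_error(calibrate_tau(tau_grid = numeric(0)), "empty")
  expect_error(calibrate_tau(tau_grid = 0.5), "within")
})

test_that("interventions are null at zero dose and monotone in the dose", {
  spec <- default_spec_cached()
  par <- simulation_params(n_agents = 400, steps = 50, seed = 17)
  ex0 <- intervention_experiment(par, delta_ci = 0, replicates = 2,
                                 spec = spec)
  expect_equal(ex0$uplift_vs_control, 0, tolerance = 1e-12)

  ex1 <- intervention_experiment(par, delta_ci = 0.1, replicates = 3,
                                 spec = spec)
  ex2 <- intervention_experiment(par, delta_ci = 0.2, replicates = 3,
                                 spec = spec)
  expect_gt(ex1$uplift_vs_control, 0)
  expect_gte(ex2$uplift_vs_control, ex1$uplift_vs_control)
  # the intervention does not fatten the lower tail
  expect_lte(ex1$lower_tail[["treated"]], ex1$lower_tail[["control"]] + 1e-9)

  expect_error(intervention_experiment(par, delta_ci = -0.1), "non-negative")
  expect_error(intervention_experiment(par, target_ages = character(0)),
               "empty")
})

test_that("the sensitivity sweep tabulates uplift per transmission rate", {
  spec <- default_spec_cached()
  par <- simulation_params(n_agents = 300, steps = 40, seed = 19)
  one <- sensitivity_sweep(taus = 0.05, params = par, replicates = 2,
                           spec = spec)
  expect_equal(nrow(one), 1)
  expect_true(all(c("uplift_vs_baseline", "uplift_vs_control",
                    "uplift_vs_baseline_se") %in% names(one)))
  expect_error(sensitivity_sweep(taus = c(-0.1, 0.05)), "non-negative")
})
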