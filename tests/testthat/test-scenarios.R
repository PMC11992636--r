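# Interventions, replicated experiments, sensitivity and calibration.

test_that("interventions set the documented multipliers", {
  p <- apply_intervention(default_params(), "none")
  expect_equal(unlist(p$intervention), c(hl_mult = 1, social_mult = 1,
                                         barrier_mult = 1, distance_mult = 1))
  aw <- apply_intervention(default_params(), "awareness")
  expect_equal(aw$intervention$hl_mult, 1.2)
  expect_equal(aw$intervention$social_mult, 1.15)
  # awareness on a literacy score of 0.5 gives 0.6
  expect_equal(min(1, 0.5 * aw$intervention$hl_mult), 0.6)
  ac <- apply_intervention(default_params(), "access")
  expect_equal(ac$intervention$barrier_mult, 0.70)
  expect_equal(ac$intervention$distance_mult, 0.75)
  # access on barriers 1.0 and a 10 km distance
  expect_equal(1.0 * ac$intervention$barrier_mult, 0.7)
  expect_equal(10 * ac$intervention$distance_mult, 7.5)
  expect_error(apply_intervention(default_params(), "banana"), "unknown")
})

test_that("scenario specs validate their fields", {
  sp <- scenario("gilgandra", "hbm", "none", 100, 2, 5)
  expect_equal(sp$theories, "hbm")
  expect_error(scenario(theories = character(0)), "non-empty")
  expect_error(scenario(replications = 0), "replications")
})

test_that("experiments aggregate replications with normal-approximation CIs", {
  cfg <- tiny_config(n_agents = 100)
  ex <- run_experiment(scenario(cfg, replications = 3, horizon = 500, base_seed = 1))
  expect_equal(nrow(ex$summaries), 3)
  expect_equal(ex$summaries$seed, 1:3)
  st <- ex$stats[ex$stats$metric == "n_diagnosed", ]
  expect_equal(st$mean, mean(ex$summaries$n_diagnosed))
  # one replication: the CI collapses onto the point estimate
  ex1 <- run_experiment(scenario(cfg, replications = 1, horizon = 300, base_seed = 9))
  st1 <- ex1$stats[ex1$stats$metric == "late_rate", ]
  expect_equal(st1$ci_lower, st1$mean)
  expect_equal(st1$ci_upper, st1$mean)
})

test_that("pooled means over disjoint seed blocks equal the weighted block means", {
  cfg <- tiny_config(n_agents = 100)
  a <- run_experiment(scenario(cfg, replications = 2, horizon = 400, base_seed = 1))
  b <- run_experiment(scenario(cfg, replications = 2, horizon = 400, base_seed = 3))
  ab <- run_experiment(scenario(cfg, replications = 4, horizon = 400, base_seed = 1))
  expect_equal(mean(c(a$summaries$n_diagnosed, b$summaries$n_diagnosed)),
               mean(ab$summaries$n_diagnosed))
})

test_that("experiment reproducibility: same spec and base seed, same summary", {
  cfg <- tiny_config(n_agents = 80)
  sp <- scenario(cfg, replications = 2, horizon = 300, base_seed = 4)
  expect_identical(run_experiment(sp)$summaries, run_experiment(sp)$summaries)
})

test_that("sensitivity reports zero change for null and inactive perturbations", {
  cfg <- tiny_config(n_agents = 80)
  sens <- ofat_sensitivity(target_params = "behavior.decision.risk",
                           perturbations = 0, runs_per_setting = 2,
                           region = cfg, horizon = 400, n_agents = NULL,
                           metric = "n_diagnosed", seed = 2)
  expect_true(all(sens$changes$pct_change == 0))
  # a zero weight stays zero under relative perturbation: no output change
  p0 <- default_params()
  p0$behavior$decision[["efficacy"]] <- 0
  sens0 <- ofat_sensitivity(p0, target_params = "behavior.decision.efficacy",
                            perturbations = c(-0.2, 0.2), runs_per_setting = 2,
                            region = cfg, horizon = 400, n_agents = NULL,
                            metric = "n_diagnosed", seed = 2)
  expect_true(all(sens0$changes$pct_change == 0))
  expect_true(all(is.finite(sens0$by_param$iqr_half_width)))
})

test_that("calibration returns near-zero objective when targets are already met", {
  cfg <- tiny_config(n_agents = 120, undiagnosed = 0.4)
  base <- run_experiment(scenario(cfg, replications = 2, horizon = 600, base_seed = 1001))
  tgt <- base$stats[base$stats$metric == "late_rate", "mean"]
  targets <- data.frame(metric = "late_rate", target = tgt, tolerance = 5)
  fit <- calibrate_params(targets, list("care.q_mild" = c(0.5, 0.9)),
                          budget = 4, seed = 0, region = cfg,
                          horizon = 600, replications = 2, n_agents = NULL)
  expect_true(fit$converged)
  expect_lt(fit$objective, 4)
  expect_error(calibrate_params(targets[0, ], list("care.q_mild" = c(0, 1)),
                                region = cfg), "non-empty")
})

test_that("a hospital-share target of 100% drives q_mild towards zero", {
  cfg <- tiny_config(n_agents = 60, undiagnosed = 0.5)
  targets <- data.frame(metric = "hospital_share", target = 100, tolerance = 2)
  fit <- calibrate_params(targets, list("care.q_mild" = c(0, 1)),
                          budget = 20, seed = 3, region = cfg,
                          horizon = 500, replications = 2, n_agents = NULL)
  best_q <- fit$params$care$q_mild
  expect_lt(best_q, 0.35)
})
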