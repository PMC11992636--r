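# Daily loop, determinism, conservation and result summaries.

test_that("identical (config, params, seed) give identical results", {
  cfg <- tiny_config(n_agents = 100)
  r1 <- run_simulation(cfg, horizon = 400, seed = 7)
  r2 <- run_simulation(cfg, horizon = 400, seed = 7)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$diagnoses, r2$diagnoses)
  expect_identical(r1$visits, r2$visits)
  r3 <- run_simulation(cfg, horizon = 400, seed = 8)
  expect_false(identical(r1$diagnoses, r3$diagnoses))  # stochasticity smoke test
})

test_that("a world without diabetics produces no diagnosis or visit events", {
  cfg <- tiny_config(n_agents = 60, undiagnosed = 0, diagnosed = 0)
  res <- run_simulation(cfg, horizon = 200, seed = 1)
  expect_equal(nrow(res$diagnoses), 0)
  expect_equal(nrow(res$visits), 0)
  expect_true(all(res$series$undiagnosed == 0))
})

test_that("an urgent undiagnosed agent is hospital-diagnosed on the first day", {
  cfg <- tiny_config(n_agents = 30, undiagnosed = 1, diagnosed = 0)
  p <- default_params()
  p$init$si_max <- 0.999  # some agents start past the urgent threshold
  res <- run_simulation(cfg, p, horizon = 1, seed = 2)
  urgent0 <- res$diagnoses[res$diagnoses$si_at_diagnosis >= p$disease$s_urgent, ]
  expect_gt(nrow(urgent0), 0)
  expect_true(all(urgent0$day == 1))
  expect_true(all(urgent0$provider_kind == "hospital"))
  expect_true(all(!urgent0$planned))
})

test_that("horizon zero returns initial counts only", {
  cfg <- tiny_config(n_agents = 50)
  res <- run_simulation(cfg, horizon = 0, seed = 1)
  expect_equal(nrow(res$series), 0)
  expect_equal(nrow(res$diagnoses), 0)
  expect_equal(res$meta$n_undiagnosed_initial, 25)
})

test_that("every diagnosis appears exactly once in kind and planned tallies", {
  cfg <- tiny_config(n_agents = 120, undiagnosed = 0.4)
  res <- run_simulation(cfg, horizon = 1500, seed = 3)
  dg <- res$diagnoses
  expect_gt(nrow(dg), 0)
  expect_equal(anyDuplicated(dg$agent), 0)  # each agent diagnosed at most once
  expect_equal(sum(dg$provider_kind == "hospital") +
                 sum(dg$provider_kind == "medical_center"), nrow(dg))
  expect_equal(sum(dg$planned) + sum(!dg$planned), nrow(dg))
  # the diagnosed series is nondecreasing and consistent with the event log
  expect_true(all(diff(res$series$diagnosed) >= 0))
  expect_equal(res$series$diagnosed[nrow(res$series)],
               res$meta$n_diagnosed_initial + nrow(dg))
  # status conservation at every day
  expect_true(all(res$series$undiagnosed + res$series$diagnosed <=
                    res$meta$n_agents))
  expect_equal(res$series$undiagnosed + res$series$diagnosed,
               rep(res$meta$n_undiagnosed_initial + res$meta$n_diagnosed_initial,
                   nrow(res$series)))
})

test_that("faster undiagnosed progression does not slow diagnosis", {
  cfg <- tiny_config(n_agents = 100, undiagnosed = 0.5)
  slow <- update_params(default_params(), "disease.rp_undiagnosed" = 0.010)
  fast <- update_params(default_params(), "disease.rp_undiagnosed" = 0.020)
  mean_day <- function(p, seed) {
    res <- run_simulation(cfg, p, horizon = 2500, seed = seed)
    mean(res$diagnoses$day)
  }
  diffs <- vapply(1:4, function(s) mean_day(slow, s) - mean_day(fast, s), 0)
  expect_true(mean(diffs) > 0)  # earlier urgent overrides under faster progression
})

test_that("summary statistics match a hand-built event log", {
  res <- structure(list(
    diagnoses = data.frame(
      day = c(100, 200, 300, 900, 1200, 1500, 2000, 2500, 3100, 3500),
      agent = 1:10, gender = rep(c("male", "female"), 5),
      provider = 1L,
      provider_kind = c(rep("hospital", 6), rep("medical_center", 4)),
      planned = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
      late = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
      si_at_diagnosis = runif(10)),
    visits = data.frame(provider_kind = c("medical_center", "hospital"),
                        cost = c(100, 600)),
    meta = list(horizon = 4000, n_undiagnosed_initial = 10)
  ), class = "careseek_result")
  s <- summarize_result(res)
  expect_equal(s$hospital_share, 60)
  expect_equal(s$planned_share, 75)  # 6 planned of 8 before day 3000
  expect_equal(s$gap_days, 100)     # first diagnosis crosses 5% of 10
  expect_equal(s$late_rate, 60)
  expect_equal(s$late_rate_male, 80)
  expect_equal(s$late_rate_female, 40)
  expect_equal(s$cost_medical, 100)
  expect_equal(s$cost_hospital, 600)
})

test_that("zero-diagnosis summaries report undefined shares, not zeros", {
  cfg <- tiny_config(n_agents = 40, undiagnosed = 0, diagnosed = 0.2)
  res <- run_simulation(cfg, horizon = 100, seed = 1)
  s <- summarize_result(res)
  expect_true(is.na(s$hospital_share))
  expect_true(is.na(s$gap_days))
  expect_true(is.na(s$late_rate_male))
  expect_equal(s$n_diagnosed, 0)
})

test_that("a long-horizon baseline diagnoses nearly the whole undiagnosed cohort", {
  cfg <- tiny_config(n_agents = 200, undiagnosed = 0.3)
  res <- run_simulation(cfg, horizon = 4000, seed = 5)
  expect_gte(nrow(res$diagnoses), 0.95 * res$meta$n_undiagnosed_initial)
})

test_that("results round-trip through the result directory writer", {
  cfg <- tiny_config(n_agents = 60)
  res <- run_simulation(cfg, horizon = 300, seed = 2)
  dir <- tempfile("careseek")
  write_result(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("series.csv", "diagnoses.csv", "visits.csv", "summary.csv", "manifest.yaml")))))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 2)
  expect_equal(manifest$horizon, 300)
  rep <- report_result(dir)
  expect_true(is.data.frame(rep$costs))
})
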