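# Factor functions of the health-seeking decision.

test_that("attitude is logistic in the weighted factor sum", {
  p0 <- default_params()
  p0$behavior$attitude[] <- 0
  expect_equal(attitude_score(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, p0), 0.5)
  # weighted sum = ln 3  ->  logistic gives 3/4
  p1 <- p0
  p1$behavior$attitude[["health"]] <- log(3)
  expect_equal(attitude_score(1, 0, 0, 0, 0, 0, p1), 0.75)
  p2 <- p0
  p2$behavior$attitude[["health"]] <- 1e6
  expect_equal(attitude_score(1, 0, 0, 0, 0, 0, p2), 1)  # asymptote
})

test_that("perceived behavioural control falls with barriers, rises with efficacy", {
  p <- default_params()
  p$behavior$pbc[] <- c(barriers = 0.5, efficacy = 0.5)
  expect_equal(pbc_score(0, 0.6, p), 0.5 + 0.3)       # log(1) = 0
  expect_equal(pbc_score(exp(1) - 1, 0.6, p), 0.55)   # log(1+BA) = 1
  expect_lt(pbc_score(1e12, 0.0, p), 0.02)            # barrier term -> 0
  expect_error(pbc_score(-1, 0.5, p), "nonnegative")
})

test_that("social influence is the matching fraction of the window", {
  expect_equal(social_influence(rep(TRUE, 10), TRUE), 1)
  expect_equal(social_influence(rep(FALSE, 10), TRUE), 0)
  expect_equal(social_influence(c(rep(TRUE, 3), rep(FALSE, 7)), TRUE, 10), 0.3)
  expect_error(social_influence(logical(0), TRUE, 0), "window")
})

test_that("social norms combine influence and interaction frequency", {
  p <- default_params()
  p$behavior$norms$freq_weight <- 0.5
  expect_equal(social_norms_score(numeric(0), numeric(0), 10, 100, p), 0)
  expect_equal(social_norms_score(1, 100, 10, 100, p), 0.6)  # (1/10 + 0.5)*1
  expect_equal(social_norms_score(c(0, 0, 0), c(5, 50, 100), 10, 100, p), 0)
  expect_equal(social_norms_score(0.5, 50, 0, 100, p), 0)  # t = 0
})

test_that("self-efficacy persists and grows with continuity and health", {
  p <- default_params()
  p$behavior$efficacy[] <- c(persist = 1, gain = 0)
  expect_equal(self_efficacy_update(0.37, 0.9, 0.9, p), 0.37)
  p$behavior$efficacy[] <- c(persist = 0.5, gain = 0.1)
  expect_equal(self_efficacy_update(0.4, 0, 0, p), 0.4)  # 0.2 + 0.1*2
  p$behavior$efficacy[] <- c(persist = 1, gain = 1)
  expect_equal(self_efficacy_update(0.9, 0.5, 0.5, p), 1)  # saturates
})

test_that("risk aversion rises with severity and is damped by its history", {
  p <- default_params()
  p$behavior$risk[] <- c(severity = 1, damping = 0.25)
  expect_equal(risk_aversion_update(0, 0, p), 0)
  expect_equal(risk_aversion_update(exp(1) - 1, 0.6, p), 0.35)  # 0.6 - 0.25*log(e)
  p$behavior$risk[] <- c(severity = 0, damping = 0.5)
  expect_equal(risk_aversion_update(0.9, 0.9, p), 0)  # clamped at 0
})

test_that("health seeking is the weighted mean of active factors with urgent override", {
  p <- default_params()
  f0 <- list(attitude = 0, pbc = 0, norms = 0, risk = 0, efficacy = 0, hedonic = 0)
  hs <- health_seeking(f0, p)
  expect_equal(hs$score, 0)
  expect_false(hs$seek)
  f6 <- lapply(f0, function(x) 0.6)
  hs6 <- health_seeking(f6, p)
  expect_equal(hs6$score, 0.6)  # weighted mean of a constant
  expect_true(hs6$seek)
  expect_true(health_seeking(f0, p, urgent = TRUE)$seek)
  p0 <- p
  p0$behavior$decision[] <- 0
  expect_error(health_seeking(f6, p0), "weights")
})

test_that("theory subsets use only their own factors (hedonic always active)", {
  p <- default_params()
  f <- list(attitude = 1, pbc = 1, norms = 1, risk = 0, efficacy = 0, hedonic = 0.2)
  w <- p$behavior$decision
  hbm_expect <- (w[["risk"]] * 0 + w[["efficacy"]] * 0 + w[["hedonic"]] * 0.2) /
    (w[["risk"]] + w[["efficacy"]] + w[["hedonic"]])
  expect_equal(health_seeking(f, p, theories = "hbm")$score, hbm_expect)
  tpb_expect <- (w[["attitude"]] + w[["pbc"]] + w[["norms"]] + w[["hedonic"]] * 0.2) /
    (w[["attitude"]] + w[["pbc"]] + w[["norms"]] + w[["hedonic"]])
  expect_equal(health_seeking(f, p, theories = "tpb")$score, tpb_expect)
})

test_that("score respects the weighted-mean bounds and equal-weight closed form", {
  set.seed(71)
  for (rep in 1:50) {
    f <- as.list(stats::setNames(runif(6), names(default_params()$behavior$decision)))
    p <- random_params()
    s <- health_seeking(f, p)$score
    expect_gte(s, min(unlist(f)) - 1e-12)
    expect_lte(s, max(unlist(f)) + 1e-12)
    pe <- default_params()
    pe$behavior$decision[] <- 1
    expect_equal(health_seeking(f, pe)$score, mean(unlist(f)))
  }
})

test_that("monotonicity: attitude in factors, pbc in barriers, risk in severity, efficacy in continuity", {
  p <- default_params()
  a1 <- attitude_score(0.2, 0.5, 0.5, 0.5, 0.5, 0.5, p)
  expect_gt(attitude_score(0.6, 0.5, 0.5, 0.5, 0.5, 0.5, p), a1)
  expect_gt(attitude_score(0.2, 0.5, 0.9, 0.5, 0.5, 0.5, p), a1)
  expect_lt(pbc_score(2, 0.5, p), pbc_score(0.5, 0.5, p))
  expect_gt(risk_aversion_update(0.3, 0.8, p), risk_aversion_update(0.3, 0.2, p))
  p$behavior$efficacy[["gain"]] <- 0.05
  expect_gt(self_efficacy_update(0.4, 0.9, 0.4, p), self_efficacy_update(0.4, 0.1, 0.4, p))
})
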