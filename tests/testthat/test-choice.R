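# Provider choice and the trust/reputation dynamics feeding it.

test_that("hedonic goal falls linearly with normalised distance and time", {
  p <- default_params()
  expect_equal(hedonic_goal(0, dis_max = 10, params = p), 1)
  p5 <- p
  p5$choice$distance <- 0.5; p5$choice$time <- 0.5
  expect_equal(hedonic_goal(10, dis_max = 10, params = p5), 0)  # 1 - (0.5+0.5)
  p0 <- p
  p0$choice$distance <- 0; p0$choice$time <- 0
  expect_equal(hedonic_goal(c(0, 5, 10), dis_max = 10, params = p0), c(1, 1, 1))
  # distances beyond the maximum are treated as the maximum
  expect_equal(hedonic_goal(25, dis_max = 10, params = p5),
               hedonic_goal(10, dis_max = 10, params = p5))
})

test_that("normative goal is a clamped power combination of reputation and trust", {
  p <- default_params()
  p$choice$reputation <- 1; p$choice$trust <- 0
  p$choice$pow_reputation <- 0.5
  expect_equal(normative_goal(0.25, 0.9, p), 0.5)  # sqrt(0.25)
  expect_equal(normative_goal(0, 0, p), 0)
  p2 <- default_params()
  p2$choice$pow_reputation <- 1; p2$choice$pow_trust <- 1
  expect_equal(normative_goal(1, 1, p2),
               min(1, p2$choice$reputation + p2$choice$trust))
})

test_that("choose_service picks the utility argmax with deterministic tie-breaks", {
  p <- default_params()
  # two identical providers, one co-located and one at the extent: nearer wins
  j <- choose_service(hg = c(1, 0.2), reputation = c(0.6, 0.6),
                      trust = c(0.6, 0.6), dis = c(0, 10),
                      kind = c("medical_center", "medical_center"),
                      open = c(TRUE, TRUE), p)
  expect_equal(j, 1)
  # exact utility tie: smaller distance, then lower id
  j <- choose_service(hg = c(0.5, 0.5), reputation = c(0.6, 0.6),
                      trust = c(0.6, 0.6), dis = c(4, 2),
                      kind = rep("medical_center", 2), open = c(TRUE, TRUE), p)
  expect_equal(j, 2)
  # singleton roster
  expect_equal(choose_service(0.4, 0.5, 0.5, 3, "hospital", TRUE, p), 1)
  expect_error(choose_service(numeric(0), numeric(0), numeric(0), numeric(0),
                              character(0), logical(0), p), "non-empty")
})

test_that("urgent cases fall back to the hospital when centres are closed or congested", {
  p <- default_params()
  hg <- c(0.9, 0.5); rp <- c(0.9, 0.5); tr <- c(0.9, 0.5)
  kind <- c("medical_center", "hospital")
  # centre closed at 2am: hospital despite its lower utility
  j <- choose_service(hg, rp, tr, dis = c(1, 3), kind, open = c(FALSE, TRUE),
                      p, urgent = TRUE)
  expect_equal(j, 2)
  # centre open but the expected wait exceeds the urgent bound
  j <- choose_service(hg, rp, tr, dis = c(1, 3), kind, open = c(TRUE, TRUE),
                      p, urgent = TRUE, expected_wait = c(3, 0))
  expect_equal(j, 2)
  # switched agents consider hospitals only
  j <- choose_service(hg, rp, tr, dis = c(1, 3), kind, open = c(TRUE, TRUE),
                      p, prefer_hospital = TRUE)
  expect_equal(j, 2)
  # ordering invariance: permuting providers permutes the answer
  j2 <- choose_service(hg[2:1], rp[2:1], tr[2:1], dis = c(3, 1), kind[2:1],
                       open = c(TRUE, TRUE), p, urgent = TRUE,
                       expected_wait = c(0, 3))
  expect_equal(j2, 1)
})

test_that("trust reinforces on success and erodes on failure", {
  p <- default_params()
  p$choice$trust_persist <- 1; p$choice$trust_gain <- 0; p$choice$trust_penalty <- 0
  expect_equal(trust_update(0.41, TRUE, p), 0.41)
  p$choice$trust_persist <- 0.9; p$choice$trust_gain <- 0.1; p$choice$trust_penalty <- 0.2
  expect_equal(trust_update(0.5, TRUE, p), 0.55)
  expect_equal(trust_update(0.5, FALSE, p), 0.25)
  expect_equal(trust_update(0, FALSE, p), 0)  # clamped
})

test_that("with constant success trust converges to the gain/(1-persistence) fixed point", {
  p <- default_params()
  p$choice$trust_persist <- 0.8; p$choice$trust_gain <- 0.1; p$choice$trust_penalty <- 0.2
  tr <- 0.1
  for (i in 1:300) tr <- trust_update(tr, TRUE, p)
  expect_equal(tr, min(1, 0.1 / (1 - 0.8)), tolerance = 1e-8)
  p$choice$trust_gain <- 0.5  # fixed point above 1 clamps at 1
  tr <- 0.1
  for (i in 1:300) tr <- trust_update(tr, TRUE, p)
  expect_equal(tr, 1)
})

test_that("reputation decays towards mean network feedback", {
  p <- default_params()
  p$choice$rep_decay <- 1
  expect_equal(reputation_update(0.4, c(1, 1, 1), p), 0.4)
  p$choice$rep_decay <- 0.5
  expect_equal(reputation_update(0.4, 1, p), 0.7)
  expect_equal(reputation_update(0.4, numeric(0), p), 0.4)  # no feedback tick
})
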