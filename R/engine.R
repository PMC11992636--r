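# Simulation engine: world initialisation, the daily step with its imposed
# phase order, and observable collection.
#
# The world is held in an environment with one vector per agent attribute and
# one n x J matrix per agent-provider score (trust, reputation, continuity),
# so that every phase of the daily step is a vectorised operation over the
# (small) set of agents active that day.

init_world <- function(config, params, theories, horizon, seed) {
  config <- validate_region_config(config)
  if (!is.null(config$network)) {
    unknown <- setdiff(names(config$network), names(params$network))
    if (length(unknown)) config_error("unknown network key(s): ",
                                      paste(unknown, collapse = ", "))
    params$network <- utils::modifyList(params$network, config$network)
  }
  validate_params(params)
  pop_seed <- as.integer(seed)
  net_seed <- pop_seed + 1L
  dyn_seed <- pop_seed + 2L

  agents <- synthesize_population(config, pop_seed, params)
  providers <- build_providers(config, params)
  iv <- params$intervention

  w <- new.env(parent = emptyenv())
  n <- nrow(agents); J <- nrow(providers)
  w$n <- n; w$J <- J
  w$params <- params
  w$theories <- theories
  w$horizon <- horizon
  w$config_name <- config$name %||% "region"

  w$gender <- agents$gender
  w$age <- agents$age
  w$ses_base <- agents$ses_base
  w$education <- agents$education
  w$ses <- agents$ses
  w$hl <- clamp01(agents$health_literacy * iv$hl_mult)
  w$md <- agents$mental_health
  w$hb <- agents$health_behaviors
  w$cl <- agents$cultural_beliefs
  w$ba <- agents$barriers * iv$barrier_mult
  w$chronic_sum <- agents$chronic_sum
  w$status <- match(agents$diabetes_status, c("none", "undiagnosed", "diagnosed")) - 1L
  w$si <- agents$si
  w$se <- agents$se
  w$ra <- agents$ra
  w$check_interval <- agents$check_interval
  w$failed_mc <- integer(n)
  w$prefer_hosp <- logical(n)
  w$appt_day <- rep(NA_integer_, n)
  w$appt_prov <- rep(NA_integer_, n)

  w$pr_kind <- providers$kind
  w$pr_hosp <- providers$kind == "hospital"
  w$pr_cap <- providers$capacity
  w$pr_q <- providers$q_mild
  w$pr_cost <- providers$cost_visit
  w$pr_rep0 <- providers$reputation

  # static geography: per-region distance normalisation
  dis_max <- sqrt(sum(config$extent_km^2))
  dm <- matrix(0, n, J)
  for (j in seq_len(J)) {
    dm[, j] <- sqrt((agents$x - providers$x[j])^2 + (agents$y - providers$y[j])^2)
  }
  dm <- dm * iv$distance_mult
  w$dis <- dm
  w$dis_max <- dis_max
  hg <- matrix(0, n, J)
  for (j in seq_len(J)) hg[, j] <- hedonic_goal(dm[, j], dis_max, params = params)
  w$hg <- hg
  hb_best <- hg[, 1]
  if (J > 1) for (j in 2:J) hb_best <- pmax(hb_best, hg[, j])
  w$hg_best <- hb_best

  w$net <- build_network(agents, params, net_seed)
  w$adj <- build_adjacency(w$net)

  set.seed(dyn_seed)
  ini <- params$init
  w$tr <- clamp01(matrix(rep(providers$reputation, each = n), n, J) +
                    stats::runif(n * J, -ini$trust_noise, ini$trust_noise))
  w$rp <- clamp01(matrix(rep(providers$reputation, each = n), n, J) +
                    stats::runif(n * J, -ini$rep_noise, ini$rep_noise))
  w$ex <- matrix(0, n, J)
  w$ex_best <- numeric(n)
  w$next_check <- 1L + floor(stats::runif(n) * w$check_interval)

  win <- params$behavior$norms$window_days
  w$win <- win
  w$seek_count <- integer(n)
  p_int <- min(1, params$network$interaction_prob * iv$social_mult)
  w$fq_max <- max(1, horizon * p_int)

  w$pf_sender <- integer(0); w$pf_prov <- integer(0); w$pf_score <- numeric(0)

  cap <- max(256L, 16L * sum(w$status == 1L))
  w$v_day <- integer(cap); w$v_agent <- integer(cap); w$v_prov <- integer(cap)
  w$v_stage <- character(cap); w$v_planned <- logical(cap)
  w$v_diag <- logical(cap); w$v_cost <- numeric(cap); w$nv <- 0L
  dcap <- max(64L, sum(w$status == 1L) + 8L)
  w$d_day <- integer(dcap); w$d_agent <- integer(dcap); w$d_prov <- integer(dcap)
  w$d_planned <- logical(dcap); w$d_late <- logical(dcap); w$d_si <- numeric(dcap)
  w$nd <- 0L
  w$series <- matrix(0L, max(horizon, 1), 2)
  w$n_undiag0 <- sum(w$status == 1L)
  w$n_diag0 <- sum(w$status == 2L)
  w$active <- which(w$status == 1L)
  w$diabetic <- which(w$status > 0L)
  w$hosp_ids <- which(w$pr_hosp)
  act_f <- active_factors(theories)
  w$hs_w <- params$behavior$decision[act_f]
  if (sum(w$hs_w) <= 0) config_error("active decision weights must not all be zero")
  w$hs_threshold <- params$behavior$threshold
  w$cnt_undiag <- w$n_undiag0
  w$cnt_diag <- w$n_diag0
  # the behaviour-history ring is kept only for rows that can ever act
  w$ring_rows <- w$active
  w$ring_idx <- rep(NA_integer_, n)
  w$ring_idx[w$ring_rows] <- seq_along(w$ring_rows)
  w$seek_hist <- matrix(FALSE, length(w$ring_rows), win)
  w
}

record_visit <- function(w, t, agent, prov, stage, planned, diagnosed, cost) {
  if (w$nv == length(w$v_day)) {  # grow deterministically
    grow <- function(v) c(v, v)
    w$v_day <- grow(w$v_day); w$v_agent <- grow(w$v_agent)
    w$v_prov <- grow(w$v_prov); w$v_stage <- grow(w$v_stage)
    w$v_planned <- grow(w$v_planned); w$v_diag <- grow(w$v_diag)
    w$v_cost <- grow(w$v_cost)
  }
  i <- w$nv + 1L
  w$v_day[i] <- t; w$v_agent[i] <- agent; w$v_prov[i] <- prov
  w$v_stage[i] <- stage; w$v_planned[i] <- planned
  w$v_diag[i] <- diagnosed; w$v_cost[i] <- cost
  w$nv <- i
}

record_diagnosis <- function(w, t, agent, prov, planned) {
  w$status[agent] <- 2L
  w$active <- w$active[w$active != agent]
  w$cnt_undiag <- w$cnt_undiag - 1L
  w$cnt_diag <- w$cnt_diag + 1L
  w$failed_mc[agent] <- 0L
  w$prefer_hosp[agent] <- FALSE   # switch flag cleared on diagnosis
  w$appt_day[agent] <- NA_integer_
  i <- w$nd + 1L
  w$d_day[i] <- t; w$d_agent[i] <- agent; w$d_prov[i] <- prov
  w$d_planned[i] <- planned
  w$d_late[i] <- w$si[agent] >= w$params$disease$s_late
  w$d_si[i] <- w$si[agent]
  w$nd <- i
}

# post-visit bookkeeping shared by every visit: trust learning, continuity of
# care, queued network feedback
after_visit <- function(w, agent, prov, success) {
  p <- w$params
  w$tr[agent, prov] <- trust_update(w$tr[agent, prov], success, p)
  newex <- min(1, w$ex[agent, prov] + p$care$ex_increment)
  w$ex[agent, prov] <- newex
  if (newex > w$ex_best[agent]) w$ex_best[agent] <- newex
  fe <- if (success) 1 else p$care$feedback_partial
  w$pf_sender <- c(w$pf_sender, agent)
  w$pf_prov <- c(w$pf_prov, prov)
  w$pf_score <- c(w$pf_score, fe)
}

# execute one visit of `agent` to provider `prov` (urgent referrals trigger
# the hospital leg in the same call)
do_visit <- function(w, t, agent, prov, stage, planned) {
  out <- process_visit(w$status[agent] == 1L, stage, w$pr_kind[prov],
                       w$params, q_mild = w$pr_q[prov], cost = w$pr_cost[prov])
  record_visit(w, t, agent, prov, stage, planned, out$diagnosed, out$cost)
  if (out$referred) {
    after_visit(w, agent, prov, TRUE)  # urgent need met by correct referral
    hosp <- w$hosp_ids
    jh <- hosp[which.min(w$dis[agent, hosp])]
    out2 <- process_visit(w$status[agent] == 1L, stage, "hospital",
                          w$params, cost = w$pr_cost[jh])
    record_visit(w, t, agent, jh, stage, FALSE, out2$diagnosed, out2$cost)
    if (out2$diagnosed) record_diagnosis(w, t, agent, jh, FALSE)
    after_visit(w, agent, jh, out2$diagnosed)
    return(invisible())
  }
  if (out$diagnosed) {
    record_diagnosis(w, t, agent, prov, planned)
  } else if (!w$pr_hosp[prov] && w$status[agent] == 1L) {
    w$failed_mc[agent] <- w$failed_mc[agent] + 1L
    if (switch_rule(w$failed_mc[agent], w$params)) w$prefer_hosp[agent] <- TRUE
  }
  after_visit(w, agent, prov, out$diagnosed)
  invisible()
}

# vectorised social-norms scores for the checking agents
norms_for <- function(w, ck, t) {
  p <- w$params
  nm <- p$behavior$norms
  deg <- w$adj$deg[ck]
  sn <- numeric(length(ck))
  has <- which(deg > 0)
  if (length(has)) {
    cks <- ck[has]
    dg <- deg[has]
    idx <- sequence(dg, from = w$adj$start[cks])
    nbrs <- w$adj$nbr[idx]
    eids <- w$adj$eid[idx]
    grp <- rep(seq_along(cks), dg)
    inn <- w$seek_count[nbrs] / w$win
    tt <- if (identical(nm$time_mode, "window")) nm$window_days else t
    fw <- nm$freq_weight * p$intervention$social_mult
    term <- (inn / tt + fw * w$net$fq[eids] / w$fq_max) * inn
    sn[has] <- clamp01(rowsum(term, grp)[, 1] / dg)
  }
  sn
}

step_day <- function(w, t) {
  p <- w$params
  dz <- p$disease

  # (1) disease progression over the fixed diabetic set (active-set layout:
  # only undiagnosed diabetics can generate events, so per-day work scales
  # with their count, not with the population size)
  db <- w$diabetic
  if (length(db)) {
    rd <- dz$rp_diagnosed / 30
    rate <- rd + (w$status[db] == 1L) * (dz$rp_undiagnosed - dz$rp_diagnosed) / 30
    w$si[db] <- pmin(1, w$si[db] + rate)
  }

  # (2) routine and forced health checks (undiagnosed only)
  act <- w$active
  si_a <- w$si[act]
  due_a <- w$next_check[act] <= t
  if (any(due_a)) w$next_check[act[due_a]] <- t + w$check_interval[act[due_a]]
  urg_a <- si_a >= dz$s_urgent
  appt_a <- !is.na(w$appt_day[act])
  check_a <- (due_a | si_a >= dz$s_notice) & si_a >= dz$s_onset &
    (!appt_a | urg_a)
  ck <- act[check_a]
  urg <- logical(w$n); urg[act[urg_a]] <- TRUE
  seekers <- integer(0)

  # (3) factor updates and the health-seeking decision
  if (length(ck)) {
    h <- clamp01(dz$condition_weight * w$chronic_sum[ck] + dz$si_weight * w$si[ck])
    att <- attitude_score(h, w$ses[ck], w$hl[ck], w$md[ck], w$hb[ck], w$cl[ck], p)
    ra_new <- risk_aversion_update(w$ra[ck], w$si[ck], p)
    se_new <- self_efficacy_update(w$se[ck], w$ex_best[ck], h, p)
    w$ra[ck] <- ra_new
    w$se[ck] <- se_new
    pbc <- pbc_score(w$ba[ck], se_new, p)
    sn <- norms_for(w, ck, t)
    fac <- list(attitude = att, pbc = pbc, norms = sn, risk = ra_new,
                efficacy = se_new, hedonic = w$hg_best[ck])
    num <- 0
    for (k in names(w$hs_w)) num <- num + w$hs_w[[k]] * fac[[k]]
    score <- num / sum(w$hs_w)
    seekers <- ck[score >= w$hs_threshold | urg[ck]]
    w$appt_day[seekers] <- NA_integer_  # urgent overrides cancel bookings
  }

  # (4) provider choice and visit processing
  appts <- act[appt_a & !urg_a]
  appts <- appts[!is.na(w$appt_day[appts]) & w$appt_day[appts] == t &
                   w$status[appts] == 1L]
  weekday <- !p$care$mc_weekdays_only || ((t - 1L) %% 7L) < 5L
  arrivals <- numeric(w$J)
  for (a in appts) {
    j <- w$appt_prov[a]
    w$appt_day[a] <- NA_integer_
    arrivals[j] <- arrivals[j] + 1
    stage <- as.character(symptom_stage(w$si[a], p))
    do_visit(w, t, a, j, stage, planned = TRUE)
  }
  sought_idx <- appts
  if (length(seekers)) {
    ord <- seekers[sample.int(length(seekers))]  # daily dynamic order
    hours <- stats::runif(length(ord), p$engine$visit_hour_min, p$engine$visit_hour_max)
    for (s in seq_along(ord)) {
      i <- ord[s]
      hour <- hours[s]
      mc_open <- weekday && hour >= p$care$mc_open_hour && hour < p$care$mc_close_hour
      urgent_i <- urg[i]
      open <- w$pr_hosp | mc_open
      wait <- arrivals / w$pr_cap
      if (urgent_i) {
        j <- choose_service(w$hg[i, ], w$rp[i, ], w$tr[i, ], w$dis[i, ],
                            w$pr_kind, open, p, urgent = TRUE,
                            prefer_hospital = w$prefer_hosp[i],
                            expected_wait = wait)
        arrivals[j] <- arrivals[j] + 1
        do_visit(w, t, i, j, "urgent", planned = FALSE)
      } else {
        # planned care: pick the preferred provider; closed medical centres
        # take a booking for their next opening day instead of losing the
        # visit to the emergency department
        j <- choose_service(w$hg[i, ], w$rp[i, ], w$tr[i, ], w$dis[i, ],
                            w$pr_kind, open = rep(TRUE, w$J), p,
                            prefer_hospital = w$prefer_hosp[i])
        stage <- as.character(symptom_stage(w$si[i], p))
        if (w$pr_hosp[j] || (mc_open && arrivals[j] < w$pr_cap[j])) {
          arrivals[j] <- arrivals[j] + 1
          do_visit(w, t, i, j, stage, planned = TRUE)
        } else {
          d <- t + 1L
          if (p$care$mc_weekdays_only) while (((d - 1L) %% 7L) >= 5L) d <- d + 1L
          w$appt_day[i] <- d
          w$appt_prov[i] <- j
        }
      }
    }
    sought_idx <- c(sought_idx, ord)
  }

  # (5)-(6) reputation feedback and network interactions
  p_int <- min(1, p$network$interaction_prob * p$intervention$social_mult)
  m <- length(w$net$i)
  # interaction counts are advanced in weekly Binomial(7, p) batches --
  # statistically identical to daily Bernoulli firing for the cumulative FQ
  if (t %% 7L == 0L) {
    w$net$fq <- w$net$fq + stats::rbinom(m, 7L, p_int)
  }
  if (length(w$pf_sender)) {
    d_agent <- integer(0); d_prov <- integer(0); d_score <- numeric(0)
    for (r in seq_along(w$pf_sender)) {
      snd <- w$pf_sender[r]
      dg <- w$adj$deg[snd]
      if (dg == 0) next
      nbrs <- w$adj$nbr[w$adj$start[snd] + seq_len(dg) - 1L]
      hit <- nbrs[stats::runif(dg) < p_int]
      if (length(hit)) {
        d_agent <- c(d_agent, hit)
        d_prov <- c(d_prov, rep(w$pf_prov[r], length(hit)))
        d_score <- c(d_score, rep(w$pf_score[r], length(hit)))
      }
    }
    w$pf_sender <- integer(0); w$pf_prov <- integer(0); w$pf_score <- numeric(0)
    if (length(d_agent)) {
      key <- (d_prov - 1L) * w$n + d_agent
      ukey <- unique(key)
      grp <- match(key, ukey)
      mfe <- rowsum(d_score, grp)[, 1] / tabulate(grp)
      tgt <- cbind((ukey - 1L) %% w$n + 1L, (ukey - 1L) %/% w$n + 1L)
      lam <- p$choice$rep_decay
      w$rp[tgt] <- clamp01(lam * w$rp[tgt] + (1 - lam) * mfe)
    }
  }
  pos <- ((t - 1L) %% w$win) + 1L
  newcol <- logical(length(w$ring_rows))
  newcol[w$ring_idx[sought_idx]] <- TRUE
  w$seek_count[w$ring_rows] <- w$seek_count[w$ring_rows] -
    w$seek_hist[, pos] + newcol
  w$seek_hist[, pos] <- newcol

  w$series[t, 1] <- w$cnt_undiag
  w$series[t, 2] <- w$cnt_diag

  # (7) slow network churn (monthly) and annual demographic updates
  if (t %% 30L == 0L && p$network$churn_monthly_prob > 0) {
    w$net <- network_churn(w$net, p, adj = w$adj)
    w$adj <- build_adjacency(w$net)
  }
  if (t %% 365L == 0L) {
    band <- w$age >= 20 & w$age <= 40
    w$age <- w$age + 1
    inc <- p$init$education_increment
    w$education[band] <- clamp01(w$education[band] * (1 + inc))
    w$ses <- clamp01(0.6 * w$ses_base + 0.4 * w$education)
  }
  invisible(w)
}

#' Run one simulation
#'
#' Synthesises the population and provider roster, builds the social network,
#' applies the scenario's theory set and intervention, and steps the world
#' day by day for the horizon. Each day executes a fixed phase order: disease
#' progression; routine and forced health checks; behavioural factor updates
#' and the health-seeking decision; provider choice and visit processing;
#' trust, continuity, feedback and reputation updates; network interactions;
#' and annual demographic updates every 365 days. Agent iteration order
#' within a day is shuffled with the run RNG.
#'
#' All randomness derives from `seed` (population `seed`, network `seed + 1`,
#' dynamics `seed + 2`), so identical `(config, params, theories,
#' intervention, horizon, seed)` give identical results.
#'
#' @param config a region configuration, or the name of a shipped region
#'   (`"gilgandra"`, `"narromine"`).
#' @param params model parameters; see [default_params()].
#' @param theories active decision-theory set, a subset of
#'   `c("tpb", "hbm")` (goal framing always governs provider choice).
#' @param intervention `"none"`, `"awareness"` or `"access"`; applied via
#'   [apply_intervention()].
#' @param horizon simulation length in days.
#' @param seed integer seed (all randomness flows from it).
#' @return An object of class `careseek_result` with elements `series`
#'   (daily undiagnosed/diagnosed counts), `diagnoses` (one row per diagnosis
#'   event with day, agent, gender, provider kind, planned flag, late flag
#'   and severity at diagnosis), `visits` (the full visit log with costs)
#'   and `meta`.
#' @export
#' @examples
#' \donttest{
#' res <- run_simulation("gilgandra", horizon = 400, seed = 1)
#' summarize_result(res)
#' }
run_simulation <- function(config, params = default_params(),
                           theories = c("tpb", "hbm"),
                           intervention = "none",
                           horizon = 4000, seed = 1L) {
  if (is.character(config)) config <- region_config(config)
  if (!is_count(horizon)) config_error("horizon must be a nonnegative count")
  if (!is.null(config$params) && length(config$params)) {
    params <- do.call(update_params, c(list(params), config$params))
  }
  params <- apply_intervention(params, intervention)
  w <- init_world(config, params, theories, horizon, seed)
  for (t in seq_len(horizon)) step_day(w, t)
  finish_result(w, config, intervention, seed)
}

finish_result <- function(w, config, intervention, seed) {
  nv <- seq_len(w$nv); nd <- seq_len(w$nd)
  visits <- data.frame(
    day = w$v_day[nv], agent = w$v_agent[nv], provider = w$v_prov[nv],
    provider_kind = w$pr_kind[w$v_prov[nv]], stage = w$v_stage[nv],
    planned = w$v_planned[nv], diagnosed = w$v_diag[nv], cost = w$v_cost[nv]
  )
  diagnoses <- data.frame(
    day = w$d_day[nd], agent = w$d_agent[nd],
    gender = w$gender[w$d_agent[nd]],
    provider = w$d_prov[nd], provider_kind = w$pr_kind[w$d_prov[nd]],
    planned = w$d_planned[nd], late = w$d_late[nd], si_at_diagnosis = w$d_si[nd]
  )
  series <- data.frame(day = seq_len(nrow(w$series)),
                       undiagnosed = w$series[, 1], diagnosed = w$series[, 2])
  if (w$horizon == 0) series <- series[0, ]
  structure(list(
    series = series, diagnoses = diagnoses, visits = visits,
    meta = list(region = w$config_name, n_agents = w$n,
                n_undiagnosed_initial = w$n_undiag0,
                n_diagnosed_initial = w$n_diag0,
                theories = w$theories, intervention = intervention,
                horizon = w$horizon, seed = seed)
  ), class = c("careseek_result", "list"))
}

#' @export
print.careseek_result <- function(x, ...) {
  m <- x$meta
  cat("careseek simulation:", m$region, "|", paste(m$theories, collapse = "+"),
      "| intervention:", m$intervention, "\n")
  cat("  ", m$n_agents, "agents,", m$horizon, "days, seed", m$seed, "\n")
  cat("  ", nrow(x$diagnoses), "diagnoses (", m$n_undiagnosed_initial,
      "initially undiagnosed ),", nrow(x$visits), "visits\n")
  invisible(x)
}

#' Summarise a simulation result
#'
#' Computes the headline observables of a run: the hospital share of
#' diagnoses, the planned share of diagnoses before a cutoff day, the
#' diagnostic gap (days until cumulative diagnoses exceed a fraction of the
#' run's final total), late-diagnosis rates overall, by gender and by
#' provider kind, visit intensity and cost totals. Shares are percentages;
#' with zero qualifying diagnoses a share is `NA` (undefined), not 0.
#'
#' @param result a `careseek_result`.
#' @param planned_before cutoff day for the planned share.
#' @param gap_fraction fraction of the final diagnosis total defining the
#'   diagnostic gap (default from the engine parameters, 0.05).
#' @return A named list of summary statistics.
#' @export
summarize_result <- function(result, planned_before = 3000, gap_fraction = 0.05) {
  dg <- result$diagnoses
  ntot <- nrow(dg)
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  early <- dg[dg$day < planned_before, ]
  gap <- NA_real_
  if (ntot > 0) {
    days <- sort(dg$day)
    gap <- days[min(which(seq_len(ntot) > gap_fraction * ntot))]
  }
  costs <- accrue_costs(result$visits)
  years <- max(result$meta$horizon, 1) / 365
  list(
    n_diagnosed = ntot,
    hospital_share = pct(dg$provider_kind == "hospital"),
    planned_share = pct(early$planned),
    gap_days = gap,
    late_rate = pct(dg$late),
    late_rate_male = pct(dg$late[dg$gender == "male"]),
    late_rate_female = pct(dg$late[dg$gender == "female"]),
    late_rate_hospital = pct(dg$late[dg$provider_kind == "hospital"]),
    late_rate_medical_center = pct(dg$late[dg$provider_kind == "medical_center"]),
    visits_per_agent_year = nrow(result$visits) /
      max(result$meta$n_undiagnosed_initial, 1) / years,
    cost_medical = costs$total_medical,
    cost_hospital = costs$total_hospital,
    cost_total = costs$total
  )
}
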