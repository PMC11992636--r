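#' Synthesise an agent population
#'
#' Generates the synthetic patient population of a region by Monte-Carlo
#' assignment of initial states: every attribute is drawn independently from
#' its configured marginal, residential locations are uniform within the
#' region extent, and diabetes status is assigned according to the configured
#' prevalence. Identical `(config, seed)` pairs yield identical populations.
#'
#' Initial self-efficacy and risk aversion are drawn uniformly on the
#' configured initialisation ranges; the initial severity index of
#' undiagnosed agents is drawn uniformly on `[0, init$si_max]` so that
#' disease stages are heterogeneous at the start of a run. Routine self-check
#' intervals are drawn per agent from the configured range and shifted
#' shorter for older and more health-literate agents.
#'
#' @param config a `careseek_config` region configuration
#'   (see [region_config()]).
#' @param seed integer seed.
#' @param params model parameters (only the `init` section is used here).
#' @return A data frame with one row per agent: location, sociodemographics,
#'   cognitive-normative scores, chronic-condition load, diabetes status,
#'   severity index, self-efficacy, risk aversion and self-check interval.
#' @export
#' @examples
#' cfg <- region_config("gilgandra")
#' pop <- synthesize_population(cfg, seed = 1)
#' nrow(pop)  # 4101
synthesize_population <- function(config, seed, params = default_params()) {
  config <- validate_region_config(config)
  set.seed(as.integer(seed))
  n <- config$n_agents
  dm <- config$demographics
  ini <- params$init

  x <- stats::runif(n, 0, config$extent_km[1])
  y <- stats::runif(n, 0, config$extent_km[2])
  age <- draw_marginal(dm$age %||% list(dist = "normal", mean = 45, sd = 18, min = 18, max = 90),
                       n, "age")
  gender <- draw_marginal(dm$gender %||% list(male = 0.5, female = 0.5), n, "gender")
  ind_spec <- dm$indigenous %||% 0.1
  indigenous <- if (is.numeric(ind_spec) && length(ind_spec) == 1) {
    stats::runif(n) < ind_spec  # scalar shorthand: Bernoulli probability
  } else {
    as.logical(draw_marginal(ind_spec, n, "indigenous"))
  }
  ses_base <- clamp01(draw_marginal(dm$ses %||% list(dist = "beta", shape1 = 3, shape2 = 3), n, "ses"))
  education <- clamp01(draw_marginal(dm$education %||% list(dist = "beta", shape1 = 3, shape2 = 3),
                                     n, "education"))
  hl <- clamp01(draw_marginal(dm$health_literacy %||% list(dist = "beta", shape1 = 2.5, shape2 = 2.5),
                              n, "health_literacy", gender = gender))
  md <- clamp01(draw_marginal(dm$mental_health %||% list(dist = "beta", shape1 = 4, shape2 = 2.5),
                              n, "mental_health"))
  hb <- clamp01(draw_marginal(dm$health_behaviors %||% list(dist = "beta", shape1 = 3.5, shape2 = 3),
                              n, "health_behaviors"))
  cl <- clamp01(draw_marginal(dm$cultural_beliefs %||% list(dist = "beta", shape1 = 3, shape2 = 3),
                              n, "cultural_beliefs"))
  ba <- draw_marginal(dm$barriers %||% list(dist = "lognormal", meanlog = -0.2, sdlog = 0.9),
                      n, "barriers")

  chronic <- dm$chronic %||% list(max_conditions = 2, base_prob = 0.15, age_coef = 0.004)
  sev_spec <- chronic$severity %||% list(dist = "beta", shape1 = 2, shape2 = 5)
  p_cond <- clamp01(chronic$base_prob + chronic$age_coef * pmax(age - 40, 0))
  n_chronic <- integer(n)
  chronic_sum <- numeric(n)
  for (z in seq_len(chronic$max_conditions %||% 2)) {
    has <- stats::runif(n) < p_cond
    sev <- clamp01(draw_marginal(sev_spec, n, "chronic.severity"))
    n_chronic <- n_chronic + has
    chronic_sum <- chronic_sum + ifelse(has, sev, 0)
  }

  # diabetes status by prevalence, exact counts up to rounding
  pv <- config$prevalence
  n_u <- round(pv$undiagnosed * n)
  n_d <- round(pv$diagnosed * n)
  status <- rep("none", n)
  pick <- sample.int(n, n_u + n_d)
  if (n_u > 0) status[pick[seq_len(n_u)]] <- "undiagnosed"
  if (n_d > 0) status[pick[n_u + seq_len(n_d)]] <- "diagnosed"

  si <- numeric(n)
  si[status == "undiagnosed"] <- stats::runif(n_u, 0, ini$si_max)
  si[status == "diagnosed"] <- stats::runif(n_d, 0, 0.5)

  se <- stats::runif(n, ini$se_range[1], ini$se_range[2])
  ra <- stats::runif(n, ini$ra_range[1], ini$ra_range[2])

  # routine self-check cadence: shorter for older, more health-literate agents
  base <- stats::runif(n, ini$check_range[1], ini$check_range[2])
  age_f <- clamp01((age - 40) / 50)
  check_interval <- pmax(7, round(base * (1.25 - 0.5 * hl - 0.25 * age_f)))

  data.frame(
    id = seq_len(n), x = x, y = y, age = age, gender = gender,
    indigenous = indigenous, ses_base = ses_base, education = education,
    ses = clamp01(0.6 * ses_base + 0.4 * education),
    health_literacy = hl, mental_health = md, health_behaviors = hb,
    cultural_beliefs = cl, barriers = ba,
    n_chronic = n_chronic, chronic_sum = chronic_sum,
    diabetes_status = status, si = si, se = se, ra = ra,
    check_interval = check_interval,
    stringsAsFactors = FALSE
  )
}

#' Build the provider roster of a region
#'
#' Providers carry a location within the region extent, an operating-hours
#' model (hospitals are always open; medical centres keep the configured
#' weekday hours), diagnosis behaviour, per-visit tariffs, daily capacity and
#' a base reputation. Per-provider values in the configuration override the
#' `care` parameter defaults.
#'
#' @inheritParams synthesize_population
#' @return A data frame with one row per provider.
#' @export
#' @examples
#' build_providers(region_config("gilgandra"))
build_providers <- function(config, params = default_params()) {
  config <- validate_region_config(config)
  care <- params$care
  rows <- lapply(seq_along(config$providers), function(j) {
    p <- config$providers[[j]]
    hosp <- p$kind == "hospital"
    loc <- as.numeric(unlist(p$location))
    data.frame(
      id = j, kind = p$kind, x = loc[1], y = loc[2],
      always_open = hosp,
      capacity = p$capacity %||% if (hosp) Inf else care$mc_capacity,
      q_mild = p$q_mild %||% if (hosp) 1 else care$q_mild,
      cost_visit = if (hosp) p$cost_ed %||% care$cost_ed else p$cost_screen %||% care$cost_screen,
      reputation = p$reputation %||% if (hosp) 0.7 else 0.6,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Annual demographic update
#'
#' Applied every 365 simulated days: age increases by one year and, for
#' agents aged 20 to 40, education advances by the configured proportional
#' increment (the socioeconomic composite is recomputed accordingly). All
#' other fields are untouched.
#'
#' @param agents an agent data frame from [synthesize_population()].
#' @param increment proportional annual education increment for agents aged
#'   20-40.
#' @return The updated agent data frame.
#' @export
annual_update <- function(agents, increment = default_params()$init$education_increment) {
  band <- agents$age >= 20 & agents$age <= 40
  agents$age <- agents$age + 1
  agents$education[band] <- clamp01(agents$education[band] * (1 + increment))
  agents$ses <- clamp01(0.6 * agents$ses_base + 0.4 * agents$education)
  agents
}

#' Write a population to CSV
#'
#' One row per agent, one column per field, header row, UTF-8.
#'
#' @param agents agent data frame.
#' @param path output file path.
#' @export
export_population <- function(agents, path) {
  utils::write.csv(agents, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
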