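#' Default model parameters
#'
#' Returns the full nested parameter set of the simulator. The shipped values
#' are the calibrated defaults: behavioural weights, progression rates and
#' tariffs were fitted with [calibrate_params()] against published regional
#' summaries of diagnosis shares, planned-visit shares, the initial
#' low-diagnosis period and aggregate screening costs (see the methods
#' vignette for the calibration protocol).
#'
#' Sections:
#' \describe{
#'   \item{disease}{`condition_weight` (weight per chronic condition),
#'     `si_weight` (scaling of the diabetes severity index in the overall
#'     health score), monthly severity progression rates `rp_undiagnosed`
#'     and `rp_diagnosed` (per 30 days), symptom-stage thresholds
#'     `s_onset < s_notice < s_urgent` on the severity scale, and `s_late`,
#'     the severity at diagnosis above which a diagnosis counts as late.}
#'   \item{behavior}{Decision weights (one per factor of the health-seeking
#'     utility), the 0.5 decision threshold, and the weight sets of the
#'     attitude, perceived-behavioural-control, social-norms, self-efficacy
#'     and risk-aversion functions.}
#'   \item{choice}{Provider-choice weights: hedonic vs normative goal weights,
#'     distance and travel-time disutility weights, reputation/trust weights
#'     and exponents, trust persistence/gain/penalty, reputation decay,
#'     travel speed and the urgent waiting-time bound.}
#'   \item{care}{Visit processing: per-visit probability `q_mild` that a
#'     mild-stage diabetic is diagnosed at a medical centre, the repeat-failure
#'     switch count `n_fail`, per-visit tariffs (AUD), medical-centre opening
#'     hours and daily capacity, the partial feedback score and the
#'     continuity-of-care increment.}
#'   \item{network}{Social-network construction and interaction parameters.}
#'   \item{engine}{Within-day clock (visit hour window) and the cumulative
#'     fraction used to measure the diagnostic gap.}
#'   \item{init}{Monte-Carlo initialisation ranges for self-efficacy, risk
#'     aversion, trust/reputation noise, initial severity, routine
#'     self-check intervals and the annual education increment.}
#'   \item{intervention}{Multipliers applied by [apply_intervention()]; all 1
#'     at baseline.}
#' }
#'
#' @return A nested list of class `careseek_params`.
#' @export
#' @examples
#' p <- default_params()
#' p$disease$s_urgent
default_params <- function() {
  p <- list(
    disease = list(
      condition_weight = 0.5,
      si_weight        = 0.5,
      rp_undiagnosed   = 0.0145,
      rp_diagnosed     = 0.004,
      s_onset          = 0.2,
      s_notice         = 0.5,
      s_urgent         = 0.8,
      s_late           = 0.5
    ),
    behavior = list(
      decision = c(attitude = 2.0, pbc = 0.8, norms = 1.18, risk = 0.75,
                   efficacy = 0.6, hedonic = 0.36),
      threshold = 0.5,
      attitude = c(health = 0.3, ses = 0.2, literacy = 3.0, mental = 0.1,
                   behaviors = 0.1, cultural = 0.1),
      pbc = c(barriers = 0.5, efficacy = 0.5),
      norms = list(freq_weight = 0.5, window_days = 14, time_mode = "day"),
      efficacy = c(persist = 0.9, gain = 0.013),
      risk = c(severity = 0.55, damping = 0.25)
    ),
    choice = list(
      hedonic = 0.6, normative = 0.4,
      distance = 0.4, time = 0.4,
      reputation = 0.5, trust = 0.5,
      pow_reputation = 1.5, pow_trust = 0.8,
      trust_persist = 0.9, trust_gain = 0.1, trust_penalty = 0.06,
      rep_decay = 0.9,
      travel_speed_kmh = 40,
      urgent_wait_days = 1
    ),
    care = list(
      q_mild = 0.75, n_fail = 3,
      cost_screen = 100, cost_ed = 1600,
      mc_capacity = 40,
      mc_open_hour = 9, mc_close_hour = 17, mc_weekdays_only = TRUE,
      feedback_partial = 0.3, ex_increment = 0.1
    ),
    network = list(
      mean_degree = 8, rewiring_prob = 0.1, distance_scale_km = 3,
      interaction_prob = 0.2, churn_monthly_prob = 0.02
    ),
    engine = list(
      visit_hour_min = 8, visit_hour_max = 20,
      gap_fraction = 0.05
    ),
    init = list(
      se_range = c(0.3, 0.7), ra_range = c(0.3, 0.7),
      trust_noise = 0.1, rep_noise = 0.05,
      si_max = 0.3,
      check_range = c(14, 56),
      education_increment = 0.01
    ),
    intervention = list(hl_mult = 1, social_mult = 1,
                        barrier_mult = 1, distance_mult = 1)
  )
  class(p) <- c("careseek_params", "list")
  p
}

#' Modify model parameters by dotted paths
#'
#' @param params a `careseek_params` list.
#' @param ... named values; each name is a dotted path into the nested
#'   parameter list, e.g. `"behavior.decision.risk" = 1.2` or
#'   `"care.q_mild" = 0.5`. Unknown paths are an error (this protects
#'   against silent typos in weight names).
#' @return The modified parameter list.
#' @export
#' @examples
#' p <- update_params(default_params(), "care.q_mild" = 0.5)
update_params <- function(params, ...) {
  mods <- list(...)
  if (length(mods) && is.null(names(mods))) cs_stop("modifications must be named")
  for (path in names(mods)) params <- set_path(params, path, mods[[path]])
  validate_params(params)
  params
}

#' @rdname update_params
#' @export
validate_params <- function(params) {
  d <- params$disease
  if (!(d$s_onset > 0 && d$s_onset < d$s_notice && d$s_notice < d$s_urgent &&
        d$s_urgent <= 1)) {
    config_error("disease stage thresholds must satisfy 0 < s_onset < s_notice <= s_urgent <= 1")
  }
  if (d$rp_undiagnosed < 0 || d$rp_diagnosed < 0) {
    config_error("disease progression rates must be nonnegative")
  }
  if (d$rp_diagnosed > d$rp_undiagnosed) {
    config_error("rp_diagnosed must not exceed rp_undiagnosed")
  }
  b <- params$behavior
  if (any(b$decision < 0)) config_error("behavior.decision weights must be nonnegative")
  if (sum(b$decision) <= 0) config_error("behavior.decision weights must not all be zero")
  if (b$norms$window_days < 1) config_error("behavior.norms.window_days must be >= 1")
  ch <- params$choice
  if (ch$trust_persist < 0 || ch$trust_persist > 1) config_error("choice.trust_persist must lie in [0, 1]")
  if (ch$rep_decay < 0 || ch$rep_decay > 1) config_error("choice.rep_decay must lie in [0, 1]")
  if (params$care$q_mild < 0 || params$care$q_mild > 1) config_error("care.q_mild must lie in [0, 1]")
  if (params$network$interaction_prob < 0 || params$network$interaction_prob > 1) {
    config_error("network.interaction_prob must lie in [0, 1]")
  }
  invisible(params)
}
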