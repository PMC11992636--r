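#' Attitude towards seeking care
#'
#' A logistic function of the weighted sum of health status, socioeconomic
#' status, health literacy, mental health, health behaviours and cultural
#' health beliefs:
#' `A = 1 / (1 + exp(-(w_h*H + w_s*SES + w_l*HL + w_m*MD + w_b*HB + w_c*CL)))`.
#' Strictly increasing in every factor with a positive weight. All inputs are
#' scores in `[0, 1]` (mental health and health behaviours are coded so that
#' higher means healthier).
#'
#' @param health,ses,literacy,mental,behaviors,cultural factor scores in
#'   `[0, 1]` (vectorised).
#' @param params model parameters (`behavior$attitude` weights).
#' @return Attitude score in `(0, 1)`.
#' @export
attitude_score <- function(health, ses, literacy, mental, behaviors, cultural,
                           params = default_params()) {
  w <- params$behavior$attitude
  s <- w[["health"]] * health + w[["ses"]] * ses + w[["literacy"]] * literacy +
    w[["mental"]] * mental + w[["behaviors"]] * behaviors + w[["cultural"]] * cultural
  1 / (1 + exp(-s))
}

#' Perceived behavioural control
#'
#' Combines external barriers with self-efficacy:
#' `PBC = w_p * 1/(1 + log(1 + BA)) + w_e * SE` (natural logarithm), clamped
#' to `[0, 1]`. Decreasing in barriers, increasing in self-efficacy.
#'
#' @param barriers nonnegative barrier score (vectorised).
#' @param efficacy self-efficacy in `[0, 1]`.
#' @param params model parameters (`behavior$pbc` weights).
#' @return PBC score in `[0, 1]`.
#' @export
pbc_score <- function(barriers, efficacy, params = default_params()) {
  if (any(barriers < 0)) cs_stop("barriers must be nonnegative")
  w <- params$behavior$pbc
  clamp01(w[["barriers"]] / (1 + log1p(barriers)) + w[["efficacy"]] * efficacy)
}

#' Social influence of one contact
#'
#' The influence of a contact is the fraction of days within the
#' consistency window on which the contact performed the target behaviour:
#' `IN = (# days with a_k == target) / window`.
#'
#' @param history vector of the contact's daily actions over the last
#'   `window` days (pad with non-matching values before simulation start).
#' @param target the target behaviour to match.
#' @param window window length in days (defaults to the history length).
#' @return Influence in `[0, 1]`.
#' @export
#' @examples
#' social_influence(c(TRUE, FALSE, TRUE, TRUE), TRUE)  # 0.75
social_influence <- function(history, target, window = length(history)) {
  if (window <= 0) config_error("influence window must be at least 1 day")
  sum(history == target) / window
}

#' Social norms score
#'
#' Averages, over the agent's social contacts, a term combining each
#' contact's behavioural influence and the accumulated interaction frequency:
#' `SN = mean_k (IN_k / t + w_n * FQ_k / FQ_max) * IN_k`, clamped to `[0, 1]`.
#' As printed, the first term divides by the current simulation day `t`, so
#' behavioural alignment dominates early and interaction frequency dominates
#' late; setting `behavior$norms$time_mode` to `"window"` divides by the
#' window length instead. An empty contact set, or `t = 0`, gives 0.
#'
#' @param influence per-contact influence scores in `[0, 1]`.
#' @param freq per-contact cumulative interaction counts.
#' @param t current simulation day (>= 1 for a nonzero score).
#' @param fq_max normaliser for interaction counts.
#' @param params model parameters (`behavior$norms`).
#' @return Social norms score in `[0, 1]`.
#' @export
social_norms_score <- function(influence, freq, t, fq_max, params = default_params()) {
  if (length(influence) == 0 || t < 1) return(0)
  nm <- params$behavior$norms
  tt <- if (identical(nm$time_mode, "window")) nm$window_days else t
  clamp01(mean((influence / tt + nm$freq_weight * freq / fq_max) * influence))
}

#' Self-efficacy update
#'
#' Confidence in managing the disease evolves with continuity of care and
#' health status: `SE_t = clamp(w_p * SE_{t-1} + w_g * (exp(EX) + exp(H)))`.
#' Nondecreasing in continuity and in health status.
#'
#' @param se_prev previous self-efficacy in `[0, 1]` (vectorised).
#' @param ex continuity-of-care score in `[0, 1]`.
#' @param health health score in `[0, 1]`.
#' @param params model parameters (`behavior$efficacy` weights).
#' @return Updated self-efficacy in `[0, 1]`.
#' @export
self_efficacy_update <- function(se_prev, ex, health, params = default_params()) {
  w <- params$behavior$efficacy
  clamp01(w[["persist"]] * se_prev + w[["gain"]] * (exp(ex) + exp(health)))
}

#' Risk aversion update
#'
#' Prospect-theory-flavoured: sensitivity grows with disease severity while a
#' logarithmic term damps it as risk aversion accumulates:
#' `RA_t = clamp(w_s * SI_{t-1} - w_d * log(1 + RA_{t-1}))` (natural log).
#' Increasing in severity.
#'
#' @param ra_prev previous risk aversion in `[0, 1]` (vectorised).
#' @param si_prev previous severity index in `[0, 1]`.
#' @param params model parameters (`behavior$risk` weights).
#' @return Updated risk aversion in `[0, 1]`.
#' @export
risk_aversion_update <- function(ra_prev, si_prev, params = default_params()) {
  w <- params$behavior$risk
  clamp01(w[["severity"]] * si_prev - w[["damping"]] * log1p(ra_prev))
}

# factors entering the health-seeking utility under each theory set;
# the goal-framing (hedonic) term is active in every experiment
active_factors <- function(theories) {
  theories <- match.arg(tolower(theories), c("tpb", "hbm"), several.ok = TRUE)
  f <- "hedonic"
  if ("tpb" %in% theories) f <- c("attitude", "pbc", "norms", f)
  if ("hbm" %in% theories) f <- c(f, "risk", "efficacy")
  f
}

#' Health-seeking decision
#'
#' The health-seeking score is the weighted mean of the active behavioural
#' factors, `HS = sum(w_k * X_k) / sum(w_k)`, taken over the factors of the
#' active theory set only: attitude, perceived behavioural control and social
#' norms under the theory of planned behaviour; risk aversion and
#' self-efficacy under the health belief model; the hedonic (best available
#' provider) goal is active in every experiment. Agents with a score at or
#' above the decision threshold (default 0.5) seek care; agents at the urgent
#' symptom stage seek care immediately regardless of their score.
#'
#' @param factors named list or data frame with components `attitude`, `pbc`,
#'   `norms`, `risk`, `efficacy`, `hedonic` (vectors of equal length; only the
#'   active ones are required).
#' @param params model parameters (`behavior$decision` weights + threshold).
#' @param theories character subset of `c("tpb", "hbm")`.
#' @param urgent logical (vectorised): whether the agent is at the urgent
#'   stage.
#' @return A list with `score` (the HS score) and `seek` (logical).
#' @export
#' @examples
#' health_seeking(list(attitude = 0.6, pbc = 0.6, norms = 0.6,
#'                     risk = 0.6, efficacy = 0.6, hedonic = 0.6))$seek
health_seeking <- function(factors, params = default_params(),
                           theories = c("tpb", "hbm"), urgent = FALSE) {
  act <- active_factors(theories)
  w <- params$behavior$decision[act]
  if (sum(w) <= 0) config_error("active decision weights must not all be zero")
  num <- 0
  for (k in act) {
    if (is.null(factors[[k]])) cs_stop("missing factor '", k, "'")
    num <- num + w[[k]] * factors[[k]]
  }
  score <- num / sum(w)
  list(score = score, seek = score >= params$behavior$threshold | urgent)
}
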