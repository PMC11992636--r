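#' Hedonic goal of visiting a provider
#'
#' Disutility grows with normalised travel distance and travel time:
#' `HG = 1 - (w_d * DIS/DIS_max + w_t * TT/TT_max)`, clamped to `[0, 1]`.
#' Travel time is distance over the configured travel speed; distances above
#' `DIS_max` are treated as `DIS_max`.
#'
#' @param dis distance to the provider in km (vectorised).
#' @param dis_max maximum possible distance in the region (km).
#' @param tt_max maximum travel time in the region (minutes); defaults to
#'   `dis_max` over the travel speed.
#' @param params model parameters (`choice` weights).
#' @return Hedonic goal in `[0, 1]`.
#' @export
#' @examples
#' hedonic_goal(0, dis_max = 10)  # 1: no disutility when co-located
hedonic_goal <- function(dis, dis_max, tt_max = NULL, params = default_params()) {
  ch <- params$choice
  speed <- ch$travel_speed_kmh / 60  # km per minute
  if (is.null(tt_max)) tt_max <- dis_max / speed
  dis <- pmin(dis, dis_max)
  tt <- dis / speed
  clamp01(1 - (ch$distance * dis / dis_max + ch$time * tt / tt_max))
}

#' Normative goal of visiting a provider
#'
#' Nonlinear in reputation and trust:
#' `NG = w_r * RP^a_r + w_q * TR^a_q`, clamped to `[0, 1]`. Exponents above 1
#' give accelerating returns, below 1 diminishing returns.
#'
#' @param reputation provider reputation as perceived by the agent, in
#'   `[0, 1]` (vectorised).
#' @param trust the agent's trust in the provider, in `[0, 1]`.
#' @param params model parameters (`choice` weights and exponents).
#' @return Normative goal in `[0, 1]`.
#' @export
normative_goal <- function(reputation, trust, params = default_params()) {
  ch <- params$choice
  clamp01(ch$reputation * reputation^ch$pow_reputation +
            ch$trust * trust^ch$pow_trust)
}

#' Choose a care provider
#'
#' Utility-maximising provider choice: the agent selects the candidate
#' provider maximising `w_h * HG + w_v * NG`. Candidates are restricted to
#' open providers (hospitals are always open); an agent at the urgent stage
#' falls back to hospitals only when no medical centre is open with an
#' expected wait within the urgent bound; an agent that has switched to
#' hospital care considers hospitals only. Ties are broken by smaller
#' distance, then lower provider id.
#'
#' @param hg per-provider hedonic goals.
#' @param reputation,trust per-provider reputation and trust scores.
#' @param dis per-provider distances (km), used for tie-breaking.
#' @param kind per-provider kind (`"hospital"` or `"medical_center"`).
#' @param open logical: provider currently open.
#' @param params model parameters.
#' @param urgent is the agent at the urgent stage?
#' @param prefer_hospital has the agent switched to hospital-only care?
#' @param expected_wait per-provider expected wait in days.
#' @return The index of the chosen provider.
#' @export
choose_service <- function(hg, reputation, trust, dis, kind, open,
                           params = default_params(), urgent = FALSE,
                           prefer_hospital = FALSE, expected_wait = 0) {
  if (length(hg) == 0) cs_stop("provider list must be non-empty")
  ch <- params$choice
  hosp <- kind == "hospital"
  cand <- open | hosp
  expected_wait <- rep_len(expected_wait, length(hg))
  if (prefer_hospital) cand <- cand & hosp
  if (urgent && !any(cand & !hosp & expected_wait <= ch$urgent_wait_days)) {
    cand <- cand & hosp
  }
  if (!any(cand)) cs_stop("no provider available (roster must contain a hospital)")
  u <- ch$hedonic * hg + ch$normative * normative_goal(reputation, trust, params)
  # deterministic tie-break: smaller distance, then lower provider id
  u <- u - 1e-9 * dis / max(dis, 1) - 1e-12 * seq_along(u)
  u[!cand] <- -Inf
  which.max(u)
}

#' Trust update after a visit
#'
#' Experience-based learning: a successful diagnosis reinforces trust and an
#' unsuccessful one erodes it:
#' `TR_t = clamp(a * TR_{t-1} + g * D - d * (1 - D))` with `D = 1` on a
#' successful diagnosis (or met urgent need) and 0 otherwise.
#'
#' @param trust_prev previous trust in `[0, 1]` (vectorised).
#' @param success diagnosis outcome indicator (logical or 0/1).
#' @param params model parameters (`choice$trust_*`).
#' @return Updated trust in `[0, 1]`.
#' @export
#' @examples
#' trust_update(0.5, TRUE)   # reinforced
#' trust_update(0.5, FALSE)  # penalised
trust_update <- function(trust_prev, success, params = default_params()) {
  ch <- params$choice
  d <- as.numeric(success)
  clamp01(ch$trust_persist * trust_prev + ch$trust_gain * d -
            ch$trust_penalty * (1 - d))
}

#' Reputation update from network feedback
#'
#' Collective satisfaction within the agent's network, with recent feedback
#' weighted against accumulated reputation:
#' `RP_t = lambda * RP_{t-1} + (1 - lambda) * mean(FE)`. With no feedback
#' this tick the reputation is unchanged.
#'
#' @param rep_prev previous reputation in `[0, 1]`.
#' @param feedback numeric vector of feedback scores in `[0, 1]` received
#'   this tick (may be empty).
#' @param params model parameters (`choice$rep_decay`).
#' @return Updated reputation in `[0, 1]`.
#' @export
reputation_update <- function(rep_prev, feedback, params = default_params()) {
  if (length(feedback) == 0) return(rep_prev)
  lam <- params$choice$rep_decay
  clamp01(lam * rep_prev + (1 - lam) * mean(feedback))
}
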