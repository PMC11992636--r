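#' Overall health status
#'
#' The overall health score of an agent combines chronic-condition severities
#' and the diabetes severity index:
#' `H = sum(w_z * C_z) + p * SI`, clamped to `[0, 1]`, where 0 is completely
#' healthy and 1 completely unhealthy. All chronic conditions share the same
#' weight (`disease$condition_weight`, default 0.5) and `p`
#' (`disease$si_weight`) scales the contribution of the severity index.
#'
#' @param conditions numeric vector of chronic-condition severities in
#'   `[0, 1]` for one agent (may be empty).
#' @param si diabetes severity index in `[0, 1]`.
#' @param params model parameters.
#' @return Health score in `[0, 1]`.
#' @export
#' @examples
#' health_status(c(1), 0.4)  # 0.5*1 + 0.5*0.4 = 0.7
health_status <- function(conditions, si, params = default_params()) {
  d <- params$disease
  clamp01(sum(d$condition_weight * conditions) + d$si_weight * si)
}

#' Advance the diabetes severity index
#'
#' Severity advances linearly at a monthly base rate that differs between
#' undiagnosed and diagnosed agents: `SI_t = min(1, SI_{t-1} + rp * dt/30)`.
#' Monotone nondecreasing; non-diabetic agents are returned unchanged.
#'
#' @param si current severity index (vectorised).
#' @param status `"none"`, `"undiagnosed"` or `"diagnosed"` (vectorised).
#' @param dt_days elapsed days.
#' @param params model parameters.
#' @return Updated severity index.
#' @export
#' @examples
#' progress_severity(0.2, "undiagnosed", 30,
#'                   update_params(default_params(), "disease.rp_undiagnosed" = 0.003))
progress_severity <- function(si, status, dt_days = 1, params = default_params()) {
  d <- params$disease
  rate <- ifelse(status == "undiagnosed", d$rp_undiagnosed,
                 ifelse(status == "diagnosed", d$rp_diagnosed, 0))
  pmin(1, si + rate * dt_days / 30)
}

.stages <- c("asymptomatic", "mild", "noticeable", "urgent")

#' Classify the symptom stage of a severity index
#'
#' Half-open threshold intervals: `[0, s_onset)` asymptomatic,
#' `[s_onset, s_notice)` mild, `[s_notice, s_urgent)` noticeable,
#' `[s_urgent, 1]` urgent.
#'
#' @param si severity index in `[0, 1]` (vectorised).
#' @param params model parameters.
#' @return Factor with levels asymptomatic, mild, noticeable, urgent.
#' @export
#' @examples
#' symptom_stage(c(0, 0.35, 0.5, 0.9))
symptom_stage <- function(si, params = default_params()) {
  d <- params$disease
  idx <- findInterval(si, c(d$s_onset, d$s_notice, d$s_urgent)) + 1L
  factor(.stages[idx], levels = .stages)
}
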