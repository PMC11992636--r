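#' Process a single visit
#'
#' Hospital visits go straight to the emergency department where diabetes
#' diagnosis is certain for a diabetic visitor. Medical centres diagnose
#' noticeable-stage diabetics via lab-test referral, diagnose mild-stage
#' diabetics with per-visit probability `q_mild` (otherwise the patient is
#' sent home undiagnosed), and refer urgent cases directly to hospital for
#' same-day treatment. Non-diabetic visitors are never diagnosed with
#' diabetes. Each visit is charged the provider's tariff.
#'
#' The mild-stage diagnosis draw uses the current R random number stream.
#'
#' @param diabetic is the visitor an (undiagnosed) diabetic?
#' @param stage symptom stage (`"asymptomatic"`, `"mild"`, `"noticeable"`,
#'   `"urgent"`).
#' @param provider_kind `"hospital"` or `"medical_center"`.
#' @param params model parameters.
#' @param q_mild per-visit mild-stage diagnosis probability (defaults to
#'   `params$care$q_mild`).
#' @param cost tariff for this visit (defaults to the kind's tariff).
#' @return A list with `diagnosed`, `referred` (urgent referral to hospital)
#'   and `cost` (AUD for this visit only; a referral's hospital leg is a
#'   separate visit).
#' @export
process_visit <- function(diabetic, stage, provider_kind,
                          params = default_params(),
                          q_mild = NULL, cost = NULL) {
  care <- params$care
  stage <- as.character(stage)
  if (provider_kind == "hospital") {
    return(list(diagnosed = isTRUE(diabetic), referred = FALSE,
                cost = cost %||% care$cost_ed))
  }
  cost <- cost %||% care$cost_screen
  if (stage == "urgent") {
    return(list(diagnosed = FALSE, referred = TRUE, cost = cost))
  }
  diagnosed <- isTRUE(diabetic) && (
    stage == "noticeable" ||
      (stage == "mild" && stats::runif(1) < (q_mild %||% care$q_mild))
  )
  list(diagnosed = diagnosed, referred = FALSE, cost = cost)
}

#' Repeat-failure switch rule
#'
#' Once a medical centre has repeatedly failed to identify diabetes, the
#' patient switches to hospital care: after `n_fail` failed medical-centre
#' visits (default 3) the candidate set is restricted to hospitals until
#' diagnosis, which clears the counter.
#'
#' @param failed_visits number of failed medical-centre visits (vectorised).
#' @param params model parameters.
#' @return Logical: prefer hospitals from now on.
#' @export
switch_rule <- function(failed_visits, params = default_params()) {
  failed_visits >= params$care$n_fail
}

#' Aggregate visit costs
#'
#' Sums per-visit costs by provider kind. Deterministic given the log and
#' additive over log partitions.
#'
#' @param visits a visit log data frame with columns `provider_kind` and
#'   `cost` (as produced by [run_simulation()]).
#' @return A list with `total_medical`, `total_hospital` and `total`.
#' @export
accrue_costs <- function(visits) {
  mc <- sum(visits$cost[visits$provider_kind == "medical_center"])
  h <- sum(visits$cost[visits$provider_kind == "hospital"])
  list(total_medical = mc, total_hospital = h, total = mc + h)
}
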