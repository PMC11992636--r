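# Shared fixtures and independent oracle transcriptions.
#
# The oracle functions below are deliberately naive scalar transcriptions of
# the model's update equations, written independently of the package
# implementation, so that equation-level tests compare two separately coded
# routes.

clamp_ <- function(x) min(1, max(0, x))
`%||%` <- function(a, b) if (is.null(a)) b else a

or_trust <- function(tr, a, g, d, D) clamp_(a * tr + g * D - d * (1 - D))
or_influence <- function(hist, target, dt) sum(hist == target) / dt
or_reputation <- function(rp, lam, fe) {
  if (length(fe) == 0) return(rp)
  clamp_(lam * rp + (1 - lam) * sum(fe) / length(fe))
}
or_health <- function(C, w, p, si) clamp_(sum(w * C) + p * si)
or_progress <- function(si, rp) min(1, si + rp)
or_decision <- function(x, w) sum(w * x) / sum(w)
or_attitude <- function(x, th) 1 / (1 + exp(-sum(th * x)))
or_pbc <- function(ba, se, thp, the) clamp_(thp * (1 / (1 + log(1 + ba))) + the * se)
or_norms <- function(inf, fq, t, thn, fqmax) {
  if (length(inf) == 0 || t < 1) return(0)
  clamp_(sum((inf / t + thn * fq / fqmax) * inf) / length(inf))
}
or_efficacy <- function(se, ex, h, thp, thj) clamp_(thp * se + thj * (exp(ex) + exp(h)))
or_risk <- function(ra, si, ths, thr) clamp_(ths * si - thr * log(1 + ra))
or_choice <- function(hg, ng, th, tv) which.max(th * hg + tv * ng)
or_hedonic <- function(dis, dmax, tt, ttmax, thd, tht) {
  clamp_(1 - (thd * dis / dmax + tht * tt / ttmax))
}
or_normative <- function(rp, tr, thr, thq, ar, aq) clamp_(thr * rp^ar + thq * tr^aq)

# a small in-code region for fast engine tests
tiny_config <- function(n_agents = 80, undiagnosed = 0.5, diagnosed = 0.1,
                        providers = NULL) {
  if (is.null(providers)) {
    providers <- list(
      list(kind = "hospital", location = c(2, 2), reputation = 0.66),
      list(kind = "medical_center", location = c(1.2, 2.4), reputation = 0.62)
    )
  }
  validate_region_config(list(
    name = "tinytown",
    n_agents = n_agents,
    extent_km = c(4, 4),
    prevalence = list(undiagnosed = undiagnosed, diagnosed = diagnosed),
    providers = providers,
    demographics = list(),
    network = list(mean_degree = 4)
  ))
}

# random parameter sets with every weight drawn afresh (for oracle sweeps)
random_params <- function() {
  p <- default_params()
  p$behavior$decision[] <- runif(6, 0.1, 2)
  p$behavior$attitude[] <- runif(6, 0, 2)
  p$behavior$pbc[] <- runif(2, 0, 1)
  p$behavior$norms$freq_weight <- runif(1, 0, 1)
  p$behavior$efficacy[] <- runif(2, 0, 1)
  p$behavior$risk[] <- runif(2, 0, 1)
  p$choice$hedonic <- runif(1, 0, 1); p$choice$normative <- runif(1, 0, 1)
  p$choice$distance <- runif(1, 0, 1); p$choice$time <- runif(1, 0, 1)
  p$choice$reputation <- runif(1, 0, 1); p$choice$trust <- runif(1, 0, 1)
  p$choice$pow_reputation <- runif(1, 0.3, 2); p$choice$pow_trust <- runif(1, 0.3, 2)
  p$choice$trust_persist <- runif(1); p$choice$trust_gain <- runif(1, 0, 0.5)
  p$choice$trust_penalty <- runif(1, 0, 0.5); p$choice$rep_decay <- runif(1)
  p
}
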