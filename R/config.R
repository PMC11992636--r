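#' Region configurations
#'
#' A region configuration describes one simulated community: the number of
#' patient agents, the spatial extent, the provider roster (medical centres
#' and at least one hospital), the demographic marginals the population
#' synthesiser draws from, baseline diabetes prevalence (split into
#' undiagnosed and already-diagnosed), and social-network parameters.
#'
#' Two stylised configurations ship with the package, `"gilgandra"` (4,101
#' agents, 3 medical centres + 1 hospital) and `"narromine"` (6,190 agents,
#' 1 medical centre + 1 hospital). Their demographic marginals are shaped on
#' census/health-survey style variables but are deliberately stylised, not
#' reproductions of any survey.
#'
#' @param name `"gilgandra"` or `"narromine"`.
#' @param path path to a YAML region file.
#' @param config a region configuration list.
#' @return A validated list of class `careseek_config`.
#' @export
#' @examples
#' cfg <- region_config("gilgandra")
#' cfg$n_agents
region_config <- function(name) {
  file <- system.file("extdata", paste0(name, ".yaml"), package = "careseek")
  if (file == "") config_error("no shipped region configuration named '", name, "'")
  load_region_config(file)
}

#' @rdname region_config
#' @export
load_region_config <- function(path) {
  if (!file.exists(path)) config_error("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_region_config(cfg)
}

#' @rdname region_config
#' @export
save_region_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

.config_keys <- c("name", "n_agents", "extent_km", "prevalence", "providers",
                  "demographics", "network", "params")
.provider_keys <- c("kind", "location", "reputation", "capacity", "q_mild",
                    "cost_screen", "cost_ed")
.demographic_keys <- c("age", "gender", "indigenous", "ses", "education",
                       "health_literacy", "mental_health", "health_behaviors",
                       "cultural_beliefs", "barriers", "chronic")

#' @rdname region_config
#' @export
validate_region_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) config_error("unknown configuration key(s): ",
                                    paste(unknown, collapse = ", "))
  if (!is_count(config$n_agents) || config$n_agents < 1) {
    config_error("n_agents must be a positive count")
  }
  ext <- unlist(config$extent_km)
  if (length(ext) != 2 || any(ext <= 0)) config_error("extent_km must be two positive numbers")
  config$extent_km <- as.numeric(ext)

  pv <- config$prevalence
  if (is.null(pv$undiagnosed) || is.null(pv$diagnosed)) {
    config_error("prevalence must give both undiagnosed and diagnosed fractions")
  }
  if (pv$undiagnosed < 0 || pv$diagnosed < 0 ||
      pv$undiagnosed > 1 || pv$diagnosed > 1 ||
      pv$undiagnosed + pv$diagnosed > 1) {
    config_error("prevalence fractions must lie in [0, 1] and sum to at most 1")
  }

  if (length(config$providers) == 0) config_error("provider roster must be non-empty")
  kinds <- vapply(config$providers, function(p) p$kind %||% "", "")
  if (!all(kinds %in% c("hospital", "medical_center"))) {
    config_error("provider kind must be 'hospital' or 'medical_center'")
  }
  if (!any(kinds == "hospital")) {
    config_error("provider roster must contain at least one hospital (urgent referral would be undefined)")
  }
  for (p in config$providers) {
    unknown <- setdiff(names(p), .provider_keys)
    if (length(unknown)) config_error("unknown provider key(s): ",
                                      paste(unknown, collapse = ", "))
    loc <- unlist(p$location)
    if (length(loc) != 2 || any(loc < 0) || loc[1] > config$extent_km[1] ||
        loc[2] > config$extent_km[2]) {
      config_error("provider location must lie within the region extent")
    }
  }

  unknown <- setdiff(names(config$demographics), .demographic_keys)
  if (length(unknown)) config_error("unknown demographic key(s): ",
                                    paste(unknown, collapse = ", "))
  for (field in names(config$demographics)) {
    validate_marginal(config$demographics[[field]], field)
  }
  structure(config, class = c("careseek_config", "list"))
}

# a marginal is either a scalar (fixed / Bernoulli probability), a named set
# of category probabilities, a distribution spec with a `dist` key, or a
# gender-conditional list of such specs
validate_marginal <- function(spec, field) {
  if (is.numeric(spec) && length(spec) == 1) return(invisible(TRUE))
  if (!is.list(spec)) config_error("invalid marginal for '", field, "'")
  if (field == "chronic") {
    # structured chronic-condition block: counts + a severity marginal
    if (!is.null(spec$severity)) validate_marginal(spec$severity, "chronic.severity")
    return(invisible(TRUE))
  }
  if (is.null(spec$dist)) {
    if (all(names(spec) %in% c("male", "female")) && is.list(spec[[1]])) {
      for (g in names(spec)) validate_marginal(spec[[g]], paste0(field, ".", g))
      return(invisible(TRUE))
    }
    probs <- unlist(spec)
    if (!is.numeric(probs) || is.null(names(probs))) {
      config_error("invalid marginal for '", field, "'")
    }
    if (abs(sum(probs) - 1) > 1e-8) {
      config_error("category probabilities for '", field, "' must sum to 1")
    }
    return(invisible(TRUE))
  }
  ok <- switch(spec$dist,
    uniform   = !is.null(spec$min) && !is.null(spec$max),
    normal    = !is.null(spec$mean) && !is.null(spec$sd),
    beta      = !is.null(spec$shape1) && !is.null(spec$shape2),
    lognormal = !is.null(spec$meanlog) && !is.null(spec$sdlog),
    bernoulli = !is.null(spec$prob),
    fixed     = !is.null(spec$value),
    NULL)
  if (is.null(ok) && field == "chronic") return(invisible(TRUE))
  if (is.null(ok) || !ok) config_error("invalid distribution spec for '", field, "'")
  invisible(TRUE)
}

# draw n values from a marginal spec; `gender` enables gender-conditional specs
draw_marginal <- function(spec, n, field, gender = NULL) {
  if (is.numeric(spec) && length(spec) == 1) return(rep(as.numeric(spec), n))
  if (is.null(spec$dist)) {
    if (all(names(spec) %in% c("male", "female")) && is.list(spec[[1]])) {
      if (is.null(gender)) config_error("gender-conditional marginal for '", field,
                                        "' requires gender to be drawn first")
      out <- numeric(n)
      for (g in names(spec)) {
        idx <- which(gender == g)
        if (length(idx)) out[idx] <- draw_marginal(spec[[g]], length(idx), field)
      }
      return(out)
    }
    probs <- unlist(spec)
    return(sample(names(probs), n, replace = TRUE, prob = probs))
  }
  switch(spec$dist,
    uniform   = stats::runif(n, spec$min, spec$max),
    normal    = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      if (!is.null(spec$min)) x <- pmax(spec$min, x)
      if (!is.null(spec$max)) x <- pmin(spec$max, x)
      x
    },
    beta      = stats::rbeta(n, spec$shape1, spec$shape2),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    bernoulli = stats::runif(n) < spec$prob,
    fixed     = rep(spec$value, n),
    config_error("invalid distribution spec for '", field, "'"))
}
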