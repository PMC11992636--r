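#' Apply an intervention to the model parameters
#'
#' Two intervention programmes are supported, applied as population-level
#' multipliers when a world is initialised:
#' \describe{
#'   \item{awareness}{Targeted health-education campaigns: every agent's
#'     health literacy is multiplied by 1.20 (clamped to 1) and the social
#'     interaction parameters (daily edge interaction probability and the
#'     interaction-frequency weight of the social-norms function) by 1.15.}
#'   \item{access}{Improved infrastructure and service availability:
#'     perceived barriers to care are multiplied by 0.70 and all
#'     agent-provider distances by 0.75.}
#' }
#' `"none"` is the identity.
#'
#' @param params model parameters.
#' @param intervention `"none"`, `"awareness"` or `"access"`.
#' @return The parameter list with the intervention multipliers set.
#' @export
#' @examples
#' p <- apply_intervention(default_params(), "awareness")
#' p$intervention$hl_mult  # 1.2
apply_intervention <- function(params, intervention = "none") {
  if (!intervention %in% c("none", "awareness", "access")) {
    config_error("unknown intervention: ", intervention)
  }
  iv <- list(hl_mult = 1, social_mult = 1, barrier_mult = 1, distance_mult = 1)
  if (intervention == "awareness") {
    iv$hl_mult <- 1.20
    iv$social_mult <- 1.15
  } else if (intervention == "access") {
    iv$barrier_mult <- 0.70
    iv$distance_mult <- 0.75
  }
  params$intervention <- iv
  params
}

#' Define a simulation scenario
#'
#' A scenario bundles a region, an active theory set (goal framing always
#' governs provider choice), an intervention, the horizon, the number of
#' replications and the base seed. Replication `r` runs with seed
#' `base_seed + r - 1`.
#'
#' @param region region name or `careseek_config`.
#' @param theories non-empty subset of `c("tpb", "hbm")`.
#' @param intervention `"none"`, `"awareness"` or `"access"`.
#' @param horizon days.
#' @param replications number of replications (>= 1).
#' @param base_seed integer seed of the first replication.
#' @return A list of class `careseek_scenario`.
#' @export
scenario <- function(region = "gilgandra", theories = c("tpb", "hbm"),
                     intervention = "none", horizon = 4000,
                     replications = 100, base_seed = 1L) {
  if (length(theories) == 0) config_error("theories must be non-empty")
  theories <- match.arg(tolower(theories), c("tpb", "hbm"), several.ok = TRUE)
  if (!is_count(replications) || replications < 1) {
    config_error("replications must be a positive count")
  }
  structure(list(region = region, theories = theories,
                 intervention = intervention, horizon = horizon,
                 replications = replications, base_seed = as.integer(base_seed)),
            class = c("careseek_scenario", "list"))
}

#' Run a replicated experiment
#'
#' Runs the scenario's replications with consecutive seeds and aggregates
#' the per-run summary statistics into means with normal-approximation 95%
#' confidence intervals (`mean +/- 1.96 * SE`).
#'
#' @param spec a `careseek_scenario`.
#' @param params model parameters.
#' @param planned_before cutoff day for the planned share (see
#'   [summarize_result()]).
#' @return A list of class `careseek_experiment` with `summaries` (one row
#'   per replication) and `stats` (per-metric mean, sd and 95% CI).
#' @export
#' @examples
#' \donttest{
#' ex <- run_experiment(scenario("gilgandra", replications = 2, horizon = 600))
#' ex$stats
#' }
run_experiment <- function(spec, params = default_params(), planned_before = 3000) {
  if (is.character(spec$region)) spec$region <- region_config(spec$region)
  rows <- vector("list", spec$replications)
  for (r in seq_len(spec$replications)) {
    res <- run_simulation(spec$region, params, spec$theories,
                          spec$intervention, spec$horizon,
                          seed = spec$base_seed + r - 1L)
    s <- summarize_result(res, planned_before = planned_before)
    rows[[r]] <- as.data.frame(s)
    rows[[r]]$replication <- r
    rows[[r]]$seed <- spec$base_seed + r - 1L
  }
  summaries <- do.call(rbind, rows)
  metrics <- setdiff(names(summaries), c("replication", "seed"))
  stats <- do.call(rbind, lapply(metrics, function(mname) {
    v <- summaries[[mname]]
    v <- v[!is.na(v)]
    if (!length(v)) return(data.frame(metric = mname, mean = NA_real_,
                                      sd = NA_real_, ci_lower = NA_real_,
                                      ci_upper = NA_real_, n = 0L))
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(metric = mname, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               ci_lower = mean(v) - 1.96 * se, ci_upper = mean(v) + 1.96 * se,
               n = length(v))
  }))
  structure(list(summaries = summaries, stats = stats, scenario = spec),
            class = c("careseek_experiment", "list"))
}

#' @export
print.careseek_experiment <- function(x, ...) {
  sp <- x$scenario
  cat("careseek experiment:", if (is.character(sp$region)) sp$region else sp$region$name,
      "|", paste(sp$theories, collapse = "+"), "| intervention:",
      sp$intervention, "|", sp$replications, "replications\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' One-factor-at-a-time sensitivity analysis
#'
#' Perturbs each target parameter over a grid of relative perturbations
#' (default -20% to +20%), runs a batch of seeded replications per setting,
#' and records the percentage change of a summary statistic against the
#' seed-matched unperturbed baseline. Perturbations that violate parameter
#' invariants are skipped with a warning.
#'
#' @param params model parameters.
#' @param target_params character vector of dotted parameter paths, e.g.
#'   `"behavior.decision.attitude"`.
#' @param perturbations relative perturbation grid.
#' @param runs_per_setting seeded runs per grid point.
#' @param region,theories,horizon,n_agents scenario of the runs;
#'   `n_agents` overrides the region's agent count (subsampling).
#' @param metric name of the summary statistic to track.
#' @param seed base seed.
#' @return A list of class `careseek_ofat` with `changes` (long table of
#'   percentage changes) and `by_param` (per-parameter median, quartiles and
#'   IQR half-width of the change distribution).
#' @export
ofat_sensitivity <- function(params = default_params(),
                             target_params = paste0("behavior.decision.",
                                                    c("attitude", "pbc", "norms",
                                                      "risk", "efficacy", "hedonic")),
                             perturbations = c(-0.20, -0.15, -0.10, -0.05,
                                               0.05, 0.10, 0.15, 0.20),
                             runs_per_setting = 10,
                             region = "gilgandra", theories = c("tpb", "hbm"),
                             horizon = 3000, n_agents = 1000,
                             metric = "late_rate", seed = 1L) {
  config <- if (is.character(region)) region_config(region) else region
  if (!is.null(n_agents)) config$n_agents <- as.integer(n_agents)
  seeds <- seed + seq_len(runs_per_setting) - 1L
  run_metric <- function(pp, s) {
    res <- run_simulation(config, pp, theories, "none", horizon, seed = s)
    summarize_result(res)[[metric]]
  }
  baseline <- vapply(seeds, function(s) run_metric(params, s), 0)
  rows <- list()
  for (path in target_params) {
    base_val <- get_path(params, path)
    for (d in perturbations) {
      pp <- try(do.call(update_params,
                        c(list(params), stats::setNames(list(base_val * (1 + d)), path))),
                silent = TRUE)
      if (inherits(pp, "try-error")) {
        warning("skipping infeasible perturbation ", path, " ", d)
        next
      }
      vals <- vapply(seeds, function(s) run_metric(pp, s), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        param = path, perturbation = d, run = seq_along(seeds),
        baseline = baseline, value = vals,
        pct_change = 100 * (vals - baseline) / baseline)
    }
  }
  changes <- do.call(rbind, rows)
  by_param <- do.call(rbind, lapply(split(changes, changes$param), function(df) {
    q <- stats::quantile(df$pct_change, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(param = df$param[1], median = q[[2]], q25 = q[[1]], q75 = q[[3]],
               iqr_half_width = (q[[3]] - q[[1]]) / 2)
  }))
  rownames(by_param) <- NULL
  structure(list(changes = changes, by_param = by_param, metric = metric),
            class = c("careseek_ofat", "list"))
}

#' Calibrate model parameters to summary-statistic targets
#'
#' Seeded random search with local refinement: free parameters are sampled
#' uniformly within their bounds, each candidate is scored by a small
#' replication batch, and the best candidate is refined by shrinking
#' perturbations. The objective is
#' `sum(((simulated - target) / tolerance)^2)` over the targets. The shipped
#' default parameters are the output of this procedure against published
#' regional summaries.
#'
#' @param targets data frame with columns `metric`, `target`, `tolerance`
#'   (metric names as in [summarize_result()]).
#' @param search_space named list of `c(lower, upper)` bounds; names are
#'   dotted parameter paths.
#' @param budget total number of candidate evaluations.
#' @param seed integer seed for the search and the simulation batches.
#' @param params starting parameters.
#' @param region,theories,horizon,replications,n_agents evaluation scenario
#'   (`n_agents` subsamples the region for cheaper evaluations).
#' @return A list with the best `params`, the `achieved` statistics, the
#'   `objective` value, whether the search `converged` (every target within
#'   twice its tolerance), and the evaluation `history`.
#' @export
calibrate_params <- function(targets, search_space, budget = 40, seed = 1L,
                             params = default_params(),
                             region = "gilgandra", theories = c("tpb", "hbm"),
                             horizon = 3000, replications = 2, n_agents = 1000) {
  if (!nrow(targets)) config_error("calibration target list must be non-empty")
  if (!all(c("metric", "target", "tolerance") %in% names(targets))) {
    config_error("targets must have columns metric, target, tolerance")
  }
  config <- if (is.character(region)) region_config(region) else region
  if (!is.null(n_agents)) config$n_agents <- as.integer(n_agents)
  paths <- names(search_space)
  evaluate <- function(pp) {
    vals <- sapply(seq_len(replications), function(r) {
      res <- run_simulation(config, pp, theories, "none", horizon,
                            seed = seed + 1000L + r)
      unlist(summarize_result(res)[targets$metric])
    })
    ach <- if (is.matrix(vals)) rowMeans(vals) else mean(vals)
    obj <- sum(((ach - targets$target) / targets$tolerance)^2)
    list(achieved = ach, objective = obj)
  }
  set.seed(as.integer(seed))
  apply_point <- function(point) {
    do.call(update_params, c(list(params), as.list(stats::setNames(point, paths))))
  }
  best <- list(params = params, point = vapply(paths, function(p) get_path(params, p), 0))
  ev <- evaluate(params)
  best$achieved <- ev$achieved; best$objective <- ev$objective
  history <- data.frame(eval = 1L, objective = ev$objective)
  n_explore <- max(1L, floor(budget * 0.6))
  for (e in seq_len(budget)) {
    # the simulation runs inside evaluate() reset the global RNG, so the
    # search stream is re-seeded deterministically for every candidate
    set.seed(as.integer(seed) + 7919L + e)
    point <- if (e <= n_explore) {
      vapply(search_space, function(b) stats::runif(1, b[1], b[2]), 0)
    } else {
      # local refinement around the incumbent, shrinking with progress
      shrink <- 0.25 * (1 - (e - n_explore) / (budget - n_explore + 1))
      pmax(vapply(search_space, `[`, 0, 1),
           pmin(vapply(search_space, `[`, 0, 2),
                best$point + vapply(search_space, function(b) {
                  stats::rnorm(1, 0, shrink * (b[2] - b[1]))
                }, 0)))
    }
    pp <- try(apply_point(point), silent = TRUE)
    if (inherits(pp, "try-error")) next
    ev <- evaluate(pp)
    history <- rbind(history, data.frame(eval = e + 1L, objective = ev$objective))
    if (ev$objective < best$objective) {
      best <- list(params = pp, point = point, achieved = ev$achieved,
                   objective = ev$objective)
    }
  }
  converged <- all(abs(best$achieved - targets$target) <= 2 * targets$tolerance)
  list(params = best$params, achieved = best$achieved,
       objective = best$objective, converged = converged, history = history)
}
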