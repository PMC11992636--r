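#' Write a simulation result to a directory
#'
#' Serialises a `careseek_result` as a directory of CSV files
#' (`series.csv`, `diagnoses.csv`, `visits.csv`, `summary.csv`) plus a
#' `manifest.yaml` carrying everything needed to reproduce the run: region,
#' theory set, intervention, horizon, seed and package version.
#'
#' @param result a `careseek_result`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$series, file.path(dir, "series.csv"), row.names = FALSE)
  utils::write.csv(result$diagnoses, file.path(dir, "diagnoses.csv"), row.names = FALSE)
  utils::write.csv(result$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  s <- summarize_result(result)
  utils::write.csv(data.frame(metric = names(s), value = unlist(s)),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  manifest <- c(result$meta,
                list(package_version = as.character(utils::packageVersion("careseek")),
                     r_version = as.character(getRversion())))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Recompute summary tables from a stored result directory
#'
#' Reads the CSV files written by [write_result()] and recomputes the
#' headline summary tables: diagnoses by provider kind and planned status,
#' late-diagnosis rates by gender and provider kind, and cost totals.
#'
#' @param dir a directory written by [write_result()].
#' @return A list of data frames.
#' @export
report_result <- function(dir) {
  dg <- utils::read.csv(file.path(dir, "diagnoses.csv"))
  vs <- utils::read.csv(file.path(dir, "visits.csv"))
  by_kind <- as.data.frame(table(kind = dg$provider_kind, planned = dg$planned))
  late <- stats::aggregate(late ~ gender + provider_kind, dg, mean)
  names(late)[3] <- "late_rate"
  costs <- stats::aggregate(cost ~ provider_kind, vs, sum)
  list(diagnoses_by_kind = by_kind, late_rates = late, costs = costs)
}
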