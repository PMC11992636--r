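#' @keywords internal
"_PACKAGE"

# clamp to the unit interval; every recursively updated score in the model
# is kept in [0, 1] after each update
clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

`%||%` <- function(a, b) if (is.null(a)) b else a

cs_stop <- function(..., class = "careseek_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

config_error <- function(...) cs_stop(..., class = "careseek_config_error")

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)

# get / set a value in a nested list by a dotted path such as
# "behavior.decision.attitude" (used by the sensitivity and calibration tools)
get_path <- function(lst, path) {
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(lst[[key]])) cs_stop("unknown parameter path: ", path)
    lst <- lst[[key]]
  }
  lst
}

set_path <- function(lst, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    if (is.null(lst[[keys]])) cs_stop("unknown parameter path: ", path)
    lst[[keys]] <- value
    return(lst)
  }
  head <- keys[1]
  if (is.null(lst[[head]])) cs_stop("unknown parameter path: ", path)
  lst[[head]] <- set_path(lst[[head]], paste(keys[-1], collapse = "."), value)
  lst
}
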