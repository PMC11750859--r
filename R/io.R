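# Trace and configuration I/O: CSV traces (column 1 = time in ms, one
# column per recording site), YAML/JSON parameter trees.

#' Write / read a trace set as CSV
#'
#' Column 1 is `time_ms`; the remaining columns are one per recording site,
#' with the site labels as header.
#'
#' @param traces a `trace_set` (or `mf_fixture`, which is converted).
#' @param path CSV file path.
#' @return `write_trace_csv`: the path, invisibly; `read_trace_csv`: a
#'   `trace_set` (with `dt` inferred from the time grid).
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "mf_fixture")) traces <- fixture_trace_set(traces)
  write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param stim_end optional stimulus-end time to attach, ms.
#' @export
read_trace_csv <- function(path, stim_end = NA) {
  d <- read.csv(path, check.names = FALSE)
  time <- d[[1]]
  dt <- diff(time)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-8 * max(abs(dt[1]), 1)))
    stop("trace file must have a uniform time grid")
  trace_set(time = time, v = as.matrix(d[-1]), dt = dt[1],
            sites = names(d)[-1], stim_end = stim_end)
}

#' Read / write a configuration tree (YAML or JSON by extension)
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config`: a list; `write_config`: the path, invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(path))
  if (ext == "json")
    return(jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE))
  stop("unsupported config extension: .", ext)
}

#' @rdname read_config
#' @param x a list to serialize.
#' @export
write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else stop("unsupported config extension: .", ext)
  invisible(path)
}
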