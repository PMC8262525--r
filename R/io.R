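#' Read and write exit-time datasets
#'
#' Datasets are plain CSV with header `release_position,exit_time`, one
#' record per row, integer-valued; optionally a sidecar JSON records
#' provenance (geometry, seed, design).
#'
#' @param path CSV file path.
#' @return `read_exit_times()` returns an exit-time data frame; malformed
#'   rows raise errors naming the offending line (header is line 1).
#' @export
read_exit_times <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("release_position", "exit_time") %in% names(df)))
    stop("CSV must have columns `release_position` and `exit_time`",
         call. = FALSE)
  check_int <- function(x, col) {
    bad <- which(!grepl("^[0-9]+$", trimws(x)))
    if (length(bad))
      stop(sprintf("non-integer %s on line %s", col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    as.integer(x)
  }
  rel <- check_int(df$release_position, "release_position")
  tt <- check_int(df$exit_time, "exit_time")
  bad <- which(tt < 1L)
  if (length(bad))
    stop(sprintf("exit_time < 1 on line %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  bad <- which(rel < 1L)
  if (length(bad))
    stop(sprintf("release_position < 1 on line %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  structure(data.frame(release_position = rel, exit_time = tt),
            class = c("exit_time_data", "data.frame"))
}

#' @rdname read_exit_times
#' @param data Exit-time data frame.
#' @param provenance Optional list written as a JSON sidecar
#'   (`<path>.json`).
#' @export
write_exit_times <- function(data, path, provenance = NULL) {
  utils::write.csv(data[, c("release_position", "exit_time")], path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a geometry / experiment configuration
#'
#' YAML (or JSON) configuration with a geometry block
#' (`interfaces: [0, 30, 60, 100]`, `hop_rates: [0.2, 0.3, 0.4]`) and,
#' for full case studies, optional `design`, `likelihood`, `profile`,
#' `reduction` and `seed` blocks (see [run_case_study()]).
#'
#' @param path YAML file path.
#' @return The configuration as a named list; `config_geometry()` builds
#'   the [layered_geometry()] from it.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
config_geometry <- function(config) {
  g <- if (!is.null(config$geometry)) config$geometry else config
  layered_geometry(g$interfaces, g$hop_rates)
}
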