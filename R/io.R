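#' Load rate constants from a fixture or a file
#'
#' @param source either the name of a packaged fixture (currently
#'   `"reference"`, the published tristable estimate) or a path to a JSON or
#'   YAML file with the 23 fields `a1..a7, b1..b6, c1..c7, k1..k3`.
#' @return a validated [rate_constants()] vector.
#' @export
#' @examples
#' load_parameters("reference")
load_parameters <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  if (source == "reference") return(reference_params())
  if (!file.exists(source)) {
    stop("unknown fixture or unreadable file: ", source, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(source))
  values <- switch(ext,
    json = jsonlite::read_json(source, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(source),
    stop("unsupported parameter file format: .", ext,
         " (use .json or .yaml)", call. = FALSE)
  )
  rate_constants(unlist(values))
}

#' Write rate constants to JSON or YAML
#'
#' @param params a [rate_constants()] vector.
#' @param path output path; format chosen by extension (.json, .yaml, .yml).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- rate_constants(params)
  values <- as.list(setNames(as.numeric(params), names(params)))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(values, path),
    stop("unsupported parameter file format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write a switch schedule to JSON or YAML
#'
#' @param schedule a [switch_schedule()].
#' @param path output path (.json, .yaml, .yml).
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "switch_schedule"))
  values <- unclass(schedule)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(values, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(values, path),
    stop("unsupported schedule file format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read a switch schedule from JSON or YAML
#'
#' @param path file with fields `k2_star`, `t_on`, `t_off`, `mu`.
#' @return a [switch_schedule()].
#' @export
read_schedule <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported schedule file format: .", ext, call. = FALSE)
  )
  switch_schedule(v$k2_star, v$t_on, v$t_off, v$mu)
}

#' Write a trajectory as CSV
#'
#' Deterministic trajectories are written with header `time,x,y,z`
#' (concentrations), stochastic ones with `time,X,Y,Z` (copy numbers),
#' matching the column names of the trajectory.
#'
#' @param trajectory a `gata_trajectory` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "gata_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Generate random constraint-satisfying parameter sets
#'
#' Test-data generator built on the constrained sampler: `n` independent
#' genomes are drawn uniformly and mapped through [sample_parameters()], so
#' every returned set satisfies all seven stability inequalities.
#'
#' @param seed integer seed (reproducible).
#' @param n number of sets (>= 1).
#' @param k synthesis scale factor (default 1000).
#' @param fixed fixed constants, defaults to [data_derived_constants()].
#' @return list of `n` [rate_constants()] vectors.
#' @export
#' @examples
#' sets <- generate_fixture_parameters(seed = 1, n = 3)
#' stability_conditions(sets[[1]])
generate_fixture_parameters <- function(seed, n, k = 1000,
                                        fixed = data_derived_constants()) {
  if (!is.numeric(n) || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    sample_parameters(unit_genome(runif(10, 1e-6, 1 - 1e-6), k), fixed)
  })
}

#' Write a run manifest
#'
#' Records the resolved configuration, seed and package version next to any
#' output artifact, so a run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param command the command or function that produced the outputs.
#' @param config a list of resolved settings (must include the seed).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config) {
  manifest <- list(
    command = command,
    config = config,
    package = "gataswitch",
    version = as.character(utils::packageVersion("gataswitch")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
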