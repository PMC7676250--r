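# ---------------------------------------------------------------------------
# World / scenario directory I/O and run manifests.
# ---------------------------------------------------------------------------

#' Write a synthetic world to a directory
#'
#' Writes the driver panels, the observation panels, and the true
#' parameter set (`truth.json`) as plain CSV/JSON files that
#' [read_world()] and the command-line pipeline can consume.
#'
#' @param world A list as returned by [make_world()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(world$drivers$income, file.path(dir, "income.csv"))
  write_panel(world$drivers$population, file.path(dir, "population.csv"))
  for (kind in c("height", "bmi_shares", "demand", "composition", "diet_quality")) {
    write_panel(world$observations[[kind]], file.path(dir, paste0(kind, ".csv")))
  }
  write_params(world$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a world directory
#'
#' @param dir Directory written by [write_world()] (or hand-assembled CSVs
#'   with the same names/schemas). `truth.json` is optional.
#' @return List with `drivers`, `observations` and (if present) `truth`.
#' @export
read_world <- function(dir) {
  drivers <- structure(list(
    income = read_panel(file.path(dir, "income.csv"), "income"),
    population = read_panel(file.path(dir, "population.csv"), "population")
  ), class = "ns_drivers")
  observations <- structure(lapply(
    stats::setNames(nm = c("height", "bmi_shares", "demand", "composition",
                           "diet_quality")),
    function(kind) {
      path <- file.path(dir, paste0(kind, ".csv"))
      if (file.exists(path)) read_panel(path, kind) else NULL
    }), class = "ns_observations")
  truth_path <- file.path(dir, "truth.json")
  out <- list(drivers = drivers, observations = observations)
  if (file.exists(truth_path)) out$truth <- read_params(truth_path)
  out
}

#' Write scenario outputs to a directory
#'
#' One CSV per output variable plus a JSON run manifest (input hashes,
#' seed, package version, clip/fallback logs) for reproducibility.
#'
#' @param result An `ns_scenario`.
#' @param dir Output directory.
#' @param inputs Optional character vector of input file paths to hash
#'   into the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(result, dir, inputs = character(), seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- c("height", "bmi_shares", "pal", "energy", "composition",
               "diet_quality")
  for (nm in outputs) write_panel(result[[nm]], file.path(dir, paste0(nm, ".csv")))
  readr::write_csv(global_aggregate(result), file.path(dir, "global_aggregate.csv"),
                   progress = FALSE)
  manifest <- list(
    package = "nutrisim",
    version = as.character(utils::packageVersion("nutrisim")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = if (length(inputs)) {
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    } else list(),
    outputs = paste0(c(outputs, "global_aggregate"), ".csv"),
    calibrated = !is.null(result$calibration),
    log = result$log,
    clips = nrow(result$clip_log))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
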