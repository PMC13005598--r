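#' Write FSP curves to a delimited file
#'
#' Long-format CSV with columns `direction`, `abscissa`, `intensity`,
#' `mus_prime`, `normalization` — the curve dialect shared by all
#' subcommands.
#'
#' @param curves an [fsp_curve()] or list of them.
#' @param path output file path.
#' @export
write_fsp_csv <- function(curves, path) {
  if (inherits(curves, "fsp_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(direction = cv$direction, abscissa = cv$abscissa,
               intensity = cv$intensity,
               mus_prime = cv$mu_s_reduced_label,
               normalization = cv$normalization)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read FSP curves from a delimited file
#'
#' @param path CSV file written by [write_fsp_csv()].
#' @return A list of [fsp_curve()] objects (one per `mus_prime` and
#'   direction combination).
#' @export
read_fsp_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("direction", "abscissa", "intensity", "mus_prime",
            "normalization")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  key <- paste(tab$direction, tab$mus_prime, sep = "\r")
  lapply(split(tab, key), function(d) {
    d <- d[order(d$abscissa), ]
    fsp_curve(d$abscissa, d$intensity, direction = d$direction[1],
              mu_s_reduced_label = d$mus_prime[1],
              normalization = as.character(d$normalization[1]))
  })
}

#' Read a YAML configuration file
#'
#' Keys follow the `optics.*` / `dual_source.*` layout: `optics.mu_a`,
#' `optics.mu_s`, `optics.g`, `dual_source.n`,
#' `dual_source.boundary_factor`, `dual_source.literal_diffusion_const`.
#'
#' @param path YAML file.
#' @return A named list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    optics = list(mu_a = 0.1, mu_s = NULL, g = 0.9),
    dual_source = list(n = 10, boundary_factor = 1,
                       literal_diffusion_const = TRUE))
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(b[[nm]]) && is.list(a[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge2(defaults, if (is.null(cfg)) list() else cfg)
}

#' Write a run manifest
#'
#' Records the command, resolved configuration, seeds, package version,
#' output paths and wall time of a run as JSON next to the outputs.
#'
#' @param command subcommand name.
#' @param config named list of resolved parameters.
#' @param seed seed(s) used.
#' @param outputs character vector of output paths.
#' @param wall_time elapsed seconds.
#' @param path manifest path (default `<first output>.manifest.json`).
#' @export
write_manifest <- function(command, config, seed, outputs, wall_time,
                           path = NULL) {
  if (is.null(path)) path <- paste0(outputs[1], ".manifest.json")
  manifest <- list(
    command = command, config = config, seed = seed,
    version = as.character(utils::packageVersion("iplendo")),
    outputs = outputs, wall_time_s = wall_time,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
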