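# Configuration I/O: YAML load/save with validation, plus run manifests.

#' Load a model configuration from YAML
#'
#' Reads a YAML file with the blocks \code{compartments}, \code{diffusion},
#' \code{transporters}, \code{mglur}, \code{ip3r}, \code{calcium},
#' \code{iglur}, \code{simulation}, fills unspecified values with the package
#' defaults and validates the result.
#'
#' @param path YAML file; default the packaged model configuration
#' @return a validated \code{\link{spine_config}}
#' @export
load_config <- function(path = system.file("extdata", "spine_model.yaml",
                                           package = "spinesim")) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- spine_config()
  for (blk in intersect(names(raw), names(cfg)))
    cfg[[blk]] <- utils::modifyList(cfg[[blk]], raw[[blk]])
  extra <- setdiff(names(raw), names(cfg))
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "))
  validate_config(cfg)
  cfg
}

#' Save a model configuration to YAML
#'
#' @param cfg a \code{spine_config}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  out <- lapply(unclass(cfg), function(b) lapply(b, identity))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Order-independent digest of every numeric value, used in run manifests.
#'
#' @param cfg a \code{spine_config}
#' @return character scalar
#' @export
config_hash <- function(cfg) {
  u <- unlist(cfg)
  u <- u[order(names(u))]
  txt <- paste(names(u), format(u, digits = 15), collapse = ";")
  # small polynomial rolling hash (no external digest dependency)
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run manifest for reproducibility
#'
#' @param result a \code{spine_result}
#' @return list with the configuration snapshot, its hash, package version
#'   and series metadata; serialisable with \code{jsonlite}
#' @export
run_manifest <- function(result) {
  list(
    package = "spinesim",
    version = as.character(utils::packageVersion("spinesim")),
    config = unclass(result$config),
    config_hash = config_hash(result$config),
    n_events = nrow(result$protocol),
    n_samples = nrow(result$series),
    t_end = max(result$series$time)
  )
}

#' Write a simulation result to CSV
#'
#' @param result a \code{spine_result}
#' @param path output CSV; a JSON manifest is written alongside as
#'   \code{<path>.json}
#' @return \code{path}, invisibly
#' @export
write_result <- function(result, path) {
  utils::write.csv(result$series, path, row.names = FALSE)
  jsonlite::write_json(run_manifest(result),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
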