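# Configuration files, trajectory summaries and run manifests.  Summaries are
# TSV with a '#'-prefixed metadata header; all floating-point output uses 17
# significant digits so write/read round trips are lossless.

# small deterministic string hash (djb2) for tamper detection in summaries
.djb2 <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Load a simulation configuration
#'
#' Reads a YAML key-value file and merges it over the full default
#' configuration (an empty file yields all defaults).  Unknown keys are
#' rejected; values are range-checked with the offending key named.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @seealso [save_config()]; shipped presets under
#'   `system.file("extdata", "config", package = "nucstir")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  extra <- vals[["activity"]]
  vals[["activity"]] <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(sim_config, vals)
  attr(cfg, "activity") <- extra
  cfg
}

#' Save a simulation configuration
#'
#' @param config a [sim_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Write a trajectory summary
#'
#' TSV with a commented metadata header (seed, dt, series, condition, scaled
#' flag, content hash) followed by the `time_h`, `n_droplets`,
#' `mean_radius_um`, `activity` columns at 17 significant digits.
#'
#' @param summary a `trajectory_summary` from [run_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  df <- as.data.frame(summary)
  body <- paste(
    vapply(seq_len(nrow(df)), function(i)
      paste(c(format(df$time_h[i], digits = 17),
              as.character(df$n_droplets[i]),
              format(df$mean_radius_um[i], digits = 17),
              format(df$activity[i], digits = 17)), collapse = "\t"),
      character(1)),
    collapse = "\n")
  meta <- c(
    sprintf("# seed=%s", format(attr(summary, "seed"))),
    sprintf("# dt=%s", format(attr(summary, "dt"), digits = 17)),
    sprintf("# series=%s", format(attr(summary, "series"))),
    sprintf("# condition=%s", format(attr(summary, "condition"))),
    sprintf("# scaled=%s", format(isTRUE(attr(summary, "scaled")))),
    sprintf("# hash=%s", .djb2(body)))
  writeLines(c(meta, "time_h\tn_droplets\tmean_radius_um\tactivity", body),
             path)
  invisible(path)
}

#' Read a trajectory summary
#'
#' Restores the metadata attributes, verifies the content hash (warning on
#' mismatch) and rejects files whose droplet counts are not non-increasing
#' integers.
#'
#' @param path summary TSV path.
#' @return A `trajectory_summary` data frame.
#' @export
read_summary <- function(path) {
  lines <- readLines(path)
  metaln <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in metaln) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  datal <- lines[!grepl("^#", lines)]
  if (length(datal) < 2) stop("parse error: no data rows")
  hdr <- strsplit(datal[1], "\t")[[1]]
  body <- paste(datal[-1], collapse = "\n")
  if (!is.null(meta$hash) && !identical(.djb2(body), meta$hash))
    warning("summary hash mismatch: file may have been modified")
  df <- read.table(text = body, sep = "\t", col.names = hdr)
  if (any(df$n_droplets != round(df$n_droplets)) || is.unsorted(-df$n_droplets))
    stop("parse error: droplet counts must be non-increasing integers (line ",
         which(diff(df$n_droplets) > 0)[1] + 1, ")")
  structure(df, class = c("trajectory_summary", "data.frame"),
            seed = as.integer(meta$seed), dt = as.numeric(meta$dt),
            series = as.integer(meta$series), condition = meta$condition,
            scaled = identical(meta$scaled, "TRUE"))
}

#' Run manifest
#'
#' A JSON manifest recording everything needed to reproduce a run bit for
#' bit: seed, time step, the full parameter snapshot, package version,
#' timestamp and a hash of the parameter snapshot.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param dt integration step, s.
#' @param path optional output path; when given the manifest is written as
#'   JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, seed, dt = config$dt, path = NULL) {
  snap <- unclass(config)
  m <- list(seed = seed, dt = dt, parameters = snap,
            version = as.character(utils::packageVersion("nucstir")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            config_hash = .djb2(paste(names(snap),
                                      vapply(snap, format, character(1),
                                             digits = 17),
                                      collapse = ";")))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(m))
  }
  m
}
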