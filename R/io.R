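# Plain-text serialization: parameter tables, spike patterns and rasters as
# tab-separated event lists, configurations as YAML (see dg_config_write),
# and JSON run manifests capturing seeds and config hashes.

#' Write / read a neuron parameter table
#'
#' Tab-separated, one row per neuron: subtype plus the ten aEIF parameters.
#'
#' @param params parameter data.frame.
#' @param path file path.
#' @return \code{read_params} returns the validated data.frame.
#' @export
write_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  check_neuron_params(p)
  p
}

#' Write / read a spike pattern as an event list
#'
#' Tab-separated columns \code{train}, \code{time_ms}; pattern metadata
#' (train count, duration, rate, beta, seed) is carried in '#'-prefixed
#' header lines so empty trains survive the round trip.
#'
#' @param P a \code{spike_pattern}.
#' @param path file path.
#' @return \code{read_pattern} returns the \code{spike_pattern}.
#' @export
write_pattern <- function(P, path) {
  stopifnot(inherits(P, "spike_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_trains=%d duration=%g rate_hz=%g beta=%g seed=%s",
                     P$n_trains, P$duration, P$rate_hz, P$beta,
                     ifelse(is.null(P$seed), "NA", P$seed)), con)
  writeLines("train\ttime_ms", con)
  for (i in seq_along(P$trains)) {
    tr <- P$trains[[i]]
    if (length(tr) > 0)
      writeLines(sprintf("%d\t%.6g", i, tr), con)
  }
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  first <- readLines(path, n = 1)
  meta <- as.list(stats::setNames(
    sub(".*=", "", strsplit(sub("^# ", "", first), " ")[[1]]),
    sub("=.*", "", strsplit(sub("^# ", "", first), " ")[[1]])))
  ev <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n <- as.integer(meta$n_trains)
  trains <- split(ev$time_ms, factor(ev$train, levels = seq_len(n)))
  trains <- lapply(trains, function(v) sort(unname(v)))
  seed <- if (identical(meta$seed, "NA")) NULL else as.integer(meta$seed)
  structure(list(trains = trains, n_trains = n,
                 duration = as.numeric(meta$duration),
                 rate_hz = as.numeric(meta$rate_hz),
                 beta = as.numeric(meta$beta), seed = seed),
            class = "spike_pattern")
}

#' Write a simulation raster as an event list
#'
#' Tab-separated columns \code{population}, \code{neuron}, \code{time_ms}.
#'
#' @param sim a \code{dg_sim}.
#' @param path file path.
#' @export
write_raster <- function(sim, path) {
  stopifnot(inherits(sim, "dg_sim"))
  ev <- do.call(rbind, lapply(names(sim$spikes), function(p) {
    s <- sim$spikes[[p]]
    if (nrow(s) == 0) return(NULL)
    data.frame(population = p, neuron = s$neuron, time_ms = s$time)
  }))
  if (is.null(ev))
    ev <- data.frame(population = character(0), neuron = integer(0),
                     time_ms = numeric(0))
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of seeds, configuration hash and free-form fields, enough to
#' reproduce a run exactly.
#'
#' @param path file path.
#' @param seed master seed.
#' @param config \code{dg_config} (hashed into the manifest).
#' @param ... further scalar fields.
#' @export
write_manifest <- function(path, seed, config, ...) {
  m <- list(seed = seed, config_hash = config_hash(config),
            profile = config$profile, created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
            ...)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
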