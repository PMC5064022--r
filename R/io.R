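# Round-trip file I/O: schemes and protocols as JSON, recordings as CSV
# with a JSON metadata sidecar, dose-response tables as CSV, fit results
# as JSON.

#' Write / read a gating scheme as JSON
#'
#' The JSON document holds the state labels with conducting flags, the
#' transition list (label, source, target, amplitude, charge) and the
#' physical constants.  The packaged presets live in
#' `system.file("extdata", ..., package = "iksim")`.
#'
#' @param scheme An `iks_scheme`.
#' @param path File path.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()`
#'   returns an `iks_scheme`.
#' @examples
#' p <- file.path(tempdir(), "scheme.json")
#' write_scheme(iks_scheme(), p)
#' read_scheme(p)
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "iks_scheme"))
  doc <- list(
    name = scheme$name,
    constants = list(F = scheme$constants$F, R = scheme$constants$R,
                     T = scheme$constants$T),
    states = purrr::pmap(scheme$states, function(state, conducting) {
      list(label = state, conducting = conducting)
    }),
    transitions = purrr::pmap(scheme$transitions,
      function(label, from, to, amplitude, charge) {
        list(label = label, from = from, to = to,
             amplitude = amplitude, charge = charge)
      }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Scheme file not found: ", path), class = "iksim_io_error")
  }
  doc <- jsonlite::read_json(path)
  scheme_from_list(doc)
}

scheme_from_list <- function(doc) {
  gating_scheme(
    states = tibble::tibble(
      state = purrr::map_chr(doc$states, "label"),
      conducting = purrr::map_lgl(doc$states, "conducting")),
    transitions = tibble::tibble(
      label = purrr::map_chr(doc$transitions, "label"),
      from = purrr::map_chr(doc$transitions, "from"),
      to = purrr::map_chr(doc$transitions, "to"),
      amplitude = purrr::map_dbl(doc$transitions, "amplitude"),
      charge = purrr::map_dbl(doc$transitions, "charge")),
    constants = phys_constants(temperature_K = doc$constants$T,
                               faraday = doc$constants$F,
                               gas_constant = doc$constants$R),
    name = doc$name %||% "scheme")
}

scheme_to_list <- function(scheme) {
  list(name = scheme$name,
       constants = list(F = scheme$constants$F, R = scheme$constants$R,
                        T = scheme$constants$T),
       states = purrr::pmap(scheme$states, function(state, conducting) {
         list(label = state, conducting = conducting)
       }),
       transitions = purrr::pmap(scheme$transitions,
         function(label, from, to, amplitude, charge) {
           list(label = label, from = from, to = to,
                amplitude = amplitude, charge = charge)
         }))
}

#' Locate a packaged gating-scheme fixture
#'
#' @param drug `"free"` or `"bound"`.
#' @return Path to the packaged JSON scheme file.
#' @export
iks_scheme_file <- function(drug = c("free", "bound")) {
  drug <- match.arg(drug)
  system.file("extdata", paste0("iks-scheme-", drug, ".json"),
              package = "iksim", mustWork = TRUE)
}

protocol_to_list <- function(protocol) {
  list(name = protocol_name(protocol),
       dt_s = protocol_dt(protocol),
       reset = protocol_reset(protocol),
       holding_mV = protocol_holding(protocol),
       segments = purrr::pmap(
         as.data.frame(protocol),
         function(sweep_id, segment_id, role, duration_s, voltage_mV) {
           list(sweep_id = sweep_id, segment_id = segment_id, role = role,
                duration_s = duration_s, voltage_mV = voltage_mV)
         }))
}

protocol_from_list <- function(doc) {
  voltage_protocol(
    tibble::tibble(
      sweep_id = purrr::map_int(doc$segments, "sweep_id"),
      segment_id = purrr::map_int(doc$segments, "segment_id"),
      role = purrr::map_chr(doc$segments, "role"),
      duration_s = purrr::map_dbl(doc$segments, "duration_s"),
      voltage_mV = purrr::map_dbl(doc$segments, "voltage_mV")),
    dt_s = doc$dt_s, name = doc$name, reset = doc$reset,
    holding_mV = doc$holding_mV)
}

#' Write / read a voltage protocol as JSON
#' @param protocol An `iks_protocol`.
#' @param path File path.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns an `iks_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "iks_protocol"))
  jsonlite::write_json(protocol_to_list(protocol), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Protocol file not found: ", path), class = "iksim_io_error")
  }
  protocol_from_list(jsonlite::read_json(path))
}

#' Write / read a recording as CSV plus JSON metadata sidecar
#'
#' The CSV holds the canonical columns `sweep_id`, `time_s`,
#' `voltage_mV`, `current_uA`; the sidecar (`<path>.json`) holds the full
#' provenance metadata (scheme, protocol, settings, noise, seed), which
#' is sufficient to regenerate the recording deterministically.
#' `read_recording()` reconstructs segment roles from the protocol.
#'
#' @param recording An `iks_recording`.
#' @param path CSV file path; the sidecar is written at `<path>.json`.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns an `iks_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "iks_recording"))
  md <- recording_metadata(recording)
  utils::write.csv(
    as.data.frame(recording)[c("sweep_id", "time_s", "voltage_mV",
                               "current_uA")],
    path, row.names = FALSE)
  sidecar <- list(
    scheme = scheme_to_list(md$scheme),
    scheme_hash = md$scheme_hash,
    protocol = protocol_to_list(md$protocol),
    settings = unclass(md$settings),
    noise = if (!is.null(md$noise)) unclass(md$noise),
    seed = md$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json"))) {
    abort(paste0("Recording CSV or sidecar not found for: ", path),
          class = "iksim_io_error")
  }
  data <- tibble::as_tibble(utils::read.csv(path))
  needed <- c("sweep_id", "time_s", "voltage_mV", "current_uA")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Recording CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "iksim_io_error")
  }
  md <- jsonlite::read_json(paste0(path, ".json"))
  scheme <- scheme_from_list(md$scheme)
  protocol <- protocol_from_list(md$protocol)
  settings <- simulation_settings(gmax_uS = md$settings$gmax_uS,
                                  erev_mV = md$settings$erev_mV)
  noise <- if (!is.null(md$noise)) do.call(noise_model, md$noise)
  # reassign segment roles from the protocol's within-sweep time bins
  data$segment <- NA_character_
  for (sw in unique(data$sweep_id)) {
    segs <- protocol[protocol$sweep_id == sw, ]
    edges <- c(0, cumsum(segs$duration_s))
    rows <- which(data$sweep_id == sw)
    bin <- findInterval(data$time_s[rows], edges, left.open = TRUE)
    bin[bin == 0] <- 1L
    bin <- pmin(bin, nrow(segs))
    data$segment[rows] <- segs$role[bin]
  }
  data$popen <- NA_real_
  rec <- new_recording(data[c("sweep_id", "time_s", "voltage_mV",
                              "current_uA", "popen", "segment")],
                       scheme, protocol, settings, noise,
                       seed = md$seed)
  rec
}

#' Write / read a dose-response table as CSV
#' @param table A data frame with columns `concentration_M`, `replicate`,
#'   `response`.
#' @param path CSV file path.
#' @return `write_dose_response()` returns `path` invisibly;
#'   `read_dose_response()` returns a tibble.
#' @export
write_dose_response <- function(table, path) {
  stopifnot(all(c("concentration_M", "replicate", "response") %in%
                  names(table)))
  utils::write.csv(
    as.data.frame(table)[c("concentration_M", "replicate", "response")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  data <- tibble::as_tibble(utils::read.csv(path))
  missing_cols <- setdiff(c("concentration_M", "replicate", "response"),
                          names(data))
  if (length(missing_cols)) {
    abort(paste0("Dose-response CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "iksim_io_error")
  }
  data
}

#' Write / read a fit result as JSON
#' @param fit An `iks_fit`.
#' @param path JSON file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` returns a
#'   list (family, parameters, errors, rss, converged, tag).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "iks_fit"))
  doc <- list(family = fit$family,
              parameters = as.list(fit$estimate),
              std_errors = as.list(fit$std_error),
              rss = fit$rss,
              converged = fit$converged,
              tag = fit$tag,
              n = fit$n)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Fit file not found: ", path), class = "iksim_io_error")
  }
  jsonlite::read_json(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
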