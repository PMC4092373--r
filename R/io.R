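## Plain-text file formats: delimited data with a '#'-prefixed key:value
## header.  No community exchange format exists for DPV data, so the package
## defines a simple self-describing dialect and additionally accepts generic
## two-column instrument exports when the metadata is supplied separately.

.FORMAT_VERSION <- 1L

fmt_num <- function(x) sprintf("%.17g", x)

header_lines <- function(kv) {
  vapply(names(kv), function(k) {
    v <- kv[[k]]
    if (k == "metadata")
      paste0("# metadata: ",
             as.character(jsonlite::toJSON(v, auto_unbox = TRUE,
                                           digits = NA, null = "null")))
    else paste0("# ", k, ": ", as.character(v))
  }, character(1))
}

read_header <- function(lines) {
  hdr <- list()
  n_used <- 0L
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    n_used <- n_used + 1L
    body <- sub("^#\\s*", "", ln)
    m <- regexpr(":", body, fixed = TRUE)
    if (m < 0) next
    key <- trimws(substr(body, 1, m - 1))
    val <- trimws(substr(body, m + 1, nchar(body)))
    hdr[[key]] <- if (key == "metadata")
      jsonlite::fromJSON(val, simplifyVector = TRUE)
    else val
  }
  list(header = hdr, n_used = n_used)
}

require_keys <- function(hdr, keys, path) {
  for (k in keys)
    if (is.null(hdr[[k]]))
      stop_dpv(sprintf("file '%s' is missing mandatory header key '%s'",
                       path, k), "dpvkit_format_error")
  invisible(hdr)
}

num <- function(x) as.numeric(x)

#' Write / read voltammograms as delimited text
#'
#' The on-disk format is a CSV of `potential_V,current_uA_cm2` preceded by a
#' `#`-prefixed `key: value` header carrying the pulse settings, reference
#' scale, temperature, electrode area and a JSON-encoded free-form metadata
#' block. Values are written at full double precision, so a write/read round
#' trip is lossless. `read_voltammogram()` also accepts a headerless
#' two-column CSV when the acquisition metadata is supplied through the
#' `pulse`/`temperature_K`/... arguments.
#'
#' @param v A [voltammogram()].
#' @param path File path.
#' @return `write_voltammogram()`: `path`, invisibly. `read_voltammogram()`:
#'   a [voltammogram()].
#' @export
write_voltammogram <- function(v, path) {
  stopifnot(inherits(v, "voltammogram"))
  p <- v$pulse
  hdr <- list(format_version = .FORMAT_VERSION, kind = "dpv",
              reference_scale = v$reference_scale,
              temperature_K = fmt_num(v$temperature_K),
              electrode_area_cm2 = fmt_num(v$electrode_area_cm2),
              pulse_increment_mV = fmt_num(p$increment_mV),
              pulse_amplitude_mV = fmt_num(p$amplitude_mV),
              pulse_width_ms = fmt_num(p$width_ms),
              pulse_period_ms = fmt_num(p$period_ms),
              pulse_sampling_delay_ms = fmt_num(p$sampling_delay_ms),
              scan_direction = p$scan_direction)
  if (length(v$metadata)) hdr$metadata <- v$metadata
  writeLines(c(header_lines(hdr), "potential_V,current_uA_cm2",
               paste(fmt_num(v$potentials_V), fmt_num(v$currents_uA_cm2),
                     sep = ",")), path)
  invisible(path)
}

#' @rdname write_voltammogram
#' @param pulse,temperature_K,electrode_area_cm2,reference_scale,metadata
#'   Acquisition metadata for headerless two-column files; ignored when the
#'   file carries its own header.
#' @export
read_voltammogram <- function(path, pulse = NULL, temperature_K = NULL,
                              electrode_area_cm2 = NULL,
                              reference_scale = NULL, metadata = NULL) {
  lines <- readLines(path)
  h <- read_header(lines)
  body <- lines[(h$n_used + 1L):length(lines)]
  dat <- read.csv(text = paste(body, collapse = "\n"),
                  header = grepl("[A-Za-z]", body[1]))
  if (ncol(dat) < 2L)
    stop_dpv(sprintf("file '%s': expected two data columns", path),
             "dpvkit_format_error")
  if (h$n_used > 0L) {
    hdr <- require_keys(h$header,
                        c("kind", "reference_scale", "temperature_K",
                          "electrode_area_cm2", "pulse_increment_mV",
                          "pulse_amplitude_mV", "pulse_width_ms",
                          "pulse_period_ms"), path)
    if (!identical(hdr$kind, "dpv"))
      stop_dpv(sprintf("file '%s' has kind '%s', expected 'dpv'", path,
                       hdr$kind), "dpvkit_format_error")
    pulse <- pulse_params(num(hdr$pulse_increment_mV),
                          num(hdr$pulse_amplitude_mV),
                          num(hdr$pulse_width_ms),
                          num(hdr$pulse_period_ms),
                          num(hdr$pulse_sampling_delay_ms %||% "0"),
                          hdr$scan_direction %||% "anodic")
    temperature_K <- num(hdr$temperature_K)
    electrode_area_cm2 <- num(hdr$electrode_area_cm2)
    reference_scale <- hdr$reference_scale
    metadata <- hdr$metadata %||% list()
  } else {
    if (is.null(pulse))
      stop_dpv(sprintf(
        "file '%s' has no header; supply pulse settings and metadata explicitly",
        path), "dpvkit_format_error")
  }
  voltammogram(dat[[1]], dat[[2]], pulse = pulse,
               temperature_K = temperature_K %||% .T_DEFAULT,
               electrode_area_cm2 = electrode_area_cm2 %||% 3.1,
               reference_scale = reference_scale %||% "SHE",
               metadata = as_metadata_list(metadata))
}

as_metadata_list <- function(m) {
  if (is.null(m)) return(list())
  if (!is.list(m)) return(as.list(m))
  m
}

#' Write / read chronoamperometry traces
#'
#' CSV of `time_s,current_uA_cm2` with a `#` header (potential, pH, strain,
#' flavin, metadata). Events are stored in a JSON sidecar file at
#' `<path>.events.json` and restored on read.
#'
#' @param trace A [current_trace()].
#' @param path File path.
#' @return `write_current_trace()`: `path`, invisibly;
#'   `read_current_trace()`: a [current_trace()].
#' @export
write_current_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  hdr <- list(format_version = .FORMAT_VERSION, kind = "trace",
              reference_scale = "SHE",
              potential_V = fmt_num(trace$potential_V),
              pH = fmt_num(trace$pH), strain = trace$strain,
              flavin = trace$flavin,
              flavin_conc_uM = fmt_num(trace$flavin_conc_uM))
  if (length(trace$metadata)) hdr$metadata <- trace$metadata
  writeLines(c(header_lines(hdr), "time_s,current_uA_cm2",
               paste(fmt_num(trace$times_s), fmt_num(trace$currents_uA_cm2),
                     sep = ",")), path)
  if (length(trace$events)) {
    evs <- lapply(trace$events, function(e)
      list(time_s = e$time_s, kind = e$kind, payload = e$payload))
    jsonlite::write_json(evs, paste0(path, ".events.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_current_trace
#' @export
read_current_trace <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines)
  hdr <- require_keys(h$header, c("kind", "potential_V", "pH", "strain",
                                  "flavin"), path)
  if (!identical(hdr$kind, "trace"))
    stop_dpv(sprintf("file '%s' has kind '%s', expected 'trace'", path,
                     hdr$kind), "dpvkit_format_error")
  body <- lines[(h$n_used + 1L):length(lines)]
  dat <- read.csv(text = paste(body, collapse = "\n"),
                  header = grepl("[A-Za-z]", body[1]))
  events <- list()
  sidecar <- paste0(path, ".events.json")
  if (file.exists(sidecar)) {
    raw <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
    events <- lapply(raw, function(e)
      trace_event(e$time_s, e$kind, e$payload))
  }
  current_trace(dat[[1]], dat[[2]], potential_V = num(hdr$potential_V),
                pH = num(hdr$pH), strain = hdr$strain,
                flavin = hdr$flavin,
                flavin_conc_uM = num(hdr$flavin_conc_uM %||% "0"),
                events = events,
                metadata = as_metadata_list(hdr$metadata))
}

#' Write / read titration series
#'
#' CSV of `concentration_uM,peak_current_uA_cm2` with a `#` header.
#'
#' @param series Data frame or [make_titration()] result.
#' @param path File path.
#' @return `write_titration()`: `path`, invisibly; `read_titration()`: a
#'   data frame `(concentration_uM, peak_current_uA_cm2)`.
#' @export
write_titration <- function(series, path) {
  s <- as_titration_series(series)
  writeLines(c(header_lines(list(format_version = .FORMAT_VERSION,
                                 kind = "titration")),
               "concentration_uM,peak_current_uA_cm2",
               paste(fmt_num(s$concentration_uM),
                     fmt_num(s$peak_current_uA_cm2), sep = ",")), path)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines)
  body <- lines[(h$n_used + 1L):length(lines)]
  read.csv(text = paste(body, collapse = "\n"))
}

#' Export a peak report
#'
#' Writes a [summarize_peaks()] table as CSV or JSON.
#'
#' @param peaks Data frame from [summarize_peaks()] (or `$peaks` of
#'   [analyze_dpv()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(peaks, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") write.csv(peaks, path, row.names = FALSE)
  else jsonlite::write_json(peaks, path, dataframe = "rows",
                            auto_unbox = TRUE, digits = NA)
  invisible(path)
}
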