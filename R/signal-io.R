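# Reading/writing the study's interchange formats and sweep segmentation.

#' Construct a continuous ECG trace
#'
#' @param samples numeric vector of voltages (mV).
#' @param fs sampling rate (Hz).
#' @param start_s recording start in seconds from the schedule anchor
#'   (lights-on of day 1).
#' @param species `"mouse"` or `"human"`.
#' @param label channel label.
#' @return An object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, fs, start_s = 0,
                      species = c("human", "mouse"), label = "ECG") {
  species <- match.arg(species)
  if (fs <= 0) abort("fs must be positive")
  if (!all(is.finite(samples))) abort("samples must be finite")
  structure(
    list(samples = as.numeric(samples), fs = fs, start_s = start_s,
         species = species, label = label),
    class = "ecg_trace"
  )
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat("<ecg_trace>", x$label, ":", length(x$samples), "samples @", x$fs,
      "Hz (", round(length(x$samples) / x$fs, 1), "s ),", x$species, "\n")
  invisible(x)
}

# ---- EDF (European Data Format) -------------------------------------------

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write one or more channels to an EDF file
#'
#' Minimal EDF writer (16-bit, one fixed record duration, physical units as
#' given). Values are scaled linearly into the signed 16-bit digital range,
#' so a write/read round trip is lossless up to that quantization.
#'
#' @param traces a single [ecg_trace()] or list of traces sharing a common
#'   duration (whole seconds).
#' @param path output file.
#' @param record_s data record duration in seconds.
#' @param units physical dimension string recorded per channel (default mV).
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, path, record_s = 1, units = "mV") {
  if (inherits(traces, "ecg_trace")) traces <- list(traces)
  fs <- vapply(traces, function(t) t$fs, numeric(1))
  n <- vapply(traces, function(t) length(t$samples), numeric(1))
  dur <- n / fs
  if (length(unique(round(dur, 6))) != 1) abort("channels must share duration")
  n_rec <- floor(dur[1] / record_s)
  if (n_rec < 1) abort("trace shorter than one data record")

  ns <- length(traces)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("X X X X", 80), pad_ascii("Startdate X", 80),
    pad_ascii("01.01.26", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (ns + 1), 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(format(record_s), 8), pad_ascii(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- range(traces[[i]]$samples)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    phys_min[i] <- rng[1]; phys_max[i] <- rng[2]
  }
  field <- function(f, width) {
    writeChar(paste0(vapply(seq_len(ns), f, character(1)), collapse = ""),
              con, eos = NULL)
    invisible(NULL)
  }
  field(function(i) pad_ascii(traces[[i]]$label, 16), 16)
  field(function(i) pad_ascii("", 80), 80)
  field(function(i) pad_ascii(units, 8), 8)
  field(function(i) pad_ascii(format(phys_min[i], digits = 7), 8), 8)
  field(function(i) pad_ascii(format(phys_max[i], digits = 7), 8), 8)
  field(function(i) pad_ascii(-32768, 8), 8)
  field(function(i) pad_ascii(32767, 8), 8)
  field(function(i) pad_ascii("", 80), 80)
  field(function(i) pad_ascii(fs[i] * record_s, 8), 8)
  field(function(i) pad_ascii("", 32), 32)

  scale <- (phys_max - phys_min) / (32767 - (-32768))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      spr <- fs[i] * record_s
      seg <- traces[[i]]$samples[((r - 1) * spr + 1):(r * spr)]
      dig <- round((seg - phys_min[i]) / scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an ECG channel from an EDF/EDF+ file
#'
#' @param path EDF file.
#' @param channel channel label to extract; `NULL` picks the single channel
#'   or errors listing the available labels.
#' @param species species tag to attach to the returned trace.
#' @return An [ecg_trace()]; microvolt channels are converted to mV.
#' @export
read_edf <- function(path, channel = NULL, species = "human") {
  if (!file.exists(path)) abort(paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) abort("not a parsable EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                      # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)                      # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  if (is.null(channel)) {
    if (ns > 1) {
      abort(paste0("multiple channels; pick one of: ",
                   paste(labels, collapse = ", ")))
    }
    ch <- 1L
  } else {
    ch <- match(channel, labels)
    if (is.na(ch)) {
      abort(paste0("channel '", channel, "' not found; available: ",
                   paste(labels, collapse = ", ")))
    }
  }
  unit <- units[ch]
  if (!unit %in% c("mV", "uV", "µV")) {
    abort(paste0("unsupported physical dimension '", unit, "' (need mV or uV)"))
  }

  out <- numeric(n_rec * spr[ch])
  pos <- 1L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                      endian = "little")
      if (i == ch) {
        out[pos:(pos + spr[i] - 1)] <- vals
        pos <- pos + spr[i]
      }
    }
  }
  scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  phys <- (out - dig_min[ch]) * scale + phys_min[ch]
  if (unit != "mV") phys <- phys / 1000
  ecg_trace(phys, fs = spr[ch] / record_s, species = species,
            label = labels[ch])
}

# ---- telemetry CSV dialect ------------------------------------------------

#' Write a sweep recording to the telemetry CSV dialect
#'
#' Two plain-text files: an ECG file with one row per sweep
#' (`sweep_id,t0_iso8601,t0_s,fs,species` followed by the sample values) and,
#' when behaviour data are present, a companion file with one row per 5-min
#' bin (`t0_iso8601,t0_s,activity,temp_c`). Sample indices in the optional
#' annotation file are 0-based; times are seconds; intervals milliseconds.
#'
#' @param rec an `ecg_recording` from [synth_ecg_waveform()].
#' @param ecg_path,behavior_path,annotation_path output files
#'   (`NULL` = skip that file).
#' @param anchor POSIXct mapped to recording time 0 for the ISO-8601 stamps.
#' @return `ecg_path`, invisibly.
#' @export
write_telemetry_csv <- function(rec, ecg_path, behavior_path = NULL,
                                annotation_path = NULL,
                                anchor = as.POSIXct("2026-01-01 00:00:00",
                                                    tz = "UTC")) {
  stopifnot(inherits(rec, "ecg_recording"))
  sw <- rec$sweeps
  iso <- format(anchor + sw$t0_s, "%Y-%m-%dT%H:%M:%S")
  lines <- vapply(seq_len(nrow(sw)), function(i) {
    paste(c(sw$sweep_id[i], iso[i], sw$t0_s[i], sw$fs[i], sw$species[i],
            formatC(sw$samples[[i]], format = "g", digits = 7)),
          collapse = ",")
  }, character(1))
  writeLines(c("sweep_id,t0_iso8601,t0_s,fs,species,samples", lines), ecg_path)

  act <- rec$truth$activity
  if (!is.null(behavior_path) && !is.null(act)) {
    readr::write_csv(
      tibble::tibble(
        t0_iso8601 = format(anchor + act$t0_s, "%Y-%m-%dT%H:%M:%S"),
        t0_s = act$t0_s, activity = act$activity,
        temp_c = round(act$temp_c, 3)
      ),
      behavior_path
    )
  }
  if (!is.null(annotation_path)) {
    a <- rec$annotations
    readr::write_csv(
      tibble::tibble(
        beat_time_s = a$time_s, label = a$label,
        P = a$p_peak_sample - 1L, Poff = a$p_off_sample - 1L,
        Qon = a$q_on_sample - 1L, R = a$r_sample - 1L,
        Tpk = a$t_peak_sample - 1L, Toff = a$t_off_sample - 1L,
        sweep_id = a$sweep_id
      ),
      annotation_path
    )
  }
  invisible(ecg_path)
}

#' Read a telemetry CSV recording
#'
#' Counterpart of [write_telemetry_csv()]. Malformed rows (wrong field
#' count, unparsable numbers) and duplicated sweep ids raise errors naming
#' the offending row. A missing behaviour file marks activity as absent;
#' activity-dependent analyses then refuse to run.
#'
#' @param ecg_path sweep CSV.
#' @param behavior_path optional behaviour CSV.
#' @return A list of class `telemetry_recording` with `sweeps` (tibble with
#'   list-column `samples`), `activity` (tibble or `NULL`), `fs`, `species`.
#' @export
read_telemetry_csv <- function(ecg_path, behavior_path = NULL) {
  lines <- readLines(ecg_path)
  if (length(lines) < 2) abort("no sweeps in file")
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6)) {
    abort(paste0("malformed row ", which(nf < 6)[1] + 1, ": expected at least 6 fields"))
  }
  sweep_id <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(sweep_id)) {
    abort(paste0("duplicate sweep_id '", sweep_id[anyDuplicated(sweep_id)], "'"))
  }
  t0_s <- as.numeric(vapply(parts, `[[`, character(1), 3))
  fs <- as.numeric(vapply(parts, `[[`, character(1), 4))
  species <- vapply(parts, `[[`, character(1), 5)
  samples <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][-(1:5)]))
    if (anyNA(v)) abort(paste0("malformed row ", i + 1, ": non-numeric sample"))
    v
  })
  if (anyNA(t0_s) || anyNA(fs)) abort("malformed row: bad t0_s or fs")
  sweeps <- tibble::tibble(
    sweep_id = suppressWarnings(as.integer(sweep_id)) %na% sweep_id,
    t0_s = t0_s, t_h = t0_s / 3600, fs = fs, species = species,
    n_samples = lengths(samples), samples = samples
  )
  activity <- NULL
  if (!is.null(behavior_path) && file.exists(behavior_path)) {
    activity <- readr::read_csv(behavior_path, show_col_types = FALSE)
  }
  structure(
    list(sweeps = sweeps, activity = activity,
         fs = fs[1], species = species[1]),
    class = "telemetry_recording"
  )
}

`%na%` <- function(a, b) if (anyNA(a)) b else a

#' Cut a continuous trace into fixed-length analysis sweeps
#'
#' Non-overlapping consecutive windows of `sweep_len` samples tile the trace;
#' a trailing partial window is flagged and excluded from analysis. At 128 Hz
#' a 10,000-sample sweep spans ~78 s; at 256 Hz ~39 s; at 1 kHz, 10 s.
#'
#' @param trace an [ecg_trace()].
#' @param sweep_len samples per sweep (default 10,000).
#' @return A tibble with one row per full sweep: `sweep_id`, `t0_s`, `t_h`,
#'   `fs`, `species`, `samples` (list-column); attribute `n_partial` counts
#'   the excluded trailing samples.
#' @export
segment_sweeps <- function(trace, sweep_len = 10000) {
  stopifnot(inherits(trace, "ecg_trace"))
  n <- length(trace$samples)
  n_full <- n %/% sweep_len
  if (n_full == 0) {
    warn("trace shorter than one sweep; returning no sweeps")
  }
  idx <- seq_len(n_full)
  out <- tibble::tibble(
    sweep_id = idx,
    t0_s = trace$start_s + (idx - 1) * sweep_len / trace$fs,
    fs = trace$fs, species = trace$species,
    samples = lapply(idx, function(i) {
      trace$samples[((i - 1) * sweep_len + 1):(i * sweep_len)]
    })
  )
  out$t_h <- out$t0_s / 3600
  attr(out, "n_partial") <- n - n_full * sweep_len
  attr(out, "sweep_duration_s") <- sweep_len / trace$fs
  out
}
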