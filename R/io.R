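# Columnar text I/O for raw ECG recordings and cohort tables.
#
# ECG text format: comment header lines ("# key: value" for
# participant_id, sampling_rate_hz, units), then a tab-separated table
# with one column per lead. Units are converted to mV on read.

canonicalize_lead <- function(lead) {
  l <- toupper(trimws(gsub("(?i)^lead[ _]*", "", lead, perl = TRUE)))
  map <- c(C1 = "V1", C2 = "V2", C3 = "V3", C4 = "V4", C5 = "V5", C6 = "V6")
  ifelse(l %in% names(map), unname(map[l]), l)
}

#' Write a raw ECG as columnar text
#'
#' @param ecg a `raw_ecg` object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ecg <- function(ecg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# participant_id: %s", ecg$participant_id),
               sprintf("# sampling_rate_hz: %g", ecg$sampling_rate_hz),
               "# units: mV",
               paste(ecg$lead_names, collapse = "\t")), con)
  write.table(format(ecg$samples, digits = 7, trim = TRUE, scientific = FALSE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a raw ECG from columnar text
#'
#' Parses the package's columnar text ECG format, converts physical units
#' to mV (a `# units: uV` header divides values by 1000), and maps lead
#' aliases (`v1`, `C1`, `lead I`, ...) to the canonical names. All eight
#' required leads (I, II, V1-V6) must be present; extra leads are dropped.
#'
#' @param path file path.
#' @param format only `"text"` is supported.
#' @return a `raw_ecg` object.
#' @export
read_ecg <- function(path, format = c("text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default = NA) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[1]))
  }
  participant_id <- get_field("participant_id", "unknown")
  fs <- as.numeric(get_field("sampling_rate_hz"))
  if (!is.finite(fs) || fs <= 0) stop_invalid("missing or invalid sampling_rate_hz header")
  units <- tolower(get_field("units", "mv"))
  body_start <- length(hdr) + 1
  leads_raw <- strsplit(lines[body_start], "\t")[[1]]
  leads <- canonicalize_lead(leads_raw)
  x <- read.table(text = lines[(body_start + 1):length(lines)], sep = "\t",
                  col.names = leads, check.names = FALSE)
  required <- canonical_leads()
  absent <- setdiff(required, leads)
  if (length(absent)) {
    stop_invalid("ECG file %s is missing required lead(s): %s",
                 basename(path), paste(absent, collapse = ", "))
  }
  scale <- switch(units,
                  "mv" = 1, "millivolt" = 1, "millivolts" = 1,
                  "uv" = 1e-3, "microvolt" = 1e-3, "microvolts" = 1e-3,
                  "v" = 1e3, "volt" = 1e3, "volts" = 1e3,
                  stop_invalid("cannot convert units '%s' to mV", units))
  samples <- as.matrix(x[, required, drop = FALSE]) * scale
  structure(list(participant_id = participant_id, lead_names = required,
                 samples = samples, sampling_rate_hz = fs,
                 duration_s = nrow(samples) / fs, meta = list()),
            class = "raw_ecg")
}

#' Write median beats as a columnar archive with a JSON manifest
#'
#' One tab-separated waveform file per participant plus a
#' `beats_manifest.json` recording, for each participant, the window
#' length, sampling rate, R index, mean R-R interval, ventricular rate
#' and beat-retention counts.
#'
#' @param beats list of `median_beat` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a data.frame.
#' @export
write_median_beats <- function(beats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(beats, function(b) {
    stopifnot(inherits(b, "median_beat"))
    f <- paste0(b$participant_id, ".beat.tsv")
    con <- file(file.path(dir, f), "w")
    writeLines(paste(b$lead_names, collapse = "\t"), con)
    write.table(format(b$waveforms, digits = 7, trim = TRUE, scientific = FALSE),
                con, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    close(con)
    data.frame(participant_id = b$participant_id, file = f,
               n_samples = nrow(b$waveforms),
               sampling_rate_hz = b$sampling_rate_hz, r_index = b$r_index,
               mean_rr_ms = b$mean_rr_ms,
               ventricular_rate_bpm = b$ventricular_rate_bpm,
               n_beats_detected = b$n_beats_detected,
               n_beats_retained = b$n_beats_retained,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "beats_manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}

#' Read a median-beat archive written by [write_median_beats()]
#'
#' @param dir directory containing `beats_manifest.json`.
#' @return named list of `median_beat` objects.
#' @export
read_median_beats <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "beats_manifest.json"),
                                  simplifyVector = TRUE)
  beats <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    x <- read.table(file.path(dir, m$file), sep = "\t", header = TRUE,
                    check.names = FALSE)
    structure(list(participant_id = m$participant_id,
                   waveforms = as.matrix(x), lead_names = colnames(x),
                   sampling_rate_hz = m$sampling_rate_hz,
                   r_index = m$r_index, mean_rr_ms = m$mean_rr_ms,
                   ventricular_rate_bpm = m$ventricular_rate_bpm,
                   n_beats_detected = m$n_beats_detected,
                   n_beats_retained = m$n_beats_retained),
              class = "median_beat")
  })
  names(beats) <- manifest$participant_id
  beats
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`, `clinical.csv`,
#'   `cmr.csv` and the per-participant ECG text files.
#' @return list with `clinical`, `cmr` (data.frames) and `ecgs`
#'   (named list of `raw_ecg`).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  clinical <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  cmr <- read.csv(file.path(dir, "cmr.csv"), stringsAsFactors = FALSE)
  ecgs <- lapply(manifest$ecg_file, function(f) read_ecg(file.path(dir, f)))
  names(ecgs) <- manifest$participant_id
  list(clinical = clinical, cmr = cmr, ecgs = ecgs)
}
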