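#' @include montage.R
NULL

# Read a comma/tab-delimited table, skipping "#" comment lines, with the
# delimiter autodetected from the header line.
readDelimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) >
             lengths(regmatches(lines[1], gregexpr(",", lines[1])))) "\t" else ","
  utils::read.table(text = lines, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Pull "# key=value" comment metadata out of a delimited file.
readFileMeta <- function(path) {
  lines <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE)
  kv <- regmatches(lines, regexec("#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(\\S+)", lines))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}

#' Construct and validate an event schedule
#'
#' @param onset_s event onsets in seconds, non-decreasing
#' @param duration_s event durations in seconds
#' @param label integer activity codes: 1 = no activity, 2 = mental drawing,
#'   3 = spatial navigation
#' @return data.frame of class \code{"EventSchedule"} with those columns
#' @export
eventSchedule <- function(onset_s, duration_s, label) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   label = as.integer(label))
  if (nrow(ev) && is.unsorted(ev$onset_s))
    stop("event onsets must be non-decreasing")
  bad <- which(!ev$label %in% c(1L, 2L, 3L))
  if (length(bad))
    stop("event labels must be 1, 2 or 3; row ", bad[1],
         " has label ", ev$label[bad[1]])
  if (any(ev$duration_s < 0)) stop("event durations must be >= 0")
  class(ev) <- c("EventSchedule", "data.frame")
  ev
}

#' Read an event schedule file
#'
#' Delimited text with header \code{onset_s,duration_s,label}.
#' @param path file path
#' @return an event schedule (see [eventSchedule()])
#' @export
readEvents <- function(path) {
  d <- readDelimited(path)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(d)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  eventSchedule(d$onset_s, d$duration_s, d$label)
}

#' Load a raw fNIRS session from delimited files
#'
#' The raw data file has one row per channel x wavelength with header
#' \code{channel,wavelength_nm,s0,s1,...} and an optional \code{# fs_hz=}
#' comment carrying the sampling rate (argument \code{fs} is the fallback).
#' Channel ids are \code{"source-detector"} and must reference montage
#' optodes; each channel must appear at both wavelengths and all intensities
#' must be strictly positive.
#'
#' @param data_path raw intensity table
#' @param montage_path optode sidecar (see [readMontage()])
#' @param events_path event schedule (see [readEvents()])
#' @param fs sampling rate in Hz used when the data file carries none
#' @return list with elements \code{scan} (\linkS4class{RawScan}),
#'   \code{events}, \code{montage}
#' @export
loadRaw <- function(data_path, montage_path, events_path, fs = 12.5) {
  montage <- readMontage(montage_path)
  events <- readEvents(events_path)
  d <- readDelimited(data_path)
  if (!all(c("channel", "wavelength_nm") %in% names(d)))
    stop("raw data file must start with columns channel, wavelength_nm")
  meta <- readFileMeta(data_path)
  if ("fs_hz" %in% names(meta)) fs <- as.numeric(meta[["fs_hz"]])

  channel <- as.character(d$channel)
  wavelength <- as.numeric(d$wavelength_nm)
  values <- as.matrix(d[, setdiff(names(d), c("channel", "wavelength_nm")),
                        drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- NULL

  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive or non-finite intensity at data row ", bad[1, 1],
         " (channel ", channel[bad[1, 1]], ", ", wavelength[bad[1, 1]],
         " nm), sample column ", bad[1, 2])

  parts <- strsplit(channel, "-", fixed = TRUE)
  opt <- montage@optodes$label
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 2L || !all(parts[[i]] %in% opt))
      stop("data row ", i, ": channel id '", channel[i],
           "' does not reference montage optodes")
  }

  all_ch <- enumerateChannels(montage)
  ids <- unique(channel)
  chset <- channelSubset(all_ch, ids)
  scan <- new("RawScan", values = values, wavelength = wavelength,
              channel = channel, fs = fs, channels = chset)
  list(scan = scan, events = events, montage = montage)
}

# Writers used by the synthetic-session fixture emitter (round-trip tested
# against loadRaw/readMontage/readEvents).
writeMontageFile <- function(montage, path) {
  utils::write.table(montage@optodes, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  path
}

writeEventsFile <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  path
}

writeRawFile <- function(scan, path) {
  n <- ncol(scan@values)
  header <- paste(c("channel", "wavelength_nm",
                    paste0("s", seq_len(n) - 1L)), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.17g", scan@fs), con)
  writeLines(header, con)
  body <- vapply(seq_len(nrow(scan@values)), function(i) {
    paste(c(scan@channel[i], sprintf("%.17g", scan@wavelength[i]),
            sprintf("%.17g", scan@values[i, ])), collapse = ",")
  }, "")
  writeLines(body, con)
  path
}
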