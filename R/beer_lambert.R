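#' @include epoch.R
NULL

#' Default molar extinction coefficients for HbO/HbR
#'
#' Standard compiled values at 760 and 850 nm, in 1/(mM*mm), shipped as a
#' versioned data file and overridable by passing any table of the same
#' shape.
#'
#' @param path optional path to a delimited table with columns
#'   \code{wavelength_nm, chromophore, epsilon_per_mM_mm}
#' @return 2x2 numeric matrix, rows named by wavelength ("760", "850"),
#'   columns \code{HbO}, \code{HbR}
#' @export
defaultExtinction <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "fnirsdecode", mustWork = TRUE)
  d <- readDelimited(path)
  wl <- sort(unique(d$wavelength_nm))
  ext <- matrix(NA_real_, length(wl), 2,
                dimnames = list(as.character(wl), c("HbO", "HbR")))
  for (i in seq_len(nrow(d)))
    ext[as.character(d$wavelength_nm[i]), d$chromophore[i]] <-
      d$epsilon_per_mM_mm[i]
  if (anyNA(ext)) stop("extinction table incomplete: ", path)
  if (abs(det(ext)) < 1e-12)
    stop("extinction matrix is singular; HbO/HbR are not identifiable")
  ext
}

#' Mean baseline intensity per channel-wavelength row
#'
#' Reference intensities I0 over a baseline window; differencing against
#' this reference is what cancels the unknown scattering geometric term of
#' the modified Beer-Lambert law.
#'
#' @param scan a \linkS4class{RawScan}
#' @param window numeric length-2, seconds \code{c(start, end)}; samples
#'   with time in \code{[start, end)} are averaged
#' @return numeric vector, one reference intensity per row
#' @export
baselineReference <- function(scan, window = c(0, 2)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  n <- ncol(scan@values)
  t <- (seq_len(n) - 1) / scan@fs
  if (window[1] < 0 || window[2] > n / scan@fs)
    stop("baseline window [", window[1], ", ", window[2],
         ") falls outside the recording (0-", n / scan@fs, " s)")
  idx <- which(t >= window[1] & t < window[2])
  if (!length(idx)) stop("baseline window contains no samples")
  rowMeans(scan@values[, idx, drop = FALSE])
}

#' Convert raw intensities to optical-density changes
#'
#' \eqn{\Delta OD(t) = -\log_{10}(I(t)/I_0)} elementwise. Because the
#' reference is taken from the recording itself, \eqn{\Delta OD} averages
#' zero over the baseline window and is invariant to rescaling I and I0 by
#' a common constant.
#'
#' @param scan a \linkS4class{RawScan}
#' @param I0 per-row reference intensities (see [baselineReference()])
#' @return an \linkS4class{OdSeries}
#' @export
intensityToOd <- function(scan, I0) {
  stopifnot(length(I0) == nrow(scan@values))
  if (any(!is.finite(I0) | I0 <= 0))
    stop("reference intensities must be finite and strictly positive")
  od <- -log10(scan@values / I0)
  new("OdSeries", od = od, wavelength = scan@wavelength,
      channel = scan@channel, fs = scan@fs)
}

# epsilon * DPF * d system matrix for one channel (rows = wavelengths,
# cols = chromophores); concentrations solved in mM then reported in uM.
blSystemMatrix <- function(ext, dpf, d_mm) {
  wl <- rownames(ext)
  E <- ext * dpf[wl] * d_mm
  E
}

#' Solve optical-density changes for hemoglobin concentration changes
#'
#' Per channel and sample, inverts the two-wavelength linear system
#' \eqn{\Delta OD(\lambda) = [\epsilon_{HbO}(\lambda)\Delta HbO +
#' \epsilon_{HbR}(\lambda)\Delta HbR] \cdot DPF(\lambda) \cdot d}. The
#' scattering term is absent because \eqn{\Delta OD} is differential.
#'
#' @param od an \linkS4class{OdSeries}
#' @param channels \linkS4class{ChannelSet} supplying source-detector
#'   distances (mm)
#' @param ext extinction matrix as from [defaultExtinction()], 1/(mM*mm)
#' @param dpf named numeric, differential pathlength factor per wavelength;
#'   default 6.0 at both wavelengths (common adult value)
#' @param cond_max maximum accepted condition number of the per-channel
#'   system matrix
#' @return an \linkS4class{HbSeries} in micromolar
#' @export
odToHb <- function(od, channels, ext = defaultExtinction(),
                   dpf = c("760" = 6, "850" = 6), cond_max = 1e8) {
  ids <- channelIds(channels)
  dist <- channels@channels$distance_mm
  wl <- rownames(ext)
  n <- ncol(od@od)
  hbo_m <- matrix(NA_real_, length(ids), n)
  hbr_m <- matrix(NA_real_, length(ids), n)
  for (i in seq_along(ids)) {
    rows <- vapply(wl, function(w)
      which(od@channel == ids[i] & od@wavelength == as.numeric(w))[1],
      integer(1))
    if (anyNA(rows))
      stop("channel ", ids[i], " is missing a wavelength row")
    E <- blSystemMatrix(ext, dpf, dist[i])
    if (kappa(E, exact = TRUE) > cond_max)
      stop("ill-conditioned Beer-Lambert system for channel ", ids[i],
           " (condition number > ", cond_max, ")")
    conc <- solve(E, od@od[rows, , drop = FALSE])  # mM
    hbo_m[i, ] <- conc[1, ] * 1000                 # -> uM
    hbr_m[i, ] <- conc[2, ] * 1000
  }
  new("HbSeries", hbo = hbo_m, hbr = hbr_m, channel = ids, fs = od@fs)
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (uM) to optical-density changes;
#' the exact inverse of [odToHb()]. Used by the synthetic generator and by
#' round-trip tests.
#'
#' @inheritParams odToHb
#' @param hbo,hbr channels x samples matrices, micromolar
#' @param fs sampling rate, Hz
#' @return an \linkS4class{OdSeries} with rows ordered channels-major,
#'   wavelengths inner (ascending)
#' @export
hbToOd <- function(hbo, hbr, channels, ext = defaultExtinction(),
                   dpf = c("760" = 6, "850" = 6), fs = 12.5) {
  ids <- channelIds(channels)
  dist <- channels@channels$distance_mm
  wl <- rownames(ext)
  stopifnot(nrow(hbo) == length(ids), identical(dim(hbo), dim(hbr)))
  od <- matrix(NA_real_, 2L * length(ids), ncol(hbo))
  channel <- character(2L * length(ids))
  wavelength <- numeric(2L * length(ids))
  for (i in seq_along(ids)) {
    E <- blSystemMatrix(ext, dpf, dist[i])
    conc <- rbind(hbo[i, ], hbr[i, ]) / 1000  # uM -> mM
    rows <- (2L * i - 1L):(2L * i)
    od[rows, ] <- E %*% conc
    channel[rows] <- ids[i]
    wavelength[rows] <- as.numeric(wl)
  }
  new("OdSeries", od = od, wavelength = wavelength, channel = channel,
      fs = fs)
}

#' Split an HbSeries into its HbO and HbR streams
#'
#' All downstream feature and classification stages run once per stream.
#'
#' @param hb an \linkS4class{HbSeries}
#' @return named list of two channels x samples matrices with a
#'   \code{"stream"} attribute each
#' @export
splitStreams <- function(hb) {
  o <- hbo(hb); r <- hbr(hb)
  rownames(o) <- rownames(r) <- channelIds(hb)
  attr(o, "stream") <- "HbO"
  attr(r, "stream") <- "HbR"
  list(HbO = o, HbR = r)
}

#' Merge HbO/HbR stream matrices back into an HbSeries
#'
#' Inverse of [splitStreams()]; \code{mergeStreams(splitStreams(x), x)}
#' reproduces \code{x}.
#'
#' @param streams list with elements \code{HbO} and \code{HbR}
#' @param template \linkS4class{HbSeries} supplying channels and fs
#' @return an \linkS4class{HbSeries}
#' @export
mergeStreams <- function(streams, template) {
  o <- streams$HbO; r <- streams$HbR
  attr(o, "stream") <- NULL; attr(r, "stream") <- NULL
  dimnames(o) <- dimnames(r) <- NULL
  new("HbSeries", hbo = o, hbr = r, channel = channelIds(template),
      fs = samplingRate(template))
}
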