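#' @include fnirsdecode-package.R
NULL

#' Optode montage for a continuous-wave fNIRS cap
#'
#' Holds the optode table of a recording montage: 10-20 position labels,
#' source/detector roles and 3-D scalp coordinates in millimetres.
#'
#' @slot optodes data.frame with columns \code{label}, \code{role}
#'   (\code{"source"} or \code{"detector"}), \code{x_mm}, \code{y_mm},
#'   \code{z_mm}.
#' @seealso [readMontage()], [standardMontage()], [enumerateChannels()]
#' @export
setClass("FnirsMontage", representation(optodes = "data.frame"))

setValidity("FnirsMontage", function(object) {
  o <- object@optodes
  need <- c("label", "role", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(o)))
    return(paste("optodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(o$label)) return("optode labels must be unique")
  if (!all(o$role %in% c("source", "detector")))
    return("role must be 'source' or 'detector'")
  pos <- as.matrix(o[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(pos))) return("optode positions must be finite")
  TRUE
})

#' Enumerated source-detector channels
#'
#' Ordered set of source-detector pairs with their Euclidean inter-optode
#' distances. Order is sources-major in montage order; downstream channel
#' indices ("channel 4") refer to this order.
#'
#' @slot channels data.frame with columns \code{source}, \code{detector},
#'   \code{distance_mm}.
#' @export
setClass("ChannelSet", representation(channels = "data.frame"))

setValidity("ChannelSet", function(object) {
  ch <- object@channels
  need <- c("source", "detector", "distance_mm")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(paste(ch$source, ch$detector, sep = "\r")))
    return("duplicate (source, detector) pairs")
  if (any(ch$distance_mm < 0) || !all(is.finite(ch$distance_mm)))
    return("distances must be finite and >= 0")
  TRUE
})

#' Raw two-wavelength intensity recording
#'
#' Channel-by-wavelength rows of strictly positive light intensities in
#' arbitrary units, one column per sample.
#'
#' @slot values numeric matrix, rows = channel x wavelength, cols = samples.
#' @slot wavelength numeric, nanometres per row.
#' @slot channel character, channel id ("source-detector") per row.
#' @slot fs numeric, sampling rate in Hz.
#' @slot channels \linkS4class{ChannelSet} describing the channel ids.
#' @export
setClass("RawScan", representation(
  values = "matrix", wavelength = "numeric", channel = "character",
  fs = "numeric", channels = "ChannelSet"
))

setValidity("RawScan", function(object) {
  v <- object@values
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be > 0")
  if (nrow(v) != length(object@wavelength) || nrow(v) != length(object@channel))
    return("wavelength/channel annotations must match row count")
  if (any(v <= 0) || !all(is.finite(v)))
    return("all intensities must be finite and strictly positive")
  wl_by_ch <- split(object@wavelength, object@channel)
  bad <- names(wl_by_ch)[vapply(wl_by_ch, function(w)
    length(w) != 2L || length(unique(w)) != 2L, logical(1))]
  if (length(bad))
    return(paste("each channel needs exactly one row per wavelength; bad:",
                 paste(bad, collapse = ", ")))
  TRUE
})

#' Optical-density change series
#'
#' Dimensionless \eqn{\Delta OD} per channel x wavelength row, referenced to
#' a baseline window (so the scattering geometric term cancels).
#'
#' @slot od numeric matrix, same layout as the source [RawScan-class].
#' @slot wavelength,channel row annotations as in [RawScan-class].
#' @slot fs sampling rate, Hz.
#' @export
setClass("OdSeries", representation(
  od = "matrix", wavelength = "numeric", channel = "character", fs = "numeric"
))

#' Hemoglobin concentration-change series
#'
#' \eqn{\Delta}HbO and \eqn{\Delta}HbR per channel and sample, micromolar.
#'
#' @slot hbo,hbr numeric matrices, channels x samples.
#' @slot channel character channel ids (row order).
#' @slot fs sampling rate, Hz.
#' @export
setClass("HbSeries", representation(
  hbo = "matrix", hbr = "matrix", channel = "character", fs = "numeric"
))

setValidity("HbSeries", function(object) {
  if (!identical(dim(object@hbo), dim(object@hbr)))
    return("hbo and hbr must have identical dimensions")
  if (nrow(object@hbo) != length(object@channel))
    return("channel ids must match row count")
  if (!all(is.finite(object@hbo)) || !all(is.finite(object@hbr)))
    return("concentrations must be finite")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be > 0")
  TRUE
})

#' Fitted blind-source-separation model
#'
#' Unmixing/mixing matrices with whitener and channel means; sources are
#' \code{W \%*\% whitener \%*\% (X - means)} and reconstruction back-projects
#' through \code{A}.
#'
#' @slot W unmixing matrix (components x whitened dims).
#' @slot A mixing matrix (channels x components).
#' @slot whitener whitening matrix (whitened dims x channels).
#' @slot means per-channel offsets removed before whitening.
#' @slot method one of \code{"fastica"}, \code{"picard"}, \code{"infomax"}.
#' @slot seed,iterations,tol convergence metadata.
#' @slot converged logical.
#' @export
setClass("IcaModel", representation(
  W = "matrix", A = "matrix", whitener = "matrix", means = "numeric",
  method = "character", seed = "integer", iterations = "integer",
  tol = "numeric", converged = "logical"
))

setValidity("IcaModel", function(object) {
  if (!all(is.finite(object@W))) return("unmixing matrix must be finite")
  if (!object@method %in% c("fastica", "picard", "infomax"))
    return("method must be fastica, picard or infomax")
  ident <- object@W %*% object@whitener %*% object@A
  if (max(abs(ident - diag(nrow(ident)))) > 1e-6)
    return("W * whitener * A must equal identity on the component subspace")
  TRUE
})

setMethod("show", "FnirsMontage", function(object) {
  o <- object@optodes
  cat("FnirsMontage:", sum(o$role == "source"), "sources,",
      sum(o$role == "detector"), "detectors\n")
  cat("  labels:", paste(o$label, collapse = " "), "\n")
})

setMethod("show", "ChannelSet", function(object) {
  ch <- object@channels
  cat("ChannelSet:", nrow(ch), "channels, distances",
      if (nrow(ch)) paste0(round(min(ch$distance_mm), 1), "-",
                           round(max(ch$distance_mm), 1), " mm") else "",
      "\n")
})

setMethod("show", "RawScan", function(object) {
  cat("RawScan:", length(unique(object@channel)), "channels x",
      length(unique(object@wavelength)), "wavelengths,",
      ncol(object@values), "samples @", object@fs, "Hz\n")
})

setMethod("show", "HbSeries", function(object) {
  cat("HbSeries:", nrow(object@hbo), "channels,", ncol(object@hbo),
      "samples @", object@fs, "Hz (units uM)\n")
})

setMethod("show", "IcaModel", function(object) {
  cat("IcaModel (", object@method, "): ", nrow(object@W), " components, ",
      object@iterations, " iterations, converged = ", object@converged,
      "\n", sep = "")
})

#' @rdname accessors
#' @param object an object with a sampling rate or channels
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))

#' Accessors for fNIRS containers
#'
#' \code{samplingRate} returns the sampling frequency in Hz; \code{nChannels}
#' the number of distinct channels; \code{channelIds} the
#' \code{"source-detector"} identifiers in canonical order.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "RawScan", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "OdSeries", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "HbSeries", function(object) object@fs)
#' @rdname accessors
setMethod("nChannels", "ChannelSet", function(object) nrow(object@channels))
#' @rdname accessors
setMethod("nChannels", "RawScan", function(object)
  length(unique(object@channel)))
#' @rdname accessors
setMethod("nChannels", "HbSeries", function(object) nrow(object@hbo))
#' @rdname accessors
setMethod("channelIds", "ChannelSet", function(object)
  paste(object@channels$source, object@channels$detector, sep = "-"))
#' @rdname accessors
setMethod("channelIds", "HbSeries", function(object) object@channel)

#' Extract the channel table
#' @param object a \linkS4class{ChannelSet} or object carrying one
#' @return data.frame with columns source, detector, distance_mm
#' @export
setGeneric("channelTable", function(object) standardGeneric("channelTable"))
#' @rdname channelTable
setMethod("channelTable", "ChannelSet", function(object) object@channels)
#' @rdname channelTable
setMethod("channelTable", "RawScan", function(object)
  object@channels@channels)

#' @rdname hbAccess
#' @export
setGeneric("hbo", function(object) standardGeneric("hbo"))
#' @rdname hbAccess
#' @export
setGeneric("hbr", function(object) standardGeneric("hbr"))

#' Hemoglobin stream accessors
#'
#' Matrices of concentration changes (uM), channels x samples.
#' @param object an \linkS4class{HbSeries}
#' @name hbAccess
#' @rdname hbAccess
NULL
#' @rdname hbAccess
setMethod("hbo", "HbSeries", function(object) object@hbo)
#' @rdname hbAccess
setMethod("hbr", "HbSeries", function(object) object@hbr)

#' @rdname icaAccess
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))
#' @rdname icaAccess
#' @export
setGeneric("unmixingMatrix", function(object) standardGeneric("unmixingMatrix"))

#' ICA model accessors
#' @param object an \linkS4class{IcaModel}
#' @name icaAccess
#' @rdname icaAccess
NULL
#' @rdname icaAccess
setMethod("mixingMatrix", "IcaModel", function(object) object@A)
#' @rdname icaAccess
setMethod("unmixingMatrix", "IcaModel", function(object) object@W)
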