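#' @include AllClasses.R
NULL

#' Construct a montage from an optode table
#'
#' @param optodes data.frame with columns \code{label}, \code{role}
#'   (\code{"source"}/\code{"detector"}), \code{x_mm}, \code{y_mm},
#'   \code{z_mm}.
#' @return a \linkS4class{FnirsMontage}
#' @export
fnirsMontage <- function(optodes) {
  optodes <- as.data.frame(optodes, stringsAsFactors = FALSE)
  optodes$label <- as.character(optodes$label)
  optodes$role <- as.character(optodes$role)
  new("FnirsMontage", optodes = optodes)
}

#' Read a montage sidecar file
#'
#' Delimited text (comma or tab, autodetected) with header
#' \code{label,role,x_mm,y_mm,z_mm}.
#'
#' @param path file path
#' @return a \linkS4class{FnirsMontage}
#' @export
readMontage <- function(path) {
  fnirsMontage(readDelimited(path))
}

#' The bundled 3x6 probe layout over left sensorimotor cortex
#'
#' Sources on FC3, C3, CP3 and detectors on FC5, C5, CP5, FC1, C1, CP1 at
#' standard 10-20 scalp coordinates (head frame, millimetres). Enumerating
#' this montage yields 18 source-detector channels; the conventional 60 mm
#' distance cutoff retains 14 of them.
#'
#' @return a \linkS4class{FnirsMontage} with 9 optodes
#' @export
standardMontage <- function() {
  readMontage(system.file("extdata", "montage_1020.csv",
                          package = "fnirsdecode", mustWork = TRUE))
}

#' Enumerate all source-detector channels of a montage
#'
#' Every source x detector pair becomes one channel, with the Euclidean
#' inter-optode distance computed from the montage coordinates. Order is
#' deterministic: sources outer, detectors inner, both in montage order.
#'
#' @param montage a \linkS4class{FnirsMontage} with at least one source and
#'   one detector
#' @return a \linkS4class{ChannelSet}
#' @examples
#' nChannels(enumerateChannels(standardMontage()))  # 18
#' @export
setGeneric("enumerateChannels",
           function(montage) standardGeneric("enumerateChannels"))

#' @rdname enumerateChannels
setMethod("enumerateChannels", "FnirsMontage", function(montage) {
  o <- montage@optodes
  src <- o[o$role == "source", , drop = FALSE]
  det <- o[o$role == "detector", , drop = FALSE]
  if (nrow(src) == 0L || nrow(det) == 0L)
    stop("montage needs at least one source and one detector optode")
  grid <- expand.grid(d = seq_len(nrow(det)), s = seq_len(nrow(src)))
  # expand.grid varies the first factor fastest; we want sources-major
  s <- src[grid$s, ]
  d <- det[grid$d, ]
  dist <- sqrt((s$x_mm - d$x_mm)^2 + (s$y_mm - d$y_mm)^2 +
               (s$z_mm - d$z_mm)^2)
  new("ChannelSet", channels = data.frame(
    source = s$label, detector = d$label, distance_mm = dist,
    stringsAsFactors = FALSE, row.names = NULL))
})

#' Drop channels whose inter-optode distance exceeds a cutoff
#'
#' Long-separation channels carry too little cortical signal; the
#' conventional cutoff of 60 mm reduces the bundled 18-channel layout to the
#' 14 channels used throughout the pipeline. Order is preserved and the
#' operation is idempotent.
#'
#' @param channels a \linkS4class{ChannelSet}
#' @param max_mm maximum distance kept, millimetres (> 0)
#' @return a \linkS4class{ChannelSet} with channels at distance
#'   \code{<= max_mm}
#' @examples
#' ch <- enumerateChannels(standardMontage())
#' nChannels(filterByDistance(ch, 60))  # 14
#' @export
setGeneric("filterByDistance",
           function(channels, max_mm = 60) standardGeneric("filterByDistance"))

#' @rdname filterByDistance
setMethod("filterByDistance", "ChannelSet", function(channels, max_mm = 60) {
  stopifnot(is.numeric(max_mm), length(max_mm) == 1L, max_mm > 0)
  keep <- channels@channels$distance_mm <= max_mm
  new("ChannelSet",
      channels = channels@channels[keep, , drop = FALSE])
})

# Subset a ChannelSet by channel ids, preserving set order.
channelSubset <- function(channels, ids) {
  all_ids <- channelIds(channels)
  missing <- setdiff(ids, all_ids)
  if (length(missing))
    stop("unknown channel ids: ", paste(missing, collapse = ", "))
  new("ChannelSet",
      channels = channels@channels[match(ids, all_ids), , drop = FALSE])
}
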