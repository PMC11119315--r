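#' @include io.R
NULL

#' Cut a channel-by-sample series into event-locked trial epochs
#'
#' One epoch per event, starting at the event onset plus \code{offset_s},
#' spanning \code{round(window_s * fs)} samples and carrying the event
#' label. Overlapping epochs are allowed. Onsets are converted to sample
#' indices by rounding to the nearest sample (index 0 = recording start).
#'
#' @param x numeric matrix, channels x samples
#' @param fs sampling rate, Hz
#' @param events event schedule (see [eventSchedule()])
#' @param window_s epoch length in seconds (> 0); default 10 s, the span of
#'   a hemodynamic response
#' @param offset_s start offset relative to the event onset, seconds
#' @return list of epochs, each a list with \code{data} (channels x
#'   samples), \code{label}, \code{window = c(start_s, length_s)}
#' @export
epochSeries <- function(x, fs, events, window_s = 10, offset_s = 0) {
  stopifnot(is.matrix(x), fs > 0, window_s > 0)
  n_win <- round(window_s * fs)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    start <- round((events$onset_s[i] + offset_s) * fs) + 1L
    end <- start + n_win - 1L
    if (start < 1L || end > ncol(x))
      stop("epoch for event ", i, " (onset ", events$onset_s[i],
           " s, label ", events$label[i], ") extends outside the recording")
    out[[i]] <- list(data = x[, start:end, drop = FALSE],
                     label = events$label[i],
                     window = c(start_s = events$onset_s[i] + offset_s,
                                length_s = window_s))
  }
  out
}
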