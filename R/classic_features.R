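#' @include wavelets.R
NULL

#' Classical time-domain moment features of a sample vector
#'
#' Mean, variance, skewness and excess kurtosis with the conventions used
#' throughout the pipeline: variance is the population form (1/N);
#' skewness and kurtosis use a 1/N numerator moment over a 1/(N-1) inner
#' second moment (the difference from the textbook g1/g2 vanishes for
#' large N). Kurtosis is excess (Gaussian = 0).
#'
#' @param x numeric vector with at least 4 samples and nonzero variance
#' @return named numeric vector: \code{mean}, \code{variance},
#'   \code{skewness}, \code{kurtosis}
#' @examples
#' timeDomainFeatures(c(1, 2, 3, 4))  # mean 2.5, variance 1.25
#' @export
timeDomainFeatures <- function(x) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 samples for stable moment features")
  mu <- mean(x)
  dev <- x - mu
  v_pop <- mean(dev^2)                 # 1/N convention
  v_inner <- sum(dev^2) / (n - 1)      # 1/(N-1) inner denominator
  if (v_inner == 0)
    stop("zero variance: skewness and kurtosis are undefined")
  c(mean = mu,
    variance = v_pop,
    skewness = mean(dev^3) / v_inner^1.5,
    kurtosis = mean(dev^4) / v_inner^2 - 3)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into overlapping
#' segments, mean-detrended, Hann-windowed, and the one-sided periodograms
#' are averaged. Scaling is density (signal^2/Hz): the integral of the PSD
#' approximates the signal variance (Parseval, up to windowing loss).
#'
#' @param x numeric sample vector
#' @param fs sampling rate, Hz
#' @param segment segment length in samples; default \code{min(N, 256)}
#' @param overlap fractional overlap between segments, in [0, 1); default
#'   0.5
#' @param window \code{"hann"} (default) or \code{"rect"}
#' @return object of class \code{"PsdEstimate"}: list with \code{freq}
#'   (Hz, ascending, within [0, fs/2]) and \code{power} (>= 0)
#' @export
psdWelch <- function(x, fs, segment = min(length(x), 256L), overlap = 0.5,
                     window = c("hann", "rect")) {
  window <- match.arg(window)
  n <- length(x)
  segment <- as.integer(segment)
  if (segment > n) stop("segment length exceeds the signal length")
  stopifnot(segment >= 2L, overlap >= 0, overlap < 1, fs > 0)
  step <- max(1L, as.integer(round(segment * (1 - overlap))))
  starts <- seq(1L, n - segment + 1L, by = step)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, segment - 1) / (segment - 1))
  else rep(1, segment)
  u <- sum(w^2)
  nf <- segment %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    p1 <- p[seq_len(nf)]
    # fold negative frequencies into the one-sided estimate
    dbl <- 2:(nf - if (segment %% 2L == 0L) 1L else 0L)
    p1[dbl] <- 2 * p1[dbl]
    acc <- acc + p1
  }
  structure(list(freq = (seq_len(nf) - 1) * fs / segment,
                 power = acc / length(starts)),
            class = "PsdEstimate")
}

#' Spectral peak and FWHM-band features of a PSD estimate
#'
#' Peak frequency (ties resolved toward the lowest frequency), peak power,
#' and the mean power over the full-width-half-maximum band: the
#' contiguous run of frequency bins around the peak whose power stays at
#' or above half the peak (bin resolution, no interpolation).
#'
#' @param p a \code{"PsdEstimate"} with some nonzero power
#' @return named numeric vector: \code{peak_frequency}, \code{peak_power},
#'   \code{fwhm_band_power}
#' @export
frequencyFeatures <- function(p) {
  pow <- p$power
  if (!length(pow) || all(pow == 0))
    stop("all-zero PSD: spectral peak is undefined")
  k <- which.max(pow)  # first maximum = lowest-frequency tie-break
  half <- pow[k] / 2
  lo <- k
  while (lo > 1L && pow[lo - 1L] >= half) lo <- lo - 1L
  hi <- k
  while (hi < length(pow) && pow[hi + 1L] >= half) hi <- hi + 1L
  c(peak_frequency = p$freq[k],
    peak_power = pow[k],
    fwhm_band_power = mean(pow[lo:hi]))
}

#' Classical per-epoch, per-channel feature table
#'
#' For every epoch and channel: the four time-domain moments and the three
#' spectral features of [frequencyFeatures()], concatenated into one named
#' row. Feature names are \code{chNN_<feature>} in canonical channel
#' order, stable across runs.
#'
#' @param epochs list of epochs from [epochSeries()]
#' @param fs sampling rate, Hz
#' @param psd_segment,psd_overlap forwarded to [psdWelch()]
#' @param stream stream tag recorded in the table ("HbO"/"HbR")
#' @return data.frame: columns \code{epoch}, \code{label}, \code{stream},
#'   \code{feature_set} ("classical"), then one column per feature
#' @export
classicalFeatures <- function(epochs, fs, psd_segment = NULL,
                              psd_overlap = 0.5, stream = "HbO") {
  stopifnot(length(epochs) >= 1L)
  n_ch <- nrow(epochs[[1L]]$data)
  fnames <- as.vector(t(outer(sprintf("ch%02d", seq_len(n_ch)),
                              c("mean", "variance", "skewness", "kurtosis",
                                "peak_frequency", "peak_power",
                                "fwhm_band_power"), paste, sep = "_")))
  rows <- matrix(NA_real_, length(epochs), length(fnames),
                 dimnames = list(NULL, fnames))
  for (e in seq_along(epochs)) {
    dat <- epochs[[e]]$data
    seg <- if (is.null(psd_segment)) min(ncol(dat), 256L) else psd_segment
    vals <- lapply(seq_len(n_ch), function(i) {
      td <- tryCatch(timeDomainFeatures(dat[i, ]), error = function(err)
        stop("epoch ", e, ", channel ", i, ": ", conditionMessage(err)))
      fd <- frequencyFeatures(psdWelch(dat[i, ], fs, segment = seg,
                                       overlap = psd_overlap))
      c(td, fd)
    })
    rows[e, ] <- unlist(vals)
  }
  cbind(data.frame(epoch = seq_along(epochs),
                   label = vapply(epochs, `[[`, 0L, "label"),
                   stream = stream, feature_set = "classical",
                   stringsAsFactors = FALSE),
        as.data.frame(rows))
}
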