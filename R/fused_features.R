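#' @include classic_features.R
NULL

#' Hjorth activity of a sample vector
#'
#' The sample variance with N-1 denominator — the power level of the
#' signal, first of the Hjorth descriptors.
#'
#' @param x numeric vector, length >= 2
#' @return nonnegative scalar (signal units squared)
#' @examples
#' hjorthActivity(c(1, 2, 3, 4))  # 5/3
#' @export
hjorthActivity <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  stats::var(x)
}

#' Hjorth mobility of a sample vector
#'
#' The variance of the time derivative (first difference scaled by the
#' sampling rate) divided by the activity — an index of the dominant
#' oscillation rate. The default is the plain variance ratio; the
#' conventional square-root form is available via \code{sqrt_mobility}.
#'
#' @param x numeric vector, length >= 3, nonzero activity
#' @param fs sampling rate, Hz (scales the difference quotient)
#' @param sqrt_mobility if TRUE return the square root of the ratio
#'   (standard Hjorth definition); default FALSE, the plain ratio
#' @return nonnegative scalar; for a pure sinusoid of frequency f the
#'   plain ratio approaches \eqn{(2\pi f)^2} in the continuous-time limit
#' @export
hjorthMobility <- function(x, fs = 1, sqrt_mobility = FALSE) {
  if (length(x) < 3L) stop("need at least 3 samples")
  a <- hjorthActivity(x)
  if (a == 0) stop("zero activity: mobility is undefined")
  r <- stats::var(diff(x) * fs) / a
  if (sqrt_mobility) sqrt(r) else r
}

#' First fused series: Hjorth- and wavelet-weighted channels
#'
#' Per channel, \code{fnew_i(t) = (w_i + alpha_i + beta_i) * f_i(t)}:
#' channels whose trimmed wavelet weight, activity and mobility are large
#' (i.e. channels carrying task-related signal) are amplified, quiet
#' channels attenuated.
#'
#' @param f channels x samples matrix
#' @param w numeric vector of channel weights
#' @param alpha,beta numeric vectors of Hjorth activity/mobility; a
#'   channel with undefined mobility (NA) yields an all-zero fused row
#'   with a warning rather than an error
#' @return matrix of the same shape as \code{f}
#' @export
fuse1 <- function(f, w, alpha, beta) {
  stopifnot(is.matrix(f), length(w) == nrow(f), length(alpha) == nrow(f),
            length(beta) == nrow(f))
  coef <- w + alpha + beta
  bad <- !is.finite(coef)
  if (any(bad)) {
    warning("channel(s) ", paste(which(bad), collapse = ", "),
            " have undefined Hjorth parameters; fused rows set to 0")
    coef[bad] <- 0
  }
  f * coef
}

#' Single-level undecimated symlet smoothing
#'
#' Circular (periodic-boundary) convolution with the symlet scaling
#' filter, normalized to unit DC gain, keeping the input length: a
#' shift-invariant lowpass that preserves slow hemodynamic structure and
#' suppresses high-frequency content (the filter has a spectral zero at
#' Nyquist). Linear in its input.
#'
#' @param f numeric sample vector, at least as long as the filter
#' @param wavelet symlet family member; default \code{"sym4"}
#' @return smoothed vector, same length as \code{f}
#' @export
symletStream <- function(f, wavelet = "sym4") {
  h <- waveletFilters(wavelet)$dec_lo
  h <- h / sum(h)  # unit DC gain
  n <- length(f)
  if (n < length(h)) stop("signal shorter than the symlet filter")
  out <- numeric(n)
  for (m in seq_along(h)) {
    idx <- ((seq_len(n) - m) %% n) + 1L
    out <- out + h[m] * f[idx]
  }
  out
}

#' Instantaneous amplitude envelope via the analytic signal
#'
#' Magnitude of the Hilbert-transform analytic signal, computed in the
#' frequency domain: positive frequencies doubled, negative zeroed. For a
#' pure tone of amplitude A the envelope is A away from the edges; for an
#' amplitude-modulated tone it recovers the modulator.
#'
#' @param f numeric sample vector, length >= 4
#' @return real-valued envelope, same length as \code{f}
#' @export
hilbertStream <- function(f) {
  n <- length(f)
  if (n < 4L) stop("need at least 4 samples")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(f) * h, inverse = TRUE) / n)
}

#' Second fused series: weighted symlet + Hilbert streams
#'
#' \code{fnew1_i(t) = w_i * (h_i(t) + s_i(t))}: the envelope (phase/energy
#' information) and the symlet smoothing (edge/texture information) of
#' each channel, gated by the channel's wavelet weight.
#'
#' @param w numeric vector of channel weights
#' @param h channels x samples matrix of Hilbert envelopes
#' @param s channels x samples matrix of symlet streams
#' @return matrix of the same shape
#' @export
fuse2 <- function(w, h, s) {
  stopifnot(is.matrix(h), identical(dim(h), dim(s)), length(w) == nrow(h))
  (h + s) * w
}

#' Run the full fused-feature generation on a channel matrix
#'
#' The complete per-stream recipe: per channel, Hjorth activity and
#' mobility; multilevel Daubechies decomposition; zeroing of the extreme
#' fraction of detail coefficients; channel weight from the surviving
#' coefficients at the weighting level; then the two fused series
#' \code{fnew} (weighted input) and \code{fnew1} (weighted symlet +
#' envelope streams). Constant (zero-activity) channels yield zero fused
#' rows with a warning instead of aborting the run.
#'
#' @param X channels x samples matrix (continuous, artifact-cleaned)
#' @param fs sampling rate, Hz
#' @param wavelet decomposition wavelet; default \code{"db4"}
#' @param levels decomposition depth; default 5
#' @param trim_frac fraction of detail coefficients zeroed; default 0.25
#' @param trim_tail which magnitude tail is zeroed; default
#'   \code{"largest"}
#' @param weight_level detail level supplying channel weights; default 4
#' @param symlet symlet family member for the smoothing stream
#' @param hilbert_output \code{"envelope"} (default) or \code{"phase"}
#' @param sqrt_mobility see [hjorthMobility()]
#' @return list with \code{fnew}, \code{fnew1} (matrices shaped like
#'   \code{X}), \code{weights}, \code{activity}, \code{mobility},
#'   \code{trim} (removal records per channel)
#' @export
fusedStreams <- function(X, fs, wavelet = "db4", levels = 5L,
                         trim_frac = 0.25, trim_tail = "largest",
                         weight_level = 4L, symlet = "sym4",
                         hilbert_output = c("envelope", "phase"),
                         sqrt_mobility = FALSE) {
  hilbert_output <- match.arg(hilbert_output)
  stopifnot(is.matrix(X))
  n_ch <- nrow(X)
  alpha <- numeric(n_ch); beta <- numeric(n_ch); w <- numeric(n_ch)
  trims <- vector("list", n_ch)
  H <- matrix(0, n_ch, ncol(X)); S <- matrix(0, n_ch, ncol(X))
  for (i in seq_len(n_ch)) {
    xi <- X[i, ]
    alpha[i] <- hjorthActivity(xi)
    beta[i] <- if (alpha[i] > 0)
      hjorthMobility(xi, fs, sqrt_mobility) else NA_real_
    dec <- trimCoefficients(dwtDecompose(xi, wavelet, levels),
                            frac = trim_frac, tail = trim_tail)
    trims[[i]] <- dec$removed
    cw <- channelWeight(dec, min(weight_level, dec$level))
    w[i] <- cw$w
    S[i, ] <- symletStream(xi, symlet)
    H[i, ] <- if (hilbert_output == "envelope") hilbertStream(xi) else {
      an <- stats::fft(stats::fft(xi) * hilbertMask(length(xi)),
                       inverse = TRUE) / length(xi)
      Arg(an)
    }
  }
  list(fnew = fuse1(X, w, alpha, beta),
       fnew1 = fuse2(w, H, S),
       weights = w, activity = alpha, mobility = beta, trim = trims)
}

# frequency-domain mask of the analytic-signal construction
hilbertMask <- function(n) {
  h <- numeric(n)
  if (n %% 2L == 0L) { h[c(1L, n / 2L + 1L)] <- 1; h[2:(n / 2L)] <- 2 }
  else { h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2 }
  h
}

#' Per-epoch summaries of the fused series
#'
#' Epochs both fused matrices on the event schedule and summarizes every
#' epoch, channel and fused stream by mean, variance (1/N) and energy
#' (mean square), concatenated into one named feature row per epoch. With
#' 14 channels this yields 14 x 2 x 3 = 84 features. Names are stable
#' across runs.
#'
#' @param fnew,fnew1 channels x samples fused matrices
#' @param fs sampling rate, Hz
#' @param events event schedule (see [eventSchedule()])
#' @param window_s,offset_s epoch window, as in [epochSeries()]
#' @param stream stream tag recorded in the table
#' @return data.frame: \code{epoch}, \code{label}, \code{stream},
#'   \code{feature_set} ("fused"), then one column per feature
#' @export
featurizeFused <- function(fnew, fnew1, fs, events, window_s = 10,
                           offset_s = 0, stream = "HbO") {
  ep1 <- epochSeries(fnew, fs, events, window_s, offset_s)
  ep2 <- epochSeries(fnew1, fs, events, window_s, offset_s)
  stopifnot(length(ep1) >= 1L)
  n_ch <- nrow(fnew)
  fnames <- as.vector(t(outer(
    as.vector(t(outer(sprintf("ch%02d", seq_len(n_ch)),
                      c("fnew", "fnew1"), paste, sep = "_"))),
    c("mean", "variance", "energy"), paste, sep = "_")))
  summarize <- function(v)
    c(mean(v), mean((v - mean(v))^2), mean(v^2))
  rows <- matrix(NA_real_, length(ep1), length(fnames),
                 dimnames = list(NULL, fnames))
  for (e in seq_along(ep1)) {
    vals <- lapply(seq_len(n_ch), function(i)
      c(summarize(ep1[[e]]$data[i, ]), summarize(ep2[[e]]$data[i, ])))
    rows[e, ] <- unlist(vals)
  }
  cbind(data.frame(epoch = seq_along(ep1),
                   label = vapply(ep1, `[[`, 0L, "label"),
                   stream = stream, feature_set = "fused",
                   stringsAsFactors = FALSE),
        as.data.frame(rows))
}
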