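#' @include ica.R
NULL

# Orthonormal filter banks (decomposition/reconstruction, low/high) for the
# wavelet families used by the fused-feature stage. Taps frozen at double
# precision from the standard Daubechies/symlet constructions.
.wfilters <- list(
  db4 = list(
    dec_lo = c(-0.01059740178506903, 0.0328830116668852, 0.03084138183556076,
               -0.18703481171909309, -0.02798376941685986, 0.6308807679298589,
               0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
               -0.02798376941685986, 0.18703481171909309, 0.03084138183556076,
               -0.0328830116668852, -0.01059740178506903),
    rec_lo = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
               -0.02798376941685986, -0.18703481171909309, 0.03084138183556076,
               0.0328830116668852, -0.01059740178506903),
    rec_hi = c(-0.01059740178506903, -0.0328830116668852, 0.03084138183556076,
               0.18703481171909309, -0.02798376941685986, -0.6308807679298589,
               0.7148465705529157, -0.2303778133088965)
  ),
  sym4 = list(
    dec_lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
               0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
               -0.01260396726203783, 0.0322231006040427),
    dec_hi = c(-0.0322231006040427, -0.01260396726203783, 0.09921954357684722,
               0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
               0.02963552764599851, -0.07576571478927333),
    rec_lo = c(0.0322231006040427, -0.01260396726203783, -0.09921954357684722,
               0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
               -0.02963552764599851, -0.07576571478927333),
    rec_hi = c(-0.07576571478927333, 0.02963552764599851, 0.49761866763201545,
               -0.8037387518059161, 0.29785779560527736, 0.09921954357684722,
               -0.01260396726203783, -0.0322231006040427)
  )
)

waveletFilters <- function(wavelet) {
  f <- .wfilters[[wavelet]]
  if (is.null(f)) stop("unknown wavelet '", wavelet, "'; available: ",
                       paste(names(.wfilters), collapse = ", "))
  f
}

# One decimated analysis step with periodization boundary handling
# (signal of odd length is extended by repeating its last sample).
# Convention (0-based): y[k] = sum_m f[m] * x[(2k + L/2 - m) mod n]; this
# phase matches the standard periodized filter-bank layout, verified
# against an independent reference implementation in the tests.
dwtStep <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L) { x <- c(x, x[n]); n <- n + 1L }
  L <- length(lo)
  half <- n %/% 2L
  delta <- L %/% 2L
  a <- numeric(half); d <- numeric(half)
  for (m in 0:(L - 1L)) {
    idx <- ((2L * seq_len(half) - 2L + delta - m) %% n) + 1L
    a <- a + lo[m + 1L] * x[idx]
    d <- d + hi[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# Inverse of dwtStep: upsample, convolve with synthesis filters, sum.
# Synthesis phase 1 - L/2 is the exact adjoint of the analysis phase.
idwtStep <- function(a, d, rec_lo, rec_hi) {
  half <- length(a)
  n <- 2L * half
  L <- length(rec_lo)
  delta <- 1L - L %/% 2L
  x <- numeric(n)
  for (m in 0:(L - 1L)) {
    idx <- ((2L * seq_len(half) - 2L + delta + m) %% n) + 1L
    x[idx] <- x[idx] + rec_lo[m + 1L] * a + rec_hi[m + 1L] * d
  }
  x
}

#' Multilevel decimated discrete wavelet decomposition
#'
#' Mallat cascade with periodization boundary handling; the inverse
#' transform ([dwtReconstruct()]) reproduces the input to numerical
#' precision. If the signal is too short for the requested depth
#' (\code{length(x) < filter length * 2^level}), the depth is reduced with
#' a warning.
#'
#' @param x numeric sample vector
#' @param wavelet \code{"db4"} (default) or \code{"sym4"}
#' @param level decomposition depth M (>= 1); default 5
#' @return object of class \code{"WaveletDecomp"}: list with \code{approx}
#'   (level-M approximation coefficients), \code{details} (list, element j
#'   = level-j detail coefficients, j = 1 finest), \code{wavelet},
#'   \code{level}, \code{n}
#' @export
dwtDecompose <- function(x, wavelet = "db4", level = 5L) {
  f <- waveletFilters(wavelet)
  if (level < 1L) stop("level must be >= 1")
  L <- length(f$dec_lo)
  M <- as.integer(level)
  while (M > 1L && length(x) < L * 2^M) M <- M - 1L
  if (M < level)
    warning("signal of length ", length(x), " too short for level ", level,
            "; using level ", M)
  details <- vector("list", M)
  lens <- integer(M)
  a <- x
  for (j in seq_len(M)) {
    lens[j] <- length(a)  # pre-step length, needed to undo odd-length padding
    st <- dwtStep(a, f$dec_lo, f$dec_hi)
    details[[j]] <- st$d
    a <- st$a
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 level = M, n = length(x), lens = lens),
            class = "WaveletDecomp")
}

#' Inverse multilevel wavelet transform
#'
#' @param d a \code{"WaveletDecomp"} (possibly trimmed)
#' @return reconstructed sample vector of the original length
#' @export
dwtReconstruct <- function(d) {
  f <- waveletFilters(d$wavelet)
  a <- d$approx
  for (j in rev(seq_len(d$level))) {
    a <- idwtStep(a, d$details[[j]], f$rec_lo, f$rec_hi)
    a <- a[seq_len(d$lens[j])]
  }
  a
}

#' Zero the extreme fraction of wavelet detail coefficients
#'
#' Within each detail-coefficient array, the \code{floor(frac * length)}
#' coefficients with the largest magnitude are zeroed (default tail
#' \code{"largest"}: extreme-amplitude content is treated as artifact).
#' Tails \code{"smallest"} and \code{"both"} (the count split evenly,
#' larger half from the large-magnitude end) are supported. Ties are
#' broken by removing the earlier index first. Approximation coefficients
#' are never trimmed.
#'
#' @param d a \code{"WaveletDecomp"}
#' @param frac fraction removed per array, in [0, 1); default 0.25
#' @param tail \code{"largest"}, \code{"smallest"} or \code{"both"}
#' @return a \code{"TrimmedDecomp"} (a \code{"WaveletDecomp"} plus a
#'   \code{removed} record: per level, the zeroed indices, fraction, tail)
#' @export
trimCoefficients <- function(d, frac = 0.25,
                             tail = c("largest", "smallest", "both")) {
  tail <- match.arg(tail)
  stopifnot(frac >= 0, frac < 1)
  removed <- vector("list", d$level)
  for (j in seq_len(d$level)) {
    v <- d$details[[j]]
    k <- floor(frac * length(v))
    idx <- integer(0)
    if (k > 0) {
      by_big <- order(-abs(v), seq_along(v))
      by_small <- order(abs(v), seq_along(v))
      idx <- switch(tail,
        largest = by_big[seq_len(k)],
        smallest = by_small[seq_len(k)],
        both = {
          k_hi <- ceiling(k / 2); k_lo <- k - k_hi
          hi <- by_big[seq_len(k_hi)]
          lo <- setdiff(by_small, hi)[seq_len(k_lo)]
          c(hi, lo)
        })
      v[idx] <- 0
      d$details[[j]] <- v
    }
    removed[[j]] <- list(level = j, indices = sort(idx), frac = frac,
                         tail = tail)
  }
  d$removed <- removed
  class(d) <- c("TrimmedDecomp", "WaveletDecomp")
  d
}

#' Channel weight from surviving wavelet coefficients
#'
#' The mean absolute value of the non-zeroed detail coefficients at the
#' chosen level (default 4, where task-related hemodynamic energy
#' concentrates at 12.5 Hz). A signed mean would vanish by construction;
#' the absolute mean keeps high-activity channels heavily weighted. If
#' every coefficient at that level was zeroed, the weight is 0.
#'
#' @param d a \code{"TrimmedDecomp"} (or untrimmed \code{"WaveletDecomp"})
#' @param level detail level used for weighting (<= decomposition depth)
#' @return list with \code{w} (nonnegative scalar weight) and \code{K}
#'   (number of coefficients averaged)
#' @export
channelWeight <- function(d, level = 4L) {
  if (level > d$level)
    stop("weight level ", level, " exceeds decomposition depth ", d$level)
  v <- d$details[[level]]
  zeroed <- if (!is.null(d$removed)) d$removed[[level]]$indices else integer(0)
  keep <- setdiff(seq_along(v), zeroed)
  if (!length(keep)) return(list(w = 0, K = 0L))
  list(w = mean(abs(v[keep])), K = length(keep))
}
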