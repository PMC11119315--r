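#' @include beer_lambert.R
NULL

#' Center and whiten multichannel data
#'
#' Removes per-channel means and applies a PCA whitener so the output has
#' identity sample covariance — the standard preconditioning for
#' fixed-point ICA.
#'
#' @param X numeric matrix, channels x samples (at least 2 channels, more
#'   samples than channels)
#' @param n_components number of whitened dimensions kept (default: all)
#' @return list with \code{Z} (whitened data), \code{whitener}
#'   (dims x channels), \code{means}, \code{dewhitener} (channels x dims)
#' @export
centerWhiten <- function(X, n_components = nrow(X)) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2L) stop("need at least 2 channels")
  if (ncol(X) <= nrow(X)) stop("need more samples than channels")
  stopifnot(n_components >= 1L, n_components <= nrow(X))
  means <- rowMeans(X)
  Xc <- X - means
  C <- tcrossprod(Xc) / (ncol(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[n_components] < max(eg$values) * 1e-10)
    stop("rank-deficient channel covariance; remove duplicated channels ",
         "or reduce n_components")
  vals <- eg$values[seq_len(n_components)]
  vecs <- eg$vectors[, seq_len(n_components), drop = FALSE]
  whitener <- diag(1 / sqrt(vals), n_components) %*% t(vecs)
  dewhitener <- vecs %*% diag(sqrt(vals), n_components)
  list(Z = whitener %*% Xc, whitener = whitener, means = means,
       dewhitener = dewhitener)
}

#' Fit FastICA by symmetric fixed-point iteration
#'
#' Estimates an unmixing matrix maximizing non-Gaussianity of the
#' components (logcosh contrast by default), with symmetric decorrelation
#' after every update. Deterministic for a fixed seed. The fitted model
#' satisfies \code{W \%*\% whitener \%*\% A = I} on the component subspace.
#'
#' @param X numeric matrix, channels x samples
#' @param n_components number of components (default: channel count)
#' @param seed RNG seed for the random orthogonal initialization
#' @param tol convergence tolerance on the fixed-point update
#' @param max_iter maximum iterations before an error is raised
#' @param nonlinearity contrast derivative: \code{"logcosh"} (tanh) or
#'   \code{"cube"}
#' @param on_nonconvergence \code{"error"} (default: abort, reporting the
#'   last fixed-point delta) or \code{"warn"} (return the last iterate
#'   with \code{converged = FALSE}; useful when some components are
#'   near-Gaussian noise, where the fixed point cannot settle but the
#'   non-Gaussian components are already separated)
#' @return an \linkS4class{IcaModel}
#' @export
fasticaFit <- function(X, n_components = nrow(X), seed = 1L, tol = 1e-6,
                       max_iter = 1000L, nonlinearity = c("logcosh", "cube"),
                       on_nonconvergence = c("error", "warn")) {
  nonlinearity <- match.arg(nonlinearity)
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (n_components > nrow(X))
    stop("n_components exceeds the channel count")
  cw <- centerWhiten(X, n_components)
  Z <- cw$Z
  n <- ncol(Z)
  p <- n_components

  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, .Machine$double.eps)), p) %*%
      t(s$vectors) %*% W
  }

  W <- withSeed(seed, matrix(rnorm(p * p), p, p))
  W <- sym_decorrelate(W)
  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    WZ <- W %*% Z
    if (nonlinearity == "logcosh") {
      G <- tanh(WZ)
      gprime_mean <- rowMeans(1 - G^2)
    } else {
      G <- WZ^3
      gprime_mean <- rowMeans(3 * WZ^2)
    }
    W1 <- (G %*% t(Z)) / n - gprime_mean * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  converged <- delta < tol
  if (!converged) {
    msg <- paste0("FastICA did not converge after ", max_iter,
                  " iterations (last delta = ", signif(delta, 3),
                  "); sources may be Gaussian or tol too tight")
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  A <- cw$dewhitener %*% t(W)  # W orthonormal in whitened space
  new("IcaModel", W = W, A = A, whitener = cw$whitener, means = cw$means,
      method = "fastica", seed = as.integer(seed), iterations = it,
      tol = tol, converged = converged)
}

#' Fit a blind-source-separation model
#'
#' Backend dispatcher behind a single model contract. \code{"fastica"} is
#' implemented natively; \code{"picard"} and \code{"infomax"} are interface
#' hooks for external implementations and raise an informative error when
#' no backend is registered.
#'
#' @inheritParams fasticaFit
#' @param method one of \code{"fastica"}, \code{"picard"}, \code{"infomax"}
#' @return an \linkS4class{IcaModel}
#' @export
icaFit <- function(X, method = c("fastica", "picard", "infomax"), ...) {
  method <- match.arg(method)
  if (method != "fastica")
    stop("no '", method, "' backend is registered in this installation; ",
         "use method = 'fastica' or plug in a backend returning an IcaModel")
  fasticaFit(X, ...)
}

#' Apply an unmixing model to channel data
#'
#' \code{s = W * whitener * (X - means)} using the model's stored means.
#'
#' @param model an \linkS4class{IcaModel}
#' @param X channels x samples matrix with the model's channel count
#' @return components x samples source activation matrix
#' @export
unmixSources <- function(model, X) {
  if (!is.matrix(X) || nrow(X) != ncol(model@whitener))
    stop("X must be a matrix with ", ncol(model@whitener), " channel rows")
  model@W %*% model@whitener %*% (X - model@means)
}

#' Flag artifact components by excess kurtosis
#'
#' Transient artifacts (spikes, abrupt shifts) concentrate in components
#' with heavy-tailed activations; components whose excess kurtosis exceeds
#' the threshold are flagged for removal. Oscillatory physiological
#' components (excess kurtosis of a sinusoid is -1.5) are never flagged.
#'
#' @param sources components x samples matrix
#' @param kurtosis_threshold flag components with excess kurtosis above
#'   this value (default 5)
#' @return logical rejection mask, one entry per component
#' @export
defaultRejection <- function(sources, kurtosis_threshold = 5) {
  stopifnot(is.matrix(sources), nrow(sources) >= 1L)
  unname(apply(sources, 1L, function(s) {
    v <- mean((s - mean(s))^2)
    if (v == 0) return(FALSE)
    (mean((s - mean(s))^4) / v^2 - 3) > kurtosis_threshold
  }))
}

#' Flag narrowband physiological-oscillation components
#'
#' Cardiac, respiratory and Mayer-wave activity concentrates its spectral
#' power in a narrow band around a peak well above the hemodynamic band;
#' a component is flagged when the share of Welch-PSD power within
#' \code{bandwidth} Hz of its spectral peak exceeds \code{peak_share} and
#' the peak lies at or above \code{protect_below} (task-evoked responses
#' live below ~0.08 Hz and are never flagged).
#'
#' @param sources components x samples matrix
#' @param fs sampling rate, Hz
#' @param protect_below components peaking below this frequency (Hz) are
#'   never flagged
#' @param peak_share minimum share of total power near the peak
#' @param bandwidth half-width (Hz) of the band counted around the peak
#' @param segment Welch segment length
#' @return logical rejection mask
#' @export
oscillationRejection <- function(sources, fs, protect_below = 0.08,
                                 peak_share = 0.5, bandwidth = 0.05,
                                 segment = min(ncol(sources), 1024L)) {
  stopifnot(is.matrix(sources), nrow(sources) >= 1L)
  unname(apply(sources, 1L, function(v) {
    if (stats::var(v) == 0) return(FALSE)
    p <- psdWelch(v, fs, segment = segment)
    k <- which.max(p$power)
    if (p$freq[k] < protect_below) return(FALSE)
    share <- sum(p$power[abs(p$freq - p$freq[k]) <= bandwidth]) /
      sum(p$power)
    share > peak_share
  }))
}

#' Remove flagged components and reconstruct channel data
#'
#' Unmixes \code{X}, zeroes the masked component rows, back-projects
#' through the mixing matrix and restores channel means. With an all-FALSE
#' mask this is the identity up to numerical tolerance.
#'
#' @param model an \linkS4class{IcaModel}
#' @param X channels x samples matrix
#' @param mask logical vector, one entry per component; TRUE = remove
#' @return cleaned channels x samples matrix
#' @export
rejectAndReconstruct <- function(model, X, mask) {
  if (length(mask) != nrow(model@W))
    stop("mask length must equal the component count (", nrow(model@W), ")")
  s <- unmixSources(model, X)
  s[mask, ] <- 0
  model@A %*% s + model@means
}

#' One-call ICA cleaning of a channel matrix
#'
#' Fits the requested model on the continuous data, flags artifact
#' components and reconstructs. Two pluggable criteria are combined by
#' default: excess-kurtosis ([defaultRejection()], transient
#' spikes/shifts) and narrowband spectral concentration
#' ([oscillationRejection()], cardiac/respiratory/Mayer oscillations).
#' Each step is also available separately.
#'
#' @inheritParams icaFit
#' @param kurtosis_threshold see [defaultRejection()]
#' @param rejection which criteria to apply: subset of
#'   \code{c("kurtosis", "oscillation")}
#' @param fs sampling rate (Hz), needed by the oscillation criterion
#' @param ... passed to the backend fit
#' @return list with \code{clean} (matrix), \code{model}, \code{mask}
#' @export
icaClean <- function(X, method = "fastica", kurtosis_threshold = 5,
                     rejection = c("kurtosis", "oscillation"), fs = 12.5,
                     ...) {
  rejection <- match.arg(rejection, several.ok = TRUE)
  model <- icaFit(X, method = method, ...)
  src <- unmixSources(model, X)
  mask <- rep(FALSE, nrow(src))
  if ("kurtosis" %in% rejection)
    mask <- mask | defaultRejection(src, kurtosis_threshold)
  if ("oscillation" %in% rejection)
    mask <- mask | oscillationRejection(src, fs)
  list(clean = rejectAndReconstruct(model, X, mask), model = model,
       mask = mask)
}
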