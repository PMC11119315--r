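#' @include rank_tests.R
NULL

#' Configuration for the synthetic fNIRS session generator
#'
#' Defaults emulate the study conditions the pipeline targets: 14 retained
#' channels of a 3x6 left-sensorimotor montage sampled at 12.5 Hz, 20
#' trials per class (no activity / mental drawing / spatial navigation) of
#' 10 s with 10 s inter-trial intervals, event-locked double-gamma
#' hemodynamic responses of 1 uM peak dHbO in class-specific channel
#' subsets with dHbR = -0.3 x dHbO, sinusoidal physiological noise
#' (cardiac 1.1 Hz, respiratory 0.25 Hz, Mayer waves 0.1 Hz), white noise,
#' and spike/baseline-shift motion artifacts.
#'
#' @param n_trials integer length-3: trials per class (labels 1, 2, 3)
#' @param fs sampling rate, Hz
#' @param trial_s,iti_s trial duration and inter-trial interval, seconds
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio double-gamma response
#'   shape: peak time, undershoot time, undershoot amplitude ratio
#' @param active_channels list with elements \code{"2"} and \code{"3"}:
#'   channel indices (canonical order) carrying each task's activity
#' @param amplitude_uM peak dHbO response amplitude, micromolar
#' @param hbr_ratio dHbR = hbr_ratio x dHbO (anticorrelated, attenuated)
#' @param noise_cardiac,noise_resp,noise_mayer sinusoid amplitudes, uM
#' @param cardiac_hz,resp_hz,mayer_hz sinusoid frequencies, Hz
#' @param noise_white white-noise standard deviation, uM
#' @param hbr_noise_scale noise amplitude multiplier for the HbR stream
#' @param spike_per_min expected motion spikes per minute (Poisson)
#' @param spike_amp_uM spike amplitude, uM
#' @param shift_prob per-channel probability of one baseline shift
#' @param shift_amp_uM baseline-shift step size, uM
#' @param seed generator seed; all randomness flows from it
#' @return list of class \code{"SynthConfig"}
#' @export
synthConfig <- function(n_trials = c(20L, 20L, 20L), fs = 12.5,
                        trial_s = 10, iti_s = 10,
                        hrf_peak_s = 6, hrf_undershoot_s = 16,
                        hrf_ratio = 1 / 6,
                        active_channels = list(`2` = c(3L, 4L, 5L),
                                               `3` = c(9L, 10L, 11L)),
                        amplitude_uM = 1.0, hbr_ratio = -0.3,
                        noise_cardiac = 0.25, cardiac_hz = 1.1,
                        noise_resp = 0.15, resp_hz = 0.25,
                        noise_mayer = 0.25, mayer_hz = 0.1,
                        noise_white = 0.15, hbr_noise_scale = 0.5,
                        spike_per_min = 1, spike_amp_uM = 4,
                        shift_prob = 0.05, shift_amp_uM = 1,
                        seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials), fs = fs, trial_s = trial_s,
              iti_s = iti_s, hrf_peak_s = hrf_peak_s,
              hrf_undershoot_s = hrf_undershoot_s, hrf_ratio = hrf_ratio,
              active_channels = active_channels,
              amplitude_uM = amplitude_uM, hbr_ratio = hbr_ratio,
              noise_cardiac = noise_cardiac, cardiac_hz = cardiac_hz,
              noise_resp = noise_resp, resp_hz = resp_hz,
              noise_mayer = noise_mayer, mayer_hz = mayer_hz,
              noise_white = noise_white, hbr_noise_scale = hbr_noise_scale,
              spike_per_min = spike_per_min, spike_amp_uM = spike_amp_uM,
              shift_prob = shift_prob, shift_amp_uM = shift_amp_uM,
              seed = as.integer(seed))
  stopifnot(length(cfg$n_trials) == 3L, all(cfg$n_trials >= 0L),
            cfg$fs > 0, cfg$trial_s > 0, cfg$iti_s >= 0,
            cfg$amplitude_uM >= 0,
            cfg$noise_cardiac >= 0, cfg$noise_resp >= 0,
            cfg$noise_mayer >= 0, cfg$noise_white >= 0,
            cfg$spike_per_min >= 0, cfg$shift_prob >= 0,
            cfg$shift_prob <= 1)
  class(cfg) <- "SynthConfig"
  cfg
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities — a positive lobe peaking at
#' \code{peak_s} and an undershoot peaking at \code{undershoot_s} scaled by
#' \code{ratio} — normalized to unit peak amplitude. Zero at t = 0 and
#' decaying to zero for large t.
#'
#' @param t time in seconds (>= 0)
#' @param peak_s,undershoot_s,ratio shape parameters
#' @return response amplitude at \code{t}
#' @export
hrfDoubleGamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  raw <- function(tt)
    stats::dgamma(tt, shape = peak_s + 1, rate = 1) -
      ratio * stats::dgamma(tt, shape = undershoot_s + 1, rate = 1)
  peak_val <- max(raw(seq(0, peak_s + undershoot_s + 16, by = 0.01)))
  raw(t) / peak_val
}

#' Generate a synthetic two-wavelength fNIRS session
#'
#' Builds a shuffled event schedule, convolves per-class boxcars with the
#' hemodynamic kernel into the active channels (scaled so the single-trial
#' peak equals \code{amplitude_uM}), adds physiological sinusoids with
#' random per-channel phases plus white noise, injects spike and
#' baseline-shift artifacts, and pushes the resulting concentration series
#' through the forward Beer-Lambert model (baseline intensity 1.0) to emit
#' raw intensities. Bit-for-bit reproducible from (config, seed).
#'
#' @param config a [synthConfig()]
#' @return list of class \code{"SynthSession"}: \code{scan}
#'   (\linkS4class{RawScan}), \code{events}, \code{montage}, and
#'   \code{truth} (true dHbO/dHbR matrices, artifact log, config)
#' @export
simulateSession <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  montage <- standardMontage()
  channels <- filterByDistance(enumerateChannels(montage), 60)
  n_ch <- nChannels(channels)
  fs <- config$fs

  n_total <- sum(config$n_trials)
  period <- config$trial_s + config$iti_s
  total_s <- config$iti_s + n_total * period + 20  # tail for HRF decay
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs

  out <- withSeed(config$seed, {
    labels <- sample(rep(1:3, times = config$n_trials))
    onsets <- config$iti_s + (seq_len(n_total) - 1) * period
    events <- eventSchedule(onsets, rep(config$trial_s, n_total), labels)

    # single-trial response template, unit peak after convolution scaling
    kern <- hrfDoubleGamma(seq(0, 32, by = 1 / fs), config$hrf_peak_s,
                           config$hrf_undershoot_s, config$hrf_ratio)
    box1 <- rep(0, round(config$trial_s * fs) + length(kern))
    box1[seq_len(round(config$trial_s * fs))] <- 1
    conv1 <- stats::convolve(box1, rev(kern), type = "open")[seq_along(box1)]
    scale <- config$amplitude_uM / max(conv1)

    hbo_true <- matrix(0, n_ch, n)
    for (cls in c(2L, 3L)) {
      box <- numeric(n)
      for (i in which(labels == cls)) {
        s0 <- round(onsets[i] * fs) + 1L
        s1 <- min(n, s0 + round(config$trial_s * fs) - 1L)
        box[s0:s1] <- 1
      }
      resp <- stats::convolve(box, rev(kern), type = "open")[seq_len(n)] *
        scale
      for (ch in config$active_channels[[as.character(cls)]])
        hbo_true[ch, ] <- hbo_true[ch, ] + resp
    }
    hbr_true <- config$hbr_ratio * hbo_true

    addNoise <- function(mat, scale_amp) {
      sines <- rbind(c(config$noise_cardiac, config$cardiac_hz),
                     c(config$noise_resp, config$resp_hz),
                     c(config$noise_mayer, config$mayer_hz))
      for (ch in seq_len(n_ch)) {
        for (k in seq_len(nrow(sines)))
          mat[ch, ] <- mat[ch, ] + scale_amp * sines[k, 1] *
            sin(2 * pi * sines[k, 2] * t + stats::runif(1, 0, 2 * pi))
        mat[ch, ] <- mat[ch, ] +
          stats::rnorm(n, sd = scale_amp * config$noise_white)
      }
      mat
    }
    hbo <- addNoise(hbo_true, 1)
    hbr <- addNoise(hbr_true, config$hbr_noise_scale)

    artifacts <- data.frame(time_s = numeric(0), channel = integer(0),
                            kind = character(0))
    n_spikes <- stats::rpois(1, config$spike_per_min * total_s / 60)
    for (k in seq_len(n_spikes)) {
      ch <- sample.int(n_ch, 1)
      at <- sample.int(n, 1)
      amp <- config$spike_amp_uM * sample(c(-1, 1), 1)
      idx <- at:min(n, at + 2L)
      decay <- amp * c(1, 0.5, 0.25)[seq_along(idx)]
      hbo[ch, idx] <- hbo[ch, idx] + decay
      hbr[ch, idx] <- hbr[ch, idx] + decay * config$hbr_noise_scale
      artifacts <- rbind(artifacts, data.frame(
        time_s = (at - 1) / fs, channel = ch, kind = "spike"))
    }
    for (ch in seq_len(n_ch)) {
      if (stats::runif(1) < config$shift_prob) {
        at <- sample.int(n, 1)
        step <- config$shift_amp_uM * sample(c(-1, 1), 1)
        hbo[ch, at:n] <- hbo[ch, at:n] + step
        hbr[ch, at:n] <- hbr[ch, at:n] + step * config$hbr_noise_scale
        artifacts <- rbind(artifacts, data.frame(
          time_s = (at - 1) / fs, channel = ch, kind = "baseline_shift"))
      }
    }
    list(events = events, hbo = hbo, hbr = hbr,
         hbo_true = hbo_true, hbr_true = hbr_true, artifacts = artifacts)
  })

  od <- hbToOd(out$hbo, out$hbr, channels, fs = fs)
  intensities <- 10^(-od@od)  # I0 = 1
  scan <- new("RawScan", values = intensities, wavelength = od@wavelength,
              channel = od@channel, fs = fs, channels = channels)
  structure(list(scan = scan, events = out$events, montage = montage,
                 channels = channels,
                 truth = list(hbo = out$hbo_true, hbr = out$hbr_true,
                              hbo_noisy = out$hbo, hbr_noisy = out$hbr,
                              artifacts = out$artifacts,
                              active_channels = config$active_channels,
                              config = config, seed = config$seed)),
            class = "SynthSession")
}

#' @export
print.SynthSession <- function(x, ...) {
  cat("SynthSession:", nChannels(x$channels), "channels,",
      nrow(x$events), "events,", ncol(x$truth$hbo), "samples @",
      samplingRate(x$scan), "Hz;", nrow(x$truth$artifacts),
      "artifacts injected\n")
  invisible(x)
}

#' Write a synthetic session as a delimited fixture directory
#'
#' Emits \code{raw.csv} (intensity table with a \code{# fs_hz} header
#' comment), \code{montage.csv} and \code{events.csv} in the formats read
#' back by [loadRaw()]; the round trip reproduces the written values.
#'
#' @param session a \code{"SynthSession"}
#' @param directory output directory (created if needed)
#' @return named character vector of the written file paths
#' @export
writeFixture <- function(session, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  c(raw = writeRawFile(session$scan, file.path(directory, "raw.csv")),
    montage = writeMontageFile(session$montage,
                               file.path(directory, "montage.csv")),
    events = writeEventsFile(session$events,
                             file.path(directory, "events.csv")))
}
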