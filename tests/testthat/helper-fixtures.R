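# Shared fixture builders; everything is generated in code at test time.

# A small, quick synthetic session (6 trials) for plumbing tests.
tinySession <- function(seed = 5L, ...) {
  simulateSession(synthConfig(n_trials = c(2L, 2L, 2L), seed = seed, ...))
}

# Preprocess a session up to the HbSeries (no ICA).
sessionToHb <- function(session, baseline = c(0, 10)) {
  I0 <- baselineReference(session$scan, baseline)
  odToHb(intensityToOd(session$scan, I0), session$channels)
}

# A toy two-column montage for enumeration arithmetic.
toyMontage <- function(n_src, n_det, spacing = 30) {
  lab <- c(paste0("S", seq_len(n_src)), paste0("D", seq_len(n_det)))
  fnirsMontage(data.frame(
    label = lab,
    role = rep(c("source", "detector"), c(n_src, n_det)),
    x_mm = c(seq_len(n_src) * spacing, seq_len(n_det) * spacing),
    y_mm = rep(c(0, spacing), c(n_src, n_det)),
    z_mm = 0))
}

# Separable two-class feature table: class means +/- delta on one feature.
separableTable <- function(n_per = 20L, delta = 4, seed = 1L, sd = 1) {
  withSeed(seed, {
    lab <- rep(c(1L, 2L), each = n_per)
    f1 <- stats::rnorm(2L * n_per, mean = ifelse(lab == 2L, delta, -delta),
                       sd = sd)
    f2 <- stats::rnorm(2L * n_per)
    data.frame(epoch = seq_along(lab), label = lab, stream = "HbO",
               feature_set = "toy", f1 = f1, f2 = f2)
  })
}
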