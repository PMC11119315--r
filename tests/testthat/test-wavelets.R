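# Reference decomposition frozen from an independent wavelet implementation
# (periodized db4, level 3, 64 samples).
refSignal <- c(
  0.00123, 0.298746, -0.274138, -0.890592, -0.454671, -0.991647, 0.060144,
  1.340215, -0.492207, -0.620475, 0.489842, 0.356887, 0.105414, -0.930468,
  -0.029252, 0.695303, -1.344215, -0.457616, -1.901223, -1.289538,
  -1.841735, -0.235091, -1.267446, 0.271264, 0.156751, -0.186931, -2.51676,
  -0.538693, -0.048501, 0.113309, -1.530136, -0.477753, -0.978519,
  -0.808837, 1.060899, -0.807535, -0.032522, 0.88439, -0.5836, -0.111702,
  0.110464, 0.063782, -1.225056, 0.07614, 1.358823, -1.547145, 0.859383,
  0.119354, -0.64147, 2.000417, 0.76226, -1.199289, 0.074516, 0.57669,
  -0.188782, 0.68291, -0.066517, 0.667248, 1.438523, -0.675662, 0.203139,
  -0.463308, 0.127268, -1.187195)
refApprox3 <- c(
  0.729666615103, 0.434846569533, -0.973905769904, 0.082538012465,
  -2.339172855640, -2.165137997814, -0.589412108118, -0.087067381966)
refDetail3 <- c(
  0.851214804967, 0.366208672270, 1.594462525590, -0.867188636783,
  0.043296673194, 0.724444238884, 0.005632058068, -0.275553628726)
refDetail2 <- c(
  -1.142122049610, -1.060925179961, -0.748326085099, -0.141214546975,
  0.377147090135, 0.840724566936, 1.539727599384, -0.423354423222,
  0.330031756966, 0.377590542956, 0.304164183295, 0.656649314825,
  -0.178014718024, 0.105858287525, -0.331864732566, 0.830082528382)

test_that("db4 decomposition matches the independent reference", {
  d <- dwtDecompose(refSignal, "db4", 3)
  expect_equal(d$level, 3L)
  expect_lt(max(abs(d$approx - refApprox3)), 1e-10)
  expect_lt(max(abs(d$details[[3]] - refDetail3)), 1e-10)
  expect_lt(max(abs(d$details[[2]] - refDetail2)), 1e-10)
})

test_that("wavelet transform reconstructs perfectly", {
  for (wavelet in c("db4", "sym4")) {
    for (n in c(256L, 1000L, 1001L)) {
      x <- withSeed(n, rnorm(n))
      d <- suppressWarnings(dwtDecompose(x, wavelet, 5))
      expect_lt(max(abs(dwtReconstruct(d) - x)), 1e-10)
    }
  }
})

test_that("constant signals have vanishing detail coefficients", {
  d <- dwtDecompose(rep(3.7, 512), "db4", 5)
  expect_lt(max(abs(unlist(d$details))), 1e-10)
  # DC survives in the approximation (orthonormal lowpass gain sqrt(2)/lvl)
  expect_lt(max(abs(d$approx - 3.7 * 2^(5 / 2))), 1e-9)
})

test_that("impulse detail coefficients reproduce the highpass taps", {
  # an impulse convolved with the analysis highpass filter leaves the
  # filter taps (decimated) in the level-1 details
  n <- 64L
  x <- numeric(n); x[32] <- 1
  d <- dwtDecompose(x, "db4", 1)
  hi <- fnirsdecode:::.wfilters$db4$dec_hi
  got <- d$details[[1]][d$details[[1]] != 0]
  expect_setequal(round(got, 12),
                  round(hi[c(2, 4, 6, 8)], 12))  # even-phase taps
})

test_that("signals too short for the requested depth reduce with warning", {
  x <- rnorm(40)
  expect_warning(d <- dwtDecompose(x, "db4", 5), "too short")
  expect_lt(d$level, 5L)
  expect_lt(max(abs(dwtReconstruct(d) - x)), 1e-10)
  expect_error(dwtDecompose(x, "db4", 0), "level")
})

test_that("coefficient trimming zeroes floor(frac * length) per array", {
  x <- withSeed(2, rnorm(256))
  d <- dwtDecompose(x, "db4", 3)
  tr <- trimCoefficients(d, 0.25)
  for (j in 1:3) {
    expect_equal(sum(tr$details[[j]] == 0),
                 floor(0.25 * length(d$details[[j]])))
    expect_equal(tr$removed[[j]]$indices,
                 sort(order(-abs(d$details[[j]]))[
                   seq_len(floor(0.25 * length(d$details[[j]])))]))
  }
  # approximation is untouched
  expect_equal(tr$approx, d$approx)

  # frac 0 -> unchanged
  tr0 <- trimCoefficients(d, 0)
  expect_equal(tr0$details, d$details)

  # 8 coefficients, frac 0.25 -> exactly 2 zeroed
  d8 <- dwtDecompose(withSeed(3, rnorm(128)), "db4", 1)
  expect_equal(length(d8$details[[1]]), 64L)
  expect_equal(sum(trimCoefficients(d8, 0.25)$details[[1]] == 0), 16L)
})

test_that("trimming tails select the right coefficients", {
  d <- dwtDecompose(withSeed(4, rnorm(64)), "db4", 1)
  d$details[[1]] <- c(5, -1, 0.5, -0.2, rep(0.01, 28))

  big <- trimCoefficients(d, frac = 1 / 32)  # one coefficient
  expect_equal(big$details[[1]][1], 0)       # |5| is the largest
  expect_equal(big$details[[1]][-1], d$details[[1]][-1])

  small <- trimCoefficients(d, frac = 1 / 32, tail = "smallest")
  expect_equal(small$removed[[1]]$indices, 5L)  # first of the tied 0.01s

  both <- trimCoefficients(d, frac = 4 / 32, tail = "both")
  expect_equal(length(both$removed[[1]]$indices), 4L)
  expect_true(1L %in% both$removed[[1]]$indices)   # largest end
  expect_true(5L %in% both$removed[[1]]$indices)   # smallest end
})

test_that("channel weights average surviving absolute coefficients", {
  d <- dwtDecompose(withSeed(5, rnorm(512)), "db4", 5)

  # all-equal magnitudes -> weight equals the magnitude
  d2 <- d
  d2$details[[4]] <- c(2, -2, 2, -2, 2, -2, 2, -2)
  expect_equal(channelWeight(d2, 4)$w, 2)
  expect_equal(channelWeight(d2, 4)$K, 8L)

  # zero signal -> zero weight
  dz <- dwtDecompose(rep(0, 512), "db4", 5)
  expect_equal(channelWeight(trimCoefficients(dz, 0.25), 4)$w, 0)

  # homogeneity: scaling the signal scales the weight
  x <- withSeed(6, rnorm(512))
  w1 <- channelWeight(trimCoefficients(dwtDecompose(x, "db4", 5), 0.25), 4)$w
  w3 <- channelWeight(trimCoefficients(dwtDecompose(3 * x, "db4", 5), 0.25),
                      4)$w
  expect_equal(w3, 3 * w1, tolerance = 1e-12)

  # level beyond depth errors; all-zeroed level gives w = 0
  expect_error(channelWeight(d, 6), "depth")
  tr_all <- trimCoefficients(d, 0.96875)  # 31/32 leaves floor only
  dall <- d; dall$details[[4]] <- rep(0, 8)
  dall$removed <- lapply(1:5, function(j)
    list(level = j, indices = seq_along(dall$details[[j]]), frac = 1,
         tail = "largest"))
  expect_equal(channelWeight(dall, 4)$w, 0)
})
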