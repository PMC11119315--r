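# Match recovered components to true sources by absolute correlation.
matchedCorrelations <- function(S_true, S_hat) {
  C <- abs(stats::cor(t(S_true), t(S_hat)))
  best <- numeric(nrow(S_true))
  used <- integer(0)
  for (i in seq_len(nrow(S_true))) {
    j <- which.max(replace(C[i, ], used, -Inf))
    best[i] <- C[i, j]
    used <- c(used, j)
  }
  best
}

# Mixture of independent non-Gaussian (uniform) sources with a known A.
uniformMixture <- function(p = 3, n = 5000, seed = 21) {
  withSeed(seed, {
    S <- matrix(runif(p * n, -1, 1), p)
    A <- matrix(rnorm(p * p), p)
    list(S = S, A = A, X = A %*% S)
  })
}

test_that("center_whiten yields identity sample covariance", {
  X <- withSeed(1, matrix(rnorm(5 * 2000), 5) * c(1, 3, 0.2, 7, 1) + 2)
  cw <- centerWhiten(X)
  expect_lt(max(abs(rowMeans(cw$Z))), 1e-12)
  covZ <- tcrossprod(cw$Z) / (ncol(X) - 1)
  expect_lt(max(abs(covZ - diag(5))), 1e-8)

  # duplicated channel -> rank-deficient error
  Xdup <- rbind(X, X[1, ])
  expect_error(centerWhiten(Xdup), "rank-deficient")

  # already-white data: whitener is (close to) an orthonormal rotation
  Zw <- withSeed(2, matrix(rnorm(4 * 50000), 4))
  cw2 <- centerWhiten(Zw)
  WWt <- cw2$whitener %*% t(cw2$whitener)
  expect_lt(max(abs(WWt - diag(4))), 0.05)
})

test_that("FastICA recovers independent non-Gaussian sources", {
  mix <- uniformMixture()
  model <- fasticaFit(mix$X, seed = 7)
  expect_true(model@converged)
  S_hat <- unmixSources(model, mix$X)
  cors <- matchedCorrelations(mix$S, S_hat)
  expect_true(all(cors >= 0.99))

  # permutation-corrected gain matrix is close to a signed permutation
  G <- model@W %*% model@whitener %*% mix$A
  G <- abs(G / apply(abs(G), 1, max))
  off <- apply(G, 1, function(r) sum(r) - max(r))
  expect_true(all(off < 0.1))
})

test_that("FastICA is deterministic for a fixed seed", {
  mix <- uniformMixture(seed = 5)
  m1 <- fasticaFit(mix$X, seed = 3)
  m2 <- fasticaFit(mix$X, seed = 3)
  expect_identical(m1@W, m2@W)
  expect_identical(m1@iterations, m2@iterations)
})

test_that("single-source stream is recovered nearly perfectly", {
  n <- 4000
  src <- withSeed(8, runif(n, -1, 1))
  X <- rbind(2 * src + 0.3, -1 * src + 1)
  model <- fasticaFit(X, n_components = 1, seed = 2)
  s_hat <- unmixSources(model, X)
  expect_gte(abs(cor(drop(s_hat), src)), 0.999)
})

test_that("Gaussian sources trip the non-convergence error path", {
  X <- withSeed(13, matrix(rnorm(3 * 3000), 3))
  expect_error(fasticaFit(X, seed = 1, tol = 1e-12, max_iter = 3),
               "did not converge")
})

test_that("unmix/reconstruct form an inverse pair", {
  mix <- uniformMixture(p = 4, seed = 9)
  model <- fasticaFit(mix$X, seed = 4)

  # empty mask: identity within 1e-6 relative error
  clean <- rejectAndReconstruct(model, mix$X, rep(FALSE, 4))
  rel <- max(abs(clean - mix$X)) / max(abs(mix$X))
  expect_lt(rel, 1e-6)

  # reject all: channel means replicated
  all_gone <- rejectAndReconstruct(model, mix$X, rep(TRUE, 4))
  expect_equal(all_gone, matrix(rowMeans(mix$X), 4, ncol(mix$X)),
               tolerance = 1e-8)

  # mix(unmix) consistency on the retained subspace
  s <- unmixSources(model, mix$X)
  back <- model@A %*% s + model@means
  expect_equal(back, mix$X, tolerance = 1e-8)

  # shape guards
  expect_error(unmixSources(model, mix$X[1:2, ]), "channel")
  expect_error(rejectAndReconstruct(model, mix$X, c(TRUE, FALSE)),
               "mask length")

  # single-sample matrix does not crash
  expect_equal(dim(unmixSources(model, mix$X[, 1, drop = FALSE])),
               c(4L, 1L))
})

test_that("kurtosis rejection flags spikes but not sinusoids", {
  n <- 2500
  t <- seq_len(n) / 12.5
  sines <- rbind(sin(2 * pi * 0.5 * t), sin(2 * pi * 1.1 * t))
  expect_equal(defaultRejection(sines), c(FALSE, FALSE))

  spike <- numeric(n); spike[1234] <- 50
  S <- rbind(sines, spike)
  expect_equal(defaultRejection(S), c(FALSE, FALSE, TRUE))

  # threshold = Inf never flags
  expect_equal(sum(defaultRejection(S, Inf)), 0L)

  # constant component: kurtosis undefined, never flagged
  expect_equal(defaultRejection(rbind(spike, rep(1, n)))[2], FALSE)
})

test_that("rejecting a spike component removes spike energy, keeps signal", {
  n <- 6000
  t <- seq_len(n) / 12.5
  slow <- sin(2 * pi * 0.05 * t)           # event-locked-like slow signal
  osc <- withSeed(3, runif(n, -1, 1))
  spikes <- numeric(n)
  spike_at <- c(500, 2200, 4100)
  spikes[spike_at] <- c(40, -35, 45)
  S_true <- rbind(slow, osc, spikes)
  A <- withSeed(4, matrix(rnorm(9), 3))
  X <- A %*% S_true

  model <- fasticaFit(X, seed = 6)
  s_hat <- unmixSources(model, X)
  mask <- defaultRejection(s_hat, 5)
  expect_equal(sum(mask), 1L)
  clean <- rejectAndReconstruct(model, X, mask)

  # spike-band energy (at spike samples) drops by >= 90%
  spike_energy <- function(M) sum(M[, spike_at]^2)
  expect_lt(spike_energy(clean - A %*% rbind(slow, osc, 0 * spikes)),
            0.1 * spike_energy(A %*% rbind(0 * slow, 0 * osc, spikes)))

  # event-locked content survives: channel correlation with the
  # spike-free ground truth stays high
  X_clean_true <- A %*% rbind(slow, osc, 0 * spikes)
  cors <- vapply(1:3, function(i) cor(clean[i, ], X_clean_true[i, ]),
                 numeric(1))
  expect_true(all(cors >= 0.9))
})

test_that("narrowband rejection flags oscillations above the task band", {
  fs <- 12.5
  n <- 5000
  t <- seq_len(n) / fs
  noise <- withSeed(21, rnorm(n, sd = 0.1))
  cardiac <- sin(2 * pi * 1.1 * t) + noise
  mayer <- sin(2 * pi * 0.1 * t) + noise
  slow_task <- sin(2 * pi * 0.05 * t) + noise  # below the protected edge
  broadband <- withSeed(22, rnorm(n))
  S <- rbind(cardiac, mayer, slow_task, broadband)
  mask <- oscillationRejection(S, fs)
  expect_equal(mask, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("icaClean combines the pluggable rejection criteria", {
  n <- 5000
  t <- seq_len(n) / 12.5
  osc <- sin(2 * pi * 1.1 * t)
  spike <- numeric(n); spike[2500] <- 80
  base <- withSeed(23, matrix(runif(2 * n, -1, 1), 2))
  X <- rbind(base, osc, spike) + withSeed(24, matrix(rnorm(4 * n, sd = 0.05), 4))
  A <- withSeed(25, matrix(rnorm(16), 4))
  mixed <- A %*% X

  both <- icaClean(mixed, seed = 5, on_nonconvergence = "warn")
  expect_gte(sum(both$mask), 2L)  # spike and oscillation both flagged

  k_only <- icaClean(mixed, seed = 5, rejection = "kurtosis",
                     on_nonconvergence = "warn")
  expect_lt(sum(k_only$mask), sum(both$mask))
})

test_that("unavailable ICA backends raise an informative error", {
  X <- withSeed(1, matrix(runif(3 * 500), 3))
  expect_error(icaFit(X, method = "picard"), "backend")
  expect_error(icaFit(X, method = "infomax"), "backend")
})
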