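test_that("OTF is normalised, band-limited and matches the closed form", {
  cfg <- optical_config(image_size = 64)
  tf <- make_otf(cfg)
  n <- cfg$image_size
  ctr <- floor(n / 2) + 1
  expect_equal(tf$otf[ctr, ctr], 1.0)
  expect_equal(tf$cutoff_frequency,
               2 * cfg$numerical_aperture / cfg$emission_wavelength *
                 cfg$pixel_size)
  f <- (seq_len(n) - 1 - floor(n / 2)) / n
  kr <- sqrt(outer(f^2, f^2, "+"))
  expect_true(all(tf$otf[kr > tf$cutoff_frequency] == 0))
  expect_true(all(tf$otf >= 0 & tf$otf <= 1))
  # half-cutoff value of the pupil autocorrelation:
  # (2/pi)(acos(1/2) - (1/2) sqrt(3)/2)
  expect_equal(otf_radial(0.5),
               (2 / pi) * (acos(0.5) - 0.5 * sqrt(1 - 0.25)),
               tolerance = 1e-12)
  expect_equal(otf_radial(0.5), 0.39100221895577053, tolerance = 1e-10)
})

test_that("PSF is non-negative, unit-sum and dual to the OTF", {
  tf <- make_otf(optical_config(image_size = 64))
  expect_true(all(tf$psf >= 0))
  expect_equal(sum(tf$psf), 1, tolerance = 1e-12)
  # convolving a centred point source must reproduce the PSF
  n <- 64
  point <- matrix(0, n, n)
  point[floor(n / 2) + 1, floor(n / 2) + 1] <- 1
  ones <- matrix(1, n, n)
  frame <- apply_forward(point, ones, tf)
  expect_lt(max(abs(frame - tf$psf)), 1e-8)
})

test_that("invalid optical configurations are rejected, super-Nyquist cutoff warns", {
  expect_error(optical_config(numerical_aperture = 0))
  expect_error(optical_config(pixel_size = -1))
  expect_error(optical_config(image_size = 15 * 2 + 1))
  expect_error(optical_config(image_size = 8))
  # pixel size so large the optical cutoff exceeds the grid Nyquist
  expect_warning(make_otf(optical_config(pixel_size = 200, image_size = 32)),
                 "Nyquist")
})

test_that("illumination pattern follows the sinusoidal model", {
  # zero modulation: constant at the mean intensity
  p0 <- illumination_params(k0 = 0.3, theta = 1, phi = 2, m = 0, I0 = 1.7)
  expect_equal(illumination_pattern(p0, 16), matrix(1.7, 16, 16))
  # direct substitution at the origin: I0 (1 - m/2 cos(phi))
  p1 <- illumination_params(k0 = 0.3, theta = 0.4, phi = 0, m = 1, I0 = 1)
  expect_equal(illumination_pattern(p1, 8)[1, 1], 0.5)
  # range bounds
  img <- illumination_pattern(
    illumination_params(0.27, 0.9, 1.3, m = 0.8, I0 = 2), 32)
  expect_true(all(img >= 2 * (1 - 0.4) - 1e-12))
  expect_true(all(img <= 2 * (1 + 0.4) + 1e-12))
})

test_that("three canonical phases average to homogeneous illumination", {
  set.seed(101)
  for (rep in 1:10) {
    k0 <- runif(1, 0.05, 0.45)
    th <- runif(1, 0, pi)
    m <- runif(1, 0, 1)
    I0 <- runif(1, 0.5, 2)
    acc <- 0
    for (phi in c(0, 2 * pi / 3, 4 * pi / 3)) {
      acc <- acc + illumination_pattern(
        illumination_params(k0, th, phi, m, I0), 24)
    }
    expect_lt(max(abs(acc / 3 - I0)), 1e-9)
  }
})

test_that("frequency-space forward model matches brute-force circular convolution", {
  set.seed(7)
  n <- 8
  tf <- small_tf(n, kc = 0.45)
  S <- matrix(runif(n * n), n)
  I <- matrix(runif(n * n), n)
  D <- apply_forward(S, I, tf)
  # O(n^4) direct-space circular convolution oracle
  E <- S * I
  ctr <- floor(n / 2)
  Db <- matrix(0, n, n)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    acc <- 0
    for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
      acc <- acc + E[p + 1, q + 1] *
        tf$psf[((i - p + ctr) %% n) + 1, ((j - q + ctr) %% n) + 1]
    }
    Db[i + 1, j + 1] <- acc
  }
  expect_lt(max(abs(D - Db)), 1e-8)
})

test_that("identity OTF reduces the forward model to the fluorescent response", {
  set.seed(8)
  n <- 16
  tf <- transfer_functions(matrix(1, n, n))
  S <- matrix(runif(n * n), n)
  I <- matrix(runif(n * n), n)
  expect_equal(apply_forward(S, I, tf), S * I, tolerance = 1e-12)
})

test_that("noiseless forward model is linear and conserves energy", {
  set.seed(9)
  n <- 32
  tf <- small_tf(n)
  S1 <- matrix(runif(n * n), n); S2 <- matrix(runif(n * n), n)
  I <- illumination_pattern(illumination_params(0.3, 0.7, 0.2, 0.9), n)
  a <- 0.7; b <- -1.3
  lhs <- apply_forward(a * S1 + b * S2, I, tf)
  rhs <- a * apply_forward(S1, I, tf) + b * apply_forward(S2, I, tf)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  D <- apply_forward(S1, I, tf)
  expect_equal(sum(D), sum(S1 * I), tolerance = 1e-6)
})

test_that("raw-frame spectrum is confined to the OTF support shifted by the pattern frequency", {
  set.seed(10)
  n <- 64
  kc <- 0.25
  tf <- small_tf(n, kc = kc)
  S <- matrix(runif(n * n), n)
  k0 <- 0.2; th <- 0.5
  I <- illumination_pattern(illumination_params(k0, th, 0.3, 1), n)
  D <- apply_forward(S, I, tf)
  spec <- abs(simrecon:::fftshift2(stats::fft(D)))
  f <- (seq_len(n) - 1 - floor(n / 2)) / n
  kxg <- outer(rep(1, n), f); kyg <- outer(f, rep(1, n))
  # distance to nearest wrapped alias of each carrier frequency
  wrapdist <- function(cx, cy) {
    d <- matrix(Inf, n, n)
    for (wx in c(-1, 0, 1)) for (wy in c(-1, 0, 1)) {
      d <- pmin(d, sqrt((kxg - cx + wx)^2 + (kyg - cy + wy)^2))
    }
    d
  }
  supp <- wrapdist(0, 0) <= kc
  for (s in c(-1, 1)) {
    supp <- supp | (wrapdist(s * k0 * cos(th), s * k0 * sin(th)) <= kc)
  }
  # one bin of margin for the discrete cutoff boundary
  margin <- wrapdist(0, 0) <= kc + 1.5 / n
  for (s in c(-1, 1)) {
    margin <- margin |
      (wrapdist(s * k0 * cos(th), s * k0 * sin(th)) <= kc + 1.5 / n)
  }
  expect_lt(max(spec[!margin]) / max(spec), 1e-8)
})

test_that("Gaussian noise level scales with the blurred frame's standard deviation", {
  set.seed(11)
  n <- 256
  tf <- small_tf(n)
  S <- matrix(runif(n * n), n)
  I <- matrix(1, n, n)
  clean <- apply_forward(S, I, tf)
  noisy <- apply_forward(S, I, tf, noise_spec("gaussian", 2, seed = 99))
  expect_equal(sd(noisy - clean), 2 * sd(clean), tolerance = 0.05)
  # shape mismatch and bad level are rejected
  expect_error(apply_forward(S[1:128, ], I, tf), "shape")
  expect_error(noise_spec("gaussian", -1))
})
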