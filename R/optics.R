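#' Optical configuration of the simulated microscope
#'
#' Collects the optical parameters that determine the diffraction-limited
#' transfer functions of a widefield fluorescence microscope: objective
#' numerical aperture, fluorescence emission wavelength, sample-plane pixel
#' size and (square) image size.
#'
#' @param numerical_aperture Objective NA (dimensionless, > 0).
#' @param emission_wavelength Emission wavelength in nanometres.
#' @param pixel_size Sample-plane pixel size in nanometres per pixel.
#' @param image_size Image side length in pixels; must be even and >= 16.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$numerical_aperture
#' @export
optical_config <- function(numerical_aperture = 1.2,
                           emission_wavelength = 525,
                           pixel_size = 80,
                           image_size = 512) {
  stopifnot(
    numerical_aperture > 0,
    emission_wavelength > 0,
    pixel_size > 0,
    image_size >= 16,
    image_size %% 2 == 0
  )
  structure(
    list(
      numerical_aperture = numerical_aperture,
      emission_wavelength = emission_wavelength,
      pixel_size = pixel_size,
      image_size = as.integer(image_size)
    ),
    class = "optical_config"
  )
}

#' Parameters of one sinusoidal illumination pattern
#'
#' One stripe pattern is described by its spatial frequency `k0` (cycles per
#' pixel), orientation `theta` (radians, relative to the horizontal axis),
#' phase `phi` (radians, the lateral shift along the pattern direction),
#' modulation depth `m` (the relative strength of the super-resolution
#' information carried by the stripes) and mean intensity `I0`.
#'
#' @param k0 Pattern spatial frequency in cycles per pixel (> 0).
#' @param theta Orientation in radians.
#' @param phi Phase in radians.
#' @param m Modulation depth in \[0, 1\].
#' @param I0 Mean illumination intensity (> 0, arbitrary units).
#' @return An object of class `illumination_params`.
#' @export
illumination_params <- function(k0, theta, phi, m = 0.8, I0 = 1) {
  stopifnot(k0 > 0, m >= 0, m <= 1, I0 > 0,
            is.finite(theta), is.finite(phi))
  structure(
    list(k0 = k0, theta = theta, phi = phi, m = m, I0 = I0),
    class = "illumination_params"
  )
}

#' Noise model specification
#'
#' Gaussian noise is parameterised by a dimensionless `level` eta: i.i.d.
#' per-pixel noise with standard deviation `eta * sigma`, where `sigma` is
#' the standard deviation of the noiseless blurred frame the noise is added
#' to. Poisson noise treats `level` as the photon-scaling constant (expected
#' photons at unit intensity); `none` disables noise.
#'
#' @param model One of `"gaussian"`, `"poisson"`, `"none"`.
#' @param level Noise level (eta for Gaussian; photons per unit intensity
#'   for Poisson). Must be >= 0.
#' @param seed Optional integer seed making a single `apply_forward()` call
#'   reproducible in isolation. Leave `NULL` to draw from the current RNG
#'   stream (the simulator seeds that stream itself).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("gaussian", "poisson", "none"),
                       level = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(level >= 0, is.null(seed) || is.numeric(seed))
  structure(list(model = model, level = level, seed = seed),
            class = "noise_spec")
}

# Centred frequency grid in cycles per pixel for an n-pixel axis
freq_axis <- function(n) {
  (seq_len(n) - 1 - floor(n / 2)) / n
}

# Undo/apply fftshift on a matrix (centred layout <-> DFT layout)
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((ceiling(n1 / 2) + 1):n1, 1:ceiling(n1 / 2)),
    c((ceiling(n2 / 2) + 1):n2, 1:ceiling(n2 / 2))]
}

#' Radial profile of the ideal incoherent OTF
#'
#' The autocorrelation of a circular pupil ("chat" function):
#' `(2/pi) * (acos(rho) - rho * sqrt(1 - rho^2))` for normalised radial
#' frequency `rho = k / kc`, zero beyond the cutoff.
#'
#' @param rho Normalised radial frequency (vector or array).
#' @return OTF values in \[0, 1\], same shape as `rho`.
#' @export
otf_radial <- function(rho) {
  out <- rho * 0
  inside <- rho < 1
  r <- rho[inside]
  out[inside] <- (2 / pi) * (acos(r) - r * sqrt(1 - r^2))
  out
}

#' Diffraction-limited transfer functions
#'
#' Builds the ideal incoherent optical transfer function (OTF) of a
#' widefield microscope on the discrete frequency grid of an
#' `image_size^2` image, together with its real-space point spread
#' function (PSF). The cutoff frequency is `kc = 2 NA / lambda`, converted
#' to cycles per pixel through the pixel size.
#'
#' The OTF is returned in centred layout (zero frequency at
#' `floor(n/2) + 1`); the PSF is centred the same way and normalised to
#' unit sum.
#'
#' @param cfg An [optical_config()].
#' @return An object of class `transfer_functions` with elements `otf`,
#'   `psf`, `cutoff_frequency` (cycles per pixel) and `cfg`.
#' @examples
#' tf <- make_otf(optical_config(image_size = 64))
#' tf$otf[33, 33]  # unity at zero frequency
#' @export
make_otf <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  n <- cfg$image_size
  kc <- 2 * cfg$numerical_aperture / cfg$emission_wavelength * cfg$pixel_size
  if (kc > 0.5) {
    warning("OTF cutoff (", signif(kc, 4),
            " cycles/pixel) exceeds the Nyquist frequency of the grid; ",
            "the effective band limit is the grid, not the optics")
  }
  f <- freq_axis(n)
  kr <- sqrt(outer(f^2, f^2, "+"))
  otf <- otf_radial(kr / kc)
  # PSF: inverse transform of the OTF; clip residual negatives from
  # discretisation and renormalise to unit sum
  psf <- Re(stats::fft(ifftshift2(otf), inverse = TRUE)) / n^2
  psf <- fftshift2(psf)
  psf[psf < 0] <- 0
  psf <- psf / sum(psf)
  structure(
    list(otf = otf, psf = psf, cutoff_frequency = kc, cfg = cfg),
    class = "transfer_functions"
  )
}

#' Construct transfer functions from an explicit OTF
#'
#' Lower-level companion to [make_otf()]: wraps an arbitrary OTF matrix
#' (centred layout) into a `transfer_functions` object, deriving the PSF
#' by inverse transform. Useful for idealised cases (e.g. an identity
#' OTF, whose PSF is a delta) and for grids smaller than a realistic
#' acquisition.
#'
#' @param otf A square OTF matrix in centred layout with value 1 at zero
#'   frequency.
#' @param cutoff_frequency Cutoff in cycles per pixel (`NA` if not
#'   applicable).
#' @return A `transfer_functions` object.
#' @export
transfer_functions <- function(otf, cutoff_frequency = NA_real_) {
  stopifnot(is.matrix(otf), nrow(otf) == ncol(otf))
  n <- nrow(otf)
  stopifnot(abs(otf[floor(n / 2) + 1, floor(n / 2) + 1] - 1) < 1e-12)
  psf <- Re(stats::fft(ifftshift2(otf), inverse = TRUE)) / n^2
  psf <- fftshift2(psf)
  psf <- psf / sum(psf)
  structure(
    list(otf = otf, psf = psf, cutoff_frequency = cutoff_frequency,
         cfg = NULL),
    class = "transfer_functions"
  )
}

#' Sinusoidal illumination pattern
#'
#' Evaluates the stripe pattern
#' `I(x, y) = I0 * (1 - (m/2) * cos(2 pi (kx x + ky y) + phi))` with
#' `kx = k0 cos(theta)`, `ky = k0 sin(theta)` on the pixel grid. Pixel
#' indices are 0-based; `x` is the column index and `y` the row index.
#'
#' @param params An [illumination_params()].
#' @param image_size Side length of the (square) output in pixels.
#' @return An `image_size` x `image_size` intensity matrix with values in
#'   `[I0 (1 - m/2), I0 (1 + m/2)]`.
#' @export
illumination_pattern <- function(params, image_size) {
  stopifnot(inherits(params, "illumination_params"), image_size >= 1)
  kx <- params$k0 * cos(params$theta)
  ky <- params$k0 * sin(params$theta)
  x <- seq_len(image_size) - 1  # columns
  y <- seq_len(image_size) - 1  # rows
  arg <- 2 * pi * (outer(y * ky, x * kx, "+")) + params$phi
  params$I0 * (1 - (params$m / 2) * cos(arg))
}

#' Image-formation forward model
#'
#' Produces one raw SIM frame: the sample's fluorescent response (pixelwise
#' product of sample and illumination) is blurred by the PSF via
#' multiplication with the OTF in frequency space (circular convolution)
#' and noise is added. Gaussian noise is drawn i.i.d. per pixel with
#' standard deviation `level * sigma`, where `sigma` is the standard
#' deviation of the noiseless blurred frame. The output is not clipped.
#'
#' @param sample Ground-truth image matrix, values nominally in \[0, 1\].
#' @param illum Illumination intensity matrix, same shape as `sample`.
#' @param tf A `transfer_functions` object whose grid matches `sample`.
#' @param noise A [noise_spec()]; defaults to no noise.
#' @return A raw frame matrix, same shape as `sample`.
#' @export
apply_forward <- function(sample, illum, tf, noise = noise_spec("none")) {
  stopifnot(inherits(tf, "transfer_functions"), inherits(noise, "noise_spec"))
  if (!all(dim(sample) == dim(illum)) || !all(dim(sample) == dim(tf$otf))) {
    stop("sample, illumination and transfer-function grids must have ",
         "identical shapes")
  }
  emission <- sample * illum
  h <- ifftshift2(tf$otf)
  blurred <- Re(stats::fft(stats::fft(emission) * h, inverse = TRUE)) /
    length(emission)
  if (noise$model == "none" || noise$level == 0) {
    return(blurred)
  }
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
  }
  if (noise$model == "gaussian") {
    sigma <- stats::sd(blurred)
    blurred + matrix(stats::rnorm(length(blurred), sd = noise$level * sigma),
                     nrow(blurred))
  } else {
    # Poisson: level = expected photons at unit intensity
    lam <- pmax(blurred, 0) * noise$level
    matrix(stats::rpois(length(lam), lam), nrow(blurred)) / noise$level
  }
}
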