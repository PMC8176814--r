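#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in decibels. Identical images have
#' zero MSE; the PSNR is then reported as `Inf` (an explicit sentinel
#' rather than an error).
#'
#' @param test,reference Image matrices of identical shape.
#' @param data_range Dynamic range of the data (1 for \[0, 1\] images).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(test, reference, data_range = 1) {
  if (!all(dim(test) == dim(reference))) stop("shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((test - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard constants: 11x11 Gaussian window
#' (sigma 1.5), `k1 = 0.01`, `k2 = 0.03`, population (uncorrected)
#' local variances. Local statistics are computed with edge-replicating
#' filtering and the window-radius border is excluded from the mean.
#'
#' @param test,reference Image matrices of identical shape, min side
#'   >= 11.
#' @param data_range Dynamic range of the data.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(test, reference, data_range = 1) {
  if (!all(dim(test) == dim(reference))) stop("shape mismatch")
  rad <- 5L
  if (min(dim(test)) < 2 * rad + 1) {
    stop("images smaller than the 11x11 SSIM window")
  }
  k <- stats::dnorm(-rad:rad, sd = 1.5)
  k <- k / sum(k)
  f <- function(m) gfilt_sep(m, k, rad)
  mu_x <- f(test); mu_y <- f(reference)
  sxx <- f(test^2) - mu_x^2
  syy <- f(reference^2) - mu_y^2
  sxy <- f(test * reference) - mu_x * mu_y
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  core <- s[(rad + 1):(nrow(s) - rad), (rad + 1):(ncol(s) - rad)]
  mean(core)
}

# separable filtering with edge replication
gfilt_sep <- function(m, k, rad) {
  n1 <- nrow(m); n2 <- ncol(m)
  pad_r <- m[c(rep(1, rad), seq_len(n1), rep(n1, rad)), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (i in seq_along(k)) {
    out <- out + k[i] * pad_r[i:(i + n1 - 1), , drop = FALSE]
  }
  pad_c <- out[, c(rep(1, rad), seq_len(n2), rep(n2, rad)), drop = FALSE]
  out2 <- matrix(0, n1, n2)
  for (i in seq_along(k)) {
    out2 <- out2 + k[i] * pad_c[, i:(i + n2 - 1), drop = FALSE]
  }
  out2
}

#' Score a reconstruction against ground truth
#'
#' @param test,reference Images of identical shape.
#' @param data_range Dynamic range.
#' @param test_id,reference_id Provenance strings.
#' @return A list (`metric_report`) with `psnr`, `ssim` and provenance.
#' @export
metric_report <- function(test, reference, data_range = 1,
                          test_id = "test", reference_id = "reference") {
  structure(
    list(psnr = psnr(test, reference, data_range),
         ssim = ssim(test, reference, data_range),
         test_id = test_id, reference_id = reference_id),
    class = "metric_report"
  )
}

#' Noise-robustness sweep
#'
#' For each noise level eta, simulates raw stacks from a ground truth
#' with Gaussian noise of standard deviation `eta * sigma` added to every
#' frame (`sigma` = the noiseless frame's standard deviation), then
#' scores the widefield projection and the model reconstruction against
#' the ground truth. Repeated over seeds; per-seed scores and per-eta
#' medians are returned.
#'
#' @param gt Ground-truth matrix matching `cfg$image_size`.
#' @param ckpt A `sim_checkpoint` (or `sim_network`).
#' @param etas Noise levels to sweep (default 0..9).
#' @param n_seeds Number of random repeats per eta.
#' @param cfg,layout,ranges Simulation settings; pattern parameters are
#'   resampled per repeat.
#' @param seed Master seed.
#' @return A list with `scores` (long data frame: seed, eta, method,
#'   psnr, ssim) and `summary` (per eta and method, median psnr/ssim).
#' @export
noise_sweep <- function(gt, ckpt, etas = 0:9, n_seeds = 5,
                        cfg = optical_config(image_size = nrow(gt)),
                        layout = stack_layout(),
                        ranges = simulation_ranges(), seed = 1) {
  stopifnot(all(etas >= 0), n_seeds >= 1)
  net <- if (inherits(ckpt, "sim_network")) ckpt else load_network(ckpt)
  tf <- make_otf(cfg)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    params <- sample_stack_params(layout, ranges, tf$cutoff_frequency)
    for (eta in etas) {
      set.seed(seed + s + 7919L * match(eta, etas))
      stack <- simulate_stack(gt, params, tf,
                              noise_spec("gaussian", eta), layout = layout)
      x <- stack_array(stack)
      wf <- normalise_stack(widefield_projection(x))
      rec <- reconstruct_stack(x, net)$image
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, eta = eta, method = c("widefield", "model"),
        psnr = c(psnr(wf, gt), psnr(rec, gt)),
        ssim = c(ssim(wf, gt), ssim(rec, gt)))
    }
  }
  scores <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(psnr, ssim) ~ eta + method, scores,
                              stats::median)
  list(scores = scores, summary = summary[order(summary$method,
                                                summary$eta), ])
}

#' Recover illumination-pattern parameters from a raw stack
#'
#' Diagnostic estimator of the stripe frequency and orientation for each
#' pattern orientation of a raw SIM stack, verifying that simulated (or
#' acquired) stacks carry recoverable pattern information.
#'
#' For one orientation, the phase-weighted frame sum
#' `b1(x) = sum_j D_j(x) exp(-i a_j)` (canonical phases
#' `a_j = 2 pi j / n_phases`) cancels the widefield component and
#' isolates the modulated band: a complex envelope riding on the carrier
#' `exp(i 2 pi k0 . x)`. Both `b1` and the widefield band `b0` are
#' Wiener-weighted by the system OTF (`OTF / (OTF^2 + c^2)`), which
#' suppresses out-of-band white noise without attenuating the band-edge
#' frequencies where SIM patterns live, and the spectrum of `b1 b0` --
#' the cross-correlation of the two bands -- peaks at the pattern
#' frequency. Candidate peaks are
#' collected in the annulus where SIM patterns physically live (0.45 to
#' 1.05 of the cutoff) and disambiguated across orientations by a
#' consensus constraint: all orientations of one stack share a single
#' `|k0|`, while false peaks from periodic sample structure or noise have
#' no common radius. Sub-bin precision comes from an intensity-weighted
#' centroid around the chosen peak.
#'
#' Estimates are flagged when no cross-orientation consensus exists
#' (noise-dominated, e.g. `m = 0` with noise) or when two orientations
#' pick nearly collinear frequencies (sample structure leaking through
#' imperfect phase cancellation, e.g. `m = 0` without noise -- sample
#' structure is orientation-independent, genuine patterns are spread
#' ~ pi / n_orientations apart).
#'
#' @param stack A `sim_stack` (or list of frames with the layout supplied
#'   via `layout`).
#' @param layout The stack's [stack_layout()]; taken from the stack if
#'   present. At least 3 phases per orientation are required.
#' @param cutoff OTF cutoff frequency in cycles/pixel; taken from the
#'   stack's provenance metadata if present.
#' @param n_candidates Local maxima retained per orientation for the
#'   consensus step.
#' @param wiener_reg Regularisation constant `c` of the Wiener band
#'   weighting.
#' @return A data frame with one row per orientation: `k0_hat` (cycles/
#'   pixel), `theta_hat` (radians, in \[0, pi)), `support` (number of
#'   orientations agreeing on the radius), `flagged`.
#' @export
estimate_pattern_params <- function(stack, layout = NULL, cutoff = NULL,
                                    n_candidates = 12, wiener_reg = 0.1) {
  frames <- if (inherits(stack, "sim_stack")) stack$frames else stack
  if (is.null(layout) && inherits(stack, "sim_stack")) layout <- stack$layout
  if (is.null(cutoff) && inherits(stack, "sim_stack")) {
    cutoff <- stack$cutoff_frequency
  }
  stopifnot(inherits(layout, "stack_layout"), layout$n_phases >= 3,
            is.numeric(cutoff), cutoff > 0)
  n <- nrow(frames[[1]])
  f <- freq_axis(n)
  kr <- sqrt(outer(f^2, f^2, "+"))
  annulus <- kr >= 0.45 * cutoff & kr <= 1.02 * cutoff
  otf <- ifftshift2(otf_radial(kr / min(cutoff, 0.5)))
  otf <- otf / (otf^2 + wiener_reg^2)
  n_or <- layout$n_orientations

  cands <- vector("list", n_or)
  for (o in seq_len(n_or)) {
    i0 <- (o - 1) * layout$n_phases
    b0 <- 0; b1 <- 0
    for (j in seq_len(layout$n_phases)) {
      b0 <- b0 + frames[[i0 + j]] / layout$n_phases
      b1 <- b1 + frames[[i0 + j]] * exp(-1i * layout$base_phases[j])
    }
    b0f <- Re(stats::fft(stats::fft(b0) * otf, inverse = TRUE)) / n^2
    b1f <- stats::fft(stats::fft(b1) * otf, inverse = TRUE) / n^2
    spec <- abs(fftshift2(stats::fft(b1f * b0f)))
    masked <- spec
    masked[!annulus] <- 0
    peaks <- NULL
    for (k in seq_len(n_candidates)) {
      mx <- max(masked)
      if (mx <= 0) break
      pk <- which(masked == mx, arr.ind = TRUE)[1, ]
      rr <- pmax(1, pk[1] - 1):pmin(n, pk[1] + 1)
      cc <- pmax(1, pk[2] - 1):pmin(n, pk[2] + 1)
      wts <- spec[rr, cc]^2
      peaks <- rbind(peaks, c(
        kx = sum(outer(rep(1, length(rr)), f[cc]) * wts) / sum(wts),
        ky = sum(outer(f[rr], rep(1, length(cc))) * wts) / sum(wts),
        mag = mx))
      sr <- pmax(1, pk[1] - 3):pmin(n, pk[1] + 3)
      sc <- pmax(1, pk[2] - 3):pmin(n, pk[2] + 3)
      masked[sr, sc] <- 0
    }
    cands[[o]] <- peaks
  }

  # consensus: the radius best supported across orientations
  tol <- 2.5 / n
  radii <- unlist(lapply(cands, function(cm) sqrt(cm[, 1]^2 + cm[, 2]^2)))
  best_r <- NA_real_; best_score <- -1
  for (r in radii) {
    score <- 0
    for (cm in cands) {
      rs <- sqrt(cm[, 1]^2 + cm[, 2]^2)
      ok <- abs(rs - r) <= tol
      if (any(ok)) score <- score + max(cm[ok, 3] / max(cm[, 3]))
    }
    if (score > best_score) { best_score <- score; best_r <- r }
  }
  support <- sum(vapply(cands, function(cm) {
    any(abs(sqrt(cm[, 1]^2 + cm[, 2]^2) - best_r) <= tol)
  }, TRUE))

  picks <- lapply(cands, function(cm) {
    rs <- sqrt(cm[, 1]^2 + cm[, 2]^2)
    ok <- which(abs(rs - best_r) <= tol)
    if (!length(ok)) ok <- which.min(abs(rs - best_r))
    cm[ok[which.max(cm[ok, 3])], 1:2]
  })

  # orientation collision: sample structure is orientation-independent,
  # genuine patterns are spread across orientations
  thetas <- vapply(picks, function(p) atan2(p[2], p[1]) %% pi, 0)
  collide <- rep(FALSE, n_or)
  if (n_or >= 2) {
    for (o in seq_len(n_or)) {
      others <- thetas[-o]
      dth <- abs(others - thetas[o])
      dth <- pmin(dth, pi - dth)
      collide[o] <- any(dth < 0.1)
    }
  }
  no_consensus <- n_or >= 2 && support < max(2, ceiling(0.6 * n_or))

  out <- data.frame(
    orientation = seq_len(n_or),
    k0_hat = vapply(picks, function(p) sqrt(sum(p^2)), 0),
    theta_hat = thetas,
    support = support,
    flagged = no_consensus | collide
  )
  rownames(out) <- NULL
  out
}
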