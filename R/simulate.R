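#' Acquisition layout of a raw SIM stack
#'
#' A SIM acquisition records `n_orientations * n_phases` frames: for each
#' stripe orientation (evenly spaced over pi), the pattern is shifted
#' through equally spaced phases (increments of `2 pi / n_phases`). The
#' conventional layout is 3 x 3 = 9 frames; 5 x 5 stacks are supported by
#' changing the two counts.
#'
#' Layouts with fewer than 3 phases are permitted but flagged as
#' underdetermined: the analytical unmixing problem they induce has fewer
#' equations than unknowns and is solvable only through learned priors.
#'
#' @param n_orientations Number of pattern orientations (>= 1).
#' @param n_phases Number of phase steps per orientation (>= 1).
#' @return An object of class `stack_layout` with base orientations and
#'   phases and an `underdetermined` flag.
#' @export
stack_layout <- function(n_orientations = 3, n_phases = 3) {
  stopifnot(n_orientations >= 1, n_phases >= 1)
  structure(
    list(
      n_orientations = as.integer(n_orientations),
      n_phases = as.integer(n_phases),
      base_orientations = (seq_len(n_orientations) - 1) * pi / n_orientations,
      base_phases = (seq_len(n_phases) - 1) * 2 * pi / n_phases,
      n_frames = as.integer(n_orientations * n_phases),
      underdetermined = n_phases < 3
    ),
    class = "stack_layout"
  )
}

#' Randomisation ranges for simulated acquisitions
#'
#' Controls the per-stack sampling of pattern parameters and the random
#' errors added to them, emulating the uncertainty of experimental pattern
#' generation. `k0` and `m` are drawn uniformly once per stack;
#' orientations receive a per-stack global offset (optional) plus
#' per-orientation Gaussian jitter; phases receive per-frame Gaussian
#' jitter; `k0` may additionally receive per-frame jitter. The noise level
#' eta is drawn per stack from `noise_level_range`.
#'
#' `k0_range` is expressed as a fraction of the OTF cutoff so the same
#' ranges apply across optical configurations; patterns near the cutoff
#' maximise the resolution gain.
#'
#' @param k0_range Pattern frequency range, fraction of the OTF cutoff.
#' @param m_range Modulation-depth range.
#' @param noise_level_range Range of the Gaussian noise level eta.
#' @param phase_jitter_sd SD of per-frame phase error (radians).
#' @param angle_jitter_sd SD of per-orientation angle error (radians).
#' @param k0_jitter_sd SD of per-frame frequency error (cycles/pixel).
#' @param randomise_orientation_offset Randomise the global stripe
#'   direction per stack (uniform over pi)?
#' @return An object of class `simulation_ranges`.
#' @export
simulation_ranges <- function(k0_range = c(0.7, 0.95),
                              m_range = c(0.5, 1.0),
                              noise_level_range = c(0, 4),
                              phase_jitter_sd = 0.05,
                              angle_jitter_sd = 0.05,
                              k0_jitter_sd = 0,
                              randomise_orientation_offset = TRUE) {
  stopifnot(
    length(k0_range) == 2, k0_range[1] <= k0_range[2], k0_range[1] > 0,
    length(m_range) == 2, m_range[1] <= m_range[2],
    m_range[1] >= 0, m_range[2] <= 1,
    length(noise_level_range) == 2,
    noise_level_range[1] <= noise_level_range[2], noise_level_range[1] >= 0,
    phase_jitter_sd >= 0, angle_jitter_sd >= 0, k0_jitter_sd >= 0
  )
  structure(
    list(
      k0_range = k0_range, m_range = m_range,
      noise_level_range = noise_level_range,
      phase_jitter_sd = phase_jitter_sd,
      angle_jitter_sd = angle_jitter_sd,
      k0_jitter_sd = k0_jitter_sd,
      randomise_orientation_offset = randomise_orientation_offset
    ),
    class = "simulation_ranges"
  )
}

#' Sample illumination parameters for one stack
#'
#' Draws one [illumination_params()] per frame in orientation-major order
#' (all phases of orientation 1, then orientation 2, ...). A single `k0`
#' and `m` are drawn per stack; angles and phases are the layout's base
#' values plus Gaussian jitter (and an optional global orientation
#' offset).
#'
#' @param layout A [stack_layout()].
#' @param ranges A [simulation_ranges()].
#' @param cutoff OTF cutoff frequency in cycles/pixel, used to convert
#'   the relative `k0_range` to absolute frequencies.
#' @param seed Optional integer seed; if `NULL`, draws from the current
#'   RNG stream.
#' @return A list of `layout$n_frames` [illumination_params()].
#' @export
sample_stack_params <- function(layout, ranges, cutoff, seed = NULL) {
  stopifnot(inherits(layout, "stack_layout"),
            inherits(ranges, "simulation_ranges"), cutoff > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  k0 <- stats::runif(1, ranges$k0_range[1], ranges$k0_range[2]) * cutoff
  m <- stats::runif(1, ranges$m_range[1], ranges$m_range[2])
  offset <- if (ranges$randomise_orientation_offset) {
    stats::runif(1, 0, pi)
  } else 0
  angles <- layout$base_orientations + offset +
    stats::rnorm(layout$n_orientations, 0, ranges$angle_jitter_sd)
  params <- vector("list", layout$n_frames)
  i <- 1
  for (o in seq_len(layout$n_orientations)) {
    for (p in seq_len(layout$n_phases)) {
      phi <- layout$base_phases[p] +
        stats::rnorm(1, 0, ranges$phase_jitter_sd)
      k0_f <- k0 + if (ranges$k0_jitter_sd > 0) {
        stats::rnorm(1, 0, ranges$k0_jitter_sd)
      } else 0
      params[[i]] <- illumination_params(k0 = k0_f, theta = angles[o],
                                         phi = phi, m = m, I0 = 1)
      i <- i + 1
    }
  }
  params
}

#' Simulate a raw SIM stack
#'
#' Applies the image-formation model frame by frame: each frame is the
#' ground truth multiplied by its sinusoidal illumination pattern, blurred
#' by the PSF and noised.
#'
#' @param gt Ground-truth matrix in \[0, 1\], square, matching
#'   `cfg$image_size`.
#' @param params List of per-frame [illumination_params()], orientation-major.
#' @param cfg An [optical_config()] (or a precomputed `transfer_functions`
#'   object to avoid rebuilding the OTF).
#' @param noise A [noise_spec()].
#' @param layout The [stack_layout()] the parameters follow.
#' @param source_id Provenance string stored with the stack.
#' @return An object of class `sim_stack`: list with `frames` (list of
#'   matrices), `layout`, `true_params`, `source_id`.
#' @export
simulate_stack <- function(gt, params, cfg, noise = noise_spec("none"),
                           layout = stack_layout(), source_id = "unknown") {
  tf <- if (inherits(cfg, "transfer_functions")) cfg else make_otf(cfg)
  stopifnot(length(params) == layout$n_frames,
            all(dim(gt) == dim(tf$otf)))
  frames <- lapply(params, function(p) {
    apply_forward(gt, illumination_pattern(p, nrow(gt)), tf, noise)
  })
  structure(
    list(frames = frames, layout = layout, true_params = params,
         cutoff_frequency = tf$cutoff_frequency, source_id = source_id),
    class = "sim_stack"
  )
}

#' Stack frames as an array
#'
#' @param stack A `sim_stack` or list of frame matrices.
#' @return A height x width x frames numeric array.
#' @export
stack_array <- function(stack) {
  frames <- if (inherits(stack, "sim_stack")) stack$frames else stack
  stopifnot(length(frames) >= 1)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Build a paired training dataset
#'
#' Generates `n` training pairs by drawing ground truths from a source
#' (a folder of raster images, cycled and prepared with
#' [prepare_ground_truth()], or the built-in procedural generator),
#' sampling randomised illumination parameters and noise per stack, and
#' simulating the raw frames. Stacks are written as multi-page float32
#' TIFFs (page order = frame order), targets as single-page TIFFs, and a
#' JSON manifest records the seed, configuration and every sampled
#' parameter, making the dataset exactly reproducible.
#'
#' A held-out fraction of pairs is tagged `"validation"` in the manifest;
#' the remainder are `"train"`.
#'
#' @param source `"procedural"` or a directory containing raster images.
#' @param n Number of pairs (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param cfg An [optical_config()].
#' @param layout A [stack_layout()].
#' @param ranges A [simulation_ranges()].
#' @param seed Integer master seed.
#' @param validation_fraction Fraction of pairs held out for validation.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
build_dataset <- function(source = "procedural", n, out_dir,
                          cfg = optical_config(),
                          layout = stack_layout(),
                          ranges = simulation_ranges(),
                          seed = 1, validation_fraction = 0.125) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- NULL
  if (!identical(source, "procedural")) {
    files <- list.files(source, full.names = TRUE,
                        pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE)
    if (length(files) == 0) stop("source folder contains no raster images")
  }
  tf <- make_otf(cfg)
  set.seed(as.integer(seed))
  n_val <- max(1L, round(n * validation_fraction))
  val_idx <- if (n > 1) sample.int(n, min(n_val, n - 1)) else integer(0)
  pair_seeds <- sample.int(2^31 - 1, n)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(pair_seeds[i])
    gt <- if (is.null(files)) {
      generate_procedural_image(cfg$image_size,
                                seed = pair_seeds[i])
    } else {
      prepare_ground_truth(files[[(i - 1) %% length(files) + 1]],
                           cfg$image_size)
    }
    params <- sample_stack_params(layout, ranges, tf$cutoff_frequency)
    eta <- stats::runif(1, ranges$noise_level_range[1],
                        ranges$noise_level_range[2])
    noise_seed <- sample.int(2^31 - 1, 1)
    set.seed(noise_seed)
    stack <- simulate_stack(gt, params, tf, noise_spec("gaussian", eta),
                            layout = layout,
                            source_id = sprintf("pair_%04d", i))
    stack_file <- sprintf("stack_%04d.tif", i)
    target_file <- sprintf("target_%04d.tif", i)
    norm <- write_stack_tiff(stack$frames, file.path(out_dir, stack_file))
    tiff::writeTIFF(gt, file.path(out_dir, target_file),
                    bits.per.sample = 32L)
    records[[i]] <- list(
      index = i,
      split = if (i %in% val_idx) "validation" else "train",
      seed = pair_seeds[i],
      stack_file = stack_file,
      target_file = target_file,
      noise = list(model = "gaussian", level = round(eta, 10),
                   noise_seed = noise_seed),
      norm = norm,
      params = lapply(params, function(p) {
        lapply(unclass(p), function(v) round(v, 12))
      })
    )
  }
  manifest <- list(
    seed = seed,
    n = n,
    source = if (is.null(files)) "procedural" else source,
    optical_config = unclass(cfg),
    layout = unclass(layout)[c("n_orientations", "n_phases")],
    ranges = unclass(ranges),
    validation_fraction = validation_fraction,
    pairs = records
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Write frames to a multi-page float TIFF; values are affinely mapped to
# [0,1] for storage and the mapping returned so it can be inverted.
write_stack_tiff <- function(frames, path) {
  lo <- min(vapply(frames, min, 0))
  hi <- max(vapply(frames, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  list(offset = lo, scale = scale)
}

#' Read a raw stack from a multi-page TIFF
#'
#' @param path TIFF file path.
#' @param norm Optional `list(offset, scale)` (as recorded in a dataset
#'   manifest) to undo storage normalisation.
#' @return A list of frame matrices.
#' @export
read_stack_tiff <- function(path, norm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 0) stop("empty or unreadable TIFF: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    if (!is.null(norm)) p * norm$scale + norm$offset else p
  })
  pages
}

#' Load a built dataset into memory
#'
#' Reads a dataset directory written by [build_dataset()] and returns the
#' pairs as arrays ready for training.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A list with `pairs` (each `list(input, target, split)` where
#'   `input` is an H x W x frames array) and the `manifest`.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  pairs <- lapply(manifest$pairs, function(rec) {
    frames <- read_stack_tiff(file.path(dir, rec$stack_file),
                              norm = rec$norm)
    target <- tiff::readTIFF(file.path(dir, rec$target_file))
    if (length(dim(target)) == 3) target <- target[, , 1]
    list(input = stack_array(frames), target = target, split = rec$split)
  })
  list(pairs = pairs, manifest = manifest)
}
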