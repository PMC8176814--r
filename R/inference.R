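#' Widefield projection of a raw stack
#'
#' The pixelwise arithmetic mean of all frames. Because the three
#' canonical phases of a sinusoidal pattern sum to a constant, this mean
#' is equivalent to imaging under homogeneous illumination and serves as
#' the diffraction-limited baseline.
#'
#' @param stack A `sim_stack`, list of frame matrices, or H x W x N array.
#' @return The H x W mean-projection matrix.
#' @export
widefield_projection <- function(stack) {
  x <- if (is.array(stack) && length(dim(stack)) == 3) {
    stack
  } else {
    stack_array(stack)
  }
  if (dim(x)[3] < 1) stop("stack must contain at least one frame")
  out <- x[, , 1]
  if (dim(x)[3] > 1) {
    for (i in 2:dim(x)[3]) out <- out + x[, , i]
  }
  out / dim(x)[3]
}

#' Reconstruct a raw stack with a trained model
#'
#' Normalises the stack (per-stack min-max), selects the frames the
#' checkpoint expects, runs the forward pass (tiled with
#' overlap-and-blend for large inputs) and optionally clips to \[0, 1\].
#'
#' @param stack A `sim_stack`, list of frames, or H x W x N array.
#' @param ckpt A `sim_checkpoint` or a `sim_network`.
#' @param clip Clip the output to \[0, 1\]?
#' @param tile Tile side for tiled inference; inputs up to `tile` pixels
#'   are processed in one pass.
#' @param overlap Tile overlap in pixels (blended linearly).
#' @return An object of class `reconstruction_result`: `image`,
#'   `widefield`, `model_fingerprint`, `timing` (seconds).
#' @export
reconstruct_stack <- function(stack, ckpt, clip = TRUE, tile = 512,
                              overlap = 32) {
  net <- if (inherits(ckpt, "sim_network")) ckpt else load_network(ckpt)
  x <- if (is.array(stack) && length(dim(stack)) == 3) {
    stack
  } else {
    stack_array(stack)
  }
  t0 <- proc.time()[["elapsed"]]
  wf <- widefield_projection(x)
  xin <- normalise_stack(frames_subset(x, net$cfg$in_frames))
  img <- if (max(dim(xin)[1:2]) <= tile) {
    net_forward(net, xin)
  } else {
    tiled_forward(net, xin, tile, overlap)
  }
  if (clip) img <- pmin(pmax(img, 0), 1)
  structure(
    list(image = img, widefield = wf,
         model_fingerprint = if (inherits(ckpt, "sim_checkpoint")) {
           ckpt$fingerprint
         } else "network",
         timing = proc.time()[["elapsed"]] - t0),
    class = "reconstruction_result"
  )
}

tiled_forward <- function(net, x, tile, overlap) {
  d <- dim(x)
  out <- matrix(0, d[1], d[2])
  wsum <- matrix(0, d[1], d[2])
  step <- tile - overlap
  r_starts <- unique(pmin(seq(1, d[1], step), max(1, d[1] - tile + 1)))
  c_starts <- unique(pmin(seq(1, d[2], step), max(1, d[2] - tile + 1)))
  ramp <- function(n) {
    w <- rep(1, n)
    k <- min(overlap, n)
    if (k > 1) {
      edge <- seq(0.05, 1, length.out = k)
      w[1:k] <- pmin(w[1:k], edge)
      w[(n - k + 1):n] <- pmin(w[(n - k + 1):n], rev(edge))
    }
    w
  }
  for (r0 in r_starts) for (c0 in c_starts) {
    r1 <- min(r0 + tile - 1, d[1]); c1 <- min(c0 + tile - 1, d[2])
    patch <- net_forward(net, x[r0:r1, c0:c1, , drop = FALSE])
    w <- outer(ramp(r1 - r0 + 1), ramp(c1 - c0 + 1))
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] + patch * w
    wsum[r0:r1, c0:c1] <- wsum[r0:r1, c0:c1] + w
  }
  out / wsum
}

#' Reconstruct a TIFF file (or folder) with a trained model
#'
#' Reads a multi-page TIFF whose page count equals the checkpoint's
#' expected frame count -- or an integer multiple of it, treated as a
#' timelapse of consecutive stacks -- reconstructs each stack, and writes
#' the result(s) next to `out`.
#'
#' @param path Input TIFF file, or a directory (every `.tif`/`.tiff`
#'   inside is processed).
#' @param ckpt A `sim_checkpoint` (or path to one saved with
#'   [save_checkpoint()]).
#' @param out Output file (single input) or directory.
#' @param float Write float32 TIFFs instead of 16-bit?
#' @param clip,tile Passed to [reconstruct_stack()].
#' @return Invisibly, a list of `reconstruction_result` objects.
#' @export
reconstruct_file <- function(path, ckpt, out, float = FALSE, clip = TRUE,
                             tile = 512) {
  if (is.character(ckpt)) ckpt <- readRDS(ckpt)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stop("no TIFF files in ", path)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    res <- lapply(files, function(f) {
      reconstruct_file(f, ckpt, file.path(out, basename(f)), float = float,
                       clip = clip, tile = tile)[[1]]
    })
    return(invisible(res))
  }
  pages <- read_stack_tiff(path)
  nf <- if (inherits(ckpt, "sim_checkpoint")) ckpt$net_cfg$in_frames else
    ckpt$cfg$in_frames
  if (length(pages) %% nf != 0) {
    stop("page-count mismatch: ", path, " has ", length(pages),
         " pages, expected a multiple of ", nf,
         " (frames per stack of this model)")
  }
  n_stacks <- length(pages) %/% nf
  net <- load_network(ckpt)
  results <- lapply(seq_len(n_stacks), function(s) {
    frames <- pages[((s - 1) * nf + 1):(s * nf)]
    reconstruct_stack(frames, net, clip = clip, tile = tile)
  })
  imgs <- lapply(results, function(r) pmin(pmax(r$image, 0), 1))
  tiff::writeTIFF(if (length(imgs) == 1) imgs[[1]] else imgs, out,
                  bits.per.sample = if (float) 32L else 16L)
  invisible(results)
}
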