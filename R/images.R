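#' Prepare a ground-truth image
#'
#' Converts an arbitrary raster image to the simulator's ground-truth
#' format: square `size` x `size`, grayscale, intensities rescaled to
#' \[0, 1\]. Colour images are converted by Rec. 709 luminance weighting;
#' non-square inputs are centre-cropped to square before resizing
#' (bilinear).
#'
#' @param image A file path readable by `EBImage::readImage()`, or a
#'   numeric matrix / 3-d array (height x width x channels) with intensity
#'   values.
#' @param size Target side length in pixels.
#' @return A `size` x `size` matrix in \[0, 1\].
#' @export
prepare_ground_truth <- function(image, size = 512) {
  if (is.character(image)) {
    img <- EBImage::imageData(EBImage::readImage(image))
    # EBImage stores x (columns) in dim 1; transpose to row-major matrix
    img <- if (length(dim(img)) == 2) t(img) else aperm(img, c(2, 1, 3))
    image <- img
  }
  if (length(dim(image)) == 3) {
    nc <- dim(image)[3]
    w <- switch(as.character(min(nc, 3)),
                "1" = 1, "2" = c(1, 0), "3" = c(0.2126, 0.7152, 0.0722))
    gray <- matrix(0, nrow(image), ncol(image))
    for (c in seq_along(w)) gray <- gray + w[c] * image[, , c]
    image <- gray
  }
  if (!is.matrix(image) || length(image) == 0) {
    stop("image must be a non-empty matrix, array or readable file")
  }
  # centre-crop to square
  h <- nrow(image); w <- ncol(image)
  s <- min(h, w)
  r0 <- floor((h - s) / 2); c0 <- floor((w - s) / 2)
  image <- image[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s), drop = FALSE]
  if (s != size) image <- resize_bilinear(image, size)
  rng <- range(image)
  if (rng[2] > rng[1]) {
    image <- (image - rng[1]) / (rng[2] - rng[1])
  } else {
    image <- matrix(min(1, max(0, rng[1])), size, size)
  }
  image
}

resize_bilinear <- function(m, size) {
  ebi <- EBImage::resize(EBImage::Image(t(m)), w = size, h = size)
  t(EBImage::imageData(ebi))
}

#' Procedural ground-truth image generator
#'
#' Composites randomised primitives -- curved filaments, discs,
#' single-pixel points, line gratings of varying spacing and orientation,
#' filled convex polygons and smooth background gradients -- into a
#' grayscale image in \[0, 1\]. The mixture is designed to mimic the
#' variety of structures found in natural-image training sets and in
#' resolution test targets (isolated point emitters, densely spaced
#' lines), so that simulated raw stacks carry frequency content beyond
#' the widefield passband.
#'
#' @param size Side length in pixels (>= 16).
#' @param seed Integer seed; the image is a deterministic function of
#'   `(size, seed)`.
#' @return A `size` x `size` matrix in \[0, 1\].
#' @export
generate_procedural_image <- function(size = 512, seed = 1) {
  stopifnot(size >= 16)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))

  img <- proc_background(size)
  sc <- size / 512  # primitive counts scale with area

  for (i in seq_len(rpois1(12 * sc^2 + 2))) img <- proc_filament(img)
  for (i in seq_len(rpois1(8 * sc^2 + 2)))  img <- proc_disc(img)
  for (i in seq_len(rpois1(2 * sc^2 + 1)))  img <- proc_polygon(img)
  for (i in seq_len(rpois1(1.5 * sc^2 + 0.7))) img <- proc_grating(img)
  img <- proc_points(img, n_points = rpois1(40 * sc^2 + 8))

  img <- pmin(pmax(img, 0), 1)
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  img
}

rpois1 <- function(lambda) stats::rpois(1, lambda)

proc_background <- function(n) {
  # smooth gradient: low-order 2-d polynomial surface
  u <- (seq_len(n) - 1) / (n - 1)
  a <- stats::runif(5, -0.3, 0.3)
  base <- stats::runif(1, 0.02, 0.2)
  base + a[1] * outer(u, rep(1, n)) + a[2] * outer(rep(1, n), u) +
    a[3] * outer(u, u) + a[4] * outer(u^2, rep(1, n)) +
    a[5] * outer(rep(1, n), u^2)
}

# stamp intensity at (row, col) float coordinates with bilinear footprint
stamp <- function(img, r, cc, val) {
  n <- nrow(img)
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    keep <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    if (!any(keep)) next
    wr <- if (dr == 0) 1 - fr else fr
    wc <- if (dc == 0) 1 - fc else fc
    wt <- (wr * wc)[keep]
    idx <- cbind(ri[keep], ci[keep])
    img[idx] <- pmin(img[idx] + val[keep] * wt, 1.5)
  }
  img
}

proc_filament <- function(img) {
  n <- nrow(img)
  len <- stats::runif(1, 0.3, 1.5) * n
  steps <- max(10, round(len * 2))         # half-pixel steps
  pos <- stats::runif(2, 1, n)
  dir <- stats::runif(1, 0, 2 * pi)
  curv <- stats::rnorm(1, 0, 0.02)
  val <- stats::runif(1, 0.3, 1)
  width <- sample(1:2, 1)
  dirs <- cumsum(c(dir, rep(curv, steps - 1) +
                     stats::rnorm(steps - 1, 0, 0.03)))
  path_r <- pos[1] + 0.5 * cumsum(sin(dirs))
  path_c <- pos[2] + 0.5 * cumsum(cos(dirs))
  inb <- path_r >= 1 & path_r <= n & path_c >= 1 & path_c <= n
  stop_at <- if (all(inb)) steps else which(!inb)[1] - 1
  if (stop_at < 1) return(img)
  keep <- seq_len(stop_at)
  off <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  pr <- rep(path_r[keep], width) + rep(off, each = stop_at) *
    rep(cos(dirs[keep]), width)
  pc <- rep(path_c[keep], width) - rep(off, each = stop_at) *
    rep(sin(dirs[keep]), width)
  stamp(img, pr, pc, rep(val * 0.5, length(pr)))
}

proc_disc <- function(img) {
  n <- nrow(img)
  r <- stats::runif(1, 2, max(3, n / 25))
  ctr <- stats::runif(2, 1, n)
  val <- stats::runif(1, 0.25, 1)
  rr <- max(1, floor(ctr[1] - r)):min(n, ceiling(ctr[1] + r))
  cc <- max(1, floor(ctr[2] - r)):min(n, ceiling(ctr[2] + r))
  d2 <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, "+")
  patch <- img[rr, cc, drop = FALSE]
  inside <- d2 <= r^2
  patch[inside] <- pmin(patch[inside] + val, 1.3)
  img[rr, cc] <- patch
  img
}

proc_polygon <- function(img) {
  n <- nrow(img)
  ctr <- stats::runif(2, n * 0.15, n * 0.85)
  rad <- stats::runif(1, n / 30, n / 8)
  k <- sample(3:6, 1)
  ang <- sort(stats::runif(k, 0, 2 * pi))
  vr <- ctr[1] + rad * sin(ang)
  vc <- ctr[2] + rad * cos(ang)
  val <- stats::runif(1, 0.2, 0.8)
  rr <- max(1, floor(min(vr))):min(n, ceiling(max(vr)))
  cc <- max(1, floor(min(vc))):min(n, ceiling(max(vc)))
  if (!length(rr) || !length(cc)) return(img)
  pts_r <- rep(rr, times = length(cc))
  pts_c <- rep(cc, each = length(rr))
  inside <- point_in_poly(pts_r, pts_c, vr, vc)
  idx <- cbind(pts_r[inside], pts_c[inside])
  img[idx] <- pmin(img[idx] + val, 1.3)
  img
}

point_in_poly <- function(pr, pc, vr, vc) {
  k <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- k
  for (i in seq_len(k)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

proc_grating <- function(img) {
  n <- nrow(img)
  side <- round(stats::runif(1, n / 8, n / 3))
  r0 <- sample.int(n - side, 1); c0 <- sample.int(n - side, 1)
  spacing <- stats::runif(1, 2, 8)            # pixels per line period
  ang <- sample(c(0, pi / 2, stats::runif(1, 0, pi)), 1)
  val <- stats::runif(1, 0.4, 1)
  rr <- r0:(r0 + side - 1); cc <- c0:(c0 + side - 1)
  phase <- outer(rr * sin(ang), cc * cos(ang), "+") * 2 * pi / spacing
  lines <- (cos(phase) > 0.2) * val
  img[rr, cc] <- pmin(img[rr, cc] + lines, 1.3)
  img
}

proc_points <- function(img, n_points) {
  n <- nrow(img)
  if (n_points < 1) return(img)
  idx <- cbind(sample.int(n, n_points, replace = TRUE),
               sample.int(n, n_points, replace = TRUE))
  img[idx] <- pmin(img[idx] + stats::runif(n_points, 0.6, 1), 1.5)
  img
}
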