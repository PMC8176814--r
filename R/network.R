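#' Reconstruction network configuration
#'
#' Describes a stack-to-image reconstruction network. All architectures
#' take `in_frames` input channels (the raw SIM frames, in acquisition
#' order) and emit a single output image at the same spatial resolution:
#' no spatial up- or downsampling of the result is performed anywhere.
#'
#' * `rcan_style` (default): residual groups of residual blocks with
#'   channel attention and a long skip connection — the default depth,
#'   10 groups of 3 blocks, gives on the order of 100 convolutional
#'   layers.
#' * `edsr_style`: a flat sequence of residual blocks without attention
#'   (residual branches scaled by 0.1).
#' * `unet_style`: a standard 4-level encoder–decoder with skip
#'   concatenations.
#'
#' @param architecture One of `"rcan_style"`, `"edsr_style"`,
#'   `"unet_style"`.
#' @param in_frames Number of input frames/channels (1 for the
#'   widefield-input ablation).
#' @param n_residual_groups Residual groups (rcan_style).
#' @param n_residual_blocks_per_group Residual blocks per group; for
#'   `edsr_style` the total block count is groups x blocks.
#' @param n_features Channel width of the feature maps.
#' @param attention_reduction Bottleneck reduction factor of the channel
#'   attention.
#' @return An object of class `network_config`.
#' @export
network_config <- function(architecture = c("rcan_style", "edsr_style",
                                            "unet_style"),
                           in_frames = 9,
                           n_residual_groups = 10,
                           n_residual_blocks_per_group = 3,
                           n_features = 64,
                           attention_reduction = 16) {
  architecture <- match.arg(architecture)
  stopifnot(in_frames >= 1, n_residual_groups >= 1,
            n_residual_blocks_per_group >= 1, n_features >= 1,
            attention_reduction >= 1)
  structure(
    list(architecture = architecture,
         in_frames = as.integer(in_frames),
         n_residual_groups = as.integer(n_residual_groups),
         n_residual_blocks_per_group = as.integer(n_residual_blocks_per_group),
         n_features = as.integer(n_features),
         attention_reduction = as.integer(attention_reduction)),
    class = "network_config"
  )
}

#' Build a reconstruction network
#'
#' Instantiates the architecture described by a [network_config()] with
#' randomly initialised weights (He initialisation, drawn from the
#' current RNG stream — seed beforehand for reproducibility). All
#' convolutions are 3x3, stride 1, size-preserving; activations are
#' rectified-linear inside blocks and the final layer is linear.
#'
#' @param cfg A [network_config()].
#' @return An object of class `sim_network`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (!cfg$architecture %in% c("rcan_style", "edsr_style", "unet_style")) {
    stop("unknown architecture: ", cfg$architecture)
  }
  f <- cfg$n_features
  root <- switch(cfg$architecture,
    rcan_style = {
      # residual branches start at zero (zero-initialised branch-final
      # conv) so the untrained network is an identity plus a linear
      # head/tail path; training then switches the branches on gradually
      make_block <- function() {
        mod_skip(mod_seq(list(mod_conv(f, f), mod_relu(),
                              mod_conv(f, f, zero_init = TRUE),
                              mod_ca(f, cfg$attention_reduction))),
                 scale = 1, tag = "residual_block")
      }
      make_group <- function() {
        blocks <- lapply(seq_len(cfg$n_residual_blocks_per_group),
                         function(i) make_block())
        mod_skip(mod_seq(c(blocks, list(mod_conv(f, f, zero_init = TRUE)))),
                 scale = 1, tag = "residual_group")
      }
      groups <- lapply(seq_len(cfg$n_residual_groups),
                       function(i) make_group())
      mod_seq(list(
        mod_conv(cfg$in_frames, f, mean_init = TRUE),
        mod_skip(mod_seq(c(groups, list(mod_conv(f, f, zero_init = TRUE)))),
                 scale = 1, tag = "long_skip"),
        mod_conv(f, 1)
      ))
    },
    edsr_style = {
      n_blocks <- cfg$n_residual_groups * cfg$n_residual_blocks_per_group
      make_block <- function() {
        mod_skip(mod_seq(list(mod_conv(f, f), mod_relu(),
                              mod_conv(f, f, zero_init = TRUE))),
                 scale = 0.1, tag = "residual_block")
      }
      blocks <- lapply(seq_len(n_blocks), function(i) make_block())
      mod_seq(list(
        mod_conv(cfg$in_frames, f, mean_init = TRUE),
        mod_skip(mod_seq(c(blocks, list(mod_conv(f, f, zero_init = TRUE)))),
                 scale = 1, tag = "long_skip"),
        mod_conv(f, 1)
      ))
    },
    unet_style = {
      enc_block <- function(cin, cout, mean_first = FALSE) {
        mod_seq(list(mod_conv(cin, cout, mean_init = mean_first), mod_relu(),
                     mod_conv(cout, cout), mod_relu()))
      }
      # level 4 (bottleneck) upward; decoder input = skip + upsampled
      l4 <- mod_ulevel(enc = enc_block(4 * f, 8 * f))
      l3 <- mod_ulevel(enc = enc_block(2 * f, 4 * f), sub = l4,
                       dec = enc_block(4 * f + 8 * f, 4 * f))
      l2 <- mod_ulevel(enc = enc_block(f, 2 * f), sub = l3,
                       dec = enc_block(2 * f + 4 * f, 2 * f))
      l1 <- mod_ulevel(enc = enc_block(cfg$in_frames, f, mean_first = TRUE), sub = l2,
                       dec = enc_block(f + 2 * f, f))
      mod_seq(list(l1, mod_conv(f, 1)))
    }
  )
  structure(list(cfg = cfg, module = root), class = "sim_network")
}

#' Structural summary of a network
#'
#' Walks the module tree and reports counts established by construction:
#' residual groups, residual blocks and trainable parameters.
#'
#' @param net A `sim_network`.
#' @return A list with `n_residual_groups`, `n_residual_blocks`,
#'   `n_parameters`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "sim_network"))
  groups <- 0L; blocks <- 0L
  walk_mods(net$module, function(m) {
    if (identical(m$tag, "residual_group")) groups <<- groups + 1L
    if (identical(m$tag, "residual_block")) blocks <<- blocks + 1L
  })
  list(n_residual_groups = groups, n_residual_blocks = blocks,
       n_parameters = n_params_mod(net$module))
}

#' Forward pass through a reconstruction network
#'
#' @param net A `sim_network`.
#' @param x Input stack as an H x W x `in_frames` array (a matrix is
#'   accepted for single-frame networks). For `unet_style`, H and W must
#'   be divisible by 8.
#' @return The reconstructed H x W image matrix.
#' @export
net_forward <- function(net, x) {
  stopifnot(inherits(net, "sim_network"))
  x <- as_hwc(x)
  if (dim(x)[3] != net$cfg$in_frames) {
    stop("frame-count mismatch: network expects ", net$cfg$in_frames,
         " input frames, got ", dim(x)[3])
  }
  if (net$cfg$architecture == "unet_style" &&
      any(dim(x)[1:2] %% 8 != 0)) {
    stop("unet_style requires spatial dimensions divisible by 8")
  }
  y <- forward_mod(net$module, x)
  y[, , 1]
}

#' Select the network input from a raw stack
#'
#' Frame-subset ablations use the first `in_frames` frames in stack
#' order; `in_frames = 1` is the widefield-input ablation and uses the
#' mean of all frames.
#'
#' @param x H x W x N stack array.
#' @param in_frames Number of input frames the network expects.
#' @return An H x W x `in_frames` array.
#' @export
frames_subset <- function(x, in_frames) {
  x <- as_hwc(x)
  if (in_frames == 1) {
    array(apply(x, c(1, 2), mean), dim = c(dim(x)[1:2], 1))
  } else {
    stopifnot(in_frames <= dim(x)[3])
    x[, , seq_len(in_frames), drop = FALSE]
  }
}

#' Per-stack min-max normalisation to \[0, 1\]
#'
#' The network contract: inputs are normalised stack-wise so that
#' reconstruction is invariant to global affine intensity rescaling of
#' the raw data (arbitrary camera offsets and gains).
#'
#' @param x Stack array or matrix.
#' @return Normalised array of the same shape.
#' @export
normalise_stack <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' Count trainable parameters
#' @param net A `sim_network`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) n_params_mod(net$module)
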