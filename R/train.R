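#' Training configuration
#'
#' Optimisation protocol for supervised reconstruction training: Adam
#' with a stepped learning-rate schedule
#' `lr(e) = initial_lr * 0.5^floor(e / lr_halving_period)`. The reference
#' protocol is 200 epochs at initial rate 1e-4 halved every 20 epochs;
#' the `"desk"` preset (see [train_presets()]) scales the run down to
#' minutes on one CPU.
#'
#' @param epochs Number of epochs (>= 1).
#' @param initial_lr Initial learning rate (> 0).
#' @param lr_halving_period Epochs between halvings.
#' @param batch_size Gradient-accumulation batch size.
#' @param loss `"mse"` (default) or `"l1"`.
#' @param seed Integer seed controlling initialisation, splits, shuffling
#'   and crops.
#' @param validation_fraction Fraction of pairs held out when the dataset
#'   has no split of its own.
#' @param crop_size Random training-crop side in pixels, or `NULL` to
#'   train on full images.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200, initial_lr = 1e-4,
                         lr_halving_period = 20, batch_size = 4,
                         loss = c("mse", "l1"), seed = 1,
                         validation_fraction = 0.125, crop_size = NULL) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, initial_lr > 0, lr_halving_period >= 1,
            batch_size >= 1, validation_fraction > 0,
            validation_fraction < 1)
  structure(
    list(epochs = as.integer(epochs), initial_lr = initial_lr,
         lr_halving_period = as.integer(lr_halving_period),
         batch_size = as.integer(batch_size), loss = loss,
         seed = as.integer(seed),
         validation_fraction = validation_fraction,
         crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size)),
    class = "train_config"
  )
}

#' Named training presets
#'
#' `"full_scale"` mirrors the full protocol (200 epochs, halving every
#' 20); `"desk"` is a small-scale profile that trains a tiny network in
#' minutes on one CPU and is used throughout the test-suite experiments.
#'
#' @param preset `"desk"` or `"full_scale"`.
#' @param seed Seed stored in the returned config.
#' @return A list with `train` ([train_config()]) and `network`
#'   ([network_config()]) entries.
#' @export
train_presets <- function(preset = c("desk", "full_scale"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    list(
      train = train_config(epochs = 10, initial_lr = 1e-3,
                           lr_halving_period = 4, batch_size = 1,
                           seed = seed),
      network = network_config("rcan_style", in_frames = 9,
                               n_residual_groups = 2,
                               n_residual_blocks_per_group = 2,
                               n_features = 16)
    )
  } else {
    list(
      train = train_config(epochs = 200, initial_lr = 1e-4,
                           lr_halving_period = 20, batch_size = 4,
                           seed = seed, crop_size = 256),
      network = network_config("rcan_style", in_frames = 9)
    )
  }
}

#' Learning rate at a given epoch
#'
#' @param cfg A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate `initial_lr * 0.5^floor(epoch / period)`.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(epoch >= 0)
  cfg$initial_lr * 0.5^floor(epoch / cfg$lr_halving_period)
}

loss_value <- function(pred, target, loss) {
  if (loss == "mse") mean((pred - target)^2) else mean(abs(pred - target))
}

loss_grad <- function(pred, target, loss) {
  if (loss == "mse") {
    2 * (pred - target) / length(pred)
  } else {
    sign(pred - target) / length(pred)
  }
}

split_pairs <- function(pairs, validation_fraction) {
  splits <- vapply(pairs, function(p) {
    if (is.null(p$split)) NA_character_ else p$split
  }, "")
  if (all(is.na(splits))) {
    n <- length(pairs)
    n_val <- max(1L, round(n * validation_fraction))
    val <- sample.int(n, min(n_val, n - 1))
    splits <- ifelse(seq_len(n) %in% val, "validation", "train")
  }
  list(train = pairs[splits == "train"],
       val = pairs[splits == "validation"])
}

prepare_pair <- function(pair, in_frames, crop_size) {
  x <- pair$input
  t <- pair$target
  if (!is.null(crop_size) && crop_size < dim(x)[1]) {
    r0 <- sample.int(dim(x)[1] - crop_size + 1, 1)
    c0 <- sample.int(dim(x)[2] - crop_size + 1, 1)
    x <- x[r0:(r0 + crop_size - 1), c0:(c0 + crop_size - 1), ,
           drop = FALSE]
    t <- t[r0:(r0 + crop_size - 1), c0:(c0 + crop_size - 1)]
  }
  list(input = normalise_stack(frames_subset(x, in_frames)), target = t)
}

#' Train a reconstruction model
#'
#' Supervised training with Adam and the stepped halving schedule.
#' Gradients are accumulated over `batch_size` pairs per step. Per-epoch
#' training loss and validation PSNR/SSIM are logged; the weights with
#' the best validation PSNR are retained in the returned checkpoint.
#'
#' @param dataset Either the list returned by [load_dataset()], a
#'   dataset directory, or a bare list of pairs
#'   (`list(input = array, target = matrix, split = ...)`).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param quiet Suppress per-epoch progress messages?
#' @return A checkpoint object (class `sim_checkpoint`): best weights,
#'   configs, training `log` data frame and a fingerprint.
#' @export
train_model <- function(dataset, net_cfg, train_cfg, quiet = TRUE) {
  pairs <- as_pairs(dataset)
  stopifnot(length(pairs) >= 2)
  set.seed(train_cfg$seed)
  sp <- split_pairs(pairs, train_cfg$validation_fraction)
  if (length(sp$train) == 0 || length(sp$val) == 0) {
    stop("training and validation splits must both be non-empty")
  }
  net <- build_network(net_cfg)
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_psnr = numeric(),
                    val_ssim = numeric())
  best <- list(psnr = -Inf, weights = NULL, epoch = NA_integer_)
  t_adam <- 0L
  for (epoch in seq_len(train_cfg$epochs) - 1L) {
    lr <- lr_at_epoch(train_cfg, epoch)
    order_idx <- sample(seq_along(sp$train))
    epoch_loss <- 0; n_seen <- 0
    i <- 1
    while (i <= length(order_idx)) {
      batch <- order_idx[i:min(i + train_cfg$batch_size - 1,
                               length(order_idx))]
      zero_grads(net$module)
      for (j in batch) {
        pp <- prepare_pair(sp$train[[j]], net_cfg$in_frames,
                           train_cfg$crop_size)
        pred <- forward_mod(net$module, pp$input)
        l <- loss_value(pred[, , 1], pp$target, train_cfg$loss)
        if (!is.finite(l)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        epoch_loss <- epoch_loss + l; n_seen <- n_seen + 1
        dy <- loss_grad(pred[, , 1], pp$target, train_cfg$loss) /
          length(batch)
        backward_mod(net$module, array(dy, dim = dim(pred)))
      }
      t_adam <- t_adam + 1L
      adam_step(net$module, lr, t_adam)
      i <- i + train_cfg$batch_size
    }
    val <- evaluate_on_pairs(net, sp$val)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = epoch_loss / n_seen,
                                 val_psnr = val$psnr,
                                 val_ssim = val$ssim))
    if (val$psnr > best$psnr) {
      best <- list(psnr = val$psnr,
                   weights = get_weights_mod(net$module), epoch = epoch)
    }
    if (!quiet) {
      message(sprintf("epoch %3d  lr %.2e  loss %.5f  val PSNR %.2f dB",
                      epoch, lr, epoch_loss / n_seen, val$psnr))
    }
  }
  set_weights_mod(net$module, best$weights)
  structure(
    list(weights = best$weights, net_cfg = net_cfg,
         train_cfg = train_cfg, log = log,
         best_epoch = best$epoch, best_val_psnr = best$psnr,
         fingerprint = checkpoint_fingerprint(net_cfg, train_cfg)),
    class = "sim_checkpoint"
  )
}

as_pairs <- function(dataset) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  if (!is.null(dataset$pairs)) dataset$pairs else dataset
}

evaluate_on_pairs <- function(net, pairs) {
  scores <- vapply(pairs, function(p) {
    x <- normalise_stack(frames_subset(p$input, net$cfg$in_frames))
    pred <- net_forward(net, x)
    c(psnr(pred, p$target, data_range = 1),
      ssim(pred, p$target, data_range = 1))
  }, c(0, 0))
  list(psnr = mean(pmin(scores[1, ], 100)), ssim = mean(scores[2, ]))
}

checkpoint_fingerprint <- function(net_cfg, train_cfg) {
  paste0(net_cfg$architecture, "_f", net_cfg$in_frames, "_g",
         net_cfg$n_residual_groups, "x", net_cfg$n_residual_blocks_per_group,
         "_w", net_cfg$n_features, "_seed", train_cfg$seed)
}

#' Restore a network from a checkpoint
#'
#' @param ckpt A `sim_checkpoint` (or a path saved with
#'   [save_checkpoint()]).
#' @return A `sim_network` with the checkpoint's weights.
#' @export
load_network <- function(ckpt) {
  if (is.character(ckpt)) ckpt <- readRDS(ckpt)
  stopifnot(inherits(ckpt, "sim_checkpoint"))
  net <- build_network(ckpt$net_cfg)
  set_weights_mod(net$module, ckpt$weights)
  net
}

#' Save a checkpoint to disk
#' @param ckpt A `sim_checkpoint`.
#' @param path Output file path (RDS).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "sim_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' Train and compare several configurations
#'
#' Trains every configuration on the same dataset with the same protocol
#' and returns the aligned validation-PSNR curves, as used to compare
#' architectures and input-frame counts.
#'
#' @param dataset As in [train_model()].
#' @param configs Named list of [network_config()] objects (names label
#'   the rows).
#' @param train_cfg Shared [train_config()].
#' @return A data frame with columns `config`, `epoch`, `lr`,
#'   `train_loss`, `val_psnr`, `val_ssim`; attribute `"checkpoints"`
#'   carries the per-config checkpoints.
#' @export
compare_configs <- function(dataset, configs, train_cfg) {
  stopifnot(length(configs) >= 1)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) {
      paste0(cf$architecture, "_", cf$in_frames, "f")
    }, "")
  }
  out <- list(); ckpts <- list()
  for (nm in names(configs)) {
    ck <- train_model(dataset, configs[[nm]], train_cfg)
    out[[nm]] <- cbind(config = nm, ck$log)
    ckpts[[nm]] <- ck
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "checkpoints") <- ckpts
  res
}
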