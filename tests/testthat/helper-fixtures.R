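# Shared fixtures, built once per test run and cached. The desk-scale
# profile (64-pixel images, 32 procedural pairs, tiny 2x2x16 attention
# network, 10 epochs) is the package's small-scale study condition; the
# heavier objects are built lazily so cheap test files stay cheap.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env, inherits = FALSE)) {
    assign(name, builder(), .fixture_env)
  }
  get(name, .fixture_env)
}

desk_optical <- function(size = 64) {
  optical_config(image_size = size, pixel_size = 80)
}

# a small chat-function transfer function on an arbitrary even grid
small_tf <- function(n, kc = 0.4) {
  f <- (seq_len(n) - 1 - floor(n / 2)) / n
  kr <- sqrt(outer(f^2, f^2, "+"))
  transfer_functions(otf_radial(kr / kc), kc)
}

desk_dataset_dir <- function() {
  fixture("desk_dataset_dir", function() {
    d <- file.path(tempdir(), "simrecon-desk-dataset")
    build_dataset("procedural", n = 32, out_dir = d,
                  cfg = desk_optical(), seed = 5)
    d
  })
}

desk_dataset <- function() {
  fixture("desk_dataset", function() load_dataset(desk_dataset_dir()))
}

# tiny model trained under the desk-scale conditions; reused by the
# training, inference and evaluation experiments
desk_checkpoint <- function() {
  fixture("desk_checkpoint", function() {
    pre <- train_presets("desk", seed = 11)
    train_model(desk_dataset(), pre$network, pre$train)
  })
}

validation_pairs <- function(ds) {
  Filter(function(p) identical(p$split, "validation"), ds$pairs)
}

widefield_psnr_on <- function(pairs) {
  vapply(pairs, function(p) {
    psnr(normalise_stack(widefield_projection(p$input)), p$target)
  }, 0)
}
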