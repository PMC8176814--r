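# independent dense reference convolution (zero padding) used to verify
# the compiled path
conv_ref <- function(x, W, b, cout) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; cin <- d[3]
  out <- array(0, c(H, Wd, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, Wd)
    for (ci in seq_len(cin)) {
      for (dj in -1:1) for (di in -1:1) {
        w <- W[co, (ci - 1) * 9 + (dj + 1) * 3 + (di + 2)]
        shifted <- matrix(0, H, Wd)
        rs <- max(1, 1 - di):min(H, H - di)
        cs <- max(1, 1 - dj):min(Wd, Wd - dj)
        shifted[rs, cs] <- x[rs + di, cs + dj, ci]
        acc <- acc + w * shifted
      }
    }
    out[, , co] <- acc
  }
  out
}

test_that("default architecture has 10 residual groups of 3 blocks", {
  set.seed(1)
  net <- build_network(network_config())
  s <- network_summary(net)
  expect_equal(s$n_residual_groups, 10)
  expect_equal(s$n_residual_blocks, 30)
})

test_that("all architectures map an N-frame stack to one same-size image", {
  set.seed(2)
  x <- array(runif(32 * 32 * 9), c(32, 32, 9))
  for (arch in c("rcan_style", "edsr_style", "unet_style")) {
    net <- build_network(network_config(arch, in_frames = 9,
                                        n_residual_groups = 1,
                                        n_residual_blocks_per_group = 1,
                                        n_features = 8,
                                        attention_reduction = 4))
    y <- net_forward(net, x)
    expect_equal(dim(y), c(32, 32))
    expect_true(all(is.finite(y)))
  }
  expect_error(build_network(structure(
    list(architecture = "transformer"), class = "network_config")))
})

test_that("frame-count mismatches are rejected with a named expectation", {
  set.seed(3)
  net <- build_network(network_config(in_frames = 9,
                                      n_residual_groups = 1,
                                      n_residual_blocks_per_group = 1,
                                      n_features = 4))
  x <- array(runif(16 * 16 * 6), c(16, 16, 6))
  expect_error(net_forward(net, x), "expects 9.*got 6")
})

test_that("parameter count grows with depth and width", {
  set.seed(4)
  count <- function(g, f) {
    n_parameters(build_network(network_config(
      n_residual_groups = g, n_residual_blocks_per_group = 1,
      n_features = f, attention_reduction = 4)))
  }
  expect_lt(count(1, 8), count(2, 8))
  expect_lt(count(2, 8), count(3, 8))
  expect_lt(count(2, 8), count(2, 16))
})

test_that("forward pass is deterministic and respects the skip structure", {
  set.seed(5)
  cfgn <- network_config(in_frames = 2, n_residual_groups = 1,
                         n_residual_blocks_per_group = 1, n_features = 4,
                         attention_reduction = 2)
  net <- build_network(cfgn)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  expect_identical(net_forward(net, x), net_forward(net, x))
  # residual branches are zero-initialised, so before training the
  # network is exactly its linear head -> tail path
  w <- simrecon:::get_weights_mod(net$module)
  head_w <- w[[1]]; tail_w <- w[[length(w)]]
  lin <- conv_ref(conv_ref(x, head_w$W, head_w$b, 4),
                  tail_w$W, tail_w$b, 1)
  expect_lt(max(abs(net_forward(net, x) - lin[, , 1])), 1e-10)
})

test_that("analytic gradients agree with finite differences in every module", {
  set.seed(6)
  for (arch in c("rcan_style", "edsr_style", "unet_style")) {
    cfgn <- network_config(arch, in_frames = 2, n_residual_groups = 1,
                           n_residual_blocks_per_group = 1,
                           n_features = 4, attention_reduction = 2)
    net <- build_network(cfgn)
    x <- array(runif(16 * 16 * 2), c(16, 16, 2))
    tgt <- matrix(runif(256), 16)
    lossf <- function() {
      y <- simrecon:::forward_mod(net$module, x)
      mean((y[, , 1] - tgt)^2)
    }
    y <- simrecon:::forward_mod(net$module, x)
    simrecon:::zero_grads(net$module)
    simrecon:::backward_mod(net$module,
                            array(2 * (y[, , 1] - tgt) / 256, dim = dim(y)))
    eps <- 1e-6
    for (m in simrecon:::param_mods(net$module)) {
      p <- m$pnames[1]
      W <- get(p, m)
      idx <- min(2, length(W))
      g <- get(paste0("g", p), m)[idx]
      W2 <- W; W2[idx] <- W2[idx] + eps; assign(p, W2, m); lp <- lossf()
      W2[idx] <- W2[idx] - 2 * eps; assign(p, W2, m); lm <- lossf()
      assign(p, W, m)
      expect_equal(g, (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("reconstruction is translation-equivariant away from boundaries", {
  set.seed(7)
  net <- build_network(network_config(in_frames = 3,
                                      n_residual_groups = 1,
                                      n_residual_blocks_per_group = 1,
                                      n_features = 8,
                                      attention_reduction = 4))
  # make the residual path active so the test exercises the full network
  for (m in simrecon:::param_mods(net$module)) {
    for (p in m$pnames) {
      assign(p, get(p, m) + 0.01, m)
    }
  }
  n <- 48; s <- 4
  x <- array(runif(n * n * 3), c(n, n, 3))
  xs <- x[c((s + 1):n, 1:s), , , drop = FALSE]  # cyclic row shift
  y <- net_forward(net, x)
  ys <- net_forward(net, xs)
  core <- 12:(n - 12)
  # zero padding and the global pooling in the attention gate make the
  # equivariance approximate; declared interior tolerance 5e-3
  expect_lt(max(abs(ys[core - s, core] - y[core, core])), 5e-3)
})

test_that("compiled convolution matches a dense reference implementation", {
  set.seed(8)
  x <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  W <- matrix(rnorm(2 * 27), 2)
  b <- rnorm(2)
  got <- simrecon:::conv2d_fwd(x, W, b, 3L)
  want <- conv_ref(x, W, b, 2)
  expect_lt(max(abs(got - want)), 1e-12)
})
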