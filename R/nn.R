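# Minimal neural-network engine used by the reconstruction networks.
# Modules are environments holding parameters, gradients and per-pass
# caches; forward/backward walk the module tree recursively. Images flow
# through as H x W x C arrays; convolutions run in compiled code.

new_mod <- function(.kind, ..., tag = NULL) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$tag <- tag
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "sim_module"
  e
}

he_init <- function(nout, nin_eff) {
  matrix(stats::rnorm(nout * nin_eff, sd = sqrt(2 / nin_eff)),
         nrow = nout)
}

mod_conv <- function(cin, cout, k = 3, zero_init = FALSE,
                     mean_init = FALSE) {
  W <- if (zero_init) {
    matrix(0, cout, cin * k * k)
  } else if (mean_init) {
    # widefield prior: every input channel shares one spatial kernel
    # scaled by 1/cin, so the layer initially convolves the frame mean
    k1 <- he_init(cout, k * k)
    do.call(cbind, rep(list(k1 / cin), cin))
  } else {
    he_init(cout, cin * k * k)
  }
  m <- new_mod("conv", k = as.integer(k), W = W, b = numeric(cout))
  m$pnames <- c("W", "b")
  m$gW <- m$W * 0; m$gb <- m$b * 0
  m
}

mod_relu <- function() new_mod("relu")

mod_seq <- function(children, tag = NULL) new_mod("seq", children = children,
                                                  tag = tag)

# y = x + scale * inner(x)
mod_skip <- function(inner, scale = 1, tag = NULL) {
  new_mod("skip", inner = inner, scale = scale, tag = tag)
}

# channel attention: global average pool -> bottleneck MLP -> sigmoid gate
mod_ca <- function(features, reduction = 16) {
  hidden <- max(1L, as.integer(features / reduction))
  m <- new_mod("ca",
               W1 = he_init(hidden, features), b1 = numeric(hidden),
               W2 = he_init(features, hidden), b2 = numeric(features))
  m$pnames <- c("W1", "b1", "W2", "b2")
  for (p in m$pnames) assign(paste0("g", p), get(p, m) * 0, envir = m)
  m
}

mod_pool <- function() new_mod("pool")   # 2x2 average pool
mod_up <- function() new_mod("up")       # 2x nearest-neighbour upsample

# one U-level: enc block, then (optionally) pooled recursion concatenated
# back and decoded
mod_ulevel <- function(enc, sub = NULL, dec = NULL) {
  m <- new_mod("ulevel", enc = enc, sub = sub, dec = dec)
  if (!is.null(sub)) {
    m$pool_mod <- mod_pool()
    m$up_mod <- mod_up()
  }
  m
}

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1)) else x
}

forward_mod <- function(m, x) {
  switch(m$kind,
    conv = {
      m$x <- x
      conv2d_fwd(x, m$W, m$b, m$k)
    },
    relu = {
      m$mask <- x > 0
      x * m$mask
    },
    seq = {
      for (ch in m$children) x <- forward_mod(ch, x)
      x
    },
    skip = x + m$scale * forward_mod(m$inner, x),
    ca = {
      d <- dim(x)
      hw <- d[1] * d[2]
      s <- colMeans(matrix(x, nrow = hw))
      z1 <- drop(m$W1 %*% s) + m$b1
      a1 <- pmax(z1, 0)
      g <- 1 / (1 + exp(-(drop(m$W2 %*% a1) + m$b2)))
      m$x <- x; m$s <- s; m$z1 <- z1; m$a1 <- a1; m$g <- g
      x * rep(g, each = hw)
    },
    pool = {
      d <- dim(x)
      m$din <- d
      x4 <- x[seq(1, d[1], 2), , , drop = FALSE]
      y <- (x4[, seq(1, d[2], 2), , drop = FALSE] +
            x4[, seq(2, d[2], 2), , drop = FALSE] +
            x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
            x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
      y
    },
    up = {
      d <- dim(x)
      x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
        drop = FALSE]
    },
    ulevel = {
      e <- forward_mod(m$enc, x)
      if (is.null(m$sub)) return(e)
      s <- forward_mod(m$up_mod, forward_mod(m$sub, forward_mod(m$pool_mod, e)))
      m$c_e <- dim(e)[3]
      z <- array(c(e, s), dim = c(dim(e)[1:2], dim(e)[3] + dim(s)[3]))
      forward_mod(m$dec, z)
    },
    stop("unknown module kind: ", m$kind)
  )
}

backward_mod <- function(m, dy) {
  switch(m$kind,
    conv = {
      r <- conv2d_bwd(m$x, m$W, dy, m$k)
      m$gW <- m$gW + r$gw
      m$gb <- m$gb + drop(r$gb)
      r$dx
    },
    relu = dy * m$mask,
    seq = {
      for (ch in rev(m$children)) dy <- backward_mod(ch, dy)
      dy
    },
    skip = dy + backward_mod(m$inner, m$scale * dy),
    ca = {
      d <- dim(m$x)
      hw <- d[1] * d[2]
      dg <- colSums(matrix(dy * m$x, nrow = hw))
      dx <- dy * rep(m$g, each = hw)
      dz2 <- dg * m$g * (1 - m$g)
      m$gW2 <- m$gW2 + dz2 %*% t(m$a1)
      m$gb2 <- m$gb2 + dz2
      dz1 <- drop(t(m$W2) %*% dz2) * (m$z1 > 0)
      m$gW1 <- m$gW1 + dz1 %*% t(m$s)
      m$gb1 <- m$gb1 + dz1
      ds <- drop(t(m$W1) %*% dz1)
      dx + rep(ds / hw, each = hw)
    },
    pool = {
      d <- m$din
      g <- dy / 4
      g[rep(seq_len(d[1] / 2), each = 2), rep(seq_len(d[2] / 2), each = 2), ,
        drop = FALSE]
    },
    up = {
      d <- dim(dy)
      dy[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
        dy[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
        dy[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
        dy[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
    },
    ulevel = {
      if (is.null(m$sub)) return(backward_mod(m$enc, dy))
      dz <- backward_mod(m$dec, dy)
      ce <- m$c_e
      de <- dz[, , seq_len(ce), drop = FALSE]
      dsv <- dz[, , -seq_len(ce), drop = FALSE]
      de2 <- backward_mod(m$pool_mod,
                          backward_mod(m$sub, backward_mod(m$up_mod, dsv)))
      backward_mod(m$enc, de + de2)
    },
    stop("unknown module kind: ", m$kind)
  )
}

# walk the tree applying fn to every module (depth-first)
walk_mods <- function(m, fn) {
  fn(m)
  if (m$kind == "seq") for (ch in m$children) walk_mods(ch, fn)
  if (m$kind == "skip") walk_mods(m$inner, fn)
  if (m$kind == "ulevel") {
    walk_mods(m$enc, fn)
    if (!is.null(m$sub)) {
      walk_mods(m$pool_mod, fn); walk_mods(m$sub, fn)
      walk_mods(m$up_mod, fn); walk_mods(m$dec, fn)
    }
  }
  invisible(NULL)
}

param_mods <- function(root) {
  out <- list()
  walk_mods(root, function(m) {
    if (!is.null(m$pnames)) out[[length(out) + 1]] <<- m
  })
  out
}

zero_grads <- function(root) {
  for (m in param_mods(root)) {
    for (p in m$pnames) assign(paste0("g", p), get(p, m) * 0, envir = m)
  }
}

n_params_mod <- function(root) {
  sum(vapply(param_mods(root), function(m) {
    sum(vapply(m$pnames, function(p) length(get(p, m)), 0))
  }, 0))
}

get_weights_mod <- function(root) {
  lapply(param_mods(root), function(m) {
    stats::setNames(lapply(m$pnames, get, envir = m), m$pnames)
  })
}

set_weights_mod <- function(root, weights) {
  mods <- param_mods(root)
  stopifnot(length(mods) == length(weights))
  for (i in seq_along(mods)) {
    for (p in mods[[i]]$pnames) {
      cur <- get(p, mods[[i]])
      new <- weights[[i]][[p]]
      stopifnot(length(cur) == length(new))
      dim(new) <- dim(cur)
      assign(p, new, envir = mods[[i]])
    }
  }
  invisible(root)
}

# one Adam update over all parameters; grads are assumed accumulated
adam_step <- function(root, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (m in param_mods(root)) {
    for (p in m$pnames) {
      g <- get(paste0("g", p), m)
      mn <- paste0("adam_m_", p); vn <- paste0("adam_v_", p)
      mo <- if (exists(mn, m, inherits = FALSE)) get(mn, m) else g * 0
      vo <- if (exists(vn, m, inherits = FALSE)) get(vn, m) else g * 0
      mo <- beta1 * mo + (1 - beta1) * g
      vo <- beta2 * vo + (1 - beta2) * g^2
      assign(mn, mo, m); assign(vn, vo, m)
      mhat <- mo / (1 - beta1^t)
      vhat <- vo / (1 - beta2^t)
      assign(p, get(p, m) - lr * mhat / (sqrt(vhat) + eps), m)
    }
  }
  invisible(root)
}
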