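# Internal engine for the separable-convolution residual classifier.
#
# Parameters live in a flat named list of numeric arrays; batch-norm running
# moments live in a parallel `state` list (they are updated by forward passes
# in training mode, never by the optimiser). Activations are channel-fastest
# (C, H, W, N) arrays handed to the C++ kernels in src/nn_ops.cpp.

glorot_uniform <- function(dim, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dim), -limit, limit), dim)
}

nn_init_params <- function(spec) {
  e1 <- spec$entry_widths[1]
  e2 <- spec$entry_widths[2]
  mw <- spec$middle_widths
  fw <- spec$final_width
  p <- list()
  s <- list()
  add_bn <- function(name, c) {
    p[[paste0(name, ".g")]] <<- rep(1, c)
    p[[paste0(name, ".b")]] <<- rep(0, c)
    s[[paste0(name, ".rm")]] <<- rep(0, c)
    s[[paste0(name, ".rv")]] <<- rep(1, c)
  }
  p[["c1.w"]] <- glorot_uniform(c(3, 3, 3, e1), 9 * 3, 9 * e1)
  p[["c1.b"]] <- rep(0, e1)
  add_bn("bn1", e1)
  p[["c2.w"]] <- glorot_uniform(c(3, 3, e1, e2), 9 * e1, 9 * e2)
  p[["c2.b"]] <- rep(0, e2)
  add_bn("bn2", e2)
  cin <- e2
  for (k in seq_along(mw)) {
    w <- mw[k]
    pre <- sprintf("bk%d", k)
    p[[paste0(pre, ".s1dw")]] <- glorot_uniform(c(3, 3, cin), 9, 9)
    p[[paste0(pre, ".s1pw")]] <- glorot_uniform(c(1, 1, cin, w), cin, w)
    p[[paste0(pre, ".s1b")]] <- rep(0, w)
    add_bn(paste0(pre, ".bna"), w)
    p[[paste0(pre, ".s2dw")]] <- glorot_uniform(c(3, 3, w), 9, 9)
    p[[paste0(pre, ".s2pw")]] <- glorot_uniform(c(1, 1, w, w), w, w)
    p[[paste0(pre, ".s2b")]] <- rep(0, w)
    add_bn(paste0(pre, ".bnb"), w)
    p[[paste0(pre, ".pj.w")]] <- glorot_uniform(c(1, 1, cin, w), cin, w)
    p[[paste0(pre, ".pj.b")]] <- rep(0, w)
    cin <- w
  }
  p[["fin.dw"]] <- glorot_uniform(c(3, 3, cin), 9, 9)
  p[["fin.pw"]] <- glorot_uniform(c(1, 1, cin, fw), cin, fw)
  p[["fin.b"]] <- rep(0, fw)
  add_bn("bnf", fw)
  p[["out.w"]] <- glorot_uniform(c(fw, 1), fw, 1)
  p[["out.b"]] <- 0
  list(params = p, state = s)
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

nn_bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Forward pass. `x` is (3, H, W, N) in 0..255 (channel-fastest). Training mode uses batch
# statistics (and updates running moments); `dropout_mask` is an inverted
# dropout mask over the pooled features (final_width x N) or NULL.
nn_forward <- function(params, state, x, spec, training = FALSE,
                       dropout_mask = NULL, keep_cache = FALSE) {
  mom <- spec$bn_momentum
  eps <- spec$bn_eps
  cc <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  bn <- function(name, x) {
    r <- nn_bn_fwd(
      x, params[[paste0(name, ".g")]], params[[paste0(name, ".b")]],
      state[[paste0(name, ".rm")]], state[[paste0(name, ".rv")]],
      mom, eps, training
    )
    if (training) {
      state[[paste0(name, ".rm")]] <<- r$rmean
      state[[paste0(name, ".rv")]] <<- r$rvar
    }
    if (keep_cache) {
      assign(paste0(name, ".x"), x, envir = cc)
      assign(paste0(name, ".mean"), r$mean, envir = cc)
      assign(paste0(name, ".var"), r$var, envir = cc)
    }
    r$y
  }
  keep <- function(name, val) {
    if (keep_cache) assign(name, val, envir = cc)
    val
  }

  a0 <- keep("a0", x / 255)
  z1 <- nn_conv2d_fwd(a0, params[["c1.w"]], params[["c1.b"]], 2L)
  b1 <- keep("pre_relu1", bn("bn1", z1))
  r1 <- keep("r1", nn_relu_fwd(b1))
  z2 <- nn_conv2d_fwd(r1, params[["c2.w"]], params[["c2.b"]], 1L)
  b2 <- keep("pre_relu2", bn("bn2", z2))
  a <- nn_relu_fwd(b2)

  nb <- length(spec$middle_widths)
  for (k in seq_len(nb)) {
    pre <- sprintf("bk%d", k)
    keep(paste0(pre, ".in"), a)
    t0 <- keep(paste0(pre, ".t0"), nn_relu_fwd(a))
    t1 <- keep(paste0(pre, ".t1"), nn_dwconv_fwd(t0, params[[paste0(pre, ".s1dw")]]))
    t2 <- nn_conv2d_fwd(t1, params[[paste0(pre, ".s1pw")]], params[[paste0(pre, ".s1b")]], 1L)
    t3 <- keep(paste0(pre, ".t3"), bn(paste0(pre, ".bna"), t2))
    t4 <- keep(paste0(pre, ".t4"), nn_relu_fwd(t3))
    t5 <- keep(paste0(pre, ".t5"), nn_dwconv_fwd(t4, params[[paste0(pre, ".s2dw")]]))
    t6 <- nn_conv2d_fwd(t5, params[[paste0(pre, ".s2pw")]], params[[paste0(pre, ".s2b")]], 1L)
    t7 <- keep(paste0(pre, ".t7"), bn(paste0(pre, ".bnb"), t6))
    mp <- nn_maxpool_fwd(t7, 3L, 2L)
    if (keep_cache) {
      assign(paste0(pre, ".amax"), mp$argmax, envir = cc)
      assign(paste0(pre, ".t7dim"), dim(t7), envir = cc)
    }
    pr <- nn_conv2d_fwd(a, params[[paste0(pre, ".pj.w")]], params[[paste0(pre, ".pj.b")]], 2L)
    a <- mp$y + pr
  }

  f1 <- keep("fin.t1", nn_dwconv_fwd(keep("fin.in", a), params[["fin.dw"]]))
  f2 <- nn_conv2d_fwd(f1, params[["fin.pw"]], params[["fin.b"]], 1L)
  f3 <- keep("fin.pre_relu", bn("bnf", f2))
  f4 <- keep("fin.act", nn_relu_fwd(f3))
  g <- keep("gap", nn_gap_fwd(f4))
  gd <- if (is.null(dropout_mask)) g else g * dropout_mask
  keep("gap_dropped", gd)
  keep("fdim", dim(f4))
  logit <- drop(crossprod(params[["out.w"]], gd)) + params[["out.b"]]
  list(prob = nn_sigmoid(logit), logit = logit, cache = cc, state = state)
}

# Backward pass from d(loss)/d(logit). Returns gradients for every entry of
# `params` under the same names.
nn_backward <- function(params, spec, cache, dlogit, dropout_mask = NULL) {
  eps <- spec$bn_eps
  g <- list()
  cg <- function(n) get(n, envir = cache)

  gd <- cg("gap_dropped")
  dlogit <- matrix(dlogit, nrow = 1)
  g[["out.w"]] <- gd %*% t(dlogit)
  g[["out.b"]] <- sum(dlogit)
  dg <- params[["out.w"]] %*% dlogit # fw x N
  if (!is.null(dropout_mask)) dg <- dg * dropout_mask
  df4 <- nn_gap_bwd(dg, cg("fdim"))
  df3 <- nn_relu_bwd(cg("fin.pre_relu"), df4)
  bnb <- nn_bn_bwd(cg("bnf.x"), params[["bnf.g"]], cg("bnf.mean"), cg("bnf.var"), eps, df3)
  g[["bnf.g"]] <- bnb$dgamma
  g[["bnf.b"]] <- bnb$dbeta
  cb <- nn_conv2d_bwd(cg("fin.t1"), params[["fin.pw"]], bnb$dx, 1L)
  g[["fin.pw"]] <- cb$dw
  g[["fin.b"]] <- cb$db
  db <- nn_dwconv_bwd(cg("fin.in"), params[["fin.dw"]], cb$dx)
  g[["fin.dw"]] <- db$dw
  da <- db$dx

  nb <- length(spec$middle_widths)
  for (k in rev(seq_len(nb))) {
    pre <- sprintf("bk%d", k)
    a_in <- cg(paste0(pre, ".in"))
    pj <- nn_conv2d_bwd(a_in, params[[paste0(pre, ".pj.w")]], da, 2L)
    g[[paste0(pre, ".pj.w")]] <- pj$dw
    g[[paste0(pre, ".pj.b")]] <- pj$db
    dt7 <- nn_maxpool_bwd(da, cg(paste0(pre, ".amax")), cg(paste0(pre, ".t7dim")))
    bb <- nn_bn_bwd(
      cg(paste0(pre, ".bnb.x")), params[[paste0(pre, ".bnb.g")]],
      cg(paste0(pre, ".bnb.mean")), cg(paste0(pre, ".bnb.var")), eps, dt7
    )
    g[[paste0(pre, ".bnb.g")]] <- bb$dgamma
    g[[paste0(pre, ".bnb.b")]] <- bb$dbeta
    c2 <- nn_conv2d_bwd(cg(paste0(pre, ".t5")), params[[paste0(pre, ".s2pw")]], bb$dx, 1L)
    g[[paste0(pre, ".s2pw")]] <- c2$dw
    g[[paste0(pre, ".s2b")]] <- c2$db
    d2 <- nn_dwconv_bwd(cg(paste0(pre, ".t4")), params[[paste0(pre, ".s2dw")]], c2$dx)
    g[[paste0(pre, ".s2dw")]] <- d2$dw
    dt3 <- nn_relu_bwd(cg(paste0(pre, ".t3")), d2$dx)
    ba <- nn_bn_bwd(
      cg(paste0(pre, ".bna.x")), params[[paste0(pre, ".bna.g")]],
      cg(paste0(pre, ".bna.mean")), cg(paste0(pre, ".bna.var")), eps, dt3
    )
    g[[paste0(pre, ".bna.g")]] <- ba$dgamma
    g[[paste0(pre, ".bna.b")]] <- ba$dbeta
    c1 <- nn_conv2d_bwd(cg(paste0(pre, ".t1")), params[[paste0(pre, ".s1pw")]], ba$dx, 1L)
    g[[paste0(pre, ".s1pw")]] <- c1$dw
    g[[paste0(pre, ".s1b")]] <- c1$db
    d1 <- nn_dwconv_bwd(cg(paste0(pre, ".t0")), params[[paste0(pre, ".s1dw")]], c1$dx)
    g[[paste0(pre, ".s1dw")]] <- d1$dw
    da <- nn_relu_bwd(a_in, d1$dx) + pj$dx
  }

  db2 <- nn_relu_bwd(cg("pre_relu2"), da)
  bn2 <- nn_bn_bwd(cg("bn2.x"), params[["bn2.g"]], cg("bn2.mean"), cg("bn2.var"), eps, db2)
  g[["bn2.g"]] <- bn2$dgamma
  g[["bn2.b"]] <- bn2$dbeta
  cv2 <- nn_conv2d_bwd(cg("r1"), params[["c2.w"]], bn2$dx, 1L)
  g[["c2.w"]] <- cv2$dw
  g[["c2.b"]] <- cv2$db
  db1 <- nn_relu_bwd(cg("pre_relu1"), cv2$dx)
  bn1 <- nn_bn_bwd(cg("bn1.x"), params[["bn1.g"]], cg("bn1.mean"), cg("bn1.var"), eps, db1)
  g[["bn1.g"]] <- bn1$dgamma
  g[["bn1.b"]] <- bn1$dbeta
  cv1 <- nn_conv2d_bwd(cg("a0"), params[["c1.w"]], bn1$dx, 2L)
  g[["c1.w"]] <- cv1$dw
  g[["c1.b"]] <- cv1$db
  g
}

nn_adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

nn_adam_step <- function(params, grads, opt, lr = 0.001, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (n in names(params)) {
    gn <- grads[[n]]
    opt$m[[n]] <- beta1 * opt$m[[n]] + (1 - beta1) * gn
    opt$v[[n]] <- beta2 * opt$v[[n]] + (1 - beta2) * gn * gn
    mhat <- opt$m[[n]] / corr1
    vhat <- opt$v[[n]] / corr2
    params[[n]] <- params[[n]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# Stack a list of (H, W, 3) tiles into the channel-fastest (3, S, S, N)
# training layout, resizing each to the square network input first.
nn_stack_tiles <- function(tiles, input_size) {
  n <- length(tiles)
  out <- array(0, c(3L, input_size, input_size, n))
  for (i in seq_len(n)) {
    t <- tiles[[i]]
    d <- dim(t)
    if (d[1] != input_size || d[2] != input_size) {
      t <- nn_resize_bilinear(t, input_size, input_size)
    }
    out[, , , i] <- aperm(t, c(3, 1, 2))
  }
  out
}
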