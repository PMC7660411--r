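# Minimal dense-network engine: fully connected layers with optional batch
# normalization, ReLU / leaky-ReLU / tanh activations, residual blocks, and
# Adam. Everything operates on row-major minibatches (samples x features).
# Batch-norm conventions follow the common deep-learning defaults:
# eps = 1e-3, running-statistic momentum = 0.99, population batch variance.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# ---- layer constructors -----------------------------------------------------

# He-normal for rectifier layers, Glorot-uniform for tanh/linear outputs.
init_weight <- function(n_in, n_out, act) {
  if (act %in% c("relu", "lrelu")) {
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  } else {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
}

new_dense <- function(n_in, n_out, act = "relu", bn = FALSE) {
  par <- list(W = init_weight(n_in, n_out, act), b = numeric(n_out))
  if (bn) {
    par$gamma <- rep(1, n_out)
    par$beta <- numeric(n_out)
  }
  list(type = "dense", act = act, bn = bn, par = par,
       run = if (bn) list(mean = numeric(n_out), var = rep(1, n_out)) else NULL)
}

# Residual block: two width-preserving dense+BN layers, identity skip added
# before the final ReLU.
new_residual <- function(width) {
  list(type = "res",
       l1 = new_dense(width, width, act = "relu", bn = TRUE),
       l2 = new_dense(width, width, act = "linear", bn = TRUE))
}

new_net <- function(layers, n_in, n_out) {
  structure(list(layers = layers, n_in = n_in, n_out = n_out), class = "dense_net")
}

# ---- activations ------------------------------------------------------------

act_fwd <- function(z, act) {
  switch(act,
    relu   = pmax(z, 0),
    lrelu  = ifelse(z > 0, z, 0.2 * z),
    tanh   = tanh(z),
    linear = z,
    stop("unknown activation: ", act)
  )
}

act_bwd <- function(da, z, a, act) {
  switch(act,
    relu   = da * (z > 0),
    lrelu  = da * ifelse(z > 0, 1, 0.2),
    tanh   = da * (1 - a * a),
    linear = da,
    stop("unknown activation: ", act)
  )
}

# ---- forward / backward -----------------------------------------------------

# Forward through one layer. Returns list(out, cache, layer) -- `layer` is
# returned because training-mode batch norm updates running statistics.
layer_fwd <- function(layer, x, training) {
  if (layer$type == "res") {
    f1 <- layer_fwd(layer$l1, x, training)
    f2 <- layer_fwd(layer$l2, f1$out, training)
    s <- f2$out + x
    out <- pmax(s, 0)
    layer$l1 <- f1$layer; layer$l2 <- f2$layer
    return(list(out = out, layer = layer,
                cache = list(c1 = f1$cache, c2 = f2$cache, s = s, x = x)))
  }
  z <- x %*% layer$par$W
  z <- sweep(z, 2, layer$par$b, "+")
  cache <- list(x = x, z_pre = z)
  if (layer$bn) {
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(z * z) - mu * mu
      va <- pmax(va, 0)
      m <- BN_MOMENTUM
      layer$run$mean <- m * layer$run$mean + (1 - m) * mu
      layer$run$var  <- m * layer$run$var  + (1 - m) * va
    } else {
      mu <- layer$run$mean
      va <- layer$run$var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    xhat <- sweep(sweep(z, 2, mu, "-"), 2, inv_sd, "*")
    z <- sweep(sweep(xhat, 2, layer$par$gamma, "*"), 2, layer$par$beta, "+")
    cache$xhat <- xhat
    cache$inv_sd <- inv_sd
    cache$bn_training <- training
  }
  a <- act_fwd(z, layer$act)
  cache$z <- z
  cache$a <- a
  list(out = a, layer = layer, cache = cache)
}

# Backward through one layer: `da` is dL/d(out). Returns list(grads, dx);
# grads mirrors layer$par (or the residual sub-structure).
layer_bwd <- function(layer, cache, da) {
  if (layer$type == "res") {
    ds <- da * (cache$s > 0)
    b2 <- layer_bwd(layer$l2, cache$c2, ds)
    b1 <- layer_bwd(layer$l1, cache$c1, b2$dx)
    return(list(grads = list(l1 = b1$grads, l2 = b2$grads),
                dx = b1$dx + ds))
  }
  dz <- act_bwd(da, cache$z, cache$a, layer$act)
  # grads must mirror layer$par field-for-field (W, b[, gamma, beta])
  gamma_grad <- beta_grad <- NULL
  if (layer$bn) {
    gamma_grad <- colSums(dz * cache$xhat)
    beta_grad <- colSums(dz)
    dxhat <- sweep(dz, 2, layer$par$gamma, "*")
    if (isTRUE(cache$bn_training)) {
      m <- nrow(dz)
      t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dz <- sweep(t1 - t2, 2, cache$inv_sd, "*")
    } else {
      dz <- sweep(dxhat, 2, cache$inv_sd, "*")
    }
  }
  grads <- list(W = crossprod(cache$x, dz), b = colSums(dz))
  if (layer$bn) {
    grads$gamma <- gamma_grad
    grads$beta <- beta_grad
  }
  list(grads = grads, dx = dz %*% t(layer$par$W))
}

# Full-network forward. training = TRUE uses batch statistics (and updates
# running statistics); training = FALSE uses frozen running statistics.
net_fwd <- function(net, x, training = FALSE, keep_cache = FALSE) {
  if (ncol(x) != net$n_in) {
    stop(sprintf("input has %d features, network expects %d", ncol(x), net$n_in),
         call. = FALSE)
  }
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    f <- layer_fwd(net$layers[[i]], x, training)
    x <- f$out
    net$layers[[i]] <- f$layer
    if (keep_cache) caches[[i]] <- f$cache
  }
  list(out = x, net = net, caches = if (keep_cache) caches)
}

# Full-network backward from dL/d(output). Returns grads (list per layer,
# mirroring the parameter structure) and dL/d(input).
net_bwd <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (i in rev(seq_along(net$layers))) {
    b <- layer_bwd(net$layers[[i]], caches[[i]], dx)
    grads[[i]] <- b$grads
    dx <- b$dx
  }
  list(grads = grads, dx = dx)
}

# ---- parameter plumbing -----------------------------------------------------

# Extract / replace the trainable parameters of a network as a nested list
# of numeric leaves (one element per layer, mirroring what net_bwd returns).
net_params <- function(net) {
  lapply(net$layers, function(l) {
    if (l$type == "res") list(l1 = l$l1$par, l2 = l$l2$par) else l$par
  })
}

net_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    if (net$layers[[i]]$type == "res") {
      net$layers[[i]]$l1$par <- params[[i]]$l1
      net$layers[[i]]$l2$par <- params[[i]]$l2
    } else {
      net$layers[[i]]$par <- params[[i]]
    }
  }
  net
}

# Apply f elementwise over parallel nested lists of numeric leaves.
# Elements are matched by name when names are present, by position otherwise.
param_map <- function(f, ...) {
  args <- list(...)
  if (is.numeric(args[[1]])) return(do.call(f, args))
  keys <- names(args[[1]]) %||% seq_along(args[[1]])
  out <- vector("list", length(keys))
  names(out) <- names(args[[1]])
  for (i in seq_along(keys)) {
    out[[i]] <- do.call(param_map, c(list(f), lapply(args, `[[`, keys[[i]])))
  }
  out
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- param_map(function(p) p * 0, params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- network factories ------------------------------------------------------

# Multi-class expression classifier ("target model"): three ReLU dense
# layers (1024, 512, 128 by default, no batch norm) and a linear logit head.
make_target_net <- function(n_genes, n_classes, widths = c(1024L, 512L, 128L)) {
  dims <- c(n_genes, widths)
  layers <- lapply(seq_along(widths), function(i) {
    new_dense(dims[i], dims[i + 1], act = "relu", bn = FALSE)
  })
  layers <- c(layers, list(new_dense(dims[length(dims)], n_classes,
                                     act = "linear", bn = FALSE)))
  new_net(layers, n_genes, n_classes)
}

# Discriminator: three dense+BN+leaky-ReLU(0.2) layers and a single linear
# output unit (required by the least-squares GAN objective).
make_discriminator_net <- function(n_genes, widths = c(512L, 256L, 128L)) {
  dims <- c(n_genes, widths)
  layers <- lapply(seq_along(widths), function(i) {
    new_dense(dims[i], dims[i + 1], act = "lrelu", bn = TRUE)
  })
  layers <- c(layers, list(new_dense(dims[length(dims)], 1L,
                                     act = "linear", bn = FALSE)))
  new_net(layers, n_genes, 1L)
}

# Generator: hourglass encoder (512, 256, 128) with BN+ReLU, three
# width-128 residual blocks, decoder (256, 512) with BN+ReLU, and a tanh
# output layer without batch norm (BN would fight the [-1, 1] bound).
make_generator_net <- function(n_genes, encoder = c(512L, 256L, 128L),
                               n_residual = 3L, decoder = c(256L, 512L)) {
  dims <- c(n_genes, encoder)
  layers <- lapply(seq_along(encoder), function(i) {
    new_dense(dims[i], dims[i + 1], act = "relu", bn = TRUE)
  })
  width <- encoder[length(encoder)]
  layers <- c(layers, lapply(seq_len(n_residual), function(i) new_residual(width)))
  dims2 <- c(width, decoder)
  layers <- c(layers, lapply(seq_along(decoder), function(i) {
    new_dense(dims2[i], dims2[i + 1], act = "relu", bn = TRUE)
  }))
  layers <- c(layers, list(new_dense(dims2[length(dims2)], n_genes,
                                     act = "tanh", bn = FALSE)))
  new_net(layers, n_genes, n_genes)
}

# ---- shared numeric helpers -------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
}
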