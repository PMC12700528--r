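# Conditional normalizing flows: stacks of (transform, batch-norm,
# permutation) layers mapping parameters to base Gaussian noise given a
# conditioning feature vector. The MAF stack follows the published
# configuration (5 transforms, 2 blocks of 50 tanh units, batch
# normalization); the NSF stack uses 5 transforms with ReLU residual
# conditioners and 10 rational-quadratic spline bins.

new_flow <- function(family = c("maf", "nsf"), d, m, n_transforms = 5,
                     hidden = 50, n_bins = 10, tail_bound = 3, seed = 1) {
  family <- match.arg(family)
  layers <- list()
  with_seed(seed, {
    for (t in seq_len(n_transforms)) {
      layers[[length(layers) + 1]] <- if (family == "maf") {
        maf_layer_new(d, m, hidden)
      } else {
        nsf_layer_new(d, m, hidden, K = n_bins, B = tail_bound)
      }
      # MAF interleaves invertible batch norm; NSF a learnable affine, which
      # gives the spline stack a fast location/scale path
      layers[[length(layers) + 1]] <- if (family == "maf") {
        bn_layer_new(d)
      } else {
        affine_layer_new(d)
      }
      if (t < n_transforms)
        layers[[length(layers) + 1]] <- perm_layer_new(d)
    }
  })
  structure(list(family = family, d = d, m = m, layers = layers),
            class = "nf_flow")
}

flow_forward <- function(flow, x, y, training = FALSE) {
  n <- nrow(x)
  logdet <- numeric(n)
  caches <- vector("list", length(flow$layers))
  for (li in seq_along(flow$layers)) {
    layer <- flow$layers[[li]]
    fw <- switch(layer$type,
      maf = maf_forward(layer, x, y),
      nsf = nsf_forward(layer, x, y),
      bn = bn_forward(layer, x, training),
      affine = affine_forward(layer, x),
      perm = perm_forward(layer, x))
    x <- fw$u
    logdet <- logdet + fw$logdet
    caches[[li]] <- fw$cache
  }
  list(z = x, logdet = logdet, caches = caches)
}

# mean negative log-density loss and parameter gradients
flow_loss_grads <- function(flow, theta, y, training = TRUE) {
  n <- nrow(theta)
  fw <- flow_forward(flow, theta, y, training = training)
  z <- fw$z
  lp <- -0.5 * rowSums(z^2) - 0.5 * flow$d * log(2 * pi) + fw$logdet
  loss <- -mean(lp)
  gx <- z / n
  gld <- rep(-1 / n, n)
  grads <- vector("list", length(flow$layers))
  for (li in rev(seq_along(flow$layers))) {
    layer <- flow$layers[[li]]
    bk <- switch(layer$type,
      maf = maf_backward(layer, fw$caches[[li]], gx, gld),
      nsf = nsf_backward(layer, fw$caches[[li]], gx, gld),
      bn = bn_backward(layer, fw$caches[[li]], gx, gld),
      affine = affine_backward(layer, fw$caches[[li]], gx, gld),
      perm = list(gx = perm_backward(layer, gx), grads = list()))
    gx <- bk$gx
    grads[[li]] <- bk$grads
  }
  list(loss = loss, grads = grads, caches = fw$caches)
}

flow_log_prob <- function(flow, theta, y) {
  fw <- flow_forward(flow, theta, y, training = FALSE)
  -0.5 * rowSums(fw$z^2) - 0.5 * flow$d * log(2 * pi) + fw$logdet
}

flow_sample <- function(flow, y, n_draws, seed = 1) {
  z <- with_seed(seed, matrix(stats::rnorm(n_draws * flow$d), n_draws, flow$d))
  if (nrow(y) == 1) y <- y[rep(1, n_draws), , drop = FALSE]
  x <- z
  for (li in rev(seq_along(flow$layers))) {
    layer <- flow$layers[[li]]
    x <- switch(layer$type,
      maf = maf_inverse(layer, x, y),
      nsf = nsf_inverse(layer, x, y),
      bn = bn_inverse(layer, x),
      affine = affine_inverse(layer, x),
      perm = perm_inverse(layer, x))
  }
  x
}

# ---- Adam optimizer over the nested layer-parameter lists -------------------

adam_state_new <- function(flow) {
  lapply(flow$layers, function(layer) {
    lapply(layer$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(flow, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (li in seq_along(flow$layers)) {
    ps <- flow$layers[[li]]$params
    if (length(ps) == 0) next
    for (pn in names(ps)) {
      g <- grads[[li]][[pn]]
      st <- state[[li]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      flow$layers[[li]]$params[[pn]] <- ps[[pn]] - lr * mhat / (sqrt(vhat) + eps)
      state[[li]][[pn]] <- st
    }
  }
  list(flow = flow, state = state)
}

# ---- training loop with validation early stopping ---------------------------

train_flow <- function(flow, theta, y, batch_size = 256, lr = 5e-4,
                       max_epochs = 500, patience = 20, val_frac = 0.1,
                       seed = 1, verbose = FALSE) {
  n <- nrow(theta)
  idx <- with_seed(derive_seed(seed, 101), sample.int(n))
  n_val <- max(1L, floor(val_frac * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  state <- adam_state_new(flow)
  best <- list(loss = Inf, flow = flow, epoch = 0)
  history <- numeric(0)
  t_step <- 0
  for (epoch in seq_len(max_epochs)) {
    ord <- with_seed(derive_seed(seed, 1000 + epoch), sample(tr_idx))
    nb <- ceiling(length(ord) / batch_size)
    for (b in seq_len(nb)) {
      take <- ord[((b - 1) * batch_size + 1):min(b * batch_size, length(ord))]
      if (length(take) < 2) next
      lg <- flow_loss_grads(flow, theta[take, , drop = FALSE],
                            y[take, , drop = FALSE], training = TRUE)
      if (!is.finite(lg$loss))
        stop("flow training produced a non-finite loss at epoch ", epoch,
             "; inspect feature scaling")
      t_step <- t_step + 1
      up <- adam_step(flow, lg$grads, state, lr, t_step)
      flow <- up$flow
      state <- up$state
      # refresh batch-norm running statistics
      for (li in seq_along(flow$layers)) {
        if (flow$layers[[li]]$type == "bn")
          flow$layers[[li]] <- bn_update_running(flow$layers[[li]], lg$caches[[li]])
      }
    }
    val_lp <- flow_log_prob(flow, theta[val_idx, , drop = FALSE],
                            y[val_idx, , drop = FALSE])
    val_loss <- -mean(val_lp)
    history <- c(history, val_loss)
    if (is.finite(val_loss) && val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, flow = flow, epoch = epoch)
    } else if (epoch - best$epoch >= patience) {
      break
    }
    if (verbose && epoch %% 10 == 0)
      message(sprintf("epoch %d: val loss %.4f (best %.4f)", epoch, val_loss,
                      best$loss))
  }
  list(flow = best$flow, val_loss = best$loss, history = history,
       epochs_run = length(history))
}
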