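# Layer-level machinery for the conditional normalizing flows.
#
# Conventions: the "density direction" maps parameters theta (n x d) to base
# noise z with accumulated log|det J|; loss is the mean negative conditional
# log-density. Every layer implements forward (with cache) and backward
# (returning input gradients and parameter gradients); gradients are exact
# and are checked against finite differences in the test suite.

# ---- masked autoregressive (MADE) degrees and masks -------------------------

made_degrees <- function(d, hidden) {
  din <- seq_len(d)
  dh <- if (d == 1) rep(0L, hidden) else rep(seq_len(d - 1L), length.out = hidden)
  list(input = din, hidden = dh, output = seq_len(d))
}

# mask for input -> hidden: connect when hidden degree >= input degree
# mask hidden -> hidden: >= ; mask hidden -> output: output degree > hidden
made_masks <- function(d, hidden) {
  dg <- made_degrees(d, hidden)
  M1 <- outer(dg$input, dg$hidden, `<=`) * 1
  M2 <- outer(dg$hidden, dg$hidden, `<=`) * 1
  Mo <- outer(dg$hidden, dg$output, `<`) * 1
  list(M1 = M1, M2 = M2, Mo = Mo)
}

rand_mat <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)

# ---- MAF transform (Gaussian MADE): u = (x - mu) * exp(-alpha) --------------

ALPHA_CAP <- 6 # soft cap keeps exp(alpha) bounded during early training

maf_layer_new <- function(d, m, hidden = 50) {
  mk <- made_masks(d, hidden)
  list(type = "maf", d = d, m = m, hidden = hidden, masks = mk,
       params = list(
         W1 = rand_mat(d, hidden, sqrt(1 / max(1, d))) * mk$M1,
         V1 = rand_mat(m, hidden, sqrt(1 / max(1, m))),
         b1 = numeric(hidden),
         W2 = rand_mat(hidden, hidden, sqrt(1 / hidden)) * mk$M2,
         b2 = numeric(hidden),
         Wmu = rand_mat(hidden, d, 0.01) * mk$Mo,
         bmu = numeric(d),
         Wa = rand_mat(hidden, d, 0.01) * mk$Mo,
         ba = numeric(d)
       ))
}

maf_made <- function(layer, x, y) {
  p <- layer$params
  a1 <- x %*% (p$W1 * layer$masks$M1) + y %*% p$V1 +
    matrix(p$b1, nrow(x), layer$hidden, byrow = TRUE)
  h1 <- tanh(a1)
  a2 <- h1 %*% (p$W2 * layer$masks$M2) +
    matrix(p$b2, nrow(x), layer$hidden, byrow = TRUE)
  h2 <- tanh(a2)
  mu <- h2 %*% (p$Wmu * layer$masks$Mo) + matrix(p$bmu, nrow(x), layer$d, byrow = TRUE)
  ahat <- h2 %*% (p$Wa * layer$masks$Mo) + matrix(p$ba, nrow(x), layer$d, byrow = TRUE)
  alpha <- ALPHA_CAP * tanh(ahat / ALPHA_CAP)
  list(mu = mu, alpha = alpha, ahat = ahat, h1 = h1, h2 = h2)
}

maf_forward <- function(layer, x, y) {
  md <- maf_made(layer, x, y)
  u <- (x - md$mu) * exp(-md$alpha)
  logdet <- -rowSums(md$alpha)
  list(u = u, logdet = logdet,
       cache = list(x = x, y = y, md = md, u = u))
}

# gu: dL/du (n x d); gld: dL/dlogdet_i (n)
maf_backward <- function(layer, cache, gu, gld) {
  p <- layer$params
  md <- cache$md
  x <- cache$x
  ea <- exp(-md$alpha)
  gmu <- -gu * ea
  galpha <- -gu * cache$u - matrix(gld, nrow(x), layer$d)
  gahat <- galpha * (1 - (md$alpha / ALPHA_CAP)^2)
  gx_direct <- gu * ea

  Mo <- layer$masks$Mo
  gh2 <- gmu %*% t(p$Wmu * Mo) + gahat %*% t(p$Wa * Mo)
  ga2 <- gh2 * (1 - md$h2^2)
  gh1 <- ga2 %*% t(p$W2 * layer$masks$M2)
  ga1 <- gh1 * (1 - md$h1^2)
  gx_made <- ga1 %*% t(p$W1 * layer$masks$M1)

  grads <- list(
    W1 = (t(x) %*% ga1) * layer$masks$M1,
    V1 = t(cache$y) %*% ga1,
    b1 = colSums(ga1),
    W2 = (t(md$h1) %*% ga2) * layer$masks$M2,
    b2 = colSums(ga2),
    Wmu = (t(md$h2) %*% gmu) * Mo,
    bmu = colSums(gmu),
    Wa = (t(md$h2) %*% gahat) * Mo,
    ba = colSums(gahat)
  )
  list(gx = gx_direct + gx_made, grads = grads)
}

# invert u -> x given context: autoregressive, one dimension per pass
maf_inverse <- function(layer, u, y) {
  x <- matrix(0, nrow(u), layer$d)
  for (i in seq_len(layer$d)) {
    md <- maf_made(layer, x, y)
    x[, i] <- u[, i] * exp(md$alpha[, i]) + md$mu[, i]
  }
  x
}

# ---- invertible batch normalization -----------------------------------------

BN_EPS <- 1e-5

bn_layer_new <- function(d) {
  list(type = "bn", d = d,
       params = list(gamma = numeric(d), beta = numeric(d)),
       running = list(mean = numeric(d), var = rep(1, d)))
}

bn_forward <- function(layer, x, training) {
  n <- nrow(x)
  if (training && n > 1) {
    m <- colMeans(x)
    v <- colMeans(x^2) - m^2
    v <- pmax(v, 0)
  } else {
    m <- layer$running$mean
    v <- layer$running$var
  }
  s <- sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2, m), 2, s, "/")
  g <- exp(layer$params$gamma)
  u <- sweep(sweep(xhat, 2, g, "*"), 2, layer$params$beta, "+")
  logdet <- rep(sum(layer$params$gamma) - 0.5 * sum(log(v + BN_EPS)), n)
  list(u = u, logdet = logdet,
       cache = list(x = x, xhat = xhat, m = m, v = v, s = s,
                    batch_stats = training && n > 1))
}

bn_backward <- function(layer, cache, gu, gld) {
  n <- nrow(cache$x)
  g <- exp(layer$params$gamma)
  gxhat <- sweep(gu, 2, g, "*")
  gld_tot <- sum(gld)
  gbeta <- colSums(gu)
  ggamma <- colSums(gu * cache$xhat) * g + gld_tot * 1
  if (cache$batch_stats) {
    xm <- sweep(cache$x, 2, cache$m)
    gv <- colSums(gxhat * xm) * (-0.5) * (cache$v + BN_EPS)^(-1.5) +
      gld_tot * (-0.5) / (cache$v + BN_EPS)
    gm <- colSums(gxhat) * (-1 / cache$s)
    gx <- sweep(gxhat, 2, cache$s, "/") +
      sweep(xm, 2, gv * 2 / n, "*") +
      matrix(gm / n, n, layer$d, byrow = TRUE)
  } else {
    gx <- sweep(gxhat, 2, cache$s, "/")
  }
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

bn_update_running <- function(layer, cache, momentum = 0.1) {
  if (cache$batch_stats) {
    layer$running$mean <- (1 - momentum) * layer$running$mean + momentum * cache$m
    layer$running$var <- (1 - momentum) * layer$running$var + momentum * cache$v
  }
  layer
}

bn_inverse <- function(layer, u) {
  g <- exp(layer$params$gamma)
  s <- sqrt(layer$running$var + BN_EPS)
  xhat <- sweep(sweep(u, 2, layer$params$beta), 2, g, "/")
  sweep(sweep(xhat, 2, s, "*"), 2, layer$running$mean, "+")
}

# ---- dimension-reversal permutation -----------------------------------------

perm_layer_new <- function(d) {
  list(type = "perm", d = d, perm = rev(seq_len(d)), params = list())
}

perm_forward <- function(layer, x) {
  list(u = x[, layer$perm, drop = FALSE], logdet = rep(0, nrow(x)),
       cache = NULL)
}

perm_backward <- function(layer, gu) {
  gx <- gu
  gx[, layer$perm] <- gu
  gx
}

perm_inverse <- function(layer, u) {
  x <- u
  x[, layer$perm] <- u
  x
}

# ---- learnable per-dimension affine (ActNorm-style) -------------------------

affine_layer_new <- function(d) {
  list(type = "affine", d = d, params = list(gamma = numeric(d), beta = numeric(d)))
}

affine_forward <- function(layer, x) {
  g <- exp(layer$params$gamma)
  u <- sweep(sweep(x, 2, g, "*"), 2, layer$params$beta, "+")
  list(u = u, logdet = rep(sum(layer$params$gamma), nrow(x)),
       cache = list(x = x))
}

affine_backward <- function(layer, cache, gu, gld) {
  g <- exp(layer$params$gamma)
  ggamma <- colSums(gu * cache$x) * g + sum(gld)
  gbeta <- colSums(gu)
  gx <- sweep(gu, 2, g, "*")
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

affine_inverse <- function(layer, u) {
  sweep(sweep(u, 2, layer$params$beta), 2, exp(layer$params$gamma), "/")
}
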