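# Monotone rational-quadratic spline transform (the element of a neural
# spline flow): K bins on [-B, B], identity tails, raw parameters mapped
# through softmax (widths, heights) and softplus (interior knot derivatives).
# Forward, exact gradients, and the analytic inverse.

SPLINE_MIN_BIN <- 1e-3
SPLINE_MIN_DERIV <- 1e-3

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# raw: n x (3K - 1) slice for one dimension; returns knot/derivative arrays
spline_params <- function(raw, K, B) {
  n <- nrow(raw)
  rw <- raw[, 1:K, drop = FALSE]
  rh <- raw[, (K + 1):(2 * K), drop = FALSE]
  rd <- raw[, (2 * K + 1):(3 * K - 1), drop = FALSE]
  smax <- function(r) {
    e <- exp(r - apply(r, 1, max))
    e / rowSums(e)
  }
  sw <- smax(rw)
  sh <- smax(rh)
  widths <- SPLINE_MIN_BIN * 2 * B + (1 - K * SPLINE_MIN_BIN) * 2 * B * sw
  heights <- SPLINE_MIN_BIN * 2 * B + (1 - K * SPLINE_MIN_BIN) * 2 * B * sh
  xk <- cbind(-B, -B + t(apply(widths, 1, cumsum)))
  yk <- cbind(-B, -B + t(apply(heights, 1, cumsum)))
  xk[, K + 1] <- B
  yk[, K + 1] <- B
  derivs <- cbind(1, SPLINE_MIN_DERIV + softplus(rd), 1)
  list(sw = sw, sh = sh, widths = widths, heights = heights,
       xk = xk, yk = yk, derivs = derivs, rd = rd, n = n)
}

# forward pass for one dimension; x is a length-n vector
spline_forward_dim <- function(x, raw, K, B) {
  sp <- spline_params(raw, K, B)
  n <- length(x)
  inside <- x > -B & x < B
  u <- x
  logdet <- numeric(n)
  cache <- list(sp = sp, inside = inside, K = K, B = B, x = x)
  if (any(inside)) {
    idx <- which(inside)
    # bin index per element
    bin <- vapply(idx, function(i) {
      as.integer(max(1L, min(K, findInterval(x[i], sp$xk[i, ],
                                             rightmost.closed = TRUE))))
    }, integer(1))
    pick <- cbind(idx, bin)
    xk <- sp$xk[pick]; wk <- sp$widths[pick]
    yk <- sp$yk[pick]; hk <- sp$heights[pick]
    d0 <- sp$derivs[pick]; d1 <- sp$derivs[cbind(idx, bin + 1L)]
    xi <- (x[idx] - xk) / wk
    t1 <- xi * (1 - xi)
    s <- hk / wk
    D <- s + (d0 + d1 - 2 * s) * t1
    N <- hk * (s * xi^2 + d0 * t1)
    u[idx] <- yk + N / D
    Q <- d1 * xi^2 + 2 * s * t1 + d0 * (1 - xi)^2
    logdet[idx] <- 2 * log(s) + log(Q) - 2 * log(D)
    cache <- c(cache, list(idx = idx, bin = bin, xk = xk, wk = wk, yk = yk,
                           hk = hk, d0 = d0, d1 = d1, xi = xi, t1 = t1,
                           s = s, D = D, N = N, Q = Q))
  }
  list(u = u, logdet = logdet, cache = cache)
}

# gu, gld: length-n gradients wrt u and this dimension's logdet.
# Returns graw (n x (3K-1)) and gx (length n).
spline_backward_dim <- function(cache, gu, gld) {
  K <- cache$K; B <- cache$B
  sp <- cache$sp
  n <- sp$n
  gx <- gu # identity tails
  graw <- matrix(0, n, 3 * K - 1)
  if (is.null(cache$idx) || length(cache$idx) == 0)
    return(list(graw = graw, gx = gx))
  idx <- cache$idx
  xi <- cache$xi; t1 <- cache$t1; s <- cache$s
  D <- cache$D; N <- cache$N; Q <- cache$Q
  d0 <- cache$d0; d1 <- cache$d1
  wk <- cache$wk; hk <- cache$hk
  cpl <- d0 + d1 - 2 * s

  dN_dxi <- hk * (2 * s * xi + d0 * (1 - 2 * xi))
  dD_dxi <- cpl * (1 - 2 * xi)
  du_dxi <- (dN_dxi * D - N * dD_dxi) / D^2
  dN_ds <- hk * xi^2
  dD_ds <- 1 - 2 * t1
  du_ds <- (dN_ds * D - N * dD_ds) / D^2
  du_dd0 <- (hk * t1 * D - N * t1) / D^2
  du_dd1 <- -N * t1 / D^2
  du_dhk <- (N / hk) / D + du_ds / wk
  du_dwk <- du_dxi * (-xi / wk) + du_ds * (-s / wk)
  du_dxk <- -du_dxi / wk
  du_dyk <- 1

  dQ_dxi <- 2 * d1 * xi + 2 * s * (1 - 2 * xi) - 2 * d0 * (1 - xi)
  dl_dxi <- dQ_dxi / Q - 2 * dD_dxi / D
  dl_ds <- 2 / s + 2 * t1 / Q - 2 * dD_ds / D
  dl_dd0 <- (1 - xi)^2 / Q - 2 * t1 / D
  dl_dd1 <- xi^2 / Q - 2 * t1 / D
  dl_dhk <- dl_ds / wk
  dl_dwk <- dl_dxi * (-xi / wk) + dl_ds * (-s / wk)
  dl_dxk <- -dl_dxi / wk

  gui <- gu[idx]; gli <- gld[idx]
  g_xk <- gui * du_dxk + gli * dl_dxk
  g_wk <- gui * du_dwk + gli * dl_dwk
  g_yk <- gui * du_dyk
  g_hk <- gui * du_dhk + gli * dl_dhk
  g_d0 <- gui * du_dd0 + gli * dl_dd0
  g_d1 <- gui * du_dd1 + gli * dl_dd1
  gx[idx] <- gui * du_dxi / wk + gli * dl_dxi / wk

  # chain to the K widths/heights: knot position gets all earlier bins
  bin <- cache$bin
  gW <- matrix(0, n, K)   # grads wrt bin widths
  gH <- matrix(0, n, K)
  for (jj in seq_along(idx)) {
    i <- idx[jj]; b <- bin[jj]
    if (b > 1) {
      gW[i, 1:(b - 1)] <- g_xk[jj]
      gH[i, 1:(b - 1)] <- g_yk[jj]
    }
    gW[i, b] <- gW[i, b] + g_wk[jj]
    gH[i, b] <- gH[i, b] + g_hk[jj]
  }
  # derivatives: interior knots 2..K map to raw columns 1..K-1
  gDv <- matrix(0, n, K + 1)
  gDv[cbind(idx, bin)] <- g_d0
  gDv[cbind(idx, bin + 1L)] <- gDv[cbind(idx, bin + 1L)] + g_d1

  # softmax chains
  scale <- (1 - K * SPLINE_MIN_BIN) * 2 * B
  smax_back <- function(gOut, sm) {
    inner <- rowSums(gOut * sm)
    scale * sm * (gOut - inner)
  }
  graw[, 1:K] <- smax_back(gW, sp$sw)
  graw[, (K + 1):(2 * K)] <- smax_back(gH, sp$sh)
  gInterior <- gDv[, 2:K, drop = FALSE]
  graw[, (2 * K + 1):(3 * K - 1)] <- gInterior * stats::plogis(sp$rd)
  list(graw = graw, gx = gx)
}

# analytic inverse for one dimension
spline_inverse_dim <- function(u, raw, K, B) {
  sp <- spline_params(raw, K, B)
  x <- u
  inside <- u > -B & u < B
  if (any(inside)) {
    idx <- which(inside)
    bin <- vapply(idx, function(i) {
      as.integer(max(1L, min(K, findInterval(u[i], sp$yk[i, ],
                                             rightmost.closed = TRUE))))
    }, integer(1))
    pick <- cbind(idx, bin)
    xk <- sp$xk[pick]; wk <- sp$widths[pick]
    yk <- sp$yk[pick]; hk <- sp$heights[pick]
    d0 <- sp$derivs[pick]; d1 <- sp$derivs[cbind(idx, bin + 1L)]
    s <- hk / wk
    dy <- u[idx] - yk
    cpl <- d0 + d1 - 2 * s
    a <- hk * (s - d0) + dy * cpl
    b <- hk * d0 - dy * cpl
    cc <- -s * dy
    disc <- pmax(b^2 - 4 * a * cc, 0)
    xi <- 2 * cc / (-b - sqrt(disc))
    xi <- pmin(pmax(xi, 0), 1)
    x[idx] <- xk + xi * wk
  }
  x
}

# ---- NSF transform: MADE conditioner (ReLU, residual block) -> splines -----

nsf_layer_new <- function(d, m, hidden = 50, K = 10, B = 3) {
  mk <- made_masks(d, hidden)
  P <- 3 * K - 1
  # output mask expanded over the P spline parameters of each dimension
  Mo_big <- mk$Mo[, rep(seq_len(d), each = P), drop = FALSE]
  list(type = "nsf", d = d, m = m, hidden = hidden, K = K, B = B,
       masks = list(M1 = mk$M1, M2 = mk$M2, Mo = Mo_big),
       params = list(
         W1 = rand_mat(d, hidden, sqrt(1 / max(1, d))) * mk$M1,
         V1 = rand_mat(m, hidden, sqrt(1 / max(1, m))),
         b1 = numeric(hidden),
         W2 = rand_mat(hidden, hidden, sqrt(1 / hidden)) * mk$M2,
         b2 = numeric(hidden),
         Wo = rand_mat(hidden, d * P, 0.001) * Mo_big,
         bo = numeric(d * P)
       ))
}

relu <- function(x) pmax(x, 0)

nsf_conditioner <- function(layer, x, y) {
  p <- layer$params
  a1 <- x %*% (p$W1 * layer$masks$M1) + y %*% p$V1 +
    matrix(p$b1, nrow(x), layer$hidden, byrow = TRUE)
  h1 <- relu(a1)
  a2 <- h1 %*% (p$W2 * layer$masks$M2) +
    matrix(p$b2, nrow(x), layer$hidden, byrow = TRUE)
  h2 <- relu(a2) + h1 # residual block (degrees equal across hidden layers)
  raw <- h2 %*% (p$Wo * layer$masks$Mo) +
    matrix(p$bo, nrow(x), ncol(p$Wo), byrow = TRUE)
  list(a1 = a1, h1 = h1, a2 = a2, h2 = h2, raw = raw)
}

nsf_forward <- function(layer, x, y) {
  cond <- nsf_conditioner(layer, x, y)
  K <- layer$K; P <- 3 * K - 1
  n <- nrow(x)
  u <- matrix(0, n, layer$d)
  logdet <- numeric(n)
  dim_caches <- vector("list", layer$d)
  for (j in seq_len(layer$d)) {
    raw_j <- cond$raw[, ((j - 1) * P + 1):(j * P), drop = FALSE]
    fw <- spline_forward_dim(x[, j], raw_j, K, layer$B)
    u[, j] <- fw$u
    logdet <- logdet + fw$logdet
    dim_caches[[j]] <- fw$cache
  }
  list(u = u, logdet = logdet,
       cache = list(x = x, y = y, cond = cond, dim_caches = dim_caches))
}

nsf_backward <- function(layer, cache, gu, gld) {
  K <- layer$K; P <- 3 * K - 1
  n <- nrow(cache$x)
  graw <- matrix(0, n, layer$d * P)
  gx <- matrix(0, n, layer$d)
  for (j in seq_len(layer$d)) {
    bk <- spline_backward_dim(cache$dim_caches[[j]], gu[, j], gld)
    graw[, ((j - 1) * P + 1):(j * P)] <- bk$graw
    gx[, j] <- gx[, j] + bk$gx
  }
  p <- layer$params
  cond <- cache$cond
  gh2 <- graw %*% t(p$Wo * layer$masks$Mo)
  ga2 <- gh2 * (cond$a2 > 0)
  gh1 <- ga2 %*% t(p$W2 * layer$masks$M2) + gh2 # residual path
  ga1 <- gh1 * (cond$a1 > 0)
  gx <- gx + ga1 %*% t(p$W1 * layer$masks$M1)
  grads <- list(
    W1 = (t(cache$x) %*% ga1) * layer$masks$M1,
    V1 = t(cache$y) %*% ga1,
    b1 = colSums(ga1),
    W2 = (t(cond$h1) %*% ga2) * layer$masks$M2,
    b2 = colSums(ga2),
    Wo = (t(cond$h2) %*% graw) * layer$masks$Mo,
    bo = colSums(graw)
  )
  list(gx = gx, grads = grads)
}

nsf_inverse <- function(layer, u, y) {
  K <- layer$K; P <- 3 * K - 1
  x <- matrix(0, nrow(u), layer$d)
  for (i in seq_len(layer$d)) {
    cond <- nsf_conditioner(layer, x, y)
    raw_i <- cond$raw[, ((i - 1) * P + 1):(i * P), drop = FALSE]
    x[, i] <- spline_inverse_dim(u[, i], raw_i, K, layer$B)
  }
  x
}
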