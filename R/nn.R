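# Minimal neural-network engine: the layer primitives, forward/backward
# passes, binary cross-entropy on logits, and Adam.  Everything operates on
# batches: window inputs are N x L x C arrays, dense activations N x D
# matrices.  All randomness (init, shuffling, dropout) draws from the
# session RNG so training is reproducible under set.seed().
#
# Implemented from first principles because the classifier families and
# their train/predict contracts are the package's core; gradients are
# verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out, dims = c(n_in, n_out)) {
  lim <- sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

## ---- layer constructors (parameters + shape bookkeeping) -----------------

nn_dense <- function(n_in, n_out, activation = c("identity", "relu")) {
  list(kind = "dense", activation = match.arg(activation),
       W = glorot(n_in, n_out), b = numeric(n_out))
}

nn_flatten <- function() list(kind = "flatten")

nn_dropout <- function(rate) list(kind = "dropout", rate = rate)

nn_conv1d <- function(n_in_channels, n_filters, kernel) {
  # "same" padding, stride 1, ReLU applied by a separate layer if desired
  list(kind = "conv1d", K = kernel, C = n_in_channels, F = n_filters,
       W = glorot(kernel * n_in_channels, n_filters,
                  dims = c(kernel, n_in_channels, n_filters)),
       b = numeric(n_filters))
}

nn_relu <- function() list(kind = "relu")

nn_maxpool <- function(size = 2L) list(kind = "maxpool", size = as.integer(size))

nn_lstm <- function(n_in, n_hidden, return_seq = FALSE) {
  H <- n_hidden
  l <- list(kind = "lstm", H = H, return_seq = return_seq,
            Wx = glorot(n_in, 4 * H, dims = c(n_in, 4 * H)),
            Wh = glorot(H, 4 * H, dims = c(H, 4 * H)),
            b = numeric(4 * H))
  l$b[(H + 1):(2 * H)] <- 1        # forget-gate bias starts open
  l
}

nn_gru <- function(n_in, n_hidden, return_seq = FALSE) {
  H <- n_hidden
  list(kind = "gru", H = H, return_seq = return_seq,
       Wx = glorot(n_in, 3 * H, dims = c(n_in, 3 * H)),
       Wh = glorot(H, 3 * H, dims = c(H, 3 * H)),
       b = numeric(3 * H))
}

## ---- forward -------------------------------------------------------------

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$kind,
    flatten = {
      n <- dim(x)[1]
      list(out = matrix(x, nrow = n), cache = dim(x))
    },
    dense = {
      z <- x %*% layer$W
      z <- sweep(z, 2, layer$b, `+`)
      if (layer$activation == "relu") {
        out <- pmax(z, 0)
        list(out = out, cache = list(x = x, z = z))
      } else {
        list(out = z, cache = list(x = x))
      }
    },
    relu = list(out = pmax(x, 0), cache = x > 0),
    dropout = {
      if (train && layer$rate > 0) {
        keep <- array(stats::runif(length(x)) >= layer$rate, dim = dim(x))
        list(out = x * keep / (1 - layer$rate), cache = keep)
      } else {
        list(out = x, cache = NULL)
      }
    },
    conv1d = conv1d_forward(layer, x),
    maxpool = maxpool_forward(layer, x),
    lstm = lstm_forward(layer, x),
    gru = gru_forward(layer, x),
    stop("unknown layer kind: ", layer$kind)
  )
}

conv1d_forward <- function(layer, x) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  K <- layer$K
  pad_l <- (K - 1L) %/% 2L           # "same" output length
  pad_r <- K - 1L - pad_l
  xp <- array(0, dim = c(n, L + pad_l + pad_r, C))
  xp[, pad_l + seq_len(L), ] <- x
  out <- matrix(0, n * L, layer$F)
  for (k in seq_len(K)) {
    slice <- matrix(xp[, k - 1L + seq_len(L), , drop = FALSE], nrow = n * L)
    out <- out + slice %*% matrix(layer$W[k, , ], nrow = C)
  }
  out <- sweep(out, 2, layer$b, `+`)
  list(out = array(out, dim = c(n, L, layer$F)),
       cache = list(xp = xp, L = L, pad_l = pad_l))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  P <- L %/% layer$size
  x <- x[, seq_len(P * layer$size), , drop = FALSE]
  x1 <- x[, seq(1, P * 2, by = 2), , drop = FALSE]
  x2 <- x[, seq(2, P * 2, by = 2), , drop = FALSE]
  take_first <- x1 >= x2
  list(out = ifelse(take_first, x1, x2),
       cache = list(take_first = take_first, L = L))
}

lstm_forward <- function(layer, x) {
  d <- dim(x); n <- d[1]; L <- d[2]; H <- layer$H
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  caches <- vector("list", L)
  seq_out <- if (layer$return_seq) array(0, dim = c(n, L, H)) else NULL
  # input projections for every timestep in one matmul; row block t of the
  # (n*L) x C matrix view corresponds to timestep t (column-major layout)
  px <- matrix(x, nrow = n * L) %*% layer$Wx
  for (t in seq_len(L)) {
    a <- px[(t - 1L) * n + seq_len(n), , drop = FALSE] + h %*% layer$Wh
    a <- sweep(a, 2, layer$b, `+`)
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(a[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    caches[[t]] <- list(h_prev = h_prev, c_prev = c_prev,
                        i = i, f = f, o = o, g = g, tc = tc)
    if (layer$return_seq) seq_out[, t, ] <- h
  }
  list(out = if (layer$return_seq) seq_out else h,
       cache = list(steps = caches, L = L, n = n, x = x))
}

gru_forward <- function(layer, x) {
  d <- dim(x); n <- d[1]; L <- d[2]; H <- layer$H
  h <- matrix(0, n, H)
  caches <- vector("list", L)
  seq_out <- if (layer$return_seq) array(0, dim = c(n, L, H)) else NULL
  px <- matrix(x, nrow = n * L) %*% layer$Wx
  for (t in seq_len(L)) {
    rows <- (t - 1L) * n + seq_len(n)
    a <- px[rows, 1:(2 * H), drop = FALSE] +
      h %*% layer$Wh[, 1:(2 * H), drop = FALSE]
    a <- sweep(a, 2, layer$b[1:(2 * H)], `+`)
    z <- sigmoid(a[, 1:H, drop = FALSE])
    r <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    rh <- r * h
    ac <- px[rows, (2 * H + 1):(3 * H), drop = FALSE] +
      rh %*% layer$Wh[, (2 * H + 1):(3 * H), drop = FALSE]
    ac <- sweep(ac, 2, layer$b[(2 * H + 1):(3 * H)], `+`)
    cand <- tanh(ac)
    h_prev <- h
    h <- z * h_prev + (1 - z) * cand
    caches[[t]] <- list(h_prev = h_prev, z = z, r = r,
                        rh = rh, cand = cand)
    if (layer$return_seq) seq_out[, t, ] <- h
  }
  list(out = if (layer$return_seq) seq_out else h,
       cache = list(steps = caches, L = L, n = n, x = x))
}

## ---- backward ------------------------------------------------------------

# returns list(grads = <same shapes as layer params or NULL>, dx = ...)
layer_backward <- function(layer, dout, cache) {
  switch(layer$kind,
    flatten = list(grads = NULL, dx = array(dout, dim = cache)),
    dense = {
      x <- cache$x
      if (layer$activation == "relu") dout <- dout * (cache$z > 0)
      list(grads = list(W = crossprod(x, dout), b = colSums(dout)),
           dx = dout %*% t(layer$W))
    },
    relu = list(grads = NULL, dx = dout * cache),
    dropout = {
      if (is.null(cache)) list(grads = NULL, dx = dout)
      else list(grads = NULL, dx = dout * cache / (1 - layer$rate))
    },
    conv1d = conv1d_backward(layer, dout, cache),
    maxpool = maxpool_backward(layer, dout, cache),
    lstm = lstm_backward(layer, dout, cache),
    gru = gru_backward(layer, dout, cache),
    stop("unknown layer kind: ", layer$kind)
  )
}

conv1d_backward <- function(layer, dout, cache) {
  xp <- cache$xp; L <- cache$L; pad_l <- cache$pad_l
  d <- dim(xp); n <- d[1]; Lp <- d[2]; C <- d[3]
  K <- layer$K
  dmat <- matrix(dout, nrow = n * L)          # (n*L) x F
  dW <- array(0, dim = dim(layer$W))
  dxp <- array(0, dim = d)
  for (k in seq_len(K)) {
    cols <- k - 1L + seq_len(L)
    slice <- matrix(xp[, cols, , drop = FALSE], nrow = n * L)
    dW[k, , ] <- crossprod(slice, dmat)
    dslice <- dmat %*% t(matrix(layer$W[k, , ], nrow = C))
    dxp[, cols, ] <- dxp[, cols, , drop = FALSE] +
      array(dslice, dim = c(n, L, C))
  }
  list(grads = list(W = dW, b = colSums(dmat)),
       dx = dxp[, pad_l + seq_len(L), , drop = FALSE])
}

maxpool_backward <- function(layer, dout, cache) {
  tf <- cache$take_first
  d <- dim(tf); n <- d[1]; P <- d[2]; C <- d[3]
  dx <- array(0, dim = c(n, cache$L, C))
  dx[, seq(1, 2 * P, by = 2), ] <- dout * tf
  dx[, seq(2, 2 * P, by = 2), ] <- dout * !tf
  list(grads = NULL, dx = dx)
}

lstm_backward <- function(layer, dout, cache) {
  n <- cache$n; L <- cache$L; H <- layer$H
  dWh <- array(0, dim = dim(layer$Wh))
  DA <- matrix(0, n * L, 4 * H)          # gate pre-activation grads, all t
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(L))) {
    s <- cache$steps[[t]]
    dh <- dh_next
    if (layer$return_seq) dh <- dh + matrix(dout[, t, ], nrow = n)
    else if (t == L) dh <- dh + dout
    do_ <- dh * s$tc
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc_next <- dc * s$f
    dA <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                do_ * s$o * (1 - s$o),
                dg * (1 - s$g^2))
    DA[(t - 1L) * n + seq_len(n), ] <- dA
    dWh <- dWh + crossprod(s$h_prev, dA)
    dh_next <- dA %*% t(layer$Wh)
  }
  xmat <- matrix(cache$x, nrow = n * L)
  list(grads = list(Wx = crossprod(xmat, DA), Wh = dWh, b = colSums(DA)),
       dx = array(DA %*% t(layer$Wx), dim = dim(cache$x)))
}

gru_backward <- function(layer, dout, cache) {
  n <- cache$n; L <- cache$L; H <- layer$H
  iz <- 1:H; ir <- (H + 1):(2 * H); ic <- (2 * H + 1):(3 * H)
  dWh <- array(0, dim = dim(layer$Wh))
  DA <- matrix(0, n * L, 3 * H)          # z/r/candidate pre-activation grads
  dh_next <- matrix(0, n, H)
  for (t in rev(seq_len(L))) {
    s <- cache$steps[[t]]
    dh <- dh_next
    if (layer$return_seq) dh <- dh + matrix(dout[, t, ], nrow = n)
    else if (t == L) dh <- dh + dout
    dz <- dh * (s$h_prev - s$cand)
    dcand <- dh * (1 - s$z)
    dh_prev <- dh * s$z
    dac <- dcand * (1 - s$cand^2)
    drh <- dac %*% t(layer$Wh[, ic, drop = FALSE])
    dr <- drh * s$h_prev
    dh_prev <- dh_prev + drh * s$r
    dA2 <- cbind(dz * s$z * (1 - s$z), dr * s$r * (1 - s$r))
    DA[(t - 1L) * n + seq_len(n), ] <- cbind(dA2, dac)
    dWh[, c(iz, ir)] <- dWh[, c(iz, ir), drop = FALSE] +
      crossprod(s$h_prev, dA2)
    dWh[, ic] <- dWh[, ic, drop = FALSE] + crossprod(s$rh, dac)
    dh_next <- dh_prev + dA2 %*% t(layer$Wh[, c(iz, ir), drop = FALSE])
  }
  xmat <- matrix(cache$x, nrow = n * L)
  list(grads = list(Wx = crossprod(xmat, DA), Wh = dWh, b = colSums(DA)),
       dx = array(DA %*% t(layer$Wx), dim = dim(cache$x)))
}

## ---- network-level passes ------------------------------------------------

net_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    fw <- layer_forward(layers[[li]], x, train = train)
    x <- fw$out
    caches[[li]] <- fw$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[li]], dout, caches[[li]])
    grads[li] <- list(bw$grads)      # keep NULL slots for param-free layers
    dout <- bw$dx
  }
  grads
}

# binary cross-entropy on logits; returns loss and d(loss)/d(logit)
bce_with_logits <- function(z, y) {
  z <- as.numeric(z)
  loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  dz <- matrix((sigmoid(z) - y) / length(y), ncol = 1)
  list(loss = loss, dz = dz)
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- intersect(names(l), c("W", "b", "Wx", "Wh"))
    if (length(pn) == 0) return(NULL)
    st <- lapply(pn, function(p) list(m = array(0, dim = dim0(l[[p]])),
                                      v = array(0, dim = dim0(l[[p]]))))
    names(st) <- pn
    st
  })
}

dim0 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[li]][[p]] <- layers[[li]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[li]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

n_params_layers <- function(layers) {
  sum(vapply(layers, function(l) {
    pn <- intersect(names(l), c("W", "b", "Wx", "Wh"))
    sum(vapply(pn, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}
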