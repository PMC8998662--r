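# Minimal neural-network engine used by the generator, critic and promoter
# classifier. Batches are dense matrices of shape (B, L*C) with the channel
# index varying fastest, i.e. column (l-1)*C + c holds channel c of position l.
# All layers implement an exact reverse-mode backward pass; optimization is
# Adam. Everything here is deterministic given R's RNG state.

# ---- layout helpers ---------------------------------------------------------

# (B, L*C) -> (B*L, C); row b + B*(l-1) holds position l of batch item b
flat_to_blc <- function(M, C) {
  B <- nrow(M)
  L <- ncol(M) / C
  A <- array(M, dim = c(B, C, L))
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(B * L, C)
  A
}

# inverse of flat_to_blc
blc_to_flat <- function(N, B) {
  L <- nrow(N) / B
  C <- ncol(N)
  A <- array(N, dim = c(B, L, C))
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(B, L * C)
  A
}

# ---- layer constructors -----------------------------------------------------

nn_linear <- function(d_in, d_out) {
  stopifnot(d_in >= 1, d_out >= 1)
  list(kind = "linear", d_in = d_in, d_out = d_out)
}

nn_conv1d <- function(c_in, c_out, kernel, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  stopifnot(c_in >= 1, c_out >= 1, kernel >= 1)
  if (pad == "same" && kernel %% 2 == 0) {
    stop("'same' padding requires an odd kernel length")
  }
  list(kind = "conv1d", c_in = c_in, c_out = c_out, kernel = kernel, pad = pad)
}

nn_relu <- function() list(kind = "relu")

nn_maxpool <- function(window, channels) {
  stopifnot(window >= 1, channels >= 1)
  list(kind = "maxpool", window = window, channels = channels)
}

nn_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(kind = "dropout", p = p)
}

nn_flatten <- function() list(kind = "flatten")

nn_reshape <- function(L, C) list(kind = "reshape", L = L, C = C)

# softmax over groups of `channels` consecutive columns (per sequence position)
nn_softmax <- function(channels) {
  stopifnot(channels >= 1)
  list(kind = "softmax", channels = channels)
}

# residual block: x + scale * F(x), F a sub-network preserving shape
nn_residual <- function(layers, scale) {
  stopifnot(is.list(layers), scale <= 1)
  list(kind = "residual", layers = layers, scale = scale)
}

nn_net <- function(...) {
  structure(list(layers = list(...)), class = "nn_net")
}

# ---- initialization ---------------------------------------------------------

# He-style initialization; draws from the current RNG stream
nn_init_layer <- function(layer) {
  switch(layer$kind,
    linear = {
      sd <- sqrt(2 / layer$d_in)
      list(
        W = matrix(stats::rnorm(layer$d_in * layer$d_out, sd = sd),
                   layer$d_in, layer$d_out),
        b = numeric(layer$d_out)
      )
    },
    conv1d = {
      sd <- sqrt(2 / (layer$kernel * layer$c_in))
      list(
        W = array(stats::rnorm(layer$kernel * layer$c_in * layer$c_out, sd = sd),
                  dim = c(layer$kernel, layer$c_in, layer$c_out)),
        b = numeric(layer$c_out)
      )
    },
    residual = lapply(layer$layers, nn_init_layer),
    NULL
  )
}

nn_init <- function(net) {
  lapply(net$layers, nn_init_layer)
}

# ---- forward / backward -----------------------------------------------------

# columns of the k-th slot of each of the first n_out pooling windows
pool_cols <- function(k, n_out, w, C) {
  rep(((seq_len(n_out) - 1L) * w + (k - 1L)) * C, each = C) +
    rep(seq_len(C), n_out)
}

conv1d_geometry <- function(layer, L) {
  K <- layer$kernel
  if (layer$pad == "same") {
    list(L_out = L, shift = -(K - 1L) / 2L)
  } else {
    if (L < K) stop("input length ", L, " shorter than kernel ", K)
    list(L_out = L - K + 1L, shift = 0L)
  }
}

layer_forward <- function(layer, params, X, training = FALSE) {
  switch(layer$kind,
    linear = {
      out <- X %*% params$W
      out <- sweep(out, 2L, params$b, "+")
      list(out = out, cache = list(X = X))
    },
    conv1d = {
      C_in <- layer$c_in
      C_out <- layer$c_out
      K <- layer$kernel
      B <- nrow(X)
      L <- ncol(X) / C_in
      g <- conv1d_geometry(layer, L)
      L_out <- g$L_out
      Ybl <- matrix(params$b, B * L_out, C_out, byrow = TRUE)
      Xkbl <- vector("list", K)
      for (k in seq_len(K)) {
        in_pos <- seq_len(L_out) + (k - 1L) + g$shift
        valid <- which(in_pos >= 1L & in_pos <= L)
        Xk <- matrix(0, B, L_out * C_in)
        if (length(valid)) {
          cols_src <- rep((in_pos[valid] - 1L) * C_in, each = C_in) +
            rep(seq_len(C_in), length(valid))
          cols_dst <- rep((valid - 1L) * C_in, each = C_in) +
            rep(seq_len(C_in), length(valid))
          Xk[, cols_dst] <- X[, cols_src]
        }
        Xkbl[[k]] <- flat_to_blc(Xk, C_in)
        Wk <- matrix(params$W[k, , ], C_in, C_out)
        Ybl <- Ybl + Xkbl[[k]] %*% Wk
      }
      out <- blc_to_flat(Ybl, B)
      list(out = out, cache = list(Xkbl = Xkbl, B = B, L = L, L_out = L_out))
    },
    relu = {
      out <- X
      out[out < 0] <- 0
      list(out = out, cache = list(pos = X > 0))
    },
    maxpool = {
      # non-overlapping windows (stride = window); a short final window is
      # kept, so no trailing positions are discarded: L_out = ceiling(L / w)
      C <- layer$channels
      w <- layer$window
      B <- nrow(X)
      L <- ncol(X) / C
      L_out <- as.integer(ceiling(L / w))
      Y <- X[, pool_cols(1L, L_out, w, C), drop = FALSE]
      idx <- matrix(1L, nrow(Y), ncol(Y))
      if (w > 1L) {
        for (k in 2L:w) {
          lmax <- (L - k) %/% w + 1L  # outputs whose k-th window slot exists
          if (lmax < 1L) next
          colsY <- pool_cols(1L, lmax, 1L, C)
          Sk <- X[, pool_cols(k, lmax, w, C), drop = FALSE]
          sub <- Y[, colsY, drop = FALSE]
          upd <- Sk > sub
          sub[upd] <- Sk[upd]
          Y[, colsY] <- sub
          subi <- idx[, colsY, drop = FALSE]
          subi[upd] <- k
          idx[, colsY] <- subi
        }
      }
      list(out = Y, cache = list(idx = idx, L = L, L_out = L_out))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- matrix(
          (stats::runif(length(X)) >= layer$p) / (1 - layer$p),
          nrow(X), ncol(X)
        )
        list(out = X * mask, cache = list(mask = mask))
      } else {
        list(out = X, cache = list(mask = NULL))
      }
    },
    flatten = list(out = X, cache = NULL),
    reshape = list(out = X, cache = NULL),
    softmax = {
      C <- layer$channels
      B <- nrow(X)
      Z <- flat_to_blc(X, C)
      Z <- Z - apply(Z, 1L, max)
      E <- exp(Z)
      P <- E / rowSums(E)
      list(out = blc_to_flat(P, B), cache = list(P = P, B = B))
    },
    residual = {
      caches <- vector("list", length(layer$layers))
      H <- X
      for (i in seq_along(layer$layers)) {
        fw <- layer_forward(layer$layers[[i]], params[[i]], H, training)
        H <- fw$out
        caches[i] <- list(fw$cache)
      }
      list(out = X + layer$scale * H, cache = caches)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# returns list(dX, grads); grads mirrors the params structure (NULL when none)
layer_backward <- function(layer, params, cache, dY) {
  switch(layer$kind,
    linear = {
      list(
        dX = dY %*% t(params$W),
        grads = list(W = crossprod(cache$X, dY), b = colSums(dY))
      )
    },
    conv1d = {
      C_in <- layer$c_in
      C_out <- layer$c_out
      K <- layer$kernel
      B <- cache$B
      L <- cache$L
      L_out <- cache$L_out
      g <- conv1d_geometry(layer, L)
      dYbl <- flat_to_blc(dY, C_out)
      dW <- array(0, dim = c(K, C_in, C_out))
      dX <- matrix(0, B, L * C_in)
      for (k in seq_len(K)) {
        dW[k, , ] <- crossprod(cache$Xkbl[[k]], dYbl)
        Wk <- matrix(params$W[k, , ], C_in, C_out)
        dXk <- blc_to_flat(dYbl %*% t(Wk), B)
        in_pos <- seq_len(L_out) + (k - 1L) + g$shift
        valid <- which(in_pos >= 1L & in_pos <= L)
        if (length(valid)) {
          cols_src <- rep((in_pos[valid] - 1L) * C_in, each = C_in) +
            rep(seq_len(C_in), length(valid))
          cols_dst <- rep((valid - 1L) * C_in, each = C_in) +
            rep(seq_len(C_in), length(valid))
          dX[, cols_src] <- dX[, cols_src] + dXk[, cols_dst]
        }
      }
      list(dX = dX, grads = list(W = dW, b = colSums(dYbl)))
    },
    relu = list(dX = dY * cache$pos, grads = NULL),
    maxpool = {
      C <- layer$channels
      w <- layer$window
      L <- cache$L
      dX <- matrix(0, nrow(dY), L * C)
      for (k in seq_len(w)) {
        lmax <- (L - k) %/% w + 1L
        if (lmax < 1L) next
        colsY <- pool_cols(1L, lmax, 1L, C)
        colsX <- pool_cols(k, lmax, w, C)
        dX[, colsX] <- dX[, colsX] +
          dY[, colsY, drop = FALSE] * (cache$idx[, colsY, drop = FALSE] == k)
      }
      list(dX = dX, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    flatten = list(dX = dY, grads = NULL),
    reshape = list(dX = dY, grads = NULL),
    softmax = {
      P <- cache$P
      G <- flat_to_blc(dY, layer$channels)
      dZ <- (G - rowSums(G * P)) * P
      list(dX = blc_to_flat(dZ, cache$B), grads = NULL)
    },
    residual = {
      dH <- layer$scale * dY
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        bw <- layer_backward(layer$layers[[i]], params[[i]], cache[[i]], dH)
        dH <- bw$dX
        grads[i] <- list(bw$grads)
      }
      list(dX = dY + dH, grads = grads)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

nn_forward <- function(net, params, X, training = FALSE) {
  caches <- vector("list", length(net$layers))
  H <- X
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], params[[i]], H, training)
    H <- fw$out
    caches[i] <- list(fw$cache)
  }
  list(out = H, caches = caches)
}

nn_backward <- function(net, params, caches, dY) {
  grads <- vector("list", length(net$layers))
  dH <- dY
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], params[[i]], caches[[i]], dH)
    dH <- bw$dX
    grads[i] <- list(bw$grads)
  }
  list(dX = dH, grads = grads)
}

# ---- nested parameter-list arithmetic ---------------------------------------

param_map <- function(f, a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, function(x) param_map(f, x)))
  f(a)
}

param_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    return(mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- param_map(function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x)), params)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1, beta2, eps = 1e-8) {
  t <- opt$t + 1L
  m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- param_map2(function(mh, vh) (mh / bc1) / (sqrt(vh / bc2) + eps), m, v)
  params <- param_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, opt = list(m = m, v = v, t = t))
}
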