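# Network engine: batched forward/backward passes for the two architectures.
#
# Conventions
#   * A mini-batch of B feature matrices [F x L] is held as one matrix
#     [F, L*B] (sample blocks side by side), so every layer is a handful of
#     BLAS calls regardless of batch size.
#   * Trainable parameters live in model$params (nested named lists); batch
#     norm running moments live in model$state and are not parameters.
#   * Training-mode forward passes consume the R RNG (dropout masks); the
#     training loop seeds it, which makes whole runs reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

relu_fwd <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batch normalization over each filter row ------------------------------

bn_forward <- function(x, gamma, beta, state, training) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * inv
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
    list(y = gamma * xhat + beta, xhat = xhat, inv = inv, xc = xc,
         state = state)
  } else {
    inv <- 1 / sqrt(state$var + BN_EPS)
    xhat <- (x - state$mean) * inv
    list(y = gamma * xhat + beta, xhat = xhat, inv = inv, state = state)
  }
}

bn_backward <- function(dy, cache, gamma) {
  n <- ncol(dy)
  dxhat <- dy * gamma
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  # standard batch-norm gradient, vectorized per filter row
  dx <- cache$inv / n *
    (n * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout ---------------------------------------------------------------

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= p) / (1 - p),
                 nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

# ---- channel-combining convolution (kernel spans the channel axis) ---------

conv1_forward <- function(W, b, x) W %*% x + b

conv1_backward <- function(dy, W, x) {
  list(dW = tcrossprod(dy, x), db = rowSums(dy), dx = crossprod(W, dy))
}

# ---- 1-d spectral convolution, 'same' padding ------------------------------

conv2_pad_idx <- function(L, B, K) {
  pad_left <- (K - 1L) %/% 2L
  LP <- L + K - 1L
  base <- rep((seq_len(B) - 1L) * LP, each = L) + seq_len(L)
  list(LP = LP, core = base + pad_left,
       taps = lapply(seq_len(K), function(k) base + (k - 1L)))
}

conv2_forward <- function(W, b, x, L, B) {
  out <- .conv2_fwd_cpp(W, b, x, as.integer(L), as.integer(B))
  out$L <- as.integer(L); out$B <- as.integer(B)
  out
}

conv2_backward <- function(dy, W, cache) {
  .conv2_bwd_cpp(W, dy, cache$xc, cache$L, cache$B)
}

# Pure-R reference implementations of the spectral convolution, kept as the
# independent oracle for the compiled kernels.
conv2_forward_ref <- function(W, b, x, L, B) {
  K <- dim(W)[3]
  idx <- conv2_pad_idx(L, B, K)
  xpad <- matrix(0, nrow(x), idx$LP * B)
  xpad[, idx$core] <- x
  y <- matrix(b, nrow = dim(W)[1], ncol = L * B)
  for (k in seq_len(K))
    y <- y + W[, , k] %*% xpad[, idx$taps[[k]]]
  list(y = y, xpad = xpad, idx = idx)
}

conv2_backward_ref <- function(dy, W, cache) {
  K <- dim(W)[3]
  fin <- dim(W)[2]
  idx <- cache$idx
  dW <- array(0, dim(W))
  for (k in seq_len(K))
    dW[, , k] <- tcrossprod(dy, cache$xpad[, idx$taps[[k]]])
  # dx as a correlation with the reversed kernel over padded dy: placing dy
  # at tap position K - pad_left makes tap (K + 1 - k) of the padded grid
  # line up with the shift the chain rule requires, avoiding any scatter.
  pad_left <- (K - 1L) %/% 2L
  dypad <- matrix(0, nrow(dy), ncol(cache$xpad))
  dypad[, idx$taps[[K - pad_left]]] <- dy
  dx <- matrix(0, fin, ncol(dy))
  for (k in seq_len(K))
    dx <- dx + crossprod(W[, , k], dypad[, idx$taps[[K + 1L - k]]])
  list(dW = dW, db = rowSums(dy), dx = dx)
}

# ---- squeeze-and-excitation ------------------------------------------------

# global average pool per filter map: [F, L*B] -> [F, B]
se_squeeze <- function(x, L, B) {
  colSums(aperm(array(x, dim = c(nrow(x), L, B)), c(2, 1, 3))) / L
}

se_expand <- function(w, L, B) w[, rep(seq_len(B), each = L), drop = FALSE]

se_forward <- function(p, key, value, L, B) {
  s <- se_squeeze(key, L, B)
  h <- relu_fwd(p$W1 %*% s + p$b1)
  w <- sigmoid(p$W2 %*% h + p$b2)
  list(y = value * se_expand(w, L, B), s = s, h = h, w = w)
}

# Returns gradients wrt the excitation parameters, the key tensor and the
# value tensor. The key/value split mirrors the adjusted connection: the
# attention weights are computed from the dropout-passed maps (key) but are
# applied to the maps that skipped dropout (value).
se_backward <- function(dy, p, cache, value, L, B) {
  wexp <- se_expand(cache$w, L, B)
  dvalue <- dy * wexp
  dw <- se_squeeze(dy * value, L, B) * L      # sum, not mean, over spatial
  dz2 <- dw * cache$w * (1 - cache$w)
  dW2 <- tcrossprod(dz2, cache$h)
  db2 <- rowSums(dz2)
  dh <- crossprod(p$W2, dz2) * (cache$h > 0)
  dW1 <- tcrossprod(dh, cache$s)
  db1 <- rowSums(dh)
  ds <- crossprod(p$W1, dh)
  dkey <- se_expand(ds, L, B) / L
  list(dvalue = dvalue, dkey = dkey,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(W, b, x) W %*% x + b

dense_backward <- function(dy, W, x) {
  list(dW = tcrossprod(dy, x), db = rowSums(dy), dx = crossprod(W, dy))
}

# ---- softmax cross-entropy -------------------------------------------------

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# labels are 0-based; returns mean cross-entropy and dlogits
xent_grad <- function(probs, labels) {
  B <- ncol(probs)
  pick <- cbind(labels + 1L, seq_len(B))
  loss <- -mean(log(pmax(probs[pick], 1e-300)))
  d <- probs
  d[pick] <- d[pick] - 1
  list(loss = loss, dlogits = d / B)
}

# ---- parameter-tree helpers -------------------------------------------------

params_zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, params_zero_like))
  p * 0
}
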