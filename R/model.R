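#' Architecture hyperparameters
#'
#' Configuration shared by the attention model and the plain
#' complex-spectrum CNN baseline. Defaults follow the published design:
#' 32 filters in both convolutional layers, a `[1 x 20]` spectral kernel with
#' 'same' padding in the second layer, a 144-unit hidden dense layer, dropout
#' 0.25 and L2 weight decay 0.001.
#'
#' @param n_channels number of EEG channels (Nch); the first convolution
#'   spans this axis with 'valid' padding and collapses it.
#' @param n_features spectral feature length per channel (Nsp, i.e.
#'   `2 * n_bins`).
#' @param n_classes number of stimulus targets.
#' @param n_filters filters per convolutional layer.
#' @param conv2_kernel spectral kernel width of the second convolution.
#' @param dense_width hidden dense layer width (attention model only).
#' @param dropout dropout fraction in `[0, 1)`.
#' @param se_ratio squeeze-and-excitation reduction ratio; `n_filters` must
#'   be divisible by it. Default 4 (32 -> 8 -> 32).
#' @param l2 weight-decay coefficient applied to convolutional and dense
#'   weight matrices (penalty `l2 * sum(w^2)`), never to biases or batch-norm
#'   parameters.
#' @return A list of class `ssvep_model_config`.
#' @export
model_config <- function(n_channels, n_features, n_classes,
                         n_filters = 32L, conv2_kernel = 20L,
                         dense_width = 144L, dropout = 0.25,
                         se_ratio = 4L, l2 = 0.001) {
  stopifnot(n_channels >= 1, n_features >= 1, n_classes >= 2,
            n_filters >= 1, conv2_kernel >= 1, dense_width >= 1,
            dropout >= 0, dropout < 1, l2 >= 0, se_ratio >= 1)
  if (n_filters %% se_ratio != 0)
    stop("n_filters (", n_filters, ") must be divisible by se_ratio (",
         se_ratio, ")")
  if (n_features < conv2_kernel)
    stop("spectral axis too short: n_features = ", n_features,
         " < conv2_kernel = ", conv2_kernel)
  structure(
    list(n_channels = as.integer(n_channels),
         n_features = as.integer(n_features),
         n_classes = as.integer(n_classes),
         n_filters = as.integer(n_filters),
         conv2_kernel = as.integer(conv2_kernel),
         dense_width = as.integer(dense_width),
         dropout = dropout, se_ratio = as.integer(se_ratio), l2 = l2),
    class = "ssvep_model_config"
  )
}

he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

glorot_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

init_se <- function(f, r) {
  list(W1 = he_mat(f %/% r, f, f), b1 = rep(0, f %/% r),
       W2 = glorot_mat(f, f %/% r), b2 = rep(0, f))
}

bn_params <- function(f) list(gamma = rep(1, f), beta = rep(0, f))
bn_state0 <- function(f) list(mean = rep(0, f), var = rep(1, f))

#' Build the attention-augmented complex-spectrum CNN
#'
#' Two stacked convolution-attention blocks followed by a hidden dense layer
#' and a softmax classifier. Each block runs convolution -> ReLU -> batch
#' norm -> dropout; the squeeze-and-excitation module computes its per-filter
#' weights from the dropout-passed maps and applies them to the maps that
#' skipped dropout (the adjusted connection), so at inference, where dropout
#' is the identity, both paths coincide. The first convolution spans the
#' channel axis ('valid' padding, one kernel row per EEG channel) and learns
#' a per-filter channel weighting; the second convolves along the spectral
#' axis with 'same' padding.
#'
#' Weights use variance-scaling initialization drawn from the current RNG
#' stream; seed the RNG for reproducible builds.
#'
#' @param config a [model_config()].
#' @return An object of class `ssvep_cnn` with `arch = "atten_ccnn"`.
#' @export
build_atten_ccnn <- function(config) {
  stopifnot(inherits(config, "ssvep_model_config"))
  f <- config$n_filters
  nsp <- config$n_features
  params <- list(
    conv1 = list(W = he_mat(f, config$n_channels, config$n_channels),
                 b = rep(0, f)),
    bn1 = bn_params(f),
    se1 = init_se(f, config$se_ratio),
    conv2 = list(W = array(stats::rnorm(f * f * config$conv2_kernel, 0,
                                        sqrt(2 / (f * config$conv2_kernel))),
                           dim = c(f, f, config$conv2_kernel)),
                 b = rep(0, f)),
    bn2 = bn_params(f),
    se2 = init_se(f, config$se_ratio),
    dense1 = list(W = he_mat(config$dense_width, f * nsp, f * nsp),
                  b = rep(0, config$dense_width)),
    out = list(W = glorot_mat(config$n_classes, config$dense_width),
               b = rep(0, config$n_classes))
  )
  structure(
    list(arch = "atten_ccnn", config = config, params = params,
         state = list(bn1 = bn_state0(f), bn2 = bn_state0(f)),
         trained = FALSE, history = NULL),
    class = "ssvep_cnn"
  )
}

#' Build the plain complex-spectrum CNN baseline
#'
#' The backbone the attention model extends: two convolutional blocks
#' (convolution -> batch norm -> ReLU -> dropout) and a single dense softmax
#' classifier — no attention modules and no hidden dense layer.
#'
#' @param config a [model_config()].
#' @return An object of class `ssvep_cnn` with `arch = "ccnn"`.
#' @export
build_ccnn <- function(config) {
  stopifnot(inherits(config, "ssvep_model_config"))
  f <- config$n_filters
  nsp <- config$n_features
  params <- list(
    conv1 = list(W = he_mat(f, config$n_channels, config$n_channels),
                 b = rep(0, f)),
    bn1 = bn_params(f),
    conv2 = list(W = array(stats::rnorm(f * f * config$conv2_kernel, 0,
                                        sqrt(2 / (f * config$conv2_kernel))),
                           dim = c(f, f, config$conv2_kernel)),
                 b = rep(0, f)),
    bn2 = bn_params(f),
    out = list(W = glorot_mat(config$n_classes, f * nsp),
               b = rep(0, config$n_classes))
  )
  structure(
    list(arch = "ccnn", config = config, params = params,
         state = list(bn1 = bn_state0(f), bn2 = bn_state0(f)),
         trained = FALSE, history = NULL),
    class = "ssvep_cnn"
  )
}

# ---- forward/backward ------------------------------------------------------

# Xarr: [B, Nch, Nsp] -> stacked [Nch, Nsp*B]
stack_batch <- function(Xarr) {
  d <- dim(Xarr)
  matrix(aperm(Xarr, c(2, 3, 1)), d[2], d[3] * d[1])
}

nn_forward <- function(model, Xarr, training = FALSE,
                       force_unit_attention = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- dim(Xarr)[1]
  L <- cfg$n_features
  f <- cfg$n_filters
  x <- stack_batch(Xarr)
  cache <- list(x = x, B = B, L = L)

  if (model$arch == "atten_ccnn") {
    z1 <- conv1_forward(p$conv1$W, p$conv1$b, x)
    a1 <- relu_fwd(z1)
    bn1 <- bn_forward(a1, p$bn1$gamma, p$bn1$beta, model$state$bn1, training)
    d1 <- dropout_forward(bn1$y, cfg$dropout, training)
    se1 <- se_forward(p$se1, key = d1$y, value = bn1$y, L, B)
    y1 <- if (force_unit_attention) bn1$y else se1$y

    c2 <- conv2_forward(p$conv2$W, p$conv2$b, y1, L, B)
    a2 <- relu_fwd(c2$y)
    bn2 <- bn_forward(a2, p$bn2$gamma, p$bn2$beta, model$state$bn2, training)
    d2 <- dropout_forward(bn2$y, cfg$dropout, training)
    se2 <- se_forward(p$se2, key = d2$y, value = bn2$y, L, B)
    y2 <- if (force_unit_attention) bn2$y else se2$y

    flat <- matrix(y2, f * L, B)
    zh <- dense_forward(p$dense1$W, p$dense1$b, flat)
    h <- relu_fwd(zh)
    logits <- dense_forward(p$out$W, p$out$b, h)
    cache <- c(cache, list(z1 = z1, a1 = a1, bn1 = bn1, d1 = d1, se1 = se1,
                           y1 = y1, c2 = c2, a2 = a2, bn2 = bn2, d2 = d2,
                           se2 = se2, flat = flat, zh = zh, h = h))
  } else {
    z1 <- conv1_forward(p$conv1$W, p$conv1$b, x)
    bn1 <- bn_forward(z1, p$bn1$gamma, p$bn1$beta, model$state$bn1, training)
    a1 <- relu_fwd(bn1$y)
    d1 <- dropout_forward(a1, cfg$dropout, training)

    c2 <- conv2_forward(p$conv2$W, p$conv2$b, d1$y, L, B)
    bn2 <- bn_forward(c2$y, p$bn2$gamma, p$bn2$beta, model$state$bn2, training)
    a2 <- relu_fwd(bn2$y)
    d2 <- dropout_forward(a2, cfg$dropout, training)

    flat <- matrix(d2$y, f * L, B)
    logits <- dense_forward(p$out$W, p$out$b, flat)
    cache <- c(cache, list(z1 = z1, bn1 = bn1, a1 = a1, d1 = d1, c2 = c2,
                           bn2 = bn2, a2 = a2, d2 = d2, flat = flat))
  }
  probs <- softmax_cols(logits)
  new_state <- list(bn1 = cache$bn1$state, bn2 = cache$bn2$state)
  list(probs = probs, logits = logits, cache = cache, state = new_state)
}

nn_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  cc <- fwd$cache
  L <- cc$L; B <- cc$B; f <- cfg$n_filters
  g <- list()

  if (model$arch == "atten_ccnn") {
    db_out <- dense_backward(dlogits, p$out$W, cc$h)
    g$out <- list(W = db_out$dW, b = db_out$db)
    dh <- db_out$dx * (cc$zh > 0)
    db_d1 <- dense_backward(dh, p$dense1$W, cc$flat)
    g$dense1 <- list(W = db_d1$dW, b = db_d1$db)
    dy2 <- matrix(db_d1$dx, f, L * B)

    sb2 <- se_backward(dy2, p$se2, cc$se2, value = cc$bn2$y, L, B)
    g$se2 <- sb2$grads
    dkey2 <- if (is.null(cc$d2$mask)) sb2$dkey else sb2$dkey * cc$d2$mask
    dbn2y <- sb2$dvalue + dkey2
    bb2 <- bn_backward(dbn2y, cc$bn2, p$bn2$gamma)
    g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
    dz2 <- bb2$dx * (cc$c2$y > 0)
    cb2 <- conv2_backward(dz2, p$conv2$W, cc$c2)
    g$conv2 <- list(W = cb2$dW, b = cb2$db)
    dy1 <- cb2$dx

    sb1 <- se_backward(dy1, p$se1, cc$se1, value = cc$bn1$y, L, B)
    g$se1 <- sb1$grads
    dkey1 <- if (is.null(cc$d1$mask)) sb1$dkey else sb1$dkey * cc$d1$mask
    dbn1y <- sb1$dvalue + dkey1
    bb1 <- bn_backward(dbn1y, cc$bn1, p$bn1$gamma)
    g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
    dz1 <- bb1$dx * (cc$z1 > 0)
    cb1 <- conv1_backward(dz1, p$conv1$W, cc$x)
    g$conv1 <- list(W = cb1$dW, b = cb1$db)
  } else {
    db_out <- dense_backward(dlogits, p$out$W, cc$flat)
    g$out <- list(W = db_out$dW, b = db_out$db)
    dd2 <- matrix(db_out$dx, f, L * B)
    if (!is.null(cc$d2$mask)) dd2 <- dd2 * cc$d2$mask
    da2 <- dd2 * (cc$bn2$y > 0)
    bb2 <- bn_backward(da2, cc$bn2, p$bn2$gamma)
    g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
    cb2 <- conv2_backward(bb2$dx, p$conv2$W, cc$c2)
    g$conv2 <- list(W = cb2$dW, b = cb2$db)

    dd1 <- cb2$dx
    if (!is.null(cc$d1$mask)) dd1 <- dd1 * cc$d1$mask
    da1 <- dd1 * (cc$bn1$y > 0)
    bb1 <- bn_backward(da1, cc$bn1, p$bn1$gamma)
    g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
    cb1 <- conv1_backward(bb1$dx, p$conv1$W, cc$x)
    g$conv1 <- list(W = cb1$dW, b = cb1$db)
  }
  g[names(p)]
}

#' Apply squeeze-and-excitation attention to feature maps
#'
#' The adjusted connection used inside each convolution-attention block,
#' exposed as a stand-alone operation: per-filter weights are computed from
#' `post_dropout_maps` (squeeze: global average over the spatial axis;
#' excitation: reduction dense + ReLU, expansion dense + sigmoid) and applied
#' multiplicatively to `pre_dropout_maps`. At inference dropout is the
#' identity and the two arguments coincide.
#'
#' @param pre_dropout_maps,post_dropout_maps numeric matrices
#'   `[n_filters x spatial]` of identical shape.
#' @param excitation list with `W1` (`[n_filters/r x n_filters]`), `b1`,
#'   `W2` (`[n_filters x n_filters/r]`), `b2`.
#' @return A list with `output` (same shape as `pre_dropout_maps`) and
#'   `weights` (per-filter attention weights, all in (0, 1)).
#' @export
se_attention <- function(pre_dropout_maps, post_dropout_maps, excitation) {
  if (!identical(dim(pre_dropout_maps), dim(post_dropout_maps)))
    stop("shape mismatch: pre-dropout maps are ",
         paste(dim(pre_dropout_maps), collapse = "x"),
         ", post-dropout maps are ",
         paste(dim(post_dropout_maps), collapse = "x"))
  fwd <- se_forward(excitation, key = post_dropout_maps,
                    value = pre_dropout_maps,
                    L = ncol(pre_dropout_maps), B = 1L)
  list(output = fwd$y, weights = as.numeric(fwd$w))
}

#' Number of trainable parameters
#'
#' Counts weights, biases and batch-norm scale/shift; running batch-norm
#' moments are state, not parameters, and are excluded.
#'
#' @param model an `ssvep_cnn`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(unlist(lapply(model$params, function(layer)
    vapply(layer, length, integer(1)))))
}

#' Predict target labels from complex-spectrum features
#'
#' Runs the network in inference mode (dropout disabled, batch norm using
#' running moments), so repeated calls are identical.
#'
#' @param object an `ssvep_cnn` model.
#' @param newdata a [spectrum_features] object or a numeric array
#'   `[n_segments, n_channels, Nsp]` (a single `[n_channels x Nsp]` matrix is
#'   also accepted).
#' @param type `"class"` for 0-based label indices, `"prob"` for the
#'   `[n_segments x n_classes]` class-probability matrix.
#' @param ... unused.
#' @return Labels or probability matrix, per `type`.
#' @export
predict.ssvep_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Xarr <- if (inherits(newdata, "spectrum_features")) newdata$features
          else newdata
  if (is.matrix(Xarr)) Xarr <- array(Xarr, dim = c(1L, dim(Xarr)))
  d <- dim(Xarr)
  cfg <- object$config
  if (length(d) != 3L || d[2] != cfg$n_channels || d[3] != cfg$n_features)
    stop("feature shape mismatch: expected [n, ", cfg$n_channels, ", ",
         cfg$n_features, "], received [", paste(d, collapse = ", "), "]")
  probs <- t(nn_forward(object, Xarr, training = FALSE)$probs)
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

#' @export
print.ssvep_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s: %d-channel x %d-feature input, %d classes, %s parameters\n",
              if (x$arch == "atten_ccnn")
                "Attention complex-spectrum CNN (atten-CCNN)"
              else "Complex-spectrum CNN (CCNN)",
              cfg$n_channels, cfg$n_features, cfg$n_classes,
              format(count_params(x), big.mark = ",")))
  cat(if (x$trained)
        sprintf("  trained: %d epochs, final loss %.4f\n",
                length(x$history$loss), utils::tail(x$history$loss, 1))
      else "  untrained\n")
  invisible(x)
}

#' @export
summary.ssvep_cnn <- function(object, ...) {
  counts <- vapply(object$params, function(layer)
    sum(vapply(layer, length, integer(1))), numeric(1))
  df <- data.frame(layer = names(counts), parameters = as.integer(counts),
                   row.names = NULL)
  cat(sprintf("Architecture: %s\n", object$arch))
  print(df)
  cat(sprintf("Total trainable parameters: %d\n", count_params(object)))
  invisible(df)
}

#' @export
coef.ssvep_cnn <- function(object, ...) object$params
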