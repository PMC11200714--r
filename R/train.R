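#' Training hyperparameters
#'
#' Defaults follow the published recipe: SGD at learning rate 0.001 with L2
#' regularization 0.001 (held in [model_config()]), dropout 0.25, 120 epochs,
#' batch size 256 for the subject-independent protocol and 16 for the
#' subject-dependent protocol. Momentum is not stated in the recipe; the
#' default 0.9 is the common choice and plain SGD is `momentum = 0`.
#'
#' @param learning_rate SGD step size.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size (capped at the training-set size).
#' @param momentum SGD momentum coefficient in `[0, 1)`.
#' @param seed integer seed controlling shuffling, dropout masks and — via
#'   [loso_cv()]/[kfold_cv()] — weight initialization.
#' @return A list of class `ssvep_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 120L,
                         batch_size = 256L, momentum = 0.9, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            momentum >= 0, momentum < 1)
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), momentum = momentum,
         seed = as.integer(seed)),
    class = "ssvep_train_config"
  )
}

# In-place SGD-momentum step over the parameter tree. params and velocity
# must be uniquely-owned copies (see train_decoder); weight decay applies to
# weight matrices/arrays only (names starting with W), never to biases or
# batch-norm scale/shift.
sgd_update <- function(params, grads, velocity, lr, momentum, l2) {
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      .sgd_step_cpp(params[[ln]][[pn]], grads[[ln]][[pn]],
                    velocity[[ln]][[pn]], lr, momentum,
                    if (grepl("^W", pn)) l2 else 0)
    }
  }
  invisible(NULL)
}

params_deep_copy <- function(p) {
  if (is.list(p)) return(lapply(p, params_deep_copy))
  p + 0
}

#' Train a complex-spectrum CNN
#'
#' Mini-batch SGD with momentum on the categorical cross-entropy, with L2
#' weight decay on convolutional and dense weight matrices. The RNG is
#' seeded from `config$seed` at entry, so a run is a pure function of
#' (model, features, config).
#'
#' @param model an `ssvep_cnn` from [build_atten_ccnn()] or [build_ccnn()].
#' @param features a [spectrum_features] object with labels covering every
#'   class.
#' @param config a [train_config()].
#' @param verbose print the epoch loss every 10 epochs.
#' @return The trained `ssvep_cnn`, with `history$loss` (mean cross-entropy
#'   per epoch, regularization excluded).
#' @export
train_decoder <- function(model, features, config = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "ssvep_cnn"),
            inherits(features, "spectrum_features"),
            inherits(config, "ssvep_train_config"))
  labels <- features$labels
  n_classes <- model$config$n_classes
  missing <- setdiff(seq_len(n_classes) - 1L, unique(labels))
  if (length(missing) > 0)
    stop("class(es) absent from training data: ",
         paste(missing, collapse = ", "))
  Xarr <- features$features
  n <- dim(Xarr)[1]
  bs <- min(config$batch_size, n)

  set.seed(config$seed)
  # the optimizer updates parameters in place; copy the tree once so the
  # caller's model object is never mutated
  model$params <- params_deep_copy(model$params)
  velocity <- params_zero_like(model$params)
  l2 <- model$config$l2
  loss_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      fwd <- nn_forward(model, Xarr[idx, , , drop = FALSE], training = TRUE)
      model$state <- fwd$state
      ce <- xent_grad(fwd$probs, labels[idx])
      grads <- nn_backward(model, fwd, ce$dlogits)
      sgd_update(model$params, grads, velocity,
                 config$learning_rate, config$momentum, l2)
      ep_loss <- ep_loss + ce$loss
      nb <- nb + 1L
    }
    loss_hist[ep] <- ep_loss / nb
    if (verbose && (ep %% 10L == 0L || ep == 1L))
      message(sprintf("epoch %3d/%d  loss %.4f", ep, config$epochs,
                      loss_hist[ep]))
  }
  model$trained <- TRUE
  model$history <- list(loss = loss_hist)
  model
}
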