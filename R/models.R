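# The seven classifier families: architecture descriptors, construction,
# training (Adam + binary cross-entropy with early stopping) and prediction.

MODEL_FAMILIES <- c("LINEAR", "MLP", "CNN", "RNN_LSTM", "RNN_GRU",
                    "STACKED_LSTM", "STACKED_GRU")

#' Describe a crash-prediction model architecture
#'
#' Family defaults reproduce the reference architectures: an MLP with three
#' 50-neuron ReLU hidden layers; a CNN with two (128-filter conv, size-2 max
#' pool) stages of kernel sizes 3 and 4 and a 100-neuron dense layer;
#' single LSTM/GRU with hidden size 100, 0.5 dropout and a 128-neuron ReLU
#' head; stacked (two-layer) LSTM/GRU with both hidden states of size 100;
#' and a simple linear classifier (one affine map of the flattened window
#' through a sigmoid) as the non-deep baseline.  All models end in a single
#' sigmoid output unit trained with binary cross-entropy.
#'
#' @param family one of `"LINEAR"`, `"MLP"`, `"CNN"`, `"RNN_LSTM"`,
#'   `"RNN_GRU"`, `"STACKED_LSTM"`, `"STACKED_GRU"`.
#' @param hidden width of the hidden layers (MLP layer width, RNN hidden
#'   state size); family default if `NULL`.
#' @param head_width neurons in the fully connected layer before the output
#'   (RNN families and CNN dense stage).
#' @param filters convolution filters per stage (CNN only).
#' @param dropout_rate dropout rate after single-RNN hidden output.
#' @param lr,batch_size,max_epochs,patience Adam learning rate, minibatch
#'   size, epoch cap, and early-stopping patience (epochs without
#'   validation-loss improvement).
#' @param lr_decay per-epoch multiplicative learning-rate decay (1 = none).
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return A `model_spec` object.
#' @examples
#' model_spec("STACKED_GRU")
#' model_spec("MLP", hidden = 32)  # scaled-down profile
#' @export
model_spec <- function(family, hidden = NULL, head_width = NULL,
                       filters = NULL, dropout_rate = 0.5,
                       lr = 1e-3, lr_decay = 1, batch_size = 256L,
                       max_epochs = 100L, patience = 10L, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  defaults <- switch(family,
    LINEAR = list(hidden = 0L, head_width = 0L, filters = 0L),
    MLP = list(hidden = 50L, head_width = 0L, filters = 0L),
    CNN = list(hidden = 0L, head_width = 100L, filters = 128L),
    list(hidden = 100L, head_width = 128L, filters = 0L)   # RNN families
  )
  spec <- list(
    family = family,
    hidden = as.integer(hidden %||% defaults$hidden),
    head_width = as.integer(head_width %||% defaults$head_width),
    filters = as.integer(filters %||% defaults$filters),
    dropout_rate = dropout_rate,
    lr = lr, lr_decay = lr_decay, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seed = as.integer(seed)
  )
  if (spec$dropout_rate < 0 || spec$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  structure(spec, class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaled-down architecture profile
#'
#' Same family, reduced widths and epochs, for quick experiments and the
#' test suite (hidden 32, head 32, 16 filters, at most `max_epochs` epochs).
#'
#' @param family model family, as in [model_spec()].
#' @param max_epochs epoch cap (default 20).
#' @param ... passed to [model_spec()].
#' @return A `model_spec`.
#' @export
scaled_spec <- function(family, max_epochs = 20L, ...) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (family == "LINEAR") return(model_spec("LINEAR", max_epochs = max_epochs, ...))
  model_spec(family, hidden = 32L, head_width = 32L, filters = 16L,
             max_epochs = max_epochs, ...)
}

#' Build an untrained model
#'
#' Instantiates the layer stack of `spec` for windows of `input_steps` time
#' steps by `input_channels` channels, with weights drawn from the RNG
#' seeded by `spec$seed`.
#'
#' @param spec a [model_spec()].
#' @param input_steps window length L in samples.
#' @param input_channels feature channels per step (4: position, velocity,
#'   joystick, destabilizing-deflection flag).
#' @return A `crash_model` object (layers + spec + input shape).
#' @export
build_model <- function(spec, input_steps, input_channels = 4L) {
  stopifnot(inherits(spec, "model_spec"), input_steps >= 1)
  L <- as.integer(input_steps); C <- as.integer(input_channels)
  set.seed(spec$seed)
  h <- spec$hidden; hw <- spec$head_width
  layers <- switch(spec$family,
    LINEAR = list(nn_flatten(), nn_dense(L * C, 1L)),
    MLP = list(nn_flatten(),
               nn_dense(L * C, h, "relu"),
               nn_dense(h, h, "relu"),
               nn_dense(h, h, "relu"),
               nn_dense(h, 1L)),
    CNN = {
      P1 <- L %/% 2L; P2 <- P1 %/% 2L
      list(nn_conv1d(C, spec$filters, 3L), nn_relu(), nn_maxpool(2L),
           nn_conv1d(spec$filters, spec$filters, 4L), nn_relu(), nn_maxpool(2L),
           nn_flatten(),
           nn_dense(P2 * spec$filters, hw, "relu"),
           nn_dense(hw, 1L))
    },
    RNN_LSTM = list(nn_lstm(C, h), nn_dropout(spec$dropout_rate),
                    nn_dense(h, hw, "relu"), nn_dense(hw, 1L)),
    RNN_GRU = list(nn_gru(C, h), nn_dropout(spec$dropout_rate),
                   nn_dense(h, hw, "relu"), nn_dense(hw, 1L)),
    STACKED_LSTM = list(nn_lstm(C, h, return_seq = TRUE), nn_lstm(h, h),
                        nn_dense(h, hw, "relu"), nn_dense(hw, 1L)),
    STACKED_GRU = list(nn_gru(C, h, return_seq = TRUE), nn_gru(h, h),
                       nn_dense(h, hw, "relu"), nn_dense(hw, 1L))
  )
  structure(list(spec = spec, layers = layers, L = L, C = C,
                 trained = FALSE, history = NULL),
            class = "crash_model")
}

#' Number of trainable parameters
#' @param model a `crash_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "crash_model"))
  n_params_layers(model$layers)
}

#' @export
print.crash_model <- function(x, ...) {
  cat(sprintf("crash_model %s: input %d x %d, %d parameters%s\n",
              x$spec$family, x$L, x$C, n_params(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Train a crash-prediction model
#'
#' Minibatch Adam on binary cross-entropy, with early stopping on
#' validation loss: training stops after `spec$patience` epochs without
#' improvement and the best-validation weights are restored.  Training and
#' validation windows must come from disjoint episode sets (checked).
#' Deterministic for a fixed `spec$seed`.
#'
#' @param model a `crash_model` from [build_model()].
#' @param train_ws training `window_set` (standardized; see
#'   [channel_stats()]).
#' @param val_ws validation `window_set`, or `NULL` to train for
#'   `spec$max_epochs` flat.
#' @param verbose print per-epoch losses.
#' @return The trained `crash_model` with a `history` data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_model <- function(model, train_ws, val_ws = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "crash_model"), inherits(train_ws, "window_set"))
  spec <- model$spec
  if (!is.null(val_ws)) {
    overlap <- intersect(unique(train_ws$meta$episode_id),
                         unique(val_ws$meta$episode_id))
    if (length(overlap) > 0) {
      stop("training and validation share episodes: leakage (e.g. ",
           overlap[1], ")")
    }
  }
  X <- train_ws$X; y <- train_ws$y
  n <- dim(X)[1]
  stopifnot(n > 0, dim(X)[2] == model$L, dim(X)[3] == model$C)
  set.seed(spec$seed + 1L)
  layers <- model$layers
  state <- adam_init(layers)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  bad_epochs <- 0L
  hist_tr <- numeric(0); hist_va <- numeric(0)
  step <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    lr_now <- spec$lr * spec$lr_decay^(epoch - 1L)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
      fw <- net_forward(layers, X[idx, , , drop = FALSE], train = TRUE)
      lo <- bce_with_logits(fw$out, y[idx])
      if (!is.finite(lo$loss)) {
        stop("NaN/Inf training loss at epoch ", epoch,
             "; lower the learning rate")
      }
      grads <- net_backward(layers, lo$dz, fw$caches)
      step <- step + 1L
      up <- adam_update(layers, grads, state, lr_now, step)
      layers <- up$layers; state <- up$state
      ep_loss <- ep_loss + lo$loss * length(idx); nb <- nb + length(idx)
    }
    hist_tr <- c(hist_tr, ep_loss / nb)
    if (!is.null(val_ws)) {
      va <- predict_scores(layers, val_ws$X, spec$batch_size)
      vloss <- bce_loss_probs(va, val_ws$y)
      hist_va <- c(hist_va, vloss)
      if (verbose) {
        message(sprintf("epoch %d train %.4f val %.4f", epoch,
                        ep_loss / nb, vloss))
      }
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, layers = layers, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= spec$patience) break
      }
    } else if (verbose) {
      message(sprintf("epoch %d train %.4f", epoch, ep_loss / nb))
    }
  }
  model$layers <- if (!is.null(val_ws) && is.finite(best$loss))
    best$layers else layers
  model$trained <- TRUE
  model$history <- data.frame(
    epoch = seq_along(hist_tr), train_loss = hist_tr,
    val_loss = if (length(hist_va)) hist_va else NA_real_)
  model
}

bce_loss_probs <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

predict_scores <- function(layers, X, batch_size = 1024L) {
  n <- dim(X)[1]
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    fw <- net_forward(layers, X[idx, , , drop = FALSE], train = FALSE)
    out[idx] <- sigmoid(as.numeric(fw$out))
  }
  out
}

#' Score windows with a trained model
#'
#' @param object a `crash_model`.
#' @param windows a `window_set` whose window shape matches the model input.
#' @param ... unused.
#' @return A `prediction_records` data.frame: one row per window, in input
#'   order, with `score` (sigmoid output in \[0, 1\]), `label`,
#'   `episode_id`, `max_abs_theta`, `end_time`, `end_index`.
#' @export
predict.crash_model <- function(object, windows, ...) {
  stopifnot(inherits(windows, "window_set"))
  X <- windows$X
  if (dim(X)[1] > 0 &&
      (dim(X)[2] != object$L || dim(X)[3] != object$C)) {
    stop("window shape ", dim(X)[2], "x", dim(X)[3],
         " does not match model input ", object$L, "x", object$C)
  }
  scores <- predict_scores(object$layers, X)
  structure(data.frame(
    score = scores,
    label = windows$y,
    episode_id = windows$meta$episode_id,
    trial_key = windows$meta$trial_key,
    max_abs_theta = windows$meta$max_abs_theta,
    end_time = windows$meta$end_time,
    end_index = windows$meta$end_index,
    stringsAsFactors = FALSE
  ), class = c("prediction_records", "data.frame"))
}
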