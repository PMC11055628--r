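# Adam optimization of all trainable tensors, plateau scheduling, and the
# training loop with per-step parameter/delay clipping.

adam_state <- function(param) list(m = param * 0, v = param * 0)

adam_update <- function(param, grad, state, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^step)
  vhat <- state$v / (1 - beta2^step)
  param <- param - lr * mhat / (sqrt(vhat) + eps)
  list(param = param, state = state)
}

init_optimizer <- function(model) {
  lapply(model$layers, function(ly) {
    st <- list(W = adam_state(ly$W), bias = adam_state(ly$bias))
    if (!is.null(ly$delays) && ly$delays$trainable) {
      st$delays <- adam_state(ly$delays$d)
    }
    if (!is.null(ly$params)) {
      st$params <- lapply(ly$params[ly$params$trainable], adam_state)
    }
    st
  })
}

apply_gradients <- function(model, grads, opt, lr_w, lr_d, step) {
  for (l in 1:3) {
    ly <- model$layers[[l]]
    up <- adam_update(ly$W, grads[[l]]$W, opt[[l]]$W, lr_w, step)
    ly$W <- up$param; opt[[l]]$W <- up$state
    up <- adam_update(ly$bias, grads[[l]]$bias, opt[[l]]$bias, lr_w, step)
    ly$bias <- up$param; opt[[l]]$bias <- up$state
    if (!is.null(opt[[l]]$delays) && !is.null(grads[[l]]$delays)) {
      up <- adam_update(ly$delays$d, grads[[l]]$delays, opt[[l]]$delays,
                        lr_d, step)
      ly$delays$d <- up$param; opt[[l]]$delays <- up$state
      ly$delays <- clip_delays(ly$delays)
    }
    if (!is.null(ly$params)) {
      for (nm in ly$params$trainable) {
        up <- adam_update(ly$params[[nm]], grads[[l]]$params[[nm]],
                          opt[[l]]$params[[nm]], lr_w, step)
        ly$params[[nm]] <- up$param; opt[[l]]$params[[nm]] <- up$state
      }
      ly$params <- clip_neuron_params(ly$params)
    }
    model$layers[[l]] <- ly
  }
  list(model = model, opt = opt)
}

pad_if_delayed <- function(x, config) {
  if (config$delay_mode == "none") x else pad_for_delays(x, config$d_max)
}

#' Train an SNN by surrogate-gradient BPTT
#'
#' Adam-optimizes weights, biases, per-neuron adaptation parameters and
#' (when learnable) per-synapse delays; delays use their own learning rate.
#' After every optimizer step, neuron parameters and delays are clipped to
#' their bounds. A plateau scheduler multiplies both learning rates by
#' \code{scheduler_factor} when the monitored validation accuracy has not
#' improved for \code{scheduler_patience} epochs. The run is fully seeded:
#' identical seeds give identical histories and final models.
#'
#' @param model an \code{"snn_model"}.
#' @param data list with \code{x} (samples x T x n_in, unpadded) and
#'   \code{y} (integer labels in \code{1..n_out}).
#' @param cfg a \code{"training_config"}.
#' @param val optional validation list like \code{data}; defaults to
#'   monitoring training accuracy.
#' @param context temporal-context half-width of the delay rule.
#' @param verbose print per-epoch metrics.
#' @return list with the trained \code{model} and \code{history}, a
#'   data.frame with one row per epoch (loss, accuracies, spike rate,
#'   learning rates).
#' @export
snn_train <- function(model, data, cfg, val = NULL, context = 3L,
                      verbose = FALSE) {
  stopifnot(inherits(model, "snn_model"), inherits(cfg, "training_config"))
  set.seed(cfg$seed)
  x <- pad_if_delayed(data$x, model$config)
  y <- as.integer(data$y)
  n <- dim(x)[1]
  stopifnot(length(y) == n)
  opt <- init_optimizer(model)
  lr_w <- cfg$lr_weights; lr_d <- cfg$lr_delays
  best <- -Inf; stale <- 0L; step <- 0L
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_correct <- 0L
    for (bi in batches) {
      xb <- x[bi, , , drop = FALSE]
      res <- snn_grad(model, xb, y[bi], training = TRUE, context = context)
      if (!is.finite(res$loss)) {
        stop("training diverged: non-finite loss at epoch ", ep,
             " (step ", step + 1, ")")
      }
      step <- step + 1L
      upd <- apply_gradients(model, res$grads, opt, lr_w, lr_d, step)
      model <- upd$model; opt <- upd$opt
      ep_loss <- ep_loss + res$loss * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(res$scores, ties.method = "first") == y[bi])
    }
    train_loss <- ep_loss / n
    train_acc <- ep_correct / n
    if (!is.null(val)) {
      ev <- snn_evaluate(model, val)
      val_acc <- ev$accuracy; spk <- ev$spikes_per_neuron
    } else {
      ev <- snn_evaluate(model, data)
      val_acc <- ev$accuracy; spk <- ev$spikes_per_neuron
    }
    monitored <- val_acc
    if (monitored > best + 1e-12) {
      best <- monitored; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$scheduler_patience) {
        lr_w <- lr_w * cfg$scheduler_factor
        lr_d <- lr_d * cfg$scheduler_factor
        stale <- 0L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = train_loss,
                             train_acc = train_acc, val_acc = val_acc,
                             spikes_per_neuron = spk,
                             lr_weights = lr_w, lr_delays = lr_d)
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  train acc %.3f  val acc %.3f  spk/neuron %.2f",
        ep, train_loss, train_acc, val_acc, spk))
    }
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Evaluate a model: accuracy and spike economy
#'
#' Dropout is disabled. Spikes per neuron is the total hidden spike count
#' divided by (number of hidden neurons x number of samples), the standard
#' energy proxy for neuromorphic deployment; a per-layer breakdown is
#' included.
#'
#' @param model an \code{"snn_model"}.
#' @param data list with \code{x} (samples x T x n_in, unpadded) and
#'   \code{y} labels.
#' @param chunk samples per forward chunk.
#' @return list with \code{accuracy}, \code{spikes_per_neuron},
#'   \code{per_layer_spikes_per_neuron}, \code{predicted}, \code{n}.
#' @export
snn_evaluate <- function(model, data, chunk = 64L) {
  x <- pad_if_delayed(data$x, model$config)
  y <- as.integer(data$y)
  n <- dim(x)[1]
  if (n == 0) stop("empty dataset")
  pred <- integer(n)
  layer_spikes <- c(0, 0)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- snn_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    scores <- aggregate_readout(fw$u_out)
    pred[idx] <- max.col(scores, ties.method = "first")
    layer_spikes <- layer_spikes + c(sum(fw$hidden[[1]]$s),
                                     sum(fw$hidden[[2]]$s))
  }
  sizes <- model$config$hidden_sizes
  list(accuracy = mean(pred == y),
       spikes_per_neuron = sum(layer_spikes) / (sum(sizes) * n),
       per_layer_spikes_per_neuron = layer_spikes / (sizes * n),
       predicted = pred, n = n)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a versioned R list (format \code{snncolearn-checkpoint v1})
#' holding the network config, all weights, biases, neuron parameters and
#' delays, the training config and history, and the RNG state, serialized
#' with \code{saveRDS}.
#'
#' @param model an \code{"snn_model"}.
#' @param path file path.
#' @param cfg optional \code{"training_config"}.
#' @param history optional training history.
#' @return \code{save_checkpoint}: the path, invisibly.
#'   \code{load_checkpoint}: list with \code{model}, \code{cfg},
#'   \code{history}.
#' @export
save_checkpoint <- function(model, path, cfg = NULL, history = NULL) {
  obj <- list(format = "snncolearn-checkpoint", version = 1L,
              model = model, cfg = cfg, history = history,
              rng_state = if (exists(".Random.seed", envir = globalenv()))
                get(".Random.seed", envir = globalenv()) else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "snncolearn-checkpoint")) {
    stop("not a snncolearn checkpoint: ", path)
  }
  obj[c("model", "cfg", "history")]
}
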