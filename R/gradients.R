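# Backpropagation-through-time for the feed-forward SNN: exact reverse-mode
# gradients of the aggregated-softmax cross-entropy with the spike
# nonlinearity handled by the boxcar surrogate (or its smooth relaxation),
# and the temporal-context pseudo-gradient standing in for the
# non-differentiable delay shift.

# gradient of the loss wrt the per-timestep readout potentials
readout_potential_grad <- function(u_out, labels) {
  dm <- dim(u_out); B <- dm[1]; T_len <- dm[2]; K <- dm[3]
  P <- array(0, dm)
  scores <- matrix(0, B, K)
  for (t in seq_len(T_len)) {
    Pt <- softmax_rows(matrix(u_out[, t, ], B, K))
    P[, t, ] <- Pt
    scores <- scores + Pt
  }
  idx <- cbind(seq_len(B), labels)
  coef <- -1 / (B * scores[idx])          # dL/dscores at the true class
  g <- array(0, dm)
  onehot <- matrix(0, B, K); onehot[idx] <- 1
  for (t in seq_len(T_len)) {
    Pt <- matrix(P[, t, ], B, K)
    pc <- Pt[idx]
    g[, t, ] <- (coef * pc) * (onehot - Pt)
  }
  list(g = g, scores = scores)
}

# backward through one delayed linear projection.
# gI: (B,T,post) gradient wrt the projected current; s_pre: (B,T,pre).
project_backward <- function(gI, s_pre, W, delays, context = 3L,
                             need_gs = TRUE, need_gd = TRUE) {
  gI_flat <- flat_bt(gI)
  gW <- matrix(0, nrow(W), ncol(W))
  gs <- if (need_gs) array(0, dim(s_pre)) else NULL
  gd <- NULL
  sh <- NULL
  if (!is.null(delays)) sh <- effective_shift(delays$d)
  if (!is.null(delays) && need_gd) {
    Gpre <- context_signal(s_pre, context)
    gd <- matrix(0, nrow(W), ncol(W))
  }
  for (g in delay_groups(W, delays)) {
    mask <- if (is.null(sh)) 1 else (sh == g$shift)
    gW <- gW + (t(gI_flat) %*% flat_bt(shift_time(s_pre, g$shift))) * mask
    if (need_gs) {
      A <- gI_flat %*% g$W
      gs <- gs + shift_time_back(array(A, dim(s_pre)), g$shift)
    }
    if (!is.null(gd)) {
      gd <- gd + (t(gI_flat) %*% flat_bt(shift_time(Gpre, g$shift))) * mask
    }
  }
  if (!is.null(gd)) gd <- gd * W
  list(gW = gW, gbias = colSums(gI_flat), gdelays = gd, gs_pre = gs)
}

# backward through one hidden layer's recurrent dynamics.
# gs_ext: (B,T,n) gradient arriving at the raw spike train from downstream.
hidden_layer_backward <- function(model, layer, fw, gs_ext) {
  p <- layer$params
  dm <- dim(fw$u); B <- dm[1]; T_len <- dm[2]; n <- dm[3]
  al <- matrix(p$alpha, B, n, byrow = TRUE)
  be <- matrix(p$beta, B, n, byrow = TRUE)
  aa <- matrix(p$a, B, n, byrow = TRUE)
  bb <- matrix(p$b, B, n, byrow = TRUE)
  gu_next <- gw_next <- matrix(0, B, n)
  gI <- array(0, dm)
  galpha <- gbeta <- ga <- gb <- numeric(n)
  zero <- matrix(0, B, n)
  for (t in T_len:1) {
    u_t <- matrix(fw$u[, t, ], B, n)
    gs_t <- matrix(gs_ext[, t, ], B, n) + bb * gw_next - p$theta * gu_next
    gu_t <- gs_t * spike_backward_factor(model, u_t, p$theta) +
      al * gu_next + (1 - be) * aa * gw_next
    gw_t <- be * gw_next - (1 - al) * gu_next
    if (t > 1) {
      u_prev <- matrix(fw$u[, t - 1, ], B, n)
      w_prev <- matrix(fw$w[, t - 1, ], B, n)
      s_prev <- matrix(fw$s[, t - 1, ], B, n)
    } else {
      u_prev <- w_prev <- s_prev <- zero
    }
    I_t <- matrix(fw$I[, t, ], B, n)
    galpha <- galpha + colSums(gu_t * (u_prev - I_t + w_prev))
    gbeta <- gbeta + colSums(gw_t * (w_prev - aa * u_prev))
    ga <- ga + colSums(gw_t * (1 - be) * u_prev)
    gb <- gb + colSums(gw_t * s_prev)
    gI[, t, ] <- (1 - al) * gu_t
    gu_next <- gu_t
    gw_next <- gw_t
  }
  list(gI = gI, gparams = list(alpha = galpha, beta = gbeta, a = ga, b = gb))
}

#' Loss and gradients for one batch
#'
#' Runs the forward pass, the aggregated-softmax cross-entropy, and full
#' BPTT, returning gradients for every trainable tensor: weights, biases,
#' per-neuron parameters and (when trainable) per-synapse delays. The delay
#' gradient chains the loss sensitivity of each synapse's delayed signal
#' with the temporal-context factor of [delay_pseudo_gradient()].
#'
#' @param model an \code{"snn_model"}.
#' @param x input array (batch x T x n_in), already padded for delays.
#' @param labels integer labels in \code{1..n_out}.
#' @param training logical; enables dropout.
#' @param context temporal-context half-width for the delay rule.
#' @return list with \code{loss}, \code{scores}, and \code{grads} (a
#'   3-element list mirroring the model layers).
#' @export
snn_grad <- function(model, x, labels, training = TRUE, context = 3L) {
  fw <- snn_forward(model, x, training = training)
  rg <- readout_potential_grad(fw$u_out, labels)
  loss <- snn_loss(rg$scores, labels)
  delays_trainable <- function(l) {
    !is.null(model$layers[[l]]$delays) && model$layers[[l]]$delays$trainable
  }
  pb3 <- project_backward(rg$g, fw$hidden[[2]]$s_eff,
                          model$layers[[3]]$W, model$layers[[3]]$delays,
                          context, need_gs = TRUE,
                          need_gd = delays_trainable(3))
  gs2 <- pb3$gs_pre
  if (!is.null(fw$hidden[[2]]$mask)) gs2 <- gs2 * fw$hidden[[2]]$mask
  hb2 <- hidden_layer_backward(model, model$layers[[2]], fw$hidden[[2]], gs2)
  pb2 <- project_backward(hb2$gI, fw$hidden[[1]]$s_eff,
                          model$layers[[2]]$W, model$layers[[2]]$delays,
                          context, need_gs = TRUE,
                          need_gd = delays_trainable(2))
  gs1 <- pb2$gs_pre
  if (!is.null(fw$hidden[[1]]$mask)) gs1 <- gs1 * fw$hidden[[1]]$mask
  hb1 <- hidden_layer_backward(model, model$layers[[1]], fw$hidden[[1]], gs1)
  pb1 <- project_backward(hb1$gI, fw$x,
                          model$layers[[1]]$W, model$layers[[1]]$delays,
                          context, need_gs = FALSE,
                          need_gd = delays_trainable(1))
  grads <- list(
    list(W = pb1$gW, bias = pb1$gbias, delays = pb1$gdelays,
         params = hb1$gparams),
    list(W = pb2$gW, bias = pb2$gbias, delays = pb2$gdelays,
         params = hb2$gparams),
    list(W = pb3$gW, bias = pb3$gbias, delays = pb3$gdelays, params = NULL)
  )
  list(loss = loss, scores = rg$scores, grads = grads, forward = fw)
}
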