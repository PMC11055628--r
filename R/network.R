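# Two-hidden-layer feed-forward SNN with a memoryless infinite-threshold
# readout. Batched tensors are laid out (batch, time, channels) throughout.

#' Network architecture configuration
#'
#' The architecture is a fully connected feed-forward net with exactly two
#' hidden spiking layers and a readout layer of memoryless, infinite-
#' threshold neurons whose potential is just the (possibly delayed) weighted
#' input at each timestep. Delays, when enabled, live on every feed-forward
#' synapse including the readout projection.
#'
#' @param n_in input channel count.
#' @param hidden_sizes integer vector of the two hidden-layer widths.
#' @param n_out number of classes.
#' @param variant neuron variant for the hidden layers
#'   (\code{"LIF"}, \code{"AdLIF"}, \code{"cAdLIF"}).
#' @param delay_mode \code{"none"}, \code{"learnable"} (zero-initialized,
#'   trained) or \code{"fixed_random"} (heterogeneous, frozen).
#' @param d_max delay cap in timesteps.
#' @param dropout_rate dropout probability on hidden spike trains, in
#'   \code{[0, 1)}.
#' @param delay_layers integer subset of \code{1:3} naming which
#'   projections carry delays when \code{delay_mode != "none"} (1 =
#'   input->hidden1, 2 = hidden1->hidden2, 3 = hidden2->readout). Default:
#'   all feed-forward synapses, the full co-learning setup. Controlled
#'   experiments (e.g. delay recovery against a known input lag) restrict
#'   delays to the input projection so the learned compensation has a
#'   single, measurable locus.
#' @param init_gain multiplier on the Xavier-uniform weight-init limits
#'   (gain 1 = plain Xavier). Wide, densely active inputs such as binned
#'   speech reach the spiking threshold under plain Xavier; narrow sparse
#'   inputs like the bundled lag task need a larger gain for the initial
#'   membrane-potential fluctuations to straddle the threshold, where the
#'   boxcar surrogate passes gradient.
#' @return object of class \code{"snn_config"}.
#' @export
snn_config <- function(n_in, hidden_sizes = c(128, 128), n_out,
                       variant = "cAdLIF",
                       delay_mode = c("none", "learnable", "fixed_random"),
                       d_max = 25, dropout_rate = 0, init_gain = 1,
                       delay_layers = 1:3) {
  if (length(delay_mode) > 1) delay_mode <- delay_mode[[1]]
  if (!delay_mode %in% c("none", "learnable", "fixed_random")) {
    stop("unknown delay_mode: ", delay_mode)
  }
  variant <- match_variant(variant)
  if (length(hidden_sizes) != 2) {
    stop("the architecture has exactly two hidden layers; got ",
         length(hidden_sizes), " sizes")
  }
  stopifnot(n_in >= 1, n_out >= 1, all(hidden_sizes >= 1),
            dropout_rate >= 0, dropout_rate < 1, d_max >= 0, init_gain > 0,
            all(delay_layers %in% 1:3))
  structure(list(n_in = as.integer(n_in),
                 hidden_sizes = as.integer(hidden_sizes),
                 n_out = as.integer(n_out),
                 variant = variant, delay_mode = delay_mode,
                 d_max = d_max, dropout_rate = dropout_rate,
                 init_gain = init_gain,
                 delay_layers = as.integer(delay_layers)),
            class = "snn_config")
}

#' Training hyper-parameters
#'
#' Defaults follow the reference speech-command setup: Adam, delay learning
#' rate fixed at ten times the weight learning rate, and a plateau scheduler
#' that multiplies both rates by 0.7 after 5 epochs without validation
#' improvement.
#'
#' @param lr_weights learning rate for weights, biases and neuron
#'   parameters.
#' @param lr_delays learning rate for delays; default \code{10 * lr_weights}.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param scheduler_factor multiplicative learning-rate decay on plateau.
#' @param scheduler_patience epochs without improvement before decay.
#' @param seed integer seed controlling shuffling and dropout.
#' @return object of class \code{"training_config"}.
#' @export
training_config <- function(lr_weights = 0.001, lr_delays = 10 * lr_weights,
                            epochs = 10, batch_size = 32,
                            scheduler_factor = 0.7, scheduler_patience = 5,
                            seed = 1) {
  stopifnot(lr_weights > 0, lr_delays > 0, epochs >= 1, batch_size >= 1,
            scheduler_factor > 0, scheduler_factor <= 1,
            scheduler_patience >= 1)
  structure(list(lr_weights = lr_weights, lr_delays = lr_delays,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 seed = as.integer(seed)),
            class = "training_config")
}

xavier_uniform <- function(n_post, n_pre, gain = 1) {
  lim <- gain * sqrt(6 / (n_pre + n_post))
  matrix(stats::runif(n_post * n_pre, -lim, lim), n_post, n_pre)
}

#' Build and initialize an SNN model
#'
#' Weights are Xavier-uniform, biases zero, neuron parameters uniform within
#' their variant bounds, and delays per \code{delay_mode} (learnable delays
#' start at zero, i.e. the network is initialized delay-free). All
#' randomness is consumed from a single seeded stream so identical seeds
#' give identical models.
#'
#' @param config an \code{"snn_config"}.
#' @param seed integer seed.
#' @param spike_fn \code{"heaviside"} for binary spikes with the boxcar
#'   surrogate in the backward pass, or \code{"sigmoid"} for a smooth
#'   relaxation (used by gradient checks only).
#' @param sigmoid_temp temperature of the smooth relaxation.
#' @return object of class \code{"snn_model"}.
#' @export
snn_init <- function(config, seed = 1, spike_fn = c("heaviside", "sigmoid"),
                     sigmoid_temp = 0.5) {
  stopifnot(inherits(config, "snn_config"))
  spike_fn <- match.arg(spike_fn)
  set.seed(seed)
  sizes <- c(config$n_in, config$hidden_sizes, config$n_out)
  mk_delays <- function(l, post, pre) {
    if (!(l %in% config$delay_layers)) return(NULL)
    switch(config$delay_mode,
      none = NULL,
      learnable = init_delays(c(post, pre), "learnable_zero", config$d_max),
      fixed_random = init_delays(c(post, pre), "fixed_random", config$d_max))
  }
  layers <- vector("list", 3)
  for (l in 1:3) {
    post <- sizes[l + 1]; pre <- sizes[l]
    layers[[l]] <- list(
      W = xavier_uniform(post, pre, config$init_gain),
      bias = numeric(post),
      delays = mk_delays(l, post, pre),
      params = if (l < 3) init_neuron_params(post, config$variant) else NULL
    )
  }
  structure(list(config = config, layers = layers, spike_fn = spike_fn,
                 sigmoid_temp = sigmoid_temp, seed = seed),
            class = "snn_model")
}

# --- batched time-shift helpers -------------------------------------------

# shift (batch, time, channels) later in time by k, zero-filling the front
shift_time <- function(x, k) {
  if (k == 0) return(x)
  out <- array(0, dim(x)); T_len <- dim(x)[2]
  if (k < T_len) out[, (k + 1):T_len, ] <- x[, 1:(T_len - k), ]
  out
}

# shift earlier by k, zero-filling the tail
shift_time_back <- function(x, k) {
  if (k == 0) return(x)
  out <- array(0, dim(x)); T_len <- dim(x)[2]
  if (k < T_len) out[, 1:(T_len - k), ] <- x[, (k + 1):T_len, ]
  out
}

# past-minus-future temporal context summed over half-width cw
context_signal <- function(x, cw) {
  g <- array(0, dim(x))
  for (k in seq_len(cw)) g <- g + shift_time(x, k) - shift_time_back(x, k)
  g
}

flat_bt <- function(x) matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3])

# group synapses by integer effective shift; one masked weight matrix each
delay_groups <- function(W, delays) {
  if (is.null(delays)) return(list(list(shift = 0L, W = W)))
  sh <- effective_shift(delays$d)
  lapply(sort(unique(as.vector(sh))), function(k) {
    list(shift = k, W = W * (sh == k))
  })
}

# presynaptic current I (B,T,post) from s_pre (B,T,pre) through weights,
# per-synapse integer shifts and bias
project_current <- function(s_pre, W, delays, bias) {
  dm <- dim(s_pre); B <- dm[1]; T_len <- dm[2]
  n_post <- nrow(W)
  I <- array(rep(bias, each = B * T_len), dim = c(B, T_len, n_post))
  for (g in delay_groups(W, delays)) {
    I <- I + array(flat_bt(shift_time(s_pre, g$shift)) %*% t(g$W),
                   dim = c(B, T_len, n_post))
  }
  I
}

# --- forward pass ----------------------------------------------------------

spike_forward <- function(model, u, theta) {
  if (model$spike_fn == "heaviside") (u >= theta) * 1
  else 1 / (1 + exp(-(u - theta) / model$sigmoid_temp))
}

spike_backward_factor <- function(model, u, theta) {
  if (model$spike_fn == "heaviside") surrogate_derivative(u, theta)
  else {
    s <- 1 / (1 + exp(-(u - theta) / model$sigmoid_temp))
    s * (1 - s) / model$sigmoid_temp
  }
}

hidden_layer_forward <- function(model, layer, s_pre) {
  p <- layer$params
  dm <- dim(s_pre); B <- dm[1]; T_len <- dm[2]
  n <- nrow(layer$W)
  I <- project_current(s_pre, layer$W, layer$delays, layer$bias)
  al <- matrix(p$alpha, B, n, byrow = TRUE)
  be <- matrix(p$beta, B, n, byrow = TRUE)
  aa <- matrix(p$a, B, n, byrow = TRUE)
  bb <- matrix(p$b, B, n, byrow = TRUE)
  u <- array(0, dim = c(B, T_len, n))
  w <- array(0, dim = c(B, T_len, n))
  s <- array(0, dim = c(B, T_len, n))
  u_c <- w_c <- s_c <- matrix(0, B, n)
  for (t in seq_len(T_len)) {
    I_t <- matrix(I[, t, ], B, n)
    u_n <- al * u_c + (1 - al) * (I_t - w_c) - p$theta * s_c
    w_n <- be * w_c + (1 - be) * aa * u_c + bb * s_c
    s_n <- spike_forward(model, u_n, p$theta)
    u[, t, ] <- u_n; w[, t, ] <- w_n; s[, t, ] <- s_n
    u_c <- u_n; w_c <- w_n; s_c <- s_n
  }
  list(I = I, u = u, w = w, s = s)
}

#' Forward pass of the SNN
#'
#' Runs the batched discrete-time dynamics through both hidden layers and
#' the memoryless readout, optionally applying dropout to the hidden spike
#' trains (training mode only). The input must already be right-padded via
#' [pad_for_delays()] when the model carries delays.
#'
#' @param model an \code{"snn_model"}.
#' @param x input array (batch x timesteps x n_in); binary spikes or
#'   real-valued feature frames treated as input currents.
#' @param training logical; enables dropout.
#' @return list with \code{u_out} (batch x T x n_out readout potentials),
#'   \code{hidden} (per-layer forward records, spike trains in
#'   \code{$s}), and internal caches used by the backward pass.
#' @export
snn_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "snn_model"))
  if (length(dim(x)) == 2) x <- array(x, dim = c(1, dim(x)))
  if (dim(x)[3] != model$config$n_in) {
    stop("input has ", dim(x)[3], " channels, model expects ",
         model$config$n_in)
  }
  rate <- model$config$dropout_rate
  s_pre <- x
  hidden <- vector("list", 2)
  for (l in 1:2) {
    fw <- hidden_layer_forward(model, model$layers[[l]], s_pre)
    if (training && rate > 0) {
      mask <- array(stats::rbinom(length(fw$s), 1, 1 - rate) / (1 - rate),
                    dim = dim(fw$s))
    } else {
      mask <- NULL
    }
    fw$s_eff <- if (is.null(mask)) fw$s else fw$s * mask
    fw$mask <- mask
    fw$input <- s_pre
    hidden[[l]] <- fw
    s_pre <- fw$s_eff
  }
  out_layer <- model$layers[[3]]
  u_out <- project_current(s_pre, out_layer$W, out_layer$delays,
                           out_layer$bias)
  list(u_out = u_out, hidden = hidden, x = x)
}

#' Aggregate readout potentials into class scores
#'
#' Applies a softmax over classes at every timestep and sums the resulting
#' probabilities over time, so each sample's scores are positive and sum to
#' the number of timesteps.
#'
#' @param u_out readout potentials: matrix (T x classes) for a single
#'   sample or array (batch x T x classes).
#' @return matrix (batch x classes) of aggregated scores.
#' @export
aggregate_readout <- function(u_out) {
  if (length(dim(u_out)) == 2) {
    u_out <- array(u_out, dim = c(1, dim(u_out)))
  }
  dm <- dim(u_out); B <- dm[1]; T_len <- dm[2]; K <- dm[3]
  scores <- matrix(0, B, K)
  for (t in seq_len(T_len)) {
    scores <- scores + softmax_rows(matrix(u_out[, t, ], B, K))
  }
  scores
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Cross-entropy loss on aggregated scores
#'
#' Normalizes each sample's summed softmax scores to a distribution and
#' takes the mean negative log-probability of the true class over the batch.
#'
#' @param scores matrix (batch x classes) from [aggregate_readout()].
#' @param labels integer class labels in \code{1..K}.
#' @return scalar loss.
#' @export
snn_loss <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("non-finite class scores")
  share <- scores / rowSums(scores)
  idx <- cbind(seq_along(labels), labels)
  mean(-log(share[idx]))
}

#' Count trainable parameters of an architecture
#'
#' Counts feed-forward weights, per-neuron biases (hidden and readout),
#' trainable neuron parameters (1 per hidden neuron for LIF: alpha; 4 for
#' AdLIF and cAdLIF: alpha, beta, a, b) and, when \code{delay_mode} is
#' \code{"learnable"}, one delay per synapse on every projection including
#' the readout. Frozen (fixed-random) delays are not trainable and are not
#' counted.
#'
#' @param config an \code{"snn_config"}.
#' @return integer parameter count.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "snn_config"))
  sizes <- c(config$n_in, config$hidden_sizes, config$n_out)
  per_layer <- sizes[-length(sizes)] * sizes[-1]
  n_weights <- sum(per_layer)
  n_bias <- sum(sizes[-1])
  n_hidden <- sum(config$hidden_sizes)
  n_neuron <- n_hidden * if (config$variant == "LIF") 1L else 4L
  n_delay <- if (config$delay_mode == "learnable")
    sum(per_layer[config$delay_layers]) else 0L
  as.integer(n_weights + n_bias + n_neuron + n_delay)
}
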