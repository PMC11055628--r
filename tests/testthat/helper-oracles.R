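# Independent reference implementations used as oracles. These are coded
# separately from the package internals on purpose: they share no helpers
# with the code paths they check.

# plain leaky integrate-and-fire recurrence with soft reset
lif_reference <- function(I, alpha, theta = 1) {
  I <- as.matrix(I)
  T_len <- nrow(I); n <- ncol(I)
  u <- matrix(0, T_len, n); s <- matrix(0, T_len, n)
  u_c <- numeric(n); s_c <- numeric(n)
  for (t in seq_len(T_len)) {
    u_c <- alpha * u_c + (1 - alpha) * I[t, ] - theta * s_c
    s_c <- as.numeric(u_c >= theta)
    u[t, ] <- u_c
    s[t, ] <- s_c
  }
  list(u = u, s = s)
}

# build a neuron_params object with prescribed values (bypasses random init)
make_params <- function(alpha, beta, a, b, variant = "AdLIF") {
  n <- max(length(alpha), length(beta), length(a), length(b))
  structure(list(alpha = rep_len(alpha, n), beta = rep_len(beta, n),
                 a = rep_len(a, n), b = rep_len(b, n), theta = 1,
                 variant = variant,
                 bounds = neuron_param_bounds(variant),
                 trainable = c("alpha", "beta", "a", "b")),
            class = "neuron_params")
}

# single-synapse delayed-signal loss used by the delay-gradient sign oracle:
# a leaky readout integrates the delayed spike train toward a smooth target
delay_microinstance <- function(seed, T_len = 40, d_max = 15) {
  set.seed(seed)
  s <- stats::rbinom(T_len, 1, 0.15)
  Fw <- stats::runif(1, 0.5, 2)
  al <- stats::runif(1, 0.6, 0.9)
  target <- 0.3 * sin(2 * pi * seq_len(T_len) / stats::runif(1, 10, 25) +
                        stats::runif(1, 0, 6)) + 0.3
  d0 <- sample(2:8, 1)
  leaky <- function(p) {
    u <- numeric(T_len); uc <- 0
    for (t in seq_len(T_len)) {
      uc <- al * uc + (1 - al) * Fw * p[t]
      u[t] <- uc
    }
    u
  }
  loss_at <- function(d) {
    dm <- init_delays(c(1, 1), "learnable_zero", d_max = d_max)
    dm$d[] <- d
    p <- apply_delays(matrix(s, ncol = 1), dm)[, 1, 1]
    sum((leaky(p) - target)^2)
  }
  list(s = s, Fw = Fw, al = al, target = target, d0 = d0,
       leaky = leaky, loss_at = loss_at, T_len = T_len, d_max = d_max)
}

# pseudo-gradient of the micro-instance loss wrt the delay, chained by hand
delay_microinstance_pseudograd <- function(mi, context = 3L) {
  dm <- init_delays(c(1, 1), "learnable_zero", d_max = mi$d_max)
  dm$d[] <- mi$d0
  p <- apply_delays(matrix(mi$s, ncol = 1), dm)[, 1, 1]
  u <- mi$leaky(p)
  dLdu <- 2 * (u - mi$target)
  dLdp <- numeric(mi$T_len); acc <- 0
  for (t in mi$T_len:1) {
    acc <- dLdu[t] + mi$al * acc
    dLdp[t] <- (1 - mi$al) * mi$Fw * acc
  }
  sum(dLdp * delay_pseudo_gradient(p, context))
}

# tiny reference lag-task training setup shared by several tests
tiny_lag_setup <- function(seed, delay_mode = "learnable", epochs = 5,
                           hidden = c(8, 8), lags = c(0, 5)) {
  task <- generate_lag_task(n_samples = 60, n_channels = 4, T_steps = 30,
                            lags = lags, n_ref_spikes = 6,
                            noise_rate = 0.02, seed = seed)
  net <- snn_config(4, hidden, length(lags), "cAdLIF",
                    delay_mode = delay_mode, d_max = 8, init_gain = 5)
  cfg <- training_config(lr_weights = 0.01, epochs = epochs,
                         batch_size = 20, seed = seed)
  list(task = task, net = net, cfg = cfg,
       data = list(x = task$x, y = task$y))
}
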