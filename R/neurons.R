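#' Parameter bounds for the supported neuron variants
#'
#' Each hidden neuron is an adaptive leaky integrate-and-fire (AdLIF) unit
#' with four per-neuron constants: the membrane-potential decay \code{alpha},
#' the adaptation-current decay \code{beta}, the sub-threshold coupling
#' \code{a} of the membrane potential into the adaptation current, and the
#' spike-triggered adaptation increment \code{b}. The constrained variant
#' ("cAdLIF") restricts \code{a} and \code{b} to non-negative values, which
#' excludes the self-sustaining ("chaotic") firing regime; the unconstrained
#' "AdLIF" baseline permits negative \code{a}. "LIF" fixes \code{a = b = 0}
#' so the adaptation current vanishes identically.
#'
#' @param variant one of \code{"LIF"}, \code{"AdLIF"}, \code{"cAdLIF"}.
#' @return named list of \code{c(lower, upper)} bounds for
#'   \code{alpha}, \code{beta}, \code{a}, \code{b}.
#' @export
neuron_param_bounds <- function(variant = c("cAdLIF", "AdLIF", "LIF")) {
  variant <- match_variant(variant)
  bounds <- list(
    alpha = c(0.36, 0.96),
    beta  = c(0.96, 0.99),
    a     = c(0, 1),
    b     = c(0, 2)
  )
  if (variant == "AdLIF") bounds$a <- c(-1, 1)
  if (variant == "LIF") {
    bounds$a <- c(0, 0)
    bounds$b <- c(0, 0)
  }
  bounds
}

match_variant <- function(variant) {
  if (length(variant) > 1) variant <- variant[[1]]
  ok <- c("LIF", "AdLIF", "cAdLIF")
  if (!is.character(variant) || !(variant %in% ok)) {
    stop("unknown neuron variant: ", paste(variant, collapse = ", "),
         " (expected one of ", paste(ok, collapse = ", "), ")")
  }
  variant
}

#' Initialize per-neuron trainable parameters
#'
#' Draws each parameter independently and uniformly within its variant's
#' bounds (neuronal heterogeneity); for \code{"LIF"} the adaptation
#' parameters are fixed at zero and marked non-trainable. The firing
#' threshold \code{theta} is fixed at 1 and never trained.
#'
#' @param n_neurons number of neurons (>= 1).
#' @param variant neuron variant, see [neuron_param_bounds()].
#' @param rng_seed integer seed; draws are reproducible under a fixed seed.
#' @return an object of class \code{"neuron_params"}: list with numeric
#'   vectors \code{alpha}, \code{beta}, \code{a}, \code{b} (length
#'   \code{n_neurons}), scalar \code{theta = 1}, the \code{variant} and the
#'   per-parameter \code{bounds}.
#' @export
init_neuron_params <- function(n_neurons, variant = "cAdLIF", rng_seed = NULL) {
  stopifnot(is.numeric(n_neurons), length(n_neurons) == 1, n_neurons >= 1)
  variant <- match_variant(variant)
  bounds <- neuron_param_bounds(variant)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  draw <- function(bd) stats::runif(n_neurons, bd[1], bd[2])
  p <- structure(list(
    alpha = draw(bounds$alpha),
    beta  = draw(bounds$beta),
    a     = draw(bounds$a),
    b     = draw(bounds$b),
    theta = 1,
    variant = variant,
    bounds = bounds,
    trainable = if (variant == "LIF") "alpha" else c("alpha", "beta", "a", "b")
  ), class = "neuron_params")
  p
}

#' Clip neuron parameters to their declared bounds
#'
#' Projects every parameter onto its closed interval (idempotent). Applied
#' after every optimizer step so the discrete-time dynamics stay well-posed
#' throughout training. \code{theta} is fixed at 1 and untouched.
#'
#' @param params a \code{"neuron_params"} object.
#' @return clipped \code{"neuron_params"} object.
#' @export
clip_neuron_params <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  bd <- params$bounds
  for (nm in c("alpha", "beta", "a", "b")) {
    params[[nm]] <- pmin(pmax(params[[nm]], bd[[nm]][1]), bd[[nm]][2])
  }
  params
}

#' Boxcar surrogate derivative of the spike nonlinearity
#'
#' The spike indicator s[t] = [u[t] >= theta] is a Heaviside step whose exact
#' derivative is zero almost everywhere; the backward pass replaces it with a
#' boxcar window: \code{height} when \code{|u - theta| <= half_width}
#' (boundary inclusive), 0 otherwise. Defaults are height 0.5 on a window of
#' half-width 0.5.
#'
#' @param u membrane potential (any numeric array).
#' @param theta firing threshold (default 1).
#' @param cfg list with \code{half_width} and \code{height}, both > 0.
#' @return array of the same shape as \code{u} with the surrogate factor.
#' @export
surrogate_derivative <- function(u, theta = 1,
                                 cfg = list(half_width = 0.5, height = 0.5)) {
  stopifnot(cfg$half_width > 0, cfg$height > 0)
  cfg$height * (abs(u - theta) <= cfg$half_width)
}

#' One discrete-time step of the (c)AdLIF dynamics
#'
#' Advances membrane potential \code{u}, adaptation current \code{w} and
#' spike indicator \code{s} by one step of
#' \deqn{u[t] = \alpha u[t-1] + (1-\alpha)(I[t] - w[t-1]) - \theta s[t-1]}
#' \deqn{w[t] = \beta w[t-1] + (1-\beta) a\, u[t-1] + b\, s[t-1]}
#' \deqn{s[t] = [u[t] \ge \theta]}
#' The reset is "soft": a spike subtracts \code{theta} from the next
#' potential rather than resetting it to a constant. Evaluation order matters
#' and is exactly as written: the new \code{u} uses the old \code{w}, and the
#' new \code{w} uses the old \code{u}.
#'
#' State entries may be vectors (one neuron per entry) or matrices
#' (batch x neuron); parameters broadcast along the batch dimension.
#'
#' @param state list with \code{u}, \code{w}, \code{s} at t-1.
#' @param I_t input current at t, same shape as \code{state$u}.
#' @param params a \code{"neuron_params"} object.
#' @return list with \code{u}, \code{w}, \code{s} at t.
#' @export
neuron_step <- function(state, I_t, params) {
  stopifnot(inherits(params, "neuron_params"))
  n <- length(params$alpha)
  if (ncol(as.matrix(state$u)) != n && length(state$u) != n) {
    stop("state/params shape mismatch: state has ",
         length(state$u), " entries, params ", n, " neurons")
  }
  al <- params$alpha; be <- params$beta
  if (is.matrix(state$u)) {
    al <- matrix(al, nrow(state$u), n, byrow = TRUE)
    be <- matrix(be, nrow(state$u), n, byrow = TRUE)
    aa <- matrix(params$a, nrow(state$u), n, byrow = TRUE)
    bb <- matrix(params$b, nrow(state$u), n, byrow = TRUE)
  } else {
    aa <- params$a; bb <- params$b
  }
  u_new <- al * state$u + (1 - al) * (I_t - state$w) - params$theta * state$s
  w_new <- be * state$w + (1 - be) * aa * state$u + bb * state$s
  s_new <- (u_new >= params$theta) * 1
  list(u = u_new, w = w_new, s = s_new)
}

#' Zero-initialized neuron state
#'
#' @param n_neurons number of neurons.
#' @param batch optional batch size; if given, state entries are
#'   \code{batch x n_neurons} matrices.
#' @return list with zero \code{u}, \code{w}, \code{s}.
#' @export
init_neuron_state <- function(n_neurons, batch = NULL) {
  z <- if (is.null(batch)) numeric(n_neurons) else matrix(0, batch, n_neurons)
  list(u = z, w = z, s = z)
}

#' Simulate a neuron population over a full input sequence
#'
#' Repeatedly applies [neuron_step()] from a zero state and records the
#' trajectories. Used by the single-neuron regime analysis and as a reference
#' for tests; the training path has its own batched recurrence.
#'
#' @param I matrix (timesteps x neurons) of input currents.
#' @param params a \code{"neuron_params"} object.
#' @return list of matrices \code{u}, \code{w}, \code{s}
#'   (timesteps x neurons).
#' @export
simulate_neurons <- function(I, params) {
  I <- as.matrix(I)
  T_len <- nrow(I)
  n <- ncol(I)
  st <- init_neuron_state(n)
  u <- w <- s <- matrix(0, T_len, n)
  for (t in seq_len(T_len)) {
    st <- neuron_step(st, I[t, ], params)
    u[t, ] <- st$u; w[t, ] <- st$w; s[t, ] <- st$s
  }
  list(u = u, w = w, s = s)
}
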