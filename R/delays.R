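# Per-synapse propagation delays: storage, the delayed-spike forward model,
# and the temporal-context pseudo-gradient used to train them.

#' Create a per-synapse delay matrix
#'
#' Delays are stored as continuous trainable values d (in timesteps) on
#' \code{[0, d_max]}; the forward pass uses the integer effective shift
#' \code{round(d)} (nearest, ties toward zero). Learnable delays start at
#' zero (a delay-free network); the fixed-random mode draws heterogeneous
#' frozen delays uniformly on \code{[0, d_max]}.
#'
#' @param shape integer pair \code{c(post, pre)}.
#' @param mode \code{"learnable_zero"} or \code{"fixed_random"}.
#' @param d_max delay cap in timesteps (default 25).
#' @param rng_seed integer seed for the fixed-random mode.
#' @return object of class \code{"delay_matrix"}: list with matrix \code{d}
#'   (post x pre), scalar \code{d_max} and logical \code{trainable}.
#' @export
init_delays <- function(shape, mode = c("learnable_zero", "fixed_random"),
                        d_max = 25, rng_seed = NULL) {
  if (length(mode) > 1) mode <- mode[[1]]
  if (!mode %in% c("learnable_zero", "fixed_random")) {
    stop("unknown delay mode: ", mode)
  }
  stopifnot(length(shape) == 2, all(shape >= 1), d_max >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  d <- if (mode == "learnable_zero") {
    matrix(0, shape[1], shape[2])
  } else {
    matrix(stats::runif(prod(shape), 0, d_max), shape[1], shape[2])
  }
  structure(list(d = d, d_max = d_max, trainable = mode == "learnable_zero"),
            class = "delay_matrix")
}

#' Clip delays onto [0, d_max]
#'
#' Projection onto the closed interval; idempotent. Run after every
#' optimizer step on trainable delays.
#'
#' @param delays a \code{"delay_matrix"}.
#' @return clipped \code{"delay_matrix"}.
#' @export
clip_delays <- function(delays) {
  stopifnot(inherits(delays, "delay_matrix"))
  delays$d <- pmin(pmax(delays$d, 0), delays$d_max)
  delays
}

#' Integer effective shift of a delay value
#'
#' Nearest-integer rounding with ties toward zero, so a continuous delay of
#' 2.5 shifts by 2 timesteps. Delays are non-negative by contract.
#'
#' @param d numeric delay values (>= 0).
#' @return integer shifts, same shape.
#' @export
effective_shift <- function(d) {
  s <- ceiling(d - 0.5)
  s[s < 0] <- 0
  storage.mode(s) <- "integer"
  s
}

#' Apply per-synapse delays to a presynaptic signal
#'
#' Realizes the delay kernel as an integer time shift: for synapse (i, j),
#' \code{p[t, i, j] = s[t - round(d_ij), j]}, with zeros for
#' \code{t <= round(d_ij)} and content shifted beyond the horizon dropped.
#' The result is the per-synapse delayed signal that feeds the weighted sum
#' of the presynaptic current; pad the input with [pad_for_delays()]
#' upstream if delayed content must not be truncated.
#'
#' @param s_pre matrix (timesteps x pre) of spikes or input currents.
#' @param delays a \code{"delay_matrix"} with \code{pre} columns.
#' @return array (timesteps x post x pre) of delayed signals.
#' @export
apply_delays <- function(s_pre, delays) {
  stopifnot(inherits(delays, "delay_matrix"))
  if (any(delays$d < 0) || any(delays$d > delays$d_max)) {
    stop("delays outside [0, d_max]; clip_delays must run first")
  }
  s_pre <- as.matrix(s_pre)
  T_len <- nrow(s_pre)
  n_pre <- ncol(s_pre)
  n_post <- nrow(delays$d)
  if (ncol(delays$d) != n_pre) {
    stop("delay matrix has ", ncol(delays$d), " presynaptic columns, input has ",
         n_pre, " channels")
  }
  sh <- effective_shift(delays$d)
  p <- array(0, dim = c(T_len, n_post, n_pre))
  for (i in seq_len(n_post)) {
    for (j in seq_len(n_pre)) {
      k <- sh[i, j]
      if (k < T_len) {
        p[(k + 1):T_len, i, j] <- s_pre[1:(T_len - k), j]
      }
    }
  }
  p
}

#' Temporal-context pseudo-gradient of a delayed signal
#'
#' The derivative of the delayed signal with respect to its delay is not
#' defined on the 1-timestep grid; the delay learning rule replaces it with
#' a temporal-context difference of half-width \code{c}:
#' \deqn{g[t] = \sum_{k=1}^{c} (p[t-k] - p[t+k])}
#' with out-of-range terms taken as zero. The past-minus-future window is
#' positively aligned with the true sensitivity dp/dd (shifting a signal
#' later increases it where the recent past exceeded the near future), so
#' the chained update is a plain descent step on the continuous delay.
#'
#' @param p numeric vector, matrix (timesteps x series) or array with time
#'   in the first dimension.
#' @param context integer half-width c >= 1 (default 3, the empirically
#'   optimal width).
#' @return same shape as \code{p}: the per-timestep context factor.
#' @export
delay_pseudo_gradient <- function(p, context = 3L) {
  if (!is.numeric(context) || length(context) != 1 || context < 1) {
    stop("temporal context half-width must be an integer >= 1")
  }
  context <- as.integer(context)
  dm <- dim(p)
  x <- if (is.null(dm)) matrix(p, ncol = 1) else
    matrix(p, nrow = dm[1])                      # flatten trailing dims
  T_len <- nrow(x)
  g <- matrix(0, T_len, ncol(x))
  for (k in seq_len(context)) {
    past <- rbind(matrix(0, k, ncol(x)), x[seq_len(max(T_len - k, 0)), , drop = FALSE])
    futr <- rbind(x[seq_len(T_len)[-seq_len(min(k, T_len))], , drop = FALSE],
                  matrix(0, min(k, T_len), ncol(x)))
    g <- g + past - futr
  }
  if (is.null(dm)) as.vector(g) else array(g, dim = dm)
}

#' Right-pad a time-indexed array for delayed content
#'
#' Appends \code{d_max} all-zero timesteps so spikes shifted by up to
#' \code{d_max} stay inside the simulated horizon. Vectors and matrices are
#' taken as time-first (timesteps, or timesteps x channels); 3-d arrays as
#' batched (samples x timesteps x channels), the layout produced by
#' [generate_lag_task()].
#'
#' @param x vector, matrix or 3-d array as above.
#' @param d_max number of zero timesteps to append.
#' @return extended array, T -> T + d_max.
#' @export
pad_for_delays <- function(x, d_max) {
  stopifnot(d_max >= 0)
  if (d_max == 0) return(x)
  dm <- dim(x)
  if (is.null(dm)) return(c(x, numeric(d_max)))
  if (length(dm) == 2) return(rbind(x, matrix(0, d_max, dm[2])))
  if (length(dm) == 3) {
    out <- array(0, dim = c(dm[1], dm[2] + d_max, dm[3]))
    out[, seq_len(dm[2]), ] <- x
    return(out)
  }
  stop("pad_for_delays supports vectors, matrices and 3-d arrays")
}
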