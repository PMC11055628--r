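# Single-neuron adaptation-regime mapping, learned-parameter summaries and
# spike-rate accounting.

#' Default probe spike train for the regime map
#'
#' A fixed train of regularly spaced input spikes (12 by default, one every
#' 8 timesteps) delivered through a synaptic weight chosen so that an
#' isolated spike is sub-threshold while successive spikes summate above
#' threshold: the weight is the midpoint of
#' \code{[1/((1-alpha)(1+alpha^isi)), 1/(1-alpha)]}. All regime assertions
#' are made relative to this probe; it is a configurable fixture, not a
#' universal constant.
#'
#' @param n_spikes number of probe spikes.
#' @param isi inter-spike interval in timesteps.
#' @param start timestep of the first spike.
#' @param alpha membrane decay used to scale the weight.
#' @return list with \code{spike_times}, \code{T} (horizon through the last
#'   spike), \code{weight}, \code{n_spikes}.
#' @export
default_probe <- function(n_spikes = 12, isi = 8, start = 5, alpha = 0.9) {
  times <- start + isi * (seq_len(n_spikes) - 1)
  lo <- 1 / ((1 - alpha) * (1 + alpha^isi))
  hi <- 1 / (1 - alpha)
  list(spike_times = times, T = max(times) + 1, weight = (lo + hi) / 2,
       n_spikes = n_spikes)
}

#' Map single-neuron spiking regimes over the (a, b) adaptation plane
#'
#' For every (a, b) grid cell, simulates one AdLIF neuron on the fixed probe
#' train plus \code{T_extra} silent tail steps and counts output spikes.
#' Cells producing more output spikes than the probe contains input spikes
#' are flagged chaotic: there the adaptation current feeds back positively
#' and the neuron can keep firing after input ceases. The plain LIF model
#' sits at (a, b) = (0, 0). All cells are simulated jointly as one neuron
#' population, so a 41 x 41 grid is a single vectorized run.
#'
#' Two conventions exist for how the membrane potential couples into the
#' adaptation current. The trainable neuron scales the coupling by
#' (1 - beta) (\code{coupling = "scaled"}); under that form the
#' sub-threshold map is a contraction for every |a| < 1, and each spike
#' strictly damps the marginal mode at a = -1, so no cell of the standard
#' grid can fire more than it is driven. The baseline adaptive-LIF
#' implementation lineage couples the potential unscaled,
#' w <- beta w + a u + b s (\code{coupling = "unscaled"}), which is
#' unstable for a < -(1 - beta) — essentially the whole negative-a
#' half-plane. The regime analysis defaults to the unscaled form because
#' that instability is the phenomenon motivating the non-negativity
#' constraint on a; both forms coincide at a = b = 0 (the LIF anchor).
#'
#' @param probe probe description from [default_probe()] (or a compatible
#'   list).
#' @param a_grid,b_grid numeric grids of adaptation parameters; the AdLIF
#'   probing grid spans negative and positive a.
#' @param base_params list with the shared \code{alpha} and \code{beta}.
#' @param T_extra silent steps appended after the last input spike to
#'   detect self-sustained firing.
#' @param coupling \code{"unscaled"} (default) or \code{"scaled"}, see
#'   above.
#' @return object of class \code{"regime_map"}: list with \code{a_grid},
#'   \code{b_grid}, matrices \code{counts}, \code{tail_counts} and
#'   \code{chaotic} (a x b), \code{n_input_spikes}, \code{probe},
#'   \code{base_params}, \code{coupling}.
#' @export
regime_map <- function(probe = default_probe(),
                       a_grid = seq(-1, 1, length.out = 41),
                       b_grid = seq(0, 2, length.out = 41),
                       base_params = list(alpha = 0.9, beta = 0.98),
                       T_extra = 100,
                       coupling = c("unscaled", "scaled")) {
  coupling <- match.arg(coupling)
  if (!length(a_grid) || !length(b_grid)) stop("empty (a, b) grid")
  if (!length(probe$spike_times)) stop("probe must contain >= 1 spike")
  cells <- expand.grid(a = a_grid, b = b_grid)
  n <- nrow(cells)
  a_eff <- if (coupling == "unscaled") {
    cells$a / (1 - base_params$beta)   # undo the step()-side (1-beta) scale
  } else {
    cells$a
  }
  params <- structure(list(
    alpha = rep(base_params$alpha, n), beta = rep(base_params$beta, n),
    a = a_eff, b = cells$b, theta = 1,
    variant = "AdLIF", bounds = neuron_param_bounds("AdLIF"),
    trainable = character(0)), class = "neuron_params")
  T_total <- probe$T + T_extra
  I <- matrix(0, T_total, n)
  I[probe$spike_times, ] <- probe$weight
  sim <- simulate_neurons(I, params)
  counts <- matrix(colSums(sim$s), length(a_grid), length(b_grid))
  tail_idx <- seq(max(probe$spike_times) + 1, T_total)
  tails <- matrix(colSums(sim$s[tail_idx, , drop = FALSE]),
                  length(a_grid), length(b_grid))
  structure(list(a_grid = a_grid, b_grid = b_grid, counts = counts,
                 tail_counts = tails,
                 chaotic = counts > probe$n_spikes,
                 n_input_spikes = probe$n_spikes, probe = probe,
                 base_params = base_params, coupling = coupling),
            class = "regime_map")
}

#' Tabulate a regime map
#'
#' @param rm a \code{"regime_map"}.
#' @return data.frame with columns a, b, count, tail_count, chaotic.
#' @export
regime_map_table <- function(rm) {
  stopifnot(inherits(rm, "regime_map"))
  g <- expand.grid(a = rm$a_grid, b = rm$b_grid)
  data.frame(a = g$a, b = g$b, count = as.vector(rm$counts),
             tail_count = as.vector(rm$tail_counts),
             chaotic = as.vector(rm$chaotic))
}

#' Heatmap of a regime map
#'
#' @param rm a \code{"regime_map"}.
#' @return a ggplot object: output spike count over the (a, b) plane with
#'   chaotic cells outlined.
#' @export
plot_regime_map <- function(rm) {
  df <- regime_map_table(rm)
  ggplot2::ggplot(df, ggplot2::aes(x = a, y = b)) +
    ggplot2::geom_tile(ggplot2::aes(fill = count)) +
    ggplot2::geom_point(data = df[df$chaotic, , drop = FALSE],
                        shape = 4, size = 0.6, colour = "red") +
    ggplot2::scale_fill_viridis_c(name = "output spikes") +
    ggplot2::labs(x = "a (sub-threshold coupling)",
                  y = "b (spike-triggered increment)",
                  title = sprintf("Spiking regimes, %d-spike probe",
                                  rm$n_input_spikes))
}

#' Histograms of learned parameters
#'
#' Bins the per-neuron parameters (alpha, beta, a, b) of each hidden layer
#' and, when present, the per-synapse delays of every projection (the mass
#' at zero is kept in the first bin).
#'
#' @param model an \code{"snn_model"}.
#' @param bins bin count per histogram.
#' @return data.frame with columns layer, param, mid, count.
#' @export
parameter_distributions <- function(model, bins = 20) {
  stopifnot(inherits(model, "snn_model"))
  out <- list()
  histo <- function(x, lo, hi) {
    br <- seq(lo, hi, length.out = bins + 1)
    h <- graphics::hist(pmin(pmax(x, lo), hi), breaks = br, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  for (l in 1:2) {
    p <- model$layers[[l]]$params
    for (nm in c("alpha", "beta", "a", "b")) {
      bd <- p$bounds[[nm]]
      if (bd[1] == bd[2]) bd <- bd + c(-0.5, 0.5)
      h <- histo(p[[nm]], bd[1], bd[2])
      out[[length(out) + 1]] <- cbind(layer = paste0("hidden", l),
                                      param = nm, h)
    }
  }
  for (l in 1:3) {
    dl <- model$layers[[l]]$delays
    if (!is.null(dl)) {
      h <- histo(as.vector(dl$d), 0, dl$d_max)
      out[[length(out) + 1]] <- cbind(
        layer = c("hidden1", "hidden2", "readout")[l], param = "delay", h)
    }
  }
  do.call(rbind, out)
}

#' @rdname parameter_distributions
#' @param pd a data.frame from \code{parameter_distributions()}.
#' @return \code{plot_parameter_distributions}: a ggplot object.
#' @export
plot_parameter_distributions <- function(pd) {
  ggplot2::ggplot(pd, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(layer ~ param, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "neurons / synapses")
}

#' Average spikes per neuron per sample
#'
#' @param records list of hidden spike arrays (batch x T x neurons), one
#'   per hidden layer, as recorded by [snn_forward()].
#' @param n_samples number of samples the records cover.
#' @return list with \code{overall} and \code{per_layer} spike rates.
#' @export
spike_rate_report <- function(records, n_samples) {
  stopifnot(n_samples >= 1)
  totals <- vapply(records, sum, 0)
  sizes <- vapply(records, function(r) dim(r)[3], 0)
  list(overall = sum(totals) / (sum(sizes) * n_samples),
       per_layer = totals / (sizes * n_samples))
}
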