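test_that("the discrete-time recurrence reproduces a hand-evaluated trajectory", {
  # alpha = 0.5, beta = 0.9, a = 0.5, b = 1, I = (2, 0, 0), zero init:
  # t1: u = 0.5*(2) = 1.0  -> spike; w = 0
  # t2: u = 0.5*1 + 0.5*(0 - 0) - 1 = -0.5; w = 0.9*0 + 0.1*0.5*1 + 1 = 1.05
  # t3: u = 0.5*(-0.5) + 0.5*(0 - 1.05) = -0.775; w = 0.9*1.05 + 0.1*0.5*(-0.5)
  p <- make_params(0.5, 0.9, 0.5, 1)
  sim <- simulate_neurons(matrix(c(2, 0, 0), 3, 1), p)
  expect_equal(as.vector(sim$s), c(1, 0, 0))
  expect_equal(as.vector(sim$u), c(1.0, -0.5, -0.775))
})

test_that("zero state with zero input is a fixed point", {
  p <- make_params(0.7, 0.97, 0.3, 0.5)
  sim <- simulate_neurons(matrix(0, 10, 1), p)
  expect_true(all(sim$u == 0) && all(sim$w == 0) && all(sim$s == 0))
})

test_that("with a = b = 0 the trajectory is bit-identical to a plain LIF recurrence", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(1:4, 1)
    alpha <- runif(n, 0.36, 0.96)
    p <- make_params(alpha, runif(n, 0.96, 0.99), 0, 0)
    I <- matrix(rnorm(20 * n, 0.5, 1.5), 20, n)
    sim <- simulate_neurons(I, p)
    ref <- lif_reference(I, alpha)
    expect_identical(sim$u, ref$u)
    expect_identical(sim$s, ref$s)
    expect_true(all(sim$w == 0))
  }
})

test_that("a spike at t-1 soft-resets the potential by exactly theta", {
  p <- make_params(0.8, 0.97, 0.4, 0.6)
  st_spiked <- list(u = 1.3, w = 0.2, s = 1)
  st_quiet <- list(u = 1.3, w = 0.2, s = 0)
  out_spiked <- neuron_step(st_spiked, 0.5, p)
  out_quiet <- neuron_step(st_quiet, 0.5, p)
  expect_equal(out_quiet$u - out_spiked$u, p$theta)
})

test_that("spikes are binary and state stays finite over long bounded input", {
  set.seed(5)
  p <- init_neuron_params(8, "cAdLIF", rng_seed = 3)
  st <- init_neuron_state(8)
  for (t in 1:10000) {
    st <- neuron_step(st, runif(8, -1, 2), p)
  }
  expect_true(all(st$s %in% c(0, 1)))
  expect_true(all(is.finite(st$u)) && all(is.finite(st$w)))
})

test_that("initialization draws lie within the declared bounds and are seeded", {
  p <- init_neuron_params(1000, "cAdLIF", rng_seed = 1)
  expect_true(min(p$alpha) >= 0.36 && max(p$alpha) <= 0.96)
  expect_true(min(p$beta) >= 0.96 && max(p$beta) <= 0.99)
  expect_true(min(p$a) >= 0 && max(p$a) <= 1)
  expect_true(min(p$b) >= 0 && max(p$b) <= 2)
  p2 <- init_neuron_params(1000, "cAdLIF", rng_seed = 1)
  expect_identical(p, p2)
})

test_that("LIF init forces zero adaptation and only alpha is trainable", {
  p <- init_neuron_params(4, "LIF", rng_seed = 0)
  expect_true(all(p$a == 0) && all(p$b == 0))
  expect_identical(p$trainable, "alpha")
})

test_that("unknown variant names are rejected", {
  expect_error(init_neuron_params(4, "GLIF"), "unknown neuron variant")
})

test_that("state/parameter shape mismatch is a contract violation", {
  p <- init_neuron_params(4, "cAdLIF", rng_seed = 1)
  expect_error(neuron_step(init_neuron_state(3), numeric(3), p),
               "shape mismatch")
})

test_that("the boxcar surrogate is 0.5 inside |u - theta| <= 0.5 (inclusive) and 0 outside", {
  expect_equal(surrogate_derivative(1.0), 0.5)
  expect_equal(surrogate_derivative(1.5), 0.5)
  expect_equal(surrogate_derivative(0.5), 0.5)
  expect_equal(surrogate_derivative(0.4), 0)
  expect_equal(surrogate_derivative(1.51), 0)
  expect_error(surrogate_derivative(1, cfg = list(half_width = -1, height = 0.5)))
})

test_that("clipping projects onto the bounds and is idempotent", {
  p <- init_neuron_params(50, "cAdLIF", rng_seed = 2)
  p$alpha[1] <- 1.2
  p$a[2] <- -0.3
  q <- clip_neuron_params(p)
  expect_equal(q$alpha[1], 0.96)
  expect_equal(q$a[2], 0)
  set.seed(9)
  for (rep in 1:20) {
    r <- p
    for (nm in c("alpha", "beta", "a", "b")) {
      r[[nm]] <- r[[nm]] + rnorm(50, 0, 2)
    }
    r1 <- clip_neuron_params(r)
    expect_identical(clip_neuron_params(r1), r1)
    for (nm in c("alpha", "beta", "a", "b")) {
      bd <- r1$bounds[[nm]]
      expect_true(all(r1[[nm]] >= bd[1] & r1[[nm]] <= bd[2]))
    }
  }
  expect_identical(clip_neuron_params(q), q)
})

test_that("AdLIF baseline bounds admit negative a, cAdLIF does not", {
  expect_equal(neuron_param_bounds("AdLIF")$a, c(-1, 1))
  expect_equal(neuron_param_bounds("cAdLIF")$a, c(0, 1))
})
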