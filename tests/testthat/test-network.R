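test_that("aggregated class scores are per-timestep softmaxes summed over time", {
  u0 <- array(0, dim = c(3, 10, 4))
  sc <- aggregate_readout(u0)
  expect_equal(sc, matrix(2.5, 3, 4))
  u1 <- matrix(rnorm(4), 1, 4)          # single timestep reduces to one softmax
  expect_equal(as.vector(aggregate_readout(u1)),
               as.vector(exp(u1) / sum(exp(u1))))
  set.seed(3)
  ur <- array(rnorm(2 * 7 * 5), dim = c(2, 7, 5))
  expect_equal(rowSums(aggregate_readout(ur)), c(7, 7))
})

test_that("cross-entropy on normalized scores matches arithmetic oracles", {
  expect_equal(snn_loss(matrix(1, 1, 6), 1L), log(6))
  # batch of 2 with true-class shares 0.5 and 0.25
  sc <- rbind(c(2, 1, 1), c(1, 1, 2))
  expect_equal(snn_loss(sc, c(1L, 2L)), (log(2) + log(4)) / 2)
  # true-class share -> 1 drives the loss toward 0
  sc1 <- matrix(c(1e9, 1, 1), 1, 3)
  expect_lt(snn_loss(sc1, 1L), 1e-6)
  expect_error(snn_loss(matrix(c(NaN, 1), 1, 2), 1L), "non-finite")
})

test_that("all-zero input with zero biases yields silent hidden layers and zero readout", {
  cfgn <- snn_config(5, c(6, 6), 3, "cAdLIF", "none")
  m <- snn_init(cfgn, seed = 2)
  fw <- snn_forward(m, array(0, dim = c(2, 12, 5)))
  expect_true(all(fw$u_out == 0))
  expect_equal(sum(fw$hidden[[1]]$s) + sum(fw$hidden[[2]]$s), 0)
})

test_that("a delay-enabled network with all-zero delays matches the delay-free network", {
  cfg_nd <- snn_config(4, c(8, 8), 2, "cAdLIF", "none")
  cfg_d <- snn_config(4, c(8, 8), 2, "cAdLIF", "learnable", d_max = 6)
  m_nd <- snn_init(cfg_nd, seed = 31)
  m_d <- snn_init(cfg_d, seed = 31)
  set.seed(77)
  x <- array(rbinom(3 * 20 * 4, 1, 0.3), dim = c(3, 20, 4))
  out_nd <- snn_forward(m_nd, x)
  out_d <- snn_forward(m_d, x)
  expect_identical(out_d$u_out, out_nd$u_out)
  expect_identical(out_d$hidden[[1]]$s, out_nd$hidden[[1]]$s)
})

test_that("input channel mismatch is a contract violation", {
  m <- snn_init(snn_config(4, c(5, 5), 2, "LIF", "none"), seed = 1)
  expect_error(snn_forward(m, array(0, dim = c(1, 10, 3))), "channels")
})

test_that("a LIF neuron driven by equidistant sub-threshold inputs fires at the last input", {
  # four equal-weight input spikes whose running sum first crosses threshold
  # at the fourth arrival
  alpha <- 0.9
  times <- c(5, 10, 15, 20)
  decay <- sum(alpha^(20 - times))
  w <- 1 / ((1 - alpha) * decay) * 1.02   # just supra-threshold at t4 only
  I <- matrix(0, 30, 1)
  I[times, 1] <- w
  sim <- lif_reference(I, alpha)
  p <- make_params(alpha, 0.97, 0, 0)
  sim2 <- simulate_neurons(I, p)
  expect_equal(sum(sim2$s), 1)
  expect_equal(which(sim2$s[, 1] == 1), 20)
  expect_identical(sim2$s, sim$s)
})

test_that("parameter accounting follows the architecture and delay mode", {
  gsc <- function(variant, mode) {
    count_parameters(snn_config(40, c(512, 512), 35, variant, mode))
  }
  expect_equal(round(gsc("LIF", "none") / 1e6, 2), 0.30)
  expect_equal(round(gsc("LIF", "learnable") / 1e6, 2), 0.60)
  expect_equal(round(gsc("cAdLIF", "learnable") / 1e6, 2), 0.61)
  # frozen delays are not trainable parameters
  expect_equal(gsc("cAdLIF", "fixed_random"), gsc("cAdLIF", "none"))
  # restricting delay layers counts only those projections
  c1 <- snn_config(10, c(4, 4), 2, "LIF", "learnable", delay_layers = 1L)
  expect_equal(count_parameters(c1),
               count_parameters(snn_config(10, c(4, 4), 2, "LIF", "none")) + 40L)
})

test_that("BPTT gradients match central finite differences on a small smooth net", {
  cfgn <- snn_config(3, c(3, 3), 2, "cAdLIF", "learnable", d_max = 3)
  m <- snn_init(cfgn, seed = 7, spike_fn = "sigmoid", sigmoid_temp = 0.4)
  set.seed(42)
  for (l in 1:3) {
    m$layers[[l]]$delays$d[] <- runif(length(m$layers[[l]]$delays$d), 0, 3)
  }
  x <- array(runif(2 * 5 * 3, 0, 2), dim = c(2, 5, 3))
  y <- c(1L, 2L)
  res <- snn_grad(m, x, y, training = FALSE)
  lossf <- function(mm) {
    snn_loss(aggregate_readout(snn_forward(mm, x)$u_out), y)
  }
  eps <- 1e-6
  relerr <- function(an, fd) abs(an - fd) / max(abs(an) + abs(fd), 1e-8)
  worst <- 0
  for (l in 1:3) {
    for (k in seq_along(m$layers[[l]]$W)) {
      m2 <- m
      m2$layers[[l]]$W[k] <- m$layers[[l]]$W[k] + eps
      f1 <- lossf(m2)
      m2$layers[[l]]$W[k] <- m$layers[[l]]$W[k] - eps
      f0 <- lossf(m2)
      fd <- (f1 - f0) / (2 * eps)
      if (abs(fd) > 1e-5) worst <- max(worst, relerr(res$grads[[l]]$W[k], fd))
    }
  }
  for (l in 1:2) {
    for (nm in c("alpha", "beta", "a", "b")) {
      for (k in seq_along(m$layers[[l]]$params[[nm]])) {
        m2 <- m
        m2$layers[[l]]$params[[nm]][k] <- m$layers[[l]]$params[[nm]][k] + eps
        f1 <- lossf(m2)
        m2$layers[[l]]$params[[nm]][k] <- m$layers[[l]]$params[[nm]][k] - eps
        f0 <- lossf(m2)
        fd <- (f1 - f0) / (2 * eps)
        if (abs(fd) > 1e-5) {
          worst <- max(worst, relerr(res$grads[[l]]$params[[nm]][k], fd))
        }
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("training is deterministic under a fixed seed and learns the easy lag task", {
  setup <- tiny_lag_setup(101, epochs = 8)
  fit1 <- snn_train(snn_init(setup$net, seed = 101), setup$data, setup$cfg)
  fit2 <- snn_train(snn_init(setup$net, seed = 101), setup$data, setup$cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model, fit2$model)
  expect_gt(tail(fit1$history$train_acc, 1), 0.5)
})

test_that("frozen-delay training leaves the delays at their initialization", {
  setup <- tiny_lag_setup(7, delay_mode = "fixed_random", epochs = 3)
  m0 <- snn_init(setup$net, seed = 7)
  d_before <- lapply(m0$layers, function(l) l$delays$d)
  fit <- snn_train(m0, setup$data, setup$cfg)
  d_after <- lapply(fit$model$layers, function(l) l$delays$d)
  expect_identical(d_before, d_after)
  # weights did train
  expect_false(identical(m0$layers[[1]]$W, fit$model$layers[[1]]$W))
})

test_that("evaluation reports accuracy and exact spike economy", {
  m <- snn_init(snn_config(4, c(6, 6), 2, "cAdLIF", "none", init_gain = 5),
                seed = 13)
  task <- generate_lag_task(n_samples = 12, T_steps = 20, seed = 13)
  ev <- snn_evaluate(m, list(x = task$x, y = task$y))
  fw <- snn_forward(m, task$x)
  manual <- (sum(fw$hidden[[1]]$s) + sum(fw$hidden[[2]]$s)) / (12 * 12)
  expect_equal(ev$spikes_per_neuron, manual)
  expect_equal(ev$accuracy, mean(ev$predicted == task$y))
  expect_error(snn_evaluate(m, list(x = task$x[0, , , drop = FALSE],
                                    y = integer(0))), "empty")
})

test_that("checkpoints round-trip the model and reject foreign files", {
  m <- snn_init(snn_config(3, c(4, 4), 2, "LIF", "none"), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$model, m)
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_checkpoint(other), "not a snncolearn checkpoint")
})
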