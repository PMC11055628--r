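test_that("lag-task partner spikes sit exactly at the class lag", {
  t0 <- generate_lag_task(n_samples = 30, n_channels = 3, T_steps = 40,
                          lags = c(0, 5), noise_rate = 0, seed = 2)
  for (i in 1:30) {
    ref <- t0$x[i, , 1]
    par <- t0$x[i, , 2]
    lag <- t0$true_lags[t0$y[i]]
    if (lag == 0) {
      expect_identical(par, ref)
    } else {
      expect_identical(par[(lag + 1):40], ref[1:(40 - lag)])
    }
  }
})

test_that("cross-correlation of the channel pair peaks at the generating lag", {
  t5 <- generate_lag_task(n_samples = 50, n_channels = 2, T_steps = 60,
                          lags = c(5, 5), noise_rate = 0, seed = 3)
  xc <- numeric(11) # offsets 0..10
  for (off in 0:10) {
    for (i in 1:50) {
      ref <- t5$x[i, 1:(60 - off), 1]
      par <- t5$x[i, (off + 1):60, 2]
      xc[off + 1] <- xc[off + 1] + sum(ref * par)
    }
  }
  expect_equal(which.max(xc) - 1, 5)
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_lag_task(seed = 9)
  b <- generate_lag_task(seed = 9)
  expect_identical(a, b)
  expect_error(generate_lag_task(T_steps = 10, lags = c(0, 10)), "lags")
})

test_that("the uncorrelated control class matches rates but not timing", {
  tk <- generate_lag_task(n_samples = 400, n_channels = 2, T_steps = 40,
                          lags = c(NA, 4), noise_rate = 0, seed = 12)
  n_par <- apply(tk$x[, , 2], 1, sum)
  # same marginal spike budget in both classes
  expect_equal(mean(n_par[tk$y == 1]), mean(n_par[tk$y == 2]), tolerance = 0.1)
  co_at_lag <- function(i, off) {
    sum(tk$x[i, 1:(40 - off), 1] * tk$x[i, (off + 1):40, 2])
  }
  co2 <- mean(sapply(which(tk$y == 2), co_at_lag, off = 4))
  co1 <- mean(sapply(which(tk$y == 1), co_at_lag, off = 4))
  expect_gt(co2, 3 * co1)
})

test_that("background noise matches the configured Bernoulli rate", {
  tk <- generate_lag_task(n_samples = 10, n_channels = 30, T_steps = 40,
                          noise_rate = 0.05, seed = 4)
  # channels 3+ carry only noise: 10 * 40 * 28 > 1e4 cells
  cells <- tk$x[, , 3:30]
  p_hat <- mean(cells)
  se <- sqrt(0.05 * 0.95 / length(cells))
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("event binning maps units and times onto the documented grid", {
  empty <- event_stream(numeric(0), integer(0), 0L)
  expect_true(all(bin_events(empty) == 0))
  s1 <- event_stream(0.005, 3L, 1L)
  b1 <- bin_events(s1)
  expect_equal(dim(b1), c(100, 140))
  expect_equal(sum(b1), 1)
  expect_equal(b1[1, 1], 1)      # t = 0.005 s -> first 10 ms bin, unit 3 -> group 1
  # duplicates OR rather than add; ordering is irrelevant
  s2 <- event_stream(c(0.005, 0.007, 0.007), c(3L, 4L, 3L), 1L)
  s2r <- event_stream(rev(c(0.005, 0.007, 0.007)), rev(c(3L, 4L, 3L)), 1L)
  expect_identical(bin_events(s2), bin_events(s2r))
  expect_equal(max(bin_events(s2)), 1)
  # an event at exactly t = duration lands in the last bin
  s3 <- event_stream(1, 699L, 0L)
  expect_equal(bin_events(s3)[100, 140], 1)
})

test_that("unit indices outside the declared channel count are rejected", {
  expect_error(event_stream(0.1, 700L, 0L), "out of range")
  s <- event_stream(0.1, 100L, 0L, n_units = 700)
  s$units <- 900L
  expect_error(bin_events(s), "unit index")
})

test_that("the event container round-trips streams losslessly", {
  set.seed(6)
  streams <- lapply(1:3, function(i) {
    n <- sample(5:20, 1)
    event_stream(round(runif(n), 4), sample(0:699, n, replace = TRUE),
                 i - 1L)
  })
  path <- tempfile(fileext = ".json")
  write_event_file(streams, path)
  back <- read_event_file(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$times, streams[[i]]$times)
    expect_equal(back[[i]]$units, streams[[i]]$units)
    expect_equal(back[[i]]$label, streams[[i]]$label)
  }
  # event counts survive the trip
  expect_equal(vapply(back, function(s) length(s$times), 0),
               vapply(streams, function(s) length(s$times), 0))
})

test_that("malformed containers fail with path context", {
  bad <- tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(read_event_file(bad), "malformed")
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(samples = list()), bad2, auto_unbox = TRUE)
  expect_error(read_event_file(bad2), "n_units")
  expect_error(read_event_file(tempfile()), "not found")
})

test_that("binary arrays convert to event lists and back through binning", {
  set.seed(8)
  x <- matrix(rbinom(100 * 140, 1, 0.02), 100, 140)
  ev <- array_to_events(x, label = 2L)
  xb <- bin_events(ev, n_units = 140, out_channels = 140)
  expect_identical(xb, x * 1)
})
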