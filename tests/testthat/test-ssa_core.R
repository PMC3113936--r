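test_that("channel bookkeeping: propensity sums, add/remove, error contracts", {
  eng <- ssa_engine(list(A = 1, B = 0))
  h <- ssa_add_channel(eng, function(s) 1 * s$A,
                       function(s) { s$A <- s$A - 1; s$B <- s$B + 1; s })
  expect_equal(ssa_total_propensity(eng), 1.0)

  # zero reactants -> zero propensity
  eng0 <- ssa_engine(list(A = 0))
  ssa_add_channel(eng0, function(s) 2 * s$A, function(s) s)
  expect_equal(ssa_total_propensity(eng0), 0)

  # add then remove restores the prior propensity sum
  h2 <- ssa_add_channel(eng, function(s) 0.5, function(s) s)
  expect_equal(ssa_total_propensity(eng), 1.5)
  expect_equal(ssa_remove_channels(eng, h2), 1)
  expect_equal(ssa_total_propensity(eng), 1.0)

  # removing 0 channels changes nothing
  expect_equal(ssa_remove_channels(eng, character()), 0)
  expect_equal(ssa_total_propensity(eng), 1.0)

  # duplicate and unknown handles are rejected by name
  expect_error(ssa_add_channel(eng, function(s) 1, function(s) s, handle = h),
               "duplicate")
  expect_error(ssa_remove_channels(eng, "nope"), "nope")

  # removing a batch reports the count
  hs <- vapply(1:12, function(i)
    ssa_add_channel(eng, function(s) 0, function(s) s), character(1))
  expect_equal(ssa_remove_channels(eng, hs), 12)

  # removing the only channel with an empty wait list terminates stepping
  expect_equal(ssa_remove_channels(eng, h), 1)
  expect_equal(ssa_step(eng)$type, "terminated")
})

test_that("waiting times are exponential and selection follows propensities", {
  withr::with_seed(11, {
    eng <- ssa_engine(list(A = 1))
    ssa_add_channel(eng, function(s) 2, function(s) s)
    n <- 2e4
    waits <- numeric(n)
    t_prev <- 0
    for (i in seq_len(n)) {
      st <- ssa_step(eng)
      waits[i] <- st$time - t_prev
      t_prev <- st$time
    }
    se <- sd(waits) / sqrt(n)
    expect_lt(abs(mean(waits) - 0.5), 3 * se)

    # KS vs Exponential(2): repeated runs pass at alpha = 0.01
    pass <- vapply(1:10, function(r) {
      stats::ks.test(sample(waits, 1000), "pexp", rate = 2)$p.value > 0.01
    }, logical(1))
    # (subsamples of one long run; at least 9/10 should pass)
    expect_gte(sum(pass), 9)

    # two channels with propensities 3 and 1: firing fraction -> 0.75
    eng2 <- ssa_engine(list(n1 = 0, n2 = 0))
    ssa_add_channel(eng2, function(s) 3, function(s) { s$n1 <- s$n1 + 1; s })
    ssa_add_channel(eng2, function(s) 1, function(s) { s$n2 <- s$n2 + 1; s })
    for (i in 1:2e4) ssa_step(eng2)
    frac <- eng2$state$n1 / 2e4
    expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 2e4))
  })
})

test_that("delayed releases interleave correctly with reaction firings", {
  # zero total propensity, single release at t = 40 exactly
  eng <- ssa_engine(list(X = 0))
  ssa_schedule(eng, function(s) { s$X <- 1; s }, 40)
  st <- ssa_step(eng)
  expect_identical(st$type, "delayed")
  expect_identical(st$time, 40)
  expect_equal(eng$state$X, 1)

  # delays 5 then 3 scheduled in that order release as 3 then 5 (sorted)
  eng2 <- ssa_engine(list(order = character()))
  ssa_schedule(eng2, function(s) { s$order <- c(s$order, "five"); s }, 5)
  ssa_schedule(eng2, function(s) { s$order <- c(s$order, "three"); s }, 3)
  ssa_step(eng2); ssa_step(eng2)
  expect_identical(eng2$state$order, c("three", "five"))

  # FIFO among simultaneous releases
  eng3 <- ssa_engine(list(order = character()))
  ssa_schedule(eng3, function(s) { s$order <- c(s$order, "a"); s }, 2)
  ssa_schedule(eng3, function(s) { s$order <- c(s$order, "b"); s }, 2)
  ssa_step(eng3); ssa_step(eng3)
  expect_identical(eng3$state$order, c("a", "b"))

  # a zero delay is applied before any positive-waiting-time firing
  withr::with_seed(1, {
    eng4 <- ssa_engine(list(X = 0, fired = 0))
    ssa_add_channel(eng4, function(s) 100, function(s) { s$fired <- 1; s })
    ssa_schedule(eng4, function(s) { s$X <- 1; s }, 0)
    st <- ssa_step(eng4)
    expect_identical(st$type, "delayed")
    expect_equal(eng4$state$fired, 0)
  })

  expect_error(ssa_schedule(eng, function(s) s, -1), "non-negative")
})

test_that("open-complex delay sampler is a zero-truncated normal(40, 4)", {
  withr::with_seed(21, {
    d <- sample_oc_delay(1e4)
    expect_true(all(d > 0))
    expect_lt(abs(mean(d) - 40), 3 * sd(d) / sqrt(1e4))
    expect_lt(abs(sd(d) - 4), 3 * 4 / sqrt(2 * 1e4))
    # truncation engages for means near zero
    expect_true(all(sample_oc_delay(2000, mean = 0.5, sd = 2) > 0))
  })
})

test_that("birth-death run reproduces the stationary mean and is seed-stable", {
  run_bd <- function(seed) {
    withr::with_seed(seed, {
      eng <- ssa_engine(list(N = 0))
      ssa_add_channel(eng, function(s) 1, function(s) { s$N <- s$N + 1; s })
      ssa_add_channel(eng, function(s) 0.1 * s$N,
                      function(s) { s$N <- s$N - 1; s })
      ssa_run(eng, t_end = 1500, sample_interval = 1, tracked = "N")
    })
  }
  res <- run_bd(5)
  ts <- res$timeseries
  m <- mean(ts$N[ts$time >= 100])  # discard relaxation
  # stationary mean k_birth / k_death = 10; autocorrelation time 1/k_death
  expect_lt(abs(m - 10), 1.2)
  expect_identical(res$events, run_bd(5)$events)

  # engine with no channels: flat series at the initial counts
  engf <- ssa_engine(list(N = 3))
  flat <- ssa_run(engf, t_end = 10, sample_interval = 1, tracked = "N")
  expect_true(all(flat$timeseries$N == 3))

  # channel with a delayed product: product appears only after the delay
  withr::with_seed(3, {
    eng <- ssa_engine(list(A = 1, B = 0))
    ssa_add_channel(eng, function(s) 10 * s$A, function(s) { s$A <- 0; s },
                    delay = list(type = "fixed", value = 7),
                    delayed_effect = function(s) { s$B <- 1; s })
    r <- ssa_run(eng, t_end = 20, sample_interval = 0.5, tracked = c("A", "B"))
    first_b <- min(r$timeseries$time[r$timeseries$B == 1])
    expect_gte(first_b, 7)
  })
})
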