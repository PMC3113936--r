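test_that("lone-RNAp transit matches the analytic two-stage sum per nucleotide", {
  # reactions (5)-(11) off, one RNAp, no translation: the transit from
  # promoter clearance to release is a sum of independent exponential stages:
  # activations (10 slow promoter-proximal + L-10 fast), L-1 steps, release
  g <- make_lacz_fixture("wt")
  p <- bare_transcription_params(n_rnap = 1)
  s <- simulate_expression(g, p, t_end = 5.5e4, seed = 3,
                           record = "transcription", sample_interval = 50)
  ev <- s$events
  t0 <- ev$time[ev$event == "tx_clear"]
  t1 <- ev$time[ev$event == "tx_complete"]
  n <- min(length(t0), length(t1))
  transit <- t1[1:n] - t0[1:n]
  expect_gte(n, 250)
  L <- 3072
  m_th <- 10 / 30 + (L - 10) / 114 + (L - 1) / 114 + 1 / 2
  v_th <- 10 / 900 + (L - 10) / 114^2 + (L - 1) / 114^2 + 1 / 4
  expect_lt(abs(mean(transit) - m_th), 3 * sd(transit) / sqrt(n))
  expect_lt(abs(var(transit) - v_th), 3 * v_th * sqrt(2 / (n - 1)))
  # implied unobstructed elongation speed ~ (1/k_m + 1/k_a)^-1 ~ 57 nt/s
  expect_lt(abs(L / mean(transit) - 57), 3)
})

test_that("initiation is binding + open complex and respects the RNAp pool", {
  g <- generate_random_gene(2, seed = 1)
  p <- kinetic_params(k_trans_init = 0, k_dr = 0)
  s <- simulate_expression(g, p, t_end = 1e5, seed = 7,
                           record = "transcription", sample_interval = 100)
  ev <- s$events
  binds <- ev$time[ev$event == "tx_bind"]
  ocs <- ev$time[ev$event == "tx_oc"]
  clears <- ev$time[ev$event == "tx_clear"]
  n <- min(length(binds), length(ocs), length(clears))
  # binding wait: promoter freed at clearance, next binding is exponential
  # at k_init * [free RNAp] = 0.015 * 28 -> mean 2.38 s
  waits <- c(binds[1], (binds[2:n] - clears[1:(n - 1)]))
  expect_lt(abs(mean(waits) - 1 / (28 * 0.015)), 4 * sd(waits) / sqrt(n))
  # open-complex delays are the truncated normal(40, 4)
  d <- ocs[1:n] - binds[1:n]
  expect_lt(abs(mean(d) - 40), 3 * sd(d) / sqrt(n))
  expect_lt(abs(sd(d) - 4), 3 * 4 / sqrt(2 * n))
  # full initiation interval ~ binding + delay (clearance is ~9 ms)
  expect_lt(abs(mean(diff(ocs[1:n])) - (1 / 0.42 + 40)), 1.5)
})

test_that("promoter clearance is blocked while the start region is occupied", {
  # activation switched off: the first RNAp parks on nucleotide 1 forever,
  # so a second clearance can never fire even though binding + OC recur
  g <- generate_random_gene(40, seed = 2)
  p <- kinetic_params(k_a_far = 0, k_a_near = 0, k_trans_init = 0, k_dr = 0)
  s <- simulate_expression(g, p, t_end = 2000, seed = 5,
                           record = "transcription", sample_interval = 10)
  ev <- s$events
  expect_equal(sum(ev$event == "tx_clear"), 1L)
  expect_gte(sum(ev$event == "tx_oc"), 2L)
})

test_that("annotated sites trigger with their probability, 0 and 1 included", {
  g <- generate_random_gene(80, seed = 3)
  p <- kinetic_params(k_trans_init = 0, k_dr = 0, k_pre = 0)
  run <- function(prob) {
    ga <- annotate_site(g, 120, "long_pause", prob, 2)
    s <- simulate_expression(ga, p, t_end = 3e4, seed = 6, record = "sites",
                             sample_interval = 100)
    tb <- s$events$event
    c(pass = sum(tb == "site_pass"), trig = sum(tb == "site_trigger"))
  }
  r0 <- run(0)
  expect_gt(r0[["pass"]], 100)
  expect_equal(r0[["trig"]], 0L)
  r1 <- run(1)
  expect_equal(r1[["trig"]], r1[["pass"]])
})

test_that("arrest sites stall transcription for their mean duration", {
  # a certain arrest of mean 50 s at nucleotide 120 adds ~50 s to the transit
  g <- generate_random_gene(80, seed = 3)  # 240 nt
  p <- bare_transcription_params(n_rnap = 1)
  ga <- annotate_site(g, 120, "arrest", 1, 50)
  transits <- function(gene, seed) {
    s <- simulate_expression(gene, p, t_end = 4e4, seed = seed,
                             record = "transcription", sample_interval = 100)
    ev <- s$events
    t0 <- ev$time[ev$event == "tx_clear"]; t1 <- ev$time[ev$event == "tx_complete"]
    n <- min(length(t0), length(t1))
    t1[1:n] - t0[1:n]
  }
  tr0 <- transits(g, 8)
  tr1 <- transits(ga, 8)
  d <- mean(tr1) - mean(tr0)
  se <- sqrt(var(tr1) / length(tr1) + var(tr0) / length(tr0))
  expect_lt(abs(d - 50), 4 * se)
})

test_that("collision release frees a paused leader blocked by its trailer", {
  # a near-permanent pause (mean 1e5 s) at nucleotide 120: without reaction
  # (6) nothing would complete in 2000 s; an abutting activated trailer
  # releases the leader at k_m, so transcripts flow
  g <- generate_random_gene(80, seed = 3)
  ga <- annotate_site(g, 120, "long_pause", 1, 1e5)
  p <- kinetic_params(k_trans_init = 0, k_dr = 0, k_pre = 0, k_eff = 2,
                      n_rnap = 30)
  s <- simulate_expression(ga, p, t_end = 2000, seed = 9,
                           record = "transcription", sample_interval = 10,
                           check_invariants = TRUE)
  expect_gte(sum(s$events$event == "tx_complete"), 5)
})

test_that("premature termination frees the RNAp and destroys idle strands", {
  g <- make_lacz_fixture("wt")
  p <- kinetic_params(k_pre = 0.02, k_trans_init = 0, k_dr = 0)
  s <- simulate_expression(g, p, t_end = 5000, seed = 10,
                           record = c("transcription", "rna"),
                           sample_interval = 10, check_invariants = TRUE)
  ev <- s$events
  prem <- ev[ev$event == "tx_premature", ]
  expect_gt(nrow(prem), 20)
  # with no ribosomes ever bound, destruction is simultaneous with the event
  dest <- ev[ev$event == "comp_destroy", ]
  expect_true(all(prem$comp_id %in% dest$comp_id))
  m <- match(prem$comp_id, dest$comp_id)
  expect_equal(prem$time, dest$time[m])
})

test_that("heavy pyrophosphorolysis traffic keeps every structural invariant", {
  g <- generate_random_gene(60, seed = 4)
  p <- kinetic_params(k_pyro = 10, k_eff = 1, n_rnap = 40, k_dr = 0.05)
  s <- simulate_expression(g, p, t_end = 2000, seed = 11,
                           sample_interval = 2, check_invariants = TRUE)
  expect_gt(s$counters$n_events, 1000)
  expect_gte(s$counters$event_type_counts[["tx_complete"]], 1)
})

test_that("functional mRNA lifetime is exponential at rate k_dr", {
  g <- generate_random_gene(100, seed = 5)
  p <- kinetic_params(k_trans_init = 0, k_pre = 0)
  s <- simulate_expression(g, p, t_end = 4e4, seed = 12,
                           record = c("transcription", "rna"),
                           sample_interval = 100)
  ev <- s$events
  born <- ev[ev$event == "tx_clear", ]
  mark <- ev[ev$event == "rna_mark", ]
  life <- mark$time - born$time[match(mark$comp_id, born$comp_id)]
  n <- length(life)
  expect_gt(n, 150)
  # RBS exposure lags clearance by ~44 nucleotides of elongation (~0.8 s)
  expect_lt(abs(mean(life) - (1 / 0.011 + 44 / 57)), 3 * sd(life) / sqrt(n))
})

test_that("identical seeds give bitwise-identical runs", {
  g <- make_lacz_fixture("wt")
  s1 <- simulate_expression(g, kinetic_params(), t_end = 600, seed = 42)
  s2 <- simulate_expression(g, kinetic_params(), t_end = 600, seed = 42)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$timeseries, s2$timeseries)
  s3 <- simulate_expression(g, kinetic_params(), t_end = 600, seed = 43)
  expect_false(identical(s1$events, s3$events))
})
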