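rib_transits <- function(sim) {
  ev <- sim$events
  ini <- ev[ev$event == "tl_init", ]
  fin <- ev[ev$event == "tl_complete", ]
  m <- match(fin$entity_id, ini$entity_id)
  fin$time - ini$time[m]
}

test_that("lone-ribosome transit matches the analytic stage sum", {
  # uniform class-A strand, reactions (19)-(21) off, uncontended initiation:
  # transit = (n-1) activations at k_transA + 3(n-1) translocation sub-steps
  # at k_tm + the completion stage at k_trans_f
  n_cod <- 200
  g <- uniform_gene("CTG", n_cod)  # CTG maps to class A in the default table
  expect_true(all(tidy(g)$class[1:(n_cod - 1)] == "A"))
  p <- fast_tx_params(k_bt = 0, k_drop = 0, k_tt = 0, k_trans_init = 0.02,
                      n_rnap = 3, k_eff = 0.002)
  s <- simulate_expression(g, p, t_end = 3e4, seed = 13,
                           record = "translation", sample_interval = 100)
  tr <- rib_transits(s)
  n <- length(tr)
  expect_gt(n, 400)
  m_th <- (n_cod - 1) * (3 / 1000 + 1 / 35) + 1 / 2
  v_th <- (n_cod - 1) * (3 / 1000^2 + 1 / 35^2) + 1 / 4
  expect_lt(abs(mean(tr) - m_th), 3 * sd(tr) / sqrt(n))
  expect_lt(abs(var(tr) - v_th), 3 * v_th * sqrt(2 / (n - 1)))
})

test_that("codon classes set the pace: slow stretches lengthen the transit", {
  p <- fast_tx_params(k_bt = 0, k_drop = 0, k_tt = 0, k_trans_init = 0.02,
                      n_rnap = 3)
  mean_transit <- function(gene) {
    s <- simulate_expression(gene, p, t_end = 6000, seed = 14,
                             record = "translation", sample_interval = 100)
    mean(rib_transits(s))
  }
  g_fast <- uniform_gene("CTG", 150)
  # identical sequence but 30 codons forced to class C
  override <- rep(NA_character_, 150)
  override[60:89] <- "C"
  g_slow <- gene_sequence(g_fast$nucleotides, class_override = override)
  d <- mean_transit(g_slow) - mean_transit(g_fast)
  expect_lt(abs(d - 30 * (1 / 4.5 - 1 / 35)), 1.5)

  # explicit per-codon rates override the class rate
  g_exp <- gene_sequence(g_fast$nucleotides, specific_rates = c(CTG = 2))
  expect_true(all(tidy(g_exp)$rate[1:149] == 2))
})

test_that("back-translocation slows net elongation monotonically", {
  g <- uniform_gene("CTG", 150)
  speed <- function(k_bt) {
    p <- fast_tx_params(k_bt = k_bt, k_drop = 0, k_tt = 0,
                        k_trans_init = 0.02, n_rnap = 3, k_eff = 0.005)
    s <- simulate_expression(g, p, t_end = 8000, seed = 15,
                             record = "translation", sample_interval = 100)
    mean(rib_transits(s))
  }
  tr <- vapply(c(0, 1.5, 15), speed, numeric(1))
  expect_true(all(diff(tr) > 0))
  # at codon 1 back-translocation cannot fire, so transits stay finite and
  # the k_bt = 0 case matches the stage-sum mean
  expect_lt(abs(tr[1] - (149 * (3 / 1000 + 1 / 35) + 0.5)), 0.3)
})

test_that("ribosome binding is blocked while the RBS is covered", {
  # slow translocation (k_tm = 2/s) with eager initiation: the second
  # initiation on a fresh strand must wait for the first ribosome to clear
  # the ribosome binding site, i.e. ~45 sub-steps at 2/s
  g <- uniform_gene("CTG", 60)
  p <- fast_tx_params(k_tm = 2, k_bt = 0, k_drop = 0, k_tt = 0,
                      k_trans_init = 50, n_rnap = 2, k_eff = 0.05)
  s <- simulate_expression(g, p, t_end = 8000, seed = 16,
                           record = "translation", sample_interval = 10,
                           check_invariants = TRUE)
  ini <- s$events[s$events$event == "tl_init", ]
  first_iv <- unlist(tapply(ini$time, ini$comp_id, function(tt) {
    tt <- sort(tt)
    if (length(tt) > 1) tt[2] - tt[1]
  }), use.names = FALSE)
  n <- length(first_iv)
  expect_gt(n, 20)
  expect_gt(min(first_iv), 5)
  expect_lt(abs(mean(first_iv) - 45 / 2), 4 * (22.5 / sqrt(45)) / sqrt(n) + 1)
})

test_that("drop-off frequency follows its continuous hazard", {
  g <- uniform_gene("CTG", 200)
  p <- fast_tx_params(k_bt = 0, k_tt = 0, k_drop = 0.01,
                      k_trans_init = 0.02, n_rnap = 3, k_eff = 0.002)
  s <- simulate_expression(g, p, t_end = 3e4, seed = 17,
                           record = "translation", sample_interval = 100)
  ev <- s$events
  n_drop <- sum(ev$event == "tl_drop")
  n_done <- sum(ev$event == "tl_complete")
  frac <- n_drop / (n_drop + n_done)
  # hazard 0.01/s over a ~6.8 s transit
  t_transit <- 199 * (3 / 1000 + 1 / 35) + 0.5
  p_th <- 1 - exp(-0.01 * t_transit)
  se <- sqrt(p_th * (1 - p_th) / (n_drop + n_done))
  expect_lt(abs(frac - p_th), 4 * se)
})

test_that("trans-translation clears stalled ribosomes and whole strands", {
  # premature terminations strand the ribosomes behind a frozen front;
  # trans-translation is then the only clearance route
  g <- make_lacz_fixture("wt")
  p <- kinetic_params(k_pre = 0.05, k_tt = 0.02, k_dr = 0, n_rib = 50)
  s <- simulate_expression(g, p, t_end = 6000, seed = 18,
                           record = c("transcription", "translation", "rna"),
                           sample_interval = 10, check_invariants = TRUE)
  ev <- s$events
  prem <- ev[ev$event == "tx_premature", ]
  expect_gt(nrow(prem), 10)
  dest <- ev[ev$event == "comp_destroy", ]
  early <- prem$comp_id[prem$time < 4000]
  expect_true(all(early %in% dest$comp_id))
  # every ribosome released by trans-translation returns to the pool:
  # the free pool must be exactly full whenever nothing is bound
  ts <- s$timeseries
  idle <- ts$rib_bound == 0
  expect_true(all(ts$free_rib[idle] == 50))
})

test_that("every initiation ends in exactly one of completion/drop-off/rescue", {
  g <- make_lacz_fixture("wt")
  s <- simulate_expression(g, kinetic_params(), t_end = 4000, seed = 19,
                           sample_interval = 4, check_invariants = TRUE)
  ev <- s$events
  n_init <- sum(ev$event == "tl_init")
  n_done <- sum(ev$event == "tl_complete")
  n_drop <- sum(ev$event == "tl_drop")
  n_tt <- sum(ev$value[ev$event == "tl_tt"])
  still_bound <- s$timeseries$rib_bound[nrow(s$timeseries)]
  expect_equal(n_init, n_done + n_drop + n_tt + still_bound)
  # protein ledger: completions = folded pool flux (P_prem + P + decayed)
  expect_equal(s$counters$final_p_prem + s$counters$final_p <= n_done, TRUE)
})

test_that("peptide length at completion equals the codon count", {
  g <- uniform_gene("CTG", 80)
  p <- fast_tx_params(k_drop = 0, k_tt = 0, k_trans_init = 0.05, n_rnap = 2)
  s <- simulate_expression(g, p, t_end = 5000, seed = 20,
                           record = "translation", sample_interval = 50)
  done <- s$events[s$events$event == "tl_complete", ]
  expect_gt(nrow(done), 50)
  # value column carries the peptide bond count: codons 1..n-1 activated,
  # even though back-translocation (k_bt = 1.5) forces re-activations
  expect_true(all(done$value == 79))
})

test_that("weak expression produces geometric protein bursts", {
  # strongly repressed promoter, weak translation: proteins arrive in
  # per-transcript bursts whose sizes follow a geometric distribution
  g <- generate_random_gene(300, seed = 3)
  p <- kinetic_params(k_eff = 0.005, k_trans_init = 0.1)
  s <- simulate_expression(g, p, t_end = 6e4, seed = 30,
                           record = c("transcription", "translation", "rna"),
                           sample_interval = 50)
  b <- burst_stats(s$events)$bursts$burst_size
  expect_gt(length(b), 150)
  # geometric signature: var = mean (1 + mean)
  expect_lt(abs(var(b) / (mean(b) * (1 + mean(b))) - 1), 0.35)
  # chi-square goodness of fit with the tail pooled to expected counts >= 5
  ph <- 1 / (1 + mean(b))
  expd <- stats::dgeom(0:max(b), ph) * length(b)
  cut <- max(which(expd >= 5))
  obs <- tabulate(b + 1, nbins = max(b) + 1)
  o2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
  e2 <- c(expd[1:cut], length(b) - sum(expd[1:cut]))
  stat <- sum((o2 - e2)^2 / e2)
  expect_gt(stats::pchisq(stat, df = length(o2) - 2, lower.tail = FALSE), 0.01)
})

test_that("protein folding and decay reach the birth-death stationary mean", {
  g <- uniform_gene("CTG", 60)
  p <- fast_tx_params(k_bt = 0, k_drop = 0, k_tt = 0, k_trans_init = 0.5,
                      n_rnap = 2, k_fold = 0.05, k_dec = 0.05, k_dr = 0.02)
  s <- simulate_expression(g, p, t_end = 6000, seed = 21,
                           record = "translation", sample_interval = 2)
  ts <- s$timeseries
  done <- s$events[s$events$event == "tl_complete", ]
  stat <- ts[ts$time >= 300, ]
  rate <- sum(done$time >= 300) / (6000 - 300)
  expect_lt(abs(mean(stat$p) - rate / 0.05), 0.15 * rate / 0.05)
  # activated protein lags the unfolded pool: cross-correlation peaks at
  # a strictly positive lag
  mc <- max_correlation(stat$p_prem, stat$p, max_lag = 500)
  expect_gt(mc$lag, 0)
  expect_gt(mc$r_max, 0.2)
})
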