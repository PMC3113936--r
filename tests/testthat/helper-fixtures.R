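# shared fixtures: small genes and parameter shortcuts built in code

# gene of n codons all drawn from one codon (plus TAA stop)
uniform_gene <- function(codon, n_codons) {
  gene_sequence(paste(c(rep(codon, n_codons - 1), "TAA"), collapse = ""))
}

# parameters with every alternative transcription pathway switched off
bare_transcription_params <- function(...) {
  base <- list(k_p = 0, k_ar = 0, k_ec = 0, k_pre = 0, k_pyro = 0,
               k_trans_init = 0, k_dr = 0)
  over <- list(...)
  base[names(over)] <- over
  do.call(kinetic_params, base)
}

# near-instant transcription: ribosome kinetics unconfounded by the front
fast_tx_params <- function(...) {
  base <- list(k_m = 5000, k_a_far = 5000, k_a_near = 5000,
               k_p = 0, k_ar = 0, k_ec = 0, k_pre = 0, k_pyro = 0,
               k_dr = 0)
  over <- list(...)
  base[names(over)] <- over
  do.call(kinetic_params, base)
}

# per-compartment consecutive intervals of one event type, pooled
pooled_intervals <- function(sim, type) {
  ev <- sim$events[sim$events$event == type, ]
  unlist(tapply(ev$time, ev$comp_id,
                function(tt) if (length(tt) > 1) diff(sort(tt))),
         use.names = FALSE)
}

# reference cross-correlation: naive double loop over pairs and lags
brute_force_ncc <- function(xs, ys, lags) {
  if (!is.list(xs)) { xs <- list(xs); ys <- list(ys) }
  n <- length(xs[[1]])
  out <- numeric(length(lags))
  for (i in seq_along(xs)) {
    x <- xs[[i]]; y <- ys[[i]]
    mx <- mean(x); my <- mean(y)
    sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
    for (k in seq_along(lags)) {
      tau <- lags[k]
      acc <- 0
      for (t in 1:(n - tau)) acc <- acc + (x[t] - mx) * (y[t + tau] - my)
      out[k] <- out[k] + acc / ((n - tau) * sx * sy)
    }
  }
  out / length(xs)
}
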