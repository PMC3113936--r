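#' Squared coefficient of variation
#'
#' The package's noise measure: sample variance divided by the squared
#' sample mean. For a Poisson-distributed series it approaches `1 / mean`.
#'
#' @param x Numeric vector (e.g. a sampled species count series).
#' @return A single non-negative number.
#' @export
cv2 <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x)
  if (m <= 0) stop("cv2 undefined: series mean is not positive", call. = FALSE)
  var(x) / m^2
}

# population (1/n) standard deviation; makes r(x, x, 0) exactly 1
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Normalized discrete cross-correlation between two time series
#'
#' For each lag `tau`, computes
#' `r(tau) = sum_t (x_t - m_x)(y_{t+tau} - m_y) / ((n - tau) * s_x * s_y)`
#' with `m_w` and `s_w` the full-series mean and (1/n) standard deviation,
#' averaged over `m` replicate pairs when `x` and `y` are lists of series.
#' `r(x, x, 0)` is exactly 1. With `x` = mRNA and `y` = protein levels the
#' correlation peaks at a positive lag: protein follows mRNA.
#'
#' @param x,y Equal-length numeric vectors, or lists of equal-length vectors
#'   (replicate pairs: `x[[i]]` with `y[[i]]`).
#' @param lags Integer lags in `0 .. n-1`; default all.
#' @return A tibble with columns `lag` and `r`.
#' @export
cross_correlation <- function(x, y, lags = NULL) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(x) == length(y), length(x) >= 1)
  n <- length(x[[1]])
  for (i in seq_along(x)) {
    if (length(x[[i]]) != n || length(y[[i]]) != n) {
      stop("all series in a pair set must have equal length", call. = FALSE)
    }
  }
  if (n < 2) stop("series too short for cross-correlation", call. = FALSE)
  lags <- if (is.null(lags)) 0:(n - 1) else as.integer(lags)
  if (any(lags < 0) || any(lags > n - 1)) {
    stop("lags must lie in 0 .. n-1", call. = FALSE)
  }
  acc <- numeric(length(lags))
  for (i in seq_along(x)) {
    xi <- x[[i]]; yi <- y[[i]]
    sx <- sd_pop(xi); sy <- sd_pop(yi)
    if (sx == 0 || sy == 0) {
      stop("cross-correlation undefined: a series has zero variance",
           call. = FALSE)
    }
    xc <- xi - mean(xi); yc <- yi - mean(yi)
    for (k in seq_along(lags)) {
      tau <- lags[k]
      idx <- seq_len(n - tau)
      acc[k] <- acc[k] + sum(xc[idx] * yc[idx + tau]) / ((n - tau) * sx * sy)
    }
  }
  tibble::tibble(lag = lags, r = acc / length(x))
}

#' Maximum of the normalized cross-correlation over lags
#'
#' @inheritParams cross_correlation
#' @param max_lag Largest lag searched (default `n - 1`). Ties break toward
#'   the smaller lag.
#' @return A one-row tibble: `lag`, `r_max`.
#' @export
max_correlation <- function(x, y, max_lag = NULL) {
  n <- if (is.list(x)) length(x[[1]]) else length(x)
  max_lag <- if (is.null(max_lag)) n - 1 else min(max_lag, n - 1)
  cc <- cross_correlation(x, y, lags = 0:max_lag)
  k <- which.max(cc$r)
  tibble::tibble(lag = cc$lag[k], r_max = cc$r[k])
}

moment_skewness <- function(x) {
  m <- mean(x); s <- sd_pop(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
moment_kurtosis_excess <- function(x) {
  m <- mean(x); s <- sd_pop(x)
  if (s == 0) return(0)
  mean((x - m)^4) / s^4 - 3
}

#' Summary statistics of inter-event interval distributions
#'
#' Consecutive time differences between events of one type, summarized by
#' mean, squared coefficient of variation, skewness and Sarle's bimodality
#' coefficient `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` (b is
#' 5/9 for a uniform distribution, larger for bimodal shapes; ~0.55-0.6 for
#' an exponential... the statistic is used comparatively). A squared CV well
#' below 1 marks a sub-exponential ("Gaussian-like") interval distribution;
#' near 1, an exponential-like one.
#'
#' @inheritParams event_intervals
#' @return A one-row tibble: `event`, `n_intervals`, `mean`, `cv2`,
#'   `skewness`, `bimodality`, plus a list-column `intervals` holding the
#'   raw interval vector.
#' @export
interval_stats <- function(events, type) {
  iv <- event_intervals(events, type)
  n <- length(iv)
  g1 <- moment_skewness(iv)
  g2 <- moment_kurtosis_excess(iv)
  bim <- if (n > 3) (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
         else NA_real_
  tibble::tibble(
    event = type, n_intervals = n, mean = mean(iv), cv2 = cv2(iv),
    skewness = g1, bimodality = bim, intervals = list(iv))
}

#' Protein burst statistics per mRNA compartment
#'
#' Burst size is the number of completed proteins attributable to one mRNA
#' compartment over its lifetime (zero for silent transcripts); the
#' inter-burst interval is the time between the first protein productions of
#' consecutive bursting compartments.
#'
#' @param events Event tibble from a `txsim` (needs `tx_clear` and
#'   `tl_complete` records), or the `txsim` itself.
#' @return A list of class `burst_stats`: `bursts` (tibble: `comp_id`,
#'   `burst_size`, `first_production`) and `interburst_intervals` (numeric).
#' @export
burst_stats <- function(events) {
  if (inherits(events, "txsim")) events <- events$events
  born <- events[events$event == "tx_clear", "comp_id", drop = FALSE]
  if (!nrow(born)) stop("no compartments in the event log", call. = FALSE)
  prod <- events[events$event == "tl_complete", c("time", "comp_id")]
  counts <- table(factor(prod$comp_id, levels = born$comp_id))
  firsts <- tapply(prod$time, factor(prod$comp_id, levels = born$comp_id),
                   min)
  bursts <- tibble::tibble(
    comp_id = born$comp_id,
    burst_size = as.integer(counts),
    first_production = as.numeric(firsts))
  fp <- sort(bursts$first_production[!is.na(bursts$first_production)])
  structure(list(
    bursts = bursts,
    interburst_intervals = if (length(fp) >= 2) diff(fp) else numeric()
  ), class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat("burst_stats: ", nrow(x$bursts), " compartments, mean burst size ",
      round(mean(x$bursts$burst_size), 2), "\n", sep = "")
  invisible(x)
}

#' @describeIn burst_stats One row per compartment.
#' @param x A `burst_stats` object.
#' @param ... Unused.
#' @export
tidy.burst_stats <- function(x, ...) x$bursts

#' @describeIn burst_stats One-row summary: compartment count, total
#'   proteins, mean/CV2 burst size, mean inter-burst interval.
#' @export
glance.burst_stats <- function(x, ...) {
  b <- x$bursts$burst_size
  tibble::tibble(
    n_compartments = length(b),
    total_proteins = sum(b),
    mean_burst = mean(b),
    cv2_burst = if (mean(b) > 0) var(b) / mean(b)^2 else NA_real_,
    mean_interburst = if (length(x$interburst_intervals))
      mean(x$interburst_intervals) else NA_real_)
}

#' Methionine incorporation curve after a radioactive pulse
#'
#' Emulates a pulse-labeling measurement of translation elongation speed:
#' from `pulse_time` onward, every methionine codon activated by a ribosome
#' of the labeled cohort (ribosomes initiating within `cohort_window`
#' seconds of the pulse) counts as one incorporated radioactive methionine.
#' The cumulative count at each sample time is normalized by the number of
#' methionine codons per full protein times the cohort size, so the curve
#' approaches 1 once every cohort ribosome has finished.
#'
#' @param events Event tibble from a run with `record_met = TRUE` (or the
#'   `txsim` itself).
#' @param gene The simulated `gene_seq` (supplies the methionine count).
#' @param sample_times Times (seconds) at which the curve is evaluated.
#' @param pulse_time Pulse instant (seconds).
#' @param cohort_window Labeled-cohort window after the pulse (seconds);
#'   `Inf` labels every later initiation.
#' @param completed_only Restrict the cohort to ribosomes that finish their
#'   protein (the default): label is then measured in completed chains, the
#'   curve plateaus at exactly 1, and its shape reads out elongation speed.
#'   With `FALSE`, ribosomes lost to drop-off or trans-translation depress
#'   the plateau.
#' @return A tibble: `time`, `incorporated` (raw count), `n_ribosomes`
#'   (cohort size), `normalized`.
#' @export
methionine_curve <- function(events, gene, sample_times, pulse_time = 0,
                             cohort_window = Inf, completed_only = TRUE) {
  if (inherits(events, "txsim")) events <- events$events
  stopifnot(inherits(gene, "gene_seq"))
  n_met <- length(gene$met_positions)
  if (n_met < 1) stop("gene has no methionine codons", call. = FALSE)
  init <- events[events$event == "tl_init", ]
  cohort <- init$entity_id[init$time > pulse_time &
                           init$time <= pulse_time + cohort_window]
  if (isTRUE(completed_only)) {
    done <- events$entity_id[events$event == "tl_complete"]
    cohort <- intersect(cohort, done)
  }
  met <- events[events$event == "met_act" &
                events$entity_id %in% cohort &
                events$time > pulse_time, ]
  n_cohort <- length(cohort)
  inc <- vapply(sample_times, function(tt) sum(met$time <= tt), numeric(1))
  tibble::tibble(
    time = sample_times,
    incorporated = inc,
    n_ribosomes = n_cohort,
    normalized = if (n_cohort > 0) inc / (n_met * n_cohort) else 0 * inc)
}

#' Set degradation rates to hit target mean mRNA and protein levels
#'
#' When scanning transcription- and translation-initiation rates, mRNA and
#' protein degradation rates are adjusted so the mean levels stay identical
#' across conditions; noise comparisons then reflect dynamics, not means.
#' The first pass is analytic: the net functional-mRNA production rate is
#' estimated from the initiation cycle (binding at `k_eff`, open-complex
#' delay, clearance) thinned by premature termination over the mean transit,
#' giving `k_dr = R_mrna / target_mean_mrna`; protein production is
#' `target_mean_mrna * k_trans_init` thinned by drop-off over the ribosome
#' transit, giving `k_dec = R_protein / target_mean_protein`. With
#' `calibrate = TRUE`, short pilot runs then correct both rates
#' multiplicatively until the realized means are within `tol` of target.
#'
#' @param params [kinetic_params()].
#' @param gene The `gene_seq` to be simulated.
#' @param target_mean_mrna,target_mean_protein Positive targets.
#' @param calibrate Run the pilot-simulation calibration loop.
#' @param pilot_t,pilot_reps Pilot length (seconds) and replicate count.
#' @param tol Relative tolerance on both realized means (default 5%).
#' @param max_iter Iteration cap; exceeding it is an error with diagnostics.
#' @param seed Seed for the pilot runs.
#' @return `kinetic_params` with `k_dr` and `k_dec` replaced; attributes
#'   `details` (analytic estimates) and, when calibrated, `realized` means.
#' @export
compensate_degradation <- function(params, gene, target_mean_mrna,
                                   target_mean_protein, calibrate = FALSE,
                                   pilot_t = 6000, pilot_reps = 2,
                                   tol = 0.05, max_iter = 8, seed = 1) {
  stopifnot(inherits(params, "kinetic_params"),
            target_mean_mrna > 0, target_mean_protein > 0)
  L <- gene$length
  transit_tx <- 10 / params$k_a_near + (L - 10) / params$k_a_far +
    (L - 1) / params$k_m + 1 / params$k_f
  p_survive <- exp(-params$k_pre * transit_tx)
  r_mrna <- p_survive / (1 / params$k_eff + params$toc_mean + 1 / params$k_m)
  rates <- resolve_codon_rates(gene, params)
  transit_tl <- sum(3 / params$k_tm + 1 / rates[-length(rates)]) +
    1 / params$k_trans_f
  p_rib <- exp(-params$k_drop * transit_tl)
  # ribosome-binding-site occlusion: the next initiation waits until the
  # previous ribosome has advanced ~(2*delta_rib+1)/3 codons, which throttles
  # the effective initiation rate
  n_rbs <- ceiling((2 * params$delta_rib + 1) / 3)
  t_rbs <- sum(3 / params$k_tm + 1 / rates[seq_len(min(n_rbs, length(rates)))])
  k_tr_eff <- 1 / (1 / params$k_trans_init + t_rbs)
  r_prot <- target_mean_mrna * k_tr_eff * p_rib
  # trans-translation (rate k_tt per bound ribosome) destroys functional
  # mRNA alongside reaction-13 degradation; subtract its expected hazard so
  # the total death rate hits the target mean
  nbar_rib <- min(k_tr_eff * transit_tl,
                  gene$length / (2 * params$delta_rib + 1))
  k_dr <- r_mrna / target_mean_mrna - params$k_tt * nbar_rib
  if (k_dr <= 0) {
    stop("target mean mRNA ", target_mean_mrna, " is unreachable: ",
         "trans-translation alone removes functional mRNA faster than it is ",
         "produced (required total death rate ",
         signif(r_mrna / target_mean_mrna, 3), " /s vs trans-translation ",
         signif(params$k_tt * nbar_rib, 3), " /s)", call. = FALSE)
  }
  k_dec <- r_prot / target_mean_protein
  details <- list(r_mrna = r_mrna, r_protein = r_prot,
                  transit_tx = transit_tx, transit_tl = transit_tl)
  upd <- function(p, k_dr, k_dec) {
    p$k_dr <- k_dr; p$k_dec <- k_dec
    class(p) <- "kinetic_params"
    p
  }
  out <- upd(params, k_dr, k_dec)
  realized <- NULL
  if (calibrate) {
    for (it in seq_len(max_iter + 1)) {
      if (it > max_iter) {
        stop("degradation-rate calibration did not converge after ",
             max_iter, " iterations (last means: mRNA ",
             signif(realized$mrna, 3), " vs target ", target_mean_mrna,
             ", protein ", signif(realized$protein, 3), " vs target ",
             target_mean_protein, ")", call. = FALSE)
      }
      burn <- min(0.3 * pilot_t, 5 * log(2) / out$k_dec)
      sims <- lapply(seq_len(pilot_reps), function(r) {
        simulate_expression(gene, out, t_end = pilot_t + burn,
                            sample_interval = max(1, pilot_t / 2000),
                            seed = seed + 1000 * it + r,
                            record = "transcription")
      })
      grab <- function(s, col) {
        ts <- s$timeseries
        mean(ts[[col]][ts$time >= burn])
      }
      realized <- list(mrna = mean(vapply(sims, grab, numeric(1), "mrna")),
                       protein = mean(vapply(sims, grab, numeric(1), "p")))
      ok_m <- abs(realized$mrna - target_mean_mrna) <= tol * target_mean_mrna
      ok_p <- abs(realized$protein - target_mean_protein) <=
        tol * target_mean_protein
      if (ok_m && ok_p) break
      # mean level scales ~ 1/degradation rate: multiplicative correction
      out <- upd(out, out$k_dr * realized$mrna / target_mean_mrna,
                 out$k_dec * realized$protein / target_mean_protein)
    }
  }
  attr(out, "details") <- details
  attr(out, "realized") <- realized
  out
}
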