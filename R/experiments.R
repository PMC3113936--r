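#' Noise-propagation scan over transcription and translation initiation rates
#'
#' For every grid cell `(k_eff, k_tr)`: degradation rates are compensated so
#' mean mRNA and protein levels match the shared targets; `replicates`
#' independent runs are simulated (replicate `r` uses seed `seed + r`, so
#' the same random streams recur in every cell); the burn-in window is
#' discarded; squared CVs are computed on the replicate-concatenated series
#' and the normalized maximum mRNA-protein correlation on the per-replicate
#' pairs (averaged per lag across pairs).
#'
#' @param gene A `gene_seq`.
#' @param k_eff,k_tr Numeric vectors of effective transcription-initiation
#'   and translation-initiation rates (s^-1); the grid is their cross.
#' @param params Baseline [kinetic_params()] (degradation rates are
#'   overwritten per cell).
#' @param target_mean_mrna,target_mean_protein Shared steady-state targets.
#' @param replicates Independent runs per cell.
#' @param t_burn_in,t_measure Discarded and measured durations (seconds).
#' @param sample_interval Sampling grid (seconds).
#' @param seed Base seed; replicate `r` uses `seed + r` in every cell.
#' @param max_lag Largest lag (in samples) searched for the correlation
#'   maximum; default 1/4 of the series length.
#' @param calibrate Passed to [compensate_degradation()].
#' @return A tibble of class `noise_scan`: one row per cell with `k_eff`,
#'   `k_tr`, compensated `k_dr`, `k_dec`, realized `mean_mrna`,
#'   `mean_protein`, `cv2_mrna`, `cv2_protein`, `max_corr`, `corr_lag_s`.
#' @export
run_noise_scan <- function(gene, k_eff = c(0.008, 0.03, 0.12),
                           k_tr = c(0.04, 0.12, 0.36),
                           params = kinetic_params(),
                           target_mean_mrna = 2, target_mean_protein = 30,
                           replicates = 3, t_burn_in = 2000, t_measure = 8000,
                           sample_interval = 2, seed = 1, max_lag = NULL,
                           calibrate = FALSE) {
  stopifnot(length(k_eff) >= 1, length(k_tr) >= 1, replicates >= 1,
            t_measure > 0)
  grid <- tidyr::expand_grid(k_eff = as.double(k_eff), k_tr = as.double(k_tr))
  rows <- purrr::pmap(grid, function(k_eff, k_tr) {
    p <- params
    p$k_eff <- k_eff
    p$k_trans_init <- k_tr
    class(p) <- "kinetic_params"
    p <- tryCatch(
      compensate_degradation(p, gene, target_mean_mrna, target_mean_protein,
                             calibrate = calibrate),
      error = function(e) {
        stop("degradation compensation failed at grid cell (k_eff = ", k_eff,
             ", k_tr = ", k_tr, "): ", conditionMessage(e), call. = FALSE)
      })
    sims <- lapply(seq_len(replicates), function(r) {
      s <- simulate_expression(gene, p, t_end = t_burn_in + t_measure,
                               sample_interval = sample_interval,
                               seed = seed + r, record = "transcription")
      ts <- s$timeseries
      ts[ts$time >= t_burn_in, c("mrna", "p")]
    })
    mrna_cat <- unlist(lapply(sims, `[[`, "mrna"))
    prot_cat <- unlist(lapply(sims, `[[`, "p"))
    n <- nrow(sims[[1]])
    ml <- if (is.null(max_lag)) max(2L, n %/% 4L) else max_lag
    ok <- vapply(sims, function(ts) {
      stats::sd(ts$mrna) > 0 && stats::sd(ts$p) > 0
    }, logical(1))
    if (!all(ok)) {
      warning("dropping ", sum(!ok), " zero-variance replicate pair(s) from ",
              "the correlation at (k_eff = ", k_eff, ", k_tr = ", k_tr, ")",
              call. = FALSE)
    }
    if (!any(ok)) {
      stop("all replicates have zero variance at (k_eff = ", k_eff,
           ", k_tr = ", k_tr, "); lengthen t_measure", call. = FALSE)
    }
    mc <- max_correlation(lapply(sims[ok], `[[`, "mrna"),
                          lapply(sims[ok], `[[`, "p"), max_lag = ml)
    tibble::tibble(
      k_eff = k_eff, k_tr = k_tr, k_dr = p$k_dr, k_dec = p$k_dec,
      mean_mrna = mean(mrna_cat), mean_protein = mean(prot_cat),
      cv2_mrna = cv2(mrna_cat), cv2_protein = cv2(prot_cat),
      max_corr = mc$r_max, corr_lag_s = mc$lag * sample_interval)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("noise_scan", class(out))
  attr(out, "config") <- list(replicates = replicates, t_burn_in = t_burn_in,
                              t_measure = t_measure,
                              sample_interval = sample_interval, seed = seed,
                              target_mean_mrna = target_mean_mrna,
                              target_mean_protein = target_mean_protein)
  out
}

#' @export
tidy.noise_scan <- function(x, ...) tibble::as_tibble(unclass(x))

#' @describeIn run_noise_scan One-row summary of the grid (ranges and rank
#'   correlations of the headline trends).
#' @param x A `noise_scan`.
#' @param ... Unused.
#' @export
glance.noise_scan <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    cor_cv2mrna_keff = stats::cor(x$cv2_mrna, x$k_eff, method = "spearman"),
    cor_cv2prot_keff = stats::cor(x$cv2_protein, x$k_eff, method = "spearman"),
    cor_cv2prot_ktr = stats::cor(x$cv2_protein, x$k_tr, method = "spearman"),
    cor_maxcorr_ktr = stats::cor(x$max_corr, x$k_tr, method = "spearman"))
}

#' Effect of a sequence-specific long pause on protein noise
#'
#' Simulates the same gene without annotation (baseline) and with a single
#' long-pause site of each requested mean duration, using shared replicate
#' seeds, and reports the relative change in protein-level noise
#' (squared CV) against baseline with a bootstrap interval over replicates.
#'
#' @param gene A `gene_seq` without the pause annotation.
#' @param site_position Nucleotide position of the pause site.
#' @param durations Mean pause durations to test (seconds).
#' @param probability Pausing probability on arrival (default 0.7, the
#'   his-pause-site value).
#' @param params [kinetic_params()].
#' @param replicates,t_burn_in,t_measure,sample_interval,seed As in
#'   [run_noise_scan()].
#' @param n_boot Bootstrap resamples (over replicate blocks, paired across
#'   scenarios).
#' @return A tibble of class `pause_expt`: one row per scenario with
#'   `pause_duration_s` (0 = baseline), `cv2_protein`, `rel_change`,
#'   `ci_lo`, `ci_hi` (95% bootstrap interval of `rel_change`).
#' @export
run_pause_experiment <- function(gene, site_position, durations = c(100, 500),
                                 probability = 0.7, params = kinetic_params(),
                                 replicates = 4, t_burn_in = 2000,
                                 t_measure = 6000, sample_interval = 2,
                                 seed = 1, n_boot = 500) {
  stopifnot(length(durations) >= 1, replicates >= 2)
  scen <- c(0, sort(durations))
  series <- lapply(scen, function(dur) {
    g <- if (dur > 0) {
      annotate_site(gene, site_position, "long_pause", probability, dur)
    } else gene
    lapply(seq_len(replicates), function(r) {
      s <- simulate_expression(g, params, t_end = t_burn_in + t_measure,
                               sample_interval = sample_interval,
                               seed = seed + r, record = "transcription")
      ts <- s$timeseries
      ts$p[ts$time >= t_burn_in]
    })
  })
  cv2_of <- function(reps, idx) cv2(unlist(reps[idx]))
  base_cv2 <- cv2_of(series[[1]], seq_len(replicates))
  boot_idx <- withr::with_seed(seed, {
    replicate(n_boot, sample.int(replicates, replicates, replace = TRUE),
              simplify = FALSE)
  })
  rows <- purrr::map2(series, scen, function(reps, dur) {
    v <- cv2_of(reps, seq_len(replicates))
    rel <- v / base_cv2 - 1
    if (dur == 0) {
      tibble::tibble(pause_duration_s = 0, cv2_protein = v, rel_change = 0,
                     ci_lo = NA_real_, ci_hi = NA_real_)
    } else {
      # paired bootstrap: the same replicate blocks enter both scenarios
      bs <- vapply(boot_idx, function(idx) {
        cv2_of(reps, idx) / cv2_of(series[[1]], idx) - 1
      }, numeric(1))
      qs <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
      tibble::tibble(pause_duration_s = dur, cv2_protein = v,
                     rel_change = rel, ci_lo = qs[1], ci_hi = qs[2])
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pause_expt", class(out))
  attr(out, "config") <- list(site_position = site_position,
                              probability = probability,
                              replicates = replicates, seed = seed,
                              t_measure = t_measure)
  out
}

#' @export
tidy.pause_expt <- function(x, ...) tibble::as_tibble(unclass(x))

#' Methionine pulse-labeling experiment on the LacZ-like strands
#'
#' Simulates the wild-type and slow-insert variants, pulse-labels
#' methionines, and reports the normalized incorporation curve of each
#' variant on a shared time grid (default: every 10 s after the pulse).
#' Slower-translating variants incorporate label more slowly, so their
#' curves lie below the wild type at matched times.
#'
#' @param variants Fixture variants to run (see [make_lacz_fixture()]).
#' @param params [kinetic_params()].
#' @param t_end Simulated duration; the pulse fires at `pulse_time`.
#' @param pulse_time Pulse instant (seconds).
#' @param sample_step Curve sampling step after the pulse (seconds).
#' @param horizon Curve extent after the pulse (seconds).
#' @param cohort_window Labeled-cohort window (seconds) passed to
#'   [methionine_curve()].
#' @param replicates Replicates per variant (curves are averaged).
#' @param seed Base seed (replicate `r` of every variant uses `seed + r`).
#' @param fixture_seed Seed of the shared fixture backbone.
#' @return A tibble of class `met_curves`: `variant`, `time`, `normalized`
#'   (replicate-averaged), `n_ribosomes` (total cohort size).
#' @export
run_methionine_experiment <- function(variants = c("wt", "insert24", "insert48"),
                                      params = kinetic_params(),
                                      t_end = 1500, pulse_time = 300,
                                      sample_step = 10, horizon = 900,
                                      cohort_window = 60, replicates = 2,
                                      seed = 1, fixture_seed = 1) {
  stopifnot(t_end >= pulse_time + horizon)
  times <- seq(0, horizon, by = sample_step)
  rows <- purrr::map(variants, function(v) {
    g <- make_lacz_fixture(v, seed = fixture_seed)
    curves <- lapply(seq_len(replicates), function(r) {
      s <- simulate_expression(g, params, t_end = t_end, sample_interval = 10,
                               seed = seed + r,
                               record = c("transcription", "translation"),
                               record_met = TRUE)
      methionine_curve(s, g, sample_times = pulse_time + times,
                       pulse_time = pulse_time,
                       cohort_window = cohort_window)
    })
    tibble::tibble(
      variant = v,
      time = times,
      normalized = rowMeans(sapply(curves, `[[`, "normalized")),
      n_ribosomes = sum(sapply(curves, function(cc) cc$n_ribosomes[1])))
  })
  out <- dplyr::bind_rows(rows)
  out$variant <- factor(out$variant, levels = variants)
  class(out) <- c("met_curves", class(out))
  out
}

#' @export
tidy.met_curves <- function(x, ...) tibble::as_tibble(unclass(x))
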