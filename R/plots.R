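#' @describeIn simulate_expression Species counts over time (ggplot).
#' @param object A `txsim` (for `autoplot`).
#' @param species Which species columns to draw.
#' @export
autoplot.txsim <- function(object, species = c("mrna", "p_prem", "p"), ...) {
  df <- tidy(object)
  df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count,
                                   colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "molecules", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kymograph of polymerases and ribosomes
#'
#' Positions of RNAp molecules on the DNA template (and, optionally, of the
#' ribosomes of one RNA compartment) over time, from a run with
#' `kymograph_interval` set. RNAp trajectories show pauses and collisions;
#' ribosome trajectories pile up behind the transcription exposure front.
#'
#' @param sim A `txsim` run with `kymograph_interval` set.
#' @param entity `"rnap"` or `"ribosome"`.
#' @param compartment Compartment id filter (for ribosomes).
#' @return A ggplot.
#' @export
plot_kymograph <- function(sim, entity = c("rnap", "ribosome"),
                           compartment = NULL) {
  entity <- match.arg(entity)
  ky <- sim$kymograph
  if (!nrow(ky)) stop("no kymograph samples; set kymograph_interval",
                      call. = FALSE)
  ky <- ky[ky$entity == entity, ]
  if (!is.null(compartment)) ky <- ky[ky$comp_id %in% compartment, ]
  ggplot2::ggplot(ky, ggplot2::aes(x = .data$time, y = .data$position,
                                   group = .data$entity_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (s)",
                  y = if (entity == "rnap") "template position (nt)"
                      else "transcript position (ribonucleotide)") +
    ggplot2::theme_minimal()
}

#' Histogram of inter-event intervals
#'
#' @inheritParams event_intervals
#' @param binwidth Histogram bin width (seconds).
#' @return A ggplot.
#' @export
plot_intervals <- function(events, type, binwidth = NULL) {
  iv <- event_intervals(events, type)
  ggplot2::ggplot(tibble::tibble(interval = iv),
                  ggplot2::aes(x = .data$interval)) +
    ggplot2::geom_histogram(binwidth = binwidth, bins = 40,
                            fill = "grey40", colour = "white") +
    ggplot2::labs(x = paste0("interval between ", type, " events (s)"),
                  y = "count") +
    ggplot2::theme_minimal()
}

#' @describeIn run_noise_scan Noise and correlation trends across the grid.
#' @param object A `noise_scan` (for `autoplot`).
#' @param metric `"cv2_mrna"`, `"cv2_protein"` or `"max_corr"`.
#' @export
autoplot.noise_scan <- function(object, metric = c("cv2_protein", "cv2_mrna",
                                                   "max_corr"), ...) {
  metric <- match.arg(metric)
  df <- tidy(object)
  df$k_tr_f <- factor(df$k_tr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k_eff, y = .data[[metric]],
                                   colour = .data$k_tr_f,
                                   group = .data$k_tr_f)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(k[eff] ~ (s^-1)), y = metric,
                  colour = expression(k[tr] ~ (s^-1))) +
    ggplot2::theme_minimal()
}

#' @describeIn run_methionine_experiment Incorporation curves per variant.
#' @param object A `met_curves` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.met_curves <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$normalized,
                                   colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after pulse (s)",
                  y = "normalized methionine incorporation",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_pause_experiment Relative protein-noise change per pause
#'   duration with bootstrap intervals.
#' @param object A `pause_expt` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.pause_expt <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$pause_duration_s > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pause_duration_s),
                                   y = 100 * .data$rel_change)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$ci_lo,
                                        ymax = 100 * .data$ci_hi),
                           width = 0.2) +
    ggplot2::labs(x = "mean pause duration (s)",
                  y = "protein CV² change vs baseline (%)") +
    ggplot2::theme_minimal()
}
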