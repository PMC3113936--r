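event_type_labels <- c(
  "tx_bind", "tx_oc", "tx_clear", "tx_complete", "tx_premature", "tx_detach",
  "site_pass", "site_trigger", "tl_init", "tl_complete", "tl_drop", "tl_tt",
  "rna_mark", "comp_destroy", "met_act")

record_mask_of <- function(record, record_met) {
  bits <- c(transcription = 1L, translation = 2L, rna = 4L, sites = 8L)
  unknown <- setdiff(record, names(bits))
  if (length(unknown)) {
    stop("unknown record categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(bits[record]) + if (isTRUE(record_met)) 16L else 0L
}

#' Simulate coupled transcription and translation of one gene
#'
#' Runs the delayed-SSA model: RNAp molecules bind the promoter, form the
#' open complex (normally distributed delay), clear, and elongate one
#' nucleotide at a time subject to footprint exclusion, pausing, arrests,
#' editing, premature termination and pyrophosphorolysis. Each transcript is
#' a run-time compartment in which ribosomes initiate once the ribosome
#' binding site emerges from under the RNAp footprint and translate one
#' codon at a time (three translocation sub-steps plus a codon-specific
#' activation), subject to back-translocation, drop-off and
#' trans-translation. Finished peptides fold into active protein, which
#' degrades; functional mRNA is degradation-marked at a first-order rate and
#' removed once the last ribosome leaves.
#'
#' @param gene A [gene_sequence()] (or fixture) to express.
#' @param params [kinetic_params()].
#' @param t_end Simulated duration in seconds.
#' @param sample_interval Sampling grid spacing for the species time series.
#' @param seed Optional integer; when given the run is reproducible
#'   (internally `withr::with_seed`).
#' @param record Character vector of event categories to log:
#'   `"transcription"` (promoter binding, open complex, clearance,
#'   completion, premature termination, detachment), `"translation"`
#'   (initiation, completion, drop-off, trans-translation), `"rna"`
#'   (degradation marking, compartment destruction), `"sites"` (annotated
#'   site passages and triggers).
#' @param record_met Also log methionine-codon activations (needed for
#'   [methionine_curve()]).
#' @param kymograph_interval If positive, sample every RNAp and ribosome
#'   position on this grid (for [plot_kymograph()]).
#' @param check_invariants Run structural audits (disjoint footprints, no
#'   overtaking, ribosome behind the exposure front, RNAp/ribosome
#'   conservation) at every sample instant; errors on violation.
#' @param max_events Safety cap on the number of reaction firings.
#'
#' @return A `txsim` object: list with `timeseries` (tibble: time, mrna,
#'   p_prem, p, free pools, bound counts), `events` (tibble: time, event,
#'   comp_id, entity_id, position, value), `kymograph`, and `counters`
#'   (event totals, channel-slot audit, final state).
#' @examples
#' g <- generate_random_gene(50, seed = 1)
#' sim <- simulate_expression(g, kinetic_params(), t_end = 500, seed = 1)
#' head(sim$timeseries)
#' @export
simulate_expression <- function(gene, params = kinetic_params(), t_end,
                                sample_interval = 1,
                                seed = NULL,
                                record = c("transcription", "translation",
                                           "rna", "sites"),
                                record_met = FALSE,
                                kymograph_interval = NULL,
                                check_invariants = FALSE,
                                max_events = 2e9) {
  stopifnot(inherits(gene, "gene_seq"), t_end > 0, sample_interval > 0)
  params <- if (inherits(params, "kinetic_params")) params else
    do.call(kinetic_params, params)
  control <- list(
    record_mask = record_mask_of(record, record_met),
    check_invariants = isTRUE(check_invariants),
    kymograph_interval = if (is.null(kymograph_interval)) 0
                         else as.double(kymograph_interval),
    max_events = as.double(max_events))
  run <- function() {
    .engine_run(engine_gene(gene, params), engine_params(params),
                as.double(t_end), as.double(sample_interval), control)
  }
  raw <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  ev <- tibble::as_tibble(raw$events)
  ev$event <- event_type_labels[ev$type]
  ev <- ev[, c("time", "event", "comp_id", "entity_id", "position", "value")]
  ky <- tibble::as_tibble(raw$kymograph)
  if (nrow(ky)) {
    ky$entity <- ifelse(ky$is_ribosome == 1, "ribosome", "rnap")
    ky <- ky[, c("time", "entity", "entity_id", "comp_id", "position")]
  } else {
    ky <- tibble::tibble(time = double(), entity = character(),
                         entity_id = integer(), comp_id = integer(),
                         position = integer())
  }
  counters <- raw$counters
  counters$event_type_counts <- setNames(counters$event_type_counts,
                                         event_type_labels)
  structure(list(
    timeseries = tibble::as_tibble(raw$timeseries),
    events = ev,
    kymograph = ky,
    counters = counters,
    gene_length = gene$length,
    params = params,
    t_end = t_end,
    sample_interval = sample_interval
  ), class = "txsim")
}

#' @export
print.txsim <- function(x, ...) {
  cat("txsim: ", x$t_end, " s on a ", x$gene_length, "-nt gene; ",
      format(x$counters$n_events, big.mark = ","), " reaction firings\n",
      sep = "")
  cat("  proteins completed: ",
      x$counters$event_type_counts[["tl_complete"]],
      "; transcripts completed: ",
      x$counters$event_type_counts[["tx_complete"]], "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_expression Long-format species counts
#'   (`time`, `species`, `count`).
#' @param x A `txsim` object.
#' @param ... Unused.
#' @export
tidy.txsim <- function(x, ...) {
  tidyr::pivot_longer(x$timeseries, -"time",
                      names_to = "species", values_to = "count")
}

#' @describeIn simulate_expression One-row run summary: durations, event and
#'   molecule totals, mean functional-mRNA and protein levels, and the
#'   channel-slot audit (`channel_slots_final` should equal
#'   `channel_slots_baseline` once no compartment is alive).
#' @export
glance.txsim <- function(x, ...) {
  ts <- x$timeseries
  tibble::tibble(
    t_end = x$t_end,
    n_events = x$counters$n_events,
    transcripts_completed = x$counters$event_type_counts[["tx_complete"]],
    proteins_completed = x$counters$event_type_counts[["tl_complete"]],
    mean_mrna = mean(ts$mrna),
    mean_protein = mean(ts$p),
    final_protein = x$counters$final_p,
    live_compartments = x$counters$live_compartments,
    channel_slots_final = x$counters$slots_in_use_final,
    channel_slots_baseline = x$counters$slots_baseline
  )
}

#' Interval series between consecutive events of one type
#'
#' @param events Event tibble from a `txsim` (or the `txsim` itself).
#' @param type Event label, e.g. `"tx_oc"` (transcription initiation,
#'   open-complex completion), `"tx_complete"`, `"tl_init"`, `"tl_complete"`.
#' @return Numeric vector of consecutive time differences (seconds).
#' @export
event_intervals <- function(events, type) {
  if (inherits(events, "txsim")) events <- events$events
  tt <- sort(events$time[events$event == type])
  if (length(tt) < 2) {
    stop("need at least 2 events of type '", type, "' (got ", length(tt), ")",
         call. = FALSE)
  }
  diff(tt)
}
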