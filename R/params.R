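#' Kinetic parameters of the coupled transcription-translation model
#'
#' Builds the full rate-constant set of the model. Defaults are the measured
#' E. coli (LacZ) values used throughout the package. All rates are in
#' s^-1 and all delays/durations in seconds; footprints are in nucleotides
#' (RNAp) or ribonucleotides (ribosome).
#'
#' Transcription: `k_init` (RNAp-promoter binding, per free RNAp),
#' `toc_mean`/`toc_sd` (normally distributed open-complex delay, truncated at
#' zero), `k_m` (promoter clearance and single-nucleotide elongation),
#' `k_a_far`/`k_a_near` (post-step activation; the near rate applies at
#' template positions <= 10), `k_p`/`tau_p` (ubiquitous pausing and mean pause
#' dwell), `k_ar`/`tau_ar` (arrest and mean arrest dwell; arrests are not
#' released by collisions), `k_ec`/`tau_c` (editing and mean editing dwell),
#' `k_pre` (premature termination), `k_pyro` (pyrophosphorolysis, one
#' nucleotide backwards), `k_f` (release at the last nucleotide), `k_dr`
#' (first-order functional-mRNA degradation), `delta_rnap` (the RNAp occupies
#' `2 * delta_rnap + 1` nucleotides).
#'
#' Translation: `k_trans_init` (initiation once the ribosome binding site is
#' exposed and free), `k_tm` (each of the three translocation sub-steps),
#' `k_transA`/`k_transB`/`k_transC` (codon-class activation rates),
#' `k_bt` (back-translocation by one codon), `k_drop` (ribosome drop-off,
#' applied as a continuous per-ribosome hazard), `k_tt` (trans-translation,
#' per bound ribosome; releases every ribosome and destroys the strand),
#' `k_trans_f` (completion at the stop codon), `k_fold` (folding/activation
#' of the finished peptide), `k_dec` (active-protein degradation),
#' `delta_rib` (the ribosome occupies `2 * delta_rib + 1` ribonucleotides).
#'
#' Pools and control: `n_rnap` and `n_rib` are the total RNAp and ribosome
#' pools; `k_eff` is the effective transcription-initiation propensity at a
#' full RNAp pool (s^-1). By default `k_eff = k_init * n_rnap`; lowering it
#' emulates repression of the promoter without modeling repressor molecules
#' explicitly. Internally binding fires at `k_eff / n_rnap * [free RNAp]`, so
#' RNAp conservation still gates initiation.
#'
#' Any alternative-pathway reaction is disabled by setting its rate to zero
#' (for example `k_p = 0` switches ubiquitous pausing off).
#'
#' @param ... Named overrides of any default listed above.
#' @param k_eff Effective transcription-initiation rate (s^-1). Defaults to
#'   `k_init * n_rnap` after overrides are applied.
#'
#' @return A named list of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(k_trans_init = 0.1)
#' p$k_m
#' @export
kinetic_params <- function(..., k_eff = NULL) {
  defaults <- list(
    k_init = 0.015, toc_mean = 40, toc_sd = 4,
    k_m = 114, k_a_far = 114, k_a_near = 30,
    k_p = 0.55, tau_p = 3,
    k_ar = 0.00028, tau_ar = 100,
    k_ec = 0.008, tau_c = 5,
    k_pre = 0.00019, k_pyro = 0.75, k_f = 2, k_dr = 0.011,
    delta_rnap = 12,
    k_trans_init = 0.33, k_tm = 1000,
    k_transA = 35, k_transB = 8, k_transC = 4.5,
    k_bt = 1.5, k_drop = 0.000114, k_tt = 0.000052,
    k_trans_f = 2, k_fold = 0.0024, k_dec = 0.0017,
    delta_rib = 15,
    n_rnap = 28, n_rib = 10000
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[nm] <- overrides
  }
  p <- defaults
  p$k_eff <- if (is.null(k_eff)) p$k_init * p$n_rnap else k_eff
  bad <- names(p)[vapply(p, function(v) {
    !is.numeric(v) || length(v) != 1L || is.na(v) || v < 0
  }, logical(1))]
  if (length(bad)) {
    stop("kinetic parameters must be single non-negative numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$delta_rnap != round(p$delta_rnap) || p$delta_rib != round(p$delta_rib)) {
    stop("footprint half-widths must be whole numbers", call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters of the coupled transcription-translation model\n")
  df <- tidy(x)
  cat(sprintf("  %-14s %g\n", df$parameter, df$value), sep = "")
  invisible(x)
}

#' @describeIn kinetic_params One row per parameter (`parameter`, `value`).
#' @param x A `kinetic_params` object.
#' @export
tidy.kinetic_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unlist(x, use.names = FALSE))
}

# flat list the C++ engine expects; k_eff guaranteed present
engine_params <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  unclass(params)
}
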