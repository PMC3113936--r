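#' Generic delayed stochastic simulation engine
#'
#' A small, closure-based delayed-SSA (direct method) whose reaction
#' channels can be added and removed while the simulation runs, and whose
#' products may appear after a sampled delay held in a wait list. This is
#' the algorithmic skeleton the gene-expression engine follows; it is
#' exposed for building and testing small reaction systems directly.
#'
#' State is a named list of species counts held in the engine environment.
#' A channel is a propensity function `function(state) -> rate` plus an
#' effect `function(state) -> state`; an optional `delayed_effect` is
#' applied `delay` seconds after the firing, with `delay` described by
#' `list(type = "fixed", value = )` or `list(type = "normal", mean = , sd = )`
#' (normal delays are truncated at zero by re-sampling). When a sampled SSA
#' waiting time would cross a queued release, the release is applied first
#' and the waiting time re-sampled. Simultaneous releases leave the queue in
#' first-in-first-out order.
#'
#' @param state Named list of initial species counts.
#' @return An `ssa_engine` environment.
#' @examples
#' eng <- ssa_engine(list(A = 10, B = 0))
#' ssa_add_channel(eng,
#'   propensity = function(s) 0.5 * s$A,
#'   effect = function(s) { s$A <- s$A - 1; s$B <- s$B + 1; s })
#' res <- ssa_run(eng, t_end = 5, sample_interval = 1)
#' res$timeseries
#' @export
ssa_engine <- function(state = list()) {
  eng <- new.env(parent = emptyenv())
  eng$state <- state
  eng$time <- 0
  eng$channels <- list()
  eng$queue_time <- numeric()
  eng$queue_effect <- list()
  eng$queue_seq <- integer()   # insertion order for FIFO tie-breaking
  eng$n_scheduled <- 0L
  eng$next_handle <- 1L
  class(eng) <- "ssa_engine"
  eng
}

#' @export
print.ssa_engine <- function(x, ...) {
  cat("ssa_engine: t = ", x$time, ", ", length(x$channels), " channel(s), ",
      length(x$queue_time), " pending delayed release(s)\n", sep = "")
  invisible(x)
}

#' @rdname ssa_engine
#' @param engine An `ssa_engine`.
#' @param propensity `function(state) -> rate` (must be non-negative).
#' @param effect `function(state) -> state`, applied at the firing time.
#' @param delay Optional delay spec (see Details) for `delayed_effect`.
#' @param delayed_effect Optional `function(state) -> state` applied after
#'   the sampled delay.
#' @param handle Optional channel handle (character); autogenerated if `NULL`.
#' @return `ssa_add_channel()` returns the channel handle (character).
#' @export
ssa_add_channel <- function(engine, propensity, effect, delay = NULL,
                            delayed_effect = NULL, handle = NULL) {
  stopifnot(inherits(engine, "ssa_engine"), is.function(propensity),
            is.function(effect))
  if (is.null(handle)) {
    handle <- paste0("ch", engine$next_handle)
    engine$next_handle <- engine$next_handle + 1L
  }
  handle <- as.character(handle)
  if (handle %in% names(engine$channels)) {
    stop("duplicate channel handle '", handle, "'", call. = FALSE)
  }
  if (!is.null(delay)) validate_delay_spec(delay)
  engine$channels[[handle]] <- list(propensity = propensity, effect = effect,
                                    delay = delay,
                                    delayed_effect = delayed_effect)
  handle
}

validate_delay_spec <- function(delay) {
  if (!is.list(delay) || is.null(delay$type) ||
      !delay$type %in% c("fixed", "normal")) {
    stop("delay must be list(type = 'fixed', value =) or ",
         "list(type = 'normal', mean =, sd =)", call. = FALSE)
  }
  if (delay$type == "fixed" && (is.null(delay$value) || delay$value < 0)) {
    stop("fixed delay needs a non-negative value", call. = FALSE)
  }
  if (delay$type == "normal" &&
      (is.null(delay$mean) || is.null(delay$sd) || delay$sd < 0)) {
    stop("normal delay needs mean and sd", call. = FALSE)
  }
  invisible(delay)
}

sample_delay <- function(delay) {
  switch(delay$type,
         fixed = delay$value,
         normal = sample_oc_delay(1, delay$mean, delay$sd))
}

#' Zero-truncated normal delay sampler
#'
#' Samples the promoter open-complex delay: normal with the given mean and
#' standard deviation, re-sampled while non-positive (with the default
#' 40 +/- 4 s the truncation probability is negligible, ~10 sigma).
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters in seconds (defaults 40 and 4).
#' @return Numeric vector of positive delays.
#' @export
sample_oc_delay <- function(n, mean = 40, sd = 4) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' @rdname ssa_engine
#' @param handles Character vector of channel handles to remove.
#' @param cancel_delayed Also drop pending delayed releases scheduled by the
#'   removed channels (matched by handle tag).
#' @return `ssa_remove_channels()` returns the number of channels removed.
#' @export
ssa_remove_channels <- function(engine, handles, cancel_delayed = FALSE) {
  stopifnot(inherits(engine, "ssa_engine"))
  handles <- as.character(handles)
  unknown <- setdiff(handles, names(engine$channels))
  if (length(unknown)) {
    stop("unknown channel handle(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  engine$channels[handles] <- NULL
  if (isTRUE(cancel_delayed) && length(engine$queue_time)) {
    tags <- vapply(engine$queue_effect, function(e) attr(e, "origin") %||% "",
                   character(1))
    keep <- !(tags %in% handles)
    engine$queue_time <- engine$queue_time[keep]
    engine$queue_effect <- engine$queue_effect[keep]
    engine$queue_seq <- engine$queue_seq[keep]
  }
  length(handles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname ssa_engine
#' @return `ssa_total_propensity()` returns the current propensity sum.
#' @export
ssa_total_propensity <- function(engine) {
  if (!length(engine$channels)) return(0)
  sum(vapply(engine$channels, function(ch) {
    a <- ch$propensity(engine$state)
    if (is.na(a) || a < 0) stop("negative or NA propensity", call. = FALSE)
    a
  }, numeric(1)))
}

#' @rdname ssa_engine
#' @return `ssa_schedule()` schedules `effect` at `time + delay` and returns
#'   the engine invisibly.
#' @export
ssa_schedule <- function(engine, effect, delay) {
  stopifnot(inherits(engine, "ssa_engine"), is.function(effect))
  if (is.na(delay) || delay < 0) {
    stop("delay must be non-negative", call. = FALSE)
  }
  engine$n_scheduled <- engine$n_scheduled + 1L
  engine$queue_time <- c(engine$queue_time, engine$time + delay)
  engine$queue_effect <- c(engine$queue_effect, list(effect))
  engine$queue_seq <- c(engine$queue_seq, engine$n_scheduled)
  ord <- order(engine$queue_time, engine$queue_seq)  # FIFO among ties
  engine$queue_time <- engine$queue_time[ord]
  engine$queue_effect <- engine$queue_effect[ord]
  engine$queue_seq <- engine$queue_seq[ord]
  invisible(engine)
}

#' @rdname ssa_engine
#' @return `ssa_step()` advances one event and returns
#'   `list(time, type, handle)` with `type` one of `"reaction"`, `"delayed"`,
#'   `"terminated"` (no channel can fire and the wait list is empty).
#' @export
ssa_step <- function(engine) {
  stopifnot(inherits(engine, "ssa_engine"))
  a <- if (length(engine$channels)) {
    vapply(engine$channels, function(ch) {
      v <- ch$propensity(engine$state)
      if (is.na(v) || v < 0) stop("negative or NA propensity", call. = FALSE)
      v
    }, numeric(1))
  } else numeric()
  A <- sum(a)
  t_rxn <- if (A > 0) engine$time + rexp(1) / A else Inf
  t_del <- if (length(engine$queue_time)) engine$queue_time[1] else Inf
  if (!is.finite(t_rxn) && !is.finite(t_del)) {
    return(list(time = engine$time, type = "terminated", handle = NA_character_))
  }
  if (t_del <= t_rxn) {
    engine$time <- t_del
    eff <- engine$queue_effect[[1]]
    engine$queue_time <- engine$queue_time[-1]
    engine$queue_effect <- engine$queue_effect[-1]
    engine$queue_seq <- engine$queue_seq[-1]
    engine$state <- eff(engine$state)
    return(list(time = engine$time, type = "delayed", handle = NA_character_))
  }
  engine$time <- t_rxn
  k <- sample.int(length(a), 1, prob = a)
  ch <- engine$channels[[k]]
  handle <- names(engine$channels)[k]
  engine$state <- ch$effect(engine$state)
  if (!is.null(ch$delayed_effect)) {
    d <- if (is.null(ch$delay)) 0 else sample_delay(ch$delay)
    eff <- ch$delayed_effect
    attr(eff, "origin") <- handle
    ssa_schedule(engine, eff, d)
  }
  list(time = engine$time, type = "reaction", handle = handle)
}

#' @rdname ssa_engine
#' @param t_end Stop time (seconds).
#' @param sample_interval Sampling grid spacing.
#' @param tracked Species names to sample; default all in the initial state.
#' @return `ssa_run()` returns `list(timeseries, events)`, both tibbles.
#' @export
ssa_run <- function(engine, t_end, sample_interval, tracked = NULL) {
  stopifnot(inherits(engine, "ssa_engine"), t_end > engine$time,
            sample_interval > 0)
  tracked <- tracked %||% names(engine$state)
  grid <- seq(engine$time, t_end, by = sample_interval)
  samples <- matrix(NA_real_, length(grid), length(tracked),
                    dimnames = list(NULL, tracked))
  gi <- 1L
  ev_time <- numeric(); ev_type <- character(); ev_handle <- character()
  take <- function(upto, state) {
    while (gi <= length(grid) && grid[gi] <= upto) {
      samples[gi, ] <<- unlist(state[tracked])
      gi <<- gi + 1L
    }
  }
  repeat {
    prev <- list(state = engine$state, time = engine$time,
                 qt = engine$queue_time, qe = engine$queue_effect,
                 qs = engine$queue_seq)
    st <- ssa_step(engine)
    if (st$type == "terminated") { take(t_end, engine$state); break }
    if (st$time > t_end) {
      # the firing lies beyond the horizon: sample the pre-event state and
      # roll the engine back to it
      take(t_end, prev$state)
      engine$state <- prev$state
      engine$queue_time <- prev$qt
      engine$queue_effect <- prev$qe
      engine$queue_seq <- prev$qs
      engine$time <- t_end
      break
    }
    # grid points up to and including the firing time see the pre-event state
    take(st$time, prev$state)
    ev_time <- c(ev_time, st$time)
    ev_type <- c(ev_type, st$type)
    ev_handle <- c(ev_handle, st$handle)
  }
  list(
    timeseries = tibble::as_tibble(cbind(tibble::tibble(time = grid),
                                         as.data.frame(samples))),
    events = tibble::tibble(time = ev_time, type = ev_type,
                            handle = ev_handle)
  )
}
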