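#' Build the microscale event catalog by explicit enumeration
#'
#' Enumerates one event per beta-O-4 bond (scission), one per unordered
#' liquor chain pair (condensation) and one per chain with S content
#' (demethoxylation), with propensities from the kinetics library.  With
#' `engine = "filtered"` the activation-energy threshold prunes scission
#' sites outside the per-chain margin and pairs outside the combined-mass
#' window; demethoxylation is never filtered (its activation energy is a
#' single shared constant, so no within-type energy ratio exists).
#'
#' This enumerator is quadratic in the liquor population and is meant for
#' inspection and as a brute-force oracle; the running engine maintains the
#' same propensities through incremental aggregates.
#'
#' @param sim a `lignin_sim` handle.
#' @param engine `"full"` or `"filtered"`; defaults to the simulation's
#'   configured engine.
#' @return object of class `event_catalog`: data.frame of events with an
#'   `r_tot` attribute.
#' @export
build_catalog <- function(sim, engine = sim$config$engine) {
  engine <- match.arg(engine, c("filtered", "full"))
  df <- sim_catalog(sim_ptr(sim), engine == "filtered")
  structure(df, r_tot = sum(df$propensity), engine = engine,
            class = c("event_catalog", "data.frame"))
}

#' @export
print.event_catalog <- function(x, ...) {
  cat("<event_catalog>", nrow(x), "events | r_tot =",
      format(attr(x, "r_tot"), digits = 6), "min^-1 | engine:",
      attr(x, "engine"), "\n")
  invisible(x)
}

#' One Gillespie direct-method draw from a catalog
#'
#' Samples the stochastic time increment `delta_t = -ln(xi) / r_tot` and
#' selects the next event with probability proportional to its propensity
#' (cumulative-sum inversion; ties at equal cumulative sums resolve to the
#' first index).
#'
#' @param catalog an [build_catalog()] result (or any data.frame with a
#'   `propensity` column).
#' @param u time and selection uniforms; supplied explicitly in tests,
#'   drawn from R's RNG by default.
#' @return list with `event` (one-row data.frame), `index`, and `delta_t`
#'   (min); `NULL` when `r_tot` is 0 (no microscale activity — the caller
#'   advances the macro clock instead).
#' @export
gillespie_step <- function(catalog, u = stats::runif(2)) {
  r_tot <- sum(catalog$propensity)
  if (r_tot <= 0) return(NULL)
  delta_t <- -log(u[1]) / r_tot
  cum <- cumsum(catalog$propensity)
  idx <- findInterval(u[2] * r_tot, cum, left.open = TRUE) + 1L
  idx <- min(idx, nrow(catalog))
  list(event = catalog[idx, , drop = FALSE], index = idx, delta_t = delta_t)
}

#' Run the microscale engine for one macro interval
#'
#' Repeats draw-and-execute until the accumulated stochastic time would
#' exceed `dt`; the event straddling the boundary is deferred, not
#' executed.
#'
#' @param sim a `lignin_sim` handle.
#' @param dt interval length (min).
#' @return number of executed events, invisibly.
#' @export
run_micro_interval <- function(sim, dt = sim$config$macro$dt) {
  out <- sim_run_micro(sim_ptr(sim), dt)
  invisible(out$n_events)
}

#' Integrate the coupled multiscale model
#'
#' Advances the full system (macro balances, chain transfer, micro
#' chemistry) for `duration` minutes under a piecewise-constant jacket
#' schedule, recording observables every `record_every` minutes.
#'
#' @param sim a `lignin_sim` handle (modified in place).
#' @param duration minutes to simulate.
#' @param t_ext jacket temperature (K): scalar or vector matching `times`.
#' @param mdot_ext jacket flow (mL/min): scalar or vector matching `times`.
#' @param times left edges (min, from the start of this call) at which the
#'   schedule values apply; first element must be 0.
#' @param micro logical; `FALSE` integrates the macro balances only.
#' @param record_every recording interval (min).
#' @return data.frame time series: masses, temperatures, liquor Mn/Mw/S-G,
#'   chain counts, total rate and cumulative event counts.
#' @export
run_fractionation <- function(sim, duration,
                              t_ext = sim$config$run$jacket_t_ext,
                              mdot_ext = sim$config$run$jacket_mdot,
                              times = 0,
                              micro = TRUE,
                              record_every = sim$config$run$record_every_min) {
  n <- max(length(times), length(t_ext), length(mdot_ext))
  times <- rep_len(times, n)
  t_ext <- rep_len(t_ext, n)
  mdot_ext <- rep_len(mdot_ext, n)
  if (times[1] != 0) stop("schedule must start at time 0", call. = FALSE)
  sim_run(sim_ptr(sim), duration, times, t_ext, mdot_ext, micro, record_every)
}

#' Enable or disable event logging
#'
#' @param sim a `lignin_sim` handle.
#' @param on logical.
#' @export
event_log_enable <- function(sim, on = TRUE) {
  sim_log_enable(sim_ptr(sim), on)
  invisible(sim)
}

#' Retrieve the event log
#'
#' @param sim a `lignin_sim` handle.
#' @return data.frame with `t_min`, `kind`, participants and the drawn
#'   stochastic increment.
#' @export
event_log <- function(sim) {
  sim_event_log(sim_ptr(sim))
}
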