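#' One explicit-Euler step of the chip/liquor lignin mass balance
#'
#' Delignification moves lignin from the chip phase (`L_c`) into solution
#' (`L_d`) at rate `k_D L_c`; redeposition returns it at `k_R L_d`.  Both
#' coefficients are Arrhenius: `k_D` at the chip temperature, `k_R` at the
#' liquor temperature.  The step conserves `L_c + L_d` exactly; gross
#' dissolved and redeposited masses are returned so the caller can feed the
#' chain-transfer accumulators.
#'
#' @param l_c,l_d lignin mass in the chip phase and in solution (g).
#' @param t_c,t_f chip and liquor temperatures (K).
#' @param macro macro-parameter list (see `kmc_config()$macro`).
#' @param dt step length (min); defaults to the configured 5e-4 min.
#' @return list with `l_c`, `l_d`, `dissolved` (gross g into solution),
#'   `redeposited` (gross g back to the chip) and the net rate `r_d`
#'   (g/min).
#' @export
mass_balance_step <- function(l_c, l_d, t_c, t_f, macro = kmc_config()$macro,
                              dt = macro$dt) {
  if (l_c < 0 || l_d < 0) stop("lignin masses must be non-negative", call. = FALSE)
  k_d <- arrhenius_k(macro$a_d, macro$e_d, t_c)
  k_r <- arrhenius_k(macro$a_r, macro$e_r, t_f)
  dis <- dt * k_d * l_c
  red <- dt * k_r * l_d
  l_c2 <- l_c - dis + red
  l_d2 <- l_d + dis - red
  if (l_c2 < 0) {
    warning("mass-balance step drove L_c negative; clamped to 0 ",
            "(parameters may be stiff for this dt)", call. = FALSE)
    l_d2 <- l_d2 + l_c2
    l_c2 <- 0
  }
  if (l_d2 < 0) {
    warning("mass-balance step drove L_d negative; clamped to 0", call. = FALSE)
    l_c2 <- l_c2 + l_d2
    l_d2 <- 0
  }
  list(l_c = l_c2, l_d = l_d2, dissolved = dis, redeposited = red,
       r_d = k_d * l_c - k_r * l_d)
}

#' One explicit-Euler step of the two-phase energy balance
#'
#' The chip phase gains reaction heat `dh_r * r_d` and exchanges
#' `U (T_f - T_c)` with the liquor; the liquor loses that exchange term and
#' gains `cp_ext * mdot_ext * (T_ext - T_f)` from the external heating
#' jacket.
#'
#' @param t_c,t_f chip and liquor temperatures (K).
#' @param r_d net delignification rate (g/min) entering the heat of
#'   reaction term.
#' @param t_ext jacket temperature (K).
#' @param mdot_ext jacket flow rate (mL/min).
#' @param macro macro-parameter list.
#' @param dt step length (min).
#' @return list with updated `t_c`, `t_f`.
#' @export
energy_balance_step <- function(t_c, t_f, r_d, t_ext, mdot_ext,
                                macro = kmc_config()$macro, dt = macro$dt) {
  if (t_c <= 0 || t_f <= 0) stop("temperatures must be positive", call. = FALSE)
  t_c2 <- t_c + dt * (macro$dh_r * r_d + macro$u * (t_f - t_c)) /
    (macro$cp_c * macro$m_c)
  t_f2 <- t_f + dt * (-macro$u * (t_f - t_c) +
                        macro$cp_ext * mdot_ext * (t_ext - t_f)) /
    (macro$cp_f * macro$m_f)
  if (!is.finite(t_c2) || !is.finite(t_f2)) {
    stop("energy balance diverged; use a smaller dt", call. = FALSE)
  }
  list(t_c = t_c2, t_f = t_f2)
}

#' Closed-form solution of the constant-temperature mass balance
#'
#' At fixed temperatures the mass balance is a linear two-state system with
#' conserved total: `L_c(t) = L_inf + (L_c(0) - L_inf) exp(-(k_D+k_R) t)`
#' with `L_inf = k_R (L_c + L_d) / (k_D + k_R)`.  Used as the oracle for
#' the Euler integrator.
#'
#' @param t time (min), vectorized.
#' @inheritParams mass_balance_step
#' @return data.frame with `t_min`, `l_c`, `l_d`.
#' @export
mass_balance_exact <- function(t, l_c, l_d, t_c, t_f, macro = kmc_config()$macro) {
  k_d <- arrhenius_k(macro$a_d, macro$e_d, t_c)
  k_r <- arrhenius_k(macro$a_r, macro$e_r, t_f)
  tot <- l_c + l_d
  l_inf <- if (k_d + k_r > 0) k_r * tot / (k_d + k_r) else l_c
  lc_t <- l_inf + (l_c - l_inf) * exp(-(k_d + k_r) * t)
  data.frame(t_min = t, l_c = lc_t, l_d = tot - lc_t)
}

#' One coupled macro step of a running simulation
#'
#' Executes, in order: the mass-balance Euler step (feeding the dissolution
#' and redeposition accumulators), the energy-balance step, chain transfers
#' in both directions while the accumulators permit, the threshold update
#' for the new liquor temperature, and finally the Gillespie micro engine
#' for the interval `dt`.
#'
#' @param sim a `lignin_sim` handle.
#' @param t_ext jacket temperature (K).
#' @param mdot_ext jacket flow (mL/min).
#' @param micro run the microscale engine (set `FALSE` for macro-only
#'   integration).
#' @return `sim`, invisibly.
#' @export
macro_step <- function(sim, t_ext, mdot_ext, micro = TRUE) {
  sim_macro_step(sim_ptr(sim), t_ext, mdot_ext, micro)
  invisible(sim)
}
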