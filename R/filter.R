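#' Activation-energy threshold for event filtering
#'
#' Events whose rate coefficient is more than `ratio_cutoff` times smaller
#' than the fastest event of the same type contribute negligibly to the
#' total rate.  By the Arrhenius relation this translates into an energy
#' margin `deltaE_th = R T ln(ratio_cutoff)`, reported in kJ/mol.  At 353 K
#' with the default cutoff of 1000 the threshold is 20.27 kJ/mol; it is
#' recomputed from the current liquor temperature every macro step.
#'
#' @param T temperature (K).
#' @param ratio_cutoff rate-coefficient ratio defining "negligible";
#'   must exceed 1.
#' @param r_gas gas constant (J mol^-1 K^-1).
#' @return threshold in kJ/mol.
#' @examples
#' compute_threshold(353, 1000)  # 20.27 kJ/mol
#' @export
compute_threshold <- function(T, ratio_cutoff = 1000, r_gas = R_GAS) {
  if (any(T <= 0)) stop("temperature must be positive", call. = FALSE)
  if (ratio_cutoff <= 1) {
    stop("ratio_cutoff must exceed 1 (a cutoff of 1 filters everything)",
         call. = FALSE)
  }
  r_gas * T * log(ratio_cutoff) / 1000
}

#' Scission-site filter for one chain
#'
#' Retains exactly the bonds whose activation energy lies within
#' `delta_e_th` of the chain's own lowest-energy scission site (the
#' per-chain reference; the minimum-energy bond is always retained).
#'
#' @param bond_energies numeric vector of per-bond activation energies
#'   (kJ/mol).
#' @param delta_e_th threshold from [compute_threshold()] (kJ/mol).
#' @return integer indices (1-based) of retained bonds.
#' @export
filter_bond_sites <- function(bond_energies, delta_e_th) {
  if (length(bond_energies) == 0) return(integer(0))
  which(bond_energies <= min(bond_energies) + delta_e_th)
}

#' Combined-molar-mass window for condensation
#'
#' Inverts the V-shaped condensation energy function at
#' `E_con,min + deltaE_th`: only chain pairs whose combined molar mass
#' falls inside `[mw_low, mw_high]` are kinetically relevant.  With the
#' default parameterization at 353 K the upper bound is 1672.33 g/mol, so
#' an all-G condensate can span at most 9 units (`dp_high`).
#'
#' @param T temperature (K).
#' @param cfg a [kmc_config()] object (uses its filter and kinetics
#'   sections).
#' @return list with `mw_low`, `mw_high` (g/mol), `dp_low`, `dp_high`
#'   (units) and `delta_e_th` (kJ/mol).
#' @examples
#' condensation_window(353)$dp_high  # 9
#' @export
condensation_window <- function(T, cfg = kmc_config()) {
  dEth <- compute_threshold(T, cfg$filter$ratio_cutoff, cfg$kinetics$r_gas)
  ec <- cfg$kinetics$e_con
  mw_high <- ec$vertex_mw + dEth / ec$slope_high
  mw_low <- max(ec$vertex_mw - dEth / ec$slope_low, 0)
  list(
    mw_low = mw_low,
    mw_high = mw_high,
    dp_low = 2,
    dp_high = floor(mw_high / cfg$kinetics$mw_g),
    delta_e_th = dEth
  )
}

#' Candidate-reduction statistics of a running simulation
#'
#' Cumulative counts of candidate events (all bonds, all pairs, all
#' S-containing chains) versus the events actually retained by the
#' activation-energy filter, summed over macro steps.
#'
#' @param sim a simulation handle.
#' @return data.frame with one row per event class.
#' @export
filter_stats <- function(sim) {
  ct <- sim_counters(sim_ptr(sim))
  data.frame(
    kind = c("depolymerization", "condensation", "demethoxylation"),
    candidates = c(ct$cand_dep, ct$cand_con, ct$cand_dem),
    retained = c(ct$ret_dep, ct$ret_con, ct$cand_dem),
    stringsAsFactors = FALSE
  )
}
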