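#' Arrhenius rate coefficient
#'
#' `k = A exp(-E * 1000 / (R T))` with `A` in min^-1, `E` in kJ/mol and `T`
#' in K.  The kJ -> J conversion happens here and only here; every rate law
#' in the package goes through this function (or its C++ twin).
#'
#' @param A pre-exponential factor (min^-1).
#' @param E activation energy (kJ/mol).
#' @param T temperature (K).
#' @param r_gas gas constant (J mol^-1 K^-1).
#' @return rate coefficient in min^-1 (underflow clamps to 0).
#' @examples
#' arrhenius_k(9.5e104, 764, 353)  # ~8.3e-9 min^-1
#' @export
arrhenius_k <- function(A, E, T, r_gas = R_GAS) {
  stopifnot(A > 0, E >= 0)
  if (any(T <= 0)) stop("temperature must be positive", call. = FALSE)
  A * exp(-E * 1000 / (r_gas * T))
}

#' Scission activation energy by dyad context
#'
#' Looks up `E_dep` (kJ/mol) for a bond flanked by the given dyad, with
#' linear interpolation between the table's temperature grid points and
#' clamping beyond the ends.  Pure: the same key always yields the same
#' energy.
#'
#' @param dyad one of "GG", "GS", "SG", "SS" (left unit, right unit).
#' @param T temperature (K).
#' @param table energy table (see [default_e_dep_table()]).
#' @return activation energy (kJ/mol).
#' @export
e_dep_lookup <- function(dyad, T, table = default_e_dep_table()) {
  stopifnot(dyad %in% c("GG", "GS", "SG", "SS"))
  sub <- table[table$dyad == dyad, ]
  sub <- sub[order(sub$temperature_K), ]
  if (T <= sub$temperature_K[1]) return(sub$e_dep_kj_mol[1])
  n <- nrow(sub)
  if (T >= sub$temperature_K[n]) return(sub$e_dep_kj_mol[n])
  stats::approx(sub$temperature_K, sub$e_dep_kj_mol, xout = T)$y
}

#' Condensation activation energy as a function of combined molar mass
#'
#' V-shaped function: minimal at `vertex_mw` (972 g/mol by default) and
#' increasing linearly on both sides, so that chain pairs whose combined
#' mass sits near the vertex condense fastest regardless of composition.
#'
#' @param mw combined molar mass of the two chains (g/mol); vectorized.
#' @param e_con parameter list (`vertex_mw`, `e_min`, `slope_low`,
#'   `slope_high`), see [kmc_config()].
#' @return activation energy (kJ/mol).
#' @export
e_con_fun <- function(mw, e_con = default_e_con()) {
  ifelse(mw >= e_con$vertex_mw,
         e_con$e_min + e_con$slope_high * (mw - e_con$vertex_mw),
         e_con$e_min + e_con$slope_low * (e_con$vertex_mw - mw))
}

#' Microscale propensities (reference implementations)
#'
#' Rate laws for the three dissolved-chain reactions.  Scission is first
#' order in the chain's concentration `C = 1/omega`; condensation is second
#' order (one factor of `C` per participating chain); demethoxylation is
#' first order and proportional to the chain's S-unit fraction.  These pure
#' R forms mirror the engine's internal evaluation and serve as its oracle
#' in the test-suite.
#'
#' @param e_dep activation energy of the bond (kJ/mol).
#' @param T liquor temperature (K).
#' @param omega effective volume factor; chain concentration is `1/omega`.
#' @param A pre-exponential factor override (min^-1).
#' @return propensity in min^-1.
#' @export
depolymerization_rate <- function(e_dep, T, omega, A = 4.8e22) {
  arrhenius_k(A, e_dep, T) / omega
}

#' @rdname depolymerization_rate
#' @param mw_i,mw_j molar masses of the two chains (g/mol).
#' @param e_con condensation energy parameters.
#' @export
condensation_rate <- function(mw_i, mw_j, T, omega, A = 2.5e20,
                              e_con = default_e_con()) {
  arrhenius_k(A, e_con_fun(mw_i + mw_j, e_con), T) / omega^2
}

#' @rdname depolymerization_rate
#' @param f_s S-unit fraction of the chain (S count / unit count).
#' @param e_dem demethoxylation activation energy (kJ/mol).
#' @export
demethoxylation_rate <- function(f_s, T, omega, A = 9.5e104, e_dem = 764) {
  stopifnot(f_s >= 0, f_s <= 1)
  arrhenius_k(A, e_dem, T) * f_s / omega
}
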