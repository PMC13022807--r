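#' @useDynLib ligninKMC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_sim <- function(ptr, cfg) {
  structure(list(ptr = ptr, config = cfg), class = "lignin_sim")
}

sim_ptr <- function(sim) {
  if (!inherits(sim, "lignin_sim")) stop("not a lignin_sim object", call. = FALSE)
  sim$ptr
}

#' Initialize a pristine lignin system
#'
#' Generates `n_chains` linear chains in the chip phase.  Chain lengths are
#' drawn as `1 + Poisson(lambda - 1)` with `lambda = target_mn / mu` where
#' `mu` is the expected unit mass at the target S/G ratio, so the population
#' number-average molar mass converges to `target_mn` as `n_chains` grows.
#' Each unit is S with probability `target_sg / (1 + target_sg)`; every bond
#' carries the activation energy of its flanking dyad from the energy
#' library.  The macroscale lignin masses start as `L_c = l_c0`, `L_d = 0`.
#'
#' The returned handle has reference semantics (like a connection or an
#' environment): event operations modify it in place.  Use [sim_copy()] for
#' an independent replica.
#'
#' @param cfg a [kmc_config()]; `cfg$init` holds the population targets.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the run is reproducible.
#' @return a `lignin_sim` handle.
#' @examples
#' sim <- lignin_init(kmc_config(init = list(n_chains = 20)), seed = 1)
#' observables(sim, "chip")
#' @export
lignin_init <- function(cfg = kmc_config(), seed = NULL) {
  stopifnot(inherits(cfg, "kmc_config"))
  if (!is.null(seed)) set.seed(seed)
  ptr <- sim_create(cfg, cfg$init$temperature)
  sim_populate(ptr, as.integer(cfg$init$n_chains), cfg$init$target_mn,
               cfg$init$target_sg)
  new_sim(ptr, cfg)
}

#' Create an empty system (no chains)
#'
#' Used to build bespoke systems chain-by-chain with [add_chain()]; the
#' mass scale is 1, i.e. transfer accumulators are in g/mol-equivalent
#' units.
#'
#' @inheritParams lignin_init
#' @param temperature initial chip and liquor temperature (K).
#' @export
lignin_empty <- function(cfg = kmc_config(), temperature = cfg$init$temperature) {
  stopifnot(inherits(cfg, "kmc_config"))
  new_sim(sim_create(cfg, temperature), cfg)
}

#' Add a chain with an explicit monolignol sequence
#'
#' @param sim a `lignin_sim` handle.
#' @param sequence character string over \{"S", "G"\}, e.g. `"SGS"`.
#' @param phase `"chip"` or `"liquor"`.
#' @return the new chain's id (integer).
#' @export
add_chain <- function(sim, sequence, phase = c("liquor", "chip")) {
  phase <- match.arg(phase)
  sim_add_chain(sim_ptr(sim), sequence, phase)
}

#' Deep-copy a simulation handle
#'
#' @param sim a `lignin_sim` handle.
#' @return an independent `lignin_sim` with identical state.
#' @export
sim_copy <- function(sim) {
  new_sim(sim_clone(sim_ptr(sim)), sim$config)
}

#' Apply a chain-scission event
#'
#' Replaces a liquor-phase chain by its two fragments at the given bond:
#' the left fragment keeps units `1..bond_index`, the right fragment the
#' rest.  Fragment bond energies are contiguous slices of the parent's and
#' total molar mass is conserved exactly.
#'
#' @param sim a `lignin_sim` handle.
#' @param chain_id id of a liquor-phase chain.
#' @param bond_index bond to cleave, 1-based (1 .. units-1).
#' @return integer vector of the two fragment ids (left, right).
#' @export
apply_scission <- function(sim, chain_id, bond_index) {
  sim_apply_scission(sim_ptr(sim), as.integer(chain_id),
                     as.integer(bond_index) - 1L)
}

#' Apply a condensation (chain-merging) event
#'
#' Merges two distinct liquor-phase chains into one (sequence of `i`
#' followed by sequence of `j`); the junction bond energy is looked up from
#' the dyad library like any other bond.
#'
#' @param sim a `lignin_sim` handle.
#' @param chain_i,chain_j ids of two distinct liquor-phase chains.
#' @return the merged chain's id.
#' @export
apply_condensation <- function(sim, chain_i, chain_j) {
  sim_apply_condensation(sim_ptr(sim), as.integer(chain_i), as.integer(chain_j))
}

#' Apply a demethoxylation event (S -> G)
#'
#' Converts one S unit of a liquor-phase chain to G, removing a methoxy
#' group: the chain's molar mass drops by exactly 48.0 g/mol and the
#' energies of the adjacent bonds are re-looked-up for the new dyads.
#'
#' @param sim a `lignin_sim` handle.
#' @param chain_id id of a liquor-phase chain.
#' @param unit_index 1-based index of an S unit.
#' @return the chain id, invisibly.
#' @export
apply_demethoxylation <- function(sim, chain_id, unit_index) {
  sim_apply_demethoxylation(sim_ptr(sim), as.integer(chain_id),
                            as.integer(unit_index) - 1L)
}

#' Move one chain between phases using the transfer accumulators
#'
#' A chain is selected uniformly at random among the source-phase chains
#' whose mass does not exceed the corresponding accumulator; the
#' accumulator is decremented by the moved mass.  With no eligible chain
#' the call is a no-op with a warning.
#'
#' @param sim a `lignin_sim` handle.
#' @param direction `"dissolve"` (chip to liquor) or `"redeposit"`.
#' @return moved chain id, or `0` when no chain was eligible.
#' @export
transfer_chain <- function(sim, direction = c("dissolve", "redeposit")) {
  direction <- match.arg(direction)
  id <- sim_transfer(sim_ptr(sim), direction)
  if (id == 0) {
    warning("no ", if (direction == "dissolve") "chip" else "liquor",
            "-phase chain is eligible for transfer", call. = FALSE)
  }
  id
}

#' Molecular observables of one phase
#'
#' Computed from incrementally maintained aggregates in constant time:
#' `Mn = sum(MW)/n`, `Mw = sum(MW^2)/sum(MW)`, `S/G = total S / total G`.
#' An empty phase yields an error for Mn/Mw; a phase without G units
#' reports an infinite S/G ratio with a warning.
#'
#' @param sim a `lignin_sim` handle.
#' @param phase `"liquor"` or `"chip"`.
#' @return list with `mn`, `mw`, `sg_ratio`, `n_chains`.
#' @export
observables <- function(sim, phase = c("liquor", "chip")) {
  phase <- match.arg(phase)
  out <- sim_observables_cpp(sim_ptr(sim), phase)
  if (out$n_chains == 0) {
    stop("phase '", phase, "' is empty; Mn and Mw are undefined", call. = FALSE)
  }
  if (is.infinite(out$sg_ratio)) {
    warning("phase '", phase, "' contains no G units; S/G ratio is infinite",
            call. = FALSE)
  }
  out
}

#' Molar-mass distribution histogram
#'
#' @param sim a `lignin_sim` handle.
#' @param phase `"liquor"` or `"chip"`.
#' @param bin bin width in g/mol.
#' @return data.frame with `mw_mid`, `count`, `mass_fraction`.
#' @export
mwd_histogram <- function(sim, phase = c("liquor", "chip"),
                          bin = sim$config$run$histogram_bin) {
  phase <- match.arg(phase)
  snap <- chain_snapshot(sim)
  mw <- snap$mw[snap$phase == phase]
  if (length(mw) == 0) {
    return(data.frame(mw_mid = numeric(0), count = numeric(0),
                      mass_fraction = numeric(0)))
  }
  edges <- seq(0, max(mw) + bin, by = bin)
  idx <- findInterval(mw, edges, rightmost.closed = TRUE)
  count <- tabulate(idx, nbins = length(edges) - 1)
  mass <- vapply(seq_along(count), function(i) sum(mw[idx == i]), numeric(1))
  data.frame(mw_mid = (edges[-1] + edges[-length(edges)]) / 2,
             count = count, mass_fraction = mass / sum(mw))
}

#' Snapshot of all chains
#'
#' @param sim a `lignin_sim` handle.
#' @return data.frame with one row per chain: `id`, `phase`, `sequence`,
#'   `mw`, `s_count`, `n_bonds`, `e_low` (lowest scission-site energy at
#'   the current liquor temperature; `NA` for single-unit chains).
#' @export
chain_snapshot <- function(sim) {
  sim_snapshot(sim_ptr(sim))
}

#' Per-bond activation energies of one chain
#'
#' @param sim a `lignin_sim` handle.
#' @param chain_id chain id.
#' @return numeric vector of energies (kJ/mol), one per bond.
#' @export
bond_energies <- function(sim, chain_id) {
  sim_bond_energies(sim_ptr(sim), as.integer(chain_id))
}

#' Registry aggregates (for consistency checking)
#'
#' @param sim a `lignin_sim` handle.
#' @return nested list: per-phase chain count, sum of MW, sum of MW^2,
#'   unit and S-unit totals, plus the running sum of S fractions.
#' @export
registry_aggregates <- function(sim) {
  sim_aggregates(sim_ptr(sim))
}

#' Macro state of the simulation
#'
#' @param sim a `lignin_sim` handle.
#' @return list with temperatures, clock, macroscale lignin masses,
#'   transfer accumulators, current threshold and condensation window.
#' @export
sim_state_r <- function(sim) {
  sim_state(sim_ptr(sim))
}

#' Set a macro state field (tests and scenario setup)
#'
#' @param sim a `lignin_sim` handle.
#' @param ... named scalar fields among `t_c`, `t_f`, `l_c`, `l_d`,
#'   `acc_dissolve`, `acc_redeposit`, `mass_scale`.
#' @export
sim_set_state <- function(sim, ...) {
  vals <- list(...)
  for (nm in names(vals)) sim_set(sim_ptr(sim), nm, as.numeric(vals[[nm]]))
  invisible(sim)
}

#' Serialize chains to JSON-lines
#'
#' One JSON record per chain (`id`, `phase`, `sequence`, `bond_energies`),
#' restorable with [chains_from_jsonl()].
#'
#' @param sim a `lignin_sim` handle.
#' @param path output file.
#' @export
chains_to_jsonl <- function(sim, path) {
  snap <- chain_snapshot(sim)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(snap))) {
    rec <- list(id = snap$id[i], phase = snap$phase[i],
                sequence = snap$sequence[i],
                bond_energies = as.numeric(bond_energies(sim, snap$id[i])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Restore a chain population from JSON-lines
#'
#' @param path file written by [chains_to_jsonl()].
#' @param cfg configuration for the new system.
#' @return a fresh `lignin_sim` holding the stored chains (bond energies
#'   are re-derived from the dyad library, which reproduces the stored
#'   values whenever the same library is used).
#' @export
chains_from_jsonl <- function(path, cfg = kmc_config()) {
  sim <- lignin_empty(cfg)
  for (ln in readLines(path)) {
    rec <- jsonlite::fromJSON(ln)
    add_chain(sim, rec$sequence, rec$phase)
  }
  sim
}

#' @export
print.lignin_sim <- function(x, ...) {
  st <- sim_state(sim_ptr(x))
  ag <- sim_aggregates(sim_ptr(x))
  cat("<lignin_sim> engine:", st$engine,
      "| t =", format(st$clock, digits = 4), "min",
      "| chip:", ag$chip$n_chains, "chains",
      "| liquor:", ag$liquor$n_chains, "chains",
      "| T_f =", format(st$t_f, digits = 5), "K\n")
  invisible(x)
}
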