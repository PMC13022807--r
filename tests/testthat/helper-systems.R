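# Builders for small, fully specified systems used across the suite.

# uniform-energy table (all dyads share one barrier)
flat_e_table <- function(e, temps = c(353, 363)) {
  data.frame(
    dyad = rep(c("GG", "GS", "SG", "SS"), times = length(temps)),
    temperature_K = rep(temps, each = 4),
    e_dep_kj_mol = rep(e, 4 * length(temps)),
    stringsAsFactors = FALSE
  )
}

spread_e_table <- function(e = c(186.5, 194, 201.5, 209), temps = c(353, 363)) {
  data.frame(
    dyad = rep(c("GG", "GS", "SG", "SS"), times = length(temps)),
    temperature_K = rep(temps, each = 4),
    e_dep_kj_mol = rep(e, length(temps)),
    stringsAsFactors = FALSE
  )
}

# a liquor-only toy system with the given sequences
toy_system <- function(sequences, cfg = kmc_config(), phase = "liquor") {
  sim <- lignin_empty(cfg)
  ids <- vapply(sequences, function(s) add_chain(sim, s, phase), integer(1))
  list(sim = sim, ids = ids)
}

# brute-force recomputation of registry aggregates from a snapshot
brute_aggregates <- function(sim, phase) {
  snap <- chain_snapshot(sim)
  snap <- snap[snap$phase == phase, ]
  g_count <- nchar(snap$sequence) - snap$s_count
  list(
    n_chains = nrow(snap),
    sum_mw = sum(snap$mw),
    sum_mw2 = sum(snap$mw^2),
    units = sum(nchar(snap$sequence)),
    s_count = sum(snap$s_count),
    g_count = sum(g_count)
  )
}

expect_aggregates_consistent <- function(sim, tol = 1e-6) {
  ag <- registry_aggregates(sim)
  for (phase in c("chip", "liquor")) {
    bf <- brute_aggregates(sim, phase)
    expect_equal(ag[[phase]]$n_chains, bf$n_chains)
    expect_equal(ag[[phase]]$sum_mw, bf$sum_mw, tolerance = tol)
    expect_equal(ag[[phase]]$sum_mw2, bf$sum_mw2, tolerance = tol)
    expect_equal(ag[[phase]]$units, bf$units)
    expect_equal(ag[[phase]]$s_count, bf$s_count)
  }
}

# random S/G sequence of given length
random_seq <- function(len, p_s = 0.64) {
  paste(ifelse(stats::runif(len) < p_s, "S", "G"), collapse = "")
}
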