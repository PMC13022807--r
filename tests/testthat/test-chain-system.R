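test_that("initializer recovers the target Mn, S/G ratio and mean chain length", {
  cfg <- kmc_config(init = list(n_chains = 5000))
  sim <- lignin_init(cfg, seed = 42)
  obs <- observables(sim, "chip")
  expect_equal(obs$mn, 13000, tolerance = 0.02)
  expect_equal(obs$sg_ratio, 1.76, tolerance = 0.02)
  # expected unit mass (1.76*227.2 + 179.2)/2.76 = 209.81 -> ~62 units/chain
  ag <- registry_aggregates(sim)$chip
  expect_equal(ag$units / ag$n_chains, 13000 / 209.81, tolerance = 0.02)
  # all chains start in the chip phase
  expect_equal(registry_aggregates(sim)$liquor$n_chains, 0)
})

test_that("initializer precision improves with population size", {
  errs <- vapply(c(250, 4000), function(n) {
    reps <- vapply(1:4, function(r) {
      sim <- lignin_init(kmc_config(init = list(n_chains = n)), seed = 100 * n + r)
      observables(sim, "chip")$mn
    }, numeric(1))
    stats::sd(reps)
  }, numeric(1))
  expect_lt(errs[2], errs[1])  # spread shrinks roughly as 1/sqrt(n)
})

test_that("initializer rejects degenerate configurations", {
  expect_error(kmc_config(init = list(n_chains = 0)), "n_chains")
  expect_error(kmc_config(init = list(target_mn = 100)), "target_mn")
})

test_that("single-unit chains carry the exact monomer masses", {
  ts <- toy_system(c("S", "G"))
  snap <- chain_snapshot(ts$sim)
  expect_equal(snap$mw[snap$sequence == "S"], 227.2)
  expect_equal(snap$mw[snap$sequence == "G"], 179.2)
  expect_equal(snap$n_bonds, c(0, 0))
  expect_true(all(is.na(snap$e_low)))
})

test_that("scission splits sequences and bond lists and conserves mass", {
  ts <- toy_system("SGS")
  fr <- apply_scission(ts$sim, ts$ids[1], 1)
  snap <- chain_snapshot(ts$sim)
  expect_setequal(snap$sequence, c("S", "GS"))
  expect_equal(sum(snap$mw), 227.2 + 179.2 + 227.2)  # parent mass
  expect_equal(snap$mw[snap$sequence == "GS"], 406.4)
  # fragment bond lists are contiguous slices of the parent's
  parent_e <- c(e_dep_lookup("SG", 353), e_dep_lookup("GS", 353))
  expect_equal(length(bond_energies(ts$sim, fr[1])), 0)
  expect_equal(bond_energies(ts$sim, fr[2]), parent_e[2])
  # out-of-range bond and chip-phase chains are rejected
  ts2 <- toy_system("SG", phase = "chip")
  expect_error(apply_scission(ts2$sim, ts2$ids[1], 1), "liquor")
  ts3 <- toy_system("SG")
  expect_error(apply_scission(ts3$sim, ts3$ids[1], 5), "range")
})

test_that("condensation merges chains with a library junction bond", {
  ts <- toy_system(c("G", "G"))
  m <- apply_condensation(ts$sim, ts$ids[1], ts$ids[2])
  snap <- chain_snapshot(ts$sim)
  expect_equal(snap$sequence, "GG")
  expect_equal(snap$mw, 358.4)
  expect_equal(bond_energies(ts$sim, m), e_dep_lookup("GG", 353))
  expect_error(apply_condensation(ts$sim, m, m), "distinct")
})

test_that("merging then cleaving the junction restores the original chains", {
  ts <- toy_system(c("SGS", "GSG"))
  snap0 <- chain_snapshot(ts$sim)
  m <- apply_condensation(ts$sim, ts$ids[1], ts$ids[2])
  # merged chain: sequence i then j, bond count len(i)+len(j)-1
  snap1 <- chain_snapshot(ts$sim)
  expect_equal(snap1$sequence, "SGSGSG")
  expect_equal(snap1$n_bonds, 5)
  fr <- apply_scission(ts$sim, m, 3)  # junction bond of two trimers
  snap2 <- chain_snapshot(ts$sim)
  expect_setequal(snap2$mw, snap0$mw)
  expect_setequal(snap2$sequence, snap0$sequence)
})

test_that("demethoxylation converts S to G, shifting mass by exactly -48", {
  ts <- toy_system("S")
  apply_demethoxylation(ts$sim, ts$ids[1], 1)
  snap <- chain_snapshot(ts$sim)
  expect_equal(snap$sequence, "G")
  expect_equal(snap$mw, 227.2 - 48.0)
  expect_error(apply_demethoxylation(ts$sim, ts$ids[1], 1), "S unit")
  # adjacent bond energies are re-looked-up for the new dyads
  ts2 <- toy_system("GSG")
  apply_demethoxylation(ts2$sim, ts2$ids[1], 2)
  expect_equal(bond_energies(ts2$sim, ts2$ids[1]),
               rep(e_dep_lookup("GG", 353), 2))
})

test_that("observables match their definitions on a two-chain toy", {
  ts <- toy_system(c("GSG", "S"))  # masses 585.6 and 227.2
  obs <- observables(ts$sim, "liquor")
  expect_equal(obs$mn, (585.6 + 227.2) / 2)
  expect_equal(obs$mw, (585.6^2 + 227.2^2) / (585.6 + 227.2))
  expect_equal(obs$sg_ratio, 2 / 2)
  # degenerate single-chain population: Mn = Mw = chain MW
  ts1 <- toy_system("SSG")
  obs1 <- observables(ts1$sim, "liquor")
  expect_equal(obs1$mn, obs1$mw)
  # [S,S,G] pool -> S/G = 2
  expect_equal(obs1$sg_ratio, 2)
  # empty phase errors; all-S phase flags infinite ratio
  expect_error(observables(ts1$sim, "chip"), "empty")
  tsS <- toy_system("SS")
  expect_warning(oS <- observables(tsS$sim, "liquor"), "no G units")
  expect_identical(oS$sg_ratio, Inf)
})

test_that("transfer moves a mass-eligible chain and decrements the accumulator", {
  cfg <- kmc_config()
  sim <- lignin_empty(cfg)
  add_chain(sim, "GG", "chip")           # 358.4
  heavy <- add_chain(sim, "SSG", "chip") # 633.6
  sim_set_state(sim, acc_dissolve = 500)
  id <- transfer_chain(sim, "dissolve")
  snap <- chain_snapshot(sim)
  expect_equal(snap$phase[snap$sequence == "GG"], "liquor")   # only eligible chain
  expect_equal(snap$phase[snap$sequence == "SSG"], "chip")
  expect_equal(sim_state_r(sim)$acc_dissolve, 500 - 358.4)
  # accumulator below every chain mass: warning + no-op
  expect_warning(id2 <- transfer_chain(sim, "dissolve"), "eligible")
  expect_equal(id2, 0)
  # total lignin mass unchanged by transfer
  ag <- registry_aggregates(sim)
  expect_equal(ag$chip$sum_mw + ag$liquor$sum_mw, 358.4 + 633.6)
})

test_that("aggregates stay consistent through random scission sequences", {
  set.seed(9)
  cfg <- kmc_config()
  sim <- lignin_empty(cfg)
  for (i in 1:12) add_chain(sim, random_seq(sample(5:25, 1)), "liquor")
  for (i in 1:10) {
    snap <- chain_snapshot(sim)
    cand <- snap[snap$n_bonds > 0, ]
    row <- cand[sample(nrow(cand), 1), ]
    apply_scission(sim, row$id, sample(row$n_bonds, 1))
  }
  expect_aggregates_consistent(sim)
})

test_that("chain populations round-trip through JSON-lines", {
  set.seed(4)
  ts <- toy_system(c("SGS", "GG", random_seq(15)))
  add_chain(ts$sim, "SSGG", "chip")
  path <- tempfile(fileext = ".jsonl")
  chains_to_jsonl(ts$sim, path)
  sim2 <- chains_from_jsonl(path, ts$sim$config)
  s1 <- chain_snapshot(ts$sim)
  s2 <- chain_snapshot(sim2)
  expect_setequal(paste(s1$phase, s1$sequence), paste(s2$phase, s2$sequence))
  expect_equal(sort(s1$mw), sort(s2$mw))
})

test_that("molar-mass histogram covers the population and normalizes", {
  set.seed(11)
  sim <- lignin_init(kmc_config(init = list(n_chains = 200)), seed = 11)
  h <- mwd_histogram(sim, "chip", bin = 1000)
  expect_equal(sum(h$count), 200)
  expect_equal(sum(h$mass_fraction), 1)
})
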