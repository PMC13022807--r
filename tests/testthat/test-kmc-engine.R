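test_that("full catalog enumerates the combinatorially expected events", {
  ts <- toy_system(c("SGS", "GS", "G"))  # lengths 3, 2, 1
  cat <- build_catalog(ts$sim, "full")
  expect_equal(sum(cat$kind == "depolymerization"), 2 + 1 + 0)
  expect_equal(sum(cat$kind == "condensation"), choose(3, 2))
  expect_equal(sum(cat$kind == "demethoxylation"), 2)  # G monomer has no S
  # r_tot attribute equals independent summation
  expect_equal(attr(cat, "r_tot"), sum(cat$propensity))
})

test_that("enumerated catalog total equals the engine's aggregate r_tot", {
  set.seed(21)
  cfg <- kmc_config(engine = "full")
  sim <- lignin_empty(cfg)
  for (i in 1:25) add_chain(sim, random_seq(sample(1:12, 1)), "liquor")
  cat_full <- build_catalog(sim, "full")
  expect_equal(ligninKMC:::sim_rtot(sim$ptr), attr(cat_full, "r_tot"),
               tolerance = 1e-10)
  # same check for the filtered engine against the filtered enumeration
  cfg_f <- kmc_config(engine = "filtered")
  sim_f <- lignin_empty(cfg_f)
  set.seed(21)
  for (i in 1:25) add_chain(sim_f, random_seq(sample(1:12, 1)), "liquor")
  cat_filt <- build_catalog(sim_f, "filtered")
  expect_equal(ligninKMC:::sim_rtot(sim_f$ptr), attr(cat_filt, "r_tot"),
               tolerance = 1e-10)
  # empty liquor gives an empty catalog
  empty <- lignin_empty(cfg)
  expect_equal(nrow(build_catalog(empty)), 0)
})

test_that("gillespie_step draws the closed-form waiting time and selects by propensity", {
  cat <- data.frame(kind = c("a", "b"), propensity = c(1.5, 0.5))
  # r_tot = 2, xi = exp(-1) -> delta_t = 0.5
  st <- gillespie_step(cat, u = c(exp(-1), 0.9))
  expect_equal(st$delta_t, 0.5)
  expect_equal(st$index, 2)  # 0.9 * 2 = 1.8 > 1.5 -> second event
  st2 <- gillespie_step(cat, u = c(0.5, 0.2))
  expect_equal(st2$index, 1)
  # r_tot = 0 signals no microscale activity
  expect_null(gillespie_step(data.frame(propensity = numeric(0))))
})

test_that("selection frequencies follow the 3:1 propensity ratio", {
  cat <- data.frame(propensity = c(3, 1))
  set.seed(31)
  picks <- vapply(1:10000, function(i) gillespie_step(cat)$index, numeric(1))
  tab <- table(factor(picks, levels = 1:2))
  chi <- suppressWarnings(stats::chisq.test(tab, p = c(0.75, 0.25)))
  expect_gt(chi$p.value, 1e-3)
  # mean waiting time ~ 1/r_tot within 3 standard errors
  set.seed(32)
  dts <- vapply(1:10000, function(i) gillespie_step(cat)$delta_t, numeric(1))
  se <- stats::sd(dts) / sqrt(length(dts))
  expect_lt(abs(mean(dts) - 1 / 4), 3 * se)
})

test_that("first-order decay of identical bonds matches the exponential law", {
  # 300 GG dimers, single barrier, condensation/demethoxylation switched
  # off by energetics: a pure death process with known rate
  cfg <- kmc_config(
    kinetics = list(omega = 6e-7, e_dep_table = flat_e_table(200),
                    a_con = 1e-300, a_dem = 1e-300)
  )
  sim <- lignin_empty(cfg)
  for (i in 1:300) add_chain(sim, "GG", "liquor")
  k <- arrhenius_k(4.8e22, 200, 353) / 6e-7  # per-bond propensity
  set.seed(17)
  elapsed <- 0
  for (i in 1:8) {
    run_micro_interval(sim, 0.25)
    elapsed <- elapsed + 0.25
  }
  snap <- chain_snapshot(sim)
  surv <- sum(snap$n_bonds)  # unbroken dimers
  p <- exp(-k * elapsed)
  se <- sqrt(300 * p * (1 - p))
  expect_lt(abs(surv - 300 * p), 4 * se + 1)
})

test_that("a vanishing total rate executes no events within the interval", {
  cfg <- kmc_config(kinetics = list(e_dep_table = flat_e_table(400),
                                    a_con = 1e-300, a_dem = 1e-300))
  sim <- lignin_empty(cfg)
  for (i in 1:5) add_chain(sim, "GG", "liquor")
  set.seed(3)
  n <- run_micro_interval(sim, 5e-4)
  expect_equal(n, 0)
  expect_equal(nrow(chain_snapshot(sim)), 5)
})

test_that("event sequences are reproducible under a fixed seed", {
  mk <- function() {
    cfg <- kmc_config(init = list(n_chains = 40))
    sim <- lignin_init(cfg, seed = 77)
    event_log_enable(sim)
    run_fractionation(sim, 3, t_ext = 363, record_every = 3)
    event_log(sim)
  }
  la <- mk()
  lb <- mk()
  expect_gt(nrow(la), 10)
  expect_identical(la, lb)
})

test_that("executing an event always changes the state", {
  set.seed(41)
  cfg <- kmc_config(kinetics = list(omega = 1e-6))
  sim <- lignin_empty(cfg)
  for (i in 1:20) add_chain(sim, random_seq(sample(2:8, 1)), "liquor")
  before <- chain_snapshot(sim)
  fingerprint <- function(s) paste(sort(paste(s$sequence, s$phase)), collapse = "|")
  for (i in 1:15) {
    f0 <- fingerprint(chain_snapshot(sim))
    n <- run_micro_interval(sim, 0.5)
    if (n > 0) expect_false(identical(fingerprint(chain_snapshot(sim)), f0))
  }
})

test_that("aggregates survive a long mixed event sequence (>=1000 events)", {
  cfg <- kmc_config(init = list(n_chains = 120))
  sim <- lignin_init(cfg, seed = 19)
  run_fractionation(sim, 15, t_ext = c(358, 363), times = c(0, 5), record_every = 15)
  ct <- ligninKMC:::sim_counters(sim$ptr)
  expect_gt(ct$ev_dep + ct$ev_con + ct$ev_dem, 1000)
  expect_aggregates_consistent(sim)
  # cached e_low equals the minimum bond energy for every chain
  snap <- chain_snapshot(sim)
  with_bonds <- snap[snap$n_bonds > 0, ]
  pick <- with_bonds[sample(nrow(with_bonds), min(50, nrow(with_bonds))), ]
  for (i in seq_len(nrow(pick))) {
    expect_equal(pick$e_low[i], min(bond_energies(sim, pick$id[i])))
  }
})

test_that("the mass ledger moves only through demethoxylation", {
  cfg <- kmc_config(init = list(n_chains = 60))
  sim <- lignin_init(cfg, seed = 23)
  ag0 <- registry_aggregates(sim)
  total0 <- ag0$chip$sum_mw + ag0$liquor$sum_mw
  run_fractionation(sim, 10, t_ext = 363, record_every = 10)
  ct <- ligninKMC:::sim_counters(sim$ptr)
  ag1 <- registry_aggregates(sim)
  total1 <- ag1$chip$sum_mw + ag1$liquor$sum_mw
  expect_gt(ct$ev_dem, 0)
  expect_equal(total0 - total1, 48 * ct$ev_dem, tolerance = 1e-8)
})
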