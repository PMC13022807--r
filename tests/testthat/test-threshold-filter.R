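test_that("threshold formula gives R*T*ln(1000) in kJ/mol and adapts with T", {
  expect_equal(compute_threshold(353, 1000), 20.27, tolerance = 1e-3)
  expect_equal(compute_threshold(363, 1000), 20.85, tolerance = 1e-3)
  # strictly increasing in temperature
  Ts <- seq(340, 370, by = 2)
  expect_true(all(diff(compute_threshold(Ts, 1000)) > 0))
  expect_error(compute_threshold(353, 1), "ratio_cutoff")
  expect_error(compute_threshold(-3, 1000), "temperature")
})

test_that("scission-site filter keeps bonds within the per-chain margin", {
  dEth <- compute_threshold(353, 1000)
  expect_equal(filter_bond_sites(c(100, 112, 121), dEth), c(1L, 2L))
  # all equal energies: everything retained
  expect_equal(filter_bond_sites(rep(150, 5), dEth), 1:5)
  # the minimum-energy bond is always retained
  set.seed(13)
  for (i in 1:50) {
    e <- stats::runif(sample(1:12, 1), 150, 260)
    keep <- filter_bond_sites(e, dEth)
    expect_true(which.min(e) %in% keep)
  }
})

test_that("condensation window matches the printed 353 K anchors", {
  w <- condensation_window(353)
  expect_equal(w$mw_high, 1672.33, tolerance = 1e-4)
  expect_equal(w$dp_high, 9)
  expect_equal(w$dp_low, 2)
  # two all-G pentamers (1792 g/mol combined) fall outside; G+G inside
  expect_gt(2 * 5 * 179.2, w$mw_high)
  expect_true(358.4 >= w$mw_low && 358.4 <= w$mw_high)
  # the window widens with temperature
  w2 <- condensation_window(363)
  expect_gt(w2$mw_high, w$mw_high)
})

test_that("filtered catalog equals a brute-force filter of the full catalog", {
  set.seed(29)
  cfg <- kmc_config()
  sim <- lignin_empty(cfg)
  for (i in 1:50) add_chain(sim, random_seq(sample(1:14, 1)), "liquor")
  full <- build_catalog(sim, "full")
  filt <- build_catalog(sim, "filtered")
  st <- sim_state_r(sim)
  snap <- chain_snapshot(sim)
  # brute-force reimplementation of both filter rules over the full catalog
  keep <- logical(nrow(full))
  for (i in seq_len(nrow(full))) {
    ev <- full[i, ]
    if (ev$kind == "depolymerization") {
      keep[i] <- ev$energy <= snap$e_low[snap$id == ev$chain_i] + st$delta_e_th
    } else if (ev$kind == "condensation") {
      mw_sum <- snap$mw[snap$id == ev$chain_i] + snap$mw[snap$id == ev$site_or_j]
      keep[i] <- mw_sum >= st$mw_low && mw_sum <= st$mw_high
    } else {
      keep[i] <- TRUE  # demethoxylation is never filtered
    }
  }
  expect_equal(nrow(filt), sum(keep))
  expect_equal(sort(filt$propensity), sort(full$propensity[keep]), tolerance = 1e-12)
  # subset-sum inequality
  expect_lte(attr(filt, "r_tot"), attr(full, "r_tot"))
})

test_that("every excluded scission coefficient is >1000x below its chain's fastest", {
  set.seed(37)
  cfg <- kmc_config()
  sim <- lignin_empty(cfg)
  for (i in 1:60) add_chain(sim, random_seq(sample(2:20, 1)), "liquor")
  full <- build_catalog(sim, "full")
  filt <- build_catalog(sim, "filtered")
  dep_full <- full[full$kind == "depolymerization", ]
  key <- function(d) paste(d$chain_i, d$site_or_j)
  excluded <- dep_full[!key(dep_full) %in%
                         key(filt[filt$kind == "depolymerization", ]), ]
  expect_gt(nrow(excluded), 0)  # the filter actually bites on this system
  for (cid in unique(excluded$chain_i)) {
    k_max <- max(dep_full$propensity[dep_full$chain_i == cid])
    expect_true(all(excluded$propensity[excluded$chain_i == cid] <
                      k_max / 1000 * (1 + 1e-9)))
  }
  # excluded propensity mass is a negligible fraction of the total
  expect_lt(sum(excluded$propensity) / attr(full, "r_tot"), 1e-2)
})

test_that("filtered and full engines are identical when the filter cannot bite", {
  # narrow energy spread (6 kJ/mol < threshold) and short chains (any pair
  # within the window): the filter provably retains every event, and both
  # engines must then produce bit-identical trajectories under one seed
  run_engine <- function(engine) {
    # condensation suppressed energetically: merged chains could outgrow
    # the combined-mass window, which would make the filter active
    cfg <- kmc_config(
      engine = engine,
      kinetics = list(omega = 2e-8, a_con = 1e-300,
                      e_dep_table = spread_e_table(c(200, 202, 204, 206)))
    )
    sim <- lignin_empty(cfg)
    set.seed(55)
    for (i in 1:40) add_chain(sim, random_seq(sample(1:3, 1)), "liquor")
    event_log_enable(sim)
    set.seed(56)
    for (i in 1:20) run_micro_interval(sim, 0.1)
    list(log = event_log(sim), snap = chain_snapshot(sim))
  }
  a <- run_engine("full")
  b <- run_engine("filtered")
  expect_gt(nrow(a$log), 20)
  expect_identical(a$log, b$log)
  expect_identical(a$snap, b$snap)
})

test_that("filtered and full engines agree in distribution when the filter is active", {
  # 200-chain systems run for 30 min under both engines; the final
  # molar-mass distributions must be statistically indistinguishable
  final_mw <- function(engine, seed) {
    cfg <- kmc_config(engine = engine, init = list(n_chains = 200))
    sim <- lignin_init(cfg, seed = seed)
    run_fractionation(sim, 30, t_ext = c(358, 363, 363, 358, 353, 353),
                      times = seq(0, 25, 5), record_every = 30)
    snap <- chain_snapshot(sim)
    mw <- snap$mw[snap$phase == "liquor"]
    sample(mw, min(150, length(mw)))  # equal weight per replicate
  }
  mw_f <- unlist(lapply(1:20, function(r) final_mw("filtered", 700 + r)))
  mw_g <- unlist(lapply(1:20, function(r) final_mw("full", 900 + r)))
  ks <- suppressWarnings(stats::ks.test(mw_f, mw_g))
  expect_gt(ks$p.value, 0.01)
  # and the filter did prune candidates in the filtered runs
  cfg <- kmc_config(init = list(n_chains = 200))
  sim <- lignin_init(cfg, seed = 1234)
  run_fractionation(sim, 10, t_ext = 363, record_every = 10)
  fs <- filter_stats(sim)
  expect_lt(fs$retained[fs$kind == "condensation"],
            fs$candidates[fs$kind == "condensation"])
  expect_lt(fs$retained[fs$kind == "depolymerization"],
            fs$candidates[fs$kind == "depolymerization"])
})
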