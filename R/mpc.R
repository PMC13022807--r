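#' Define the control problem
#'
#' Shrinking-horizon MPC with terminal objective
#' `sum_p w_p (X_p(t_N) - X_p,sp)^2` over the two controlled outputs
#' (liquor weight-average molar mass and S/G ratio), subject to jacket
#' temperature bounds, flow bounds and a per-interval temperature ramp
#' limit.  The default weights `1 / sp^2` normalize both outputs to
#' relative deviations.
#'
#' @param cfg a [kmc_config()]; the `mpc` section supplies defaults.
#' @param weights length-2 numeric (Mw weight, S/G weight).
#' @return object of class `control_problem`.
#' @export
control_problem <- function(cfg = kmc_config(),
                            weights = c(1 / cfg$mpc$mw_sp^2, 1 / cfg$mpc$sg_sp^2)) {
  p <- cfg$mpc
  structure(list(
    mw_sp = p$mw_sp, sg_sp = p$sg_sp, weights = weights,
    horizon = p$horizon, interval = p$interval_min,
    t_min = p$t_min, t_max = p$t_max,
    f_min = p$f_min, f_max = p$f_max,
    ramp = p$ramp_k, grid_step = p$temp_grid_step,
    flow_levels = p$flow_levels,
    n_rep = p$n_rep, model_chains = p$model_chains
  ), class = "control_problem")
}

#' Terminal MPC objective
#'
#' @param predicted length-2 numeric: predicted terminal (Mw, S/G).
#' @param problem a [control_problem()].
#' @return scalar objective (weighted sum of squared terminal deviations);
#'   `Inf` when a prediction is missing.
#' @export
mpc_objective <- function(predicted, problem) {
  if (any(!is.finite(predicted))) return(Inf)
  sp <- c(problem$mw_sp, problem$sg_sp)
  sum(problem$weights * (predicted - sp)^2)
}

#' Enumerate ramp- and box-feasible input sequences
#'
#' Move-blocked temperature sequences with two degrees of freedom: the
#' first move (a grid step in `{-ramp, ..., 0, ..., +ramp}` at resolution
#' `grid_step`) and a terminal level on the `[t_min, t_max]` lattice; the
#' remaining intervals ramp from the first value toward the terminal level
#' at the maximum admissible rate and hold once reached.  This family
#' contains heat-then-cool and cool-then-reheat shapes with a small
#' candidate count, and receding-horizon re-planning recovers more general
#' profiles.  Every value is clamped to the box, which keeps each move
#' within the ramp limit; each temperature sequence is paired with every
#' constant flow level.
#'
#' @param current_t currently applied jacket temperature (K).
#' @param n_intervals remaining horizon length.
#' @param problem a [control_problem()].
#' @return list of candidates, each `list(t_seq, flow)` with `t_seq` of
#'   length `n_intervals`.
#' @export
feasible_sequences <- function(current_t, n_intervals, problem) {
  stopifnot(n_intervals >= 1)
  clamp <- function(x) min(max(x, problem$t_min), problem$t_max)
  # hot-first enumeration: both outputs are non-increasing in time, so an
  # undershoot cannot be corrected while an overshoot can be braked; among
  # near-tied candidates the deterministic argmin then prefers early action
  moves <- seq(problem$ramp, -problem$ramp, by = -problem$grid_step)
  tails <- seq(problem$t_max, problem$t_min, by = -problem$grid_step)
  seqs <- list()
  seen <- character(0)
  push <- function(t_seq) {
    key <- paste(t_seq, collapse = ",")
    if (!key %in% seen) {
      seen <<- c(seen, key)
      seqs[[length(seqs) + 1]] <<- t_seq
    }
  }
  # family A: one free move, then maximum-rate ramp to a terminal level
  for (mv in moves) {
    t1 <- clamp(current_t + mv)
    for (tail in tails) {
      t_seq <- numeric(n_intervals)
      t_seq[1] <- t1
      if (n_intervals > 1) {
        for (k in 2:n_intervals) {
          dv <- tail - t_seq[k - 1]
          t_seq[k] <- clamp(t_seq[k - 1] + sign(dv) * min(abs(dv), problem$ramp))
        }
      }
      push(t_seq)
    }
  }
  # family B: ramp up to the hot bound, hold for h intervals, then ramp
  # down to a terminal level (the heat-then-cool shapes that drive both
  # outputs down early and brake before overshoot)
  for (h in 0:(n_intervals - 1)) {
    for (tail in tails) {
      t_seq <- numeric(n_intervals)
      t_prev <- current_t
      arrived <- FALSE
      hold_left <- h
      for (k in seq_len(n_intervals)) {
        if (!arrived) {
          t_prev <- clamp(t_prev + problem$ramp)
          if (t_prev >= problem$t_max) arrived <- TRUE
        } else if (hold_left > 0) {
          hold_left <- hold_left - 1
        } else {
          dv <- tail - t_prev
          t_prev <- clamp(t_prev + sign(dv) * min(abs(dv), problem$ramp))
        }
        t_seq[k] <- t_prev
      }
      push(t_seq)
    }
  }
  cands <- list()
  for (ts in seqs) {
    for (fl in problem$flow_levels) {
      cands[[length(cands) + 1]] <- list(t_seq = ts, flow = fl)
    }
  }
  cands
}

#' Check one input sequence against the constraints
#'
#' @param t_seq jacket temperature sequence (K).
#' @param current_t temperature applied before the sequence starts.
#' @param problem a [control_problem()].
#' @return `TRUE` when all box and ramp constraints hold.
#' @export
sequence_feasible <- function(t_seq, current_t, problem) {
  all(t_seq >= problem$t_min) && all(t_seq <= problem$t_max) &&
    all(abs(diff(c(current_t, t_seq))) <= problem$ramp + 1e-9)
}

rollout_terminal <- function(model, t_seq, flow, interval, seed) {
  rep_sim <- sim_copy(model)
  set.seed(seed)
  n <- length(t_seq)
  ts <- run_fractionation(rep_sim, duration = n * interval,
                          t_ext = t_seq, mdot_ext = rep(flow, n),
                          times = (seq_len(n) - 1) * interval,
                          record_every = n * interval)
  last <- ts[nrow(ts), ]
  c(mw = last$mw, sg = last$sg_ratio)
}

#' Solve one MPC step by grid search over feasible sequences
#'
#' Every candidate sequence is evaluated on state-matched reduced replicas
#' of the plant: each replicate seed draws its own down-sampled copy of
#' the current plant state (`model_chains` chains) together with its own
#' output-bias correction (the measured-vs-replica discrepancy at the
#' current time), so sub-sampling noise averages out across replicates
#' instead of propagating into every prediction.  Common random numbers
#' (the same replicate seeds for every candidate) make the returned move a
#' deterministic function of the plant state.  A candidate's score is its
#' expected terminal cost over replicates, which charges plans for their
#' terminal variance; a second search stage re-scores the short-listed
#' leaders with additional independent replicates before committing (the
#' plain argmin over many noisy means is biased optimistic).
#'
#' @param plant a `lignin_sim` whose current state anchors the internal
#'   model (not modified).
#' @param problem a [control_problem()].
#' @param current_t currently applied jacket temperature (K).
#' @param n_intervals remaining horizon length.
#' @param seeds integer vector of replicate seeds (common random numbers).
#' @param model_chains population of each reduced replica.
#' @param incumbent optional `list(t_seq, flow)` (typically the previous
#'   plan shifted by one interval): it joins the candidate set and is kept
#'   unless a challenger beats its objective by more than `hysteresis`
#'   (relative), which suppresses noise-driven plan churn between steps.
#' @param hysteresis relative improvement a challenger must show.
#' @return list: `t_ext` and `flow` (first move of the argmin sequence),
#'   `t_seq`, `objective`, and the per-candidate objective table.
#' @export
solve_mpc_step <- function(plant, problem, current_t, n_intervals,
                           seeds, model_chains = problem$model_chains,
                           incumbent = NULL, hysteresis = 0.1) {
  cands <- feasible_sequences(current_t, n_intervals, problem)
  inc_idx <- 0L
  if (!is.null(incumbent) &&
      length(incumbent$t_seq) == n_intervals &&
      sequence_feasible(incumbent$t_seq, current_t, problem)) {
    cands <- c(list(incumbent), cands)
    inc_idx <- 1L
  }
  if (length(cands) == 0) {
    warning("no feasible input sequence; holding previous input", call. = FALSE)
    return(list(t_ext = current_t, flow = problem$flow_levels[1],
                t_seq = rep(current_t, n_intervals), objective = NA_real_,
                table = NULL))
  }
  meas <- measure_outputs(plant)
  replicas <- new.env(parent = emptyenv())
  get_replica <- function(s) {
    key <- as.character(s)
    if (is.null(replicas[[key]])) {
      set.seed(s + 31L)
      model <- new_sim(sim_reduce(sim_ptr(plant), as.integer(model_chains)),
                       plant$config)
      out <- measure_outputs(model)
      corr <- list(mw = 1, sg = 0)
      if (all(is.finite(meas)) && all(is.finite(out)) && out[["mw"]] > 0) {
        corr <- list(mw = meas[["mw"]] / out[["mw"]],
                     sg = meas[["sg"]] - out[["sg"]])
      }
      replicas[[key]] <- list(sim = model, corr = corr)
    }
    replicas[[key]]
  }
  evaluate <- function(cand, seed_set) {
    vapply(seed_set, function(s) {
      rep <- get_replica(s)
      p <- rollout_terminal(rep$sim, cand$t_seq, cand$flow, problem$interval, s)
      c(p[[1]] * rep$corr$mw, p[[2]] + rep$corr$sg)
    }, numeric(2))
  }
  score <- function(preds) {
    # expected cost over replicates (not cost of the mean prediction):
    # plans with a wide terminal spread are charged for their variance
    mean(apply(preds, 2, mpc_objective, problem = problem))
  }
  stage1 <- lapply(cands, evaluate, seed_set = seeds)
  objs <- vapply(stage1, score, numeric(1))
  # two-stage selection against the winner's curse: the argmin over many
  # noisy rollout means is biased optimistic, so the short-listed leaders
  # are re-scored with additional independent replicates before committing
  top <- order(objs)[seq_len(min(12L, length(cands)))]
  if (inc_idx > 0 && !(inc_idx %in% top)) top <- c(inc_idx, top)
  seeds2 <- max(seeds) + 7777L + seq_len(2L * length(seeds))
  for (ci in top) {
    objs[ci] <- score(cbind(stage1[[ci]], evaluate(cands[[ci]], seeds2)))
  }
  best <- top[which.min(objs[top])]
  if (inc_idx > 0 && best != inc_idx &&
      is.finite(objs[inc_idx]) &&
      objs[best] > (1 - hysteresis) * objs[inc_idx]) {
    best <- inc_idx
  }
  cand <- cands[[best]]
  tab <- data.frame(
    candidate = seq_along(cands),
    t_first = vapply(cands, function(c) c$t_seq[1], numeric(1)),
    flow = vapply(cands, function(c) c$flow, numeric(1)),
    objective = objs,
    refined = seq_along(cands) %in% top
  )
  list(t_ext = cand$t_seq[1], flow = cand$flow, t_seq = cand$t_seq,
       objective = objs[best], table = tab)
}

measure_outputs <- function(sim) {
  ag <- sim_aggregates(sim_ptr(sim))$liquor
  if (ag$n_chains == 0) return(c(mw = NA_real_, sg = NA_real_))
  g <- ag$units - ag$s_count
  c(mw = ag$sum_mw2 / ag$sum_mw,
    sg = if (g > 0) ag$s_count / g else Inf)
}

#' Run the closed control loop
#'
#' Every `interval` minutes the plant's liquor Mw and S/G are measured,
#' one MPC step is solved on the internal model (a reduced-population
#' replica propagated in parallel under the applied inputs, with additive
#' output bias correction), and the first move is applied to the plant.
#'
#' @param plant a `lignin_sim` used as the virtual experiment (modified in
#'   place).
#' @param problem a [control_problem()].
#' @param duration total run length (min).
#' @param seed integer master seed: derives the plant stream, the model
#'   stream and the common-random-number rollout seeds.
#' @param verbose print per-interval progress.
#' @return object of class `control_trace`: per-interval applied inputs
#'   and measurements (`$trace`), final outputs and relative errors
#'   (`$final`), and a constraint audit (`$feasible`).
#' @export
run_closed_loop <- function(plant, problem = control_problem(plant$config),
                            duration = 30, seed = 1, verbose = FALSE) {
  cfg <- plant$config
  n_int <- ceiling(duration / problem$interval)
  t_applied <- cfg$run$jacket_t_ext
  flow_applied <- cfg$run$jacket_mdot
  # common random numbers held fixed over the whole run: candidate
  # comparisons stay consistent from one control step to the next
  seeds <- seed + 3000L + seq_len(problem$n_rep)
  rows <- list()
  prev_plan <- list(t_seq = numeric(0), flow = NA_real_)
  for (k in seq_len(n_int)) {
    remaining <- n_int - k + 1
    # the replica population grows as the horizon shrinks: late rollouts
    # are short, so prediction precision is bought where the terminal
    # decision is made
    target <- as.integer(ceiling(problem$model_chains * n_int / remaining))
    incumbent <- NULL
    if (k > 1 && length(prev_plan$t_seq) > 1) {
      incumbent <- list(t_seq = prev_plan$t_seq[-1], flow = prev_plan$flow)
    }
    sol <- solve_mpc_step(plant, problem, t_applied, remaining,
                          seeds + 100L * k, model_chains = target,
                          incumbent = incumbent)
    prev_plan <- list(t_seq = sol$t_seq, flow = sol$flow)
    t_applied <- sol$t_ext
    flow_applied <- sol$flow
    set.seed(seed + 1000L + k)
    run_fractionation(plant, problem$interval, t_ext = t_applied,
                      mdot_ext = flow_applied, record_every = problem$interval)
    out <- measure_outputs(plant)
    st <- sim_state(sim_ptr(plant))
    rows[[k]] <- data.frame(
      interval = k, t_min = k * problem$interval,
      t_ext = t_applied, mdot_ext = flow_applied,
      mw_meas = out[["mw"]], sg_meas = out[["sg"]],
      t_f = st$t_f, objective = sol$objective
    )
    if (verbose) {
      message(sprintf("t=%4.0f min  T_ext=%5.1f K  flow=%5.1f  Mw=%8.1f  S/G=%6.3f",
                      k * problem$interval, t_applied, flow_applied,
                      out[["mw"]], out[["sg"]]))
    }
  }
  trace <- do.call(rbind, rows)
  final <- measure_outputs(plant)
  errs <- c(
    mw = abs(final[["mw"]] - problem$mw_sp) / problem$mw_sp,
    sg = abs(final[["sg"]] - problem$sg_sp) / problem$sg_sp
  )
  feas <- sequence_feasible(trace$t_ext, cfg$run$jacket_t_ext, problem) &&
    all(trace$mdot_ext >= problem$f_min & trace$mdot_ext <= problem$f_max)
  structure(list(trace = trace,
                 final = list(mw = final[["mw"]], sg = final[["sg"]],
                              rel_error = errs),
                 feasible = feas),
            class = "control_trace")
}

#' @export
print.control_trace <- function(x, ...) {
  cat("<control_trace>", nrow(x$trace), "intervals | final Mw =",
      format(x$final$mw, digits = 6), "g/mol | final S/G =",
      format(x$final$sg, digits = 4), "| rel. errors:",
      paste(sprintf("%.2f%%", 100 * x$final$rel_error), collapse = ", "),
      "| inputs feasible:", x$feasible, "\n")
  invisible(x)
}
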