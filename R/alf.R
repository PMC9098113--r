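# Adaptive landscape flattening: iteratively estimate fixed per-substituent
# biases that equalize end-state sampling. After each short run the biases
# are updated by the population-matching increment
# db_i = -kT ln(p_i / p_ref), with an additive pseudocount of 1 on the raw
# end-state counts so zero-visit iterations stay finite. The schedule
# mirrors the field's practice: many short runs to find the landscape,
# fewer long runs to refine it, then a validation run.

# per-site marginal end-state counts of a trajectory (lambda >= cutoff)
marginal_counts <- function(traj, cutoff) {
  idx <- traj$index
  lapply(stats::setNames(unique(idx$site), unique(idx$site)), function(sn) {
    cols <- which(idx$site == sn)
    stats::setNames(colSums(traj$lambda[, cols, drop = FALSE] >= cutoff),
                    idx$substituent[cols])
  })
}

#' Run adaptive landscape flattening
#'
#' Two-stage schedule of serial biased runs (`n_short` runs of `len_short`
#' steps, then `n_long` of `len_long` steps), each followed by the
#' population-matching bias update with pseudocount regularization; the
#' reference substituent's bias is pinned to zero at every site. A final
#' validation run at the converged biases checks flatness (max/min
#' pseudocounted end-state population ratio <= `flatness_threshold`) and
#' errors if any substituent was never sampled.
#'
#' @param system a `toy_system`
#' @param phase `"solution"` or `"complex"`
#' @param schedule list with `n_short`, `len_short`, `n_long`, `len_long`
#'   (counts and lengths, in steps, of the two stages)
#' @param seed integer seed
#' @param cutoff end-state cutoff for the population counts
#' @param flatness_threshold acceptable max/min population ratio on the
#'   validation run
#' @param dt_x,dt_theta,c_exp engine parameters, see [sample_msld()]
#' @return a `bias_set`: `bias` (named list site -> named numeric),
#'   `trace` (iterations x lambda states bias history), `flatness_trace`,
#'   `validation_flatness`, `converged`, plus run metadata
#' @export
run_alf <- function(system, phase,
                    schedule = list(n_short = 40, len_short = 1500,
                                    n_long = 20, len_long = 30000),
                    seed = 1, cutoff = 0.99, flatness_threshold = 10,
                    dt_x = 0.05, dt_theta = 0.05, c_exp = 5.5) {
  stopifnot(schedule$n_short >= 0, schedule$n_long >= 0,
            schedule$len_short > 0, schedule$len_long > 0)
  idx <- lambda_index(system)
  sites <- unique(idx$site)
  kt <- kT(system$temperature)
  bias <- lapply(stats::setNames(sites, sites), function(sn)
    stats::setNames(rep(0, sum(idx$site == sn)),
                    idx$substituent[idx$site == sn]))
  lengths <- c(rep(schedule$len_short, schedule$n_short),
               rep(schedule$len_long, schedule$n_long))
  n_iter <- length(lengths)
  trace <- matrix(NA_real_, n_iter, nrow(idx),
                  dimnames = list(NULL, paste(idx$site, idx$substituent, sep = ":")))
  flat_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    traj <- sample_msld(system, phase, biases = bias,
                        n_eq = ceiling(lengths[it] * 0.1),
                        n_collect = lengths[it],
                        seed = seed + 7919L * it, dt_x = dt_x,
                        dt_theta = dt_theta, c_exp = c_exp)
    cnt <- marginal_counts(traj, cutoff)
    flats <- numeric(length(sites))
    for (si in seq_along(sites)) {
      sn <- sites[si]
      p <- (cnt[[sn]] + 1) / sum(cnt[[sn]] + 1)   # pseudocount of 1
      ref <- system$reference[[sn]]
      bias[[sn]] <- bias[[sn]] - kt * log(p / p[[ref]])
      bias[[sn]] <- bias[[sn]] - bias[[sn]][[ref]] # pin reference to 0
      flats[si] <- max(p) / min(p)
    }
    flat_trace[it] <- max(flats)
    trace[it, ] <- unlist(bias[sites], use.names = FALSE)
  }
  # final biases: average over the stable late refinement iterations, which
  # damps the per-iteration count noise once the trace has plateaued
  if (schedule$n_long >= 2) {
    h <- max(2L, floor(schedule$n_long / 2))
    late <- colMeans(trace[seq(n_iter - h + 1L, n_iter), , drop = FALSE])
    for (sn in sites) {
      cols <- paste(sn, names(bias[[sn]]), sep = ":")
      bias[[sn]] <- stats::setNames(late[cols], names(bias[[sn]]))
      bias[[sn]] <- bias[[sn]] - bias[[sn]][[system$reference[[sn]]]]
    }
  }
  # validation run at the final biases
  vtraj <- sample_msld(system, phase, biases = bias,
                       n_eq = ceiling(schedule$len_long * 0.1),
                       n_collect = schedule$len_long,
                       seed = seed + 104729L, dt_x = dt_x,
                       dt_theta = dt_theta, c_exp = c_exp)
  vcnt <- marginal_counts(vtraj, cutoff)
  for (sn in sites) {
    zero <- names(vcnt[[sn]])[vcnt[[sn]] == 0]
    if (length(zero) > 0)
      stop(sprintf(paste0("run_alf: substituent(s) %s at site %s were never ",
                          "sampled after the full schedule (non-convergence)"),
                   paste(zero, collapse = ", "), sn))
  }
  vflat <- max(vapply(sites, function(sn) {
    p <- (vcnt[[sn]] + 1) / sum(vcnt[[sn]] + 1)
    max(p) / min(p)
  }, numeric(1)))
  structure(list(bias = bias, trace = trace, flatness_trace = flat_trace,
                 validation_flatness = vflat,
                 converged = vflat <= flatness_threshold,
                 schedule = schedule, cutoff = cutoff, phase = phase,
                 seed = seed, temperature = system$temperature),
            class = "bias_set")
}

#' @export
print.bias_set <- function(x, ...) {
  cat(sprintf("bias_set (%s phase): %d ALF iterations, validation flatness %.2f (%s)\n",
              x$phase, nrow(x$trace), x$validation_flatness,
              if (x$converged) "converged" else "NOT converged"))
  for (sn in names(x$bias)) {
    cat(sprintf("  site %s: %s\n", sn,
                paste(sprintf("%s=%+.3f", names(x$bias[[sn]]), x$bias[[sn]]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Full multisite-lambda-dynamics RBFE pipeline
#'
#' For each phase: flatten the landscape with [run_alf()], run `n_replicas`
#' independent production simulations at the converged biases, bin end
#' states at `cutoff`, and Boltzmann-reweight populations back to zero bias
#' to obtain per-phase relative free energies. Relative binding free
#' energies are the per-replica complex-minus-solution differences,
#' summarized as mean and sample SD over replicas.
#'
#' @param system a `toy_system`
#' @param alf_schedule schedule passed to [run_alf()]
#' @param n_eq,n_collect production equilibration/collection steps
#' @param n_replicas independent production replicas per phase
#' @param seed integer seed
#' @param cutoff end-state cutoff (default 0.99)
#' @param dt_x,dt_theta,c_exp engine parameters
#' @return list with `estimates` (data.frame: label, ddg_mean, ddg_sd, n),
#'   `per_phase` per-replica free energies, and the two `bias_set`s
#' @export
msld_rbfe <- function(system,
                      alf_schedule = list(n_short = 40, len_short = 1500,
                                          n_long = 20, len_long = 30000),
                      n_eq = 2000, n_collect = 50000, n_replicas = 5,
                      seed = 1, cutoff = 0.99,
                      dt_x = 0.05, dt_theta = 0.05, c_exp = 5.5) {
  ref_label <- paste(unname(system$reference), collapse = "+")
  phases <- c("solution", "complex")
  per_phase <- list()
  biasets <- list()
  for (ph in phases) {
    bs <- run_alf(system, ph, schedule = alf_schedule,
                  seed = seed + ifelse(ph == "complex", 31L, 0L),
                  cutoff = cutoff, dt_x = dt_x, dt_theta = dt_theta,
                  c_exp = c_exp)
    biasets[[ph]] <- bs
    reps <- vector("list", n_replicas)
    for (r in seq_len(n_replicas)) {
      traj <- sample_msld(system, ph, biases = bs$bias, n_eq = n_eq,
                          n_collect = n_collect,
                          seed = seed + 1000L * r + ifelse(ph == "complex", 31L, 0L),
                          dt_x = dt_x, dt_theta = dt_theta, c_exp = c_exp)
      cnt <- bin_endstates(traj, cutoff)
      est <- population_ddg(cnt, biases = bs$bias, reference = ref_label)
      reps[[r]] <- stats::setNames(est$ddg, est$label)
    }
    per_phase[[ph]] <- reps
  }
  labels <- Reduce(intersect, lapply(c(per_phase$solution, per_phase$complex), names))
  rows <- lapply(labels, function(lb) {
    ddg_r <- vapply(seq_len(n_replicas), function(r)
      per_phase$complex[[r]][[lb]] - per_phase$solution[[r]][[lb]], numeric(1))
    st <- replicate_stats(ddg_r)
    data.frame(label = lb, ddg_mean = st$mean, ddg_sd = st$sd, n = st$n)
  })
  list(estimates = do.call(rbind, rows), per_phase = per_phase,
       bias_sets = biasets, reference = ref_label)
}

#' Full windowed-FEP RBFE pipeline
#'
#' Runs the staged FEP window series in both phases for `n_replicas`
#' replicas, estimates each leg with BAR, and reports the per-replica
#' complex-minus-solution differences summarized over replicas.
#'
#' @param system a `toy_system`
#' @param site,from,to transformation to perform
#' @param n_windows,n_eq,n_collect window count and per-window steps
#' @param n_replicas independent replicas
#' @param seed integer seed
#' @param dt Langevin step size
#' @return list with `ddg_mean`, `ddg_sd`, `n`, `per_replica`, `legs`
#' @export
fep_rbfe <- function(system, site, from, to, n_windows = 20,
                     n_eq = 500, n_collect = 2000, n_replicas = 5, seed = 1,
                     dt = 0.05) {
  per <- numeric(n_replicas)
  legs <- list()
  for (r in seq_len(n_replicas)) {
    ws_s <- simulate_fep(system, "solution", site, from, to, n_windows,
                         n_eq, n_collect, seed = seed + 211L * r, dt = dt)
    ws_c <- simulate_fep(system, "complex", site, from, to, n_windows,
                         n_eq, n_collect, seed = seed + 211L * r + 97L, dt = dt)
    leg_s <- bar_leg(ws_s)
    leg_c <- bar_leg(ws_c)
    per[r] <- leg_c$dg - leg_s$dg
    legs[[r]] <- list(solution = leg_s, complex = leg_c)
  }
  st <- replicate_stats(per)
  list(ddg_mean = st$mean, ddg_sd = st$sd, n = st$n, per_replica = per,
       legs = legs)
}
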