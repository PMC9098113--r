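# Stochastic sampling engine: soft-core pair kernel, staged FEP window
# schedules, fixed-lambda Langevin sampling feeding per-window energy
# differences, and dynamic multisite lambda propagation. The thermostat is
# overdamped Langevin (Euler-Maruyama, unit friction) for both coordinates
# and the lambda auxiliaries; the per-step loops live in compiled code.

#' Soft-core pair energy
#'
#' Lennard-Jones-style pair interaction scaled by the coupling parameter
#' with a padded separation, `r_eff^2 = r^2 + alpha (1 - lambda)`, so the
#' energy is finite everywhere (including r = 0) for lambda < 1, exactly the
#' full pair energy at lambda = 1, and exactly 0 at lambda = 0. This is the
#' standard device for avoiding end-point singularities when nonbonded
#' interactions are switched on or off.
#'
#' @param r separation (>= 0); vectorized
#' @param lambda coupling in \[0, 1\]
#' @param params list with `alpha` (padding, > 0), `epsilon` (well depth,
#'   kcal mol^-1) and `sigma` (minimum position)
#' @return pair energy (kcal mol^-1)
#' @export
softcore_energy <- function(r, lambda,
                            params = list(alpha = 0.5, epsilon = 1, sigma = 1)) {
  if (any(lambda < 0 | lambda > 1)) stop("softcore_energy: lambda outside [0, 1]")
  stopifnot(all(r >= 0), params$alpha > 0)
  s2 <- params$sigma^2 / (r^2 + params$alpha * (1 - lambda))
  lambda * params$epsilon * (s2^6 - 2 * s2^3)
}

#' Staged FEP lambda-window schedule
#'
#' `n_windows` evenly spaced lambda states on \[0, 1\] inclusive, with
#' staged electrostatic coupling factors: outgoing-atom electrostatics are
#' decoupled linearly over lambda in \[0, 0.5\] (factor max(0, 1 - 2 lambda))
#' and incoming-atom electrostatics are coupled over \[0.5, 1\] (factor
#' max(0, 2 lambda - 1)), while the steric coupling spans the full range.
#'
#' @param n_windows number of lambda windows (>= 2)
#' @return data.frame with columns `lambda`, `elec_outgoing`,
#'   `elec_incoming`, `steric`
#' @examples
#' fep_schedule(5)
#' @export
fep_schedule <- function(n_windows) {
  if (!is.numeric(n_windows) || n_windows < 2)
    stop("fep_schedule: at least 2 windows are required")
  lambda <- seq(0, 1, length.out = as.integer(n_windows))
  data.frame(lambda = lambda,
             elec_outgoing = pmax(0, 1 - 2 * lambda),
             elec_incoming = pmax(0, 2 * lambda - 1),
             steric = lambda)
}

# Window potential for the alchemical transformation from substituent `from`
# to `to` at one site: staged electrostatic-like offsets plus a linear mix
# of the two harmonic wells (which is itself harmonic, so both Langevin and
# exact Gaussian sampling are available).
window_potential <- function(system, phase, site, from, to, lambda) {
  pa <- get_potential(system, phase, site, from)
  pb <- get_potential(system, phase, site, to)
  out <- max(0, 1 - 2 * lambda)
  inc <- max(0, 2 * lambda - 1)
  k_eff <- (1 - lambda) * pa$k + lambda * pb$k
  mu_eff <- ((1 - lambda) * pa$k * pa$x0 + lambda * pb$k * pb$x0) / k_eff
  list(k_eff = k_eff, mu_eff = mu_eff,
       energy = function(x)
         out * pa$E0 + inc * pb$E0 +
           (1 - lambda) * 0.5 * pa$k * (x - pa$x0)^2 +
           lambda * 0.5 * pb$k * (x - pb$x0)^2)
}

new_window_samples <- function(lambda, fwd, rev, system, phase, site, from, to,
                               n_eq, n_collect, seed) {
  stopifnot(length(fwd) == length(lambda) - 1, length(rev) == length(lambda) - 1)
  structure(list(lambda = lambda, fwd = fwd, rev = rev,
                 temperature = system$temperature, phase = phase, site = site,
                 from = from, to = to, n_eq = n_eq, n_collect = n_collect,
                 seed = seed),
            class = "window_samples")
}

#' @export
print.window_samples <- function(x, ...) {
  cat(sprintf("window_samples: %d windows, %s -> %s (site %s, %s), %d samples/window\n",
              length(x$lambda), x$from, x$to, x$site, x$phase,
              if (length(x$fwd)) length(x$fwd[[1]]) else 0L))
  invisible(x)
}

#' Sample coordinates at a fixed lambda window
#'
#' Overdamped Langevin sampling of the window potential (a harmonic mixture)
#' at the system temperature; the first `n_eq` steps are discarded.
#' Reproducible under `seed`.
#'
#' @param system a `toy_system`
#' @param phase `"solution"` or `"complex"`
#' @param site,from,to site name and the outgoing/incoming substituents
#' @param lambda window coupling value in \[0, 1\]
#' @param n_eq,n_collect equilibration and collection steps
#' @param seed integer seed
#' @param dt Langevin step size
#' @param thin record every `thin`-th collected step
#' @return numeric vector of coordinate samples (possibly empty)
#' @export
sample_fixed_lambda <- function(system, phase, site, from, to, lambda,
                                n_eq = 500, n_collect = 2000, seed = 1,
                                dt = 0.05, thin = 1) {
  stopifnot(n_eq >= 0, n_collect >= 0, lambda >= 0, lambda <= 1)
  wp <- window_potential(system, phase, site, from, to, lambda)
  if (n_collect == 0) return(numeric(0))
  set.seed(as.integer(seed))
  cpp_langevin_harmonic(wp$k_eff, wp$mu_eff, kT(system$temperature),
                        dt, as.integer(n_eq), as.integer(n_collect),
                        as.integer(thin), wp$mu_eff)
}

#' Run a full staged-FEP window series
#'
#' Samples every window of [fep_schedule()] with [sample_fixed_lambda()] and
#' evaluates forward (`U_{w+1} - U_w` on window-w frames) and reverse
#' (`U_w - U_{w+1}` on window-(w+1) frames) energy differences for every
#' adjacent window pair.
#'
#' @inheritParams sample_fixed_lambda
#' @param n_windows number of lambda windows (>= 2)
#' @return a `window_samples` object
#' @export
simulate_fep <- function(system, phase, site, from, to, n_windows = 20,
                         n_eq = 500, n_collect = 2000, seed = 1,
                         dt = 0.05, thin = 1) {
  sched <- fep_schedule(n_windows)
  lambda <- sched$lambda
  n <- length(lambda)
  pots <- lapply(lambda, function(l)
    window_potential(system, phase, site, from, to, l))
  xs <- vector("list", n)
  for (w in seq_len(n))
    xs[[w]] <- sample_fixed_lambda(system, phase, site, from, to, lambda[w],
                                   n_eq, n_collect, seed = seed + 1009L * w,
                                   dt = dt, thin = thin)
  fwd <- rev_ <- vector("list", n - 1)
  for (w in seq_len(n - 1)) {
    fwd[[w]] <- pots[[w + 1]]$energy(xs[[w]]) - pots[[w]]$energy(xs[[w]])
    rev_[[w]] <- pots[[w]]$energy(xs[[w + 1]]) - pots[[w + 1]]$energy(xs[[w + 1]])
  }
  new_window_samples(lambda, fwd, rev_, system, phase, site, from, to,
                     n_eq, n_collect, seed)
}

#' Draw exact per-window samples from the stated potentials
#'
#' Fixture generator: i.i.d. Boltzmann (Gaussian) coordinate samples per
#' window, independent of the Langevin engine, converted to the same
#' forward/reverse energy-difference structure. Useful for validating the
#' estimators against samplers with no discretization or correlation error.
#'
#' @inheritParams simulate_fep
#' @param n_per_window samples per window
#' @return a `window_samples` object
#' @export
sample_windows_exact <- function(system, phase, site, from, to,
                                 n_windows = 11, n_per_window = 1000, seed = 1) {
  sched <- fep_schedule(n_windows)
  lambda <- sched$lambda
  n <- length(lambda)
  kt <- kT(system$temperature)
  set.seed(as.integer(seed))
  pots <- lapply(lambda, function(l)
    window_potential(system, phase, site, from, to, l))
  xs <- lapply(pots, function(p)
    rnorm(n_per_window, mean = p$mu_eff, sd = sqrt(kt / p$k_eff)))
  fwd <- rev_ <- vector("list", n - 1)
  for (w in seq_len(n - 1)) {
    fwd[[w]] <- pots[[w + 1]]$energy(xs[[w]]) - pots[[w]]$energy(xs[[w]])
    rev_[[w]] <- pots[[w]]$energy(xs[[w + 1]]) - pots[[w + 1]]$energy(xs[[w + 1]])
  }
  new_window_samples(lambda, fwd, rev_, system, phase, site, from, to,
                     0L, n_per_window, seed)
}

# ---- multisite lambda dynamics --------------------------------------------

# flattened (site, substituent) index table for a system
lambda_index <- function(system) {
  do.call(rbind, lapply(names(system$sites), function(sn)
    data.frame(site = sn, substituent = names(system$sites[[sn]]))))
}

flatten_biases <- function(system, biases) {
  idx <- lambda_index(system)
  if (is.null(biases)) return(numeric(nrow(idx)))
  if (is.numeric(biases) && length(system$sites) == 1 && !is.list(biases)) {
    biases <- stats::setNames(list(biases), names(system$sites))
  }
  out <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    b <- biases[[idx$site[r]]]
    bv <- if (is.null(b)) NA_real_ else unname(b[idx$substituent[r]])
    if (length(bv) != 1 || !is.finite(bv))
      stop(sprintf("bias missing or non-finite for %s:%s",
                   idx$site[r], idx$substituent[r]))
    out[r] <- bv
  }
  out
}

#' Propagate multisite lambda dynamics
#'
#' Joint overdamped-Langevin propagation of one coordinate per site and one
#' auxiliary variable per (site, substituent). The lambda vector at each
#' site is the normalized bounded exponential
#' `lambda_i = exp(c sin theta_i) / sum_j exp(c sin theta_j)`, so the
#' simplex constraint (sum to 1, all in \[0, 1\]) holds by construction on
#' every frame. The biased potential is `U - sum b_i lambda_i`: a larger
#' bias raises that substituent's occupancy.
#'
#' @param system a `toy_system`
#' @param phase `"solution"` or `"complex"`
#' @param biases named list (site -> named numeric per substituent), or a
#'   named numeric vector for single-site systems; NULL means all zero
#' @param n_eq,n_collect equilibration and collection steps
#' @param seed integer seed
#' @param dt_x,dt_theta Langevin step sizes for coordinates and auxiliaries
#' @param thin record every `thin`-th collected frame
#' @param c_exp exponent scale of the simplex map (default 5.5, the
#'   conventional value; must satisfy exp(2 c) > 99 so end states with
#'   lambda >= 0.99 are reachable)
#' @return a `lambda_trajectory`: frames of per-site lambda vectors plus the
#'   applied biases and run metadata
#' @export
sample_msld <- function(system, phase, biases = NULL, n_eq = 1000,
                        n_collect = 20000, seed = 1, dt_x = 0.05,
                        dt_theta = 0.05, thin = 1, c_exp = 5.5) {
  phase <- match.arg(phase, c("solution", "complex"))
  stopifnot(n_eq >= 0, n_collect >= 0)
  idx <- lambda_index(system)
  bias <- flatten_biases(system, biases)
  nsub <- vapply(names(system$sites), function(sn)
    length(system$sites[[sn]]), integer(1))
  kv <- x0v <- e0v <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- get_potential(system, phase, idx$site[r], idx$substituent[r])
    kv[r] <- p$k; x0v[r] <- p$x0; e0v[r] <- p$E0
  }
  if (n_collect == 0) {
    traj <- structure(list(
      lambda = matrix(numeric(0), 0, nrow(idx),
                      dimnames = list(NULL, paste(idx$site, idx$substituent, sep = ":"))),
      x = matrix(numeric(0), 0, length(nsub)),
      index = idx, bias = stats::setNames(bias, paste(idx$site, idx$substituent, sep = ":")),
      temperature = system$temperature, phase = phase, seed = seed,
      interval = thin), class = "lambda_trajectory")
    return(traj)
  }
  set.seed(as.integer(seed))
  theta0 <- rnorm(nrow(idx), 0, 0.5)
  x_init <- vapply(names(system$sites), function(sn) {
    p <- get_potential(system, phase, sn, system$reference[[sn]])
    p$x0
  }, numeric(1))
  res <- cpp_msld(as.integer(nsub), kv, x0v, e0v, bias, c_exp,
                  kT(system$temperature), dt_x, dt_theta,
                  as.integer(n_eq), as.integer(n_collect), as.integer(thin),
                  theta0, x_init)
  lam <- res$lambda
  colnames(lam) <- paste(idx$site, idx$substituent, sep = ":")
  structure(list(lambda = lam, x = res$x, index = idx,
                 bias = stats::setNames(bias, colnames(lam)),
                 temperature = system$temperature, phase = phase, seed = seed,
                 interval = thin),
            class = "lambda_trajectory")
}

#' @export
print.lambda_trajectory <- function(x, ...) {
  cat(sprintf("lambda_trajectory: %d frames, %d lambda states (%s phase), T = %g K\n",
              nrow(x$lambda), ncol(x$lambda), x$phase, x$temperature))
  invisible(x)
}
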