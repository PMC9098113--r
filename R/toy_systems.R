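# Analytically solvable alchemical model systems. Each substituent at each
# site is a 1-D harmonic well U(x) = E0 + k/2 (x - x0)^2; the "complex"
# phase differs from "solution" by substituent-specific energy offsets
# (environment coupling -> binding selectivity). Free energies are Gaussian
# configurational integrals, so every estimator in the package can be
# checked against a closed form.

#' Construct a harmonic toy potential
#'
#' @param k force constant (kcal mol^-1 unit^-2), > 0
#' @param x0 minimum position (unit)
#' @param E0 energy offset (kcal mol^-1)
#' @return a `toy_potential`
#' @export
toy_potential <- function(k, x0 = 0, E0 = 0) {
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k))
  if (k <= 0) stop("toy_potential: force constant must be positive")
  structure(list(form = "harmonic", k = unname(k), x0 = unname(x0),
                 E0 = unname(E0)),
            class = "toy_potential")
}

#' Evaluate a toy potential
#' @param pot a `toy_potential`
#' @param x coordinate(s)
#' @return energy (kcal mol^-1), vectorized over `x`
#' @export
potential_energy <- function(pot, x) pot$E0 + 0.5 * pot$k * (x - pot$x0)^2

#' Construct a two-phase toy alchemical system
#'
#' @param sites named list; each site is a named list of substituents, each
#'   a list with `solution` and `complex` entries holding `toy_potential`s
#' @param temperature temperature (K)
#' @param reference named character vector: reference substituent per site
#'   (defaults to the first substituent listed at each site)
#' @param softcore list of soft-core parameters (`alpha` padding,
#'   `epsilon`, `sigma`) used by [softcore_energy()]
#' @return a `toy_system`
#' @export
toy_system <- function(sites, temperature = 298, reference = NULL,
                       softcore = list(alpha = 0.5, epsilon = 1, sigma = 1)) {
  stopifnot(is.list(sites), length(sites) >= 1, !is.null(names(sites)))
  for (sn in names(sites)) {
    site <- sites[[sn]]
    stopifnot(is.list(site), length(site) >= 1, !is.null(names(site)))
    for (bn in names(site)) {
      sub <- site[[bn]]
      if (!all(c("solution", "complex") %in% names(sub)))
        stop(sprintf("site '%s' substituent '%s': both phases must be defined", sn, bn))
      stopifnot(inherits(sub$solution, "toy_potential"),
                inherits(sub$complex, "toy_potential"))
    }
  }
  stopifnot(is.numeric(temperature), temperature > 0)
  if (is.null(reference))
    reference <- vapply(sites, function(s) names(s)[1], character(1))
  stopifnot(all(names(sites) %in% names(reference)))
  for (sn in names(sites))
    if (!(reference[[sn]] %in% names(sites[[sn]])))
      stop(sprintf("reference substituent '%s' unknown at site '%s'",
                   reference[[sn]], sn))
  structure(list(sites = sites, temperature = temperature,
                 reference = reference[names(sites)], softcore = softcore),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %d site(s), T = %g K\n", length(x$sites), x$temperature))
  for (sn in names(x$sites))
    cat(sprintf("  site %s: %s (ref %s)\n", sn,
                paste(names(x$sites[[sn]]), collapse = ", "), x$reference[[sn]]))
  invisible(x)
}

get_potential <- function(system, phase, site, substituent) {
  phase <- match.arg(phase, c("solution", "complex"))
  st <- system$sites[[site]]
  if (is.null(st)) stop(sprintf("unknown site '%s'", site))
  sub <- st[[substituent]]
  if (is.null(sub)) stop(sprintf("unknown substituent '%s' at site '%s'",
                                 substituent, site))
  sub[[phase]]
}

#' Exact free energy of a substituent relative to the site reference
#'
#' For harmonic wells the configurational integral is Gaussian, giving
#' dA = E0_i - E0_ref + (kT/2) ln(k_i / k_ref). The site reference has
#' dA = 0 by construction.
#'
#' @param system a `toy_system`
#' @param phase `"solution"` or `"complex"`
#' @param substituent substituent name
#' @param site site name (defaults to the first site)
#' @return free energy difference (kcal mol^-1)
#' @examples
#' sys <- toy_system(list(s1 = list(
#'   A = list(solution = toy_potential(1), complex = toy_potential(1)),
#'   B = list(solution = toy_potential(2), complex = toy_potential(2)))))
#' analytic_free_energy(sys, "solution", "B") # (kT/2) ln 2 = 0.2053
#' @export
analytic_free_energy <- function(system, phase, substituent,
                                 site = names(system$sites)[1]) {
  pot <- get_potential(system, phase, site, substituent)
  ref <- get_potential(system, phase, site, system$reference[[site]])
  kt <- kT(system$temperature)
  (pot$E0 - ref$E0) + 0.5 * kt * log(pot$k / ref$k)
}

#' Exact free energy table for a toy system
#'
#' Per-substituent exact free energies versus the site reference in each
#' phase, and the exact relative binding free energy
#' ddG_bind = dG_complex - dG_solution.
#'
#' @param system a `toy_system`
#' @return data.frame with columns `site`, `substituent`, `dg_solution`,
#'   `dg_complex`, `ddg_bind`
#' @export
analytic_truth <- function(system) {
  rows <- list()
  for (sn in names(system$sites)) {
    for (bn in names(system$sites[[sn]])) {
      ds <- analytic_free_energy(system, "solution", bn, sn)
      dc <- analytic_free_energy(system, "complex", bn, sn)
      rows[[length(rows) + 1L]] <- data.frame(
        site = sn, substituent = bn, dg_solution = ds, dg_complex = dc,
        ddg_bind = dc - ds)
    }
  }
  do.call(rbind, rows)
}

#' Generate a reproducible toy fixture
#'
#' Builds a `toy_system` whose exact relative binding free energies are the
#' requested effect sizes, plus its analytic truth table and (optionally)
#' pre-sampled per-window energy-difference samples drawn from the stated
#' potentials. Force constants, minima and solution offsets are drawn from
#' seeded distributions; the complex phase adds the per-substituent binding
#' offsets, so `ddg_bind` is exact by construction whatever the draws.
#'
#' @param spec list with entries:
#'   `ddg_bind` -- list (one element per site) of numeric vectors giving the
#'   binding free energy of each non-reference substituent relative to the
#'   reference (kcal mol^-1); `temperature` (K, default 298);
#'   `k_range` (range of force constants, default c(1, 3));
#'   `x0_range` (range of minima, default c(-0.5, 0.5));
#'   `e0_sd` (SD of solution offsets, default 0.25);
#'   `window_samples` -- optional list(phase, site, from, to, n_windows,
#'   n_per_window) asking for pre-sampled `window_samples`
#' @param seed integer seed; identical seeds give identical fixtures
#' @return list with `system`, `truth`, and optionally `window_samples`
#' @export
generate_fixture <- function(spec, seed = 1) {
  stopifnot(is.list(spec), !is.null(spec$ddg_bind))
  ddg <- spec$ddg_bind
  if (!is.list(ddg)) ddg <- list(ddg)
  temperature <- spec$temperature %||% 298
  k_range <- spec$k_range %||% c(1, 3)
  x0_range <- spec$x0_range %||% c(-0.5, 0.5)
  e0_sd <- spec$e0_sd %||% 0.25
  if (any(k_range <= 0)) stop("generate_fixture: force constants must be positive")

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  sites <- list()
  for (s in seq_along(ddg)) {
    n_sub <- length(ddg[[s]]) + 1L
    offsets <- c(0, ddg[[s]])
    ks <- stats::runif(n_sub, k_range[1], k_range[2])
    x0s <- stats::runif(n_sub, x0_range[1], x0_range[2])
    e0s <- stats::rnorm(n_sub, 0, e0_sd)
    subs <- list()
    for (i in seq_len(n_sub)) {
      subs[[paste0("sub", i)]] <- list(
        solution = toy_potential(ks[i], x0s[i], e0s[i]),
        complex = toy_potential(ks[i], x0s[i], e0s[i] + offsets[i]))
    }
    sites[[paste0("site", s)]] <- subs
  }
  system <- toy_system(sites, temperature = temperature)
  out <- list(system = system, truth = analytic_truth(system))
  ws <- spec$window_samples
  if (!is.null(ws)) {
    out$window_samples <- sample_windows_exact(
      system, phase = ws$phase %||% "solution",
      site = ws$site %||% names(sites)[1],
      from = ws$from %||% "sub1", to = ws$to %||% "sub2",
      n_windows = ws$n_windows %||% 11, n_per_window = ws$n_per_window %||% 1000,
      seed = seed)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
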