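# Free-energy and statistical estimators: end-state binning of lambda
# trajectories, Boltzmann-reweighted population free energies, the Bennett
# acceptance ratio, forward/reverse convergence series, replicate summary
# statistics, and Spearman rank correlation.

#' Bin a lambda trajectory into end states
#'
#' A frame is assigned to the substituent combination (one substituent per
#' site) for which lambda >= `cutoff` at every site; frames with no site, or
#' any site, below the cutoff are counted as unassigned.
#'
#' @param traj a `lambda_trajectory`
#' @param cutoff end-state cutoff, in (0.5, 1\] (default 0.99)
#' @return an `end_state_counts`: data.frame `counts` (one column per site,
#'   plus `label` and `count`), `unassigned`, `total`, `cutoff`
#' @export
bin_endstates <- function(traj, cutoff = 0.99) {
  stopifnot(inherits(traj, "lambda_trajectory"))
  if (!is.numeric(cutoff) || cutoff <= 0.5 || cutoff > 1)
    stop("bin_endstates: cutoff must lie in (0.5, 1]")
  idx <- traj$index
  sites <- unique(idx$site)
  n_frames <- nrow(traj$lambda)
  assigned <- matrix(NA_character_, n_frames, length(sites),
                     dimnames = list(NULL, sites))
  for (sn in sites) {
    cols <- which(idx$site == sn)
    sub_lam <- traj$lambda[, cols, drop = FALSE]
    hit <- sub_lam >= cutoff
    n_hit <- rowSums(hit)
    pick <- max.col(hit, ties.method = "first")
    ok <- n_hit == 1L  # cutoff > 0.5 makes >1 hit impossible; keep the guard
    assigned[ok, sn] <- idx$substituent[cols][pick[ok]]
  }
  full <- rowSums(is.na(assigned)) == 0L
  if (any(full)) {
    labels <- apply(assigned[full, , drop = FALSE], 1, paste, collapse = "+")
    tab <- table(labels)
    combos <- do.call(rbind, strsplit(names(tab), "+", fixed = TRUE))
    counts <- data.frame(combos, stringsAsFactors = FALSE)
    names(counts) <- sites
    counts$label <- names(tab)
    counts$count <- as.integer(tab)
  } else {
    counts <- data.frame(matrix(character(0), 0, length(sites),
                                dimnames = list(NULL, sites)),
                         label = character(0), count = integer(0))
  }
  structure(list(counts = counts, unassigned = n_frames - sum(full),
                 total = n_frames, cutoff = cutoff, sites = sites,
                 temperature = traj$temperature, bias = traj$bias),
            class = "end_state_counts")
}

#' @export
print.end_state_counts <- function(x, ...) {
  cat(sprintf("end_state_counts: %d frames, cutoff %.3g, %d unassigned\n",
              x$total, x$cutoff, x$unassigned))
  print(x$counts[, c("label", "count")], row.names = FALSE)
  invisible(x)
}

# per-combination applied bias: sum over sites of the substituent bias
combo_bias <- function(counts, biases) {
  sites <- counts$sites
  if (is.null(biases)) return(rep(0, nrow(counts$counts)))
  if (!is.list(biases) && length(sites) == 1)
    biases <- stats::setNames(list(biases), sites)
  vapply(seq_len(nrow(counts$counts)), function(r) {
    sum(vapply(sites, function(sn) {
      b <- biases[[sn]][[counts$counts[[sn]][r]]]
      if (is.null(b)) stop(sprintf("no bias for %s:%s", sn, counts$counts[[sn]][r]))
      b
    }, numeric(1)))
  }, numeric(1))
}

#' Population-based relative free energies
#'
#' Boltzmann-reweights binned end-state counts back to zero bias,
#' `N~_i = N_i exp(-beta b_i)` (undoing the applied `U - sum b_i lambda_i`
#' bias), and converts count ratios against the reference combination into
#' relative free energies `ddG_i = -kT ln(N~_i / N~_ref)`. Combinations
#' with zero counts get `+Inf` and are flagged rather than dropped; a zero
#' reference count is an error.
#'
#' @param counts an `end_state_counts`
#' @param biases biases applied during the run (same structure as in
#'   [sample_msld()]); NULL means none
#' @param reference reference combination: named character vector
#'   (site -> substituent) or a single label `"subA+subB"`
#' @param temperature temperature (K); defaults to the trajectory's
#' @return data.frame with columns `label`, `count`, `weighted`, `ddg`,
#'   `flagged`; attribute `method` is `"population"`
#' @export
population_ddg <- function(counts, biases = NULL, reference,
                           temperature = counts$temperature) {
  stopifnot(inherits(counts, "end_state_counts"))
  if (length(reference) > 1 || !is.null(names(reference)))
    reference <- paste(reference[counts$sites], collapse = "+")
  tab <- counts$counts
  kt <- kT(temperature)
  b <- combo_bias(counts, biases)
  weighted <- tab$count * exp(-b / kt)
  ref_row <- match(reference, tab$label)
  if (is.na(ref_row) || tab$count[ref_row] == 0 || weighted[ref_row] <= 0)
    stop(sprintf("population_ddg: reference combination '%s' has no counts",
                 reference))
  ddg <- -kt * log(weighted / weighted[ref_row])
  out <- data.frame(label = tab$label, count = tab$count, weighted = weighted,
                    ddg = ddg, flagged = !is.finite(ddg) | tab$count == 0)
  attr(out, "method") <- "population"
  attr(out, "reference") <- reference
  out
}

# ---- Bennett acceptance ratio ---------------------------------------------

fermi <- function(x) 1 / (1 + exp(x))

#' Bennett acceptance ratio between two adjacent states
#'
#' Solves the Bennett self-consistency condition by bisection: with forward
#' energy differences `dU_F = U_1 - U_0` sampled in state 0, reverse
#' `dU_R = U_0 - U_1` sampled in state 1, and `M = kT ln(n_F / n_R)`, the
#' free energy difference dG satisfies
#' `sum_F f(beta (dU_F + M - dG)) = sum_R f(beta (dU_R - M + dG))`
#' where `f` is the Fermi function. The variance comes from the standard
#' asymptotic estimator. When the two distributions share essentially no
#' overlap, the estimate is flagged and a warning is raised.
#'
#' @param fwd forward energy differences (kcal mol^-1), sampled in state 0
#' @param rev_ reverse energy differences (kcal mol^-1), sampled in state 1
#' @param temperature temperature (K)
#' @param tol bisection tolerance on dG (kcal mol^-1)
#' @return list with `dg`, `sigma`, `method = "BAR"`, `flagged`
#' @export
bar <- function(fwd, rev_, temperature = 298, tol = 1e-8) {
  stopifnot(length(fwd) > 0, length(rev_) > 0,
            all(is.finite(fwd)), all(is.finite(rev_)))
  kt <- kT(temperature)
  nf <- length(fwd); nr <- length(rev_)
  M <- kt * log(nf / nr)
  g <- function(dg)
    sum(fermi((fwd + M - dg) / kt)) - sum(fermi((rev_ - M + dg) / kt))
  lo <- min(-rev_ , fwd) - 10 * kt - abs(M)
  hi <- max(-rev_, fwd) + 10 * kt + abs(M)
  # g is increasing in dg; widen the bracket if needed
  it <- 0
  while (g(lo) > 0 && it < 60) { lo <- lo - 2 * (hi - lo); it <- it + 1 }
  it <- 0
  while (g(hi) < 0 && it < 60) { hi <- hi + 2 * (hi - lo); it <- it + 1 }
  dg <- if (g(lo) > 0 || g(hi) < 0) {
    warning("bar: self-consistency equation has no bracketed root; flagging")
    NA_real_
  } else {
    uniroot(g, c(lo, hi), tol = tol)$root
  }
  flagged <- FALSE
  sigma <- NA_real_
  if (is.finite(dg)) {
    ff <- fermi((fwd + M - dg) / kt)
    fr <- fermi((rev_ - M + dg) / kt)
    vf <- mean(ff^2) / mean(ff)^2 - 1
    vr <- mean(fr^2) / mean(fr)^2 - 1
    sigma <- kt * sqrt(max(vf, 0) / nf + max(vr, 0) / nr)
    # degenerate overlap: all Fermi terms at machine zero on either side
    if (mean(ff) < 1e-12 || mean(fr) < 1e-12) {
      warning("bar: no phase-space overlap between the two states; flagging")
      flagged <- TRUE
    }
  } else flagged <- TRUE
  list(dg = dg, sigma = sigma, method = "BAR", flagged = flagged)
}

#' BAR free energy of a full window series
#'
#' Applies [bar()] to every adjacent window pair and sums the per-pair free
#' energies; uncertainties add in quadrature.
#'
#' @param samples a `window_samples`
#' @param temperature temperature (K); defaults to the samples'
#' @return list with `dg`, `sigma`, `per_window` (data.frame), `flagged`
#' @export
bar_leg <- function(samples, temperature = samples$temperature) {
  stopifnot(inherits(samples, "window_samples"))
  n_pair <- length(samples$fwd)
  res <- vector("list", n_pair)
  for (w in seq_len(n_pair)) {
    if (length(samples$fwd[[w]]) == 0 || length(samples$rev[[w]]) == 0)
      stop(sprintf("bar_leg: empty samples for window pair %d", w))
    res[[w]] <- bar(samples$fwd[[w]], samples$rev[[w]], temperature)
  }
  per <- data.frame(pair = seq_len(n_pair),
                    lambda_lo = samples$lambda[-length(samples$lambda)],
                    lambda_hi = samples$lambda[-1],
                    dg = vapply(res, `[[`, numeric(1), "dg"),
                    sigma = vapply(res, `[[`, numeric(1), "sigma"))
  list(dg = sum(per$dg), sigma = sqrt(sum(per$sigma^2)), per_window = per,
       method = "BAR", flagged = any(vapply(res, `[[`, logical(1), "flagged")))
}

# truncate every window of a window_samples to a slice of its samples
slice_windows <- function(samples, keep) {
  out <- samples
  out$fwd <- lapply(samples$fwd, keep)
  out$rev <- lapply(samples$rev, keep)
  out
}

#' Forward/reverse convergence series of a window-series free energy
#'
#' Recomputes the BAR leg estimate using an increasing fraction of the data:
#' the forward series uses the first `f * n` samples of every window, the
#' reverse series the last `f * n`. At `f = 1` both equal the full estimate.
#' The run is flagged converged when the two series agree within
#' `band` kcal mol^-1 for every fraction >= 0.5 (the equilibrated-region
#' band of the convergence plots).
#'
#' @param samples a `window_samples`
#' @param fractions increasing fractions in (0, 1\]
#' @param band half-width of the agreement band (kcal mol^-1, default 0.5)
#' @param temperature temperature (K)
#' @return list with `series` (data.frame fraction/forward/reverse),
#'   `converged`, `band`, `full` (the full-data estimate)
#' @export
convergence_series <- function(samples, fractions = seq(0.1, 1, by = 0.1),
                               band = 0.5, temperature = samples$temperature) {
  stopifnot(inherits(samples, "window_samples"),
            all(fractions > 0), all(fractions <= 1))
  fractions <- sort(fractions)
  n_min <- min(vapply(c(samples$fwd, samples$rev), length, integer(1)))
  rows <- list()
  for (f in fractions) {
    m <- floor(f * n_min)
    if (m < 2) {
      warning(sprintf("convergence_series: fraction %.3g leaves < 2 samples; skipped", f))
      next
    }
    fw <- bar_leg(slice_windows(samples, function(v) v[seq_len(min(m, length(v)))]),
                  temperature)$dg
    rv <- bar_leg(slice_windows(samples, function(v) {
      n <- length(v); v[seq(max(1L, n - m + 1L), n)]
    }), temperature)$dg
    rows[[length(rows) + 1L]] <- data.frame(fraction = f, forward = fw, reverse = rv)
  }
  series <- do.call(rbind, rows)
  full <- bar_leg(samples, temperature)
  late <- series[series$fraction >= 0.5, , drop = FALSE]
  converged <- nrow(late) > 0 &&
    all(abs(late$forward - late$reverse) <= band)
  list(series = series, converged = converged, band = band, full = full)
}

#' Mean and spread over replicate estimates
#'
#' Mean and sample standard deviation over independent replicas. With one
#' replica the mean is returned and the spread is flagged as undefined.
#'
#' @param estimates numeric vector of per-replica estimates
#' @return list with `mean`, `sd`, `n`, `flagged`
#' @examples
#' replicate_stats(c(0.5, 1.0, 1.5)) # mean 1.0, sd 0.5
#' @export
replicate_stats <- function(estimates) {
  stopifnot(is.numeric(estimates), length(estimates) >= 1,
            all(is.finite(estimates)))
  n <- length(estimates)
  list(mean = mean(estimates),
       sd = if (n >= 2) sd(estimates) else NA_real_,
       n = n, flagged = n < 2)
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling (delegated to
#' `stats::cor`). A constant vector makes the correlation undefined; NA is
#' returned with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return r_s in \[-1, 1\], or NA if undefined
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("spearman: need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("spearman: constant input; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
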