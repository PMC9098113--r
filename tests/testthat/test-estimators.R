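kt298 <- 0.0019872 * 298

# hand-built single-site trajectory from a lambda matrix
traj_from_lambda <- function(lam, subs = c("A", "B"), bias = NULL) {
  colnames(lam) <- paste0("site1:", subs)
  structure(list(lambda = lam, x = NULL,
                 index = data.frame(site = "site1", substituent = subs),
                 bias = setNames(if (is.null(bias)) rep(0, length(subs)) else bias,
                                 colnames(lam)),
                 temperature = 298, phase = "solution", seed = 0, interval = 1),
            class = "lambda_trajectory")
}

test_that("end-state binning assigns frames by the per-site cutoff", {
  lam <- rbind(c(1.0, 0.0), c(0.995, 0.005), c(0.5, 0.5), c(0.005, 0.995))
  cnt <- bin_endstates(traj_from_lambda(lam), cutoff = 0.99)
  expect_equal(setNames(cnt$counts$count, cnt$counts$label), c(A = 2L, B = 1L))
  expect_equal(cnt$unassigned, 1L)
  expect_equal(cnt$total, 4L)
  # all frames at the pure reference
  pure <- matrix(rep(c(1, 0), 5), ncol = 2, byrow = TRUE)
  cnt2 <- bin_endstates(traj_from_lambda(pure), cutoff = 0.99)
  expect_equal(setNames(cnt2$counts$count, cnt2$counts$label), c(A = 5L))
  expect_equal(cnt2$unassigned, 0L)
  # invalid cutoffs
  expect_error(bin_endstates(traj_from_lambda(pure), cutoff = 1.01), "cutoff")
  expect_error(bin_endstates(traj_from_lambda(pure), cutoff = 0.4), "cutoff")
})

test_that("multi-site binning requires every site above the cutoff", {
  lam <- rbind(c(1, 0, 1, 0),    # A at site1, C at site2
               c(1, 0, 0.5, 0.5), # site2 unassigned
               c(0, 1, 0, 1))    # B at site1, D at site2
  colnames(lam) <- c("site1:A", "site1:B", "site2:C", "site2:D")
  traj <- structure(list(lambda = lam, x = NULL,
                         index = data.frame(site = rep(c("site1", "site2"), each = 2),
                                            substituent = c("A", "B", "C", "D")),
                         bias = setNames(rep(0, 4), colnames(lam)),
                         temperature = 298, phase = "solution", seed = 0,
                         interval = 1),
                    class = "lambda_trajectory")
  cnt <- bin_endstates(traj, 0.99)
  expect_equal(sort(cnt$counts$label), c("A+C", "B+D"))
  expect_equal(cnt$unassigned, 1L)
})

test_that("population free energies follow Boltzmann reweighting", {
  n <- 1000
  lamAB <- rbind(matrix(rep(c(1, 0), n), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 1), round(n * exp(-1))), ncol = 2, byrow = TRUE))
  cnt <- bin_endstates(traj_from_lambda(lamAB), 0.99)
  # equal counts, zero biases -> 0
  eq <- bin_endstates(traj_from_lambda(
    rbind(matrix(rep(c(1, 0), 50), ncol = 2, byrow = TRUE),
          matrix(rep(c(0, 1), 50), ncol = 2, byrow = TRUE))), 0.99)
  est0 <- population_ddg(eq, reference = "A")
  expect_equal(est0$ddg[est0$label == "B"], 0)
  # N_B / N_A = e^-1, zero biases -> +kT
  est1 <- population_ddg(cnt, reference = "A")
  expect_equal(est1$ddg[est1$label == "B"], -kt298 * log(exp(-1)),
               tolerance = 1e-3)
  expect_equal(est1$ddg[est1$label == "B"], 0.5922, tolerance = 1e-3)
  # equal raw counts with b_B = +kT reweights to the same answer
  est2 <- population_ddg(eq, biases = list(site1 = c(A = 0, B = kt298)),
                         reference = "A")
  expect_equal(est2$ddg[est2$label == "B"], kt298, tolerance = 1e-9)
})

test_that("population estimates are invariant to a uniform bias shift", {
  lam <- rbind(matrix(rep(c(1, 0), 70), ncol = 2, byrow = TRUE),
               matrix(rep(c(0, 1), 30), ncol = 2, byrow = TRUE))
  cnt <- bin_endstates(traj_from_lambda(lam), 0.99)
  for (shift in c(-2, 0.7, 13)) {
    base <- population_ddg(cnt, biases = list(site1 = c(A = 0.2, B = -0.4)),
                           reference = "A")
    shifted <- population_ddg(cnt,
                              biases = list(site1 = c(A = 0.2 + shift,
                                                      B = -0.4 + shift)),
                              reference = "A")
    expect_equal(shifted$ddg, base$ddg, tolerance = 1e-12)
  }
})

test_that("zero counts are flagged, zero reference counts are an error", {
  lam <- matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE)
  cnt <- bin_endstates(traj_from_lambda(lam), 0.99)
  expect_error(population_ddg(cnt, reference = "B"), "reference")
  est <- population_ddg(cnt, reference = "A")
  expect_false("B" %in% est$label)  # never-seen combinations are absent
})

test_that("BAR solves the Bennett self-consistency condition", {
  # all-zero energy differences in both directions -> exactly 0
  z <- bar(rep(0, 100), rep(0, 100))
  expect_equal(z$dg, 0, tolerance = 1e-8)
  # constant offset: dU_F = +c, dU_R = -c -> dG = c
  cst <- bar(rep(1.0, 50), rep(-1.0, 50))
  expect_equal(cst$dg, 1.0, tolerance = 1e-8)
  # two harmonic states offset by 1.0 (same k): exact dA = 1.0
  sys <- two_sub_system(ddg = 1.0, kA = 1, kB = 1, x0B = 0)
  ws <- sample_windows_exact(sys, "complex", "site1", "A", "B",
                             n_windows = 2, n_per_window = 1e4, seed = 17)
  est <- bar(ws$fwd[[1]], ws$rev[[1]])
  expect_equal(est$dg, 1.0, tolerance = 0.05)
  # antisymmetry under swapping directions
  set.seed(5)
  f <- rnorm(500, 0.8, 0.7); r <- rnorm(400, -0.6, 0.7)
  expect_equal(bar(f, r)$dg, -bar(r, f)$dg, tolerance = 1e-7)
})

test_that("BAR matches the independent self-consistent oracle to 1e-6", {
  set.seed(31)
  cases <- list(
    list(f = rnorm(2000, 1.2, 0.9), r = rnorm(2000, -0.7, 0.9)),
    list(f = rnorm(500, -0.3, 0.4), r = rnorm(800, 0.5, 0.5)),
    list(f = rnorm(3000, 0, 1.5), r = rnorm(1000, 0, 1.5)))
  for (cs in cases) {
    expect_equal(bar(cs$f, cs$r)$dg, bar_oracle(cs$f, cs$r), tolerance = 1e-6)
  }
})

test_that("BAR flags vanishing phase-space overlap", {
  expect_warning(est <- bar(rep(60, 50), rep(60, 50)), "overlap|bracket")
  expect_true(est$flagged)
})

test_that("window-series BAR recovers analytic leg free energies", {
  sys <- two_sub_system(ddg = 1.0)
  truth <- analytic_free_energy(sys, "complex", "B")
  ws <- sample_windows_exact(sys, "complex", "site1", "A", "B",
                             n_windows = 11, n_per_window = 3000, seed = 23)
  est <- bar_leg(ws)
  expect_lt(abs(est$dg - truth), 0.05)
  expect_gt(est$sigma, 0)
})

test_that("convergence series equals the full estimate at f = 1 and flags drift", {
  sys <- two_sub_system(ddg = 1.0)
  ws <- sample_windows_exact(sys, "solution", "site1", "A", "B",
                             n_windows = 11, n_per_window = 2000, seed = 29)
  cs <- convergence_series(ws)
  full <- bar_leg(ws)$dg
  last <- cs$series[cs$series$fraction == 1, ]
  expect_equal(last$forward, full, tolerance = 1e-10)
  expect_equal(last$reverse, full, tolerance = 1e-10)
  # i.i.d. stationary samples: series should hug the full estimate
  expect_true(cs$converged)
  expect_lt(max(abs(cs$series$forward - full)), 0.5)
  # synthetic non-equilibration: first half of every window shifted +5
  ws_bad <- ws
  ws_bad$fwd <- lapply(ws$fwd, function(v) {
    v[seq_len(length(v) / 2)] <- v[seq_len(length(v) / 2)] + 5; v
  })
  cs_bad <- convergence_series(ws_bad)
  expect_false(cs_bad$converged)
  # too-small fractions are skipped with a warning
  expect_warning(convergence_series(ws, fractions = c(1e-4, 1)), "skipped")
})

test_that("replicate statistics summarize independent runs", {
  expect_equal(replicate_stats(c(1, 1, 1))[c("mean", "sd")], list(mean = 1, sd = 0))
  st <- replicate_stats(c(0.5, 1.0, 1.5))
  expect_equal(st$mean, 1.0)
  expect_equal(st$sd, 0.5)
  one <- replicate_stats(2.5)
  expect_true(one$flagged)
  expect_true(is.na(one$sd))
})

test_that("Spearman correlation matches the rank-difference formula", {
  expect_equal(spearman(1:5, 2 * (1:5) + 3), 1.0)
  expect_equal(spearman(1:5, rev(1:5)), -1.0)
  # hand formula on tie-free ranks: 1 - 6 sum(d^2) / (n (n^2 - 1))
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  d <- rank(x) - rank(y)
  expect_equal(spearman(x, y), 1 - 6 * sum(d^2) / (4 * 15))
  expect_equal(spearman(x, y), 0.8)
  expect_warning(r <- spearman(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
  expect_error(spearman(1:2, 1:2), "at least 3")
})
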