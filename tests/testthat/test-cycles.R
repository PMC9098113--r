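# small network fixtures ----------------------------------------------------

# neutral three-compound network plus a protonation pair for compound p10
charged_network <- function(edges = NULL) {
  nodes <- data.frame(
    id = c("c3", "c1", "c10n", "c10", "c15n", "c15"),
    site_4 = c("phenyl", "methoxyphenyl", "piperidine", "piperidine",
               "benzoic_acid", "benzoic_acid"),
    net_charge = c(0, 0, 0, 1, 0, -1),
    protonation = c("neutral", "neutral", "neutral", "protonated",
                    "neutral", "deprotonated"))
  perturbation_graph(nodes, edges)
}

test_that("perturbation graphs enforce the edge invariants", {
  # identical endpoints
  expect_error(perturbation_graph(
    data.frame(id = c("a", "b"), site_4 = "x", net_charge = 0,
               protonation = "neutral"),
    data.frame(from = "a", to = "b", ddg = 0, sigma = 0)), "identical")
  # charge change without a protonation change
  expect_error(perturbation_graph(
    data.frame(id = c("a", "b"), site_4 = c("x", "y"),
               net_charge = c(0, 1), protonation = "neutral"),
    data.frame(from = "a", to = "b", ddg = 0, sigma = 0)),
    "not a single \\(de\\)protonation")
  # charge change of 2 rejected even with a protonation tag change
  expect_error(perturbation_graph(
    data.frame(id = c("a", "b"), site_4 = "x",
               net_charge = c(-1, 1),
               protonation = c("deprotonated", "protonated")),
    data.frame(from = "a", to = "b", ddg = 0, sigma = 0)),
    "not a single \\(de\\)protonation")
  expect_error(perturbation_graph(
    data.frame(id = "a", net_charge = 0.5, protonation = "neutral")),
    "integer")
})

test_that("leg combination and path composition propagate uncertainty in quadrature", {
  r <- rbfe_from_legs(-2.0, -1.0, 0.3, 0.4)
  expect_equal(r$ddg, -1.0)
  expect_equal(r$sigma, 0.5)
  expect_equal(rbfe_from_legs(1.3, 1.3, 0.1, 0.1)$ddg, 0)
  expect_error(rbfe_from_legs(NA, 1, 0, 0), "finite")

  p <- compose_path(data.frame(ddg = c(1.0, -0.5), sigma = c(0.3, 0.4)))
  expect_equal(p$ddg, 0.5)
  expect_equal(p$sigma, 0.5)
  expect_equal(compose_path(data.frame(ddg = 2, sigma = 0.2)),
               list(ddg = 2, sigma = 0.2))
  expect_error(compose_path(data.frame(ddg = numeric(), sigma = numeric())),
               "empty")
})

test_that("graph path composition follows edge orientation", {
  g <- charged_network(data.frame(from = c("c3", "c1"), to = c("c1", "c10n"),
                                  ddg = c(1.0, 0.5), sigma = c(0.3, 0.4)))
  fwd <- compose_path(g, c("c3", "c1", "c10n"))
  expect_equal(fwd$ddg, 1.5)
  expect_equal(fwd$sigma, 0.5)
  # reversed traversal negates values, keeps sigma
  back <- compose_path(g, c("c10n", "c1", "c3"))
  expect_equal(back$ddg, -1.5)
  # out-and-back cancels with sqrt(2) sigma
  loop <- compose_path(g, c("c3", "c1", "c3"))
  expect_equal(loop$ddg, 0)
  expect_equal(loop$sigma, sqrt(2) * 0.3)
  expect_error(compose_path(g, c("c3", "c10n")), "disconnected")
  expect_error(compose_path(g, "c3"), "empty")
})

test_that("charge-preserving transformations route directly", {
  g <- charged_network()
  expect_equal(route_charge_change(g, "c3", "c1"), c("c3", "c1"))
})

test_that("net-charge changes route through the neutral protonation state", {
  g <- charged_network()
  # neutral -> +1 piperidine: via the neutral (unprotonated) form, 2 edges
  p <- route_charge_change(g, "c3", "c10")
  expect_equal(p, c("c3", "c10n", "c10"))
  # neutral -> -1 benzoate: via the benzoic acid form
  p2 <- route_charge_change(g, "c3", "c15")
  expect_equal(p2, c("c3", "c15n", "c15"))
  # charged -> charged: through both neutral forms
  p3 <- route_charge_change(g, "c10", "c15")
  expect_equal(p3, c("c10", "c10n", "c15n", "c15"))
  # every hop satisfies the edge invariant by construction
  for (i in seq_len(length(p3) - 1))
    expect_silent(rbfekit:::check_edge(g, p3[i], p3[i + 1]))
})

test_that("routing errors list the missing neutral intermediates", {
  nodes <- data.frame(id = c("a", "b"), site_4 = c("x", "y"),
                      net_charge = c(0, 1),
                      protonation = c("neutral", "protonated"))
  g <- perturbation_graph(nodes)
  expect_error(route_charge_change(g, "a", "b"), "missing intermediates.*b")
})

test_that("routing never emits a charge-changing edge that is not a (de)protonation", {
  # enumerate all source/target pairs of the mixed-charge network
  g <- charged_network()
  ids <- g$nodes$id
  for (s in ids) for (t in setdiff(ids, s)) {
    p <- route_charge_change(g, s, t)
    for (i in seq_len(length(p) - 1)) {
      a <- g$nodes[g$nodes$id == p[i], ]
      b <- g$nodes[g$nodes$id == p[i + 1], ]
      dq <- abs(b$net_charge - a$net_charge)
      expect_true(dq == 0 ||
                  (dq == 1 && a$protonation != b$protonation &&
                   a$site_4 == b$site_4))
    }
  }
})

test_that("cycles built from one analytic system close exactly", {
  sys <- toy_system(list(s = list(
    A = list(solution = toy_potential(1.0, 0, 0), complex = toy_potential(1.0, 0, 0.2)),
    B = list(solution = toy_potential(1.7, 0.2, 0.1), complex = toy_potential(1.7, 0.2, 1.1)),
    C = list(solution = toy_potential(0.8, -0.3, -0.4), complex = toy_potential(0.8, -0.3, 0.3)))))
  tr <- analytic_truth(sys)
  ddg <- setNames(tr$ddg_bind, tr$substituent)
  nodes <- data.frame(id = c("A", "B", "C"), site_1 = c("A", "B", "C"),
                      net_charge = 0, protonation = "neutral")
  edges <- data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                      ddg = c(ddg["B"] - ddg["A"], ddg["C"] - ddg["B"],
                              ddg["C"] - ddg["A"]),
                      sigma = 0)
  g <- perturbation_graph(nodes, edges)
  cc <- cycle_closure(g)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$sum, 0, tolerance = 1e-12)
  expect_true(cc$pass)
  # perturb one edge by +1: the defect shows up in the signed sum
  edges_bad <- edges
  edges_bad$ddg[2] <- edges_bad$ddg[2] + 1.0
  cc_bad <- cycle_closure(perturbation_graph(nodes, edges_bad))
  expect_equal(abs(cc_bad$sum), 1.0, tolerance = 1e-12)
  expect_false(cc_bad$pass)
})

test_that("acyclic graphs yield no cycle reports", {
  g <- charged_network(data.frame(from = c("c3", "c3"), to = c("c1", "c10n"),
                                  ddg = c(0.1, 0.2), sigma = c(0.1, 0.1)))
  expect_equal(nrow(cycle_closure(g)), 0L)
})

test_that("sampled cycles close within statistical tolerance", {
  sys <- toy_system(list(s = list(
    A = list(solution = toy_potential(1.0), complex = toy_potential(1.0, 0, 0.0)),
    B = list(solution = toy_potential(1.3), complex = toy_potential(1.3, 0, 0.6)),
    C = list(solution = toy_potential(0.9), complex = toy_potential(0.9, 0, -0.4)))))
  edge_est <- function(a, b, seed) {
    est <- sapply(seq_len(3), function(r) {
      dgc <- bar_leg(sample_windows_exact(sys, "complex", "s", a, b, 9, 800,
                                          seed = seed + r))$dg
      dgs <- bar_leg(sample_windows_exact(sys, "solution", "s", a, b, 9, 800,
                                          seed = seed + 50 + r))$dg
      dgc - dgs
    })
    st <- replicate_stats(est)
    c(st$mean, st$sd)
  }
  ab <- edge_est("A", "B", 1); bc <- edge_est("B", "C", 100); ac <- edge_est("A", "C", 200)
  nodes <- data.frame(id = c("A", "B", "C"), site_1 = c("A", "B", "C"),
                      net_charge = 0, protonation = "neutral")
  edges <- data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                      ddg = c(ab[1], bc[1], ac[1]),
                      sigma = c(ab[2], bc[2], ac[2]))
  cc <- cycle_closure(perturbation_graph(nodes, edges))
  expect_lt(abs(cc$sum), max(2 * cc$sigma, 0.1))
})

test_that("network planning spans every compound from the reference", {
  g <- charged_network()
  plan <- plan_network(g, "c3")
  expect_setequal(names(plan), setdiff(g$nodes$id, "c3"))
  expect_equal(plan$c10, c("c3", "c10n", "c10"))
  expect_equal(plan$c1, c("c3", "c1"))
})

test_that("perturbation graphs round-trip through JSON", {
  g <- charged_network(data.frame(from = "c3", to = "c1",
                                  ddg = 1.23456789012345, sigma = 0.1,
                                  method = "BAR"))
  path <- tempfile(fileext = ".json")
  write_perturbation_graph(g, path)
  g2 <- read_perturbation_graph(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges$ddg, g$edges$ddg, tolerance = 0)
})
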