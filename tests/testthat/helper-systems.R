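# Shared fixtures and independent oracles, all built in code at test time.

# canonical two-substituent system: identical phases for the reference,
# ddg_bind(B) = ddg exactly (complex offset), with distinct force constants
# so both legs are non-trivial
two_sub_system <- function(ddg = 1.0, kA = 1.0, kB = 1.5, x0B = 0.3,
                           temperature = 298) {
  toy_system(list(site1 = list(
    A = list(solution = toy_potential(kA, 0, 0),
             complex = toy_potential(kA, 0, 0)),
    B = list(solution = toy_potential(kB, x0B, 0),
             complex = toy_potential(kB, x0B, ddg)))),
    temperature = temperature)
}

# symmetric two-substituent system (identical potentials everywhere)
symmetric_system <- function(temperature = 298) {
  pot <- function() toy_potential(1.2, 0.1, 0.3)
  toy_system(list(site1 = list(
    A = list(solution = pot(), complex = pot()),
    B = list(solution = pot(), complex = pot()))),
    temperature = temperature)
}

# ---- independent BAR oracle -----------------------------------------------
# Damped fixed-point iteration of the Fermi-average self-consistency
# condition; deliberately a different algorithm from the package's bisection.
bar_oracle <- function(fwd, rev_, temperature = 298, iters = 5000) {
  kt <- 0.0019872 * temperature
  M <- kt * log(length(fwd) / length(rev_))
  f <- function(x) 1 / (1 + exp(x))
  dg <- 0
  for (i in seq_len(iters)) {
    sf <- sum(f((fwd + M - dg) / kt))
    sr <- sum(f((rev_ - M + dg) / kt))
    # sf - sr increases with dg, so relax against the imbalance
    step <- kt * log(sf / sr)
    dg <- dg - 0.5 * step
    if (abs(step) < 1e-13) break
  }
  dg
}

# ---- brute-force MCS oracle -----------------------------------------------
# Exhaustive subset enumeration on the first graph plus igraph LAD
# subgraph matching (label compatibility via domains) into the others.
# Returns the maximum common connected labeled subgraph size.
mcs_oracle_size <- function(graphs) {
  to_ig <- function(g) {
    igraph::graph_from_data_frame(
      if (nrow(g$bonds) > 0) data.frame(from = as.character(g$bonds$from),
                                        to = as.character(g$bonds$to))
      else data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = data.frame(name = as.character(g$atoms$id),
                            element = g$atoms$element))
  }
  igs <- lapply(graphs, to_ig)
  g1 <- graphs[[1]]
  n <- nrow(g1$atoms)
  best <- 0L
  for (size in n:1) {
    if (size <= best) break
    subs <- combn(seq_len(n), size, simplify = FALSE)
    for (sub in subs) {
      ids <- as.character(g1$atoms$id[sub])
      pat <- igraph::induced_subgraph(igs[[1]], ids)
      if (!igraph::is_connected(pat)) next
      pat_elem <- igraph::V(pat)$element
      ok <- TRUE
      for (j in seq_along(igs)[-1]) {
        tg <- igs[[j]]
        domains <- lapply(pat_elem, function(el)
          igraph::V(tg)[igraph::V(tg)$element == el])
        if (any(vapply(domains, length, integer(1)) == 0)) { ok <- FALSE; break }
        hit <- igraph::subgraph_isomorphic(pat, tg, method = "lad",
                                           induced = TRUE, domains = domains)
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) { best <- size; break }
    }
  }
  best
}

# check that a find_common_core mapping is a valid common connected labeled
# subgraph of all graphs
core_mapping_valid <- function(graphs, res) {
  if (res$size == 0) return(nrow(res$mapping) == 0)
  m <- res$mapping
  for (j in seq_along(graphs)) {
    g <- graphs[[j]]
    ids <- m[[j]]
    if (anyDuplicated(ids) || !all(ids %in% g$atoms$id)) return(FALSE)
  }
  # labels agree across columns
  lab <- function(g, ids) g$atoms$element[match(ids, g$atoms$id)]
  base <- lab(graphs[[1]], m[[1]])
  for (j in seq_along(graphs)[-1])
    if (!identical(lab(graphs[[j]], m[[j]]), base)) return(FALSE)
  # induced matching: adjacency among core atoms must agree in every graph
  g1 <- graphs[[1]]
  has_bond <- function(g, a, b)
    any((g$bonds$from == a & g$bonds$to == b) | (g$bonds$from == b & g$bonds$to == a))
  k <- res$size
  for (i1 in seq_len(k - 1)) {
    for (i2 in seq(i1 + 1, k)) {
      base_adj <- has_bond(g1, m[[1]][i1], m[[1]][i2])
      for (j in seq_along(graphs)[-1])
        if (has_bond(graphs[[j]], m[[j]][i1], m[[j]][i2]) != base_adj)
          return(FALSE)
    }
  }
  core_edges <- g1$bonds[g1$bonds$from %in% m[[1]] & g1$bonds$to %in% m[[1]], ,
                         drop = FALSE]
  # connectivity of the core in graph 1
  sub_ids <- m[[1]]
  comp <- rbfekit:::graph_components(sub_ids, core_edges)
  length(unique(comp)) == 1
}

# random connected labeled graph for property tests
random_mol_graph <- function(n, labels = c("C", "N", "O")) {
  atoms <- data.frame(id = seq_len(n),
                      element = sample(labels, n, replace = TRUE),
                      charge = round(stats::runif(n, -0.2, 0.2), 3))
  bonds <- if (n > 1) {
    # random spanning tree plus a few extra edges
    b <- data.frame(from = 2:n,
                    to = vapply(2:n, function(i) sample(seq_len(i - 1), 1), integer(1)))
    extra <- which(stats::runif(n) < 0.3)
    for (i in extra) {
      u <- sample(n, 2)
      if (!any((b$from == u[1] & b$to == u[2]) | (b$from == u[2] & b$to == u[1])))
        b <- rbind(b, data.frame(from = u[1], to = u[2]))
    }
    b
  } else data.frame(from = integer(), to = integer())
  mol_graph(atoms, bonds)
}
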