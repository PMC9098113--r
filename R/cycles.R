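# Thermodynamic-cycle bookkeeping on a perturbation network: compounds are
# nodes (substituent choice per site, integer net charge, protonation tag),
# alchemical transformations are edges carrying ddG +/- sigma. Legs combine
# by difference, paths by summation with quadrature uncertainties, charge
# changes route through the neutral protonation state of the charged
# substituent, and cycle closures validate the network.

#' Construct a perturbation graph
#'
#' @param nodes data.frame with columns `id` (unique), `net_charge`
#'   (integer), `protonation` (tag, e.g. "neutral", "protonated",
#'   "deprotonated"), plus any number of `site_*` columns naming the
#'   substituent chosen at each site
#' @param edges data.frame with columns `from`, `to`, `ddg`, `sigma` and
#'   optionally `method`; may have zero rows
#' @return a `perturbation_graph`
#' @export
perturbation_graph <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("id", "net_charge", "protonation") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("perturbation_graph: duplicate node ids")
  if (any(nodes$net_charge != round(nodes$net_charge)))
    stop("perturbation_graph: net charges must be integers")
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        ddg = numeric(), sigma = numeric(), method = character())
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "ddg", "sigma") %in% names(edges)))
    if (!"method" %in% names(edges)) edges$method <- NA_character_
  }
  g <- structure(list(nodes = nodes, edges = edges,
                      site_cols = grep("^site_", names(nodes), value = TRUE)),
                 class = "perturbation_graph")
  for (r in seq_len(nrow(edges))) check_edge(g, edges$from[r], edges$to[r])
  g
}

# edge invariant: endpoints differ at >= 1 site or in protonation state;
# net charge preserved, or changed by +/-1 through a single (de)protonation
# (site columns identical, protonation tag different)
check_edge <- function(graph, from, to) {
  a <- graph$nodes[graph$nodes$id == from, , drop = FALSE]
  b <- graph$nodes[graph$nodes$id == to, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop(sprintf("edge %s -> %s: unknown endpoint", from, to))
  site_diff <- vapply(graph$site_cols, function(cl) a[[cl]] != b[[cl]], logical(1))
  prot_diff <- a$protonation != b$protonation
  if (!any(site_diff) && !prot_diff)
    stop(sprintf("edge %s -> %s: endpoints are identical", from, to))
  dq <- b$net_charge - a$net_charge
  if (dq != 0) {
    if (abs(dq) != 1 || !prot_diff || any(site_diff))
      stop(sprintf(paste0("edge %s -> %s: net charge changes by %+d but the ",
                          "edge is not a single (de)protonation"),
                   from, to, dq))
  }
  invisible(TRUE)
}

#' @export
print.perturbation_graph <- function(x, ...) {
  cat(sprintf("perturbation_graph: %d compounds, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Relative binding free energy from the two alchemical legs
#'
#' `ddG_bind = dG_complex - dG_solution`, with the leg uncertainties added
#' in quadrature.
#'
#' @param dg_complex,dg_solution alchemical leg free energies (kcal mol^-1)
#' @param sigma_complex,sigma_solution leg uncertainties
#' @return list with `ddg` and `sigma`
#' @examples
#' rbfe_from_legs(-2.0, -1.0, 0.3, 0.4) # ddg -1.0, sigma 0.5
#' @export
rbfe_from_legs <- function(dg_complex, dg_solution,
                           sigma_complex = 0, sigma_solution = 0) {
  if (any(!is.finite(c(dg_complex, dg_solution, sigma_complex, sigma_solution))))
    stop("rbfe_from_legs: both legs must be present and finite")
  list(ddg = dg_complex - dg_solution,
       sigma = sqrt(sigma_complex^2 + sigma_solution^2))
}

# find an edge between u and v in either orientation; sign follows traversal
find_edge <- function(graph, u, v) {
  e <- graph$edges
  i <- which(e$from == u & e$to == v)
  if (length(i)) return(list(ddg = e$ddg[i[1]], sigma = e$sigma[i[1]], sign = 1))
  i <- which(e$from == v & e$to == u)
  if (length(i)) return(list(ddg = e$ddg[i[1]], sigma = e$sigma[i[1]], sign = -1))
  NULL
}

#' Compose a multi-edge perturbation path
#'
#' Sums edge free energies along a path; uncertainties accumulate in
#' quadrature (legs are independent simulations). The input is either a
#' `perturbation_graph` plus an ordered node sequence, or a data.frame of
#' edges with `ddg` and `sigma` columns already in path order.
#'
#' @param graph a `perturbation_graph`, or a data.frame with `ddg`, `sigma`
#' @param path ordered node ids (ignored for the data.frame form)
#' @return list with `ddg` and `sigma`
#' @examples
#' compose_path(data.frame(ddg = c(1.0, -0.5), sigma = c(0.3, 0.4)))
#' # ddg 0.5, sigma 0.5
#' @export
compose_path <- function(graph, path = NULL) {
  if (is.data.frame(graph)) {
    stopifnot(all(c("ddg", "sigma") %in% names(graph)))
    if (nrow(graph) == 0) stop("compose_path: empty path")
    return(list(ddg = sum(graph$ddg), sigma = sqrt(sum(graph$sigma^2))))
  }
  stopifnot(inherits(graph, "perturbation_graph"))
  if (is.null(path) || length(path) < 2) stop("compose_path: empty path")
  vals <- sigs <- numeric(length(path) - 1)
  for (i in seq_len(length(path) - 1)) {
    e <- find_edge(graph, path[i], path[i + 1])
    if (is.null(e))
      stop(sprintf("compose_path: path is disconnected between %s and %s",
                   path[i], path[i + 1]))
    vals[i] <- e$sign * e$ddg
    sigs[i] <- e$sigma
  }
  list(ddg = sum(vals), sigma = sqrt(sum(sigs^2)))
}

# the neutral protonation-state partner of a compound: same substituents,
# protonation tag "neutral"
neutral_form <- function(graph, id) {
  n <- graph$nodes
  a <- n[n$id == id, , drop = FALSE]
  if (a$protonation == "neutral") return(id)
  same_sites <- rep(TRUE, nrow(n))
  for (cl in graph$site_cols) same_sites <- same_sites & n[[cl]] == a[[cl]]
  hit <- n$id[same_sites & n$protonation == "neutral"]
  if (length(hit) == 0) return(NA_character_)
  hit[1]
}

#' Route a perturbation, inserting neutral intermediates on charge changes
#'
#' Transformations between compounds of equal net charge are routed as a
#' single direct edge. When the net charges differ, the route passes
#' through the neutral protonation-state form of each charged endpoint, so
#' every edge of the returned path either preserves net charge or is a
#' single (de)protonation. Missing neutral intermediates are reported in
#' the error.
#'
#' @param graph a `perturbation_graph`
#' @param source,target node ids
#' @return character vector of node ids from `source` to `target`
#' @export
route_charge_change <- function(graph, source, target) {
  n <- graph$nodes
  a <- n[n$id == source, , drop = FALSE]
  b <- n[n$id == target, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("route_charge_change: source or target not in graph")
  if (a$net_charge == b$net_charge) return(c(source, target))
  path <- source
  missing <- character(0)
  if (a$net_charge != 0) {
    na_ <- neutral_form(graph, source)
    if (is.na(na_)) missing <- c(missing, sprintf("neutral form of %s", source))
    else path <- c(path, na_)
  }
  if (b$net_charge != 0) {
    nb_ <- neutral_form(graph, target)
    if (is.na(nb_)) missing <- c(missing, sprintf("neutral form of %s", target))
    else path <- c(path, nb_)
  }
  if (length(missing) > 0)
    stop(sprintf("route_charge_change: no valid route; missing intermediates: %s",
                 paste(missing, collapse = "; ")))
  path <- c(path, target)
  path <- path[c(TRUE, path[-1] != path[-length(path)])] # drop repeated hops
  for (i in seq_len(length(path) - 1)) check_edge(graph, path[i], path[i + 1])
  path
}

#' Cycle-closure check of a perturbation network
#'
#' Finds one independent cycle per non-tree edge of a spanning forest and
#' reports each cycle's signed free energy sum with its quadrature
#' uncertainty. A cycle passes when |sum| <= 2 sigma (free energy is a
#' state function, so the true sum is zero). An acyclic graph yields an
#' empty result.
#'
#' @param graph a `perturbation_graph`
#' @return data.frame with columns `cycle`, `nodes`, `sum`, `sigma`, `pass`
#' @export
cycle_closure <- function(graph) {
  e <- graph$edges
  empty <- data.frame(cycle = integer(), nodes = character(),
                      sum = numeric(), sigma = numeric(), pass = logical())
  if (nrow(e) == 0) return(empty)
  ig <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                      vertices = graph$nodes$id)
  # spanning forest; every edge left out closes one independent cycle
  forest <- igraph::mst(ig)
  in_forest <- rep(FALSE, nrow(e))
  fe <- igraph::as_edgelist(forest)
  used <- rep(FALSE, nrow(fe))
  for (r in seq_len(nrow(e))) {
    for (q in seq_len(nrow(fe))) {
      if (used[q]) next
      if ((fe[q, 1] == e$from[r] && fe[q, 2] == e$to[r]) ||
          (fe[q, 1] == e$to[r] && fe[q, 2] == e$from[r])) {
        in_forest[r] <- TRUE; used[q] <- TRUE; break
      }
    }
  }
  rows <- list()
  ci <- 0L
  for (r in which(!in_forest)) {
    sp <- igraph::shortest_paths(forest, from = e$from[r], to = e$to[r],
                                 output = "vpath")$vpath[[1]]
    if (length(sp) == 0) next  # chord connects two components: no cycle
    cyc <- c(igraph::V(forest)$name[sp], e$from[r])
    comp <- compose_path(graph, cyc)
    ci <- ci + 1L
    rows[[ci]] <- data.frame(cycle = ci, nodes = paste(cyc, collapse = "->"),
                             sum = comp$ddg, sigma = comp$sigma,
                             pass = abs(comp$ddg) <= 2 * comp$sigma + 1e-9)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Read / write a perturbation graph as JSON
#' @param path file path
#' @param graph a `perturbation_graph`
#' @return `read_perturbation_graph` returns a `perturbation_graph`
#' @export
read_perturbation_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  perturbation_graph(as.data.frame(x$nodes),
                     if (!is.null(x$edges) && length(x$edges))
                       as.data.frame(x$edges) else NULL)
}

#' @rdname read_perturbation_graph
#' @export
write_perturbation_graph <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Spanning-tree perturbation plan from a declared reference compound
#'
#' Plans the set of transformations needed to connect every compound to the
#' reference: a breadth-first spanning tree rooted at the reference, with
#' each planned edge routed through neutral intermediates where the net
#' charge changes.
#'
#' @param graph a `perturbation_graph`
#' @param reference reference node id
#' @return list of routed paths (character vectors), one per non-reference
#'   compound
#' @export
plan_network <- function(graph, reference) {
  stopifnot(reference %in% graph$nodes$id)
  others <- setdiff(graph$nodes$id, reference)
  stats::setNames(lapply(others, function(id)
    route_charge_change(graph, reference, id)), others)
}
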