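# Labeled molecular graphs: atoms carry an element label and a partial charge
# (elementary-charge units e); bonds are undirected id pairs. No bond orders,
# no coordinates -- the minimal representation needed for common-core
# identification and charge bookkeeping.

#' Construct a labeled molecular graph
#'
#' @param atoms data.frame with columns `id` (integer, unique), `element`
#'   (character label) and `charge` (partial charge, e)
#' @param bonds data.frame with columns `from`, `to` (atom ids); may have
#'   zero rows for a single-atom graph
#' @param name optional graph name
#' @return an object of class `mol_graph`
#' @examples
#' g <- mol_graph(
#'   atoms = data.frame(id = 1:3, element = c("C", "C", "O"),
#'                      charge = c(0.1, 0.0, -0.1)),
#'   bonds = data.frame(from = c(1, 2), to = c(2, 3))
#' )
#' @export
mol_graph <- function(atoms, bonds = data.frame(from = integer(), to = integer()),
                      name = NULL) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("id", "element", "charge") %in% names(atoms)))
  if (nrow(bonds) > 0) stopifnot(all(c("from", "to") %in% names(bonds)))
  atoms$id <- as.integer(atoms$id)
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.numeric(atoms$charge)
  g <- structure(
    list(atoms = atoms[order(atoms$id), c("id", "element", "charge")],
         bonds = if (nrow(bonds) > 0)
           data.frame(from = as.integer(bonds$from), to = as.integer(bonds$to))
         else data.frame(from = integer(), to = integer()),
         name = name),
    class = "mol_graph")
  validate_mol_graph(g)
  g
}

#' Validate a mol_graph's invariants
#'
#' Checks unique atom ids, finite charges, bond endpoints that exist, and
#' connectivity (a graph with more than one atom must be connected).
#'
#' @param g a `mol_graph`
#' @return `g`, invisibly; errors on violation
#' @export
validate_mol_graph <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  a <- g$atoms
  if (anyDuplicated(a$id)) stop("mol_graph: duplicate atom ids")
  if (nrow(a) == 0) stop("mol_graph: no atoms")
  if (!all(is.finite(a$charge))) stop("mol_graph: non-finite partial charges")
  b <- g$bonds
  if (nrow(b) > 0 && !all(c(b$from, b$to) %in% a$id))
    stop("mol_graph: bond endpoint references a missing atom id")
  if (nrow(b) > 0 && any(b$from == b$to)) stop("mol_graph: self-bond")
  if (nrow(a) > 1) {
    comp <- graph_components(a$id, b)
    if (length(unique(comp)) > 1) stop("mol_graph: graph is not connected")
  }
  invisible(g)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph%s: %d atoms, %d bonds, net charge %+0.4f e\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$charge)))
  invisible(x)
}

#' Net partial charge of a molecular graph or fragment
#' @param g a `mol_graph`
#' @return sum of atomic partial charges (e)
#' @export
net_charge <- function(g) sum(g$atoms$charge)

# connected-component labels by BFS over an adjacency list
graph_components <- function(ids, bonds) {
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- idx[[as.character(bonds$from[r])]]
      j <- idx[[as.character(bonds$to[r])]]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# adjacency list keyed by position for a graph's atoms
adjacency_list <- function(g) {
  ids <- g$atoms$id
  idx <- setNames(seq_along(ids), ids)
  adj <- vector("list", length(ids))
  b <- g$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      i <- idx[[as.character(b$from[r])]]
      j <- idx[[as.character(b$to[r])]]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Read / write a molecular graph as JSON
#'
#' Plain-text JSON with an `atoms` array (id, element, charge) and a `bonds`
#' array (from, to); round-trips exactly.
#'
#' @param path file path
#' @param g a `mol_graph`
#' @return `read_mol_graph` returns a `mol_graph`
#' @export
read_mol_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mol_graph(atoms = as.data.frame(x$atoms),
            bonds = if (!is.null(x$bonds) && length(x$bonds))
              as.data.frame(x$bonds) else data.frame(from = integer(), to = integer()),
            name = x$name)
}

#' @rdname read_mol_graph
#' @export
write_mol_graph <- function(g, path) {
  validate_mol_graph(g)
  jsonlite::write_json(
    list(name = g$name, atoms = g$atoms, bonds = g$bonds),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# ---- maximum common substructure ------------------------------------------

# Enumerate every connected vertex subset of a graph exactly once
# (extension-set recursion rooted at each vertex, descendants restricted to
# ids greater than the root).
connected_subsets <- function(adj) {
  n <- length(adj)
  out <- list()
  emit <- function(s) out[[length(out) + 1L]] <<- s
  recurse <- function(sub, ext, root) {
    emit(sub)
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      new_ext <- union(ext, setdiff(adj[[w]][adj[[w]] > root],
                                    c(sub, w)))
      recurse(c(sub, w), new_ext, root)
    }
  }
  for (v in seq_len(n)) recurse(v, adj[[v]][adj[[v]] > v], v)
  out
}

# Lexicographically smallest label-preserving injective map of `pattern`
# (positions sub, with its induced edges) into graph `g2`; NULL if none.
# Induced matching: pattern edges must map onto edges of g2 AND pattern
# non-edges onto non-edges, so the common-subgraph relation is symmetric.
match_subgraph <- function(labels1, sub, edges_sub, labels2, adj2) {
  k <- length(sub)
  n2 <- length(labels2)
  # pattern adjacency matrix among positions 1..k of `sub`
  pmat <- matrix(FALSE, k, k)
  if (nrow(edges_sub) > 0) {
    for (r in seq_len(nrow(edges_sub))) {
      i <- match(edges_sub$from[r], sub); j <- match(edges_sub$to[r], sub)
      pmat[i, j] <- pmat[j, i] <- TRUE
    }
  }
  assign <- integer(k)
  used <- logical(n2)
  bt <- function(p) {
    if (p > k) return(TRUE)
    lab <- labels1[sub[p]]
    for (cand in seq_len(n2)) {
      if (used[cand] || labels2[cand] != lab) next
      ok <- TRUE
      for (q in seq_len(p - 1L)) {
        adj_tgt <- assign[q] %in% adj2[[cand]]
        if (pmat[p, q] != adj_tgt) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[p] <<- cand
      used[cand] <<- TRUE
      if (bt(p + 1L)) return(TRUE)
      used[cand] <<- FALSE
    }
    FALSE
  }
  if (bt(1L)) assign else NULL
}

#' Find the maximum common substructure (common core) of a set of graphs
#'
#' Exact search for the largest common connected induced labeled subgraph
#' present in every input graph: connected vertex subsets of the smallest
#' graph are enumerated and matched (label-preserving, injective, edge- and
#' non-edge-preserving) into every other graph, so the relation is
#' symmetric in the inputs. Ties between equal-size cores are broken
#' deterministically: smallest sorted label multiset first, then smallest
#' atom-id mapping.
#'
#' @param graphs list of two or more `mol_graph` objects, each with at most
#'   30 atoms
#' @return a list with `size` (number of core atoms) and `mapping`, a
#'   data.frame with one atom-id column per input graph (0 rows when the
#'   graphs share no substructure)
#' @examples
#' g1 <- mol_graph(data.frame(id = 1:3, element = c("C", "C", "O"), charge = 0),
#'                 data.frame(from = 1:2, to = 2:3))
#' g2 <- mol_graph(data.frame(id = 1:3, element = c("C", "C", "N"), charge = 0),
#'                 data.frame(from = 1:2, to = 2:3))
#' find_common_core(list(g1, g2))$size # 2 (the C-C unit)
#' @export
find_common_core <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 2)
  lapply(graphs, validate_mol_graph)
  sizes <- vapply(graphs, function(g) nrow(g$atoms), integer(1))
  if (any(sizes > 30))
    stop("find_common_core: graphs above 30 atoms exceed the exact-search size limit")
  base_i <- which.min(sizes)
  g1 <- graphs[[base_i]]
  others <- graphs[-base_i]
  adj1 <- adjacency_list(g1)
  labels1 <- g1$atoms$element
  adjs <- lapply(others, adjacency_list)
  labels <- lapply(others, function(g) g$atoms$element)

  subsets <- connected_subsets(adj1)
  ord <- order(-vapply(subsets, length, integer(1)))
  subsets <- subsets[ord]

  best <- NULL
  best_size <- 0L
  for (sub in subsets) {
    k <- length(sub)
    if (k < best_size) break # subsets sorted by size; no larger core remains
    sub <- sort(sub)
    edges_sub <- g1$bonds[g1$bonds$from %in% g1$atoms$id[sub] &
                          g1$bonds$to %in% g1$atoms$id[sub], , drop = FALSE]
    # translate edge endpoints (atom ids) to positions
    pos <- setNames(seq_along(g1$atoms$id), g1$atoms$id)
    edges_pos <- data.frame(from = unname(pos[as.character(edges_sub$from)]),
                            to = unname(pos[as.character(edges_sub$to)]))
    maps <- vector("list", length(others))
    ok <- TRUE
    for (j in seq_along(others)) {
      m <- match_subgraph(labels1, sub, edges_pos, labels[[j]], adjs[[j]])
      if (is.null(m)) { ok <- FALSE; break }
      maps[[j]] <- m
    }
    if (!ok) next
    cand <- list(sub = sub, maps = maps)
    if (k > best_size) {
      best <- cand; best_size <- k
    } else if (k == best_size && core_precedes(cand, best, g1, others)) {
      best <- cand
    }
  }
  col_names <- paste0("graph", seq_along(graphs))
  if (best_size == 0L) {
    mapping <- as.data.frame(setNames(rep(list(integer()), length(graphs)), col_names))
    return(list(size = 0L, mapping = mapping))
  }
  cols <- vector("list", length(graphs))
  cols[[base_i]] <- g1$atoms$id[best$sub]
  oi <- setdiff(seq_along(graphs), base_i)
  for (j in seq_along(oi))
    cols[[oi[j]]] <- others[[j]]$atoms$id[best$maps[[j]]]
  mapping <- as.data.frame(setNames(cols, col_names))
  list(size = best_size, mapping = mapping)
}

# deterministic tie-break: smaller sorted label multiset, then smaller
# base-graph atom ids, then smaller mapped ids graph by graph
core_precedes <- function(a, b, g1, others) {
  la <- paste(sort(g1$atoms$element[a$sub]), collapse = "|")
  lb <- paste(sort(g1$atoms$element[b$sub]), collapse = "|")
  if (la != lb) return(la < lb)
  ka <- g1$atoms$id[a$sub]; kb <- g1$atoms$id[b$sub]
  cmp <- vec_compare(ka, kb)
  if (cmp != 0L) return(cmp < 0L)
  for (j in seq_along(others)) {
    cmp <- vec_compare(others[[j]]$atoms$id[a$maps[[j]]],
                       others[[j]]$atoms$id[b$maps[[j]]])
    if (cmp != 0L) return(cmp < 0L)
  }
  FALSE
}

vec_compare <- function(x, y) {
  for (i in seq_len(min(length(x), length(y)))) {
    if (x[i] < y[i]) return(-1L)
    if (x[i] > y[i]) return(1L)
  }
  0L
}
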