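# Multiple-topology ligand model: a common core plus, at each substitution
# site, a set of alternative substituent fragments hung off anchor atoms.
# All substituents coexist in the topology; internal energy terms never span
# two substituents at one site (the exclusion list enumerates every such
# cross-substituent atom pair). Charge renormalization adjusts substituent
# partial charges so that any combination of substituents carries the same
# integer net charge.

#' Construct a multiple-topology ligand
#'
#' @param core a `mol_graph`: the invariant scaffold shared by all compounds
#' @param sites named list; each element is one substitution site, itself a
#'   named list of substituents. A substituent is a list with `graph` (a
#'   `mol_graph` fragment) and `anchor` (the core atom id it attaches to).
#' @return an object of class `multi_topology`
#' @export
multi_topology <- function(core, sites) {
  validate_mol_graph(core)
  stopifnot(is.list(sites), length(sites) >= 1,
            !is.null(names(sites)), all(nzchar(names(sites))))
  for (sn in names(sites)) {
    site <- sites[[sn]]
    stopifnot(is.list(site), length(site) >= 1,
              !is.null(names(site)), all(nzchar(names(site))))
    for (bn in names(site)) {
      sub <- site[[bn]]
      if (!is.list(sub) || is.null(sub$graph) || is.null(sub$anchor))
        stop(sprintf("site '%s' substituent '%s': needs $graph and $anchor", sn, bn))
      validate_mol_graph(sub$graph)
      if (!all(sub$anchor %in% core$atoms$id))
        stop(sprintf("site '%s' substituent '%s': anchor atom not in core", sn, bn))
    }
  }
  structure(list(core = core, sites = sites), class = "multi_topology")
}

#' @export
print.multi_topology <- function(x, ...) {
  cat(sprintf("multi_topology: %d core atoms, %d sites (%s)\n",
              nrow(x$core$atoms), length(x$sites),
              paste(vapply(x$sites, length, integer(1)), collapse = " x ")))
  invisible(x)
}

#' Net partial charge of each substituent, by site
#' @param topology a `multi_topology`
#' @return named list (site) of named numeric vectors (substituent net, e)
#' @export
substituent_net_charges <- function(topology) {
  lapply(topology$sites, function(site)
    vapply(site, function(s) net_charge(s$graph), numeric(1)))
}

#' Cross-substituent exclusion list
#'
#' Every pair of atoms drawn from two different substituents at the same
#' site: no internal energy term may span such a pair, so the pair is
#' excluded. Atom names are namespaced as `site:substituent:atom_id`.
#'
#' @param topology a `multi_topology`
#' @return data.frame with columns `site`, `atom_a`, `atom_b`
#' @export
exclusion_list <- function(topology) {
  rows <- list()
  for (sn in names(topology$sites)) {
    site <- topology$sites[[sn]]
    bnames <- names(site)
    if (length(bnames) < 2) next
    for (i in seq_len(length(bnames) - 1)) {
      for (j in seq(i + 1, length(bnames))) {
        aa <- paste(sn, bnames[i], site[[bnames[i]]]$graph$atoms$id, sep = ":")
        bb <- paste(sn, bnames[j], site[[bnames[j]]]$graph$atoms$id, sep = ":")
        grid <- expand.grid(atom_a = aa, atom_b = bb,
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
        grid$site <- sn
        rows[[length(rows) + 1L]] <- grid[, c("site", "atom_a", "atom_b")]
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(site = character(), atom_a = character(), atom_b = character()))
  do.call(rbind, rows)
}

#' Enumerate every combinatorial compound of a multiple topology
#'
#' One substituent per site; the total charge column is the core net charge
#' plus the chosen substituents' nets.
#'
#' @param topology a `multi_topology`
#' @return data.frame with one column per site plus `total_charge`
#' @export
enumerate_compounds <- function(topology) {
  nets <- substituent_net_charges(topology)
  choices <- lapply(topology$sites, names)
  grid <- expand.grid(choices, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(topology$sites)
  tot <- rep(net_charge(topology$core), nrow(grid))
  for (sn in names(topology$sites)) tot <- tot + nets[[sn]][grid[[sn]]]
  grid$total_charge <- tot
  grid
}

#' Renormalize substituent partial charges site by site
#'
#' At each site, every non-exempt substituent is brought to the site's target
#' net charge (the arithmetic mean of the non-exempt substituents' original
#' nets); the correction for a substituent is spread uniformly over its
#' atoms. Exempt substituents -- the protonated/deprotonated partners of a
#' charge perturbation -- keep their charges, preserving their integer
#' charge offset. After renormalization every combinatorial compound must
#' carry an integer total charge (to `tol`); otherwise a consistency error
#' is raised.
#'
#' @param topology a `multi_topology`
#' @param exempt list of `c(site, substituent)` character pairs naming
#'   substituents to leave untouched
#' @param tol tolerance on the integer-total-charge check (e)
#' @return list with `topology` (renormalized `multi_topology`) and `report`
#'   (a `charge_report`: per-atom adjustments, their RMSD, per-site targets)
#' @examples
#' # site with a 2-atom substituent at net +0.10 e and a 1-atom one at -0.02 e:
#' # target +0.04 e; adjustments -0.03, -0.03, +0.06; RMSD 0.0424 e
#' @export
renormalize_charges <- function(topology, exempt = list(), tol = 1e-6) {
  stopifnot(inherits(topology, "multi_topology"))
  exempt_keys <- vapply(exempt, function(p) {
    stopifnot(length(p) == 2)
    if (is.null(topology$sites[[p[1]]][[p[2]]]))
      stop(sprintf("exempt pair references unknown substituent '%s' at site '%s'",
                   p[2], p[1]))
    paste(p[1], p[2], sep = ":")
  }, character(1))

  sites <- topology$sites
  adj_rows <- list()
  targets <- setNames(numeric(length(sites)), names(sites))
  for (sn in names(sites)) {
    site <- sites[[sn]]
    is_ex <- paste(sn, names(site), sep = ":") %in% exempt_keys
    nets <- vapply(site, function(s) net_charge(s$graph), numeric(1))
    if (all(is_ex)) { targets[sn] <- NA_real_; next }
    target <- mean(nets[!is_ex])
    targets[sn] <- target
    for (bn in names(site)[!is_ex]) {
      g <- site[[bn]]$graph
      n_at <- nrow(g$atoms)
      delta <- (target - sum(g$atoms$charge)) / n_at
      g$atoms$charge <- g$atoms$charge + delta
      sites[[sn]][[bn]]$graph <- g
      adj_rows[[length(adj_rows) + 1L]] <- data.frame(
        site = sn, substituent = bn, atom_id = g$atoms$id,
        adjustment = rep(delta, n_at))
    }
  }
  adjustments <- if (length(adj_rows)) do.call(rbind, adj_rows) else
    data.frame(site = character(), substituent = character(),
               atom_id = integer(), adjustment = numeric())
  report <- structure(
    list(adjustments = adjustments,
         rmsd = if (nrow(adjustments)) sqrt(mean(adjustments$adjustment^2)) else 0,
         site_targets = targets),
    class = "charge_report")

  out <- multi_topology(topology$core, sites)
  # every combination of substituents must give back an integer total charge
  comp <- enumerate_compounds(out)
  dev <- abs(comp$total_charge - round(comp$total_charge))
  if (any(dev > tol)) {
    bad <- which.max(dev)
    stop(sprintf(paste0("charge renormalization: combination %s has ",
                        "non-integer total charge %.6f e"),
                 paste(unlist(comp[bad, names(topology$sites)]), collapse = "/"),
                 comp$total_charge[bad]))
  }
  list(topology = out, report = report)
}

#' @export
print.charge_report <- function(x, ...) {
  cat(sprintf("charge_report: %d atom adjustments, RMSD %.4f e\n",
              nrow(x$adjustments), x$rmsd))
  for (sn in names(x$site_targets))
    cat(sprintf("  site %s: target net %+0.4f e\n", sn, x$site_targets[sn]))
  invisible(x)
}

#' Export a multiple topology as structured text
#'
#' Writes a JSON document listing core atoms, site/substituent membership
#' with per-atom charges, anchors, and the cross-substituent exclusion list.
#'
#' @param topology a `multi_topology`
#' @param path output file path
#' @export
write_multi_topology <- function(topology, path) {
  sites <- lapply(topology$sites, function(site)
    lapply(site, function(s)
      list(anchor = s$anchor, atoms = s$graph$atoms, bonds = s$graph$bonds)))
  jsonlite::write_json(
    list(core = list(atoms = topology$core$atoms, bonds = topology$core$bonds),
         sites = sites,
         exclusions = exclusion_list(topology)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
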