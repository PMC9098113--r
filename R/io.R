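# Delimited-text I/O with provenance headers. Every artifact is plain text:
# '#'-prefixed key:value header lines (seed, temperature, units, version)
# followed by a tab-separated table. Readers round-trip writers exactly.

provenance_header <- function(meta) {
  meta$package <- as.character(utils::packageVersion("rbfekit"))
  vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 17), collapse = ",")),
    character(1))
}

parse_header <- function(lines) {
  hdr <- lines[startsWith(lines, "# ")]
  out <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*: ?", "", kv)
    out[[k]] <- v
  }
  out
}

write_table_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(meta), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a lambda trajectory as delimited text
#'
#' Tab-separated frames of per-state lambda values with a provenance header
#' (seed, temperature, sampling interval, applied biases, units).
#'
#' @param traj a `lambda_trajectory`
#' @param path file path
#' @return `read_lambda_trajectory` returns a `lambda_trajectory`
#' @export
write_lambda_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lambda_trajectory"))
  df <- as.data.frame(traj$lambda)
  meta <- list(artifact = "lambda_trajectory", seed = traj$seed,
               temperature_K = traj$temperature, phase = traj$phase,
               interval = traj$interval,
               bias_kcal_mol = paste(names(traj$bias), traj$bias,
                                     sep = "=", collapse = ";"),
               units = "lambda dimensionless")
  write_table_with_header(df, path, meta)
}

#' @rdname write_lambda_trajectory
#' @export
read_lambda_trajectory <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- lines[!startsWith(lines, "# ")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  cols <- strsplit(colnames(df), ":", fixed = TRUE)
  idx <- data.frame(site = vapply(cols, `[[`, character(1), 1),
                    substituent = vapply(cols, `[[`, character(1), 2))
  bias_pairs <- strsplit(strsplit(meta$bias_kcal_mol, ";", fixed = TRUE)[[1]],
                         "=", fixed = TRUE)
  bias <- stats::setNames(vapply(bias_pairs, function(p) as.numeric(p[2]), numeric(1)),
                          vapply(bias_pairs, `[[`, character(1), 1))
  structure(list(lambda = as.matrix(df), x = NULL, index = idx,
                 bias = bias[colnames(df)],
                 temperature = as.numeric(meta$temperature_K),
                 phase = meta$phase, seed = as.numeric(meta$seed),
                 interval = as.numeric(meta$interval)),
            class = "lambda_trajectory")
}

#' Write / read per-window energy-difference samples as delimited text
#'
#' Long-format table (`pair`, `lambda_lo`, `lambda_hi`, `direction`,
#' `delta_u`) with a provenance header.
#'
#' @param samples a `window_samples`
#' @param path file path
#' @return `read_window_samples` returns a `window_samples`
#' @export
write_window_samples <- function(samples, path) {
  stopifnot(inherits(samples, "window_samples"))
  n_pair <- length(samples$fwd)
  rows <- list()
  for (w in seq_len(n_pair)) {
    if (length(samples$fwd[[w]]))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = w, lambda_lo = samples$lambda[w], lambda_hi = samples$lambda[w + 1],
        direction = "fwd", delta_u = samples$fwd[[w]])
    if (length(samples$rev[[w]]))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = w, lambda_lo = samples$lambda[w], lambda_hi = samples$lambda[w + 1],
        direction = "rev", delta_u = samples$rev[[w]])
  }
  df <- do.call(rbind, rows)
  meta <- list(artifact = "window_samples", seed = samples$seed,
               temperature_K = samples$temperature, phase = samples$phase,
               site = samples$site, from = samples$from, to = samples$to,
               n_eq = samples$n_eq, n_collect = samples$n_collect,
               lambda = paste(format(samples$lambda, digits = 17), collapse = ";"),
               units = "delta_u kcal/mol")
  write_table_with_header(df, path, meta)
}

#' @rdname write_window_samples
#' @export
read_window_samples <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines)
  body <- lines[!startsWith(lines, "# ")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  lambda <- as.numeric(strsplit(meta$lambda, ";", fixed = TRUE)[[1]])
  n_pair <- length(lambda) - 1
  fwd <- rev_ <- vector("list", n_pair)
  for (w in seq_len(n_pair)) {
    fwd[[w]] <- df$delta_u[df$pair == w & df$direction == "fwd"]
    rev_[[w]] <- df$delta_u[df$pair == w & df$direction == "rev"]
  }
  structure(list(lambda = lambda, fwd = fwd, rev = rev_,
                 temperature = as.numeric(meta$temperature_K),
                 phase = meta$phase, site = meta$site, from = meta$from,
                 to = meta$to, n_eq = as.numeric(meta$n_eq),
                 n_collect = as.numeric(meta$n_collect),
                 seed = as.numeric(meta$seed)),
            class = "window_samples")
}

#' Serialize / deserialize a toy system as a YAML configuration
#'
#' @param system a `toy_system`
#' @param path file path
#' @return `read_toy_system` returns a `toy_system`
#' @export
write_toy_system <- function(system, path) {
  stopifnot(inherits(system, "toy_system"))
  sites <- lapply(system$sites, function(site)
    lapply(site, function(sub)
      lapply(sub[c("solution", "complex")], function(p)
        list(k = p$k, x0 = p$x0, E0 = p$E0))))
  yaml::write_yaml(list(temperature = system$temperature,
                        reference = as.list(system$reference),
                        softcore = system$softcore, sites = sites),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_toy_system
#' @export
read_toy_system <- function(path) {
  x <- yaml::read_yaml(path)
  sites <- lapply(x$sites, function(site)
    lapply(site, function(sub)
      list(solution = toy_potential(sub$solution$k, sub$solution$x0, sub$solution$E0),
           complex = toy_potential(sub$complex$k, sub$complex$x0, sub$complex$E0))))
  toy_system(sites, temperature = x$temperature,
             reference = unlist(x$reference), softcore = x$softcore)
}
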