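#' Receptor bond graph of a world
#'
#' Builds the undirected graph whose nodes are the receptors and whose edges
#' are (i) receptor-receptor dimer bonds, (ii) pairs of receptors bridged by
#' the two epitopes of one divalent ligand and (iii) pairs bridged by the two
#' sites of one crosslinker.  Connected components of this graph are the
#' receptor complexes counted by the census; cluster membership is defined
#' purely by bonds, not by spatial proximity.
#'
#' @param world an `abm_world`.
#' @return an [igraph::graph] with `length(world$rx)` vertices.
#' @export
build_bond_graph <- function(world) {
  nR <- length(world$rx)
  dimer <- world$dimer
  ## integrity: dimer bonds must be symmetric, site bonds must back-reference
  bonded <- which(!is.na(dimer))
  back <- dimer[dimer[bonded]]
  if (any(is.na(back)) || any(back != bonded)) {
    stop("integrity error: asymmetric dimer bond fields")
  }
  for (s in c("ls1", "ls2")) {
    r <- world[[s]]
    bad <- !is.na(r) & (is.na(world$lig[r]) | world$lig[r] != seq_along(r))
    if (any(bad)) stop("integrity error: ligand bond fields inconsistent")
  }
  for (s in c("xs1", "xs2")) {
    r <- world[[s]]
    bad <- !is.na(r) & (is.na(world$xl[r]) | world$xl[r] != seq_along(r))
    if (any(bad)) stop("integrity error: crosslinker bond fields inconsistent")
  }
  e_dimer <- which(!is.na(dimer) & dimer > seq_along(dimer))
  edges <- rbind(
    cbind(e_dimer, dimer[e_dimer]),
    cbind(world$ls1, world$ls2)[!is.na(world$ls1) & !is.na(world$ls2), ,
                                drop = FALSE],
    cbind(world$xs1, world$xs2)[!is.na(world$xs1) & !is.na(world$xs2), ,
                                drop = FALSE]
  )
  g <- igraph::make_empty_graph(n = nR, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::simplify(g)
}

#' Cluster census of a receptor bond graph
#'
#' Connected-component size histogram binned as 1, 2, 3, 4 and >4 receptors
#' per complex, with the fraction of receptors in each bin and the fraction
#' of receptors phosphorylated.  The size-weighted sum of complex counts
#' always equals the receptor number.
#'
#' @param graph a receptor bond graph from [build_bond_graph()].
#' @param phosphorylated logical/0-1 vector of per-receptor phosphorylation
#'   flags (same length as the vertex set).
#' @param tick tick label carried into the output.
#' @return a one-row `data.frame` with columns `tick`, `n_size_1..4`,
#'   `n_size_gt4`, `receptors_in_gt4`, `max_size`, `n_phosphorylated`,
#'   `frac_receptors_in_size_1..4`, `frac_receptors_gt4`,
#'   `frac_phosphorylated`.
#' @export
census <- function(graph, phosphorylated = NULL, tick = NA_integer_) {
  nR <- igraph::vcount(graph)
  if (is.null(phosphorylated)) phosphorylated <- rep(0L, nR)
  if (length(phosphorylated) != nR) {
    stop("invalid input: phosphorylation flags do not match the vertex set")
  }
  comp <- igraph::components(graph)
  sizes <- comp$csize
  n_k <- vapply(1:4, function(k) sum(sizes == k), 0L)
  gt4 <- sizes > 4
  out <- data.frame(
    tick = tick,
    n_size_1 = n_k[1], n_size_2 = n_k[2], n_size_3 = n_k[3],
    n_size_4 = n_k[4], n_size_gt4 = sum(gt4),
    receptors_in_gt4 = sum(sizes[gt4]),
    max_size = if (length(sizes)) max(sizes) else 0L,
    n_phosphorylated = sum(phosphorylated > 0)
  )
  for (k in 1:4) {
    out[[paste0("frac_receptors_in_size_", k)]] <- k * n_k[k] / nR
  }
  out$frac_receptors_gt4 <- out$receptors_in_gt4 / nR
  out$frac_phosphorylated <- out$n_phosphorylated / nR
  out
}

#' Census of a world (bond graph + phosphorylation flags)
#' @param world an `abm_world`.
#' @return as [census()], with the world's tick.
#' @export
world_census <- function(world) {
  census(build_bond_graph(world), world$phos, tick = world$tick)
}

#' Steady-state summary of a census time series
#'
#' Per-field mean over the final `window` recorded ticks.  The figures of
#' interest report the state at 3000 ticks; a window of 1 reproduces the
#' final-tick readout, a wider window reduces replicate variance.
#'
#' @param census_series a census `data.frame` (one row per recorded tick).
#' @param window number of trailing rows to average (default
#'   `min(500, nrow)`).
#' @return a one-row `data.frame` of means (the `tick` column reports the
#'   last tick in the window).
#' @export
summarize_timeseries <- function(census_series, window = NULL) {
  n <- nrow(census_series)
  if (is.null(n) || n == 0L) stop("invalid input: empty census series")
  if (is.null(window)) window <- min(500L, n)
  if (window < 1L || window > n) {
    stop("invalid input: window must lie in [1, nrow(census_series)]")
  }
  tail_rows <- census_series[seq.int(n - window + 1L, n), , drop = FALSE]
  out <- as.data.frame(lapply(tail_rows, mean))
  out$tick <- census_series$tick[n]
  out
}
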