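#' Exact stochastic simulation of ligand-receptor binding
#'
#' Direct-method Gillespie simulation of the sequential multivalent binding
#' network in integer copy numbers: an exponential waiting time is drawn from
#' the total propensity and the next reaction is chosen with probability
#' proportional to its propensity.  In ligand-excess mode the first binding
#' step is pseudo-first-order with constant ligand concentration; in
#' depletion mode ligand copies are tracked explicitly and concentrations are
#' converted to copy numbers through the reaction `volume`.  Receptor copies
#' are conserved exactly at every event.
#'
#' With few receptors the occupancy fluctuates strongly between runs; the
#' ensemble mean over many replicates converges to the deterministic
#' solution as copy numbers grow.
#'
#' @param scenario a [binding_scenario()]; `ligand_total` supplies the molar
#'   ligand concentration.
#' @param rates a [rate_constants()] object, recycled over binding steps.
#' @param n_receptors initial number of free receptor copies (>= 1).
#' @param t_max simulated time horizon, seconds.
#' @param seed optional integer seed (applied via [set.seed()]); identical
#'   seed and parameters give a bit-identical event sequence.
#' @param volume reaction volume in litres used to convert molar
#'   concentrations to copy numbers for the bimolecular steps (default 1 fL).
#' @return a `data.frame` of class `ssa_trajectory` with one row per event
#'   (plus the initial state and a right-extension to `t_max`): columns
#'   `time`, `free_receptor`, `bound1..boundV`, `bound_receptors`,
#'   `occupancy`, and `free_ligand` in depletion mode.
#' @examples
#' sc <- binding_scenario(valency = 1, ligand_total = 1e-6)
#' tr <- gillespie_run(sc, rate_constants(1e6, 1), n_receptors = 100,
#'                     t_max = 5, seed = 1)
#' tail(tr, 1)$occupancy   # near 0.5 at KD
#' @export
gillespie_run <- function(scenario, rates, n_receptors, t_max,
                          seed = NULL, volume = 1e-15) {
  stopifnot(inherits(scenario, "binding_scenario"),
            inherits(rates, "rate_constants"))
  if (n_receptors < 1) stop("invalid parameter: n_receptors must be >= 1")
  if (t_max <= 0) stop("invalid parameter: t_max must be > 0")
  if (!is.null(seed)) set.seed(seed)
  v <- scenario$valency
  k_on <- rep_len(rates$k_on, v)
  k_off <- rep_len(rates$k_off, v)
  avogadro <- 6.02214076e23
  conv <- avogadro * volume            # copies per molar
  excess <- scenario$ligand_excess
  nL <- if (excess) NA_integer_ else round(scenario$ligand_total * conv)

  nR <- as.integer(n_receptors)
  nC <- integer(v)
  t_now <- 0

  cap <- 1024L
  ncol_state <- 2L + v + as.integer(!excess)
  rec <- matrix(0, nrow = cap, ncol = ncol_state)
  n_rec <- 1L
  snapshot <- function() {
    if (excess) c(t_now, nR, nC) else c(t_now, nL, nR, nC)
  }
  rec[1L, ] <- snapshot()

  repeat {
    ## propensities: per step j, bind then unbind
    lig_pool <- if (excess) scenario$ligand_total else nL / conv
    subst <- c(lig_pool * conv, nC[-v])       # copies of each step's substrate
    a_bind <- k_on / conv * subst * nR
    a_unbind <- k_off * nC
    a <- c(a_bind, a_unbind)
    a0 <- sum(a)
    if (a0 <= 0) break                        # absorbing state
    t_next <- t_now + stats::rexp(1L, a0)
    if (t_next > t_max) break
    t_now <- t_next
    j <- sample.int(2L * v, 1L, prob = a)
    if (j <= v) {                             # binding step j
      if (j == 1L) {
        if (!excess) nL <- nL - 1L
      } else {
        nC[j - 1L] <- nC[j - 1L] - 1L
      }
      nR <- nR - 1L
      nC[j] <- nC[j] + 1L
    } else {                                  # unbinding step j - v
      s <- j - v
      nC[s] <- nC[s] - 1L
      if (s == 1L) {
        if (!excess) nL <- nL + 1L
      } else {
        nC[s - 1L] <- nC[s - 1L] + 1L
      }
      nR <- nR + 1L
    }
    n_rec <- n_rec + 1L
    if (n_rec > cap) {
      cap <- cap * 2L
      rec <- rbind(rec, matrix(0, nrow = cap / 2L, ncol = ncol_state))
    }
    rec[n_rec, ] <- snapshot()
  }
  ## right-extend the (piecewise-constant) path to t_max
  t_now <- t_max
  n_rec <- n_rec + 1L
  if (n_rec > cap) rec <- rbind(rec, matrix(0, 1L, ncol_state))
  rec[n_rec, ] <- snapshot()

  rec <- rec[seq_len(n_rec), , drop = FALSE]
  cols <- if (excess) {
    c("time", "free_receptor", paste0("bound", seq_len(v)))
  } else {
    c("time", "free_ligand_copies", "free_receptor",
      paste0("bound", seq_len(v)))
  }
  out <- as.data.frame(rec)
  names(out) <- cols
  bound_cols <- as.matrix(out[paste0("bound", seq_len(v))])
  out$bound_receptors <- as.vector(bound_cols %*% seq_len(v))
  out$occupancy <- out$bound_receptors / n_receptors
  attr(out, "n_receptors") <- as.integer(n_receptors)
  class(out) <- c("ssa_trajectory", "data.frame")
  out
}

#' Ensemble summary of stochastic trajectories
#'
#' Resamples event trajectories onto a common output time grid by
#' last-observation-carried-forward (sample paths are piecewise constant, so
#' this is exact) and summarises a chosen column across replicates with the
#' per-time mean and quantiles (defaults 5% and 95%).
#'
#' @param replicates a list of `ssa_trajectory` objects (>= 2).
#' @param times output time grid; defaults to 101 equispaced points spanning
#'   the common horizon.
#' @param quantiles quantile levels for the band.
#' @param column trajectory column to summarise (default `"occupancy"`).
#' @return a `data.frame` with columns `time`, `mean`, and one `q<level>`
#'   column per requested quantile.
#' @export
ensemble_stats <- function(replicates, times = NULL,
                           quantiles = c(0.05, 0.95),
                           column = "occupancy") {
  if (!is.list(replicates) || length(replicates) < 2L) {
    stop("invalid input: need at least 2 replicate trajectories")
  }
  if (is.null(times)) {
    horizon <- min(vapply(replicates, function(tr) max(tr$time), 0))
    times <- seq(0, horizon, length.out = 101L)
  }
  vals <- vapply(replicates, function(tr) {
    idx <- findInterval(times, tr$time)
    idx[idx < 1L] <- 1L
    tr[[column]][idx]
  }, numeric(length(times)))
  qs <- t(apply(vals, 1L, stats::quantile, probs = quantiles, names = FALSE))
  out <- data.frame(time = times, mean = rowMeans(vals))
  for (i in seq_along(quantiles)) {
    out[[paste0("q", format(quantiles[i] * 100, trim = TRUE))]] <- qs[, i]
  }
  out
}
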