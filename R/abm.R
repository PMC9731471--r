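#' Crosslinker and ligand affinity presets
#'
#' Per-site (on, off) tick probabilities for the built-in affinity classes.
#' Presets are parameterised by their stationary per-site occupancy
#' `p_on / (p_on + p_off)`: 0.4 for the moderate crosslinker, 0.9 for the
#' high-affinity crosslinker (a tandem-SH2 protein concentrated at the
#' membrane).  Squaring the per-site value gives the expected fraction of
#' ticks a divalent agent bridges two receptors: 16/100 (moderate) and
#' 81/100 (high).
#'
#' @param affinity `"moderate"` or `"high"`.
#' @return named numeric vector `c(p_on = , p_off = )`.
#' @export
crosslinker_preset <- function(affinity = c("moderate", "high")) {
  affinity <- match.arg(affinity)
  switch(affinity,
         moderate = c(p_on = 0.4, p_off = 0.6),
         high = c(p_on = 0.9, p_off = 0.1))
}

#' Probability that both sites of a divalent agent are bound
#'
#' Under the independent-site assumption, a divalent crosslinker or ligand
#' bridges two receptors for the square of its per-site occupancy: 0.4 ->
#' 0.16 (moderate crosslinker), 0.9 -> 0.81 (high), 0.2 -> 0.04 (ligand
#' epitope), i.e. 16, 81 and 4 ticks out of 100 on average.
#'
#' @param per_site_occupancy per-site occupancy in `[0, 1]`.
#' @return `per_site_occupancy^2`.
#' @export
both_sites_bound_fraction <- function(per_site_occupancy) {
  if (any(!is.finite(per_site_occupancy)) ||
      any(per_site_occupancy < 0) || any(per_site_occupancy > 1)) {
    stop("invalid parameter: per_site_occupancy must lie in [0, 1]")
  }
  per_site_occupancy^2
}

abm_prob_fields <- c("p_phos_on", "p_phos_off", "p_dim_on", "p_dim_off",
                     "p_xl_on", "p_xl_off", "p_lig_on", "p_lig_off")

#' Configuration of the lattice agent-based model
#'
#' A 21 x 21 toroidal patch world (441 patches).  All event probabilities
#' are per-tick Bernoulli probabilities; values quoted "per 100 ticks"
#' divide by 100.  Defaults give 100 receptors, crosslinkers and divalent
#' ligands, 3000 ticks and 30 replicates; the basal phosphorylation pair
#' (0.01, 0.09) has stationary fraction 10% and the basal dimerisation pair
#' is calibrated so a crosslinker/ligand-free run settles at ~10% of
#' receptors in dimers.  Ligand epitopes attach and detach with probability
#' 0.20 each; a ligand-bound receptor phosphorylates at
#' `ligand_bound_phos_multiplier` times the basal rate.
#'
#' @param n_receptors,n_crosslinkers,n_ligands agent counts.
#' @param width lattice side length (default 21).
#' @param p_phos_on,p_phos_off per-tick phosphorylation probabilities.
#' @param p_dim_on,p_dim_off per-tick dimerisation probabilities
#'   (`p_dim_on` is contact-conditional: one trial per partner-free receptor
#'   in contact range, i.e. on the same patch or one of its 8 neighbours).
#' @param crosslinker_affinity `"moderate"` or `"high"`; sets
#'   `p_xl_on`/`p_xl_off` unless those are given explicitly.
#' @param p_xl_on,p_xl_off per-tick crosslinker site probabilities
#'   (override the preset).
#' @param p_lig_on,p_lig_off per-tick ligand epitope probabilities.
#' @param ligand_bound_phos_multiplier phosphorylation rate multiplier for
#'   ligand-bound receptors.
#' @param cluster_slowdown if `TRUE` (default) complexes of more than three
#'   receptors move with probability `1/size` per tick; smaller complexes
#'   and free agents move every tick.
#' @param ticks run duration.
#' @param replicates default ensemble size.
#' @param seed optional default base seed used by the run functions.
#' @return an object of class `abm_config` (a validated list).
#' @export
abm_config <- function(n_receptors = 100, n_crosslinkers = 100,
                       n_ligands = 100, width = 21,
                       p_phos_on = 0.01, p_phos_off = 0.09,
                       p_dim_on = 0.003, p_dim_off = 0.10,
                       crosslinker_affinity = "moderate",
                       p_xl_on = NULL, p_xl_off = NULL,
                       p_lig_on = 0.20, p_lig_off = 0.20,
                       ligand_bound_phos_multiplier = 2,
                       cluster_slowdown = TRUE,
                       ticks = 3000, replicates = 30, seed = NULL) {
  preset <- crosslinker_preset(crosslinker_affinity)
  if (is.null(p_xl_on)) p_xl_on <- unname(preset["p_on"])
  if (is.null(p_xl_off)) p_xl_off <- unname(preset["p_off"])
  cfg <- structure(
    list(n_receptors = as.integer(n_receptors),
         n_crosslinkers = as.integer(n_crosslinkers),
         n_ligands = as.integer(n_ligands),
         width = as.integer(width),
         p_phos_on = p_phos_on, p_phos_off = p_phos_off,
         p_dim_on = p_dim_on, p_dim_off = p_dim_off,
         crosslinker_affinity = crosslinker_affinity,
         p_xl_on = p_xl_on, p_xl_off = p_xl_off,
         p_lig_on = p_lig_on, p_lig_off = p_lig_off,
         ligand_bound_phos_multiplier = ligand_bound_phos_multiplier,
         cluster_slowdown = isTRUE(cluster_slowdown),
         ticks = as.integer(ticks), replicates = as.integer(replicates),
         seed = seed),
    class = "abm_config"
  )
  validate_abm_config(cfg)
}

validate_abm_config <- function(cfg) {
  counts <- c("n_receptors", "n_crosslinkers", "n_ligands")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop("validation error: ", f, " must be a count >= 0")
    }
  }
  if (cfg$width < 2) stop("validation error: width must be >= 2")
  for (f in abm_prob_fields) {
    p <- cfg[[f]]
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("validation error: ", f, " must be a probability in [0, 1]")
    }
  }
  if (cfg$ligand_bound_phos_multiplier < 0) {
    stop("validation error: ligand_bound_phos_multiplier must be >= 0")
  }
  if (cfg$ticks < 1) stop("validation error: ticks must be >= 1")
  if (cfg$replicates < 1) stop("validation error: replicates must be >= 1")
  cfg
}

#' @export
print.abm_config <- function(x, ...) {
  cat("ABM config:", x$n_receptors, "receptors,", x$n_crosslinkers,
      "crosslinkers (", x$crosslinker_affinity, "),", x$n_ligands,
      "divalent ligands on a", x$width, "x", x$width, "torus\n")
  cat(sprintf("  phos on/off %.3g/%.3g  dim on/off %.3g/%.3g  xl on/off %.3g/%.3g  lig on/off %.3g/%.3g\n",
              x$p_phos_on, x$p_phos_off, x$p_dim_on, x$p_dim_off,
              x$p_xl_on, x$p_xl_off, x$p_lig_on, x$p_lig_off))
  cat("  ", x$ticks, "ticks x", x$replicates, "replicates\n")
  invisible(x)
}

## engine boundary: R worlds use 1-based indices with NA for "unbound";
## the C++ engine uses 0-based with -1.
to_engine_idx <- function(x) {
  x <- as.integer(x)
  x[is.na(x)] <- 0L
  x - 1L
}
from_engine_idx <- function(x) {
  x <- as.integer(x)
  x[x < 0L] <- NA_integer_
  x + 1L
}

world_to_engine <- function(world) {
  w <- world
  for (f in c("dimer", "lig", "xl", "ls1", "ls2", "xs1", "xs2")) {
    w[[f]] <- to_engine_idx(w[[f]])
  }
  for (f in c("ligsite", "xlsite")) w[[f]] <- to_engine_idx(w[[f]])
  w
}
world_from_engine <- function(w) {
  for (f in c("dimer", "lig", "xl", "ls1", "ls2", "xs1", "xs2",
              "ligsite", "xlsite")) {
    w[[f]] <- from_engine_idx(w[[f]])
  }
  class(w) <- "abm_world"
  w
}

#' Initialise an agent-based world
#'
#' Agents are placed uniformly at random on the lattice with all bonds empty;
#' initial phosphorylation of each receptor is drawn from the stationary
#' basal fraction `p_phos_on / (p_phos_on + p_phos_off)` (10% at defaults).
#'
#' @param config an [abm_config()].
#' @param seed optional integer seed (via [set.seed()]).
#' @return an object of class `abm_world`: a list of per-agent state vectors
#'   (`rx`, `ry`, `phos`, `dimer`, `lig`, `ligsite`, `xl`, `xlsite` for
#'   receptors; `lx`, `ly`, `ls1`, `ls2` for ligands; `xx`, `xy`, `xs1`,
#'   `xs2` for crosslinkers) plus `width` and `tick`.  Bond fields hold the
#'   1-based index of the bonded partner agent, or `NA`.
#' @export
init_world <- function(config, seed = NULL) {
  stopifnot(inherits(config, "abm_config"))
  if (config$n_receptors < 1) {
    stop("invalid config: need at least one receptor")
  }
  if (!is.null(seed)) set.seed(seed)
  W <- config$width
  nR <- config$n_receptors
  nL <- config$n_ligands
  nX <- config$n_crosslinkers
  basal <- if (config$p_phos_on + config$p_phos_off > 0) {
    config$p_phos_on / (config$p_phos_on + config$p_phos_off)
  } else 0
  world <- list(
    width = W, tick = 0L,
    rx = sample.int(W, nR, replace = TRUE) - 1L,
    ry = sample.int(W, nR, replace = TRUE) - 1L,
    phos = as.integer(stats::runif(nR) < basal),
    dimer = rep(NA_integer_, nR), lig = rep(NA_integer_, nR),
    ligsite = rep(NA_integer_, nR), xl = rep(NA_integer_, nR),
    xlsite = rep(NA_integer_, nR),
    lx = sample.int(W, nL, replace = TRUE) - 1L,
    ly = sample.int(W, nL, replace = TRUE) - 1L,
    ls1 = rep(NA_integer_, nL), ls2 = rep(NA_integer_, nL),
    xx = sample.int(W, nX, replace = TRUE) - 1L,
    xy = sample.int(W, nX, replace = TRUE) - 1L,
    xs1 = rep(NA_integer_, nX), xs2 = rep(NA_integer_, nX)
  )
  class(world) <- "abm_world"
  world
}

#' @export
print.abm_world <- function(x, ...) {
  cat("ABM world at tick", x$tick, ":", length(x$rx), "receptors,",
      length(x$lx), "ligands,", length(x$xx), "crosslinkers on a",
      x$width, "x", x$width, "torus\n")
  cen <- world_census(x)
  cat("  complexes 1/2/3/4/>4:",
      paste(cen[c("n_size_1", "n_size_2", "n_size_3", "n_size_4",
                  "n_size_gt4")], collapse = "/"),
      " phosphorylated:", round(100 * cen$frac_phosphorylated), "%\n")
  invisible(x)
}

#' Advance a world by one or more ticks
#'
#' One tick applies, in order: movement (bound complexes move as one unit; a
#' complex of more than three receptors moves with probability 1/size),
#' unbinding (each bond breaks independently with its off-probability),
#' binding, and phosphorylation (a crosslinker-occupied tail never
#' dephosphorylates; ligand-bound receptors phosphorylate at the multiplied
#' rate).  Binding is bimolecular and contact-based: in randomized agent
#' order, each free site runs one Bernoulli trial per eligible receptor in
#' contact range (own patch + 8 neighbours); dimerisation needs two
#' partner-free receptors, a ligand epitope a receptor with a free
#' extracellular site, a crosslinker site a phosphorylated receptor with a
#' free tail, and the second site of a divalent agent a receptor from a
#' different complex.
#'
#' @param world an `abm_world`.
#' @param config the matching [abm_config()].
#' @param n_ticks number of ticks to advance (default 1).
#' @return the updated `abm_world`.
#' @export
abm_tick <- function(world, config, n_ticks = 1L) {
  stopifnot(inherits(config, "abm_config"))
  res <- abm_engine(world_to_engine(world), config, as.integer(n_ticks), 0L)
  world_from_engine(res$world)
}

engine_census_frame <- function(mat, n_receptors) {
  cn <- c("tick", "n_size_1", "n_size_2", "n_size_3", "n_size_4",
          "n_size_gt4", "receptors_in_gt4", "max_size", "n_phosphorylated")
  df <- as.data.frame(mat)
  names(df) <- cn
  for (k in 1:4) {
    df[[paste0("frac_receptors_in_size_", k)]] <-
      k * df[[paste0("n_size_", k)]] / n_receptors
  }
  df$frac_receptors_gt4 <- df$receptors_in_gt4 / n_receptors
  df$frac_phosphorylated <- df$n_phosphorylated / n_receptors
  df
}

#' Run a single ABM replicate
#'
#' Initialises a world from `config` and advances it `config$ticks` ticks,
#' recording a cluster census of the receptor bond graph along the way.
#'
#' @param config an [abm_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param census_stride record the census every this many ticks (default 1;
#'   the final tick is always recorded).
#' @return a list with `census` (a `data.frame`: one row per recorded tick
#'   with complex counts by size 1/2/3/4/>4, receptor fractions per bin,
#'   `max_size` and the phosphorylated fraction) and `world` (the final
#'   `abm_world`).
#' @export
run_simulation <- function(config, seed = config$seed, census_stride = 1L) {
  stopifnot(inherits(config, "abm_config"))
  if (config$n_receptors < 1) stop("invalid config: need >= 1 receptor")
  if (!is.null(seed)) set.seed(seed)
  world <- init_world(config)
  res <- abm_engine(world_to_engine(world), config, config$ticks,
                    as.integer(census_stride))
  list(census = engine_census_frame(res$census, config$n_receptors),
       world = world_from_engine(res$world))
}

#' Counter-based replicate seeds
#'
#' Deterministically derives the seed of replicate `k` from a base seed, so
#' ensembles are reproducible replicate-by-replicate.
#'
#' @param base_seed integer base seed.
#' @param k replicate counter (1, 2, ...).
#' @return integer seed below 2^31.
#' @export
replicate_seed <- function(base_seed, k) {
  as.integer((as.numeric(base_seed) %% 2147483647 + 1000003 * k) %% 2147483647)
}

#' Run an ensemble of ABM replicates
#'
#' Repeats [run_simulation()] with counter-derived seeds and summarises the
#' final-tick census across replicates (mean and sample s.d. per field),
#' alongside the per-tick ensemble mean time series.
#'
#' @param config an [abm_config()].
#' @param n_replicates number of replicates (default `config$replicates`).
#' @param base_seed base seed from which replicate seeds are derived.
#' @param census_stride census recording stride within each replicate
#'   (default 10 to keep the time series light; the final tick is always
#'   recorded exactly).
#' @return a list with `final` (data.frame of per-field `mean` and `sd` at
#'   the final tick), `final_replicates` (data.frame, one row per
#'   replicate), and `timeseries` (per-tick ensemble means).
#' @export
run_ensemble <- function(config, n_replicates = config$replicates,
                         base_seed = 1L, census_stride = 10L) {
  stopifnot(inherits(config, "abm_config"))
  if (n_replicates < 2) stop("invalid parameter: n_replicates must be >= 2")
  finals <- vector("list", n_replicates)
  ts_sum <- NULL
  for (k in seq_len(n_replicates)) {
    sim <- run_simulation(config, seed = replicate_seed(base_seed, k),
                          census_stride = census_stride)
    finals[[k]] <- sim$census[nrow(sim$census), , drop = FALSE]
    ts <- as.matrix(sim$census)
    ts_sum <- if (is.null(ts_sum)) ts else ts_sum + ts
  }
  finals <- do.call(rbind, finals)
  rownames(finals) <- NULL
  num <- setdiff(names(finals), "tick")
  final <- data.frame(
    field = num,
    mean = vapply(num, function(f) mean(finals[[f]]), 0),
    sd = vapply(num, function(f) stats::sd(finals[[f]]), 0),
    row.names = NULL
  )
  timeseries <- as.data.frame(ts_sum / n_replicates)
  list(final = final, final_replicates = finals, timeseries = timeseries)
}

final_mean <- function(ensemble, field) {
  ensemble$final$mean[match(field, ensemble$final$field)]
}
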