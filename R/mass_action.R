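#' Equilibrium receptor occupancy for a monovalent ligand
#'
#' Fractional occupancy of a monomeric receptor by a monovalent ligand in
#' vast excess, at equilibrium: `[LR]/Rtot = [L] / (KD + [L])`.  The KD is the
#' ligand concentration occupying 50% of the receptors; >95% occupancy
#' requires a 19-fold higher concentration.
#'
#' @param ligand_conc free ligand concentration(s), molar.
#' @param kd equilibrium dissociation constant, molar.
#' @return fractional occupancy in `[0, 1)`, same length as `ligand_conc`.
#' @examples
#' equilibrium_occupancy(1e-6, 1e-6)      # 0.5
#' equilibrium_occupancy(19e-6, 1e-6)     # 0.95
#' @export
equilibrium_occupancy <- function(ligand_conc, kd) {
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0) {
    stop("invalid parameter: kd must be a single positive number")
  }
  if (any(!is.finite(ligand_conc)) || any(ligand_conc < 0)) {
    stop("invalid parameter: ligand_conc must be >= 0")
  }
  ligand_conc / (kd + ligand_conc)
}

#' Fold-excess of ligand over KD required for a target occupancy
#'
#' Inverts the equilibrium occupancy relation: occupancy f requires
#' `[L]/KD = f / (1 - f)`.  For f = 0.95 this is 19.
#'
#' @param target_fraction desired equilibrium occupancy, strictly in (0, 1).
#' @return the ratio `[L]/KD` (dimensionless fold over KD).
#' @examples
#' fold_for_occupancy(0.95)  # 19
#' fold_for_occupancy(0.5)   # 1: definition of KD
#' @export
fold_for_occupancy <- function(target_fraction) {
  if (any(!is.finite(target_fraction)) ||
      any(target_fraction <= 0) || any(target_fraction >= 1)) {
    stop("invalid parameter: target_fraction must lie strictly in (0, 1)")
  }
  target_fraction / (1 - target_fraction)
}

#' Kinetics of monovalent binding under ligand excess
#'
#' Closed-form solution of the linear binding ODE with constant free ligand:
#' `LR(t) = Rtot * [L]/(KD+[L]) * (1 - exp(-(k1*[L] + k-1) * t))`, starting
#' from fully free receptor.  Expressed as a fraction of `Rtot` the time
#' course is independent of the receptor concentration.
#'
#' @param ligand_conc free ligand concentration, molar (held constant).
#' @param rates a [rate_constants()] object; the first step's constants are
#'   used.
#' @param receptor_total total receptor concentration, molar.
#' @param times numeric vector of times (seconds), non-negative.
#' @return a `data.frame` of class `time_course` with columns `time`,
#'   `free_ligand`, `free_receptor`, `bound1` and `occupancy`.
#' @export
monovalent_timecourse <- function(ligand_conc, rates, receptor_total = 1e-6,
                                  times = seq(0, 10, by = 0.01)) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("invalid parameter: times must be >= 0")
  }
  if (ligand_conc < 0) stop("invalid parameter: ligand_conc must be >= 0")
  k1 <- rates$k_on[1]
  km1 <- rates$k_off[1]
  kd1 <- kd(rates, 1)
  eq <- receptor_total * ligand_conc / (kd1 + ligand_conc)
  bound <- eq * (1 - exp(-(k1 * ligand_conc + km1) * times))
  structure(
    data.frame(time = times,
               free_ligand = ligand_conc,
               free_receptor = receptor_total - bound,
               bound1 = bound,
               occupancy = bound / receptor_total),
    class = c("time_course", "data.frame")
  )
}

#' Time for monovalent binding to reach a fraction of its equilibrium
#'
#' Inverts the exponential approach to equilibrium: the bound concentration
#' reaches fraction `frac` of its equilibrium value at
#' `t = -log(1 - frac) / (k1*[L] + k-1)`.  Time to equilibrium therefore
#' decreases with increasing ligand concentration.
#'
#' @inheritParams monovalent_timecourse
#' @param frac fraction of the equilibrium value, strictly in (0, 1).
#' @return time in seconds.
#' @examples
#' r <- rate_constants(k_on = 1e6, k_off = 1)  # KD = 1 uM
#' # ligand set for 25/50/75% equilibrium occupancy:
#' time_to_equilibrium_fraction(1e-6 / 3, r, 0.95)  # 2.25 s
#' time_to_equilibrium_fraction(1e-6,     r, 0.95)  # 1.50 s
#' time_to_equilibrium_fraction(3e-6,     r, 0.95)  # 0.75 s
#' @export
time_to_equilibrium_fraction <- function(ligand_conc, rates, frac = 0.95) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(!is.finite(frac)) || any(frac <= 0) || any(frac >= 1)) {
    stop("invalid parameter: frac must lie strictly in (0, 1)")
  }
  if (ligand_conc < 0) stop("invalid parameter: ligand_conc must be >= 0")
  -log(1 - frac) / (rates$k_on[1] * ligand_conc + rates$k_off[1])
}

## ---- multivalent mass-action systems ---------------------------------------
##
## State layout for valency v: (L_free if depletion), R_free, C1 .. Cv where
## Cj is the concentration of ligand carrying j receptors.  Step j flux:
##   flux_j = k_on[j] * X_{j-1} * R - k_off[j] * C_j,   X_0 = L_free.

ma_derivs <- function(state, rates, valency, ligand_excess, ligand_total) {
  k_on <- rep_len(rates$k_on, valency)
  k_off <- rep_len(rates$k_off, valency)
  if (ligand_excess) {
    L <- ligand_total
    R <- state[1L]
    C <- state[-1L]
  } else {
    L <- state[1L]
    R <- state[2L]
    C <- state[-(1:2)]
  }
  X <- c(L, C[-valency])                      # substrate of each step
  flux <- k_on * X * R - k_off * C
  dC <- flux - c(flux[-1L], 0)
  dR <- -sum(flux)
  if (ligand_excess) c(dR, dC) else c(-flux[1L], dR, dC)
}

ma_initial_state <- function(scenario) {
  v <- scenario$valency
  if (scenario$ligand_excess) {
    c(scenario$receptor_total, numeric(v))
  } else {
    c(scenario$ligand_total, scenario$receptor_total, numeric(v))
  }
}

ma_species <- function(state, scenario) {
  state <- unname(state)
  v <- scenario$valency
  if (scenario$ligand_excess) {
    free_ligand <- scenario$ligand_total
    free_receptor <- state[1L]
    bound <- state[seq.int(2L, 1L + v)]
  } else {
    free_ligand <- state[1L]
    free_receptor <- state[2L]
    bound <- state[seq.int(3L, 2L + v)]
  }
  species_vector(free_ligand, free_receptor, bound, scenario)
}

#' @rdname solve_equilibrium
#' @param free_ligand,free_receptor,bound components of the species vector;
#'   `bound[j]` is the concentration of ligand carrying j receptors.
#' @param scenario the [binding_scenario()] the vector belongs to.
#' @export
species_vector <- function(free_ligand, free_receptor, bound, scenario) {
  structure(
    list(free_ligand = free_ligand, free_receptor = free_receptor,
         bound = as.numeric(bound), scenario = scenario),
    class = "species_vector"
  )
}

#' @export
print.species_vector <- function(x, ...) {
  v <- x$scenario$valency
  cat("Species concentrations [M] (valency ", v, ")\n", sep = "")
  cat("  free ligand  :", format(x$free_ligand, digits = 6), "\n")
  cat("  free receptor:", format(x$free_receptor, digits = 6), "\n")
  lbl <- paste0("L", if (v > 1) paste0("^", v) else "",
                vapply(seq_len(v), function(j)
                  paste(rep("R", j), collapse = ""), ""))
  for (j in seq_len(v)) {
    cat("  ", format(lbl[j], width = 13), ":",
        format(x$bound[j], digits = 6), "\n")
  }
  invisible(x)
}

#' Receptors bound per species-vector entry, and conservation checks
#' @param x a `species_vector`.
#' @return receptor concentration accounted for by `x` (molar).
#' @export
receptor_accounted <- function(x) {
  x$free_receptor + sum(seq_along(x$bound) * x$bound)
}

#' Equilibrium of a multivalent ligand / monomeric receptor system
#'
#' Computes the steady state of the sequential mass-action binding system for
#' a monovalent, divalent or tetravalent ligand.  The default method
#' integrates the ODE system to a long horizon with [deSolve::lsoda()] and
#' verifies that the residual time-derivative is numerically zero; the
#' `"algebraic"` method solves the detailed-balance relations
#' `bound[j] * free_receptor = KD[j+1] * bound[j+1]` together with the
#' conservation laws by one-dimensional root finding, and serves as an
#' independent cross-check of the integrator.
#'
#' In ligand-excess mode the free ligand concentration is pinned at
#' `ligand_total`; in depletion mode ligand is consumed by binding, which
#' right-shifts the occupancy curve.
#'
#' @param scenario a [binding_scenario()].
#' @param rates a [rate_constants()] object; constants are recycled over the
#'   scenario's binding steps.
#' @param method `"ode"` (long-time integration, the default) or
#'   `"algebraic"`.
#' @param deriv_tol convergence criterion for the ODE route: largest
#'   time-derivative relative to `receptor_total` per second.
#' @param t_max integration horizon cap (seconds) before a convergence error
#'   is raised.
#' @return a `species_vector` with elements `free_ligand`, `free_receptor`
#'   and `bound[1..valency]`.
#' @examples
#' sc <- binding_scenario(valency = 2, ligand_total = 1e-6)
#' solve_equilibrium(sc, rate_constants(1e6, 1))
#' @export
solve_equilibrium <- function(scenario, rates,
                              method = c("ode", "algebraic"),
                              deriv_tol = 1e-10, t_max = 1e7) {
  stopifnot(inherits(scenario, "binding_scenario"),
            inherits(rates, "rate_constants"))
  method <- match.arg(method)
  if (method == "algebraic") {
    return(ma_equilibrium_algebraic(scenario, rates))
  }
  v <- scenario$valency
  state <- ma_initial_state(scenario)
  rhs <- function(t, y, parms) {
    list(ma_derivs(y, rates, v, scenario$ligand_excess, scenario$ligand_total))
  }
  scale <- max(scenario$receptor_total, .Machine$double.eps)
  t_span <- 10 / max(rates$k_off[1], rates$k_on[1] * scenario$ligand_total,
                     1e-6)
  t_now <- 0
  repeat {
    sol <- deSolve::lsoda(y = state, times = c(0, t_span), func = rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12 * scale)
    state <- pmax(sol[nrow(sol), -1L], 0)
    d <- ma_derivs(state, rates, v, scenario$ligand_excess,
                   scenario$ligand_total)
    if (max(abs(d)) / scale < deriv_tol) break
    t_now <- t_now + t_span
    t_span <- t_span * 4
    if (t_now > t_max) {
      stop("convergence error: steady state not reached by t = ", t_now,
           " s (max |d/dt|/Rtot = ", format(max(abs(d)) / scale), ")")
    }
  }
  ma_species(state, scenario)
}

## Algebraic steady state: express every bound species through free R (and
## free L in depletion mode), then close the receptor conservation law with
## uniroot on free R over (0, Rtot).
ma_equilibrium_algebraic <- function(scenario, rates) {
  v <- scenario$valency
  kds <- kd(rates, v)
  Rtot <- scenario$receptor_total
  Ltot <- scenario$ligand_total
  if (Ltot == 0) {
    return(species_vector(0, Rtot, numeric(v), scenario))
  }
  bound_given <- function(R) {
    ## prod_{i<=j} (R / KD_i), cumulative ladder from one ligand molecule
    ladder <- cumprod(R / kds)
    if (scenario$ligand_excess) {
      L <- Ltot
      bound <- L * ladder
    } else {
      L <- Ltot / (1 + sum(ladder))
      bound <- L * ladder
    }
    list(L = L, bound = bound)
  }
  f <- function(R) {
    b <- bound_given(R)
    R + sum(seq_len(v) * b$bound) - Rtot
  }
  sol <- stats::uniroot(f, lower = 0, upper = Rtot, tol = 1e-15 * Rtot)
  b <- bound_given(sol$root)
  species_vector(b$L, sol$root, b$bound, scenario)
}

#' Equilibrium species over a grid of ligand concentrations
#'
#' Runs [solve_equilibrium()] once per ligand concentration and returns a
#' tidy table (one row per grid point, one column per species), the shape the
#' result writers expect.  On a semi-log axis the monovalent occupancy is
#' sigmoid; the divalent doubly bound species `L2RR` is bell-shaped with its
#' peak near `KD1`.
#'
#' @param scenario_template a [binding_scenario()] whose `ligand_total` is
#'   replaced by each grid value in turn.
#' @param ligand_grid ligand concentrations, molar; defaults to 61 log-spaced
#'   points spanning `KD1 / 1000` to `KD1 * 1000`.
#' @param rates a [rate_constants()] object.
#' @param method passed to [solve_equilibrium()]; the algebraic route is used
#'   by default for speed over dense grids.
#' @return a `data.frame` with columns `ligand_conc`, `free_ligand`,
#'   `free_receptor`, `bound1..boundV` and `occupancy` (fraction of total
#'   receptor bound in any species).
#' @export
concentration_response <- function(scenario_template,
                                   ligand_grid = NULL,
                                   rates = rate_constants(),
                                   method = "algebraic") {
  stopifnot(inherits(scenario_template, "binding_scenario"))
  if (is.null(ligand_grid)) {
    kd1 <- kd(rates, 1)[1]
    ligand_grid <- 10^seq(log10(kd1) - 3, log10(kd1) + 3, length.out = 61)
  }
  if (length(ligand_grid) == 0L) stop("invalid parameter: empty ligand_grid")
  if (any(!is.finite(ligand_grid)) || any(ligand_grid < 0)) {
    stop("invalid parameter: ligand_grid must be >= 0")
  }
  v <- scenario_template$valency
  rows <- lapply(seq_along(ligand_grid), function(i) {
    sc <- scenario_template
    sc$ligand_total <- ligand_grid[i]
    sv <- tryCatch(
      solve_equilibrium(sc, rates, method = method),
      error = function(e) {
        stop("equilibrium failed at ligand_conc = ", ligand_grid[i], ": ",
             conditionMessage(e))
      }
    )
    c(ligand_conc = ligand_grid[i], free_ligand = sv$free_ligand,
      free_receptor = sv$free_receptor,
      stats::setNames(sv$bound, paste0("bound", seq_len(v))),
      occupancy = sum(seq_len(v) * sv$bound) / sc$receptor_total)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Locate the peak of a (possibly bell-shaped) response curve
#'
#' Finds the grid point of the maximum and refines it by a local quadratic
#' interpolation (in log-concentration for positive geometric grids).  A
#' maximum on the first or last grid point is flagged as a boundary maximum,
#' i.e. the curve is not bell-shaped over the grid.
#'
#' @param ligand_grid concentrations, sorted ascending.
#' @param response numeric response values, same length.
#' @return a list with `ligand_at_max`, `max_value` and `boundary` (logical).
#' @export
find_curve_peak <- function(ligand_grid, response) {
  if (length(ligand_grid) != length(response)) {
    stop("invalid input: ligand_grid and response differ in length")
  }
  if (is.unsorted(ligand_grid, strictly = TRUE)) {
    stop("invalid input: ligand_grid must be sorted strictly ascending")
  }
  i <- which.max(response)
  n <- length(response)
  if (i == 1L || i == n) {
    return(list(ligand_at_max = ligand_grid[i], max_value = response[i],
                boundary = TRUE))
  }
  x <- ligand_grid[(i - 1):(i + 1)]
  ## interpolate in log-concentration only where the local spacing is
  ## geometric (log grids); otherwise stay linear
  use_log <- all(x > 0) &&
    abs(diff(diff(log(x)))) < 1e-8 * abs(mean(diff(log(x)))) &&
    abs(diff(diff(x))) > 1e-8 * abs(mean(diff(x)))
  if (use_log) x <- log10(x)
  y <- response[(i - 1):(i + 1)]
  ## vertex of the parabola through the three bracketing points
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) /
    denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) {                     # degenerate (flat/“valley”) neighbourhood
    xv <- x[2]
    yv <- y[2]
  } else {
    cc <- y[2] - a * x[2]^2 - b * x[2]
    xv <- min(max(-b / (2 * a), x[1]), x[3])
    yv <- max(a * xv^2 + b * xv + cc, y[2])
  }
  list(ligand_at_max = if (use_log) 10^xv else xv,
       max_value = yv, boundary = FALSE)
}
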