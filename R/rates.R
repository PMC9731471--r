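#' Rate constants for sequential multivalent binding steps
#'
#' Bundles the association and dissociation rate constants of each sequential
#' binding step of a multivalent ligand to a monomeric receptor, together with
#' the cooperativity modifiers of the second step.  Step i describes the
#' attachment of the i-th receptor to the ligand.  The equilibrium dissociation
#' constant of step i is `KD[i] = k_off[i] / k_on[i]`; for a divalent ligand
#' the coupled constant `KD3 = KD1 * KD2` (units M^2) links the fully bound
#' species to free ligand and two free receptors.
#'
#' When `alpha_plus` / `alpha_minus` are supplied with a single-step `k_on` /
#' `k_off`, the second-step constants are derived as
#' `k_on[2] = alpha_plus * k_on[1]` and `k_off[2] = alpha_minus * k_off[1]`,
#' and the cooperativity coefficient is `alpha = alpha_plus / alpha_minus`
#' (> 1 positive, = 1 neutral, < 1 negative cooperativity).
#'
#' @param k_on association rate constant(s), per-molar per-second; recycled to
#'   the number of binding steps required by a scenario.
#' @param k_off dissociation rate constant(s), per-second.
#' @param alpha_plus,alpha_minus optional multiplicative modifiers applied to
#'   the first-step constants to obtain the second-step constants.
#' @return an object of class `rate_constants` with elements `k_on`, `k_off`,
#'   `alpha_plus`, `alpha_minus`, `alpha`.
#' @examples
#' rate_constants(k_on = 1e6, k_off = 1)                    # KD = 1 uM
#' rate_constants(1e6, 1, alpha_plus = 10, alpha_minus = 1) # positive coop.
#' @export
rate_constants <- function(k_on = 1e6, k_off = 1,
                           alpha_plus = NULL, alpha_minus = NULL) {
  if (any(!is.finite(k_on)) || any(!is.finite(k_off)) ||
      any(k_on < 0) || any(k_off < 0)) {
    stop("invalid parameter: rate constants must be finite and >= 0")
  }
  alpha <- 1
  if (!is.null(alpha_plus) || !is.null(alpha_minus)) {
    if (is.null(alpha_plus)) alpha_plus <- 1
    if (is.null(alpha_minus)) alpha_minus <- 1
    if (alpha_plus < 0 || alpha_minus <= 0) {
      stop("invalid parameter: alpha_plus must be >= 0 and alpha_minus > 0")
    }
    if (length(k_on) != 1L || length(k_off) != 1L) {
      stop("alpha modifiers require scalar first-step k_on and k_off")
    }
    k_on <- c(k_on, alpha_plus * k_on)
    k_off <- c(k_off, alpha_minus * k_off)
    alpha <- alpha_plus / alpha_minus
  } else {
    alpha_plus <- alpha_minus <- 1
  }
  structure(
    list(k_on = as.numeric(k_on), k_off = as.numeric(k_off),
         alpha_plus = alpha_plus, alpha_minus = alpha_minus, alpha = alpha),
    class = "rate_constants"
  )
}

#' Equilibrium dissociation constants of each binding step
#'
#' @param rates a [rate_constants()] object.
#' @param n number of binding steps to return; constants are recycled in the
#'   same way the solvers recycle them.
#' @return numeric vector of `KD[i] = k_off[i] / k_on[i]` (molar).
#' @export
kd <- function(rates, n = length(rates$k_on)) {
  k_on <- rep_len(rates$k_on, n)
  k_off <- rep_len(rates$k_off, n)
  if (any(k_on <= 0)) stop("invalid parameter: kd undefined for k_on = 0")
  k_off / k_on
}

#' Equilibrium association constant KA = 1/KD
#' @inheritParams kd
#' @return numeric vector, per-molar.
#' @export
ka <- function(rates, n = length(rates$k_on)) 1 / kd(rates, n)

#' @export
print.rate_constants <- function(x, ...) {
  n <- length(x$k_on)
  cat("Rate constants (", n, " binding step", if (n > 1) "s", ")\n", sep = "")
  cat("  k_on  [1/M/s]:", format(x$k_on, digits = 4), "\n")
  cat("  k_off [1/s]  :", format(x$k_off, digits = 4), "\n")
  cat("  KD    [M]    :", format(x$k_off / x$k_on, digits = 4), "\n")
  if (x$alpha != 1) cat("  cooperativity alpha =", x$alpha, "\n")
  invisible(x)
}

#' Binding scenario: ligand valency, totals and ligand bookkeeping mode
#'
#' @param valency number of receptor-binding epitopes on the ligand: 1, 2
#'   (e.g. an antibody or dimerised nanobody) or 4 (a model multivalent
#'   ligand).
#' @param ligand_total total ligand concentration (molar).
#' @param receptor_total total receptor concentration (molar).
#' @param ligand_excess if `TRUE` (default) the free ligand concentration is
#'   held constant (soluble ligand in vast excess); if `FALSE` ligand is
#'   consumed by binding (ligand-depletion mode, the membrane-bound ligand
#'   case), which right-shifts the occupancy curve.
#' @return an object of class `binding_scenario`.
#' @export
binding_scenario <- function(valency = 1, ligand_total = 1e-6,
                             receptor_total = 1e-6, ligand_excess = TRUE) {
  if (!valency %in% c(1, 2, 4)) {
    stop("invalid parameter: valency must be 1, 2 or 4")
  }
  if (!is.finite(ligand_total) || ligand_total < 0) {
    stop("invalid parameter: ligand_total must be >= 0")
  }
  if (!is.finite(receptor_total) || receptor_total <= 0) {
    stop("invalid parameter: receptor_total must be > 0")
  }
  structure(
    list(valency = as.integer(valency), ligand_total = ligand_total,
         receptor_total = receptor_total,
         ligand_excess = isTRUE(ligand_excess)),
    class = "binding_scenario"
  )
}

#' @export
print.binding_scenario <- function(x, ...) {
  cat("Binding scenario: valency", x$valency,
      if (x$ligand_excess) "(ligand excess)" else "(ligand depletion)", "\n")
  cat("  ligand_total  :", format(x$ligand_total, digits = 4), "M\n")
  cat("  receptor_total:", format(x$receptor_total, digits = 4), "M\n")
  invisible(x)
}
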