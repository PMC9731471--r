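test_that("equilibrium occupancy follows the hyperbolic law", {
  kd1 <- 1e-6
  expect_equal(equilibrium_occupancy(kd1, kd1), 0.5)
  expect_equal(equilibrium_occupancy(19 * kd1, kd1), 0.95)
  expect_equal(equilibrium_occupancy(0, kd1), 0)
  ## monotone in ligand concentration
  grid <- 10^seq(-9, -3, length.out = 40)
  occ <- equilibrium_occupancy(grid, kd1)
  expect_true(all(diff(occ) > 0))
  expect_true(all(occ >= 0 & occ < 1))
  expect_error(equilibrium_occupancy(1e-6, 0), "invalid parameter")
  expect_error(equilibrium_occupancy(-1e-6, 1e-6), "invalid parameter")
})

test_that("fold over KD for a target occupancy inverts the occupancy law", {
  expect_equal(fold_for_occupancy(0.95), 19)
  expect_equal(fold_for_occupancy(0.5), 1)
  expect_equal(fold_for_occupancy(0.75), 3)
  ## consistency with the forward relation for random targets
  set.seed(1)
  f <- runif(20, 0.01, 0.99)
  expect_equal(equilibrium_occupancy(fold_for_occupancy(f) * 2e-6, 2e-6), f)
  expect_error(fold_for_occupancy(1), "invalid parameter")
  expect_error(fold_for_occupancy(0), "invalid parameter")
})

test_that("monovalent kinetics reach 95% of equilibrium at the documented times", {
  r <- rate_constants(k_on = 1e6, k_off = 1)   # KD = 1 uM
  kd1 <- 1e-6
  ## ligand levels giving 25 / 50 / 75% equilibrium occupancy
  expect_equal(round(time_to_equilibrium_fraction(kd1 / 3, r, 0.95), 2), 2.25)
  expect_equal(round(time_to_equilibrium_fraction(kd1, r, 0.95), 2), 1.50)
  expect_equal(round(time_to_equilibrium_fraction(3 * kd1, r, 0.95), 2), 0.75)
  ## time decreases with ligand; vanishes as frac -> 0+
  expect_lt(time_to_equilibrium_fraction(2e-6, r, 0.95),
            time_to_equilibrium_fraction(1e-6, r, 0.95))
  expect_lt(time_to_equilibrium_fraction(1e-6, r, 1e-9), 1e-6)
  expect_error(time_to_equilibrium_fraction(1e-6, r, 1), "invalid parameter")
})

test_that("monovalent time course starts at zero and approaches equilibrium", {
  r <- rate_constants(1e6, 1)
  tc <- monovalent_timecourse(1e-6, r, receptor_total = 1e-6,
                              times = seq(0, 20, by = 0.1))
  expect_equal(tc$occupancy[1], 0)
  ## strictly rising until the exponential saturates at machine precision
  expect_true(all(diff(tc$occupancy) >= 0))
  expect_true(all(diff(tc$occupancy[tc$time <= 5]) > 0))
  expect_equal(tc$occupancy[nrow(tc)], equilibrium_occupancy(1e-6, 1e-6),
               tolerance = 1e-8)
  ## fractional course is independent of receptor level
  tc2 <- monovalent_timecourse(1e-6, r, receptor_total = 1e-5,
                               times = seq(0, 20, by = 0.1))
  expect_equal(tc$occupancy, tc2$occupancy)
  ## 95% of equilibrium reached at the closed-form time
  t95 <- time_to_equilibrium_fraction(1e-6, r, 0.95)
  tc3 <- monovalent_timecourse(1e-6, r, times = c(0, t95))
  expect_equal(tc3$occupancy[2] / equilibrium_occupancy(1e-6, 1e-6), 0.95)
  expect_error(monovalent_timecourse(1e-6, r, times = -1), "invalid parameter")
})

test_that("equilibrium solver reduces to the closed form for a monovalent ligand", {
  set.seed(42)
  for (i in 1:8) {
    k_on <- 10^runif(1, 4, 7)
    k_off <- 10^runif(1, -2, 1)
    L <- 10^runif(1, -8, -4)
    r <- rate_constants(k_on, k_off)
    sc <- binding_scenario(1, L, receptor_total = 1e-6)
    sv <- solve_equilibrium(sc, r)
    expect_equal(sv$bound[1] / sc$receptor_total,
                 equilibrium_occupancy(L, k_off / k_on), tolerance = 1e-6)
    ## receptor conservation
    expect_equal(receptor_accounted(sv), sc$receptor_total,
                 tolerance = 1e-8 * sc$receptor_total)
  }
})

test_that("ODE and algebraic equilibrium routes agree for divalent and tetravalent ligands", {
  set.seed(7)
  for (v in c(2L, 4L)) {
    for (i in 1:4) {
      r <- rate_constants(10^runif(1, 5, 6.5), 10^runif(1, -0.5, 0.5))
      for (excess in c(TRUE, FALSE)) {
        sc <- binding_scenario(v, 10^runif(1, -7, -5), 1e-6, excess)
        ode <- solve_equilibrium(sc, r, method = "ode")
        alg <- solve_equilibrium(sc, r, method = "algebraic")
        expect_equal(ode$bound, alg$bound, tolerance = 1e-6)
        expect_equal(ode$free_receptor, alg$free_receptor, tolerance = 1e-6)
        ## conservation: receptors always, ligand in depletion mode
        expect_equal(receptor_accounted(ode), 1e-6, tolerance = 1e-8 * 1e-6)
        if (!excess) {
          expect_equal(ode$free_ligand + sum(ode$bound), sc$ligand_total,
                       tolerance = 1e-6 * sc$ligand_total)
        }
        ## detailed balance in ligand-excess mode
        if (excess) {
          kds <- kd(r, v)
          lhs <- c(ode$free_ligand, ode$bound[-v]) * ode$free_receptor
          expect_equal(lhs, kds * ode$bound, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("disabling the second binding step removes the doubly bound species", {
  r <- rate_constants(k_on = c(1e6, 0), k_off = c(1, 1))
  sc <- binding_scenario(2, 1e-6)
  sv <- solve_equilibrium(sc, r)
  expect_equal(sv$bound[2], 0, tolerance = 1e-18)
  expect_gt(sv$bound[1], 0)
})

test_that("doubly bound divalent species is bell-shaped with its peak at KD1", {
  r <- rate_constants(1e6, 1)          # KD1 = KD2 = 1 uM
  sc <- binding_scenario(2, 1e-6, 1e-6)
  tab <- concentration_response(sc, rates = r)
  peak <- find_curve_peak(tab$ligand_conc, tab$bound2)
  expect_false(peak$boundary)
  expect_equal(peak$ligand_at_max, 1e-6, tolerance = 0.05)
  ## rise-then-fall of the intermediate; singly bound keeps increasing at
  ## high ligand
  i_max <- which.max(tab$bound2)
  expect_true(all(diff(tab$bound2[1:i_max]) > 0))
  expect_true(all(diff(tab$bound2[i_max:nrow(tab)]) < 0))
  n <- nrow(tab)
  expect_true(all(diff(tab$bound1[(n - 10):n]) > 0))
})

test_that("stronger second-step association raises the bell peak", {
  sc <- binding_scenario(2, 1e-6)
  peaks <- vapply(c(1e5, 1e6, 1e7), function(k2) {
    r <- rate_constants(k_on = c(1e6, k2), k_off = c(1, 1))
    tab <- concentration_response(sc, rates = r)
    max(tab$bound2)
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("cooperativity shifts the doubly bound species at fixed ligand", {
  sc <- binding_scenario(2, 1e-6)
  b2 <- vapply(c(0.2, 1, 5), function(a_plus) {
    r <- rate_constants(1e6, 1, alpha_plus = a_plus, alpha_minus = 1)
    solve_equilibrium(sc, r)$bound[2]
  }, 0)
  expect_lt(b2[1], b2[2])   # negative cooperativity lowers L2RR
  expect_gt(b2[3], b2[2])   # positive cooperativity raises it
})

test_that("tetravalent intermediates are transient but saturation wins at high receptor", {
  r <- rate_constants(1e6, 1)
  ## (i) over ligand: intermediates rise then fall, singly bound dominates
  ##     at high ligand
  tab <- concentration_response(binding_scenario(4, 1e-6), rates = r)
  n <- nrow(tab)
  for (sp in c("bound2", "bound3", "bound4")) {
    i_max <- which.max(tab[[sp]])
    expect_gt(i_max, 1)
    expect_lt(i_max, n)
  }
  expect_gt(tab$bound1[n], tab$bound4[n])
  ## (ii) fixed 1 uM ligand, increasing receptor: fully bound species
  ##      predominates among bound species
  sc_hi <- binding_scenario(4, 1e-6, receptor_total = 2e-5)
  sv <- solve_equilibrium(sc_hi, r)
  expect_true(sv$bound[4] > max(sv$bound[1:3]))
})

test_that("ligand depletion right-shifts the occupancy curve", {
  r <- rate_constants(1e6, 1)
  grid <- 10^seq(-8, -4, length.out = 25)
  occ <- function(excess) {
    tab <- concentration_response(
      binding_scenario(1, 1e-6, 1e-6, ligand_excess = excess),
      ligand_grid = grid, rates = r)
    tab$occupancy
  }
  occ_excess <- occ(TRUE)
  occ_depl <- occ(FALSE)
  expect_true(all(occ_depl <= occ_excess + 1e-12))
  expect_gt(max(occ_excess - occ_depl), 0.01)
})

test_that("curve peak finder refines interior maxima and flags boundary ones", {
  expect_error(find_curve_peak(1:3, 1:2), "invalid input")
  mono <- find_curve_peak(1:5, c(1, 2, 3, 4, 5))
  expect_true(mono$boundary)
  expect_equal(mono$ligand_at_max, 5)
  toy <- find_curve_peak(1:5, c(1, 2, 3, 2, 1))
  expect_false(toy$boundary)
  expect_equal(toy$ligand_at_max, 3, tolerance = 1e-6)
  expect_equal(toy$max_value, 3, tolerance = 1e-6)
})

test_that("rate constant constructors expose KD, KA, KD3 and the alpha relations", {
  r <- rate_constants(1e6, 1)
  expect_equal(kd(r), 1e-6)
  expect_equal(ka(r), 1e6)
  expect_equal(prod(kd(r, 2)), 1e-12)       # KD3 = KD1 * KD2
  ra <- rate_constants(1e6, 1, alpha_plus = 4, alpha_minus = 2)
  expect_equal(ra$k_on[2], 4e6)
  expect_equal(ra$k_off[2], 2)
  expect_equal(ra$alpha, 2)
  expect_error(rate_constants(-1, 1), "invalid parameter")
  expect_error(binding_scenario(3, 1e-6), "valency")
  expect_error(binding_scenario(1, 1e-6, 0), "receptor_total")
})
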