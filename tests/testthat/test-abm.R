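quiet_cfg <- function(...) {
  abm_config(p_phos_on = 0, p_phos_off = 0, p_dim_on = 0, p_dim_off = 0,
             p_xl_on = 0, p_xl_off = 0, p_lig_on = 0, p_lig_off = 0, ...)
}

test_that("world initialisation places the configured agents with empty bonds", {
  cfg <- abm_config(n_receptors = 100, n_crosslinkers = 40, n_ligands = 60)
  w <- init_world(cfg, seed = 1)
  expect_length(w$rx, 100)
  expect_length(w$xx, 40)
  expect_length(w$lx, 60)
  expect_true(all(is.na(w$dimer)) && all(is.na(w$lig)) && all(is.na(w$xl)))
  expect_true(all(w$rx >= 0 & w$rx < 21) && all(w$ry >= 0 & w$ry < 21))
  ## determinism
  expect_identical(w, init_world(cfg, seed = 1))
  ## basal phosphorylated fraction near 10% (binomial on n = 100)
  set.seed(2)
  phos <- mean(replicate(50, sum(init_world(cfg)$phos)))
  expect_gt(phos, 6)
  expect_lt(phos, 14)
  expect_error(init_world(abm_config(n_receptors = 0)), "receptor")
})

test_that("a tick with all probabilities zero only moves agents", {
  cfg <- quiet_cfg(n_receptors = 30, n_crosslinkers = 10, n_ligands = 10)
  w0 <- init_world(cfg, seed = 3)
  w0$phos <- as.integer(seq_len(30) %% 2)
  w1 <- abm_tick(w0, cfg)
  expect_identical(w1$phos, w0$phos)
  expect_identical(w1$dimer, w0$dimer)
  expect_identical(w1$lig, w0$lig)
  expect_identical(w1$xl, w0$xl)
  ## every free agent moved one patch (Chebyshev distance 1, toroidal)
  d <- pmin(abs(w1$rx - w0$rx), 21 - abs(w1$rx - w0$rx))
  e <- pmin(abs(w1$ry - w0$ry), 21 - abs(w1$ry - w0$ry))
  expect_true(all(pmax(d, e) == 1))
})

test_that("a crosslinker-occupied tail never dephosphorylates", {
  cfg <- abm_config(n_receptors = 2, n_crosslinkers = 1, n_ligands = 0,
                    p_phos_on = 0, p_phos_off = 1, p_dim_on = 0,
                    p_xl_on = 0, p_xl_off = 0)
  w <- init_world(cfg, seed = 4)
  w$phos <- c(1L, 1L)
  ## receptor 1 tail held by crosslinker site 1; receptor 2 tail free
  w$xl[1] <- 1L
  w$xlsite[1] <- 1L
  w$xs1[1] <- 1L
  w1 <- abm_tick(w, cfg)
  expect_equal(w1$phos[1], 1L)   # protected
  expect_equal(w1$phos[2], 0L)   # dephosphorylated with certainty
})

test_that("contacting partner-free receptors dimerise when forced", {
  ## width-3 torus: every patch is within contact range of every other, so
  ## the bond formation is a sure event regardless of movement
  cfg <- quiet_cfg(n_receptors = 2, n_crosslinkers = 0, n_ligands = 0,
                   width = 3)
  cfg$p_dim_on <- 1
  w <- init_world(cfg, seed = 5)
  w1 <- abm_tick(w, cfg)
  expect_equal(w1$dimer, c(2L, 1L))
})

test_that("bound receptors move as one unit", {
  cfg <- quiet_cfg(n_receptors = 2, n_crosslinkers = 0, n_ligands = 0)
  w <- init_world(cfg, seed = 5)
  w$rx <- c(3L, 3L)
  w$ry <- c(7L, 7L)
  w$dimer <- c(2L, 1L)
  for (k in 1:5) {
    w1 <- abm_tick(w, cfg)
    expect_equal((w1$rx[1] - w$rx[1]) %% 21, (w1$rx[2] - w$rx[2]) %% 21)
    expect_equal((w1$ry[1] - w$ry[1]) %% 21, (w1$ry[2] - w$ry[2]) %% 21)
    w <- w1
  }
})

test_that("bond capacity and phosphorylation gating hold along a default run", {
  cfg <- abm_config(ticks = 300)
  sim <- run_simulation(cfg, seed = 6)
  w <- sim$world
  ## agent conservation
  expect_length(w$rx, 100)
  expect_length(w$lx, 100)
  expect_length(w$xx, 100)
  ## dimer symmetry, single bonds per receptor slot by construction;
  ## crosslinker sites only on phosphorylated receptors
  bonded <- which(!is.na(w$dimer))
  expect_true(all(w$dimer[w$dimer[bonded]] == bonded))
  xl_bound <- which(!is.na(w$xl))
  expect_true(all(w$phos[xl_bound] == 1L))
  ## ligand/crosslinker site back-references are consistent
  for (l in which(!is.na(w$ls1))) expect_equal(w$lig[w$ls1[l]], l)
  for (x in which(!is.na(w$xs1))) expect_equal(w$xl[w$xs1[x]], x)
  ## a site never binds the same receptor twice
  expect_false(any(!is.na(w$ls1) & !is.na(w$ls2) & w$ls1 == w$ls2))
  expect_false(any(!is.na(w$xs1) & !is.na(w$xs2) & w$xs1 == w$xs2))
})

test_that("census completeness and determinism hold for simulation runs", {
  cfg <- abm_config(ticks = 200)
  sim <- run_simulation(cfg, seed = 7)
  with(sim$census, {
    expect_true(all(n_size_1 + 2 * n_size_2 + 3 * n_size_3 + 4 * n_size_4 +
                      receptors_in_gt4 == 100))
  })
  sim2 <- run_simulation(cfg, seed = 7)
  expect_identical(sim$census, sim2$census)
  expect_identical(sim$world, sim2$world)
})

test_that("crosslinker-only worlds never form complexes beyond pairs", {
  ## non-dimerising receptor + high-affinity crosslinker: the single
  ## cytosolic tail caps every complex at two receptors
  cfg <- abm_config(p_dim_on = 0, n_ligands = 0,
                    crosslinker_affinity = "high", ticks = 1500)
  for (seed in 1:3) {
    sim <- run_simulation(cfg, seed = seed)
    expect_true(all(sim$census$max_size <= 2))
  }
})

test_that("dimerisation increases with receptor number and association rate", {
  run_mean <- function(cfg, seed = 13) {
    ens <- run_ensemble(cfg, n_replicates = 10, base_seed = seed,
                        census_stride = 1500)
    f <- ens$final
    f$mean[f$field == "frac_receptors_in_size_2"]
  }
  by_n <- vapply(c(50, 100, 200, 400), function(n) {
    run_mean(abm_config(n_receptors = n, n_crosslinkers = 0, n_ligands = 0,
                        ticks = 1500))
  }, 0)
  expect_true(all(diff(by_n) > 0))
  by_kon <- vapply(c(0.002, 0.007, 0.03, 0.12), function(p) {
    run_mean(abm_config(p_dim_on = p, n_crosslinkers = 0, n_ligands = 0,
                        ticks = 1500))
  }, 0)
  expect_true(all(diff(by_kon) > 0))
  by_koff <- vapply(c(0.05, 0.2, 0.8), function(p) {
    run_mean(abm_config(p_dim_off = p, n_crosslinkers = 0, n_ligands = 0,
                        ticks = 1500))
  }, 0)
  expect_true(all(diff(by_koff) < 0))
})

test_that("divalent ligand and crosslinker synergise into larger clusters", {
  mean_max <- function(cfg) {
    ens <- run_ensemble(cfg, n_replicates = 12, base_seed = 31,
                        census_stride = 1500)
    ens$final$mean[ens$final$field == "max_size"]
  }
  combined <- mean_max(abm_config(ticks = 1500))
  lig_only <- mean_max(abm_config(n_crosslinkers = 0, ticks = 1500))
  xl_only <- mean_max(abm_config(n_ligands = 0, ticks = 1500))
  expect_gt(combined, lig_only)
  expect_gt(combined, xl_only)
})

test_that("ligand bridging of a monomeric receptor yields trimers and tetramers", {
  ## divalent ligands + moderate crosslinker on a non-dimerising receptor
  cfg <- abm_config(p_dim_on = 0, n_ligands = 200, ticks = 1500)
  n3 <- n4 <- 0
  for (seed in 1:6) {
    sim <- run_simulation(cfg, seed = seed)
    tail_mean <- summarize_timeseries(sim$census, 500)
    n3 <- n3 + tail_mean$n_size_3
    n4 <- n4 + tail_mean$n_size_4
  }
  expect_gt(n3 / 6, 0)
  expect_gt(n4 / 6, 0)
})

test_that("ensemble summaries have zero spread for identical replicates", {
  cfg <- abm_config(ticks = 50)
  sim1 <- run_simulation(cfg, seed = replicate_seed(5, 1))
  ens <- run_ensemble(cfg, n_replicates = 2, base_seed = 5,
                      census_stride = 50)
  expect_equal(ens$final_replicates[1, -1],
               sim1$census[nrow(sim1$census), -1],
               ignore_attr = TRUE)
  ## identical seeds: force both replicates through the same stream
  set.seed(77)
  a <- run_simulation(cfg, seed = 123)$census
  set.seed(78)
  b <- run_simulation(cfg, seed = 123)$census
  expect_identical(a, b)
  expect_error(run_ensemble(cfg, n_replicates = 1), "n_replicates")
})

test_that("both-sites-bound arithmetic squares the per-site occupancy", {
  expect_equal(both_sites_bound_fraction(0.4), 0.16)
  expect_equal(both_sites_bound_fraction(0.9), 0.81)
  expect_equal(both_sites_bound_fraction(0.2), 0.04)
  expect_equal(both_sites_bound_fraction(1), 1)
  expect_error(both_sites_bound_fraction(1.2), "invalid parameter")
  ## presets reproduce the moderate/high stationary site occupancies
  m <- crosslinker_preset("moderate")
  h <- crosslinker_preset("high")
  expect_equal(unname(m["p_on"] / (m["p_on"] + m["p_off"])), 0.4)
  expect_equal(unname(h["p_on"] / (h["p_on"] + h["p_off"])), 0.9)
})
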