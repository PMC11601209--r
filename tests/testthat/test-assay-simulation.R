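# Simulation of competition curves, half-competition location, modulator
# occupancy along the curve, and the ligand-depletion solver.

test_that("curve specs validate their grids", {
  expect_error(competition_curve_spec("t", "c", c(1e-9, 1e-9, 1e-8)),
               class = "pl_domain_error")
  expect_error(competition_curve_spec("t", "c", c(1e-9, 0, 1e-8)),
               class = "pl_domain_error")
  sp <- competition_curve_spec("t", "c", c(0, 1e-9, 1e-8))
  expect_s3_class(sp, "competition_curve_spec")
  expect_error(competition_curve_spec("t", "c", c(0, 1e-9, 1e-8), depletion = TRUE),
               class = "pl_domain_error")
})

test_that("signal is normalized to the zero-competitor point", {
  m <- toxin_model()
  sp <- competition_curve_spec("toxin", "comp", default_competitor_grid(1e-11, 1e-6))
  cu <- simulate_competition_curve(m, sp)
  expect_equal(cu$signal[1], 1)
  expect_true(all(diff(cu$signal) <= 1e-12))   # competitor displaces label
  expect_true(all(cu$signal >= 0 & cu$signal <= 1 + 1e-12))
})

test_that("an inverse agonist half-competes at twice its closed-state Kd", {
  m <- toxin_model(gating = 1e-6, competitor_kdc = 5e-9, competitor_kdo = 5e-8)
  sp <- competition_curve_spec("toxin", "comp", default_competitor_grid(1e-11, 1e-6))
  cu <- simulate_competition_curve(m, sp)
  expect_equal(half_competition(cu) / 5e-9, 2, tolerance = 0.01)
})

test_that("half_competition agrees with the analytic toxin-toxin curve", {
  kd <- 1e-9; lab <- 1e-9
  grid <- default_competitor_grid(1e-11, 1e-6, 33)
  sig <- toxin_toxin_occupancy(5, kd, lab, grid) / toxin_toxin_occupancy(5, kd, lab, 0)
  cu <- data.frame(concentration = grid, signal = sig)
  expect_equal(half_competition(cu), toxin_half_competition(kd, lab),
               tolerance = 1e-3)
})

test_that("half_competition converges to the dense-grid crossing as grids refine", {
  kd <- 3e-9; lab <- 1e-9
  ref <- toxin_half_competition(kd, lab)
  errs <- vapply(c(9, 17, 129), function(n) {
    grid <- default_competitor_grid(1e-11, 1e-6, n)
    sig <- toxin_toxin_occupancy(5, kd, lab, grid) / toxin_toxin_occupancy(5, kd, lab, 0)
    abs(half_competition(data.frame(concentration = grid, signal = sig)) - ref) / ref
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))  # error shrinks with refinement
  expect_lt(errs[3], 1e-5)
})

test_that("curves that never cross half signal raise a not-crossed error", {
  flat <- data.frame(concentration = c(0, 1e-9, 1e-8, 1e-7), signal = rep(1, 4))
  expect_error(half_competition(flat), class = "pl_not_crossed_error")
})

test_that("a closed-stabilizing modulator right-shifts agonist curves pointwise", {
  grid <- default_competitor_grid(1e-10, 1e-4)
  bare <- agonist_model()
  modded <- agonist_model(modulator_kdc = 1e-6, modulator_kdo = 1e-4)
  sp0 <- competition_curve_spec("toxin", "comp", grid)
  spm <- competition_curve_spec("toxin", "comp", grid,
                                modulator = "mod", modulator_concentration = 1e-4)
  cu0 <- simulate_competition_curve(bare, sp0)
  cum <- simulate_competition_curve(modded, spm)
  # at every concentration the modulated curve retains at least as much label
  expect_true(all(cum$signal >= cu0$signal - 1e-12))
  expect_gte(half_competition(cum), half_competition(cu0))
})

test_that("an open-stabilizing modulator never right-shifts agonist curves", {
  grid <- default_competitor_grid(1e-10, 1e-4)
  bare <- agonist_model()
  modded <- agonist_model(modulator_kdc = 1e-4, modulator_kdo = 1e-6)
  spm <- competition_curve_spec("toxin", "comp", grid,
                                modulator = "mod", modulator_concentration = 1e-5)
  cu0 <- simulate_competition_curve(bare, competition_curve_spec("toxin", "comp", grid))
  cum <- simulate_competition_curve(modded, spm)
  expect_lte(half_competition(cum), half_competition(cu0))
})

test_that("inverse-agonist half-competition is insensitive to the modulator", {
  # on a predominantly closed receptor, a closed-stabilizing modulator
  # cannot shift the curve of a closed-state-probing competitor
  grid <- default_competitor_grid(1e-11, 1e-6)
  bare <- toxin_model()
  modded <- toxin_model(modulator_kdc = 1e-6, modulator_kdo = 1e-4)
  spm <- competition_curve_spec("toxin", "comp", grid,
                                modulator = "mod", modulator_concentration = 1e-4)
  h0 <- half_competition(simulate_competition_curve(bare, competition_curve_spec("toxin", "comp", grid)))
  hm <- half_competition(simulate_competition_curve(modded, spm))
  expect_lt(abs(hm / h0 - 1), 0.01)
})

test_that("modulator occupancy tracks the conformational transition", {
  grid <- default_competitor_grid(1e-10, 1e-4)
  modded <- agonist_model(modulator_kdc = 1e-6, modulator_kdo = 1e-4)
  spm <- competition_curve_spec("toxin", "comp", grid,
                                modulator = "mod", modulator_concentration = 1e-6)
  occ <- modulator_occupancy_profile(modded, spm)
  # agonist drives the receptor open, where the modulator binds worse:
  # occupancy decreases along the titration
  expect_true(all(diff(occ) <= 1e-12))
  # and matches the enumeration oracle at a mid-curve point
  conc <- c(toxin = 1e-9, comp = grid[10], mod = 1e-6)
  expect_equal(occ[10], enumerate_microstates(modded, conc)$mean_occupancy[["mod"]],
               tolerance = 1e-10)
  # zero modulator concentration: all zeros
  sp0 <- competition_curve_spec("toxin", "comp", grid,
                                modulator = "mod", modulator_concentration = 0)
  expect_equal(modulator_occupancy_profile(modded, sp0), rep(0, length(grid)))
  # state-independent modulator: constant occupancy along the whole curve
  neut <- agonist_model(modulator_kdc = 1e-6, modulator_kdo = 1e-6)
  occ_n <- modulator_occupancy_profile(neut, spm)
  expect_equal(diff(range(occ_n)), 0, tolerance = 1e-12)
  # spec without a modulator is rejected
  expect_error(modulator_occupancy_profile(modded,
                 competition_curve_spec("toxin", "comp", grid)),
               class = "pl_spec_error")
})

test_that("a neutral competitor gives modulator-insensitive curves", {
  grid <- default_competitor_grid(1e-9, 1e-4)
  m <- receptor_model(
    list(ligand_spec("toxin", "orthosteric", 1e-9, 1e-8),
         ligand_spec("comp", "orthosteric", 1e-6, 1e-6),
         ligand_spec("mod", "allosteric", 1e-6, 1e-4)),
    gating_unliganded = 1e-4
  )
  sp0 <- competition_curve_spec("toxin", "comp", grid)
  spm <- competition_curve_spec("toxin", "comp", grid,
                                modulator = "mod", modulator_concentration = 1e-4)
  h0 <- half_competition(simulate_competition_curve(m, sp0))
  hm <- half_competition(simulate_competition_curve(m, spm))
  expect_lt(abs(hm / h0 - 1), 0.01)
})

test_that("depletion solver conserves mass and honors its limits", {
  m <- toxin_model()
  totals <- c(toxin = 2e-9, comp = 1e-8)
  # no receptor: free = total
  free0 <- solve_free_concentrations(m, totals, 0)
  expect_equal(unname(free0[names(totals)]), unname(totals))
  # finite receptor: mass balance holds to 1e-10 relative
  free <- solve_free_concentrations(m, totals, 5e-10)
  occ <- equilibrium_occupancy(m, free)$mean_occupancy
  resid <- (free[names(totals)] + 5e-10 * occ[names(totals)] - totals) / totals
  expect_true(all(abs(resid) < 1e-10))
  expect_true(all(free[names(totals)] < totals))
  # vast receptor excess with tight binding strips the label
  tight <- receptor_model(list(ligand_spec("toxin", "orthosteric", 1e-15, 1e-15)),
                          gating_unliganded = 1e-6)
  f <- solve_free_concentrations(tight, c(toxin = 1e-9), 1e-6)
  expect_lt(f[["toxin"]], 1e-12)
})

test_that("depletion shifts simulated curves relative to the clamped regime", {
  m <- toxin_model()
  grid <- default_competitor_grid(1e-11, 1e-6)
  clamped <- simulate_competition_curve(
    m, competition_curve_spec("toxin", "comp", grid))
  depleted <- simulate_competition_curve(
    m, competition_curve_spec("toxin", "comp", grid,
                              depletion = TRUE, receptor_total = 1e-9))
  expect_false(isTRUE(all.equal(clamped$signal, depleted$signal)))
  expect_equal(depleted$signal[1], 1)
})

test_that("curve files round-trip through the delimited format", {
  m <- toxin_model()
  cu <- simulate_competition_curve(
    m, competition_curve_spec("toxin", "comp", default_competitor_grid(1e-11, 1e-6)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curves(cu, path, provenance = c("unit test"))
  back <- read_curves(path)
  expect_s3_class(back, "assay_dataset")
  expect_equal(back$concentration, cu$concentration)
  expect_equal(back$signal, cu$signal)
})
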