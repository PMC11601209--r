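# Exact equilibrium solution of the two-conformation receptor model.

test_that("ligand predicates classify conformational preference", {
  expect_true(is_agonist(ligand_spec("a", "orthosteric", 1e-6, 1e-8)))
  expect_true(is_inverse_agonist(ligand_spec("t", "orthosteric", 1e-9, 1e-8)))
  expect_true(is_neutral_ligand(ligand_spec("n", "orthosteric", 1e-6)))
  expect_error(ligand_spec("bad", "orthosteric", -1), class = "pl_domain_error")
})

test_that("liganded gating constant follows the affinity-ratio power law", {
  m <- receptor_model(list(ligand_spec("ago", "orthosteric", 1e-6, 1e-8)),
                      gating_unliganded = 1e-6)
  expect_identical(liganded_gating_constant(m, "ago", 0), 1e-6)
  expect_equal(liganded_gating_constant(m, "ago", 5), 1e4)
  # successive ratios all equal kd_closed/kd_open
  for (mm in 1:5) {
    expect_equal(liganded_gating_constant(m, "ago", mm) /
                   liganded_gating_constant(m, "ago", mm - 1), 100)
  }
  expect_error(liganded_gating_constant(m, "ago", 6), class = "pl_range_error")
  m2 <- receptor_model(list(ligand_spec("ivm", "allosteric", 1e-6, 1e-8)),
                       gating_unliganded = 1e-6)
  expect_error(liganded_gating_constant(m2, "ivm", 1), class = "pl_role_error")
})

test_that("liganded gating constant matches branch-weight ratios from enumeration", {
  # restrict the microstate sum to exactly m bound molecules of one ligand
  # and compare open/closed branch weights directly (independent route)
  kdc <- 2e-7; kdo <- 4e-9; K <- 1e-5; conc <- 3e-7; n <- 5L
  m <- receptor_model(list(ligand_spec("ago", "orthosteric", kdc, kdo)),
                      gating_unliganded = K, n_ortho = n, n_allo = 0L)
  for (mm in 0:n) {
    w_closed <- choose(n, mm) * (conc / kdc)^mm
    w_open <- K * choose(n, mm) * (conc / kdo)^mm
    expect_equal(liganded_gating_constant(m, "ago", mm), w_open / w_closed)
  }
})

test_that("state weights reduce to closed forms in simple conditions", {
  m <- receptor_model(list(ligand_spec("neu", "orthosteric", 1e-8)),
                      gating_unliganded = 1e-6)
  w0 <- state_weights(m)
  expect_equal(unname(w0), c(1, 1e-6), ignore_attr = TRUE)
  # neutral ligand at [L] = kd scales both branches by 2^5
  w <- state_weights(m, c(neu = 1e-8))
  expect_equal(unname(w), c(2^5, 1e-6 * 2^5), ignore_attr = TRUE)
})

test_that("equilibrium occupancy half-saturates at the closed-state Kd", {
  m <- receptor_model(list(ligand_spec("toxin", "orthosteric", 1e-9, 1e-8)),
                      gating_unliganded = 1e-9)
  occ <- equilibrium_occupancy(m, c(toxin = 1e-9))
  expect_equal(occ$mean_occupancy[["toxin"]], 2.5, tolerance = 1e-6)
  # zero concentrations: unliganded gating equilibrium
  occ0 <- equilibrium_occupancy(m)
  expect_equal(occ0$mean_occupancy[["toxin"]], 0)
  expect_equal(occ0$p_open, 1e-9 / (1 + 1e-9))
})

test_that("closed form matches exhaustive microstate enumeration", {
  withr::with_seed(42, {
    for (i in 1:30) {
      rc <- random_model_conditions()
      a <- equilibrium_occupancy(rc$model, rc$conc)
      b <- enumerate_microstates(rc$model, rc$conc)
      expect_equal(a$p_open, b$p_open, tolerance = 1e-10)
      expect_equal(a$p_closed, b$p_closed, tolerance = 1e-10)
      expect_equal(a$mean_occupancy, b$mean_occupancy, tolerance = 1e-10)
      expect_equal(a$p_open + a$p_closed, 1, tolerance = 1e-12)
    }
  })
})

test_that("single-site enumeration reduces to the binding isotherm", {
  m <- receptor_model(list(ligand_spec("L", "orthosteric", 1e-8, 1e-8)),
                      gating_unliganded = 1e-3, n_ortho = 1L, n_allo = 0L)
  conc <- c(L = 3e-8)
  b <- enumerate_microstates(m, conc)
  expect_equal(b$mean_occupancy[["L"]], 3e-8 / (1e-8 + 3e-8))
})

test_that("occupancies respect site-count bounds and class sums", {
  withr::with_seed(7, {
    for (i in 1:20) {
      rc <- random_model_conditions()
      occ <- equilibrium_occupancy(rc$model, rc$conc)
      expect_true(all(occ$mean_occupancy >= 0))
      expect_lte(occ$mean_occupancy[["L1"]] + occ$mean_occupancy[["L2"]],
                 rc$model$n_ortho)
      expect_lte(occ$mean_occupancy[["A1"]], rc$model$n_allo)
    }
  })
})

test_that("a neutral ligand leaves the gating equilibrium untouched", {
  m <- receptor_model(list(ligand_spec("neu", "orthosteric", 1e-8)),
                      gating_unliganded = 1e-4)
  p0 <- equilibrium_occupancy(m)$p_open
  for (conc in c(1e-9, 1e-7, 1e-5)) {
    expect_equal(equilibrium_occupancy(m, c(neu = conc))$p_open, p0)
  }
})

test_that("p_open is monotone in agonist and inverse-agonist concentration", {
  ago <- receptor_model(list(ligand_spec("a", "orthosteric", 1e-6, 1e-8)),
                        gating_unliganded = 1e-4)
  inv <- receptor_model(list(ligand_spec("t", "orthosteric", 1e-9, 1e-8)),
                        gating_unliganded = 1e-2)
  grid <- default_competitor_grid(1e-10, 1e-4, 25)
  p_ago <- vapply(grid, function(x) equilibrium_occupancy(ago, c(a = x))$p_open, 1)
  p_inv <- vapply(grid, function(x) equilibrium_occupancy(inv, c(t = x))$p_open, 1)
  expect_true(all(diff(p_ago) >= -1e-15))
  expect_true(all(diff(p_inv) <= 1e-15))
})

test_that("toxin-toxin closed forms obey half-saturation and half-competition", {
  expect_equal(toxin_toxin_occupancy(5, 1e-9, labeled = 1e-9, unlabeled = 0), 2.5)
  # at [unlabeled] = kd + labeled the bound label halves (half-competition law)
  n0 <- toxin_toxin_occupancy(5, 1e-9, 1e-9, 0)
  expect_equal(toxin_toxin_occupancy(5, 1e-9, 1e-9, unlabeled = 2e-9), n0 / 2)
  expect_equal(toxin_half_competition(1e-9, 1e-9), 2e-9)
  expect_equal(toxin_half_competition(1e-9, 0), 1e-9)
  expect_error(toxin_toxin_occupancy(5, 1e-9, -1e-9, 0), class = "pl_domain_error")
  expect_error(toxin_half_competition(0, 1e-9), class = "pl_domain_error")
})

test_that("half-competition formula matches root-finding on the occupancy curve", {
  kd <- 1e-9; lab <- 1.7e-9
  target <- toxin_toxin_occupancy(5, kd, lab, 0) / 2
  root <- uniroot(function(u) toxin_toxin_occupancy(5, kd, lab, u) - target,
                  c(0, 1e-6), tol = 1e-18)$root
  expect_equal(root, toxin_half_competition(kd, lab), tolerance = 1e-6)
})

test_that("toxin-vs-toxin competition from the full model matches the closed form", {
  # two inverse-agonist-like ligands with equal state preference on an
  # essentially closed receptor reduce to the algebraic competition formula
  m <- receptor_model(
    list(ligand_spec("lab", "orthosteric", 1e-9, 1e-8),
         ligand_spec("unl", "orthosteric", 1e-9, 1e-8)),
    gating_unliganded = 1e-9
  )
  for (u in c(0, 1e-9, 5e-9, 2e-8)) {
    occ <- equilibrium_occupancy(m, c(lab = 1e-9, unl = u))
    expect_equal(occ$mean_occupancy[["lab"]],
                 toxin_toxin_occupancy(5, 1e-9, 1e-9, u), tolerance = 1e-6)
  }
})

test_that("model config files round-trip through YAML", {
  m <- toxin_model(modulator_kdc = 1e-6, modulator_kdo = 1e-4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$gating_unliganded, m$gating_unliganded)
  expect_equal(names(m2$ligands), names(m$ligands))
  expect_equal(m2$ligands$comp$kd_closed, m$ligands$comp$kd_closed)
  # unit conversion on read
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "receptor:", "  n_ortho: 5", "  n_allo: 5", "  gating_unliganded: 1.0e-6",
    "ligands:", "  tox:", "    role: orthosteric", "    kd_closed: 1",
    "    kd_open: 10", "    units: nM"), path2)
  m3 <- read_model_config(path2)
  expect_equal(m3$ligands$tox$kd_closed, 1e-9)
  expect_equal(m3$ligands$tox$kd_open, 1e-8)
})

test_that("capacity limits on the enumeration oracle are enforced", {
  ligs <- c(lapply(1:3, function(i) ligand_spec(paste0("L", i), "orthosteric", 1e-8)),
            list(ligand_spec("A", "allosteric", 1e-6)))
  m <- receptor_model(ligs, gating_unliganded = 1e-6, n_ortho = 8L, n_allo = 8L)
  expect_error(enumerate_microstates(m, c(L1 = 1e-8)), class = "pl_capacity_error")
})
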