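# Shared fixture builders: canonical receptor models used across tests.

# Labeled toxin (inverse agonist) + competitor + optional allosteric
# modulator on a receptor that is predominantly closed when unliganded.
toxin_model <- function(gating = 1e-6,
                        competitor_kdc = 5e-9, competitor_kdo = 5e-8,
                        modulator_kdc = NULL, modulator_kdo = NULL) {
  ligs <- list(
    ligand_spec("toxin", "orthosteric", kd_closed = 1e-9, kd_open = 1e-8),
    ligand_spec("comp", "orthosteric", kd_closed = competitor_kdc,
                kd_open = competitor_kdo)
  )
  if (!is.null(modulator_kdc)) {
    ligs <- c(ligs, list(ligand_spec("mod", "allosteric",
                                     kd_closed = modulator_kdc,
                                     kd_open = modulator_kdo)))
  }
  receptor_model(ligs, gating_unliganded = gating)
}

# Agonist competitor with a 100-fold closed-to-open affinity switch on a
# receptor that flips open when fully agonist-bound (1e-4 * 100^5 = 1e6).
agonist_model <- function(modulator_kdc = NULL, modulator_kdo = NULL) {
  toxin_model(gating = 1e-4, competitor_kdc = 1e-6, competitor_kdo = 1e-8,
              modulator_kdc = modulator_kdc, modulator_kdo = modulator_kdo)
}

single_curve_dataset <- function(curve) {
  data.frame(curve_id = 1L, concentration = curve$concentration,
             signal = curve$signal)
}

# Random model with 2 orthosteric + 1 allosteric ligand for oracle sweeps.
random_model_conditions <- function() {
  ligs <- list(
    ligand_spec("L1", "orthosteric", 10^runif(1, -9, -5), 10^runif(1, -9, -5)),
    ligand_spec("L2", "orthosteric", 10^runif(1, -9, -5), 10^runif(1, -9, -5)),
    ligand_spec("A1", "allosteric", 10^runif(1, -7, -4), 10^runif(1, -7, -4))
  )
  model <- receptor_model(ligs, gating_unliganded = 10^runif(1, -7, 1))
  conc <- c(L1 = 10^runif(1, -9, -5), L2 = 10^runif(1, -9, -5),
            A1 = 10^runif(1, -7, -4))
  list(model = model, conc = conc)
}
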