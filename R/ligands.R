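#' Define a ligand by its state-specific dissociation constants
#'
#' A ligand is characterized by the dissociation equilibrium constants of
#' its complex with the closed-channel conformation (`kd_closed`) and with
#' the high-affinity open/desensitized conformation (`kd_open`), and by the
#' class of sites it occupies: the neurotransmitter-binding (orthosteric)
#' sites of the extracellular domain, or the modulator-binding (allosteric)
#' sites of the transmembrane domain.
#'
#' The ratio `kd_closed/kd_open` is the ligand's conformational preference:
#' an agonist binds the open/desensitized conformation more tightly
#' (`kd_closed > kd_open`), an inverse agonist prefers the closed
#' conformation (`kd_closed < kd_open`), and a neutral ligand binds both
#' states equally and cannot bias gating.
#'
#' @param name Ligand name (unique within a receptor model).
#' @param role `"orthosteric"` or `"allosteric"`.
#' @param kd_closed Dissociation constant from the closed conformation
#'   (molar, > 0).
#' @param kd_open Dissociation constant from the open/desensitized
#'   conformation (molar, > 0). Defaults to `kd_closed` (neutral ligand).
#' @return A `ligand_spec` object.
#' @seealso [receptor_model()], [is_agonist()]
#' @export
#' @examples
#' mla <- ligand_spec("MLA", "orthosteric", kd_closed = 5e-9, kd_open = 5e-8)
#' is_inverse_agonist(mla)
ligand_spec <- function(name, role = c("orthosteric", "allosteric"),
                        kd_closed, kd_open = kd_closed) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_pl("'name' must be a non-empty string", "pl_domain_error")
  }
  if (!is_scalar_number(kd_closed) || kd_closed <= 0) {
    stop_pl("'kd_closed' must be a positive concentration (molar)", "pl_domain_error")
  }
  if (!is_scalar_number(kd_open) || kd_open <= 0) {
    stop_pl("'kd_open' must be a positive concentration (molar)", "pl_domain_error")
  }
  structure(
    list(name = name, role = role, kd_closed = kd_closed, kd_open = kd_open),
    class = "ligand_spec"
  )
}

#' Ligand pharmacology predicates
#'
#' Classify a ligand by its conformational preference. An agonist has
#' `kd_closed > kd_open` (stabilizes the open/desensitized conformation),
#' an inverse agonist `kd_closed < kd_open` (stabilizes the closed
#' conformation), and a neutral ligand binds both conformations equally.
#'
#' @param x A [ligand_spec()].
#' @return Logical scalar.
#' @export
is_agonist <- function(x) {
  stopifnot(inherits(x, "ligand_spec"))
  x$kd_closed > x$kd_open
}

#' @rdname is_agonist
#' @export
is_inverse_agonist <- function(x) {
  stopifnot(inherits(x, "ligand_spec"))
  x$kd_closed < x$kd_open
}

#' @rdname is_agonist
#' @export
is_neutral_ligand <- function(x) {
  stopifnot(inherits(x, "ligand_spec"))
  x$kd_closed == x$kd_open
}

#' @export
print.ligand_spec <- function(x, ...) {
  kind <- if (is_agonist(x)) "agonist" else if (is_inverse_agonist(x)) "inverse agonist" else "neutral"
  cat(sprintf("<ligand> %s (%s, %s): Kd,closed = %.3g M, Kd,open = %.3g M\n",
              x$name, x$role, kind, x$kd_closed, x$kd_open))
  invisible(x)
}

# Hard cap keeping the exhaustive microstate oracle feasible.
.MAX_SITES <- 8L

#' Two-conformation allosteric receptor model
#'
#' Defines a receptor that interconverts between a low-affinity closed
#' conformation and a high-affinity conformation (open and desensitized
#' states pooled together and referred to as "open"). The receptor carries
#' `n_ortho` identical, independent orthosteric sites and `n_allo`
#' identical, independent allosteric sites; all orthosteric ligands compete
#' for the former, all allosteric ligands for the latter, and a ligand
#' occupies only its own site class. `gating_unliganded` is the
#' closed-to-open gating equilibrium constant of the unliganded receptor
#' (dimensionless); for resting pLGICs it is very small.
#'
#' @param ligands List of [ligand_spec()] objects with unique names.
#' @param gating_unliganded Unliganded gating equilibrium constant (> 0).
#' @param n_ortho Number of orthosteric sites (1..8; default 5, one per
#'   subunit of a homopentamer).
#' @param n_allo Number of allosteric sites (0..8; default 5).
#' @return A `receptor_model` object.
#' @export
#' @examples
#' m <- receptor_model(
#'   ligands = list(
#'     ligand_spec("toxin", "orthosteric", kd_closed = 1e-9, kd_open = 1e-8),
#'     ligand_spec("nicotine", "orthosteric", kd_closed = 1e-6, kd_open = 1e-8)
#'   ),
#'   gating_unliganded = 1e-6
#' )
receptor_model <- function(ligands = list(), gating_unliganded,
                           n_ortho = 5L, n_allo = 5L) {
  if (!is_scalar_number(gating_unliganded) || gating_unliganded <= 0) {
    stop_pl("'gating_unliganded' must be a positive dimensionless constant", "pl_domain_error")
  }
  if (!is_count(n_ortho, min = 1L) || n_ortho > .MAX_SITES) {
    stop_pl(sprintf("'n_ortho' must be an integer in 1..%d", .MAX_SITES), "pl_domain_error")
  }
  if (!is_count(n_allo, min = 0L) || n_allo > .MAX_SITES) {
    stop_pl(sprintf("'n_allo' must be an integer in 0..%d", .MAX_SITES), "pl_domain_error")
  }
  if (!is.list(ligands) || !all(vapply(ligands, inherits, TRUE, "ligand_spec"))) {
    stop_pl("'ligands' must be a list of ligand_spec objects", "pl_domain_error")
  }
  nms <- vapply(ligands, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_pl("ligand names must be unique", "pl_domain_error")
  names(ligands) <- nms
  structure(
    list(n_ortho = as.integer(n_ortho), n_allo = as.integer(n_allo),
         gating_unliganded = gating_unliganded, ligands = ligands),
    class = "receptor_model"
  )
}

#' @export
print.receptor_model <- function(x, ...) {
  cat(sprintf("<receptor_model> %d orthosteric + %d allosteric sites, K(C<=>O) = %.3g\n",
              x$n_ortho, x$n_allo, x$gating_unliganded))
  for (l in x$ligands) print(l)
  invisible(x)
}

# Look up a ligand by name (or pass through a ligand_spec); validates role.
.get_ligand <- function(model, ligand, role = NULL) {
  if (is.character(ligand)) {
    if (!ligand %in% names(model$ligands)) {
      stop_pl(sprintf("ligand '%s' is not part of the model", ligand), "pl_domain_error")
    }
    ligand <- model$ligands[[ligand]]
  }
  if (!inherits(ligand, "ligand_spec")) {
    stop_pl("'ligand' must be a ligand_spec or the name of one", "pl_domain_error")
  }
  if (!is.null(role) && ligand$role != role) {
    stop_pl(sprintf("ligand '%s' has role '%s'; '%s' required",
                    ligand$name, ligand$role, role), "pl_role_error")
  }
  ligand
}

# Validate free-concentration conditions: named, finite, non-negative,
# every name a model ligand. Returns a full named vector (absent = 0).
.check_conditions <- function(model, conc) {
  if (length(conc) == 0L) {
    conc <- numeric(0)
  }
  if (!is.numeric(conc) || (length(conc) > 0L && is.null(names(conc)))) {
    stop_pl("conditions must be a named numeric vector of free concentrations", "pl_domain_error")
  }
  unknown <- setdiff(names(conc), names(model$ligands))
  if (length(unknown)) {
    stop_pl(sprintf("unknown ligand(s) in conditions: %s", paste(unknown, collapse = ", ")),
            "pl_domain_error")
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_pl("free concentrations must be finite and non-negative", "pl_domain_error")
  }
  full <- stats::setNames(numeric(length(model$ligands)), names(model$ligands))
  full[names(conc)] <- conc
  full
}

#' Read or write a receptor-model configuration file
#'
#' Model parameters live in a flat YAML file with a `receptor` block
#' (`n_ortho`, `n_allo`, `gating_unliganded`) and one block per ligand
#' under `ligands` (`role`, `kd_closed`, `kd_open`, optional `units`,
#' one of M/mM/uM/nM/pM, default M). Concentrations are converted to molar
#' on read; files are written in molar.
#'
#' @param path Path to a YAML file.
#' @return `read_model_config()` returns a [receptor_model()];
#'   `write_model_config()` returns `path`, invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop_pl(sprintf("no such file: %s", path), "pl_format_error")
  cfg <- yaml::read_yaml(path)
  rec <- cfg$receptor
  if (is.null(rec) || is.null(rec$gating_unliganded)) {
    stop_pl("config must contain a 'receptor' block with 'gating_unliganded'", "pl_format_error")
  }
  ligands <- lapply(names(cfg$ligands), function(nm) {
    b <- cfg$ligands[[nm]]
    units <- if (is.null(b$units)) "M" else b$units
    ligand_spec(nm, role = b$role,
                kd_closed = to_molar(as.numeric(b$kd_closed), units),
                kd_open = to_molar(as.numeric(b$kd_open), units))
  })
  receptor_model(
    ligands = ligands,
    gating_unliganded = as.numeric(rec$gating_unliganded),
    n_ortho = if (is.null(rec$n_ortho)) 5L else as.integer(rec$n_ortho),
    n_allo = if (is.null(rec$n_allo)) 5L else as.integer(rec$n_allo)
  )
}

#' @rdname read_model_config
#' @param model A [receptor_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "receptor_model"))
  cfg <- list(
    receptor = list(n_ortho = model$n_ortho, n_allo = model$n_allo,
                    gating_unliganded = model$gating_unliganded),
    ligands = lapply(model$ligands, function(l) {
      list(role = l$role, kd_closed = l$kd_closed, kd_open = l$kd_open, units = "M")
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
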