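## Exact equilibrium solution of the two-conformation receptor.
##
## The statistical weight of a conformation c (closed weight fixed at 1 for
## the unliganded receptor, open weight = gating_unliganded) is
##   W_c = K_c * (1 + sum_L [L]/Kd_{L,c})^n_ortho * (1 + ...)^n_allo
## with one binding-polynomial factor per site class, because sites within a
## class are identical and independent given the conformation. Everything is
## evaluated in log space: (1 + x)^5-type products overflow doubles quickly
## at high concentration.

# Per-class sums of [L]/Kd for one conformation; returns list(ortho, allo).
.class_loads <- function(model, conc, state = c("closed", "open")) {
  state <- match.arg(state)
  loads <- c(orthosteric = 0, allosteric = 0)
  for (l in model$ligands) {
    x <- conc[[l$name]]
    if (x > 0) {
      kd <- if (state == "closed") l$kd_closed else l$kd_open
      loads[[l$role]] <- loads[[l$role]] + x / kd
    }
  }
  list(ortho = loads[["orthosteric"]], allo = loads[["allosteric"]])
}

.log_state_weights <- function(model, conc) {
  lc <- .class_loads(model, conc, "closed")
  lo <- .class_loads(model, conc, "open")
  list(
    closed = model$n_ortho * log1p(lc$ortho) + model$n_allo * log1p(lc$allo),
    open = log(model$gating_unliganded) +
      model$n_ortho * log1p(lo$ortho) + model$n_allo * log1p(lo$allo)
  )
}

#' Gating equilibrium constant of the m-liganded receptor
#'
#' For a receptor with `m` molecules of an orthosteric ligand bound, the
#' closed-to-open gating equilibrium constant equals the unliganded constant
#' multiplied by the ligand's conformational-preference ratio raised to the
#' number of bound molecules:
#' `K(Cm<=>Om) = K(C<=>O) * (kd_closed/kd_open)^m`.
#' Each bound agonist molecule therefore multiplies the gating equilibrium
#' by the same factor, the thermodynamic statement of identical, independent
#' sites.
#'
#' @param model A [receptor_model()].
#' @param ligand An orthosteric [ligand_spec()] or its name in `model`.
#' @param m Number of bound ligand molecules, `0..n_ortho`.
#' @return Dimensionless gating constant.
#' @export
#' @examples
#' m <- receptor_model(
#'   list(ligand_spec("ACh", "orthosteric", 1e-6, 1e-8)),
#'   gating_unliganded = 1e-6
#' )
#' liganded_gating_constant(m, "ACh", 5) # 1e-6 * 100^5 = 1e4
liganded_gating_constant <- function(model, ligand, m) {
  stopifnot(inherits(model, "receptor_model"))
  ligand <- .get_ligand(model, ligand, role = "orthosteric")
  if (!is_count(m) || m > model$n_ortho) {
    stop_pl(sprintf("'m' must be an integer in 0..%d", model$n_ortho), "pl_range_error")
  }
  model$gating_unliganded * (ligand$kd_closed / ligand$kd_open)^m
}

#' Statistical weights of the closed and open conformations
#'
#' Returns the binding-polynomial weights of the two conformations at the
#' given free-ligand concentrations, normalized so the unliganded closed
#' receptor has weight 1. The ratio open/closed is the gating equilibrium
#' constant under those conditions. Weights are computed in log space
#' internally; an error is raised if a weight cannot be represented as a
#' double (concentrations far beyond any physical regime).
#'
#' @param model A [receptor_model()].
#' @param conc Named numeric vector of free concentrations (molar); ligands
#'   not named are taken as absent.
#' @return Named numeric vector `c(closed = , open = )` with a `"log"`
#'   attribute holding the log weights.
#' @export
state_weights <- function(model, conc = numeric(0)) {
  stopifnot(inherits(model, "receptor_model"))
  conc <- .check_conditions(model, conc)
  lw <- .log_state_weights(model, conc)
  w <- c(closed = exp(lw$closed), open = exp(lw$open))
  if (any(!is.finite(w))) {
    stop_pl(sprintf(
      "state weight overflow (log closed = %.3g, log open = %.3g); concentrations too extreme",
      lw$closed, lw$open), "pl_computation_error")
  }
  attr(w, "log") <- c(closed = lw$closed, open = lw$open)
  w
}

#' Equilibrium conformational probabilities and mean site occupancies
#'
#' Solves the two-conformation model exactly at the given free-ligand
#' concentrations: the probability of the open (high-affinity) conformation
#' and, for every ligand, the expected number of its sites occupied. Given
#' the conformation, each site of a class is independently occupied by
#' ligand L with probability `x_L / (1 + sum of x over the class)`, where
#' `x_L = [L]/Kd` for that conformation; mean occupancies are these
#' single-site probabilities weighted by the conformational probabilities
#' and scaled by the class site count.
#'
#' @inheritParams state_weights
#' @return An `occupancy_result`: list with `p_open`, `p_closed`, and
#'   `mean_occupancy` (named numeric, expected sites bound per receptor).
#' @seealso [enumerate_microstates()] for the brute-force check.
#' @export
equilibrium_occupancy <- function(model, conc = numeric(0)) {
  stopifnot(inherits(model, "receptor_model"))
  conc <- .check_conditions(model, conc)
  lw <- .log_state_weights(model, conc)
  p_open <- stats::plogis(lw$open - lw$closed)
  p_closed <- 1 - p_open
  loads_c <- .class_loads(model, conc, "closed")
  loads_o <- .class_loads(model, conc, "open")
  occ <- vapply(model$ligands, function(l) {
    n_sites <- if (l$role == "orthosteric") model$n_ortho else model$n_allo
    if (n_sites == 0L || conc[[l$name]] == 0) return(0)
    xc <- conc[[l$name]] / l$kd_closed
    xo <- conc[[l$name]] / l$kd_open
    denom_c <- 1 + if (l$role == "orthosteric") loads_c$ortho else loads_c$allo
    denom_o <- 1 + if (l$role == "orthosteric") loads_o$ortho else loads_o$allo
    n_sites * (p_closed * xc / denom_c + p_open * xo / denom_o)
  }, numeric(1))
  structure(
    list(p_open = p_open, p_closed = p_closed, mean_occupancy = occ),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy> p(open) = %.4g, p(closed) = %.4g\n", x$p_open, x$p_closed))
  if (length(x$mean_occupancy)) {
    for (nm in names(x$mean_occupancy)) {
      cat(sprintf("  %s: %.4g sites bound\n", nm, x$mean_occupancy[[nm]]))
    }
  }
  invisible(x)
}

# Joint microstate cap: 2 conformations x per-site assignments.
.MAX_MICROSTATES <- 2e6

#' Exhaustive microstate enumeration (test oracle)
#'
#' Computes the same quantities as [equilibrium_occupancy()] by explicitly
#' summing the Boltzmann weight of every microstate — each conformation
#' crossed with every assignment of each individual site to "empty" or to
#' one of the ligands of its class. Exists as an independent brute-force
#' check of the closed-form binding-polynomial solution; use
#' [equilibrium_occupancy()] for real work.
#'
#' @inheritParams state_weights
#' @return An `occupancy_result`.
#' @export
enumerate_microstates <- function(model, conc = numeric(0)) {
  stopifnot(inherits(model, "receptor_model"))
  conc <- .check_conditions(model, conc)
  if (model$n_ortho > .MAX_SITES || model$n_allo > .MAX_SITES) {
    stop_pl("site counts exceed the enumeration limit", "pl_capacity_error")
  }
  if (length(model$ligands) > 4L) {
    stop_pl("enumeration oracle supports at most 4 ligands", "pl_capacity_error")
  }
  ortho <- Filter(function(l) l$role == "orthosteric", model$ligands)
  allo <- Filter(function(l) l$role == "allosteric", model$ligands)
  n_states <- 2 * (length(ortho) + 1)^model$n_ortho * (length(allo) + 1)^model$n_allo
  if (n_states > .MAX_MICROSTATES) {
    stop_pl(sprintf("%.3g microstates exceed the enumeration cap", n_states),
            "pl_capacity_error")
  }

  # Per-site statistical weight of choice j (1 = empty, j+1 = ligand j):
  # 1 or [L]/Kd for the given conformation.
  site_options <- function(ligs, state) {
    c(1, vapply(ligs, function(l) {
      conc[[l$name]] / (if (state == "closed") l$kd_closed else l$kd_open)
    }, numeric(1)))
  }
  n_sites <- model$n_ortho + model$n_allo
  choice_sets <- c(
    rep(list(seq_len(length(ortho) + 1L)), model$n_ortho),
    rep(list(seq_len(length(allo) + 1L)), model$n_allo)
  )
  grid <- as.matrix(expand.grid(choice_sets, KEEP.OUT.ATTRS = FALSE))

  state_sum <- function(state) {
    wo <- site_options(ortho, state)
    wa <- site_options(allo, state)
    w <- rep(1, nrow(grid))
    for (j in seq_len(n_sites)) {
      lookup <- if (j <= model$n_ortho) wo else wa
      w <- w * lookup[grid[, j]]
    }
    w
  }
  w_closed <- state_sum("closed")
  w_open <- model$gating_unliganded * state_sum("open")
  z_closed <- sum(w_closed)
  z_open <- sum(w_open)
  z <- z_closed + z_open

  occ <- stats::setNames(numeric(length(model$ligands)), names(model$ligands))
  for (l in model$ligands) {
    if (l$role == "orthosteric") {
      idx <- match(l$name, names(ortho)) + 1L
      cols <- seq_len(model$n_ortho)
    } else {
      idx <- match(l$name, names(allo)) + 1L
      cols <- model$n_ortho + seq_len(model$n_allo)
    }
    cnt <- if (length(cols)) rowSums(grid[, cols, drop = FALSE] == idx) else 0
    occ[[l$name]] <- sum(cnt * (w_closed + w_open)) / z
  }
  structure(
    list(p_open = z_open / z, p_closed = z_closed / z, mean_occupancy = occ),
    class = "occupancy_result"
  )
}

#' Mean labeled-toxin occupancy in a toxin-vs-toxin competition
#'
#' When both the labeled and the unlabeled ligand are the same closed-state-
#' preferring toxin, the receptor remains closed throughout the titration and
#' the mean number of sites occupied by labeled toxin reduces to the closed
#' form `n * [labeled] / (kd_closed + [labeled] + [unlabeled])`.
#'
#' @param n Total number of toxin-binding sites per receptor.
#' @param kd_closed Toxin dissociation constant from the closed conformation
#'   (molar, > 0).
#' @param labeled Free labeled-toxin concentration (molar, >= 0).
#' @param unlabeled Free unlabeled-toxin concentration(s) (molar, >= 0);
#'   may be a vector spanning a titration.
#' @return Expected number of sites bound by labeled toxin.
#' @export
#' @examples
#' toxin_toxin_occupancy(5, 1e-9, labeled = 1e-9, unlabeled = 0) # 2.5
toxin_toxin_occupancy <- function(n, kd_closed, labeled, unlabeled) {
  if (!is_count(n, min = 0L)) stop_pl("'n' must be a non-negative integer", "pl_domain_error")
  if (!is_scalar_number(kd_closed) || kd_closed <= 0) {
    stop_pl("'kd_closed' must be > 0", "pl_domain_error")
  }
  if (!is_scalar_number(labeled) || labeled < 0 ||
      !is.numeric(unlabeled) || any(!is.finite(unlabeled)) || any(unlabeled < 0)) {
    stop_pl("concentrations must be non-negative", "pl_domain_error")
  }
  n * labeled / (kd_closed + labeled + unlabeled)
}

#' Half-competition concentration of an unlabeled toxin
#'
#' The unlabeled-toxin concentration that reduces labeled-toxin binding to
#' half its no-competitor value: `kd_closed + [labeled]`. With the labeled
#' toxin clamped at one times its closed-state Kd this equals
#' `2 * kd_closed`, so the half-competition point of an inverse agonist
#' reads out its closed-state dissociation constant directly.
#'
#' @inheritParams toxin_toxin_occupancy
#' @return Concentration (molar).
#' @export
toxin_half_competition <- function(kd_closed, labeled) {
  if (!is_scalar_number(kd_closed) || kd_closed <= 0) {
    stop_pl("'kd_closed' must be > 0", "pl_domain_error")
  }
  if (!is_scalar_number(labeled) || labeled < 0) {
    stop_pl("'labeled' must be non-negative", "pl_domain_error")
  }
  kd_closed + labeled
}
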