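## Simulation of labeled-toxin competition-binding curves.

#' Specify a binding-competition titration
#'
#' Describes one competition assay: a labeled orthosteric ligand clamped at
#' a fixed free concentration (`label_level` times its closed-state Kd, as
#' in radioligand assays run at ~1 x Kd,closed), titrated against an
#' unlabeled orthosteric competitor over `competitor_grid`, optionally in
#' the constant presence of an allosteric modulator. By default the free
#' concentrations are clamped (the experimental regime in which ligand
#' depletion is negligible); setting `depletion = TRUE` interprets all
#' concentrations as totals and solves the mass balance for a finite
#' receptor concentration `receptor_total`.
#'
#' @param label Name of the labeled orthosteric ligand.
#' @param competitor Name of the unlabeled orthosteric competitor.
#' @param competitor_grid Increasing concentrations (molar); a single
#'   leading 0 is permitted (and recommended) as the normalization anchor.
#' @param label_level Free labeled-ligand concentration as a multiple of its
#'   `kd_closed` (default 1).
#' @param modulator Optional name of an allosteric modulator held at
#'   `modulator_concentration` along the whole curve.
#' @param modulator_concentration Modulator concentration (molar).
#' @param depletion Correct for ligand depletion? Default `FALSE`.
#' @param receptor_total Total receptor-site... receptor concentration
#'   (molar); required when `depletion = TRUE`.
#' @return A `competition_curve_spec` object.
#' @export
competition_curve_spec <- function(label, competitor, competitor_grid,
                                   label_level = 1, modulator = NULL,
                                   modulator_concentration = 0,
                                   depletion = FALSE, receptor_total = NULL) {
  if (!is.numeric(competitor_grid) || length(competitor_grid) < 2L ||
      any(!is.finite(competitor_grid)) || any(competitor_grid < 0)) {
    stop_pl("'competitor_grid' must be >= 2 finite non-negative concentrations",
            "pl_domain_error")
  }
  pos <- competitor_grid[competitor_grid > 0]
  if (sum(competitor_grid == 0) > 1L || any(diff(pos) <= 0) ||
      (any(competitor_grid == 0) && competitor_grid[1] != 0)) {
    stop_pl("'competitor_grid' must be strictly increasing after an optional leading 0",
            "pl_domain_error")
  }
  if (!is_scalar_number(label_level) || label_level <= 0) {
    stop_pl("'label_level' must be > 0", "pl_domain_error")
  }
  if (!is.null(modulator) &&
      (!is_scalar_number(modulator_concentration) || modulator_concentration < 0)) {
    stop_pl("'modulator_concentration' must be >= 0", "pl_domain_error")
  }
  if (isTRUE(depletion) && (!is_scalar_number(receptor_total) || receptor_total < 0)) {
    stop_pl("'receptor_total' (>= 0) is required when depletion is on", "pl_domain_error")
  }
  structure(
    list(label = label, competitor = competitor, competitor_grid = competitor_grid,
         label_level = label_level, modulator = modulator,
         modulator_concentration = modulator_concentration,
         depletion = isTRUE(depletion), receptor_total = receptor_total),
    class = "competition_curve_spec"
  )
}

# Conditions at one grid point; free or total depending on depletion flag.
.curve_conditions <- function(model, spec, competitor_conc) {
  label <- .get_ligand(model, spec$label, role = "orthosteric")
  conc <- stats::setNames(
    c(spec$label_level * label$kd_closed, competitor_conc),
    c(label$name, spec$competitor)
  )
  if (!is.null(spec$modulator)) {
    conc[[spec$modulator]] <- spec$modulator_concentration
  }
  conc
}

.curve_occupancy <- function(model, spec, competitor_conc) {
  conc <- .curve_conditions(model, spec, competitor_conc)
  if (spec$depletion) {
    conc <- solve_free_concentrations(model, conc, spec$receptor_total)
  }
  equilibrium_occupancy(model, conc)
}

#' Simulate a binding-competition curve
#'
#' Computes the equilibrium bound-label signal at every grid concentration
#' of the unlabeled competitor, normalized to the zero-competitor value
#' (fraction of control). When a modulator is present, its expected
#' allosteric-site occupancy along the curve is reported as well — the
#' modulator binds and unbinds as the receptor is driven between
#' conformations, even though its free concentration is constant.
#'
#' @param model A [receptor_model()] containing all named ligands.
#' @param spec A [competition_curve_spec()].
#' @return A `competition_curve`: data frame with columns `concentration`,
#'   `signal`, and (if a modulator is present) `modulator_occupancy`, plus
#'   attributes `spec` and `label_concentration`.
#' @export
#' @examples
#' m <- receptor_model(
#'   list(ligand_spec("toxin", "orthosteric", 1e-9, 1e-8),
#'        ligand_spec("MLA", "orthosteric", 5e-9, 5e-8)),
#'   gating_unliganded = 1e-6
#' )
#' sp <- competition_curve_spec("toxin", "MLA", default_competitor_grid(1e-11, 1e-6))
#' curve <- simulate_competition_curve(m, sp)
#' half_competition(curve) # ~2 x 5e-9
simulate_competition_curve <- function(model, spec) {
  stopifnot(inherits(model, "receptor_model"), inherits(spec, "competition_curve_spec"))
  label <- .get_ligand(model, spec$label, role = "orthosteric")
  .get_ligand(model, spec$competitor, role = "orthosteric")
  if (!is.null(spec$modulator)) .get_ligand(model, spec$modulator, role = "allosteric")

  occ0 <- .curve_occupancy(model, spec, 0)$mean_occupancy[[label$name]]
  if (!is.finite(occ0) || occ0 <= 0) {
    stop_pl("zero bound label at zero competitor; cannot normalize the curve",
            "pl_normalization_error")
  }
  res <- lapply(spec$competitor_grid, function(cc) .curve_occupancy(model, spec, cc))
  signal <- vapply(res, function(r) r$mean_occupancy[[label$name]], numeric(1)) / occ0
  out <- data.frame(concentration = spec$competitor_grid, signal = signal)
  if (!is.null(spec$modulator)) {
    out$modulator_occupancy <-
      vapply(res, function(r) r$mean_occupancy[[spec$modulator]], numeric(1))
  }
  structure(out,
            spec = spec,
            label_concentration = spec$label_level * label$kd_closed,
            class = c("competition_curve", "data.frame"))
}

#' Expected modulator occupancy along a competition curve
#'
#' @inheritParams simulate_competition_curve
#' @return Numeric vector: expected allosteric sites bound per receptor at
#'   each grid point.
#' @export
modulator_occupancy_profile <- function(model, spec) {
  stopifnot(inherits(model, "receptor_model"), inherits(spec, "competition_curve_spec"))
  if (is.null(spec$modulator)) {
    stop_pl("curve spec names no modulator", "pl_spec_error")
  }
  curve <- simulate_competition_curve(model, spec)
  curve$modulator_occupancy
}

#' Locate the half-competition concentration of a curve
#'
#' Finds the competitor concentration at which the normalized signal equals
#' 0.5, by monotone (Fritsch-Carlson) interpolation of signal against log
#' concentration followed by root bracketing/bisection to 1e-6 relative
#' precision. The curve must be monotone non-increasing and must cross 0.5.
#'
#' @param curve A `competition_curve`, or any data frame with
#'   `concentration` and `signal` columns.
#' @return Concentration (molar) at signal = 0.5.
#' @export
half_competition <- function(curve) {
  conc <- curve$concentration
  sig <- curve$signal
  if (is.null(conc) || is.null(sig)) {
    stop_pl("'curve' needs 'concentration' and 'signal' columns", "pl_domain_error")
  }
  if (any(diff(sig) > 1e-9)) {
    stop_pl("signal is not monotone non-increasing", "pl_domain_error")
  }
  if (min(sig) > 0.5 || max(sig) < 0.5) {
    stop_pl("signal never crosses 0.5; no half-competition point on this grid",
            "pl_not_crossed_error")
  }
  keep <- conc > 0
  lx <- log10(conc[keep])
  y <- sig[keep]
  if (y[1] <= 0.5) return(conc[keep][1]) # crossed at/before first titrated point
  f <- stats::splinefun(lx, y, method = "monoH.FC")
  i <- which(y <= 0.5)[1]
  root <- stats::uniroot(function(l) f(l) - 0.5, lower = lx[i - 1], upper = lx[i],
                         tol = 1e-7)$root
  10^root
}

#' Solve free-ligand concentrations under depletion
#'
#' Given total ligand concentrations and a total receptor concentration,
#' finds the free concentrations satisfying the simultaneous mass balances
#' `free_L + receptor_total * occupancy_L(free) = total_L`. Solved by
#' cyclic per-ligand bisection (each single-ligand balance is monotone in
#' its own free concentration) iterated to a relative residual below 1e-10.
#'
#' @param model A [receptor_model()].
#' @param totals Named numeric vector of total concentrations (molar).
#' @param receptor_total Total receptor concentration (molar, >= 0).
#' @param tol Relative residual tolerance.
#' @param max_sweeps Iteration cap before a convergence error.
#' @return Named numeric vector of free concentrations with attribute
#'   `"residual"` (relative mass-balance residuals).
#' @export
solve_free_concentrations <- function(model, totals, receptor_total,
                                      tol = 1e-10, max_sweeps = 200L) {
  stopifnot(inherits(model, "receptor_model"))
  totals <- .check_conditions(model, totals)
  if (!is_scalar_number(receptor_total) || receptor_total < 0) {
    stop_pl("'receptor_total' must be >= 0", "pl_domain_error")
  }
  if (receptor_total == 0 || all(totals == 0)) {
    attr(totals, "residual") <- totals * 0
    return(totals)
  }
  free <- totals
  active <- names(totals)[totals > 0]
  rel_resid <- function(free) {
    occ <- equilibrium_occupancy(model, free)$mean_occupancy
    (free + receptor_total * occ[names(free)] - totals) / pmax(totals, .Machine$double.xmin)
  }
  for (sweep in seq_len(max_sweeps)) {
    for (nm in active) {
      g <- function(fl) {
        trial <- free
        trial[[nm]] <- fl
        occ <- equilibrium_occupancy(model, trial)$mean_occupancy[[nm]]
        fl + receptor_total * occ - totals[[nm]]
      }
      # g(0) <= 0 and g(total) >= 0: bisect on [0, total]. The tolerance is
      # left at the floating-point floor because g can be extremely stiff
      # (slope ~ receptor_total * n / kd for tight binders), and Brent's
      # eps * |root| term then sets the achievable precision.
      free[[nm]] <- stats::uniroot(g, lower = 0, upper = totals[[nm]],
                                   tol = 1e-300, maxiter = 10000L)$root
    }
    r <- rel_resid(free)
    if (max(abs(r)) < tol) {
      attr(free, "residual") <- r
      return(free)
    }
  }
  stop_pl(sprintf("depletion solver did not converge in %d sweeps (max residual %.3g)",
                  max_sweeps, max(abs(rel_resid(free)))), "pl_convergence_error")
}

#' Write or read competition curves as delimited text
#'
#' The on-disk format is tab-separated with columns `concentration_M`,
#' `signal`, `modulator_occupancy` (NA when absent), and `curve_id`;
#' lines starting with `#` carry provenance and are ignored on read.
#'
#' @param curves A `competition_curve`, an `assay_dataset`, or a data frame
#'   with `concentration` and `signal` (and optionally `curve_id`,
#'   `modulator_occupancy`) columns.
#' @param path Output path.
#' @param provenance Optional character vector of header comment lines
#'   (written prefixed with `#`).
#' @return `write_curves()` returns `path` invisibly; `read_curves()`
#'   returns an [assay_dataset()].
#' @export
write_curves <- function(curves, path, provenance = NULL) {
  df <- as.data.frame(curves)
  if (is.null(df$curve_id)) df$curve_id <- 1L
  if (is.null(df$modulator_occupancy)) df$modulator_occupancy <- NA_real_
  out <- data.frame(concentration_M = df$concentration, signal = df$signal,
                    modulator_occupancy = df$modulator_occupancy,
                    curve_id = df$curve_id)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop_pl(sprintf("no such file: %s", path), "pl_format_error")
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("concentration_M", "signal", "curve_id")
  if (!all(need %in% names(df))) {
    stop_pl(sprintf("curve file must have columns %s", paste(need, collapse = ", ")),
            "pl_format_error")
  }
  assay_dataset(data.frame(curve_id = df$curve_id,
                           concentration = df$concentration_M,
                           signal = df$signal))
}
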