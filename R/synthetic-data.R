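## Seeded generators: competition-assay datasets with counting noise, and
## toy alignments with planted indels. Every other module is testable
## against these without any external data.

#' Counting-noise model for synthetic assays
#'
#' Describes how replicate competition measurements are corrupted: bound
#' label is measured as a radioactive count, so a Poisson draw with mean
#' `count_scale * (background_fraction + (1 - background_fraction) * signal)`
#' emulates gamma-counting of a washed pellet with a residual nonspecific
#' background. `count_scale` is the expected count at full (zero-competitor)
#' signal and sets the relative noise; each concentration is measured
#' `n_duplicates` times on each of `n_curves` independent curves.
#'
#' Defaults mirror a typical radioligand competition assay: ~2000 counts at
#' full signal, a 2% residual nonspecific background after washing,
#' duplicate measurements, and three independent curves per condition.
#'
#' @param count_scale Expected counts at full signal (> 0; `Inf` for
#'   noiseless data).
#' @param background_fraction Nonspecific fraction of full signal
#'   (0 <= x < 1).
#' @param n_duplicates Technical duplicates per concentration (>= 1).
#' @param n_curves Independent curves per condition (>= 1).
#' @param seed Integer seed; the single source of randomness.
#' @return A `noise_model` object.
#' @export
noise_model <- function(count_scale = 2000, background_fraction = 0.02,
                        n_duplicates = 2L, n_curves = 3L, seed = 1L) {
  if (!(is_scalar_number(count_scale) && count_scale > 0) && !identical(count_scale, Inf)) {
    stop_pl("'count_scale' must be > 0 (or Inf for noiseless data)", "pl_domain_error")
  }
  if (!is_scalar_number(background_fraction) || background_fraction < 0 ||
      background_fraction >= 1) {
    stop_pl("'background_fraction' must be in [0, 1)", "pl_domain_error")
  }
  if (!is_count(n_duplicates, min = 1L) || !is_count(n_curves, min = 1L)) {
    stop_pl("'n_duplicates' and 'n_curves' must be integers >= 1", "pl_domain_error")
  }
  if (!is_count(seed)) stop_pl("'seed' must be a single integer", "pl_domain_error")
  structure(
    list(count_scale = count_scale, background_fraction = background_fraction,
         n_duplicates = as.integer(n_duplicates), n_curves = as.integer(n_curves),
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Hill-equation ground truth for synthetic assays
#'
#' Defines a noiseless competition curve directly by Hill parameters, as an
#' alternative to simulating one from a [receptor_model()].
#'
#' @param half_competition Component IC50s (molar, > 0).
#' @param hill_coefficient Component Hill coefficients (> 0).
#' @param fraction Component amplitude fractions (sum to 1; default equal).
#' @param grid Competitor concentrations (molar), first entry 0 recommended.
#' @return A `hill_truth` object.
#' @export
hill_truth <- function(half_competition, hill_coefficient = 1,
                       fraction = NULL, grid) {
  k <- length(half_competition)
  hill_coefficient <- rep_len(hill_coefficient, k)
  if (is.null(fraction)) fraction <- rep(1 / k, k)
  if (any(half_competition <= 0) || any(hill_coefficient <= 0) ||
      abs(sum(fraction) - 1) > 1e-9) {
    stop_pl("need positive IC50s and Hill coefficients, fractions summing to 1",
            "pl_domain_error")
  }
  if (!is.numeric(grid) || any(grid < 0)) stop_pl("bad grid", "pl_domain_error")
  structure(
    list(half_competition = half_competition, hill_coefficient = hill_coefficient,
         fraction = fraction, grid = grid),
    class = "hill_truth"
  )
}

# Noiseless mean curve + reference IC50 for either kind of truth.
.truth_curve <- function(truth) {
  if (inherits(truth, "hill_truth")) {
    sig <- hill_mixture(truth$grid, truth$fraction, truth$half_competition,
                        truth$hill_coefficient)
    list(grid = truth$grid, signal = sig,
         half_competition = if (length(truth$half_competition) == 1L)
           truth$half_competition else NA_real_,
         truth = truth)
  } else if (is.list(truth) && inherits(truth$model, "receptor_model") &&
             inherits(truth$spec, "competition_curve_spec")) {
    curve <- simulate_competition_curve(truth$model, truth$spec)
    hc <- tryCatch(half_competition(curve), plgicomp_error = function(e) NA_real_)
    list(grid = curve$concentration, signal = curve$signal,
         half_competition = hc, truth = truth)
  } else {
    stop_pl("'truth' must be a hill_truth or list(model = , spec = )", "pl_domain_error")
  }
}

#' Generate a synthetic competition-assay dataset
#'
#' Draws replicate competition curves around a known noiseless truth —
#' either a mechanistic [receptor_model()] plus [competition_curve_spec()]
#' (pass `list(model = , spec = )`) or explicit Hill parameters
#' ([hill_truth()]). Raw counts are Poisson around
#' `count_scale * (bg + (1 - bg) * signal)`; the returned signal is
#' *specific* binding — the known background fraction is subtracted (as a
#' mock-transfection control subtracts nonspecific binding) and each curve
#' is normalized to its own zero-competitor mean. Identical seeds reproduce
#' identical datasets; the caller's RNG state is left untouched.
#'
#' @param truth `list(model = , spec = )` or a [hill_truth()].
#' @param noise A [noise_model()].
#' @param condition Optional condition label for the dataset.
#' @return A `synthetic_assay`: list with `data` (an [assay_dataset()]),
#'   `truth` (including the reference `half_competition` of the noiseless
#'   curve), `noiseless` (the mean curve), `noise`, and `seed`.
#' @export
generate_assay <- function(truth, noise = noise_model(), condition = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  tc <- .truth_curve(truth)
  grid <- tc$grid
  if (grid[1] != 0) {
    grid <- c(0, grid)
    tc$signal <- c(1, tc$signal)
  }
  bg <- noise$background_fraction
  mu <- noise$count_scale * (bg + (1 - bg) * tc$signal)
  rows <- with_seed(noise$seed, {
    out <- vector("list", noise$n_curves)
    for (i in seq_len(noise$n_curves)) {
      raw <- if (is.finite(noise$count_scale)) {
        matrix(stats::rpois(length(mu) * noise$n_duplicates, rep(mu, noise$n_duplicates)),
               nrow = length(mu)) / noise$count_scale
      } else {
        matrix(rep(bg + (1 - bg) * tc$signal, noise$n_duplicates), nrow = length(mu))
      }
      specific <- raw - bg
      anchor <- mean(specific[grid == 0, ])
      out[[i]] <- data.frame(
        curve_id = i,
        concentration = rep(grid, noise$n_duplicates),
        signal = as.vector(specific) / anchor
      )
    }
    do.call(rbind, out)
  })
  structure(
    list(data = assay_dataset(rows, condition = condition),
         truth = c(tc["truth"], list(half_competition = tc$half_competition)),
         noiseless = data.frame(concentration = grid, signal = tc$signal),
         noise = noise, seed = noise$seed),
    class = "synthetic_assay"
  )
}

#' Generate a toy alignment with planted indels
#'
#' Builds an `n_rows`-row gapped alignment around a reference row (always
#' row 1, id `"ref"`) of `ref_length` residues, planting the requested
#' deletion and insertion columns so that downstream classification has an
#' exactly known ground truth. A deletion plant at reference position `p`
#' gaps `n_affected` non-reference rows in the column holding reference
#' residue `p`; an insertion plant at `p` adds one column immediately after
#' reference residue `p` in which exactly `n_affected` non-reference rows
#' carry a residue and the reference is gapped.
#'
#' @param n_rows Number of sequences (>= 2).
#' @param ref_length Number of reference residues (>= 2).
#' @param planted_indels Data frame (or list coercible to one) with columns
#'   `position` (1..`ref_length`; insertions require `position <
#'   ref_length`), `kind` (`"deletion"` or `"insertion"`), `n_affected`
#'   (1..`n_rows - 1`). Two plants may not share the same position and kind.
#' @param seed Integer seed for residue content and affected-row choice.
#' @return An [alignment()] with attribute `"plan"` (the normalized plant
#'   table).
#' @export
generate_toy_alignment <- function(n_rows, ref_length, planted_indels = NULL,
                                   seed = 1L) {
  if (!is_count(n_rows, min = 2L) || !is_count(ref_length, min = 2L)) {
    stop_pl("'n_rows' >= 2 and 'ref_length' >= 2 required", "pl_domain_error")
  }
  plan <- if (is.null(planted_indels) || (is.data.frame(planted_indels) && !nrow(planted_indels))) {
    data.frame(position = integer(0), kind = character(0), n_affected = integer(0))
  } else {
    as.data.frame(planted_indels)
  }
  if (nrow(plan)) {
    need <- c("position", "kind", "n_affected")
    if (!all(need %in% names(plan))) {
      stop_pl("plants need columns position, kind, n_affected", "pl_design_error")
    }
    if (!all(plan$kind %in% c("deletion", "insertion"))) {
      stop_pl("plant kind must be 'deletion' or 'insertion'", "pl_design_error")
    }
    bad <- plan$position < 1 | plan$position > ref_length |
      (plan$kind == "insertion" & plan$position >= ref_length)
    if (any(bad)) stop_pl("plant positions outside the reference span", "pl_design_error")
    if (any(plan$n_affected < 1 | plan$n_affected > n_rows - 1)) {
      stop_pl("'n_affected' must be in 1..(n_rows - 1)", "pl_design_error")
    }
    if (anyDuplicated(plan[c("position", "kind")])) {
      stop_pl("overlapping plants: same position and kind listed twice", "pl_design_error")
    }
    plan <- plan[order(plan$position, plan$kind), , drop = FALSE]
    rownames(plan) <- NULL
  }

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    mat <- matrix(sample(aa, n_rows * ref_length, replace = TRUE), nrow = n_rows)
    cols <- lapply(seq_len(ref_length), function(p) mat[, p])
    ins_after <- vector("list", ref_length) # insertion columns keyed by position
    for (i in seq_len(nrow(plan))) {
      p <- plan$position[i]
      affected <- sample(2:n_rows, plan$n_affected[i])
      if (plan$kind[i] == "deletion") {
        cols[[p]][affected] <- "-"
      } else {
        newcol <- rep("-", n_rows)
        newcol[affected] <- sample(aa, plan$n_affected[i], replace = TRUE)
        ins_after[[p]] <- newcol
      }
    }
    all_cols <- list()
    for (p in seq_len(ref_length)) {
      all_cols[[length(all_cols) + 1L]] <- cols[[p]]
      if (!is.null(ins_after[[p]])) all_cols[[length(all_cols) + 1L]] <- ins_after[[p]]
    }
    seqs <- apply(do.call(cbind, all_cols), 1, paste, collapse = "")
    aln <- alignment(ids = c("ref", sprintf("seq%02d", seq_len(n_rows - 1L))),
                     seqs = seqs)
    attr(aln, "plan") <- plan
    aln
  })
}
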