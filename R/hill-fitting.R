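## Global weighted Hill fitting of replicate competition curves,
## component-count selection, and fold shifts with propagated uncertainty.

#' Assemble replicate competition data for fitting
#'
#' An assay dataset holds the pooled points of all replicate curves for one
#' experimental condition: `curve_id`, `concentration` (molar), normalized
#' `signal`, and a positive fitting `weight`. When the `weight` column is
#' absent it defaults to the reciprocal of the per-concentration variance of
#' the replicate signals (pooled over curves and duplicates at the same
#' concentration), falling back to unit weights when any variance is zero or
#' undefined (e.g. noiseless or unreplicated data).
#'
#' @param points Data frame with columns `curve_id`, `concentration`,
#'   `signal`, and optionally `weight`.
#' @param condition Optional condition label carried through to fits.
#' @return An `assay_dataset` (a classed data frame).
#' @export
assay_dataset <- function(points, condition = NULL) {
  need <- c("curve_id", "concentration", "signal")
  if (!is.data.frame(points) || !all(need %in% names(points))) {
    stop_pl(sprintf("'points' must be a data frame with columns %s",
                    paste(need, collapse = ", ")), "pl_domain_error")
  }
  if (any(!is.finite(points$concentration)) || any(points$concentration < 0) ||
      any(!is.finite(points$signal))) {
    stop_pl("concentrations must be finite and >= 0, signals finite", "pl_domain_error")
  }
  per_curve <- tapply(points$concentration, points$curve_id,
                      function(x) length(unique(x)))
  if (any(per_curve < 4L)) {
    stop_pl("each curve needs >= 4 distinct concentrations", "pl_domain_error")
  }
  if (is.null(points$weight)) {
    points$weight <- .default_weights(points)
  }
  if (any(!is.finite(points$weight)) || any(points$weight <= 0)) {
    stop_pl("weights must be finite and > 0", "pl_domain_error")
  }
  structure(as.data.frame(points), condition = condition,
            class = c("assay_dataset", "data.frame"))
}

# Inverse-variance weights from the replicates at each concentration. The
# per-concentration variances are smoothed through a linear variance-mean
# relation (counting noise: variance grows with the mean signal) and floored
# at 10% of their median, because weighting each point by the raw empirical
# variance of the very replicates being fitted both degrades the estimator
# and biases its standard errors low. Unit weights when replication is
# absent or the data are noiseless.
.default_weights <- function(points) {
  v <- tapply(points$signal, points$concentration, stats::var)
  if (any(!is.finite(v)) || any(v <= .Machine$double.eps) || length(v) < 3L) {
    return(rep(1, nrow(points)))
  }
  m <- as.vector(tapply(points$signal, points$concentration, mean))
  pred <- tryCatch({
    co <- stats::coef(stats::lm(as.vector(v) ~ m))
    co[1] + co[2] * m
  }, error = function(e) rep(mean(v), length(v)))
  pred <- pmax(pred, 0.1 * stats::median(as.vector(v)))
  names(pred) <- names(v)
  unname(1 / pred[as.character(points$concentration)])
}

#' Sum-of-Hill-components competition model
#'
#' Evaluates `sum_k a_k / (1 + (c/ic50_k)^nh_k)` — the lower plateau is
#' fixed at 0 because signals are normalized fractions of control.
#'
#' @param conc Concentrations (molar).
#' @param amplitude,ic50,hill Equal-length component parameter vectors.
#' @return Predicted signal.
#' @keywords internal
hill_mixture <- function(conc, amplitude, ic50, hill) {
  out <- numeric(length(conc))
  for (k in seq_along(amplitude)) {
    out <- out + amplitude[k] / (1 + (conc / ic50[k])^hill[k])
  }
  out
}

# Concentration at which the per-concentration mean signal first crosses
# `level`, log-interpolated; used only for starting values.
.crossing_conc <- function(conc, means, level) {
  pos <- conc > 0
  cc <- conc[pos]
  mm <- means[pos]
  below <- which(mm <= level)
  if (!length(below)) return(cc[length(cc)])
  i <- below[1]
  if (i == 1L) return(cc[1])
  l1 <- log10(cc[i - 1]); l2 <- log10(cc[i])
  frac <- (mm[i - 1] - level) / (mm[i - 1] - mm[i])
  10^(l1 + frac * (l2 - l1))
}

#' Fit Hill components globally to replicate competition curves
#'
#' Weighted least-squares fit of `signal = sum_k a_k / (1 + (c/ic50_k)^nh_k)`
#' with all parameters shared across the replicate curves of the dataset.
#' Optimization runs on `log(a)`, `log10(ic50)` and `log(nh)` with a
#' Levenberg-Marquardt solver and deterministic starting values (half-signal
#' crossing for ic50, nh = 1, equal amplitudes); standard errors come from
#' the inverse Gauss-Newton Hessian scaled by the reduced chi-square, mapped
#' back to the natural scale by the delta method. Sub-unity Hill
#' coefficients are reported as fitted, never clamped.
#'
#' @param data An [assay_dataset()] (or a plain data frame acceptable to it).
#' @param n_components Number of Hill components (>= 1).
#' @return A `hill_fit`: list with `n_components`; `components` (data frame
#'   of `half_competition`, `hill_coefficient`, `amplitude`, `fraction` and
#'   their SEs, ordered by increasing half-competition); amplitude total;
#'   and `gof` (weighted RSS, degrees of freedom, reduced chi-square, AICc).
#' @export
fit_hill <- function(data, n_components = 1L) {
  if (!inherits(data, "assay_dataset")) data <- assay_dataset(data)
  if (!is_count(n_components, min = 1L)) {
    stop_pl("'n_components' must be an integer >= 1", "pl_domain_error")
  }
  k <- as.integer(n_components)
  n_par <- 3L * k
  if (nrow(data) <= n_par) {
    stop_pl("not enough points to identify the requested components", "pl_identifiability_error")
  }
  conc <- data$concentration
  y <- data$signal
  sw <- sqrt(data$weight)

  ## Deterministic starting heuristic from per-concentration means.
  uc <- sort(unique(conc))
  means <- vapply(uc, function(ci) mean(y[conc == ci]), numeric(1))
  rng <- max(means) - min(means)
  if (!is.finite(rng) || rng < 0.2) {
    stop_pl("signal range too small to identify a competition component",
            "pl_identifiability_error")
  }
  top <- means[1]
  levels <- min(means) + (k:1 - 0.5) / k * rng
  ic0 <- vapply(levels, function(lv) .crossing_conc(uc, means, lv), numeric(1))
  theta0 <- c(log(rep(max(top, 0.05) / k, k)), log10(ic0), rep(0, k))

  unpack <- function(theta) {
    list(a = exp(theta[seq_len(k)]),
         ic50 = 10^theta[k + seq_len(k)],
         nh = exp(theta[2L * k + seq_len(k)]))
  }
  resid_fn <- function(theta) {
    p <- unpack(theta)
    sw * (y - hill_mixture(conc, p$a, p$ic50, p$nh))
  }
  # Analytic Jacobian of the residuals wrt (log a, log10 ic50, log nh):
  # finite differences fail when a transformed parameter sits at 0.
  jac_fn <- function(theta) {
    p <- unpack(theta)
    J <- matrix(0, length(conc), n_par)
    for (kk in seq_len(k)) {
      u <- (conc / p$ic50[kk])^p$nh[kk]
      denom <- (1 + u)^2
      dlogc <- ifelse(u > 0, log(conc / p$ic50[kk]), 0)
      J[, kk] <- -sw * p$a[kk] / (1 + u)
      J[, k + kk] <- -sw * p$a[kk] * u * p$nh[kk] * log(10) / denom
      J[, 2L * k + kk] <- sw * p$a[kk] * u * dlogc * p$nh[kk] / denom
    }
    J
  }
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13, ptol = 1e-13)
  )
  if (fit$info == 0L || fit$info == 5L) {
    stop_pl(sprintf("Hill fit did not converge (%s)", fit$message), "pl_convergence_error")
  }
  theta <- fit$par
  wrss <- sum(fit$fvec^2)
  df <- length(y) - n_par
  red_chisq <- wrss / df
  cov_theta <- tryCatch(solve(fit$hessian) * red_chisq, error = function(e) {
    stop_pl("singular covariance; fit is unidentifiable", "pl_identifiability_error")
  })
  se_theta <- sqrt(pmax(diag(cov_theta), 0))
  if (any(!is.finite(se_theta))) {
    stop_pl("non-finite parameter standard errors; fit is unidentifiable",
            "pl_identifiability_error")
  }
  p <- unpack(theta)

  ## Delta method back to natural scale.
  a_se <- p$a * se_theta[seq_len(k)]
  ic_se <- log(10) * p$ic50 * se_theta[k + seq_len(k)]
  nh_se <- p$nh * se_theta[2L * k + seq_len(k)]
  ## Amplitude fractions f_k = a_k / sum(a): gradient wrt log a_j is
  ## f_k (delta_kj - f_j); propagate with the log-amplitude covariance block.
  f <- p$a / sum(p$a)
  cov_la <- cov_theta[seq_len(k), seq_len(k), drop = FALSE]
  f_se <- vapply(seq_len(k), function(kk) {
    g <- f[kk] * ((seq_len(k) == kk) - f)
    sqrt(max(drop(t(g) %*% cov_la %*% g), 0))
  }, numeric(1))

  ord <- order(p$ic50)
  comps <- data.frame(
    half_competition = p$ic50[ord], half_competition_se = ic_se[ord],
    hill_coefficient = p$nh[ord], hill_coefficient_se = nh_se[ord],
    amplitude = p$a[ord], amplitude_se = a_se[ord],
    fraction = f[ord], fraction_se = f_se[ord]
  )
  n <- length(y)
  p_eff <- n_par + 1L # + residual scale
  aicc <- n * log(wrss / n) + 2 * p_eff +
    if (n - p_eff - 1L > 0L) 2 * p_eff * (p_eff + 1L) / (n - p_eff - 1L) else Inf
  structure(
    list(n_components = k, components = comps, amplitude_total = sum(p$a),
         gof = list(wrss = wrss, df = df, reduced_chisq = red_chisq,
                    aicc = aicc, n_points = n),
         condition = attr(data, "condition"), theta = theta, info = fit$info),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> %d component(s)%s\n", x$n_components,
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]")))
  co <- x$components
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  IC50 = %.4g +/- %.2g M, nH = %.3f +/- %.3f, fraction = %.3f +/- %.3f\n",
                co$half_competition[i], co$half_competition_se[i],
                co$hill_coefficient[i], co$hill_coefficient_se[i],
                co$fraction[i], co$fraction_se[i]))
  }
  cat(sprintf("  reduced chi-square = %.4g on %d df; AICc = %.4g\n",
              x$gof$reduced_chisq, x$gof$df, x$gof$aicc))
  invisible(x)
}

#' Choose the number of Hill components
#'
#' Fits 1..`max_components` Hill components and keeps the smallest model; a
#' larger model is adopted only when it improves the small-sample corrected
#' AIC by more than 2 *and* every one of its parameter standard errors is
#' below 50% of the corresponding estimate. The comparison trace is attached
#' as attribute `"selection"`.
#'
#' @inheritParams fit_hill
#' @param max_components Largest component count to consider (>= 1).
#' @return The selected `hill_fit`.
#' @export
select_components <- function(data, max_components = 2L) {
  if (!is_count(max_components, min = 1L)) {
    stop_pl("'max_components' must be an integer >= 1", "pl_domain_error")
  }
  best <- fit_hill(data, 1L)
  trace <- data.frame(n_components = 1L, aicc = best$gof$aicc,
                      accepted = TRUE, reason = "baseline")
  for (k in seq_len(max_components)[-1]) {
    cand <- tryCatch(fit_hill(data, k), plgicomp_error = function(e) e)
    if (inherits(cand, "error")) {
      trace <- rbind(trace, data.frame(n_components = k, aicc = NA_real_,
                                       accepted = FALSE, reason = conditionMessage(cand)))
      next
    }
    co <- cand$components
    ses_ok <- all(co$half_competition_se < 0.5 * co$half_competition) &&
      all(co$hill_coefficient_se < 0.5 * co$hill_coefficient) &&
      all(co$fraction_se < 0.5 * co$fraction)
    better <- best$gof$aicc - cand$gof$aicc > 2
    accepted <- better && ses_ok
    trace <- rbind(trace, data.frame(
      n_components = k, aicc = cand$gof$aicc, accepted = accepted,
      reason = if (accepted) "dAICc > 2 and SEs < 50%"
               else if (!better) "no AICc improvement > 2" else "parameter SEs too large"
    ))
    if (accepted) best <- cand
  }
  attr(best, "selection") <- trace
  best
}

#' Fold shift between two fitted half-competition concentrations
#'
#' The ratio of the half-competition concentrations of two single-component
#' fits, with its standard error propagated to first order:
#' `se = ratio * sqrt((se_num/ic50_num)^2 + (se_den/ic50_den)^2)`.
#'
#' @param numerator,denominator Single-component `hill_fit` objects.
#' @return A `fold_shift`: list with `ratio`, `se`, and `direction`
#'   (`"increase"` or `"decrease"` relative to 1).
#' @export
#' @examples
#' a <- list(n_components = 1L, components = data.frame(
#'   half_competition = 100e-9, half_competition_se = 8e-9))
#' b <- list(n_components = 1L, components = data.frame(
#'   half_competition = 50e-9, half_competition_se = 3e-9))
#' class(a) <- class(b) <- "hill_fit"
#' fold_shift(a, b) # 2.0 +/- 0.2
fold_shift <- function(numerator, denominator) {
  for (f in list(numerator, denominator)) {
    if (!inherits(f, "hill_fit") || f$n_components != 1L) {
      stop_pl("fold shifts require two single-component hill_fit objects", "pl_shape_error")
    }
  }
  num <- numerator$components
  den <- denominator$components
  ratio <- num$half_competition / den$half_competition
  se <- ratio * sqrt((num$half_competition_se / num$half_competition)^2 +
                       (den$half_competition_se / den$half_competition)^2)
  structure(
    list(ratio = ratio, se = se,
         direction = if (ratio >= 1) "increase" else "decrease"),
    class = "fold_shift"
  )
}

#' @export
print.fold_shift <- function(x, ...) {
  cat(sprintf("<fold_shift> %.3g +/- %.2g (%s)\n", x$ratio, x$se, x$direction))
  invisible(x)
}

#' Write or read a Hill-fit report
#'
#' Serializes a `hill_fit` (parameters, SEs, goodness of fit, and the
#' component-selection trace when present) as JSON, optionally alongside a
#' human-readable text table.
#'
#' @param fit A `hill_fit`.
#' @param path Output JSON path.
#' @param table_path Optional path for a plain-text table.
#' @param provenance Optional named list merged into the JSON under
#'   `provenance`.
#' @return `write_fit_report()` returns `path` invisibly;
#'   `read_fit_report()` returns a `hill_fit`.
#' @export
write_fit_report <- function(fit, path, table_path = NULL, provenance = NULL) {
  stopifnot(inherits(fit, "hill_fit"))
  rep <- list(
    n_components = fit$n_components,
    components = fit$components,
    amplitude_total = fit$amplitude_total,
    gof = fit$gof,
    condition = fit$condition,
    selection = attr(fit, "selection"),
    provenance = provenance
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(table_path)) {
    writeLines(utils::capture.output(print(fit)), table_path)
  }
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop_pl(sprintf("no such file: %s", path), "pl_format_error")
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(
    n_components = as.integer(rep$n_components),
    components = as.data.frame(rep$components),
    amplitude_total = rep$amplitude_total,
    gof = rep$gof,
    condition = rep$condition
  )
  class(fit) <- "hill_fit"
  if (!is.null(rep$selection)) attr(fit, "selection") <- as.data.frame(rep$selection)
  fit
}
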