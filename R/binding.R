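#' Bound protein fraction under ligand depletion
#'
#' Fraction of protein in the bound state for 1:1 binding when the bound
#' ligand is not negligible relative to total ligand, so the hyperbolic
#' approximation fails and the quadratic mass-balance solution is needed:
#' \deqn{f_B = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2P}}
#' with \eqn{P} and \eqn{L} the total protein and ligand concentrations.
#' All concentrations are totals over the whole sample (no partition
#' correction), which is what makes the fitted constant an *apparent* Kd.
#'
#' @param p_total Total protein concentration, uM (`> 0`).
#' @param l_total Total ligand concentration, uM (`>= 0`). Vectorized.
#' @param kd Dissociation constant, uM (`> 0`).
#'
#' @return Bound fraction in `[0, 1]`, same length as the longest input.
#' @export
#' @examples
#' bound_fraction(100, 400, 105)
#' bound_fraction(100, c(0, 50, 100, 250, 400), 105)
bound_fraction <- function(p_total, l_total, kd) {
  if (any(p_total <= 0)) rlang::abort("p_total must be > 0")
  if (any(l_total < 0)) rlang::abort("l_total must be >= 0")
  if (any(kd <= 0)) rlang::abort("kd must be > 0")
  s <- p_total + l_total + kd
  disc <- s^2 - 4 * p_total * l_total
  # disc >= (P - L)^2 + Kd^2 > 0 analytically; guard against rounding
  f <- (s - sqrt(pmax(disc, 0))) / (2 * p_total)
  pmin(pmax(f, 0), 1)
}

#' Predicted CSP under fast exchange
#'
#' In the fast-exchange regime the observed peak sits at the
#' population-weighted average of the free and bound positions, so the
#' measured CSP is proportional to the bound fraction:
#' `csp = dmax * bound_fraction(P, L, Kd)`, where `dmax` is the maximal
#' (saturation) CSP of the residue.
#'
#' @param kd Dissociation constant, uM.
#' @param dmax Maximal CSP at saturation, ppm.
#' @param p_total,l_total Total protein and ligand concentrations, uM.
#' @return Predicted CSP in ppm (vectorized over `l_total`).
#' @export
predict_csp <- function(kd, dmax, p_total, l_total) {
  if (any(dmax < 0)) rlang::abort("dmax must be >= 0")
  dmax * bound_fraction(p_total, l_total, kd)
}

# Extract (ligand_conc, csp) observations for one residue of a titration
# series. The reference contributes the exact zero point (CSP vs itself
# is 0 by construction).
residue_titration_data <- function(series, residue, alpha = 0.14) {
  stopifnot(inherits(series, "titration_series"))
  lc <- vapply(series$points, function(p) attr(p, "ligand_conc"), numeric(1))
  csp <- vapply(series$points, function(p) {
    prof <- compute_csp(series$reference, p, alpha = alpha)
    i <- match(residue, prof$residue)
    if (is.na(i)) NA_real_ else prof$csp[i]
  }, numeric(1))
  keep <- !is.na(csp)
  if (residue %in% series$reference$residue) {
    tibble::tibble(ligand_conc = c(0, lc[keep]), csp = c(0, csp[keep]))
  } else {
    tibble::tibble(ligand_conc = lc[keep], csp = csp[keep])
  }
}

# Profiled least squares: for a fixed Kd the amplitudes are linear, so
# dmax_hat = sum(y f) / sum(f^2) (clamped at 0) and the objective reduces
# to a 1-D problem in Kd. `y_list` is a list of numeric observation
# vectors (one per residue) and `l_list` the matching ligand
# concentrations. Returns SS and the profiled amplitudes.
profiled_ss <- function(kd, y_list, l_list, p_total) {
  ss <- 0
  dmax <- numeric(length(y_list))
  for (r in seq_along(y_list)) {
    f <- bound_fraction(p_total, l_list[[r]], kd)
    denom <- sum(f^2)
    d <- if (denom > 0) max(sum(y_list[[r]] * f) / denom, 0) else 0
    dmax[r] <- d
    ss <- ss + sum((y_list[[r]] - d * f)^2)
  }
  list(ss = ss, dmax = dmax)
}

# Minimise the profiled objective over log(Kd) on (0, kd_max]: coarse
# log-spaced scan (the multi-start) then optimize() refinement around the
# best cell.
minimise_kd <- function(y_list, l_list, p_total, kd_max,
                        n_grid = 80L, tol = 1e-8) {
  grid <- exp(seq(log(kd_max * 1e-4), log(kd_max), length.out = n_grid))
  ss_grid <- vapply(grid, function(k) {
    profiled_ss(k, y_list, l_list, p_total)$ss
  }, numeric(1))
  i <- which.min(ss_grid)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  opt <- stats::optimize(
    function(lk) profiled_ss(exp(lk), y_list, l_list, p_total)$ss,
    lower = log(lo), upper = log(hi), tol = tol
  )
  kd <- exp(opt$minimum)
  c(profiled_ss(kd, y_list, l_list, p_total), list(kd = kd))
}

# Standard error of the shared Kd at the optimum, for parameters
# (kd, dmax_1..dmax_m). Built on the Gauss-Newton Jacobian of the stacked
# residual vector (the Kd column by central finite difference of
# bound_fraction), with a heteroscedasticity-robust HC3 sandwich middle:
# the CSP magnitude observable has per-residue noise variance that
# depends on the peak's displacement direction, so the classical
# homoscedastic covariance is mildly anti-conservative here.
kd_stderr_gn <- function(kd, dmax, y_list, l_list, p_total) {
  n_obs <- sum(lengths(y_list))
  m <- length(y_list)
  p <- m + 1L
  if (n_obs <= p) return(NA_real_)
  J <- matrix(0, nrow = n_obs, ncol = p)
  resid <- numeric(n_obs)
  h <- kd * 1e-6
  row0 <- 0L
  for (r in seq_len(m)) {
    L <- l_list[[r]]
    f <- bound_fraction(p_total, L, kd)
    dfdk <- (bound_fraction(p_total, L, kd + h) -
               bound_fraction(p_total, L, kd - h)) / (2 * h)
    idx <- row0 + seq_along(L)
    J[idx, 1] <- dmax[r] * dfdk
    J[idx, 1 + r] <- f
    resid[idx] <- y_list[[r]] - dmax[r] * f
    row0 <- row0 + length(L)
  }
  bread <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  if (is.null(bread)) return(NA_real_)
  lev <- pmin(rowSums((J %*% bread) * J), 1 - 1e-8)
  meat <- crossprod(J * (resid / (1 - lev)))
  v <- bread %*% meat %*% bread
  sqrt(pmax(v[1, 1], 0))
}

#' Fit one residue's titration to the depletion isotherm
#'
#' Least-squares fit of `predict_csp()` to the (ligand concentration, CSP)
#' pairs of a single residue, with Kd constrained positive and bounded by
#' 10x the top ligand concentration. The amplitude `dmax` is profiled out
#' (it enters the model linearly at fixed Kd), leaving a robust 1-D
#' optimisation over log-Kd seeded by a coarse log-spaced scan.
#'
#' @param series A `titration_series`.
#' @param residue Residue number; must be observable at `>= 3`
#'   concentrations including the reference.
#' @param alpha CSP nitrogen weighting (see [compute_csp()]).
#'
#' @return An object of class `residue_fit`: list with `residue`, `kd`
#'   (uM), `dmax` (ppm), `r_squared`, `n_points`, `ok` (logical),
#'   `reason` (why a fit was flagged, or `NA`), and `data` (the fitted
#'   points).
#' @export
fit_residue <- function(series, residue, alpha = 0.14) {
  dat_all <- residue_titration_data(series, residue, alpha = alpha)
  if (nrow(dat_all) < 3) {
    rlang::abort(sprintf(
      "residue %d observable at only %d concentration(s); need >= 3",
      residue, nrow(dat_all)
    ))
  }
  # The reference point (0, 0) holds by construction (the CSP is measured
  # against it) and carries no measurement noise: it is excluded from the
  # least-squares observations so it cannot dilute the residual variance.
  dat <- dat_all[dat_all$ligand_conc > 0, ]
  p_total <- series$protein_conc
  kd_max <- 10 * max(dat$ligand_conc)

  res <- minimise_kd(list(dat$csp), list(dat$ligand_conc), p_total, kd_max)
  pred <- res$dmax[1] * bound_fraction(p_total, dat$ligand_conc, res$kd)
  ss_res <- sum((dat$csp - pred)^2)
  ss_tot <- sum((dat$csp - mean(dat$csp))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  ok <- TRUE
  reason <- NA_character_
  if (res$dmax[1] <= 0 || all(dat$csp == 0)) {
    ok <- FALSE
    reason <- "no response (dmax at zero boundary)"
  } else if (is.na(r2)) {
    ok <- FALSE
    reason <- "zero variance in observed CSPs"
  }

  structure(
    list(residue = as.integer(residue), kd = res$kd, dmax = res$dmax[1],
         r_squared = r2, n_points = nrow(dat_all), ok = ok, reason = reason,
         data = dat, data_full = dat_all, p_total = p_total, alpha = alpha),
    class = "residue_fit"
  )
}

#' @export
print.residue_fit <- function(x, ...) {
  cat(sprintf(
    "<residue_fit> residue %d: Kd = %.4g uM, dmax = %.4g ppm, R2 = %.4f (%d points)%s\n",
    x$residue, x$kd, x$dmax, x$r_squared, x$n_points,
    if (x$ok) "" else paste0(" [flagged: ", x$reason, "]")
  ))
  invisible(x)
}

#' Retention rule for per-residue fits
#'
#' A residue's individual fit is retained for the global fit when its
#' R-squared is at least the cutoff; fits strictly below are removed.
#' The boundary is inclusive: `R^2 = 0.85` is retained at the default
#' cutoff, `R^2 = 0.849` is not.
#'
#' @param r_squared Coefficient of determination of the individual fit.
#' @param r2_cutoff Cutoff (default 0.85).
#' @return Logical.
#' @export
retain_fit <- function(r_squared, r2_cutoff = 0.85) {
  !is.na(r_squared) & r_squared >= r2_cutoff
}

#' Global shared-Kd fit across residues
#'
#' Fits every candidate residue individually, rejects those with
#' `R^2 < r2_cutoff` (0.85 by default; a fit at exactly the cutoff is
#' retained) or with no response, then jointly refits the survivors with
#' one shared apparent Kd and a per-residue amplitude. The standard error
#' of the shared Kd comes from the parameter covariance at the optimum,
#' built on the Gauss-Newton Jacobian with a heteroscedasticity-robust
#' (HC3 sandwich) middle — the effective noise on a CSP magnitude differs
#' between residues, depending on each peak's displacement direction
#' relative to the proton and nitrogen axes.
#'
#' @param series A `titration_series`.
#' @param residues Candidate residues, typically the top shifters at the
#'   highest ligand concentration (see [select_top_shifters()]).
#' @param r2_cutoff Per-residue R-squared cutoff; fits strictly below are
#'   rejected.
#' @param alpha CSP nitrogen weighting.
#'
#' @return An object of class `global_fit`: list with `kd`, `kd_stderr`
#'   (uM), `per_residue_dmax` (named numeric, ppm), `residues_used`,
#'   `residues_rejected` (tibble residue/reason), `residue_fits` (the
#'   individual fits), `n_obs`, `fragment_id`.
#' @export
fit_global <- function(series, residues, r2_cutoff = 0.85, alpha = 0.14) {
  stopifnot(inherits(series, "titration_series"))
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0) rlang::abort("no candidate residues supplied")

  fits <- list()
  rejected <- tibble::tibble(residue = integer(), reason = character())
  for (r in residues) {
    ft <- tryCatch(fit_residue(series, r, alpha = alpha),
                   error = function(e) conditionMessage(e))
    if (is.character(ft)) {
      rejected <- dplyr::bind_rows(rejected,
                                   tibble::tibble(residue = r, reason = ft))
    } else if (!ft$ok) {
      rejected <- dplyr::bind_rows(
        rejected, tibble::tibble(residue = r, reason = ft$reason))
      fits[[as.character(r)]] <- ft
    } else if (!retain_fit(ft$r_squared, r2_cutoff)) {
      rejected <- dplyr::bind_rows(
        rejected,
        tibble::tibble(residue = r,
                       reason = sprintf("R2 = %.4f below cutoff %.2f",
                                        ft$r_squared, r2_cutoff)))
      fits[[as.character(r)]] <- ft
    } else {
      fits[[as.character(r)]] <- ft
    }
  }
  used <- setdiff(residues, rejected$residue)
  if (length(used) == 0) rlang::abort("no fit-worthy resonances")

  y_list <- lapply(as.character(used), function(r) fits[[r]]$data$csp)
  l_list <- lapply(as.character(used), function(r) fits[[r]]$data$ligand_conc)
  p_total <- series$protein_conc
  kd_max <- 10 * max(unlist(l_list))

  res <- minimise_kd(y_list, l_list, p_total, kd_max)
  dmax <- stats::setNames(res$dmax, used)
  stderr <- kd_stderr_gn(res$kd, res$dmax, y_list, l_list, p_total)

  structure(
    list(kd = res$kd, kd_stderr = stderr, per_residue_dmax = dmax,
         residues_used = used, residues_rejected = rejected,
         residue_fits = fits, n_obs = sum(lengths(y_list)),
         p_total = p_total, alpha = alpha,
         fragment_id = series$fragment_id),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf(
    "<global_fit> fragment '%s': apparent Kd = %.4g +/- %.2g uM (%d residue(s), %d obs)\n",
    x$fragment_id, x$kd, x$kd_stderr, length(x$residues_used), x$n_obs
  ))
  if (nrow(x$residues_rejected) > 0) {
    cat("  rejected:", paste(x$residues_rejected$residue, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-residue component of a global fit
#'
#' @param x A `global_fit`.
#' @param ... Unused.
#' @return A tibble with one row per candidate residue: `residue`, `dmax`
#'   (ppm, joint fit; `NA` if rejected), `individual_kd`,
#'   `individual_r_squared`, `used`, `reason`.
#' @export
tidy.global_fit <- function(x, ...) {
  res <- sort(unique(c(x$residues_used, x$residues_rejected$residue)))
  purrr::map_dfr(res, function(r) {
    ft <- x$residue_fits[[as.character(r)]]
    tibble::tibble(
      residue = r,
      dmax = unname(x$per_residue_dmax[as.character(r)])[1],
      individual_kd = if (is.null(ft)) NA_real_ else ft$kd,
      individual_r_squared = if (is.null(ft)) NA_real_ else ft$r_squared,
      used = r %in% x$residues_used,
      reason = {
        i <- match(r, x$residues_rejected$residue)
        if (is.na(i)) NA_character_ else x$residues_rejected$reason[i]
      }
    )
  })
}

#' One-row summary of a global fit
#'
#' @param x A `global_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `fragment_id`, `kd_uM`, `kd_stderr_uM`,
#'   `n_residues_used`, `n_residues_rejected`, `n_obs`.
#' @export
glance.global_fit <- function(x, ...) {
  tibble::tibble(
    fragment_id = x$fragment_id,
    kd_uM = x$kd,
    kd_stderr_uM = x$kd_stderr,
    n_residues_used = length(x$residues_used),
    n_residues_rejected = nrow(x$residues_rejected),
    n_obs = x$n_obs
  )
}

#' Plot fitted titration curves of a global fit
#'
#' Observed CSPs and the shared-Kd model curves, one colour per residue.
#'
#' @param object A `global_fit`.
#' @param n_curve Number of points for the smooth model curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.global_fit <- function(object, n_curve = 200, ...) {
  obs <- purrr::map_dfr(object$residues_used, function(r) {
    d <- object$residue_fits[[as.character(r)]]$data
    dplyr::mutate(d, residue = factor(r))
  })
  l_max <- max(obs$ligand_conc)
  grid <- seq(0, l_max, length.out = n_curve)
  curves <- purrr::map_dfr(object$residues_used, function(r) {
    tibble::tibble(
      ligand_conc = grid,
      csp = predict_csp(object$kd,
                        object$per_residue_dmax[as.character(r)],
                        object$p_total, grid),
      residue = factor(r)
    )
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$ligand_conc, y = .data$csp,
                                    colour = .data$residue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "Ligand (uM)", y = "CSP (ppm)", colour = "Residue") +
    ggplot2::theme_classic()
}

#' Classify a fragment from its global fit and endpoint profile
#'
#' A fragment is a specific **hit** when its fitted apparent Kd is below
#' `kd_cutoff` (1 mM by default) *and* its top-shifting residues are
#' structurally localized: at least `locality_fraction` of them lie on the
#' membrane interface or among the observable functional residues. A
#' localized binder with Kd at or above the cutoff is **weak**; anything
#' non-localized is **nonspecific**.
#'
#' @param fit A `global_fit`.
#' @param profile A `csp_profile` at the highest ligand concentration.
#' @param annotation An `interface_annotation`.
#' @param kd_cutoff Kd cutoff in uM (strict `<` for a hit).
#' @param locality_fraction Minimum fraction of top shifters in the
#'   interface/functional region (inclusive `>=`).
#' @param k_sigma Top-shifter selection threshold passed to
#'   [select_top_shifters()].
#'
#' @return Length-1 character, one of `"hit"`, `"weak"`, `"nonspecific"`,
#'   with attribute `locality` (the computed fraction).
#' @export
classify_fragment <- function(fit, profile, annotation, kd_cutoff = 1000,
                              locality_fraction = 0.5, k_sigma = 1) {
  if (!inherits(fit, "global_fit")) rlang::abort("missing or invalid global fit")
  stopifnot(inherits(profile, "csp_profile"),
            inherits(annotation, "interface_annotation"))
  shifters <- select_top_shifters(profile, k_sigma = k_sigma)$residues
  local_set <- union(annotation$membrane_interface,
                     annotation$observable_functional)
  locality <- if (length(shifters) == 0) {
    0
  } else {
    mean(shifters %in% local_set)
  }
  localized <- locality >= locality_fraction
  cls <- if (localized && fit$kd < kd_cutoff) {
    "hit"
  } else if (localized) {
    "weak"
  } else {
    "nonspecific"
  }
  structure(cls, locality = locality)
}
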