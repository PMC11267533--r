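#' Compute chemical shift perturbations against a reference state
#'
#' For every residue present in both lists the weighted combined
#' perturbation is
#' \deqn{\Delta\delta = \sqrt{(\Delta^{1}H)^2 + (\alpha\,\Delta^{15}N)^2}}
#' where \eqn{\Delta^{1}H} and \eqn{\Delta^{15}N} are the changes in the
#' \eqn{^1}H and \eqn{^{15}}N chemical shifts and \eqn{\alpha} rescales the
#' nitrogen axis to the proton axis (0.14 is the field-standard amide
#' weighting). Residues absent from either list are omitted from the
#' profile and recorded in the `omitted` attribute.
#'
#' @param reference A `peaklist` for the reference (typically apo) state.
#' @param observed A `peaklist` for the perturbed state.
#' @param alpha Nitrogen weighting factor, dimensionless; must be `> 0`.
#'
#' @return A tibble of class `csp_profile` with columns `residue`,
#'   `assignment`, `csp` (ppm), `delta_h`, `delta_n`; attributes carry
#'   `alpha`, `ligand_conc`, `protein_conc`, `reference_label`,
#'   `condition_label` and the omitted residues.
#' @export
#' @examples
#' ref <- peaklist(data.frame(assignment = "G79N-H", shift_n = 110,
#'                            shift_h = 8.5), ligand_conc = 0)
#' obs <- peaklist(data.frame(assignment = "G79N-H", shift_n = 110.2,
#'                            shift_h = 8.53), ligand_conc = 400)
#' compute_csp(ref, obs)$csp  # sqrt(0.03^2 + (0.14 * 0.2)^2)
compute_csp <- function(reference, observed, alpha = 0.14) {
  stopifnot(inherits(reference, "peaklist"), inherits(observed, "peaklist"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    rlang::abort("alpha must be a single number > 0")
  }

  shared <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(reference), "assignment", "residue",
                  ref_h = "shift_h", ref_n = "shift_n"),
    dplyr::select(tibble::as_tibble(observed), "assignment",
                  obs_h = "shift_h", obs_n = "shift_n"),
    by = "assignment"
  )
  if (nrow(shared) == 0) {
    rlang::abort("reference and observed peak lists share no assignments")
  }
  omitted <- sort(unique(c(
    setdiff(reference$residue, shared$residue),
    setdiff(observed$residue, shared$residue)
  )))

  prof <- shared |>
    dplyr::mutate(
      delta_h = .data$obs_h - .data$ref_h,
      delta_n = .data$obs_n - .data$ref_n,
      csp = sqrt(.data$delta_h^2 + (alpha * .data$delta_n)^2)
    ) |>
    dplyr::arrange(.data$residue) |>
    dplyr::select("residue", "assignment", "csp", "delta_h", "delta_n")

  structure(
    prof,
    alpha = alpha,
    ligand_conc = attr(observed, "ligand_conc"),
    protein_conc = attr(observed, "protein_conc"),
    reference_label = attr(reference, "condition_label"),
    condition_label = attr(observed, "condition_label"),
    omitted = omitted,
    class = c("csp_profile", class(prof))
  )
}

# population standard deviation (divisor n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Select the top-shifting resonances of a CSP profile
#'
#' Flags residues whose CSP is at least `k_sigma` population standard
#' deviations above the profile mean (inclusive: `csp >= mean + k * sigma`).
#' With `k_sigma = 1` this is the usual "1 sigma above the average CSP"
#' rule used to pick resonances for Kd fitting. When all CSPs are equal
#' (`sigma = 0`) every residue meets the inclusive threshold and a warning
#' is raised.
#'
#' @param profile A `csp_profile`, with at least 2 residues.
#' @param k_sigma Number of standard deviations above the mean; `>= 0`.
#'
#' @return An object of class `top_shifters`: a list with `residues`
#'   (integer vector), `threshold` (ppm), `k_sigma`, `mean_csp`, `sd_csp`.
#' @export
select_top_shifters <- function(profile, k_sigma = 1) {
  stopifnot(inherits(profile, "csp_profile"))
  if (nrow(profile) < 2) {
    rlang::abort("profile must contain at least 2 residues (sigma undefined)")
  }
  if (!is.numeric(k_sigma) || length(k_sigma) != 1 || k_sigma < 0) {
    rlang::abort("k_sigma must be a single number >= 0")
  }
  mu <- mean(profile$csp)
  sigma <- pop_sd(profile$csp)
  if (sigma == 0) {
    rlang::warn("all CSPs are equal (sigma = 0); every residue meets the inclusive threshold")
  }
  threshold <- mu + k_sigma * sigma
  structure(
    list(
      residues = profile$residue[profile$csp >= threshold],
      threshold = threshold,
      k_sigma = k_sigma,
      mean_csp = mu,
      sd_csp = sigma
    ),
    class = "top_shifters"
  )
}

#' @export
print.top_shifters <- function(x, ...) {
  cat(sprintf(
    "<top_shifters> %d residue(s) with CSP >= %.4f ppm (mean %.4f + %g sigma %.4f)\n",
    length(x$residues), x$threshold, x$mean_csp, x$k_sigma, x$sd_csp
  ))
  if (length(x$residues)) cat(" ", paste(x$residues, collapse = ", "), "\n")
  invisible(x)
}

#' Compare per-residue CSPs between two conditions
#'
#' Builds a paired table of CSPs for a residue set across two profiles
#' (e.g. membrane-mimetic vs aqueous), for the side-by-side comparison of
#' the strongest shifters between environments. Residues missing from the
#' second profile are reported as absent with no difference computed.
#'
#' @param profile_a,profile_b `csp_profile` objects. All `residues` must be
#'   present in `profile_a`; absence from `profile_b` is allowed.
#' @param residues Integer vector of residues to compare (nonempty).
#'
#' @return A tibble with columns `residue`, `csp_a`, `csp_b`, `difference`
#'   (`csp_a - csp_b`) and `absent_in_b`, ordered by residue number.
#' @export
compare_conditions <- function(profile_a, profile_b, residues) {
  stopifnot(inherits(profile_a, "csp_profile"),
            inherits(profile_b, "csp_profile"))
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0) rlang::abort("residue set must be nonempty")
  missing_a <- setdiff(residues, profile_a$residue)
  if (length(missing_a) > 0) {
    rlang::abort(paste0("residues absent from profile_a: ",
                        paste(missing_a, collapse = ", ")))
  }
  tibble::tibble(residue = residues) |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(profile_a),
                                   "residue", csp_a = "csp"),
                     by = "residue") |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(profile_b),
                                   "residue", csp_b = "csp"),
                     by = "residue") |>
    dplyr::mutate(
      absent_in_b = is.na(.data$csp_b),
      difference = .data$csp_a - .data$csp_b
    ) |>
    dplyr::arrange(.data$residue)
}

#' Bar plot of a CSP profile
#'
#' Per-residue CSP bars with the top-shifter threshold drawn as a dashed
#' line, in the style routinely used to present HSQC titration endpoints.
#'
#' @param object A `csp_profile`.
#' @param k_sigma Threshold line at `mean + k_sigma * sigma`; set `NULL`
#'   to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csp_profile <- function(object, k_sigma = 1, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$residue, y = .data$csp)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Residue", y = "CSP (ppm)") +
    ggplot2::theme_classic()
  if (!is.null(k_sigma) && nrow(object) >= 2) {
    thr <- mean(object$csp) + k_sigma * pop_sd(object$csp)
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Grouped bar plot of a condition comparison
#'
#' @param comparison Output of [compare_conditions()].
#' @param labels Length-2 character vector naming the two conditions.
#' @return A ggplot object.
#' @export
plot_condition_comparison <- function(comparison,
                                      labels = c("condition A", "condition B")) {
  stopifnot(is.data.frame(comparison),
            all(c("residue", "csp_a", "csp_b") %in% names(comparison)))
  long <- comparison |>
    dplyr::select("residue", "csp_a", "csp_b") |>
    tidyr::pivot_longer(c("csp_a", "csp_b"), names_to = "condition",
                        values_to = "csp") |>
    dplyr::mutate(condition = ifelse(.data$condition == "csp_a",
                                     labels[1], labels[2]))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$residue), y = .data$csp,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "Residue", y = "CSP (ppm)", fill = NULL) +
    ggplot2::theme_classic()
}
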