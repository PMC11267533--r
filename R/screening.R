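#' Triage a fragment-mixture spectrum into a priority tier
#'
#' Counts the residues of interest — membrane-interface plus observable
#' functional (cationic patch / catalytic site) residues — whose CSP
#' exceeds `csp_threshold`, and assigns a priority tier by count. The
#' default boundaries make a mixture with 1-2 shifted resonances of
#' interest low priority, 3-4 medium, and 5 or more high; mixtures with
#' nothing above threshold get `"none"`. This is a counted-resonance
#' surrogate for the by-eye ranking used at the bench, so that triage is
#' reproducible; the boundaries are configurable.
#'
#' @param profile A `csp_profile` for the mixture vs the apo reference.
#' @param annotation An `interface_annotation`; `observable_functional`
#'   must be nonempty.
#' @param csp_threshold CSP threshold in ppm (strict `>`); default 0.01.
#' @param tier_bounds Named integer vector `c(high =, medium =, low =)`
#'   giving the minimum count for each tier.
#'
#' @return A length-1 character: `"high"`, `"medium"`, `"low"` or `"none"`,
#'   with the count attached as attribute `n_above_threshold`.
#' @export
triage_mixture <- function(profile, annotation, csp_threshold = 0.01,
                           tier_bounds = c(high = 5L, medium = 3L, low = 1L)) {
  stopifnot(inherits(profile, "csp_profile"),
            inherits(annotation, "interface_annotation"))
  if (nrow(profile) == 0) rlang::abort("empty CSP profile")
  if (length(annotation$observable_functional) == 0) {
    rlang::abort("annotation has no observable functional residues")
  }
  stopifnot(all(c("high", "medium", "low") %in% names(tier_bounds)))

  of_interest <- union(annotation$membrane_interface,
                       annotation$observable_functional)
  n <- sum(profile$residue %in% of_interest & profile$csp > csp_threshold)
  tier <- if (n >= tier_bounds[["high"]]) {
    "high"
  } else if (n >= tier_bounds[["medium"]]) {
    "medium"
  } else if (n >= tier_bounds[["low"]]) {
    "low"
  } else {
    "none"
  }
  structure(tier, n_above_threshold = n)
}

#' Call a deconvolution hit from a single-fragment spectrum
#'
#' A fragment retested individually is a hit when at least `min_count` of
#' the observable functional residues (cationic patch or catalytic site,
#' the screening denominator from the annotation) show CSPs strictly
#' greater than `csp_threshold`. The defaults encode the 7-of-15 /
#' >0.01 ppm rule; a residue at exactly the threshold does not count.
#'
#' @param profile A `csp_profile` for the fragment vs the apo reference.
#' @param annotation An `interface_annotation` with nonempty
#'   `observable_functional`.
#' @param min_count Minimum number of functional residues above threshold.
#' @param csp_threshold CSP threshold, ppm (strict `>`).
#'
#' @return Logical scalar, with attribute `n_above_threshold`.
#' @export
call_hit_deconvolution <- function(profile, annotation, min_count = 7L,
                                   csp_threshold = 0.01) {
  stopifnot(inherits(profile, "csp_profile"),
            inherits(annotation, "interface_annotation"))
  if (length(annotation$observable_functional) == 0) {
    rlang::abort("annotation has no observable functional residues")
  }
  func <- annotation$observable_functional
  n <- sum(profile$residue %in% func & profile$csp > csp_threshold)
  structure(n >= min_count, n_above_threshold = n)
}

#' Summarize a fragment screen
#'
#' Tallies the stages of a screen — mixtures triaged, fragments
#' deconvoluted, hits validated by titration — and reports the library
#' hit rate as a percentage.
#'
#' @param records A list with any of the components:
#'   \describe{
#'     \item{mixtures}{tibble with a `priority` column (one row per
#'       mixture); rows with priority other than `"none"` count as
#'       flagged.}
#'     \item{deconvolution}{tibble with a logical `hit` column (one row
#'       per fragment tested individually).}
#'     \item{validation}{tibble with a `classification` column; rows with
#'       `"hit"` count as validated hits.}
#'   }
#'   Alternatively pass pre-tallied counts via `n_mixtures`, `n_flagged`,
#'   `n_deconvoluted`, `n_validated_hits` entries of the list.
#' @param library_size Number of fragments in the screened library.
#'
#' @return A one-row tibble of class `screen_summary`: `library_size`,
#'   `n_mixtures`, `n_flagged`, `n_deconvoluted`, `n_validated_hits`,
#'   `hit_rate_percent` (rounded to 2 decimals).
#' @export
#' @examples
#' summarize_screen(list(n_validated_hits = 9), library_size = 1911)
summarize_screen <- function(records, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      library_size <= 0) {
    rlang::abort("library_size must be a single count > 0")
  }
  stopifnot(is.list(records))

  count_or <- function(name, fallback) {
    if (!is.null(records[[name]])) as.integer(records[[name]]) else fallback
  }
  n_mixtures <- count_or("n_mixtures", {
    if (!is.null(records$mixtures)) nrow(records$mixtures) else 0L
  })
  n_flagged <- count_or("n_flagged", {
    if (!is.null(records$mixtures)) {
      sum(records$mixtures$priority != "none")
    } else {
      0L
    }
  })
  n_deconvoluted <- count_or("n_deconvoluted", {
    if (!is.null(records$deconvolution)) {
      sum(records$deconvolution$hit)
    } else {
      0L
    }
  })
  n_validated <- count_or("n_validated_hits", {
    if (!is.null(records$validation)) {
      sum(records$validation$classification == "hit")
    } else {
      0L
    }
  })
  if (n_validated > library_size) {
    rlang::abort("n_validated_hits cannot exceed library_size")
  }

  out <- tibble::tibble(
    library_size = as.integer(library_size),
    n_mixtures = n_mixtures,
    n_flagged = n_flagged,
    n_deconvoluted = n_deconvoluted,
    n_validated_hits = n_validated,
    hit_rate_percent = round(100 * n_validated / library_size, 2)
  )
  class(out) <- c("screen_summary", class(out))
  out
}
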