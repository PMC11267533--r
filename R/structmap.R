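#' Map per-residue CSPs onto structure annotations
#'
#' Builds the residue map table used for structure figures: every residue
#' of the profile with its CSP, its annotation category and whether it is
#' a top shifter. If a PDB file is supplied, a copy is written in which
#' the temperature-factor (B-factor) column of every ATOM/HETATM record
#' carries `CSP * 1000` (capped at 999.99; residues without a CSP set to
#' 0), so the perturbation can be coloured onto the structure in any
#' molecular viewer. Only columns 61-66 of the fixed-width records are
#' touched.
#'
#' @param profile A nonempty `csp_profile`.
#' @param shifters A `top_shifters` object (see [select_top_shifters()]),
#'   or `NULL` to flag none.
#' @param annotation An `interface_annotation`.
#' @param pdb_file Optional input PDB path.
#' @param out_pdb Output path for the annotated PDB (required when
#'   `pdb_file` is given).
#' @param residue_offset Offset added to profile residue numbers to match
#'   the PDB numbering (PDB residue = profile residue + offset).
#'
#' @return A tibble with columns `residue`, `csp`, `category`,
#'   `shifter_flag`, ordered by residue. Categories: `catalytic` and
#'   `cationic` take precedence over `interface`; residues in none of the
#'   annotation sets are `other`.
#' @export
map_to_structure <- function(profile, shifters = NULL, annotation,
                             pdb_file = NULL, out_pdb = NULL,
                             residue_offset = 0L) {
  stopifnot(inherits(profile, "csp_profile"),
            inherits(annotation, "interface_annotation"))
  if (nrow(profile) == 0) rlang::abort("empty CSP profile")
  shifter_set <- if (is.null(shifters)) integer() else shifters$residues

  categorize <- function(r) {
    if (r %in% annotation$catalytic_site) return("catalytic")
    if (r %in% annotation$cationic_patch) return("cationic")
    if (r %in% annotation$membrane_interface) return("interface")
    if (r %in% annotation$unassigned) return("unassigned")
    "other"
  }
  tab <- tibble::tibble(
    residue = profile$residue,
    csp = profile$csp,
    category = vapply(profile$residue, categorize, character(1)),
    shifter_flag = profile$residue %in% shifter_set
  ) |>
    dplyr::arrange(.data$residue)

  if (!is.null(pdb_file)) {
    if (is.null(out_pdb)) rlang::abort("out_pdb required when pdb_file is given")
    annotate_pdb_bfactor(pdb_file, out_pdb,
                         stats::setNames(tab$csp, tab$residue + residue_offset))
  }
  tab
}

# Rewrite the B-factor column (61-66) of ATOM/HETATM records with
# csp * 1000 (capped 999.99); unmapped residues get 0.00. Everything else
# is preserved byte for byte.
annotate_pdb_bfactor <- function(pdb_file, out_pdb, csp_by_residue) {
  if (!file.exists(pdb_file)) {
    rlang::abort(paste0("file not found: ", pdb_file))
  }
  lines <- readLines(pdb_file, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  pdb_res <- rep(NA_integer_, length(lines))
  pdb_res[is_atom] <- suppressWarnings(
    as.integer(trimws(substr(lines[is_atom], 23, 26)))
  )
  matched <- is_atom & !is.na(pdb_res) &
    pdb_res %in% as.integer(names(csp_by_residue))

  unmatched_prof <- setdiff(as.integer(names(csp_by_residue)),
                            unique(pdb_res[is_atom]))
  if (length(unmatched_prof) > 0) {
    rlang::warn(paste0(
      "profile residues absent from PDB (numbering mismatch?): ",
      paste(sort(unmatched_prof), collapse = ", ")
    ))
  }

  bval <- numeric(length(lines))
  bval[matched] <- pmin(
    csp_by_residue[as.character(pdb_res[matched])] * 1000, 999.99)
  out <- lines
  out[is_atom] <- paste0(
    substr(lines[is_atom], 1, 60),
    sprintf("%6.2f", bval[is_atom]),
    substring(lines[is_atom], 67)
  )
  writeLines(out, out_pdb)
  invisible(out_pdb)
}

#' Run the screening pipeline from a configuration
#'
#' Orchestrates the synthetic screening workflow end to end on seeded
#' synthetic data: `simulate` (build the screen), `screen` (triage every
#' mixture), `deconvolute` (retest each fragment of advanced mixtures
#' individually against the counted-resonance hit rule), `titrate` (fit
#' the global apparent Kd of every deconvolution hit and classify it).
#' Stage outputs are written to `out_dir` as CSV plus a `summary.json`;
#' a run log records the configuration, seed and per-stage counts.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A named list, or path to a YAML file, with entries:
#'   `seed`, `library_size`, `n_binders`, `mixture_size`,
#'   `advance_tiers` (priority tiers advanced to deconvolution; default
#'   `c("high", "medium", "low")`), `csp_threshold`, `min_count`,
#'   `r2_cutoff`, `kd_cutoff`, and any [simulation_config()] field under
#'   `sim` (e.g. `sim: {true_kd: 105, noise_h: 0}`).
#' @param out_dir Output directory; created if absent. `NULL` skips all
#'   file output.
#'
#' @return A list with `summary` (a `screen_summary` tibble), `triage`,
#'   `deconvolution`, `validation` tibbles, `fits` (named list of
#'   `global_fit`s), and `truth`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  required <- c("library_size", "n_binders")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0) {
    rlang::abort(paste0("config missing required key(s): ",
                        paste(miss, collapse = ", ")))
  }

  seed <- config$seed %||% 1L
  mixture_size <- config$mixture_size %||% 10L
  advance_tiers <- config$advance_tiers %||% c("high", "medium", "low")
  csp_threshold <- config$csp_threshold %||% 0.01
  min_count <- config$min_count %||% 7L
  r2_cutoff <- config$r2_cutoff %||% 0.85
  kd_cutoff <- config$kd_cutoff %||% 1000

  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  base_config <- do.call(simulation_config, sim_args)
  annotation <- config_annotation(base_config)

  # simulate
  screen <- simulate_screen(config$library_size, config$n_binders,
                            mixture_size = mixture_size,
                            base_config = base_config,
                            binder_ids = config$binder_ids %||% NULL)

  # screen: triage every mixture
  triage <- purrr::map_dfr(names(screen$mixtures), function(m) {
    mx <- screen$mixtures[[m]]
    prof <- compute_csp(mx$reference, mx$observed,
                        alpha = base_config$alpha)
    tier <- triage_mixture(prof, annotation, csp_threshold = csp_threshold)
    tibble::tibble(mixture_id = m, priority = as.character(tier),
                   n_above_threshold = attr(tier, "n_above_threshold"))
  })

  # deconvolute: retest members of advanced mixtures individually
  advanced <- triage$mixture_id[triage$priority %in% advance_tiers]
  decon_frags <- screen$truth$fragment_id[
    screen$truth$mixture_id %in% advanced]
  l_top <- max(base_config$ligand_concs)
  deconvolution <- purrr::map_dfr(decon_frags, function(fid) {
    sim <- simulate_fragment(screen, fid, ligand_concs = c(0, l_top))
    prof <- compute_csp(sim$series$reference, sim$series$points[[1]],
                        alpha = base_config$alpha)
    hit <- call_hit_deconvolution(prof, annotation, min_count = min_count,
                                  csp_threshold = csp_threshold)
    tibble::tibble(fragment_id = fid, hit = as.logical(hit),
                   n_above_threshold = attr(hit, "n_above_threshold"))
  })
  if (nrow(deconvolution) == 0) {
    deconvolution <- tibble::tibble(fragment_id = character(),
                                    hit = logical(),
                                    n_above_threshold = integer())
  }

  # titrate: global fit + classification for every deconvolution hit
  hits <- deconvolution$fragment_id[deconvolution$hit]
  fits <- list()
  validation <- purrr::map_dfr(hits, function(fid) {
    sim <- simulate_fragment(screen, fid)
    top_point <- sim$series$points[[length(sim$series$points)]]
    prof <- compute_csp(sim$series$reference, top_point,
                        alpha = base_config$alpha)
    shifters <- select_top_shifters(prof, k_sigma = 1)
    fit <- fit_global(sim$series, shifters$residues,
                      r2_cutoff = r2_cutoff, alpha = base_config$alpha)
    fits[[fid]] <<- fit
    cls <- classify_fragment(fit, prof, annotation, kd_cutoff = kd_cutoff)
    tibble::tibble(fragment_id = fid, kd_uM = fit$kd,
                   kd_stderr_uM = fit$kd_stderr,
                   n_residues_used = length(fit$residues_used),
                   classification = as.character(cls),
                   locality = attr(cls, "locality"))
  })
  if (nrow(validation) == 0) {
    validation <- tibble::tibble(fragment_id = character(),
                                 kd_uM = numeric(),
                                 kd_stderr_uM = numeric(),
                                 n_residues_used = integer(),
                                 classification = character(),
                                 locality = numeric())
  }

  summary <- summarize_screen(
    list(mixtures = triage, deconvolution = deconvolution,
         validation = validation),
    library_size = config$library_size
  )

  result <- list(summary = summary, triage = triage,
                 deconvolution = deconvolution, validation = validation,
                 fits = fits, truth = screen$truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(triage, file.path(out_dir, "triage.csv"),
                     row.names = FALSE)
    utils::write.csv(deconvolution, file.path(out_dir, "deconvolution.csv"),
                     row.names = FALSE)
    utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    truth_flat <- dplyr::select(screen$truth, "fragment_id", "mixture_id",
                                "is_binder", "scenario", "true_kd")
    utils::write.csv(truth_flat, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        summary = as.list(summary[1, ]),
        validated_hits = validation$fragment_id[
          validation$classification == "hit"],
        kd_uM = stats::setNames(
          as.list(validation$kd_uM),
          validation$fragment_id)
      ),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    log_lines <- c(
      sprintf("seed: %d", seed),
      sprintf("library_size: %d", config$library_size),
      sprintf("n_binders: %d", config$n_binders),
      sprintf("mixture_size: %d", mixture_size),
      sprintf("advance_tiers: %s", paste(advance_tiers, collapse = ",")),
      sprintf("csp_threshold: %g", csp_threshold),
      sprintf("min_count: %d", min_count),
      sprintf("r2_cutoff: %g", r2_cutoff),
      sprintf("kd_cutoff: %g", kd_cutoff),
      sprintf("n_mixtures: %d", nrow(triage)),
      sprintf("n_flagged: %d", sum(triage$priority != "none")),
      sprintf("n_deconvolution_hits: %d", sum(deconvolution$hit)),
      sprintf("n_validated_hits: %d",
              sum(validation$classification == "hit"))
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
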