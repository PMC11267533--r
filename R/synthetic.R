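# Default residue sets for the synthetic ~170-residue peripheral membrane
# protein. These are synthetic stand-ins (the screening denominator has
# the canonical size of 15 functional resonances); real annotations come
# from read_annotation().
default_functional <- function() {
  c(11L, 30L, 44L, 48L, 52L, 66L, 79L, 91L, 102L, 117L, 125L, 138L, 151L,
    160L, 168L)
}
default_interface <- function() {
  sort(unique(c(default_functional(),
                c(10L, 12L, 46L, 80L, 116L, 118L, 150L, 152L))))
}

#' Simulation configuration for synthetic titrations and screens
#'
#' Bundles the generative parameters of the fast-exchange two-state
#' binding simulator. The defaults encode the screen's study conditions:
#' 100 uM protein with fragment titrated at 0/50/100/250/400 uM (a 4:1
#' fragment:protein ratio at the top point), a 15-residue observable
#' functional set, an apparent Kd of 105 uM for a specific binder, maximal
#' CSPs between 0.02 and 0.10 ppm, and Gaussian ppm noise of 0.002
#' (\eqn{^1}H) / 0.01 (\eqn{^{15}}N).
#'
#' @param seed Integer RNG seed; all outputs are reproducible from it.
#' @param n_residues Number of residues in the synthetic protein.
#' @param functional_residues Observable cationic-patch/catalytic-site
#'   residues (the screening denominator).
#' @param interface_residues Membrane-interface residues.
#' @param protein_conc Total protein, uM.
#' @param ligand_concs Titration ladder, uM; must include 0.
#' @param true_kd Planted apparent Kd, uM (binder scenarios).
#' @param responsive_residues Residues displaced by binding.
#' @param dmax_range Interval for per-residue maximal CSPs, ppm.
#' @param noise_h,noise_n Gaussian noise sigma per peak per condition, ppm.
#' @param drift_per_uM Per-uM linear CSP drift for the nonspecific
#'   scenario, ppm/uM.
#' @param scenario One of `"binder"`, `"nonbinder"`,
#'   `"nonspecific_drift"`, `"weak_binder"`.
#' @param alpha CSP nitrogen weighting used to decompose displacements.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_residues = 170L,
                              functional_residues = default_functional(),
                              interface_residues = default_interface(),
                              protein_conc = 100,
                              ligand_concs = c(0, 50, 100, 250, 400),
                              true_kd = 105,
                              responsive_residues = functional_residues,
                              dmax_range = c(0.02, 0.10),
                              noise_h = 0.002,
                              noise_n = 0.01,
                              drift_per_uM = 5e-5,
                              scenario = c("binder", "nonbinder",
                                           "nonspecific_drift",
                                           "weak_binder"),
                              alpha = 0.14) {
  scenario <- match.arg(scenario)
  if (!0 %in% ligand_concs) rlang::abort("ligand_concs must include 0")
  if (any(ligand_concs < 0)) rlang::abort("ligand_concs must be >= 0")
  if (noise_h < 0 || noise_n < 0) rlang::abort("noise sigma must be >= 0")
  if (true_kd <= 0) rlang::abort("true_kd must be > 0")
  if (protein_conc <= 0) rlang::abort("protein_conc must be > 0")
  if (!all(responsive_residues %in% seq_len(n_residues))) {
    rlang::abort("responsive_residues must lie within 1..n_residues")
  }
  if (scenario %in% c("binder", "weak_binder") &&
      length(responsive_residues) == 0) {
    rlang::abort("binder scenarios require a nonempty responsive set")
  }
  if (dmax_range[1] <= 0 || dmax_range[2] < dmax_range[1]) {
    rlang::abort("dmax_range must be a positive increasing interval")
  }
  structure(
    list(seed = as.integer(seed), n_residues = as.integer(n_residues),
         functional_residues = sort(unique(as.integer(functional_residues))),
         interface_residues = sort(unique(as.integer(interface_residues))),
         protein_conc = protein_conc,
         ligand_concs = sort(unique(ligand_concs)),
         true_kd = true_kd,
         responsive_residues = sort(unique(as.integer(responsive_residues))),
         dmax_range = dmax_range, noise_h = noise_h, noise_n = noise_n,
         drift_per_uM = drift_per_uM, scenario = scenario, alpha = alpha),
    class = "simulation_config"
  )
}

#' Annotation implied by a simulation configuration
#'
#' Splits the configured functional residues into cationic-patch and
#' catalytic-site halves (the split is immaterial downstream: only their
#' union enters the screening denominator) and uses the configured
#' interface set.
#'
#' @param config A `simulation_config`.
#' @return An `interface_annotation`.
#' @export
config_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  f <- config$functional_residues
  half <- ceiling(length(f) / 2)
  interface_annotation(
    interface = config$interface_residues,
    cationic = f[seq_len(half)],
    catalytic = f[setdiff(seq_along(f), seq_len(half))]
  )
}

# Scenario CSP model: matrix of model CSP magnitudes, residues x ligand
# concentrations (excluding the reference point), given drawn per-residue
# amplitudes `amp` (named by residue).
scenario_csp <- function(config, amp, l_points) {
  n <- config$n_residues
  out <- matrix(0, nrow = n, ncol = length(l_points))
  if (config$scenario %in% c("binder", "weak_binder")) {
    f <- bound_fraction(config$protein_conc, l_points, config$true_kd)
    for (r in config$responsive_residues) {
      out[r, ] <- amp[as.character(r)] * f
    }
  } else if (config$scenario == "nonspecific_drift") {
    for (r in seq_len(n)) {
      out[r, ] <- amp[as.character(r)] * l_points
    }
  }
  out
}

#' Simulate one titration with known ground truth
#'
#' Generates a reference peak list and one perturbed list per nonzero
#' ligand concentration. Reference amide positions are drawn once from
#' plausible ranges; each responsive residue is displaced along a fixed
#' random direction in weighted shift space by
#' `dmax * bound_fraction(P, L, Kd)`, decomposed so the weighted CSP of
#' the noiseless displacement equals the model value exactly; independent
#' Gaussian noise is then added per peak per titration point. The same
#' configuration (same seed) always produces identical output.
#'
#' Scenarios: `"binder"`/`"weak_binder"` displace the responsive set by
#' the depletion isotherm; `"nonbinder"` leaves every peak at its
#' reference position (plus noise); `"nonspecific_drift"` drifts *all*
#' residues linearly in ligand concentration (non-saturating,
#' non-localized).
#'
#' @param config A `simulation_config`.
#' @param fragment_id Identifier recorded in the series and truth entry.
#'
#' @return A list with `series` (a `titration_series`) and `truth` (a
#'   one-row tibble: `fragment_id`, `scenario`, `true_kd`,
#'   `responsive_residues` and `dmax` as list-columns, `seed`).
#' @export
simulate_titration <- function(config, fragment_id = "synthetic") {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_residues
    res_letters <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                            "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                            "W", "Y"), n, replace = TRUE)
    assignment <- sprintf("%s%dN-H", res_letters, seq_len(n))
    ref_h <- stats::runif(n, 7.0, 9.8)
    ref_n <- stats::runif(n, 103, 132)
    theta <- stats::runif(n, 0, 2 * pi)

    amp_res <- if (config$scenario == "nonspecific_drift") {
      seq_len(n)
    } else {
      config$responsive_residues
    }
    amp <- stats::setNames(rep(0, n), seq_len(n))
    if (config$scenario %in% c("binder", "weak_binder")) {
      amp[as.character(amp_res)] <-
        stats::runif(length(amp_res), config$dmax_range[1],
                     config$dmax_range[2])
    } else if (config$scenario == "nonspecific_drift") {
      # per-residue drift slope, centred on drift_per_uM
      amp[as.character(amp_res)] <-
        config$drift_per_uM * stats::runif(n, 0.5, 1.5)
    }

    l_points <- setdiff(config$ligand_concs, 0)
    csp_mat <- scenario_csp(config, amp, l_points)

    reference <- peaklist(
      tibble::tibble(assignment = assignment, shift_n = ref_n,
                     shift_h = ref_h),
      condition_label = "apo", ligand_conc = 0,
      protein_conc = config$protein_conc
    )
    points <- vector("list", length(l_points))
    for (j in seq_along(l_points)) {
      # displacement decomposed so sqrt(dh^2 + (alpha dn)^2) == csp
      dh <- csp_mat[, j] * cos(theta)
      dn <- csp_mat[, j] * sin(theta) / config$alpha
      eh <- if (config$noise_h > 0) stats::rnorm(n, 0, config$noise_h) else 0
      en <- if (config$noise_n > 0) stats::rnorm(n, 0, config$noise_n) else 0
      points[[j]] <- peaklist(
        tibble::tibble(assignment = assignment,
                       shift_n = ref_n + dn + en,
                       shift_h = ref_h + dh + eh),
        condition_label = sprintf("%s_%guM", fragment_id, l_points[j]),
        ligand_conc = l_points[j], protein_conc = config$protein_conc
      )
    }
    series <- build_titration_series(c(list(reference), points),
                                     fragment_id = fragment_id)
    truth <- tibble::tibble(
      fragment_id = fragment_id,
      scenario = config$scenario,
      true_kd = if (config$scenario %in% c("binder", "weak_binder")) {
        config$true_kd
      } else {
        NA_real_
      },
      responsive_residues = list(amp_res),
      dmax = list(unname(amp[as.character(amp_res)])),
      seed = config$seed
    )
    list(series = series, truth = truth)
  })
}

# Reseed a config (keeping everything else), optionally switching scenario.
reseed_config <- function(config, seed, scenario = config$scenario) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  cfg$scenario <- scenario
  cfg
}

#' Simulate a full mixture screen with planted binders
#'
#' Partitions `library_size` fragments into consecutive mixtures of
#' `mixture_size` (ceiling partitioning: the last mixture may be smaller),
#' plants `n_binders` binder fragments, and generates one apo-vs-mixture
#' HSQC pair per mixture at the screening concentration (the top of the
#' configured ladder, 400 uM by default — the 4:1 design). A mixture's
#' observable is generated from the strongest planted binder it contains
#' (lowest Kd; remaining members contribute nothing, mirroring a
#' single-protein observable and deconvolution by individual retesting).
#'
#' @param library_size Number of fragments in the library.
#' @param n_binders Number of planted binder fragments.
#' @param mixture_size Fragments per mixture.
#' @param base_config A `simulation_config`; its seed drives all draws.
#' @param binder_ids Optional explicit fragment ids (or indices) to plant
#'   as binders; default is a seeded random draw.
#'
#' @return A list of class `synthetic_screen` with:
#'   `manifest` (tibble: `mixture_id`, `fragment_ids` list-column),
#'   `mixtures` (named list of `list(reference, observed)` peak lists),
#'   `truth` (tibble: one row per fragment with `is_binder`, `seed`,
#'   `mixture_id`), and `base_config`.
#' @export
simulate_screen <- function(library_size, n_binders, mixture_size = 10L,
                            base_config = simulation_config(),
                            binder_ids = NULL) {
  if (library_size < 1 || mixture_size < 1) {
    rlang::abort("library_size and mixture_size must be >= 1")
  }
  if (n_binders < 0 || n_binders > library_size) {
    rlang::abort("n_binders must lie in [0, library_size]")
  }
  stopifnot(inherits(base_config, "simulation_config"))

  fragment_ids <- sprintf("F%04d", seq_len(library_size))
  n_mix <- ceiling(library_size / mixture_size)
  mixture_id <- sprintf("M%03d", ceiling(seq_len(library_size) / mixture_size))

  withr::with_seed(base_config$seed, {
    if (is.null(binder_ids)) {
      binder_idx <- sort(sample.int(library_size, n_binders))
    } else {
      binder_idx <- if (is.character(binder_ids)) {
        match(binder_ids, fragment_ids)
      } else {
        as.integer(binder_ids)
      }
      if (any(is.na(binder_idx)) || length(binder_idx) != n_binders) {
        rlang::abort("binder_ids must name n_binders valid fragments")
      }
      binder_idx <- sort(binder_idx)
    }
    frag_seeds <- sample.int(.Machine$integer.max - 1L, library_size)
  })

  truth <- tibble::tibble(
    fragment_id = fragment_ids,
    mixture_id = mixture_id,
    is_binder = seq_len(library_size) %in% binder_idx,
    scenario = ifelse(seq_len(library_size) %in% binder_idx,
                      base_config$scenario, "nonbinder"),
    true_kd = ifelse(seq_len(library_size) %in% binder_idx,
                     base_config$true_kd, NA_real_),
    seed = frag_seeds
  )

  l_top <- max(base_config$ligand_concs)
  screen_concs <- c(0, l_top)
  mixtures <- vector("list", n_mix)
  names(mixtures) <- sprintf("M%03d", seq_len(n_mix))
  for (m in seq_len(n_mix)) {
    members <- which(mixture_id == names(mixtures)[m])
    planted <- intersect(members, binder_idx)
    driver <- if (length(planted) > 0) {
      # strongest binder drives the mixture observable (ties: first)
      planted[which.min(truth$true_kd[planted])]
    } else {
      members[1]
    }
    cfg <- reseed_config(base_config, truth$seed[driver],
                         scenario = truth$scenario[driver])
    cfg$ligand_concs <- screen_concs
    sim <- simulate_titration(cfg, fragment_id = truth$fragment_id[driver])
    mixtures[[m]] <- list(reference = sim$series$reference,
                          observed = sim$series$points[[1]])
  }

  members_by_mixture <- split(fragment_ids, mixture_id)
  manifest <- tibble::tibble(
    mixture_id = names(mixtures),
    fragment_ids = unname(members_by_mixture[names(mixtures)])
  )
  structure(
    list(manifest = manifest, mixtures = mixtures, truth = truth,
         base_config = base_config),
    class = "synthetic_screen"
  )
}

#' Regenerate one fragment's data from a screen truth table
#'
#' Used for the deconvolution (single point at the screening
#' concentration) and titration (full ladder) stages: rebuilds the
#' fragment's synthetic data from its recorded seed and scenario, so the
#' retest is reproducible from the truth table alone.
#'
#' @param screen A `synthetic_screen`.
#' @param fragment_id Fragment to regenerate.
#' @param ligand_concs Ladder to simulate; default the base config's.
#' @return A list with `series` and `truth` (see [simulate_titration()]).
#' @export
simulate_fragment <- function(screen, fragment_id,
                              ligand_concs = screen$base_config$ligand_concs) {
  stopifnot(inherits(screen, "synthetic_screen"))
  i <- match(fragment_id, screen$truth$fragment_id)
  if (is.na(i)) rlang::abort(paste0("unknown fragment: ", fragment_id))
  cfg <- reseed_config(screen$base_config, screen$truth$seed[i],
                       scenario = screen$truth$scenario[i])
  cfg$ligand_concs <- sort(unique(c(0, ligand_concs)))
  simulate_titration(cfg, fragment_id = fragment_id)
}
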