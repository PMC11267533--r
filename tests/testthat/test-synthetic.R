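test_that("noiseless generator output matches the binding model exactly", {
  cfg <- simulation_config(seed = 9, noise_h = 0, noise_n = 0,
                           responsive_residues = c(11, 117, 138, 151, 168))
  sim <- simulate_titration(cfg, "fragX")
  truth_dmax <- setNames(sim$truth$dmax[[1]],
                         sim$truth$responsive_residues[[1]])
  for (j in seq_along(sim$series$points)) {
    L <- attr(sim$series$points[[j]], "ligand_conc")
    prof <- compute_csp(sim$series$reference, sim$series$points[[j]])
    f <- bound_fraction(cfg$protein_conc, L, cfg$true_kd)
    for (r in names(truth_dmax)) {
      expect_equal(prof$csp[prof$residue == as.integer(r)],
                   truth_dmax[[r]] * f, tolerance = 1e-9)
    }
    # unresponsive residues do not move
    quiet <- setdiff(prof$residue, as.integer(names(truth_dmax)))
    expect_equal(max(prof$csp[prof$residue %in% quiet]), 0)
  }
})

test_that("nonbinder and drift scenarios behave as designed", {
  cfg <- simulation_config(seed = 10, noise_h = 0, noise_n = 0,
                           scenario = "nonbinder")
  sim <- simulate_titration(cfg)
  for (p in sim$series$points) {
    expect_equal(max(compute_csp(sim$series$reference, p)$csp), 0)
  }

  # drift grows linearly with ligand concentration on every residue
  cfgd <- simulation_config(seed = 10, noise_h = 0, noise_n = 0,
                            scenario = "nonspecific_drift")
  simd <- simulate_titration(cfgd)
  p1 <- compute_csp(simd$series$reference, simd$series$points[[1]])  # 50 uM
  p4 <- compute_csp(simd$series$reference, simd$series$points[[4]])  # 400 uM
  expect_equal(p4$csp, p1$csp * 8, tolerance = 1e-9)
  expect_true(all(p4$csp > 0))
})

test_that("identical config and seed give byte-identical peak lists", {
  cfg <- simulation_config(seed = 77)
  a <- simulate_titration(cfg, "f")
  b <- simulate_titration(cfg, "f")
  fa <- withr::local_tempfile(fileext = ".list")
  fb <- withr::local_tempfile(fileext = ".list")
  write_peaklist(a$series$points[[3]], fa)
  write_peaklist(b$series$points[[3]], fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$series, b$series)

  # a different seed changes the data
  c2 <- simulate_titration(simulation_config(seed = 78), "f")
  expect_false(identical(a$series$reference$shift_h,
                         c2$series$reference$shift_h))
})

test_that("config validation rejects inconsistent scenarios", {
  expect_error(simulation_config(responsive_residues = integer(),
                                 scenario = "binder"), "responsive")
  expect_error(simulation_config(ligand_concs = c(50, 100)), "include 0")
  expect_error(simulation_config(noise_h = -1), "noise")
  expect_error(simulation_config(true_kd = 0), "true_kd")
  expect_error(simulation_config(responsive_residues = 9999), "1..n_residues")
})

test_that("screen partitioning uses ceiling arithmetic and conserves fragments", {
  cfg <- simulation_config(seed = 3)
  # 1911 fragments in mixtures of 10 -> 192 mixtures, the last of size 1
  scr <- simulate_screen(1911, n_binders = 0, mixture_size = 10,
                         base_config = cfg)
  expect_equal(nrow(scr$manifest), 192)
  sizes <- lengths(scr$manifest$fragment_ids)
  expect_equal(sizes[192], 1)
  expect_true(all(sizes[1:191] == 10))
  # every fragment appears in exactly one mixture
  all_frag <- unlist(scr$manifest$fragment_ids)
  expect_equal(sort(all_frag), sort(scr$truth$fragment_id))
  expect_equal(anyDuplicated(all_frag), 0L)
})

test_that("zero-noise screen with no binders triggers no triage flags", {
  cfg <- simulation_config(seed = 5, noise_h = 0, noise_n = 0)
  scr <- simulate_screen(50, n_binders = 0, mixture_size = 10,
                         base_config = cfg)
  ann <- config_annotation(cfg)
  tiers <- vapply(scr$mixtures, function(mx) {
    as.character(triage_mixture(compute_csp(mx$reference, mx$observed),
                                ann))
  }, character(1))
  expect_true(all(tiers == "none"))
})

test_that("Kd dispersion across seeds grows with peak-position noise", {
  resp <- c(3, 7, 11, 15, 19)  # small protein keeps the sweep fast
  noise_levels <- c(0.001, 0.004, 0.012)
  n_seeds <- 50
  disp <- vapply(noise_levels, function(nh) {
    kd <- vapply(seq_len(n_seeds), function(s) {
      cfg <- simulation_config(seed = 7000 + s, noise_h = nh,
                               n_residues = 20,
                               responsive_residues = resp)
      sim <- simulate_titration(cfg, "f")
      # at high noise a titration can lose all fit-worthy residues
      tryCatch(fit_global(sim$series, resp)$kd,
               error = function(e) NA_real_)
    }, numeric(1))
    stats::sd(kd, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
})

test_that("fragment regeneration from the truth table reproduces the screen data", {
  cfg <- simulation_config(seed = 21)
  scr <- simulate_screen(30, n_binders = 2, mixture_size = 10,
                         base_config = cfg)
  binder <- scr$truth$fragment_id[scr$truth$is_binder][1]
  mix_id <- scr$truth$mixture_id[scr$truth$fragment_id == binder]
  sim <- simulate_fragment(scr, binder, ligand_concs = c(0, 400))
  # the mixture observable was generated from its strongest binder
  mix_obs <- scr$mixtures[[mix_id]]$observed
  regen <- sim$series$points[[1]]
  expect_identical(mix_obs$assignment, regen$assignment)
  expect_identical(mix_obs$shift_h, regen$shift_h)
  expect_identical(mix_obs$shift_n, regen$shift_n)
  expect_error(simulate_fragment(scr, "F9999"), "unknown fragment")
})
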