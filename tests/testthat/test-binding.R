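# Independent oracle for the bound fraction: solve the equilibrium mass
# balance (P - PL)(L - PL) / PL = Kd for the complex concentration PL by
# root bracketing, without using the closed form under test.
bound_fraction_oracle <- function(p, l, kd) {
  if (l == 0) return(0)
  g <- function(pl) (p - pl) * (l - pl) / pl - kd
  upper <- min(p, l)
  stats::uniroot(g, lower = upper * 1e-12, upper = upper * (1 - 1e-12),
                 tol = 1e-13)$root / p
}

test_that("bound fraction matches the closed-form and oracle values", {
  # no ligand, no binding
  expect_equal(bound_fraction(100, 0, 50), 0)

  # stoichiometric limit: tight binder with excess ligand saturates
  expect_equal(bound_fraction(100, 400, 1e-9), 1, tolerance = 1e-6)

  # closed-form arithmetic: P = L = Kd = 100 -> (300 - sqrt(50000)) / 200
  expect_equal(bound_fraction(100, 100, 100), (300 - sqrt(50000)) / 200,
               tolerance = 1e-15)
  expect_equal(bound_fraction(100, 100, 100), 0.3819660, tolerance = 1e-7)

  expect_error(bound_fraction(0, 100, 50), "p_total")
  expect_error(bound_fraction(100, -1, 50), "l_total")
  expect_error(bound_fraction(100, 100, 0), "kd")
})

test_that("bound fraction agrees with the equilibrium root-finder on a grid", {
  grid <- exp(seq(log(1), log(1000), length.out = 10))
  worst <- 0
  for (p in grid) for (l in grid) for (kd in grid) {
    worst <- max(worst, abs(bound_fraction(p, l, kd) -
                              bound_fraction_oracle(p, l, kd)))
  }
  expect_lt(worst, 1e-9)
})

test_that("bound fraction reduces to the hyperbolic law when P << Kd", {
  kd <- 100
  p <- kd * 1e-5
  for (l in c(10, 50, 100, 400, 1000)) {
    expect_equal(bound_fraction(p, l, kd), l / (l + kd), tolerance = 1e-4)
  }
})

test_that("bound fraction is monotone in ligand and in Kd", {
  l_grid <- seq(0, 800, by = 25)
  f <- bound_fraction(100, l_grid, 105)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))

  kd_grid <- exp(seq(log(1), log(5000), length.out = 40))
  fk <- vapply(kd_grid, function(k) bound_fraction(100, 400, k), numeric(1))
  expect_true(all(diff(fk) < 0))
})

test_that("predicted CSP is the saturation shift times the bound fraction", {
  expect_equal(predict_csp(100, 0.05, 100, 0), 0)
  expect_equal(predict_csp(1e-9, 0.05, 100, 400), 0.05, tolerance = 1e-6)
  expect_equal(predict_csp(100, 0.05, 100, 100),
               0.05 * (300 - sqrt(50000)) / 200, tolerance = 1e-12)
  expect_equal(predict_csp(100, 0.05, 100, 100), 0.0190983,
               tolerance = 1e-6)
})

test_that("single-residue fit recovers noiseless parameters exactly", {
  ser <- make_series(kd = 105, dmax_by_res = c(`11` = 0.05))
  ft <- fit_residue(ser, 11)
  expect_equal(ft$kd, 105, tolerance = 1e-6)
  expect_equal(ft$dmax, 0.05, tolerance = 1e-6)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)
  expect_true(ft$ok)
  expect_equal(ft$n_points, 5)  # 4 titration points + reference

  # flat zero response is flagged at the dmax boundary
  ser0 <- make_series(kd = 105, dmax_by_res = c(`11` = 0))
  ft0 <- fit_residue(ser0, 11)
  expect_false(ft0$ok)
  expect_match(ft0$reason, "no response")

  # too few points
  ser2 <- make_series(kd = 105, dmax_by_res = c(`11` = 0.05),
                      l_points = 400)
  expect_error(fit_residue(ser2, 11), ">= 3")
})

test_that("fit minimum agrees with a brute-force 2-D grid search", {
  # noisy data, fixed seed; oracle scans a 200 x 200 log grid over
  # (Kd, dmax) independently of the profiled optimiser
  set.seed(404)
  noise <- lapply(1:4, function(j) rnorm(1, 0, 0.002))
  ser <- make_series(kd = 105, dmax_by_res = c(`11` = 0.05),
                     extra_csp = noise)
  ft <- fit_residue(ser, 11)

  dat <- ft$data
  kd_grid <- exp(seq(log(0.4), log(4000), length.out = 200))
  dm_grid <- seq(0.001, 0.2, length.out = 200)
  ss <- outer(kd_grid, dm_grid, Vectorize(function(k, d) {
    sum((dat$csp - d * bound_fraction(100, dat$ligand_conc, k))^2)
  }))
  best <- arrayInd(which.min(ss), dim(ss))
  kd_cell <- kd_grid[best[1]]
  # within one grid cell of the oracle minimum
  cell_ratio <- kd_grid[2] / kd_grid[1]
  expect_lt(abs(log(ft$kd / kd_cell)), 1.5 * log(cell_ratio))
  expect_lt(abs(ft$dmax - dm_grid[best[2]]), 1.5 * diff(dm_grid[1:2]))
})

test_that("global fit shares Kd, rejects poor fits, and reduces correctly", {
  # single surviving residue: global Kd equals the individual fit
  ser1 <- make_series(kd = 105, dmax_by_res = c(`11` = 0.05))
  g1 <- fit_global(ser1, 11)
  expect_equal(g1$kd, fit_residue(ser1, 11)$kd, tolerance = 1e-9)

  # five noiseless residues with distinct dmax: exact shared recovery
  dmx <- c(`11` = 0.02, `117` = 0.04, `138` = 0.06, `151` = 0.08,
           `168` = 0.10)
  ser5 <- make_series(kd = 105, dmax_by_res = dmx)
  g5 <- fit_global(ser5, as.integer(names(dmx)))
  expect_equal(g5$kd, 105, tolerance = 1e-6)
  expect_setequal(g5$residues_used, as.integer(names(dmx)))
  expect_equal(unname(g5$per_residue_dmax[names(dmx)]), unname(dmx),
               tolerance = 1e-6)
  expect_equal(nrow(g5$residues_rejected), 0)

  # contamination: a pure-noise residue is rejected by the R2 cutoff and
  # the Kd matches the clean 4-residue fit within its standard error
  set.seed(505)
  resr <- c(11, 117, 138, 151, 99)
  asg <- sprintf("A%dN-H", resr)
  ref <- make_pl(asg, rep(115, 5), rep(8.2, 5))
  pts <- lapply(c(50, 100, 250, 400), function(L) {
    csp <- c(c(0.02, 0.04, 0.06, 0.08) * bound_fraction(100, L, 105),
             runif(1, 0, 0.05))
    make_pl(asg, rep(115, 5), 8.2 + csp, ligand_conc = L)
  })
  serc <- build_titration_series(c(list(ref), pts), "contaminated")
  gc_ <- fit_global(serc, resr)
  expect_true(99 %in% gc_$residues_rejected$residue)
  g4 <- fit_global(serc, c(11, 117, 138, 151))
  expect_lt(abs(gc_$kd - g4$kd), 2 * max(g4$kd_stderr, 1e-6) + 1e-6)

  # all rejected -> informative error
  ser0 <- make_series(kd = 105, dmax_by_res = c(`11` = 0, `12` = 0))
  expect_error(fit_global(ser0, c(11, 12)), "no fit-worthy")
})

test_that("global fit is invariant to residue ordering", {
  dmx <- c(`11` = 0.03, `48` = 0.05, `79` = 0.09)
  ser <- make_series(kd = 200, dmax_by_res = dmx)
  a <- fit_global(ser, c(11, 48, 79))
  b <- fit_global(ser, c(79, 11, 48))
  expect_equal(a$kd, b$kd)
  expect_equal(a$per_residue_dmax, b$per_residue_dmax)
})

test_that("R2 retention boundary is inclusive at the cutoff", {
  expect_true(retain_fit(0.85, 0.85))
  expect_false(retain_fit(0.849, 0.85))
  expect_true(retain_fit(1.0))
  expect_false(retain_fit(NA_real_))
})

test_that("tidy and glance summarise a global fit", {
  dmx <- c(`11` = 0.04, `117` = 0.08)
  ser <- make_series(kd = 105, dmax_by_res = dmx)
  g <- fit_global(ser, c(11, 117))
  td <- tidy(g)
  expect_equal(td$residue, c(11, 117))
  expect_true(all(td$used))
  expect_equal(td$dmax, unname(dmx), tolerance = 1e-6)
  gl <- glance(g)
  expect_equal(gl$kd_uM, 105, tolerance = 1e-5)
  expect_equal(gl$n_residues_used, 2L)
})

test_that("fragment classification combines affinity and locality", {
  ann <- make_annotation()
  dmx <- c(`1` = 0.05, `2` = 0.06, `3` = 0.07)

  # localized specific binder below the cutoff -> hit
  ser <- make_series(kd = 105, dmax_by_res = dmx)
  fit <- fit_global(ser, 1:3)
  prof <- compute_csp(ser$reference, ser$points[[4]])
  expect_equal(as.character(classify_fragment(fit, prof, ann)), "hit")

  # localized but above the cutoff -> weak
  serw <- make_series(kd = 2500, dmax_by_res = dmx)
  fitw <- fit_global(serw, 1:3)
  profw <- compute_csp(serw$reference, serw$points[[4]])
  expect_equal(as.character(classify_fragment(fitw, profw, ann)), "weak")

  # scattered top shifters -> nonspecific even at good affinity
  dmx_s <- c(`60` = 0.05, `70` = 0.06, `80` = 0.07, `1` = 0.055)
  sers <- make_series(kd = 300, dmax_by_res = dmx_s)
  fits <- fit_global(sers, as.integer(names(dmx_s)))
  profs <- compute_csp(sers$reference, sers$points[[4]])
  cls <- classify_fragment(fits, profs, ann)
  expect_equal(as.character(cls), "nonspecific")
  expect_lte(attr(cls, "locality"), 0.25)

  expect_error(classify_fragment(list(), prof, ann), "global fit")
})
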