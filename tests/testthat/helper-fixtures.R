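# Small builders shared across the test files. All fixtures are generated
# in code; nothing is read from disk except files the tests write first.

make_pl <- function(assignments, shift_n, shift_h, ligand_conc = 0,
                    protein_conc = 100, height = NULL, label = "test") {
  df <- tibble::tibble(assignment = assignments, shift_n = shift_n,
                       shift_h = shift_h)
  if (!is.null(height)) df$height <- height
  peaklist(df, condition_label = label, ligand_conc = ligand_conc,
           protein_conc = protein_conc)
}

# A profile built directly from two constructed peak lists: residues
# 1..n with the requested CSPs realised purely in the 1H dimension.
make_profile <- function(csp_values, residues = seq_along(csp_values),
                         ligand_conc = 400) {
  asg <- sprintf("A%dN-H", residues)
  ref <- make_pl(asg, rep(120, length(residues)), rep(8, length(residues)))
  obs <- make_pl(asg, rep(120, length(residues)),
                 8 + csp_values, ligand_conc = ligand_conc)
  compute_csp(ref, obs)
}

# Annotation with the canonical 15-residue functional set.
make_annotation <- function() {
  interface_annotation(
    interface = c(1:20, 30:40),
    cationic = 1:8,
    catalytic = 9:15
  )
}

# Noiseless titration series for one residue ladder built from the
# depletion model itself (independent of the simulator).
make_series <- function(kd, dmax_by_res, p_total = 100,
                        l_points = c(50, 100, 250, 400),
                        extra_csp = NULL) {
  residues <- as.integer(names(dmax_by_res))
  asg <- sprintf("A%dN-H", residues)
  ref <- make_pl(asg, rep(115, length(residues)), rep(8.2, length(residues)),
                 protein_conc = p_total)
  pts <- lapply(seq_along(l_points), function(j) {
    L <- l_points[j]
    csp <- unname(dmax_by_res) * bound_fraction(p_total, L, kd)
    if (!is.null(extra_csp)) csp <- csp + extra_csp[[j]]
    make_pl(asg, rep(115, length(residues)), 8.2 + csp,
            ligand_conc = L, protein_conc = p_total)
  })
  build_titration_series(c(list(ref), pts), fragment_id = "fixture")
}
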