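#' Construct a peak list
#'
#' A peak list holds the assigned amide resonances of one 2D
#' \eqn{^{15}}N-HSQC measurement: one row per backbone amide, with the
#' observed \eqn{^1}H and \eqn{^{15}}N chemical shifts, plus the sample
#' metadata (ligand and protein concentration, environment) the downstream
#' analysis needs.
#'
#' @param peaks A data frame with columns `assignment` (character, e.g.
#'   `"A11N-H"`), `shift_n` (ppm), `shift_h` (ppm) and optionally `height`.
#' @param condition_label Free-text label for the condition.
#' @param ligand_conc Total ligand (fragment) concentration, uM. Must be
#'   `>= 0`.
#' @param protein_conc Total protein concentration, uM. Must be `> 0`.
#' @param environment One of `"mmRM"`, `"micelle"`, `"bicelle"`,
#'   `"aqueous"`.
#'
#' @return A tibble of class `peaklist` with columns `assignment`,
#'   `residue`, `shift_h`, `shift_n`, `height`, carrying the metadata as
#'   attributes (retrievable with [peaklist_meta()]).
#' @export
#' @examples
#' pl <- peaklist(
#'   data.frame(assignment = c("A11N-H", "K48N-H"),
#'              shift_n = c(120.15, 118.30),
#'              shift_h = c(8.02, 7.85)),
#'   condition_label = "apo", ligand_conc = 0, protein_conc = 100
#' )
#' pl
peaklist <- function(peaks,
                     condition_label = "",
                     ligand_conc = 0,
                     protein_conc = 100,
                     environment = c("mmRM", "micelle", "bicelle", "aqueous")) {
  environment <- match.arg(environment)
  stopifnot(is.data.frame(peaks))
  required <- c("assignment", "shift_n", "shift_h")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("peaks is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(ligand_conc) || length(ligand_conc) != 1 || ligand_conc < 0) {
    rlang::abort("ligand_conc must be a single number >= 0 (uM)")
  }
  if (!is.numeric(protein_conc) || length(protein_conc) != 1 ||
      protein_conc <= 0) {
    rlang::abort("protein_conc must be a single number > 0 (uM)")
  }

  pk <- tibble::as_tibble(peaks)
  pk$assignment <- as.character(pk$assignment)
  if (!"height" %in% names(pk)) pk$height <- NA_real_
  if (anyDuplicated(pk$assignment)) {
    dups <- unique(pk$assignment[duplicated(pk$assignment)])
    rlang::abort(paste0("duplicate assignment(s) in peak list: ",
                        paste(dups, collapse = ", ")))
  }
  if (any(!nzchar(pk$assignment))) rlang::abort("empty assignment label")
  if (any(pk$shift_h < -2 | pk$shift_h > 14)) {
    rlang::abort("shift_h outside plausible amide range [-2, 14] ppm")
  }
  if (any(pk$shift_n < 90 | pk$shift_n > 140)) {
    rlang::abort("shift_n outside plausible amide range [90, 140] ppm")
  }
  pk$residue <- parse_residue_number(pk$assignment)
  pk <- pk[, c("assignment", "residue", "shift_h", "shift_n", "height")]

  structure(
    pk,
    condition_label = condition_label,
    ligand_conc = ligand_conc,
    protein_conc = protein_conc,
    environment = environment,
    class = c("peaklist", class(tibble::tibble()))
  )
}

#' Retrieve sample metadata from a peak list
#'
#' @param pl A `peaklist`.
#' @return A list with `condition_label`, `ligand_conc`, `protein_conc`,
#'   `environment`.
#' @export
peaklist_meta <- function(pl) {
  stopifnot(inherits(pl, "peaklist"))
  list(
    condition_label = attr(pl, "condition_label"),
    ligand_conc = attr(pl, "ligand_conc"),
    protein_conc = attr(pl, "protein_conc"),
    environment = attr(pl, "environment")
  )
}

# Residue number from a Sparky-style assignment label: leading residue-type
# letter(s) are tolerated but only the integer is used for matching.
parse_residue_number <- function(assignment) {
  m <- regmatches(assignment, regexpr("[0-9]+", assignment))
  bad <- lengths(regmatches(assignment, gregexpr("[0-9]+", assignment))) == 0
  if (any(bad)) {
    rlang::abort(paste0("assignment without residue number: ",
                        paste(assignment[bad], collapse = ", ")))
  }
  as.integer(m)
}

#' Read a Sparky-style peak list
#'
#' Parses a whitespace-delimited assigned peak list (the dialect written by
#' Sparky/NMRFAM-Sparky): columns `assignment`, `w1` (\eqn{^{15}}N ppm),
#' `w2` (\eqn{^1}H ppm) and optionally a height column. A single header
#' line (any line whose second field is not numeric) is skipped.
#'
#' @param path Path to the `.list` file.
#' @param condition_label,ligand_conc,protein_conc,environment Sample
#'   metadata attached to the result; see [peaklist()].
#' @param swap_columns If `TRUE`, the file stores `w1` = \eqn{^1}H and
#'   `w2` = \eqn{^{15}}N (both column conventions exist in the wild).
#'
#' @return A `peaklist` tibble.
#' @export
#' @examples
#' # synthetic demo spectra shipped with the package
#' apo <- read_peaklist(system.file("extdata", "demo_apo.list",
#'                                  package = "cspscreen"),
#'                      ligand_conc = 0, protein_conc = 100)
#' bound <- read_peaklist(system.file("extdata", "demo_400uM.list",
#'                                    package = "cspscreen"),
#'                        ligand_conc = 400, protein_conc = 100)
#' head(compute_csp(apo, bound))
read_peaklist <- function(path,
                          condition_label = basename(path),
                          ligand_conc = 0,
                          protein_conc = 100,
                          environment = "mmRM",
                          swap_columns = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))

  rows <- vector("list", length(keep))
  n_out <- 0L
  for (i in keep) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 3) {
      rlang::abort(sprintf("malformed peak-list row at line %d: %s",
                           i, lines[i]))
    }
    w1 <- suppressWarnings(as.numeric(fields[2]))
    w2 <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(w1) || is.na(w2)) {
      # tolerate a single header line; anything else is malformed
      if (n_out == 0L && i == keep[1]) next
      rlang::abort(sprintf("malformed peak-list row at line %d: %s",
                           i, lines[i]))
    }
    height <- if (length(fields) >= 4) {
      suppressWarnings(as.numeric(fields[4]))
    } else {
      NA_real_
    }
    n_out <- n_out + 1L
    rows[[n_out]] <- list(assignment = fields[1], w1 = w1, w2 = w2,
                          height = height)
  }
  rows <- rows[seq_len(n_out)]

  if (n_out == 0L) {
    pk <- tibble::tibble(assignment = character(), shift_n = numeric(),
                         shift_h = numeric(), height = numeric())
  } else {
    tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    if (swap_columns) {
      pk <- tibble::tibble(assignment = tab$assignment, shift_n = tab$w2,
                           shift_h = tab$w1, height = tab$height)
    } else {
      pk <- tibble::tibble(assignment = tab$assignment, shift_n = tab$w1,
                           shift_h = tab$w2, height = tab$height)
    }
  }
  peaklist(pk, condition_label = condition_label, ligand_conc = ligand_conc,
           protein_conc = protein_conc, environment = environment)
}

#' Write a peak list in Sparky dialect
#'
#' Writes `assignment  w1(15N)  w2(1H)  [height]` with shifts at 4 decimal
#' places, so `read_peaklist(write_peaklist(pl))` reproduces all
#' assignments and shifts at the written precision.
#'
#' @param pl A `peaklist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peaklist"))
  has_height <- any(!is.na(pl$height))
  header <- if (has_height) {
    "      Assignment         w1         w2     Height"
  } else {
    "      Assignment         w1         w2"
  }
  body <- if (nrow(pl) == 0) {
    character()
  } else if (has_height) {
    sprintf("%16s %10.4f %10.4f %10.4f", pl$assignment, pl$shift_n,
            pl$shift_h, ifelse(is.na(pl$height), 0, pl$height))
  } else {
    sprintf("%16s %10.4f %10.4f", pl$assignment, pl$shift_n, pl$shift_h)
  }
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rlang::abort(paste0("cannot write peak list to: ", path))
  invisible(path)
}

#' Assemble a titration series from peak lists
#'
#' Orders condition-matched peak lists by ascending ligand concentration,
#' taking the list with zero ligand as the reference (zero point) of the
#' titration. Residues missing from any point are retained and flagged
#' incomplete rather than dropped, and are excluded per-fit downstream.
#'
#' @param lists A list of `peaklist` objects, exactly one of which has
#'   `ligand_conc = 0`. All must share the same `protein_conc`.
#' @param fragment_id Identifier of the titrated fragment.
#'
#' @return An object of class `titration_series`: a list with elements
#'   `reference` (`peaklist`), `points` (list of `peaklist`s sorted by
#'   ligand concentration), `fragment_id`, `protein_conc`, and
#'   `incomplete_residues` (residues absent from at least one list).
#' @export
build_titration_series <- function(lists, fragment_id = "") {
  stopifnot(is.list(lists), length(lists) >= 2)
  ok <- vapply(lists, inherits, logical(1), what = "peaklist")
  if (!all(ok)) rlang::abort("all elements of `lists` must be peaklist objects")

  lconc <- vapply(lists, function(x) attr(x, "ligand_conc"), numeric(1))
  pconc <- vapply(lists, function(x) attr(x, "protein_conc"), numeric(1))
  is_zero <- lconc == 0
  if (sum(is_zero) != 1) {
    rlang::abort("exactly one peak list must have ligand_conc = 0 (the reference)")
  }
  if (length(unique(pconc)) != 1) {
    rlang::abort("protein_conc must be identical across all peak lists")
  }
  pts <- lists[!is_zero]
  pts <- pts[order(lconc[!is_zero])]
  lsort <- sort(lconc[!is_zero])
  if (any(diff(lsort) <= 0)) {
    rlang::abort("titration points must have strictly increasing ligand_conc")
  }

  all_res <- lapply(c(lists[is_zero], pts), function(x) x$residue)
  universe <- sort(unique(unlist(all_res)))
  complete <- Reduce(intersect, all_res)
  incomplete <- setdiff(universe, complete)

  structure(
    list(
      reference = lists[is_zero][[1]],
      points = pts,
      fragment_id = fragment_id,
      protein_conc = pconc[1],
      incomplete_residues = incomplete
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  lc <- vapply(x$points, function(p) attr(p, "ligand_conc"), numeric(1))
  cat(sprintf(
    "<titration_series> fragment '%s': %d point(s) at %s uM, P = %g uM\n",
    x$fragment_id, length(x$points), paste(lc, collapse = ", "),
    x$protein_conc
  ))
  if (length(x$incomplete_residues) > 0) {
    cat("  incomplete residues:",
        paste(x$incomplete_residues, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a residue annotation
#'
#' Groups residues into the structural/functional categories used for
#' triage, hit calling and classification: the membrane-binding interface,
#' the cationic patch, and the catalytic site, plus residues whose
#' resonances are unassigned (unobservable). The screening denominator,
#' `observable_functional`, is the union of cationic-patch and
#' catalytic-site residues minus the unassigned set.
#'
#' @param interface,cationic,catalytic,unassigned Integer vectors of
#'   residue numbers (any may be empty).
#' @return An object of class `interface_annotation` with elements
#'   `membrane_interface`, `cationic_patch`, `catalytic_site`,
#'   `unassigned`, `observable_functional`.
#' @export
interface_annotation <- function(interface = integer(),
                                 cationic = integer(),
                                 catalytic = integer(),
                                 unassigned = integer()) {
  as_res <- function(x) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1)) rlang::abort("invalid residue number")
    sort(unique(x))
  }
  interface <- as_res(interface)
  cationic <- as_res(cationic)
  catalytic <- as_res(catalytic)
  unassigned <- as_res(unassigned)
  structure(
    list(
      membrane_interface = interface,
      cationic_patch = cationic,
      catalytic_site = catalytic,
      unassigned = unassigned,
      observable_functional = setdiff(union(cationic, catalytic), unassigned)
    ),
    class = "interface_annotation"
  )
}

#' Read a residue annotation table
#'
#' Reads a CSV with columns `residue,category`, where `category` is one of
#' `interface`, `cationic`, `catalytic`, `unassigned`. A residue may appear
#' under several categories (one row each).
#'
#' @param path Path to the CSV file.
#' @return An `interface_annotation`; see [interface_annotation()].
#' @export
#' @examples
#' read_annotation(system.file("extdata", "demo_annotation.csv",
#'                             package = "cspscreen"))
read_annotation <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(interface_annotation())
  if (!all(c("residue", "category") %in% names(tab))) {
    rlang::abort("annotation CSV must have columns: residue, category")
  }
  allowed <- c("interface", "cationic", "catalytic", "unassigned")
  bad <- setdiff(unique(tab$category), allowed)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown annotation category token(s): ",
                        paste(bad, collapse = ", ")))
  }
  pick <- function(cat) tab$residue[tab$category == cat]
  interface_annotation(
    interface = pick("interface"),
    cationic = pick("cationic"),
    catalytic = pick("catalytic"),
    unassigned = pick("unassigned")
  )
}

#' @export
print.interface_annotation <- function(x, ...) {
  cat(sprintf(
    "<interface_annotation> interface %d | cationic %d | catalytic %d | unassigned %d | observable functional %d\n",
    length(x$membrane_interface), length(x$cationic_patch),
    length(x$catalytic_site), length(x$unassigned),
    length(x$observable_functional)
  ))
  invisible(x)
}
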