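## structure_io: PDB reading, vdW radius assignment, sampling-cell setup.
## Parsing itself is delegated to bio3d; this layer adds the validation,
## the radii table, and the axis-aligned cell the volume estimators need.

#' Van der Waals radii tables
#'
#' Loads a two-column (element, radius) table of van der Waals radii in
#' Angstrom. The bundled default is Bondi's (1964) compilation, the de-facto
#' standard radii set of solvent-accessible-surface codes.
#'
#' @param path Path to a whitespace/tab-delimited two-column file with header
#'   `element` and `radius`. `NULL` (default) loads the bundled Bondi table.
#' @param fallback Optional positive radius (Angstrom) used for elements
#'   absent from the table. `NULL` means unknown elements are an error.
#' @return An object of class `radii_table`: a named numeric vector of radii
#'   with attribute `fallback`.
#' @examples
#' tab <- radii_table()
#' tab[["C"]]  # 1.70
#' @export
radii_table <- function(path = NULL, fallback = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bondi_radii.tsv", package = "mmpbsar")
  }
  if (!file.exists(path)) {
    mmp_stop("mmpbsar_io_error", "radii table not found: %s", path)
  }
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(tab))) {
    mmp_stop("mmpbsar_schema_error",
             "radii table must have columns 'element' and 'radius'")
  }
  r <- as.numeric(tab$radius)
  if (any(!is.finite(r)) || any(r <= 0)) {
    mmp_stop("mmpbsar_domain_error", "all radii must be finite and > 0")
  }
  if (!is.null(fallback) && (!is.finite(fallback) || fallback <= 0)) {
    mmp_stop("mmpbsar_domain_error", "fallback radius must be > 0")
  }
  out <- stats::setNames(r, normalize_element(tab$element))
  structure(out, fallback = fallback, class = "radii_table")
}

## canonical element spelling: first letter upper, rest lower ("CL" -> "Cl")
normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

new_structure <- function(atoms, cell, source = NA_character_) {
  structure(list(atoms = atoms, cell = cell, source = source),
            class = "mol_structure")
}

#' Read a molecular structure from a PDB file
#'
#' Parses ATOM/HETATM records into a set of atomic spheres plus an
#' axis-aligned sampling cell (the bounding box padded by `padding`; the
#' cell is what the accessible-volume estimators subtract pore volume from).
#' Only the first model of a multi-model file is used and only the first
#' alternate location of each atom is kept (both with a warning). Radii are
#' left at 0 until [assign_radii()] is called.
#'
#' @param path Path to a PDB file with at least one ATOM/HETATM record.
#' @param padding Cell padding in Angstrom added on every side of the atom
#'   bounding box. Default 5; the probe radius in use should be added by the
#'   caller (the `surfvol` pipeline does this).
#' @return A `mol_structure`: list with `atoms` (data.frame `element`, `x`,
#'   `y`, `z`, `radius`) and `cell` (list `min`, `max`, numeric length-3).
#' @seealso [assign_radii()], [write_structure_pdb()]
#' @export
read_pdb <- function(path, padding = 5) {
  if (!file.exists(path)) {
    mmp_stop("mmpbsar_io_error", "PDB file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    mmp_stop("mmpbsar_empty_input_error",
             "no ATOM/HETATM records in %s", path)
  }
  ## pre-scan the fixed coordinate columns so format errors carry line numbers
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      mmp_stop("mmpbsar_format_error",
               "line %d: ATOM/HETATM record shorter than coordinate fields", i)
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      mmp_stop("mmpbsar_format_error",
               "line %d: unparsable coordinates in ATOM/HETATM record", i)
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = TRUE, verbose = FALSE))
  at <- pdb$atom
  el <- at$elesy
  missing_el <- is.na(el) | el == ""
  if (any(missing_el)) {
    el[missing_el] <- suppressWarnings(bio3d::atom2ele(at$elety[missing_el]))
  }
  atoms <- data.frame(
    element = normalize_element(el),
    x = at$x, y = at$y, z = at$z,
    radius = 0,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    mmp_stop("mmpbsar_format_error", "non-finite coordinates after parsing %s",
             path)
  }
  new_structure(atoms, make_cell(atoms, padding), source = path)
}

make_cell <- function(atoms, padding) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  list(min = apply(xyz, 2, min) - padding - max(atoms$radius),
       max = apply(xyz, 2, max) + padding + max(atoms$radius))
}

#' Assign van der Waals radii to a structure
#'
#' @param structure A `mol_structure` from [read_pdb()] or built in code.
#' @param table A [radii_table()]. Elements absent from the table take the
#'   table's fallback radius (with a warning) or raise a lookup error when
#'   the table has no fallback.
#' @param padding Cell padding (Angstrom) used to rebuild the sampling cell
#'   once radii are known, so the cell-containment invariant holds for any
#'   probe up to `padding`.
#' @return The structure with `atoms$radius` filled in (> 0 everywhere).
#' @export
assign_radii <- function(structure, table = radii_table(), padding = 5) {
  stopifnot(inherits(structure, "mol_structure"))
  el <- normalize_element(structure$atoms$element)
  r <- unname(table[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    fb <- attr(table, "fallback")
    offenders <- sort(unique(el[unknown]))
    if (is.null(fb)) {
      mmp_stop("mmpbsar_lookup_error",
               "no vdW radius for element(s): %s (and table has no fallback)",
               paste(offenders, collapse = ", "))
    }
    warning(sprintf("using fallback radius %.3f for element(s): %s",
                    fb, paste(offenders, collapse = ", ")))
    r[unknown] <- fb
  }
  structure$atoms$radius <- r
  structure$cell <- make_cell(structure$atoms, padding)
  structure
}

#' Write a structure back to PDB
#'
#' Fixed-width PDB output (coordinates at 1e-3 Angstrom precision); used for
#' round-trip checks and for handing synthetic sphere clusters to external
#' tools.
#'
#' @param structure A `mol_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "mol_structure"))
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("HETATM", nrow(a)),
    resno = seq_len(nrow(a)),
    resid = rep("SPH", nrow(a)),
    eleno = seq_len(nrow(a)),
    elety = a$element,
    elesy = a$element
  )
  invisible(path)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure: %d atoms (%s)\n", nrow(x$atoms),
              if (all(x$atoms$radius > 0)) "radii assigned"
              else "radii unassigned"))
  cat(sprintf("  cell: [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] A\n",
              x$cell$min[1], x$cell$max[1], x$cell$min[2], x$cell$max[2],
              x$cell$min[3], x$cell$max[3]))
  invisible(x)
}

## invariant used before any volume estimate: every probe-inflated sphere
## must sit strictly inside the cell
check_cell_containment <- function(structure, probe_radius) {
  a <- structure$atoms
  lo <- structure$cell$min
  hi <- structure$cell$max
  rr <- a$radius + probe_radius
  ok <- a$x - rr > lo[1] & a$x + rr < hi[1] &
        a$y - rr > lo[2] & a$y + rr < hi[2] &
        a$z - rr > lo[3] & a$z + rr < hi[3]
  if (!all(ok)) {
    mmp_stop("mmpbsar_geometry_error",
             "%d atom(s) (inflated by the probe) extend outside the cell",
             sum(!ok))
  }
  invisible(TRUE)
}
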