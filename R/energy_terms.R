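## energy_terms: data model and I/O for decomposed end-state energy terms,
## frame averaging for the single-trajectory protocol, and the plug-in
## contract for single-point energy providers.
##
## Units are fixed: energies kcal/mol, areas A^2, volumes A^3. Mandatory
## per-species terms: E_vdW, E_ele, G_PB, SASA, SAV; optional: E_disp, E_sp.

TERM_COLS <- c("E_vdW", "E_ele", "G_PB", "SASA", "SAV")
OPT_TERM_COLS <- c("E_disp", "E_sp")
SPECIES <- c("PL", "P", "L")

#' Read a decomposed energy-term table
#'
#' Reads per-frame, per-species (complex PL, protein P, ligand L) decomposed
#' energy terms from a delimited text file. Two dialects are supported:
#' `long` has one row per (complex_id, frame, species) with columns
#' `complex_id, frame, species, E_vdW, E_ele, G_PB, SASA, SAV[, E_disp, E_sp]`;
#' `wide` has one row per (complex_id, frame) with species-suffixed columns
#' (`E_vdW_PL`, `E_vdW_P`, `E_vdW_L`, ...). Values are kcal/mol except SASA
#' (Angstrom^2) and SAV (Angstrom^3).
#'
#' @param path CSV or TSV file (separator chosen by extension, `.tsv`/`.tab`
#'   means tab). Lines starting with `#` are comments.
#' @param dialect `"long"` or `"wide"`.
#' @return A long-format data.frame of class `frame_terms`.
#' @export
read_terms_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    mmp_stop("mmpbsar_io_error", "terms table not found: %s", path)
  }
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "long") {
    need <- c("complex_id", "frame", "species", TERM_COLS)
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      mmp_stop("mmpbsar_schema_error", "terms table missing column(s): %s",
               paste(miss, collapse = ", "))
    }
    long <- raw
  } else {
    need <- c("complex_id", "frame",
              as.vector(outer(TERM_COLS, SPECIES, paste, sep = "_")))
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      mmp_stop("mmpbsar_schema_error", "terms table missing column(s): %s",
               paste(miss, collapse = ", "))
    }
    present_opt <- OPT_TERM_COLS[vapply(OPT_TERM_COLS, function(tc)
      all(paste(tc, SPECIES, sep = "_") %in% names(raw)), logical(1))]
    cols <- c(TERM_COLS, present_opt)
    long <- do.call(rbind, lapply(SPECIES, function(sp) {
      out <- raw[, c("complex_id", "frame"), drop = FALSE]
      out$species <- sp
      for (tc in cols) out[[tc]] <- raw[[paste(tc, sp, sep = "_")]]
      out
    }))
  }
  for (tc in intersect(c(TERM_COLS, OPT_TERM_COLS), names(long))) {
    v <- suppressWarnings(as.numeric(long[[tc]]))
    bad <- which(is.na(v) & !is.na(long[[tc]]) & long[[tc]] != "")
    if (length(bad) > 0) {
      mmp_stop("mmpbsar_parse_error",
               "non-numeric value in column %s, row %d", tc, bad[1])
    }
    long[[tc]] <- v
  }
  if (!all(long$species %in% SPECIES)) {
    mmp_stop("mmpbsar_schema_error",
             "species column must contain only PL, P, L")
  }
  absent <- setdiff(OPT_TERM_COLS, names(long))
  if (length(absent) > 0) {
    attr(long, "missing_optional") <- absent
  }
  rownames(long) <- NULL
  class(long) <- c("frame_terms", "data.frame")
  long
}

#' Average per-frame deltas (single-trajectory protocol)
#'
#' For every complex computes `delta(term) = mean over frames of
#' (term_PL - term_P - term_L)` together with the standard error of that
#' mean across frames. Every (complex, frame) must have the full PL/P/L
#' species triple.
#'
#' @param frames A `frame_terms` data.frame from [read_terms_table()].
#' @param n_rot Optional data.frame `complex_id, N_rot` (rotatable-bond
#'   counts, the entropy surrogate of the empirical estimators); complexes
#'   not listed get `N_rot = 0`.
#' @return A data.frame of class `delta_terms`, one row per complex, with
#'   columns `dE_vdW, dE_ele, dG_PB, dSASA, dSAV, dE_disp, dE_sp, N_rot,
#'   n_frames` and `se_*` standard errors.
#' @export
average_deltas <- function(frames, n_rot = NULL) {
  terms <- intersect(c(TERM_COLS, OPT_TERM_COLS), names(frames))
  key <- interaction(frames$complex_id, frames$frame, drop = TRUE)
  for (k in levels(key)) {
    sp <- frames$species[key == k]
    if (!setequal(sp, SPECIES) || length(sp) != 3) {
      mmp_stop("mmpbsar_integrity_error",
               "incomplete species triple for (complex, frame) = (%s)", k)
    }
  }
  out <- lapply(split(frames, frames$complex_id), function(fc) {
    fw <- split(fc, fc$species)
    stopifnot(all(fw$PL$frame == fw$P$frame), all(fw$PL$frame == fw$L$frame))
    nf <- nrow(fw$PL)
    row <- data.frame(complex_id = fc$complex_id[1], n_frames = nf,
                      stringsAsFactors = FALSE)
    for (tc in terms) {
      d <- fw$PL[[tc]] - fw$P[[tc]] - fw$L[[tc]]
      dn <- paste0("d", tc)
      row[[dn]] <- mean(d)
      row[[paste0("se_", dn)]] <- if (nf > 1) stats::sd(d) / sqrt(nf) else 0
    }
    row
  })
  out <- do.call(rbind, out)
  for (tc in setdiff(OPT_TERM_COLS, terms)) {
    out[[paste0("d", tc)]] <- NA_real_
    out[[paste0("se_d", tc)]] <- NA_real_
  }
  out$N_rot <- 0
  if (!is.null(n_rot)) {
    idx <- match(out$complex_id, n_rot$complex_id)
    out$N_rot[!is.na(idx)] <- n_rot$N_rot[idx[!is.na(idx)]]
  }
  rownames(out) <- NULL
  class(out) <- c("delta_terms", "data.frame")
  out
}

#' Construct a delta-terms table directly
#'
#' Validating constructor for pre-averaged ensemble differences, used when
#' terms arrive already averaged (one row per complex) rather than per-frame.
#'
#' @param df data.frame with columns `complex_id, dE_vdW, dE_ele, dG_PB,
#'   dSASA, dSAV` and optionally `dE_disp, dE_sp, N_rot, n_frames`.
#' @return The data.frame with class `delta_terms`.
#' @export
delta_terms <- function(df) {
  need <- c("complex_id", "dE_vdW", "dE_ele", "dG_PB", "dSASA", "dSAV")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    mmp_stop("mmpbsar_schema_error", "delta table missing column(s): %s",
             paste(miss, collapse = ", "))
  }
  if (is.null(df$dE_disp)) df$dE_disp <- NA_real_
  if (is.null(df$dE_sp)) df$dE_sp <- NA_real_
  if (is.null(df$N_rot)) df$N_rot <- 0
  if (is.null(df$n_frames)) df$n_frames <- 1L
  if (any(df$N_rot < 0)) {
    mmp_stop("mmpbsar_domain_error", "N_rot must be non-negative")
  }
  class(df) <- unique(c("delta_terms", class(df)))
  df
}

#' Single-point energy provider contract
#'
#' A provider is a named total-energy function over a molecular geometry,
#' the plug-in point where a machine-learned potential (or the bundled mock
#' pairwise potentials, see [mock_provider()]) replaces the gas-phase
#' molecular-mechanics terms. A conforming provider is deterministic and
#' invariant under atom permutation and rigid motion; [check_provider()]
#' asserts this.
#'
#' @param name Provider name (used in logs and provenance records).
#' @param evaluate `function(elements, xyz)` returning a single total energy
#'   in kcal/mol; `elements` a character vector, `xyz` an n x 3 matrix in
#'   Angstrom.
#' @return An object of class `energy_provider`.
#' @export
energy_provider <- function(name, evaluate) {
  stopifnot(is.character(name), is.function(evaluate))
  structure(list(name = name, evaluate = evaluate),
            class = "energy_provider")
}

#' Interaction-energy deltas from a single-point provider
#'
#' Computes `dE_sp = mean over frames of E(PL) - E(P) - E(L)` on identical
#' geometries (single-trajectory convention: the fragment geometries are
#' sliced out of the complex frame, never relaxed).
#'
#' @param provider An [energy_provider()].
#' @param complexes Named list; each element is one complex, itself a list of
#'   frames, each frame a list with `elements` (character), `xyz` (n x 3
#'   matrix, Angstrom) and `is_ligand` (logical, partitioning the atoms into
#'   ligand and protein).
#' @return data.frame `complex_id, dE_sp, n_frames` of class `delta_sp`.
#' @export
provider_deltas <- function(provider, complexes) {
  stopifnot(inherits(provider, "energy_provider"))
  rows <- lapply(names(complexes), function(id) {
    des <- vapply(seq_along(complexes[[id]]), function(fi) {
      fr <- complexes[[id]][[fi]]
      if (!is.logical(fr$is_ligand) || length(fr$is_ligand) != nrow(fr$xyz)) {
        mmp_stop("mmpbsar_integrity_error",
                 "complex %s frame %d: is_ligand does not partition the atoms",
                 id, fi)
      }
      e <- tryCatch({
        e_pl <- provider$evaluate(fr$elements, fr$xyz)
        e_p <- provider$evaluate(fr$elements[!fr$is_ligand],
                                 fr$xyz[!fr$is_ligand, , drop = FALSE])
        e_l <- provider$evaluate(fr$elements[fr$is_ligand],
                                 fr$xyz[fr$is_ligand, , drop = FALSE])
        e_pl - e_p - e_l
      }, error = function(err) {
        mmp_stop("mmpbsar_provider_error",
                 "provider '%s' failed on complex %s frame %d: %s",
                 provider$name, id, fi, conditionMessage(err))
      })
      e
    }, numeric(1))
    data.frame(complex_id = id, dE_sp = mean(des), n_frames = length(des),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delta_sp", "data.frame")
  out
}

#' Assert the provider contract on a test frame
#'
#' Checks determinism, atom-permutation invariance, and rigid-motion
#' (rotation + translation) invariance of an [energy_provider()] on a given
#' geometry.
#'
#' @param provider An [energy_provider()].
#' @param elements,xyz Test geometry.
#' @param tol Absolute tolerance (kcal/mol), default 1e-8.
#' @return `TRUE` invisibly; raises a contract error otherwise.
#' @export
check_provider <- function(provider, elements, xyz, tol = 1e-8) {
  e1 <- provider$evaluate(elements, xyz)
  e2 <- provider$evaluate(elements, xyz)
  if (!isTRUE(abs(e1 - e2) <= tol)) {
    mmp_stop("mmpbsar_contract_error", "provider '%s' is not deterministic",
             provider$name)
  }
  perm <- rev(seq_along(elements))
  e3 <- provider$evaluate(elements[perm], xyz[perm, , drop = FALSE])
  if (!isTRUE(abs(e1 - e3) <= tol)) {
    mmp_stop("mmpbsar_contract_error",
             "provider '%s' is not permutation invariant", provider$name)
  }
  th <- 0.7; ax <- c(1, 2, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz_r <- xyz %*% t(R)
  xyz_r <- sweep(xyz_r, 2, c(3.2, -1.5, 0.8), `+`)
  e4 <- provider$evaluate(elements, xyz_r)
  if (!isTRUE(abs(e1 - e4) <= tol)) {
    mmp_stop("mmpbsar_contract_error",
             "provider '%s' is not rigid-motion invariant", provider$name)
  }
  invisible(TRUE)
}
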