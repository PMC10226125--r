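## synthetic_data: seed-deterministic fixture generators -- sphere-cluster
## "molecules" with oracle-computable geometry, energy-term tables drawn from
## a known linear ground truth, and mock single-point energy providers.

#' Generate a connected sphere cluster
#'
#' Builds a synthetic "molecule" of overlapping atomic spheres: each new
#' sphere is placed at a fraction (`density`) of the sum of radii from a
#' randomly chosen existing sphere, which guarantees overlap with the
#' growing union. These clusters are the geometry fixtures whose surface
#' and volume the lattice oracle can compute.
#'
#' @param n_atoms Number of spheres (>= 1).
#' @param radius_range Radii are drawn uniformly from this range (Angstrom).
#' @param density Center separation as a fraction of the radius sum
#'   (0 < density < 1 gives overlap); default 0.8.
#' @param seed Integer seed; generation is reproducible.
#' @param allow_disconnected Place spheres uniformly in a box instead of
#'   growing a connected cluster.
#' @param padding Sampling-cell padding (Angstrom); default 6.4 (5 plus a
#'   water-probe radius).
#' @return A `mol_structure` with radii assigned.
#' @export
gen_cluster <- function(n_atoms, radius_range = c(1.2, 2.0), density = 0.8,
                        seed = 1L, allow_disconnected = FALSE,
                        padding = 6.4) {
  if (n_atoms < 1) mmp_stop("mmpbsar_domain_error", "n_atoms must be >= 1")
  if (density <= 0 || density >= 1.5) {
    mmp_stop("mmpbsar_domain_error", "density must be in (0, 1.5)")
  }
  with_substream(seed, 7L, {
    r <- runif(n_atoms, radius_range[1], radius_range[2])
    el <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
    pos <- matrix(0, n_atoms, 3)
    if (allow_disconnected) {
      half <- max(2, n_atoms^(1 / 3) * mean(radius_range) * 2)
      pos[] <- runif(3 * n_atoms, -half, half)
    } else if (n_atoms > 1) {
      for (k in 2:n_atoms) {
        placed <- FALSE
        for (try in seq_len(100)) {
          j <- sample.int(k - 1, 1)
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- pos[j, ] + density * (r[j] + r[k]) * u
          d <- sqrt(rowSums((pos[seq_len(k - 1), , drop = FALSE] -
                               matrix(cand, k - 1, 3, byrow = TRUE))^2))
          if (all(d > 0.4 * (r[seq_len(k - 1)] + r[k]))) {
            pos[k, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed) {
          mmp_stop("mmpbsar_generation_error",
                   "could not place sphere %d after 100 attempts", k)
        }
      }
    }
    atoms <- data.frame(element = el, x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], radius = r, stringsAsFactors = FALSE)
    new_structure(atoms, make_cell(atoms, padding),
                  source = sprintf("gen_cluster(seed=%d)", seed))
  })
}

#' Specification for a synthetic rescoring study
#'
#' Defines the statistical ground truth an emulated protein-ligand study is
#' drawn from: per-complex delta terms are independent normals with the
#' stated means/SDs (volume differences are drawn correlated with the area
#' differences, as they are in real end-state data, but not collinearly),
#' and the experimental affinity is the chosen regime's formula at the true
#' coefficients and true dielectric pair plus Gaussian noise.
#'
#' @param n_complexes Number of complexes (default 54).
#' @param regime,coefficients True estimator regime and coefficient vector.
#' @param pair True [dielectric_pair()] baked into the experimental values.
#' @param noise_sd Gaussian noise SD on the experimental values (kcal/mol).
#' @param n_frames Frames per complex in the per-frame table; frame jitter
#'   sums to zero exactly, so frame averaging recovers the drawn deltas at
#'   machine precision.
#' @param term_means,term_sds Named means/SDs of the delta terms (kcal/mol;
#'   dSASA in A^2).
#' @param sav_coupling_sd SD of the normal offset between dSAV and dSASA
#'   (A^3 vs A^2 magnitudes are comparable for these differences).
#' @param seed Integer seed.
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(n_complexes = 54, regime = "spt",
                       coefficients = c(gamma = 0.1394, p = 0.0163, b = 0),
                       pair = dielectric_pair(1, 1),
                       noise_sd = 1, n_frames = 5,
                       term_means = c(dE_vdW = -50, dE_ele = -30,
                                      dG_PB = 45, dSASA = -750,
                                      dE_disp = -40, dE_sp = -80),
                       term_sds = c(dE_vdW = 10, dE_ele = 15,
                                    dG_PB = 15, dSASA = 150,
                                    dE_disp = 8, dE_sp = 20),
                       sav_coupling_sd = 80, seed = 1L) {
  if (noise_sd < 0 || any(term_sds < 0)) {
    mmp_stop("mmpbsar_domain_error", "noise and term SDs must be >= 0")
  }
  structure(list(n_complexes = n_complexes, regime = regime,
                 coefficients = coefficients, pair = pair,
                 noise_sd = noise_sd, n_frames = n_frames,
                 term_means = term_means, term_sds = term_sds,
                 sav_coupling_sd = sav_coupling_sd, seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate a synthetic rescoring study
#'
#' Draws delta terms, builds experimental affinities from the true model,
#' and expands the deltas into a per-frame, per-species table whose
#' zero-sum frame jitter makes [average_deltas()] exact.
#'
#' @param spec A [study_spec()].
#' @return Object of class `synthetic_study`: `delta` (`delta_terms`),
#'   `frames` (`frame_terms`), `exp` (complex_id, dG_exp), and `truth`
#'   (regime, coefficients, dielectric pair, noise SD, seed).
#' @export
gen_study <- function(spec = study_spec()) {
  stopifnot(inherits(spec, "study_spec"))
  n <- spec$n_complexes
  tm <- spec$term_means; ts <- spec$term_sds
  delta <- with_substream(spec$seed, 11L, {
    d <- data.frame(
      complex_id = sprintf("cpx%03d", seq_len(n)),
      dE_vdW = rnorm(n, tm["dE_vdW"], ts["dE_vdW"]),
      dE_ele = rnorm(n, tm["dE_ele"], ts["dE_ele"]),
      dG_PB = rnorm(n, tm["dG_PB"], ts["dG_PB"]),
      dSASA = rnorm(n, tm["dSASA"], ts["dSASA"]),
      stringsAsFactors = FALSE
    )
    d$dSAV <- d$dSASA + rnorm(n, 0, spec$sav_coupling_sd)
    d$dE_disp <- rnorm(n, tm["dE_disp"], ts["dE_disp"])
    d$dE_sp <- rnorm(n, tm["dE_sp"], ts["dE_sp"])
    d$N_rot <- sample.int(13, n, replace = TRUE) - 1L
    d$n_frames <- spec$n_frames
    delta_terms(d)
  })
  model <- model_spec(spec$regime, spec$coefficients)
  dg_true <- score(delta, model, spec$pair)$dG_pred
  dg_exp <- with_substream(spec$seed, 13L,
                           dg_true + rnorm(n, 0, spec$noise_sd))
  frames <- with_substream(spec$seed, 17L, {
    nf <- spec$n_frames
    base <- c(E_vdW = -450, E_ele = -1800, G_PB = 2400, SASA = 11000,
              SAV = 52000, E_disp = -300, E_sp = -9000)
    rows <- lapply(seq_len(n), function(ci) {
      per_term <- lapply(c(TERM_COLS, OPT_TERM_COLS), function(tc) {
        jit <- if (nf > 1) { j <- rnorm(nf, 0, 1); j - mean(j) } else 0
        p_val <- base[[tc]] * runif(1, 0.9, 1.1)
        l_val <- base[[tc]] * 0.02 * runif(1, 0.9, 1.1)
        dv <- delta[[paste0("d", tc)]][ci]
        data.frame(PL = p_val + l_val + dv + jit,
                   P = rep(p_val, nf), L = rep(l_val, nf))
      })
      names(per_term) <- c(TERM_COLS, OPT_TERM_COLS)
      do.call(rbind, lapply(SPECIES, function(sp) {
        out <- data.frame(complex_id = delta$complex_id[ci],
                          frame = seq_len(nf), species = sp,
                          stringsAsFactors = FALSE)
        for (tc in names(per_term)) out[[tc]] <- per_term[[tc]][[sp]]
        out
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("frame_terms", "data.frame")
    out
  })
  structure(list(
    delta = delta, frames = frames,
    exp = data.frame(complex_id = delta$complex_id, dG_exp = dg_exp,
                     stringsAsFactors = FALSE),
    truth = list(regime = spec$regime,
                 coefficients = as.list(spec$coefficients),
                 eps_ele = spec$pair$eps_ele, eps_pb = spec$pair$eps_pb,
                 noise_sd = spec$noise_sd, seed = spec$seed,
                 dG_true = dg_true)
  ), class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Emits `terms.csv` (wide per-frame table readable by
#' [read_terms_table()]), `exp.csv` (experimental affinities), `nrot.json`
#' (rotatable-bond sidecar) and `truth.json` (the generating ground truth).
#'
#' @param study A [gen_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- study$frames
  wide <- NULL
  for (sp in SPECIES) {
    sub <- fr[fr$species == sp, , drop = FALSE]
    cols <- intersect(c(TERM_COLS, OPT_TERM_COLS), names(sub))
    block <- sub[, cols, drop = FALSE]
    names(block) <- paste(cols, sp, sep = "_")
    wide <- if (is.null(wide)) {
      cbind(sub[, c("complex_id", "frame")], block)
    } else cbind(wide, block)
  }
  utils::write.table(wide, file.path(dir, "terms.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(study$exp, file.path(dir, "exp.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(study$delta$N_rot), study$delta$complex_id),
    file.path(dir, "nrot.json"), auto_unbox = TRUE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Mock single-point energy providers
#'
#' Closed-form pairwise potentials satisfying the full [energy_provider()]
#' contract, standing in for a machine-learned potential in tests and
#' examples. `pairwise_lj_like` is `eps * ((rmin/r)^12 - 2 (rmin/r)^6)`
#' summed over pairs (well depth `-eps` at `r = rmin`); `harmonic` is
#' `0.5 k (r - r0)^2` for pairs closer than `r0`. Both are deterministic
#' and invariant under atom permutation and rigid motion, and their
#' cross-fragment interaction energy equals an independent brute-force
#' pair sum (the attribute `pair_energy` exposes the pair function for
#' exactly that check).
#'
#' @param kind `"pairwise_lj_like"` or `"harmonic"`.
#' @param eps,rmin Well depth (kcal/mol) and minimum-energy distance (A)
#'   for the Lennard-Jones-like form.
#' @param k,r0 Force constant (kcal/mol/A^2) and contact distance (A) for
#'   the harmonic form.
#' @return An [energy_provider()] with attribute `pair_energy`.
#' @export
mock_provider <- function(kind = c("pairwise_lj_like", "harmonic"),
                          eps = 0.2, rmin = 3.5, k = 1.0, r0 = 4.0) {
  kind <- match.arg(kind)
  pair_energy <- if (kind == "pairwise_lj_like") {
    function(r) eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  } else {
    function(r) ifelse(r < r0, 0.5 * k * (r - r0)^2, 0)
  }
  evaluate <- function(elements, xyz) {
    n <- nrow(xyz)
    if (n < 2) return(0)
    d <- stats::dist(xyz)
    sum(pair_energy(as.vector(d)))
  }
  p <- energy_provider(paste0("mock_", kind), evaluate)
  attr(p, "pair_energy") <- pair_energy
  p
}
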