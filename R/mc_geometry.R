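## mc_geometry: Monte-Carlo probe-sampling estimators for accessible surface
## area (ASA) and the two accessible-volume definitions (PCAV, POAV), plus a
## deterministic lattice oracle used to validate them.
##
## Conventions: a probe of radius r_p is "probe-centered accessible" at y iff
## |y - a_i| >= r_i + r_p for every atom i. PCAV is the volume of that locus
## inside the cell; POAV additionally includes every point outside the vdW
## spheres that lies within r_p of an accessible probe center. Molecular
## volumes are cell volume minus pore volume.

#' Probe specification for Monte-Carlo geometry estimators
#'
#' @param probe_radius Spherical probe radius in Angstrom; 1.4 (a water
#'   molecule) by default. May be 0 for the vdW limit.
#' @param n_samples Total number of Monte-Carlo samples (split evenly across
#'   atoms for area estimation; drawn in the cell for volume estimation).
#' @param seed Integer seed; every estimate is bit-reproducible for a fixed
#'   (structure, probe, seed) triple.
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(probe_radius = 1.4, n_samples = 1e5, seed = 1L) {
  if (!is.finite(probe_radius) || probe_radius < 0) {
    mmp_stop("mmpbsar_domain_error", "probe_radius must be >= 0")
  }
  n_samples <- as.double(n_samples)
  if (!is.finite(n_samples) || n_samples < 1) {
    mmp_stop("mmpbsar_domain_error", "n_samples must be >= 1")
  }
  structure(list(probe_radius = probe_radius,
                 n_samples = floor(n_samples),
                 seed = as.integer(seed)),
            class = "probe_spec")
}

mc_estimate <- function(value, stderr, n, seed, quantity, units) {
  structure(list(value = value, stderr = stderr, n_samples = n, seed = seed,
                 quantity = quantity, units = units),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f +/- %.4f %s  (n = %g, seed = %d)\n",
              x$quantity, x$value, x$stderr, x$units, x$n_samples, x$seed))
  invisible(x)
}

atom_matrix <- function(structure) {
  a <- structure$atoms
  if (any(a$radius <= 0)) {
    mmp_stop("mmpbsar_domain_error",
             "structure has unassigned radii; call assign_radii() first")
  }
  list(xyz = cbind(a$x, a$y, a$z), r = a$radius)
}

## min over atoms of (|p - a_i| - r_i) for an m x 3 point matrix;
## signed clearance to the vdW surface (negative inside an atom)
vdw_clearance <- function(pts, xyz, r) {
  g <- rep(Inf, nrow(pts))
  for (i in seq_along(r)) {
    d <- sqrt((pts[, 1] - xyz[i, 1])^2 +
              (pts[, 2] - xyz[i, 2])^2 +
              (pts[, 3] - xyz[i, 3])^2) - r[i]
    g <- pmin(g, d)
  }
  g
}

#' Monte-Carlo accessible surface area
#'
#' Estimates the probe-accessible surface area by stratified sampling: equal
#' numbers of points are drawn uniformly on each atom's probe-inflated sphere
#' (radius `r_i + r_p`) and a point is accessible iff it lies outside every
#' other atom's probe-inflated sphere. The estimator is
#' `sum_i 4*pi*(r_i+r_p)^2 * accessible_fraction_i`; the standard error
#' combines per-atom binomial variances. Per-atom RNG substreams are derived
#' from `(seed, atom index)`, so the result is independent of atom iteration
#' order and of how work is batched.
#'
#' @param structure A `mol_structure` with radii assigned.
#' @param probe A [probe_spec()].
#' @return An `mc_estimate` (value and standard error in Angstrom^2).
#' @export
mc_asa <- function(structure, probe = probe_spec()) {
  am <- atom_matrix(structure)
  xyz <- am$xyz; r <- am$r
  rp <- probe$probe_radius
  n_at <- length(r)
  m <- ceiling(probe$n_samples / n_at)
  Ri <- r + rp
  area <- 0
  vr <- 0
  for (i in seq_len(n_at)) {
    sph_area <- 4 * pi * Ri[i]^2
    ## neighbours whose inflated sphere can intersect atom i's inflated sphere
    d_cent <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d_cent < Ri + Ri[i] & seq_len(n_at) != i)
    if (length(nb) == 0) {            # unoccluded sphere: exact, no sampling
      area <- area + sph_area
      next
    }
    acc <- with_substream(probe$seed, i, {
      z <- runif(m, -1, 1)
      phi <- runif(m, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - z^2))
      px <- xyz[i, 1] + Ri[i] * s * cos(phi)
      py <- xyz[i, 2] + Ri[i] * s * sin(phi)
      pz <- xyz[i, 3] + Ri[i] * z
      ok <- rep(TRUE, m)
      for (j in nb) {
        d2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
        ok <- ok & d2 >= Ri[j]^2
      }
      ok
    })
    p <- mean(acc)
    area <- area + sph_area * p
    vr <- vr + sph_area^2 * p * (1 - p) / m
  }
  mc_estimate(area, sqrt(vr), m * n_at, probe$seed,
              "accessible surface area", "A^2")
}

## 32 quasi-random directions/radii filling the unit ball (Halton 2,3,5),
## used as candidate probe centers in the POAV membership test
halton_ball <- function(k = 32L) {
  halton <- function(n, base) {
    vapply(seq_len(n), function(i) {
      f <- 1; x <- 0
      while (i > 0) { f <- f / base; x <- x + f * (i %% base); i <- i %/% base }
      x
    }, numeric(1))
  }
  u1 <- halton(k, 2); u2 <- halton(k, 3); u3 <- halton(k, 5)
  z <- 2 * u1 - 1
  phi <- 2 * pi * u2
  rad <- u3^(1 / 3)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(rad * s * cos(phi), rad * s * sin(phi), rad * z)
}

## clearance together with the one (or two) nearest atoms, for the analytic
## escape directions of the POAV membership test
vdw_clearance_nearest <- function(pts, xyz, r) {
  n <- nrow(pts)
  g1 <- rep(Inf, n); g2 <- rep(Inf, n)
  j1 <- rep(1L, n); j2 <- rep(1L, n)
  for (i in seq_along(r)) {
    d <- sqrt((pts[, 1] - xyz[i, 1])^2 +
              (pts[, 2] - xyz[i, 2])^2 +
              (pts[, 3] - xyz[i, 3])^2) - r[i]
    better1 <- d < g1
    g2[better1] <- g1[better1]; j2[better1] <- j1[better1]
    g1[better1] <- d[better1]; j1[better1] <- i
    better2 <- !better1 & d < g2
    g2[better2] <- d[better2]; j2[better2] <- i
  }
  list(g = g1, j1 = j1, j2 = j2)
}

unit_rows <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v / nrm
}

## POAV membership for border points (outside vdW, clearance < r_p): x is
## probe-occupiable iff max over the ball B(x, r_p) of the vdW clearance
## reaches r_p (i.e. some allowed probe center lies within the probe radius).
## The maximum is located by analytic escape candidates (away from the
## nearest atom; along the seam bisector of the two nearest atoms), K
## quasi-random starts, and a projected supergradient ascent of the
## clearance over the ball from the best start. Exact for single bodies and
## convex pockets; for deep necks the ascent resolves the seam regions the
## bare candidate set misses.
poav_border_occupiable <- function(pts, xyz, r, rp, k = 32L, ascent_iter = 24L) {
  n <- nrow(pts)
  if (n == 0) return(logical(0))
  fbest <- rep(-Inf, n)
  ybest <- pts
  consider <- function(cand, alive) {
    f <- vdw_clearance(cand, xyz, r)
    upd <- f > fbest[alive]
    ai <- alive[upd]
    fbest[ai] <<- f[upd]
    ybest[ai, ] <<- cand[upd, , drop = FALSE]
  }
  alive <- seq_len(n)

  nearest <- vdw_clearance_nearest(pts, xyz, r)
  ## escape away from the nearest atom (exact for a single body)
  u1 <- unit_rows(pts - xyz[nearest$j1, , drop = FALSE])
  consider(pts + rp * u1, alive)
  ## escape along the bisector of the two nearest atoms (seam geometry)
  u2 <- unit_rows(pts - xyz[nearest$j2, , drop = FALSE])
  consider(pts + rp * unit_rows(u1 + u2), alive)

  alive <- which(fbest < rp)
  if (length(alive) > 0) {
    hb <- rp * halton_ball(k)
    for (kk in seq_len(nrow(hb))) {
      cand <- pts[alive, , drop = FALSE]
      cand[, 1] <- cand[, 1] + hb[kk, 1]
      cand[, 2] <- cand[, 2] + hb[kk, 2]
      cand[, 3] <- cand[, 3] + hb[kk, 3]
      consider(cand, alive)
    }
    alive <- which(fbest < rp)
  }

  ## projected supergradient ascent of the clearance over B(x, r_p),
  ## seeded at the best candidate; diminishing cyclic step sizes cope with
  ## the nonsmooth min over atoms at seams
  if (length(alive) > 0) {
    steps <- rep(rp * c(0.30, 0.15, 0.08, 0.04), length.out = ascent_iter)
    y <- ybest[alive, , drop = FALSE]
    x0 <- pts[alive, , drop = FALSE]
    for (it in seq_len(ascent_iter)) {
      nr <- vdw_clearance_nearest(y, xyz, r)
      y <- y + steps[it] * unit_rows(y - xyz[nr$j1, , drop = FALSE])
      off <- y - x0
      d <- sqrt(rowSums(off^2))
      over <- d > rp
      if (any(over)) {
        y[over, ] <- x0[over, , drop = FALSE] +
          off[over, , drop = FALSE] * (rp / d[over])
      }
      consider(y, alive)
      keep <- fbest[alive] < rp
      if (!any(keep)) break
      if (any(!keep)) {
        alive <- alive[keep]
        y <- y[keep, , drop = FALSE]
        x0 <- x0[keep, , drop = FALSE]
      }
    }
  }
  fbest >= rp
}

## shared sampling pass over the cell: classifies each sample point as
## inside-vdW / PCAV-molecular / POAV-molecular, so the volume ordering
## vdW <= POAV <= PCAV holds sample-by-sample
sample_cell_counts <- function(structure, probe, chunk = 50000L) {
  check_cell_containment(structure, probe$probe_radius)
  am <- atom_matrix(structure)
  rp <- probe$probe_radius
  lo <- structure$cell$min
  span <- structure$cell$max - structure$cell$min
  n <- probe$n_samples
  counts <- c(vdw = 0, pcav_mol = 0, poav_mol = 0)
  with_substream(probe$seed, 0L, {
    left <- n
    while (left > 0) {
      m <- min(chunk, left)
      u <- matrix(runif(3 * m), ncol = 3)
      pts <- sweep(u, 2, span, `*`)
      pts <- sweep(pts, 2, lo, `+`)
      g <- vdw_clearance(pts, am$xyz, am$r)
      in_vdw <- g < 0
      in_pcav <- g < rp
      border <- which(!in_vdw & in_pcav)
      occ <- rep(FALSE, m)
      occ[g >= rp] <- TRUE
      if (length(border) > 0) {
        occ[border] <- poav_border_occupiable(pts[border, , drop = FALSE],
                                              am$xyz, am$r, rp)
      }
      counts["vdw"] <- counts["vdw"] + sum(in_vdw)
      counts["pcav_mol"] <- counts["pcav_mol"] + sum(in_pcav)
      counts["poav_mol"] <- counts["poav_mol"] + sum(!occ)
      left <- left - m
    }
  })
  list(counts = counts, n = n, cell_volume = prod(span))
}

#' Monte-Carlo pore volume
#'
#' Estimates the accessible ("pore") volume of the sampling cell by uniform
#' point sampling. In `probe_centered` mode a point counts iff its distance
#' to every atom center is at least `r_i + r_p` (the locus of allowed probe
#' centers, PCAV). In `probe_occupiable` mode a point counts iff it lies
#' outside every vdW sphere and within `r_p` of some probe-centered
#' accessible location (POAV). Interior voids count as pore: no reachability
#' analysis is performed.
#'
#' @inheritParams mc_asa
#' @param mode `"probe_centered"` or `"probe_occupiable"`.
#' @return An `mc_estimate` (Angstrom^3).
#' @export
mc_pore_volume <- function(structure, probe = probe_spec(),
                           mode = c("probe_centered", "probe_occupiable")) {
  mode <- match.arg(mode)
  sc <- sample_cell_counts(structure, probe)
  mol <- if (mode == "probe_centered") sc$counts[["pcav_mol"]]
         else sc$counts[["poav_mol"]]
  phat <- 1 - mol / sc$n
  mc_estimate(sc$cell_volume * phat,
              sc$cell_volume * sqrt(phat * (1 - phat) / sc$n),
              sc$n, probe$seed, sprintf("pore volume (%s)", mode), "A^3")
}

#' Molecular volume from pore subtraction
#'
#' Cell volume minus the Monte-Carlo pore volume. With `probe_centered` this
#' is the PCAV molecular volume (the analogue of the solvent-accessible
#' volume); with `probe_occupiable`, the POAV molecular volume (which
#' excludes the shell over-counted by the probe radius). The subtraction
#' makes the result independent of the cell size.
#'
#' @inheritParams mc_pore_volume
#' @return An `mc_estimate` (Angstrom^3).
#' @export
molecular_volume <- function(structure, probe = probe_spec(),
                             mode = c("probe_centered", "probe_occupiable")) {
  mode <- match.arg(mode)
  pore <- mc_pore_volume(structure, probe, mode)
  cell_volume <- prod(structure$cell$max - structure$cell$min)
  mc_estimate(cell_volume - pore$value,
              pore$stderr, pore$n_samples, probe$seed,
              sprintf("molecular volume (%s)", mode), "A^3")
}

#' All Monte-Carlo surface/volume quantities in one pass
#'
#' Runs the area estimator and a single shared volume-classification pass,
#' returning ASA, the PCAV and POAV molecular volumes and the vdW volume
#' with their standard errors. Because the volume quantities share one
#' sample, the ordering `vdw <= POAV <= PCAV` holds exactly for every seed.
#'
#' @inheritParams mc_asa
#' @return An object of class `surfvol_result`.
#' @export
surfvol <- function(structure, probe = probe_spec()) {
  asa <- mc_asa(structure, probe)
  sc <- sample_cell_counts(structure, probe)
  v <- prod(structure$cell$max - structure$cell$min)
  est <- function(count) {
    p <- count / sc$n
    c(value = v * p, stderr = v * sqrt(p * (1 - p) / sc$n))
  }
  vdw <- est(sc$counts[["vdw"]])
  pcav <- est(sc$counts[["pcav_mol"]])
  poav <- est(sc$counts[["poav_mol"]])
  structure(list(
    asa = asa$value, asa_stderr = asa$stderr,
    pcav_molecular_volume = pcav[["value"]],
    pcav_stderr = pcav[["stderr"]],
    poav_molecular_volume = poav[["value"]],
    poav_stderr = poav[["stderr"]],
    vdw_volume = vdw[["value"]], vdw_stderr = vdw[["stderr"]],
    n_samples = sc$n, seed = probe$seed,
    probe_radius = probe$probe_radius, method = "monte-carlo"
  ), class = "surfvol_result")
}

#' @export
print.surfvol_result <- function(x, ...) {
  cat(sprintf("surface/volume result (%s, probe %.2f A, n = %g)\n",
              x$method, x$probe_radius, x$n_samples))
  cat(sprintf("  ASA  : %10.3f +/- %.3f A^2\n", x$asa, x$asa_stderr))
  cat(sprintf("  PCAV : %10.3f +/- %.3f A^3 (molecular volume)\n",
              x$pcav_molecular_volume, x$pcav_stderr))
  cat(sprintf("  POAV : %10.3f +/- %.3f A^3 (molecular volume)\n",
              x$poav_molecular_volume, x$poav_stderr))
  cat(sprintf("  vdW  : %10.3f +/- %.3f A^3\n", x$vdw_volume, x$vdw_stderr))
  invisible(x)
}

## quasi-uniform Fibonacci point set on the unit sphere (deterministic)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Deterministic lattice oracle for surface and volume
#'
#' Validation reference for the Monte-Carlo estimators: voxel-center
#' inclusion counting on a regular lattice for the volumes (the POAV
#' membership uses an exact Euclidean distance transform from the
#' probe-centered accessible set, so it is free of the local-candidate
#' approximation), and fixed spherical quadrature for the area. Intended for
#' tests; cost grows as `resolution^-3`.
#'
#' @inheritParams mc_asa
#' @param resolution Lattice spacing in Angstrom (e.g. 0.05 for tight
#'   reference values).
#' @return A `surfvol_result` with zero standard errors.
#' @export
grid_oracle <- function(structure, probe = probe_spec(), resolution = 0.05) {
  if (!is.finite(resolution) || resolution <= 0) {
    mmp_stop("mmpbsar_domain_error", "resolution must be > 0")
  }
  am <- atom_matrix(structure)
  rp <- probe$probe_radius
  ## lattice over the inflated bounding box, padded so every accessible point
  ## within r_p of a counted voxel lies on the lattice
  pad <- rp + 2 * resolution
  lo <- apply(am$xyz - (am$r + rp), 2, min) - pad
  hi <- apply(am$xyz + (am$r + rp), 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / resolution))
  res <- grid_oracle_counts(am$xyz, am$r, rp, lo, dims, resolution)
  if (any(res$atom_vdw_voxels < 10)) {
    mmp_stop("mmpbsar_resolution_error",
             "resolution %.3f too coarse: %d atom(s) contain < 10 lattice points",
             resolution, sum(res$atom_vdw_voxels < 10))
  }
  vox <- resolution^3
  ## quadrature ASA: fixed Fibonacci point sets on each inflated sphere
  asa <- 0
  Ri <- am$r + rp
  for (i in seq_along(Ri)) {
    n_pts <- min(100000L, max(256L, ceiling(4 * pi * Ri[i]^2 / resolution^2)))
    pts <- fibonacci_sphere(n_pts) * Ri[i]
    pts <- sweep(pts, 2, am$xyz[i, ], `+`)
    ok <- rep(TRUE, n_pts)
    for (j in seq_along(Ri)[-i]) {
      d2 <- (pts[, 1] - am$xyz[j, 1])^2 + (pts[, 2] - am$xyz[j, 2])^2 +
            (pts[, 3] - am$xyz[j, 3])^2
      ok <- ok & d2 >= Ri[j]^2
    }
    asa <- asa + 4 * pi * Ri[i]^2 * mean(ok)
  }
  structure(list(
    asa = asa, asa_stderr = 0,
    pcav_molecular_volume = res$n_pcav_mol * vox, pcav_stderr = 0,
    poav_molecular_volume = res$n_poav_mol * vox, poav_stderr = 0,
    vdw_volume = res$n_vdw * vox, vdw_stderr = 0,
    n_samples = prod(dims), seed = NA_integer_,
    probe_radius = rp, method = sprintf("grid oracle (%.3f A)", resolution)
  ), class = "surfvol_result")
}
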