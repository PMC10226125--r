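# Fixtures built in code: sphere structures, tiny PDB files, random delta
# tables. Everything is deterministic given the seeds passed in.

sphere_structure <- function(centers, radii, elements = NULL, padding = 6.4) {
  centers <- matrix(centers, ncol = 3)
  atoms <- data.frame(
    element = elements %||% rep("C", nrow(centers)),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radii, stringsAsFactors = FALSE
  )
  mmpbsar:::new_structure(atoms, mmpbsar:::make_cell(atoms, padding))
}

single_sphere <- function(r = 1.7, padding = 10) {
  sphere_structure(c(0, 0, 0), r, padding = padding)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_mini_pdb <- function(path, n = 3) {
  fmt <- "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  el <- c("N", "C", "O", "C", "S")[seq_len(n)]
  lines <- vapply(seq_len(n), function(i) {
    sprintf(fmt, i, el[i], i, 1.5 * i, -0.8 * i, 0.25 * i, el[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# random but reproducible delta table with every term populated
rand_delta <- function(n = 10, seed = 99) {
  mmpbsar:::with_substream(seed, 0L, {
    delta_terms(data.frame(
      complex_id = sprintf("c%02d", seq_len(n)),
      dE_vdW = rnorm(n, -50, 10), dE_ele = rnorm(n, -30, 15),
      dG_PB = rnorm(n, 45, 15), dSASA = rnorm(n, -750, 150),
      dSAV = rnorm(n, -750, 150), dE_disp = rnorm(n, -40, 8),
      dE_sp = rnorm(n, -80, 20),
      N_rot = sample.int(13, n, replace = TRUE) - 1L,
      stringsAsFactors = FALSE
    ))
  })
}

# long-dialect frame terms for 2 complexes x n_frames, built by hand
mini_frames <- function(n_frames = 3) {
  grid <- expand.grid(complex_id = c("cA", "cB"),
                      frame = seq_len(n_frames),
                      species = c("PL", "P", "L"),
                      stringsAsFactors = FALSE)
  base <- c(PL = -90, P = -60, L = -20)
  for (tc in c("E_vdW", "E_ele", "G_PB", "SASA", "SAV")) {
    grid[[tc]] <- base[grid$species] +
      10 * as.integer(factor(grid$complex_id)) + 0.5 * grid$frame +
      match(tc, c("E_vdW", "E_ele", "G_PB", "SASA", "SAV"))
  }
  class(grid) <- c("frame_terms", "data.frame")
  grid
}

write_frames_csv <- function(frames, path, dialect = "long") {
  if (dialect == "long") {
    utils::write.table(frames, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else {
    wide <- NULL
    for (sp in c("PL", "P", "L")) {
      sub <- frames[frames$species == sp, , drop = FALSE]
      cols <- setdiff(names(sub), c("complex_id", "frame", "species"))
      block <- sub[, cols, drop = FALSE]
      names(block) <- paste(cols, sp, sep = "_")
      wide <- if (is.null(wide)) cbind(sub[, c("complex_id", "frame")], block)
              else cbind(wide, block)
    }
    utils::write.table(wide, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  path
}
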