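test_that("long tables read one FrameTerms row per (complex, frame, species)", {
  fr <- mini_frames(n_frames = 3)
  path <- write_frames_csv(fr, tempfile(fileext = ".csv"), "long")
  got <- read_terms_table(path, dialect = "long")
  expect_equal(nrow(got), 2 * 3 * 3)
  expect_setequal(attr(got, "missing_optional"), c("E_disp", "E_sp"))
})

test_that("long and wide dialects yield identical deltas", {
  fr <- mini_frames(n_frames = 3)
  p_long <- write_frames_csv(fr, tempfile(fileext = ".csv"), "long")
  p_wide <- write_frames_csv(fr, tempfile(fileext = ".csv"), "wide")
  d_long <- average_deltas(read_terms_table(p_long, "long"))
  d_wide <- average_deltas(read_terms_table(p_wide, "wide"))
  expect_equal(d_long, d_wide)
})

test_that("schema and parse violations raise naming errors", {
  fr <- mini_frames()
  fr$G_PB <- NULL
  path <- write_frames_csv(fr, tempfile(fileext = ".csv"), "long")
  err <- expect_error(read_terms_table(path, "long"),
                      class = "mmpbsar_schema_error")
  expect_match(conditionMessage(err), "G_PB")

  fr2 <- mini_frames()
  fr2$E_vdW <- as.character(fr2$E_vdW)
  fr2$E_vdW[4] <- "oops"
  path2 <- write_frames_csv(fr2, tempfile(fileext = ".csv"), "long")
  err2 <- expect_error(read_terms_table(path2, "long"),
                       class = "mmpbsar_parse_error")
  expect_match(conditionMessage(err2), "E_vdW")
})

test_that("frame averaging computes PL - P - L means and standard errors", {
  fr <- data.frame(
    complex_id = "c1", frame = 1,
    species = c("PL", "P", "L"),
    E_vdW = c(-55, -40, -8), E_ele = c(-50, -30, -10),
    G_PB = c(70, 20, 10), SASA = c(9000, 8500, 1200),
    SAV = c(40000, 37000, 3800), stringsAsFactors = FALSE
  )
  class(fr) <- c("frame_terms", "data.frame")
  d <- average_deltas(fr)
  expect_equal(d$dE_ele, -10)
  expect_equal(d$se_dE_ele, 0)

  fr2 <- rbind(fr, within(fr, { frame <- 2; E_ele <- E_ele + c(-2, 0, 0) }))
  class(fr2) <- c("frame_terms", "data.frame")
  d2 <- average_deltas(fr2)
  expect_equal(d2$dE_ele, -11)
  expect_equal(d2$se_dE_ele, sd(c(-10, -12)) / sqrt(2))
  expect_equal(d2$n_frames, 2)
})

test_that("incomplete species triples are an integrity error", {
  fr <- mini_frames()
  fr <- fr[!(fr$complex_id == "cB" & fr$species == "L" & fr$frame == 2), ]
  err <- expect_error(average_deltas(fr), class = "mmpbsar_integrity_error")
  expect_match(conditionMessage(err), "cB")
})

test_that("averaging is linear in frame concatenation", {
  fr1 <- mini_frames(n_frames = 2)
  fr2 <- mini_frames(n_frames = 5)
  fr2$frame <- fr2$frame + 2
  fr2$E_vdW <- fr2$E_vdW * 1.11   # make the two sets differ
  both <- rbind(fr1, fr2)
  class(both) <- c("frame_terms", "data.frame")
  d1 <- average_deltas(fr1); d2 <- average_deltas(fr2)
  dall <- average_deltas(both)
  expect_equal(dall$dE_vdW, (2 * d1$dE_vdW + 5 * d2$dE_vdW) / 7,
               tolerance = 1e-12)
})

## atoms on a jittered lattice: realistic >= 2 A separations keep the r^-12
## terms benign so the PL - P - L cancellation is exact to near machine level
make_frame <- function(n_p = 3, n_l = 2, gap = 4) {
  n <- n_p + n_l
  lattice <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 3
  xyz <- lattice[seq_len(n), ] + matrix(runif(3 * n, -0.4, 0.4), ncol = 3)
  xyz[seq_len(n_l) + n_p, 1] <- xyz[seq_len(n_l) + n_p, 1] + gap
  list(elements = rep(c("C", "O"), length.out = n),
       xyz = unname(xyz),
       is_ligand = rep(c(FALSE, TRUE), c(n_p, n_l)))
}

test_that("provider deltas equal the brute-force cross-pair sum", {
  set.seed(31)
  prov <- mock_provider("pairwise_lj_like")
  pe <- attr(prov, "pair_energy")
  fr <- make_frame()
  brute <- 0
  for (i in which(!fr$is_ligand)) {
    for (j in which(fr$is_ligand)) {
      brute <- brute + pe(sqrt(sum((fr$xyz[i, ] - fr$xyz[j, ])^2)))
    }
  }
  d <- provider_deltas(prov, list(cx = list(fr)))
  expect_equal(d$dE_sp, brute, tolerance = 1e-8)
})

test_that("infinitely separated fragments have zero interaction energy", {
  prov <- mock_provider("pairwise_lj_like")
  fr <- make_frame(gap = 1e6)
  d <- provider_deltas(prov, list(cx = list(fr)))
  expect_equal(d$dE_sp, 0, tolerance = 1e-10)
  # harmonic form is zero beyond its contact distance
  d2 <- provider_deltas(mock_provider("harmonic"), list(cx = list(fr)))
  expect_equal(d2$dE_sp, 0, tolerance = 1e-12)
})

test_that("interaction energy is invariant under rigid motion of the frame", {
  set.seed(32)
  prov <- mock_provider("pairwise_lj_like")
  fr <- make_frame()
  th <- 1.1; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                         3, 3)
  fr_rot <- fr
  fr_rot$xyz <- sweep(fr$xyz %*% R, 2, c(5, -3, 2), `+`)
  d1 <- provider_deltas(prov, list(cx = list(fr)))
  d2 <- provider_deltas(prov, list(cx = list(fr_rot)))
  expect_equal(d1$dE_sp, d2$dE_sp, tolerance = 1e-8)
})

test_that("both mock providers satisfy the full provider contract", {
  set.seed(33)
  fr <- make_frame()
  for (kind in c("pairwise_lj_like", "harmonic")) {
    expect_true(check_provider(mock_provider(kind), fr$elements, fr$xyz))
  }
})

test_that("provider failures propagate with the frame id", {
  boom <- energy_provider("boom", function(elements, xyz) stop("no"))
  fr <- make_frame()
  err <- expect_error(provider_deltas(boom, list(cx7 = list(fr))),
                      class = "mmpbsar_provider_error")
  expect_match(conditionMessage(err), "cx7")
})
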