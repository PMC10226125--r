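test_that("one-term nonpolar model reproduces textbook arithmetic", {
  expect_equal(gnp_one_term(1000, 0.00542, 0.92), 6.34)
  expect_equal(gnp_one_term(0, 0.00542, 0.92), 0.92)
  expect_equal(gnp_one_term(-800, 0.0072, 0), -5.76)
})

test_that("SPT model combines area and volume and reduces to one-term", {
  expect_equal(gnp_spt(-800, -800, 0.1394, 0.0163, 0), -124.56)
  x <- c(-900, -650)
  expect_equal(gnp_spt(x, x * 1.1, 0.0072, 0, 0.92),
               gnp_one_term(x, 0.0072, 0.92))
  v <- c(-700, -820)
  expect_equal(gnp_spt(x, v, 0, 0.0163, 0), 0.0163 * v)
})

test_that("two-term cavity-dispersion model and its linear-dispersion collapse", {
  expect_equal(gnp_two_term(-700, -20, 0.0378, -0.5692), -47.0292)
  expect_equal(gnp_two_term(-700, 0, 0.0378, -0.5692),
               gnp_one_term(-700, 0.0378, -0.5692))
  # when E_disp is exactly linear in volume the two-term model IS the SPT
  # model with transformed coefficients
  vol <- c(-820, -655, -940); area <- c(-800, -700, -900)
  c1 <- 0.031; c0 <- -2.5
  e_disp <- c1 * vol + c0
  expect_equal(gnp_two_term(vol, e_disp, 0.0378, -0.5692),
               gnp_spt(area, vol, 0, 0.0378 + c1, -0.5692 + c0))
})

test_that("dielectric rescaling divides the two electrostatic terms only", {
  d <- rand_delta(5)
  expect_equal(rescale_dielectric(d, dielectric_pair(1, 1)), d)
  d1 <- delta_terms(data.frame(complex_id = "c", dE_vdW = -40, dE_ele = -30,
                               dG_PB = 40, dSASA = -800, dSAV = -800))
  d2 <- rescale_dielectric(d1, dielectric_pair(2, 4))
  expect_equal(d2$dE_ele, -15)
  expect_equal(d2$dG_PB, 10)
  expect_equal(d2$dE_vdW, d1$dE_vdW)
  expect_equal(d2$dSASA, d1$dSASA)
  # |rescaled Coulombic term| strictly decreases with eps_ele
  eles <- vapply(c(1, 2, 4, 8), function(e) {
    abs(rescale_dielectric(d1, dielectric_pair(e, 1))$dE_ele)
  }, numeric(1))
  expect_true(all(diff(eles) < 0))
  expect_error(dielectric_pair(0.5, 1), class = "mmpbsar_domain_error")
})

test_that("scoring matches hand arithmetic for the basic regimes", {
  d0 <- rand_delta(3)
  d0[, c("dE_vdW", "dE_ele", "dG_PB", "dSASA", "dSAV")] <- 0
  m <- model_spec("spt", c(gamma = 0.1394, p = 0.0163, b = 0.7))
  expect_equal(score(d0, m)$dG_pred, rep(0.7, 3))

  d1 <- delta_terms(data.frame(complex_id = "c", dE_vdW = -40, dE_ele = -30,
                               dG_PB = 50, dSASA = -800, dSAV = -780))
  s <- score(d1, model_spec("sasa_only", c(gamma = 0.0072, b = 0)))
  expect_equal(s$dG_pred, -40 - 30 + 50 - 5.76)
})

test_that("every regime's contributions sum exactly to the prediction", {
  d <- rand_delta(8)
  models <- list(
    model_spec("sasa_only", c(gamma = 0.0072, b = 0.3)),
    model_spec("sav_only", c(gamma = 0.005, b = 0)),
    model_spec("sav_disp", c(gamma = 0.0378, b = -0.5692)),
    model_spec("spt", c(gamma = 0.1394, p = 0.0163, b = 0)),
    model_preset("pbsae-original"),
    model_spec("pbsa_ex", c(a1 = 0.45, a2 = 0.57, a3 = 0.05, a4 = 0.009,
                            a5 = -0.036)),
    model_spec("ani_one_term", c(a = 1.55, gamma = 0.06, b = 0)),
    model_spec("ani_sav_disp", c(a = 1.65, gamma = 0.118, b = 0)),
    model_spec("ani_spt", c(a = 1.75, gamma = 0.111, p = -0.064, b = 0)),
    model_spec("ani_pbsae", c(a1 = 0.757, a2 = 0.413, a3 = 0.085,
                              a4 = 0.088))
  )
  pair <- dielectric_pair(2.1, 3)
  for (m in models) {
    s <- score(d, m, pair)
    expect_equal(
      s$dG_pred,
      s$contrib_gas + s$contrib_polar + s$contrib_nonpolar + s$contrib_entropy,
      tolerance = 1e-10, info = m$regime)
  }
})

test_that("predictions are affine in each coefficient", {
  d <- rand_delta(6)
  pair <- dielectric_pair(1.5, 2.5)
  cases <- list(
    spt = c(gamma = 0.1, p = 0.02, b = 0.5),
    pbsa_e = c(a1 = 0.5, a2 = 0.6, a3 = 0.05, a4 = 0.1, gamma = 0.0072),
    ani_spt = c(a = 1.5, gamma = 0.1, p = -0.05, b = 0.2)
  )
  delta_c <- 1e-3
  for (rg in names(cases)) {
    cf <- cases[[rg]]
    for (k in names(cf)) {
      up <- cf; up[k] <- cf[k] + delta_c
      dn <- cf; dn[k] <- cf[k] - delta_c
      fd <- (score(d, model_spec(rg, up), pair)$dG_pred -
             score(d, model_spec(rg, dn), pair)$dG_pred) / (2 * delta_c)
      cf0 <- cf; cf0[k] <- 0
      cf1 <- cf; cf1[k] <- 1
      analytic <- score(d, model_spec(rg, cf1), pair)$dG_pred -
                  score(d, model_spec(rg, cf0), pair)$dG_pred
      expect_equal(fd, analytic, tolerance = 1e-8,
                   info = paste(rg, k))
    }
  }
})

test_that("regime reductions hold exactly", {
  d <- rand_delta(7)
  pair <- dielectric_pair(1, 2.1)
  expect_equal(
    score(d, model_spec("spt", c(gamma = 0.0836, p = 0, b = 0.1)), pair),
    score(d, model_spec("sasa_only", c(gamma = 0.0836, b = 0.1)), pair),
    ignore_attr = TRUE)
  expect_equal(
    score(d, model_spec("spt", c(gamma = 0, p = 0.0785, b = 0)), pair),
    score(d, model_spec("sav_only", c(gamma = 0.0785, b = 0)), pair),
    ignore_attr = TRUE)
  # ANI regime with a = 1 and dE_sp = dE_vdW + dE_ele IS the MM regime at
  # eps_ele = 1
  d2 <- d
  d2$dE_sp <- d$dE_vdW + d$dE_ele
  expect_equal(
    score(d2, model_spec("ani_spt",
                         c(a = 1, gamma = 0.13, p = 0.016, b = 0)), pair),
    score(d, model_spec("spt", c(gamma = 0.13, p = 0.016, b = 0)),
          dielectric_pair(1, 2.1)),
    ignore_attr = TRUE)
})

test_that("scoring at (eps, eps) equals the single-valued dielectric", {
  d <- rand_delta(9)
  for (m in list(model_spec("spt", c(gamma = 0.1, p = 0.01, b = 0)),
                 model_preset("pbsae-original"))) {
    for (eps in c(1, 2.1, 4)) {
      two <- score(d, m, dielectric_pair(eps, eps))
      single <- score(rescale_dielectric(d, dielectric_pair(eps, eps)), m,
                      dielectric_pair(1, 1))
      expect_equal(two$dG_pred, single$dG_pred, tolerance = 1e-12)
    }
  }
})

test_that("the empirical regime shares one scaling across both Coulombic terms", {
  d <- rand_delta(6)
  m <- model_preset("pbsae-original")
  scaled <- d
  scaled$dE_ele <- d$dE_ele / 2.1
  scaled$dG_PB <- d$dG_PB / 2.1
  expect_equal(score(d, m, dielectric_pair(2.1, 2.1))$dG_pred,
               score(scaled, m, dielectric_pair(1, 1))$dG_pred,
               tolerance = 1e-12)
})

test_that("missing coefficients or terms raise config errors naming them", {
  err <- expect_error(model_spec("spt", c(gamma = 0.1, b = 0)),
                      class = "mmpbsar_config_error")
  expect_match(conditionMessage(err), "p")
  d <- rand_delta(4)
  d$dE_sp <- NA_real_
  err2 <- expect_error(
    score(d, model_spec("ani_spt", c(a = 1, gamma = 0.1, p = 0, b = 0))),
    class = "mmpbsar_config_error")
  expect_match(conditionMessage(err2), "dE_sp")
  expect_match(conditionMessage(err2), "ani_spt")
})
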