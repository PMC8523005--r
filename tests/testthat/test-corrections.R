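test_that("restraint correction vanishes when the log arguments cancel", {
  # choose d1^2 sin(t2) sin(t3) = V0 / (pi (RT)^3) with K = 1
  d1 <- sqrt(1661 / (pi * RT298^3))
  g <- restraint_geometry(d1, pi / 2, pi / 2, k_rstr = 1)
  expect_equal(boresch_correction(g), 0, tolerance = 1e-12)
})

test_that("restraint correction scales as 3 RT ln K for any geometry", {
  set.seed(30)
  for (i in 1:10) {
    d1 <- runif(1, 2, 12)
    t2 <- runif(1, 0.3, pi - 0.3)
    t3 <- runif(1, 0.3, pi - 0.3)
    k1 <- runif(1, 0.5, 5); k2 <- k1 * runif(1, 2, 40)
    dA1 <- boresch_correction(restraint_geometry(d1, t2, t3, k1))
    dA2 <- boresch_correction(restraint_geometry(d1, t2, t3, k2))
    expect_equal(dA2 - dA1, 3 * RT298 * log(k2 / k1), tolerance = 1e-10)
  }
  # the published host-guest K-grid: 3.43 -> 7.52 -> 10.38 kcal/mol
  expect_equal(3 * RT298 * log(10), 7.52 - 3.43, tolerance = 0.01)
  expect_equal(3 * RT298 * log(50), 10.38 - 3.43, tolerance = 0.02)
})

test_that("restraint correction matches the stiff-spring quadrature oracle", {
  set.seed(31)
  for (i in 1:5) {
    g <- restraint_geometry(runif(1, 3, 9), runif(1, 0.6, pi - 0.6),
                            runif(1, 0.6, pi - 0.6),
                            k_rstr = runif(1, 20, 80))
    expect_lt(abs(boresch_correction(g) - boresch_quadrature_oracle(g)),
              0.05)
  }
  g50 <- restraint_geometry(5, 1.2, 2.0, k_rstr = 50)
  expect_lt(abs(boresch_correction(g50) - boresch_quadrature_oracle(g50)),
            0.05)
})

test_that("restraint geometry rejects singular and invalid inputs", {
  expect_error(restraint_geometry(5, 0, 1, 10), "singular")
  expect_error(restraint_geometry(5, pi, 1, 10), "singular")
  expect_error(restraint_geometry(5, 1, 1, -2), "k_rstr")
  expect_error(restraint_geometry(-1, 1, 1, 10), "d1_A")
  # degrees are converted
  ga <- restraint_geometry(5, 90, 60, 10, degrees = TRUE)
  gb <- restraint_geometry(5, pi / 2, pi / 3, 10)
  expect_equal(boresch_correction(ga), boresch_correction(gb))
})

test_that("volume correction behaves as RT ln(V0/V_site)", {
  expect_equal(volume_correction(1661), 0)
  expect_equal(volume_correction(0.836), 4.5, tolerance = 0.01)
  v <- 10^seq(-1, 4, length.out = 20)
  expect_true(all(diff(volume_correction(v)) < 0))  # monotone decreasing
  expect_error(volume_correction(-1), "> 0")
})

test_that("binding-site volume estimation recovers Gaussian truth", {
  s <- sample_com_displacements(0.2, 1e5, seed = 32)
  expect_equal(s$v_site_true, (2 * pi * 0.04)^1.5)
  est <- site_volume_estimate(s$displacements)
  expect_lt(abs(est$v_site / s$v_site_true - 1), 0.03)

  # volume_correction o site_volume_estimate recovers RT ln(V0/V_true)
  expect_lt(abs(volume_correction(est$v_site) /
                  volume_correction(s$v_site_true) - 1), 0.05)

  # doubling sigma multiplies the Gaussian volume by 8
  est2 <- site_volume_estimate(2 * s$displacements)
  expect_equal(est2$v_site / est$v_site, 8, tolerance = 1e-9)

  # rotational invariance
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  est3 <- site_volume_estimate(s$displacements %*% rot)
  expect_equal(est3$v_site, est$v_site, tolerance = 1e-9)

  expect_error(site_volume_estimate(matrix(1, 50, 3)), "degenerate")
  expect_error(site_volume_estimate(matrix(rnorm(30), 10, 3)), ">= 30")

  sph <- site_volume_estimate(s$displacements, method = "spherical")
  expect_equal(sph$method, "spherical")
  expect_gt(sph$v_site, 0)
})

test_that("symmetry entropy is RT ln(n_poses) and additive", {
  expect_equal(symmetry_entropy(1), 0)
  expect_equal(symmetry_entropy(16), 1.64, tolerance = 0.005)
  expect_equal(symmetry_entropy(16), RT298 * log(16))
  expect_equal(symmetry_entropy(4 * 6),
               symmetry_entropy(4) + symmetry_entropy(6))
  expect_error(symmetry_entropy(0), "integer >= 1")
  expect_error(symmetry_entropy(2.5), "integer")
})

test_that("ABFE assembly adds present corrections on the binding convention", {
  # restrained bidirectional leg: raw BAR + restraint correction
  a1 <- assemble_abfe(-18.65, correction_set(dAr = 7.52))
  expect_equal(a1$value, -11.13, tolerance = 1e-9)

  # unrestrained unidirectional leg with symmetry + volume terms
  a2 <- assemble_abfe(-18.5, correction_set(TdS_sym = 1.7, dG_vol = 7.5))
  expect_equal(a2$value, -9.3, tolerance = 1e-9)

  # no corrections: identity, CI propagated unchanged
  raw <- fe_estimate("BAR", 18.65, ci95 = 1.01, convention = "dissociation")
  a3 <- assemble_abfe(raw, correction_set(dAr = 7.52))
  expect_equal(a3$value, -11.13, tolerance = 1e-9)
  expect_equal(a3$ci95, 1.01)
  a4 <- assemble_abfe(raw, correction_set())
  expect_equal(a4$value, -18.65)

  # dissociation-convention output flips the sign
  a5 <- assemble_abfe(raw, correction_set(dAr = 7.52),
                      convention = "dissociation")
  expect_equal(a5$value, 11.13, tolerance = 1e-9)

  expect_error(assemble_abfe(-10, correction_set(dAr = 7.5, dG_vol = 4.5)),
               "configuration error")
})

test_that("every published restrained assembly is reproduced from its parts", {
  tab1 <- data.frame(
    bar = c(-15.34, -18.65, -21.83, -16.09, -19.81, -20.95, -15.95,
            -17.86, -22.26),
    dAr = c(3.43, 7.52, 10.38, 3.43, 7.52, 10.38, 3.43, 7.52, 10.38),
    abfe = c(-11.91, -11.13, -11.45, -12.66, -12.29, -10.57, -12.52,
             -10.34, -11.88))
  for (i in seq_len(nrow(tab1)))
    expect_equal(assemble_abfe(tab1$bar[i],
                               correction_set(dAr = tab1$dAr[i]))$value,
                 tab1$abfe[i], tolerance = 0.01)
})
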