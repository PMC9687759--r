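# Constitutive models: dielectric sigmoids, water content, effective and
# vaporization heat capacities, material table.

test_that("sigmoidal dielectric models saturate, halve at the midpoint, and decrease", {
  for (mat in c("healthy_liver", "tumor")) {
    d <- default_dielectric(mat)
    expect_equal(relative_permittivity(-1e6, d), d$s1)
    expect_equal(electrical_conductivity(-1e6, d), d$r1)
    expect_equal(relative_permittivity(d$s2 / d$s3, d), d$s1 / 2)
    expect_equal(electrical_conductivity(d$r2 / d$r3, d), d$r1 / 2)
    Tg <- seq(-20, 200, by = 0.5)
    expect_true(all(diff(relative_permittivity(Tg, d)) < 0))
    expect_true(all(diff(electrical_conductivity(Tg, d)) < 0))
  }
})

test_that("baseline 37 C dielectric values match frozen evaluations", {
  expect_equal(relative_permittivity(37, default_dielectric("healthy_liver")),
               46.915284, tolerance = 1e-6)
  expect_equal(electrical_conductivity(37, default_dielectric("tumor")),
               2.305824, tolerance = 1e-6)
})

test_that("tumor exceeds healthy liver dielectrics by the expected contrast at 37 C", {
  h <- default_dielectric("healthy_liver")
  t <- default_dielectric("tumor")
  perm_ratio <- relative_permittivity(37, t) / relative_permittivity(37, h)
  cond_ratio <- electrical_conductivity(37, t) / electrical_conductivity(37, h)
  expect_gt(perm_ratio, 1.15); expect_lt(perm_ratio, 1.35)
  expect_gt(cond_ratio, 1.05); expect_lt(cond_ratio, 1.20)
})

test_that("sigmoid coefficient invariants are enforced", {
  expect_error(sigmoid_dielectric(-1, 6, 0.07, 2, 5, 0.06), "s1 > 0")
  expect_error(sigmoid_dielectric(48, 6, -0.07, 2, 5, 0.06), "s3 > 0")
})

test_that("water content matches the steady-state plateau and both branch joins", {
  expect_equal(water_content(70), 0.778, tolerance = 5e-4)
  # both branch formulas evaluated at the joins agree
  w100_lo <- 0.778 * (1 - exp((100 - 106) / 3.42))
  w100_hi <- 7.053 - 0.064096 * 100
  expect_equal(w100_lo, w100_hi, tolerance = 1e-4)
  expect_equal(water_content(100), w100_hi)
  w104_lo <- 7.053 - 0.064096 * 104
  w104_hi <- 0.778 * exp(-(104 - 80) / 34.37)
  expect_equal(w104_lo, w104_hi, tolerance = 1e-4)
  expect_equal(water_content(104), w104_hi)
  expect_equal(w100_hi, 0.6434, tolerance = 1e-4)
  expect_equal(w104_hi, 0.387, tolerance = 1e-3)
})

test_that("water content is continuous, bounded and non-increasing on [70, 200] C", {
  Tg <- seq(70, 200, by = 0.01)
  W <- water_content(Tg)
  expect_true(all(W >= 0 & W <= 0.778))
  expect_true(all(diff(W) <= 0))
  expect_lt(max(abs(diff(W))), 1e-3)          # no branch-join jumps
  # constant extension below the first branch
  expect_equal(water_content(20), water_content(70))
})

test_that("effective specific heat adds the latent term branchwise", {
  liver <- material_lookup("healthy_liver")
  expect_equal(effective_specific_heat(50, liver), liver$specific_heat)
  # linear vaporization band: c' - c = alpha * 0.064096
  expect_equal(effective_specific_heat(102, liver) - liver$specific_heat,
               2.26e6 * 0.064096, tolerance = 1e-9)
  # exponential tail at 130 C
  expect_equal(effective_specific_heat(130, liver) - liver$specific_heat,
               2.26e6 * (0.778 / 34.37) * exp(-(130 - 80) / 34.37),
               tolerance = 1e-9)
  # alternative alpha/rho reading scales the latent term by 1/rho
  expect_equal(effective_specific_heat(102, liver, per_density = TRUE) -
                 liver$specific_heat,
               2.26e6 * 0.064096 / liver$density, tolerance = 1e-9)
})

test_that("effective specific heat matches a finite difference of alpha*W away from joins", {
  liver <- material_lookup("healthy_liver")
  h <- 1e-4
  for (Tc in c(75, 85, 95, 101, 102, 110, 130, 150)) {
    fd <- -(2.26e6) * (water_content(Tc + h) - water_content(Tc - h)) / (2 * h)
    cp <- effective_specific_heat(Tc, liver) - liver$specific_heat
    expect_equal(cp, fd, tolerance = 1e-2)
  }
  # c' >= c everywhere (W non-increasing)
  Tg <- seq(0, 200, by = 0.25)
  expect_true(all(effective_specific_heat(Tg, liver) >= liver$specific_heat))
})

test_that("enthalpy-method volumetric heat capacity follows its three branches", {
  vc <- vaporization_constants()
  expect_equal(vaporization_rho_c(50, "tissue", vc), 1079 * 3540)
  expect_equal(vaporization_rho_c(99.5, "tissue", vc),
               vc$h_fg * vc$C_w_tissue / 1)
  expect_equal(vaporization_rho_c(120, "tissue", vc), vc$rho_g * vc$c_g)
  expect_equal(vaporization_rho_c(50, "blood", vc), 1060 * 3600)
  expect_equal(vaporization_rho_c(99.5, "blood", vc),
               vc$h_fg * vc$C_w_blood / 1)
  expect_error(vaporization_constants(delta_T = 0), "positive")
  expect_error(vaporization_rho_c(-5, "tissue", vc), "T > 0")
  # gas phase must carry less heat per volume than liquid tissue
  expect_error(vaporization_constants(rho_g = 2000, c_g = 4000), "below")
})

test_that("material lookup returns the tabulated constants and rejects unknowns", {
  h <- material_lookup("healthy_liver")
  expect_equal(c(h$density, h$thermal_conductivity, h$specific_heat),
               c(1079, 0.52, 3540))
  t <- material_lookup("tumor")
  expect_equal(c(t$density, t$thermal_conductivity, t$specific_heat),
               c(1040, 0.57, 3960))
  b <- material_lookup("blood")
  expect_equal(c(b$density, b$thermal_conductivity, b$specific_heat),
               c(1060, 0.50, 3600))
  expect_equal(blood_core_temperature(), 37)
  expect_error(material_lookup("unknown"), "unknown material")
  expect_error(material_constants("x", -1, 0.5, 3000), "strictly positive")
})
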