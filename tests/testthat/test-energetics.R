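# The energy-balance core: retained/maintenance energy, the quadratic
# NE_m solve, the NE_g relation, the forward (ADG-prediction) inverse,
# and the replacement technique.

test_that("retained and maintenance energy match the closed formulas", {
  # frozen from direct evaluation of ADG^1.097 * 0.0493 * W^0.75 and
  # 0.077 * W^0.75 at the control-treatment means
  expect_equal(retained_energy(1.74, 513), 9.757026, tolerance = 1e-6)
  expect_equal(maintenance_energy(513), 8.300013, tolerance = 1e-6)
  # unit-weight and power identities
  expect_equal(retained_energy(1, 1), 0.0493)
  expect_equal(maintenance_energy(1), 0.077)
  expect_equal(maintenance_energy(256), 0.077 * 64)
  # ADG -> 0 limit of EG is 0
  expect_lt(retained_energy(1e-9, 513), 1e-8)
  expect_error(retained_energy(-1, 513), "positive")
  expect_error(maintenance_energy(0), "positive")
})

test_that("quadratic solve reproduces the control worked example", {
  w <- (386 + 640) / 2
  nem <- solve_dietary_nem(10.69, maintenance_energy(w),
                           retained_energy(1.74, w))
  expect_equal(round(nem, 2), 2.11)
  expect_equal(round(neg_from_nem(nem), 2), 1.44)
  # the root satisfies the intake identity
  expect_equal(maintenance_energy(w) / nem +
                 retained_energy(1.74, w) / neg_from_nem(nem),
               10.69, tolerance = 1e-9)
})

test_that("maintenance-only intake collapses to the closed form EM/DMI", {
  em <- 8.3
  dmi <- 10
  expect_equal(solve_dietary_nem(dmi, em, 0), em / dmi, tolerance = 1e-12)
})

test_that("solve errors on infeasible performance", {
  # with zero gain energy and intake far above EM, the only root at or
  # below the zero-gain bound is rejected (diet cannot support gain)
  expect_error(solve_dietary_nem(20, 8.3, 0), "infeasible")
  expect_error(solve_dietary_nem(0, 8.3, 9), "positive")
  expect_error(solve_dietary_nem(10, -1, 9), "positive")
})

test_that("forward model and solve are exact inverses over random inputs", {
  set.seed(71)
  for (i in 1:200) {
    nem <- runif(1, 1.6, 2.6)
    w <- runif(1, 300, 700)
    dmi_min <- maintenance_energy(w) / nem
    dmi <- runif(1, dmi_min * 1.05, dmi_min * 2.5)
    adg <- predict_adg(nem, dmi, w)
    back <- solve_dietary_nem(dmi, maintenance_energy(w),
                              retained_energy(adg, w))
    expect_equal(back, nem, tolerance = 1e-9)
  }
})

test_that("predict_adg boundary and error behaviour", {
  # intake exactly at maintenance gives zero gain
  nem <- 2.1
  w <- 500
  expect_equal(predict_adg(nem, maintenance_energy(w) / nem, w), 0)
  expect_error(predict_adg(nem, maintenance_energy(w) / nem - 0.5, w),
               "gain-infeasible")
  expect_equal(predict_adg(2.113, 10.69, 513), 1.74, tolerance = 1e-2)
})

test_that("solved NE_m is monotone in ADG and DMI", {
  w <- 513
  em <- maintenance_energy(w)
  adg <- seq(1.2, 2.2, by = 0.1)
  nem_adg <- solve_dietary_nem(10.69, em, retained_energy(adg, w))
  expect_true(all(diff(nem_adg) > 0))
  dmi <- seq(9, 13, by = 0.25)
  nem_dmi <- solve_dietary_nem(dmi, em, retained_energy(1.74, w))
  expect_true(all(diff(nem_dmi) < 0))
  # feasible solutions always exceed the zero-gain bound
  expect_true(all(c(nem_adg, nem_dmi) > nem_lower_bound()))
})

test_that("NE_g relation is affine with the documented coefficients", {
  x <- seq(0.5, 3, by = 0.25)
  y <- neg_from_nem(x)
  expect_equal(diff(y) / diff(x), rep(0.877, length(x) - 1))
  expect_equal(neg_from_nem(nem_lower_bound()), 0)
  expect_equal(round(neg_from_nem(2.08), 2), 1.41)
  expect_error(neg_from_nem(0.3), "bound")
})

test_that("replacement technique reproduces the reported ingredient values", {
  expect_equal(round(replacement_ne(2.09, 2.11, 0.2037, 2.24), 2), 2.14)
  expect_equal(round(replacement_ne(1.42, 1.44, 0.2037, 1.52), 2), 1.42)
  expect_equal(round(replacement_ne(2.08, 2.11, 0.2025, 2.24), 2), 2.09)
  expect_equal(round(replacement_ne(1.41, 1.44, 0.2025, 1.52), 2), 1.37)
})

test_that("replacement technique is linear with a no-difference identity", {
  # identical diets: the ingredient is worth exactly the displaced corn
  expect_equal(replacement_ne(2.1, 2.1, 0.5, 2.24), 2.24)
  # linear in the diet difference
  d <- seq(-0.2, 0.2, by = 0.05)
  v <- replacement_ne(2.1 + d, 2.1, 0.2, 2.24)
  expect_equal(diff(v) / diff(d), rep(1 / 0.2, length(d) - 1))
  expect_error(replacement_ne(2.1, 2.1, 0, 2.24), "inclusion")
})

test_that("pen_energetics composes the chain and the ratios", {
  res <- pen_energetics(386, 640, 1.74, 10.69, 2.09, 1.40)
  expect_equal(res$median_w_kg, 513)
  expect_equal(round(res$nem_mcal_kg, 2), 2.11)
  expect_equal(round(res$neg_mcal_kg, 2), 1.44)
  expect_equal(round(res$obs_exp_nem, 2), 1.01)
  expect_equal(round(res$obs_exp_neg, 2), 1.03)
  # observed equal to tabular gives ratios of exactly 1
  r2 <- pen_energetics(386, 640, 1.74, 10.69,
                       res$nem_mcal_kg, res$neg_mcal_kg)
  expect_equal(r2$obs_exp_nem, 1)
  expect_equal(r2$obs_exp_neg, 1)
  expect_error(pen_energetics(386, 640, 11, 10.69), "smaller than DMI")
})
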