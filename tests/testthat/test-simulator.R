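test_that("tau_for_case: constant and table kinds", {
  case <- biometry_case(24, 41, 45)
  expect_equal(tau_for_case(toricity_model("constant", constant_value = 1.46),
                            case), 1.46)

  tab <- toricity_model("table", axial_lengths = c(21, 27),
                        mean_ks = c(39, 47),
                        values = matrix(c(1.33, 1.42, 1.47, 1.75), 2, 2,
                                        byrow = TRUE))
  # nodes are exact
  expect_equal(tau_for_case(tab, biometry_case(21, 37, 41)), 1.33)
  expect_equal(tau_for_case(tab, biometry_case(27, 45, 49)), 1.75)
  # center of the cell is the average of the four corners (bilinear)
  expect_equal(tau_for_case(tab, biometry_case(24, 41, 45)),
               mean(c(1.33, 1.42, 1.47, 1.75)), tolerance = 1e-12)
  # clamped outside the grid
  expect_equal(tau_for_case(tab, biometry_case(18, 36, 40)), 1.33)
  expect_equal(tau_for_case(tab, biometry_case(33, 46, 50)), 1.75)

  expect_error(toricity_model("table", values = NULL), "empty table")
  expect_error(toricity_model("constant", constant_value = 0.9), "\\(1, 3\\)")
  expect_error(toricity_model("constant", constant_value = 3.2), "\\(1, 3\\)")
})

test_that("vergence kind matches the hand-evaluated meridional vergences", {
  case <- biometry_case(24, 41, 45)
  # frozen: n/(n/45 - 0.005) - n/(n/41 - 0.005) over 4 D, done longhand
  expect_equal(tau_for_case(toricity_model("vergence", elp_mm = 5), case),
               1.420483693, tolerance = 1e-8)
  # an IOL at the corneal plane needs corneal-plane toricity exactly
  expect_equal(tau_for_case(toricity_model("vergence", elp_mm = 1e-9), case),
               1, tolerance = 1e-6)
})

test_that("vergence tau increases in ELP, axial length (SRK/T ELP) and mean K", {
  taus_elp <- vapply(seq(3, 7, by = 0.5), function(e) {
    tau_for_case(toricity_model("vergence", elp_mm = e),
                 biometry_case(24, 41, 45))
  }, numeric(1))
  expect_true(all(diff(taus_elp) > 0))

  srkt_model <- toricity_model("vergence", elp_mm = NULL, a_constant = 118.8)
  taus_al <- vapply(seq(20, 30, by = 1), function(al) {
    tau_for_case(srkt_model, biometry_case(al, 41, 45))
  }, numeric(1))
  expect_true(all(diff(taus_al) > 0))

  taus_k <- vapply(seq(38, 48, by = 1), function(mk) {
    tau_for_case(srkt_model, biometry_case(24, mk - 2, mk + 2))
  }, numeric(1))
  expect_true(all(diff(taus_k) > 0))
  # fixed-ELP route is also K-monotone
  taus_k2 <- vapply(seq(38, 48, by = 1), function(mk) {
    tau_for_case(toricity_model("vergence", elp_mm = 5),
                 biometry_case(24, mk - 2, mk + 2))
  }, numeric(1))
  expect_true(all(diff(taus_k2) > 0))
})

test_that("the Alcon worked example simulates end to end", {
  case <- biometry_case(21, 37, 41)
  model <- toricity_model("constant", constant_value = 1.46)
  res <- simulate_calculator(case, test_catalog(), model,
                             policy = "no_overcorrection")
  sel <- res$recommendations[1, ]
  expect_equal(sel$cylinder_iol_plane_D, 5.25)       # the 5.25 D lens
  expect_equal(sel$sphere_D, 34.0)
  expect_equal(sel$residual_D, 0.40)
  expect_equal(sel$residual_axis_deg, 90)
  # under min-|r| the over-correcting 6.00 D lens wins instead (-0.11 D)
  res2 <- simulate_calculator(case, test_catalog(), model, policy = "min_abs")
  expect_equal(res2$recommendations$cylinder_iol_plane_D[1], 6.00)
  expect_equal(res2$recommendations$residual_D[1], 0.11)
})

test_that("a three-lens catalog at tau 1.33 prints the derived residuals", {
  res <- simulate_calculator(biometry_case(21, 37, 41),
                             test_catalog(c(4.50, 5.25, 6.00)),
                             toricity_model("constant", constant_value = 1.33))
  rec <- res$recommendations[order(res$recommendations$cylinder_iol_plane_D), ]
  # derived by direct forward arithmetic at tau = 1.33
  expect_equal(rec$residual_D, c(0.62, 0.05, 0.51))
  expect_equal(rec$residual_axis_deg, c(90, 90, 0))
})

test_that("a spherical cornea forces over-correction by the lowest cylinder", {
  res <- simulate_calculator(biometry_case(24, 43, 43), test_catalog(),
                             toricity_model("constant", constant_value = 1.46))
  sel <- res$recommendations[1, ]
  expect_equal(sel$cylinder_iol_plane_D, 1.50)
  expect_equal(sel$residual_exact_D, -1.50 / 1.46, tolerance = 1e-12)
})

test_that("simulator-extractor closure recovers tau before display rounding", {
  models <- list(toricity_model("constant", constant_value = 1.46),
                 toricity_model("vergence", elp_mm = 5),
                 toricity_model("vergence", elp_mm = NULL, a_constant = 118.8))
  for (model in models) for (al in c(21, 27)) {
    case <- biometry_case(al, 41, 45)
    res <- simulate_calculator(case, test_catalog(), model)
    for (i in seq_len(nrow(res$recommendations))) {
      row <- res$recommendations[i, ]
      tr <- extract_toricity(row$cylinder_iol_plane_D, res$cross_cylinder,
                             row$residual_exact_D)
      expect_equal(tr$value, res$tau, tolerance = 1e-9)
    }
  }
})

test_that("catalog permutation never changes the selected lens", {
  set.seed(3)
  cat0 <- test_catalog()
  model <- toricity_model("constant", constant_value = 1.52)
  base <- simulate_calculator(biometry_case(21, 37, 41), cat0, model)$selected
  for (i in 1:5) {
    perm <- lens_catalog(cat0[sample(nrow(cat0)), ])
    expect_equal(simulate_calculator(biometry_case(21, 37, 41), perm,
                                     model)$selected, base)
  }
})

test_that("sphere coverage and catalog validation", {
  narrow <- lens_catalog(data.frame(name = "X", cylinder_iol_plane_D = 3,
                                    sphere_min_D = 6, sphere_max_D = 10,
                                    a_constant = 118.8))
  # AL 21 / K 39 needs 34.0 D, outside [6, 10]
  expect_warning(res <- simulate_calculator(biometry_case(21, 37, 41), narrow,
                                            toricity_model("constant",
                                                           constant_value = 1.46)),
                 "no lens")
  expect_equal(nrow(res$recommendations), 0)
  expect_true(is.na(res$selected))

  expect_error(lens_catalog(data.frame(name = c("A", "A"),
                                       cylinder_iol_plane_D = 1,
                                       sphere_min_D = 0, sphere_max_D = 40,
                                       a_constant = 118.8)), "duplicate")
  expect_error(lens_catalog(data.frame(name = "A", cylinder_iol_plane_D = -1,
                                       sphere_min_D = 0, sphere_max_D = 40,
                                       a_constant = 118.8)), "row 1")
})
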