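test_that("build_cases splits mean K and inverts the sphere per cell", {
  cases <- build_cases(probe_grid(), iol_constants(118.8))
  expect_equal(nrow(cases), 9)
  short_flat <- cases[cases$axial_length_mm == 21 & cases$mean_k_D == 39, ]
  expect_equal(short_flat$k_flat_D, 37)
  expect_equal(short_flat$k_steep_D, 41)
  expect_equal(short_flat$sphere_D, 34.0)

  one <- build_cases(probe_grid(axial_lengths = 24, mean_ks = 43),
                     iol_constants(118.8))
  expect_equal(nrow(one), 1)

  # sphere depends only on the mean: an asymmetric 1.00/3.00 split matches
  asym <- build_cases(probe_grid(test_cylinder = 2), iol_constants(118.8))
  expect_equal(asym$sphere_D, cases$sphere_D)
})

test_that("probing a constant-ratio simulator fills nine identical cells", {
  calc <- simulated_calculator(test_catalog(),
                               toricity_model("constant", constant_value = 1.46))
  m <- probe(calc)
  expect_s3_class(m, "toricity_matrix")
  expect_equal(dim(m$values), c(3, 3))
  shown <- round_half_up(m$values, 2)
  expect_true(all(shown == 1.46))
  expect_equal(m$classification, "constant")
  expect_equal(round_half_up(m$constant_value, 2), 1.46)
  # orientation: mean K descending down rows, AL ascending across columns
  expect_equal(rownames(m$values), c("47", "43", "39"))
  expect_equal(colnames(m$values), c("21", "24", "27"))
})

test_that("probing a vergence simulator is classified variable with the right trend", {
  calc <- simulated_calculator(
    test_catalog(),
    toricity_model("vergence", elp_mm = NULL, a_constant = 118.8))
  m <- probe(calc)
  expect_equal(m$classification, "variable")
  # increasing left-to-right (AL) and bottom-to-top (mean K)
  for (r in 1:3) expect_true(all(diff(m$values[r, ]) > 0))
  for (col in 1:3) expect_true(all(diff(m$values[, col]) < 0))
})

test_that("probing a table simulator reproduces the nodes exactly", {
  tab <- toricity_model("table", axial_lengths = c(21, 24, 27),
                        mean_ks = c(39, 43, 47),
                        values = matrix(c(1.33, 1.38, 1.42,
                                          1.40, 1.52, 1.56,
                                          1.47, 1.63, 1.75),
                                        3, 3, byrow = TRUE))
  # display rounding off: the check targets the extraction algebra itself
  calc <- simulated_calculator(test_catalog(), tab, digits = Inf)
  m <- probe(calc)
  expect_equal(unname(m$values["39", "21"]), 1.33, tolerance = 1e-9)
  expect_equal(unname(m$values["47", "27"]), 1.75, tolerance = 1e-9)
  expect_equal(unname(m$values["43", "24"]), 1.52, tolerance = 1e-9)
  expect_equal(m$classification, "variable")
})

test_that("classification threshold reproduces the published calls", {
  const <- matrix(1.46, 3, 3, dimnames = list(c(47, 43, 39), c(21, 24, 27)))
  expect_equal(classify(const)$classification, "constant")
  expect_equal(classify(const)$constant_value, 1.46)

  spread <- const; spread[] <- c(1.47, 1.40, 1.33, 1.63, 1.52, 1.38,
                                 1.75, 1.56, 1.42)
  expect_equal(classify(spread)$classification, "variable")

  # one 1.42 cell among 1.43s is still constant at tolerance 0.02
  lone <- matrix(1.43, 3, 3, dimnames = dimnames(const)); lone[3, 3] <- 1.42
  cl <- classify(lone)
  expect_equal(cl$classification, "constant")
  expect_equal(cl$constant_value, 1.43)

  expect_equal(classify(matrix(c(1.5, NA), 1, 2))$classification,
               "indeterminate")
})

test_that("a failing cell is marked invalid but the matrix is returned", {
  # residual >= attempted correction in exactly one cell
  calc <- function(case) {
    if (case$axial_length == 24 && mean_k(case) == 43)
      data.frame(name = "BAD", cylinder_iol_plane_D = 5.25, residual_D = 4.50,
                 residual_axis_deg = 90)
    else
      data.frame(name = "OK", cylinder_iol_plane_D = 5.25, residual_D = 0.40,
                 residual_axis_deg = case$steep_axis)
  }
  m <- probe(calc)
  expect_true(is.na(m$values["43", "24"]))
  expect_equal(sum(is.finite(m$values)), 8)
  bad <- m$provenance[!m$provenance$valid, ]
  expect_match(bad$reason, "non-physical")
})

test_that("extracted cells are invariant to steep axis and to the K split", {
  model <- toricity_model("constant", constant_value = 1.57)
  m90 <- probe(simulated_calculator(test_catalog(), model, digits = Inf))
  m30 <- probe(simulated_calculator(test_catalog(), model, digits = Inf),
               probe_grid(steep_axis = 30))
  expect_equal(m90$values, m30$values, tolerance = 1e-12)
  m2 <- probe(simulated_calculator(test_catalog(), model, digits = Inf),
              probe_grid(test_cylinder = 2))
  expect_equal(unname(m90$values), unname(m2$values), tolerance = 1e-9)
})

test_that("grid validation", {
  expect_error(probe_grid(axial_lengths = c(24, 21)), "increasing")
  expect_error(probe_grid(mean_ks = c(43, 43)), "increasing")
  expect_error(probe_grid(test_cylinder = 0), "test_cylinder")
})
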