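# Per-cell estimators: length, diameters, trapezoid surfaces, Cavalieri
# volumes, shells, periplasm, ribosome totals and density.

test_that("cell length follows section count or the supplied value", {
  st <- make_stack(rep(1.8, 89), thickness = 0.04)
  expect_equal(cell_length(st), 3.56)
  st1 <- make_stack(1.8, thickness = 0.055)
  expect_equal(cell_length(st1), 0.055)
  st_sup <- make_stack(rep(1.8, 38), thickness = 0.055, length_um = 3.90)
  expect_equal(cell_length(st_sup, mode = "supplied"), 3.90)
  # supplied lengths can disagree with count x thickness (as in the
  # bundled reference data: 38 sections x 0.055 = 2.09, reported 3.90)
  expect_equal(cell_length(st_sup, mode = "section_count"), 2.09)
  expect_error(cell_length(st, mode = "supplied"), "length")
})

test_that("diameter estimators agree on constant stacks and recover geometry", {
  st <- make_stack(rep(pi * 0.58, 20))  # minor axis 0.58 everywhere
  for (est in c("median_central", "mean_all", "max")) {
    expect_equal(cell_diameter(st, "om", est), 0.58, tolerance = 1e-12)
  }
  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54)
  sliced <- slice_model(m)
  expect_equal(cell_diameter(sliced, "om"), 0.58, tolerance = 1e-12)
  expect_equal(cell_diameter(sliced, "pm"), 2 * (0.29 - 0.015),
               tolerance = 1e-12)
  zero <- make_stack(rep(0, 5))
  expect_error(cell_diameter(zero, "om"), "positive")
})

test_that("aspect ratio reproduces reported per-cell values from rounded inputs", {
  expect_equal(aspect_ratio(3.90, 0.59), 6.63, tolerance = 0.05 / 6.63)
  expect_lt(abs(aspect_ratio(3.90, 0.59) - 6.63), 0.05)
  expect_lt(abs(aspect_ratio(7.41, 0.52) - 14.35), 0.15)
  expect_equal(aspect_ratio(2, 2), 1)
  expect_error(aspect_ratio(3, 0), "positive")
})

test_that("trapezoid surface area matches hand sums and the analytic oracle", {
  expect_equal(surface_area(make_stack(rep(2, 5), thickness = 0.04)),
               4 * 2 * 0.04)
  expect_equal(surface_area(make_stack(c(0, 1, 2, 1, 0), thickness = 0.1)),
               0.40)
  expect_error(surface_area(make_stack(2)), "2 sections")

  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54)
  st <- slice_model(m)
  truth <- analytic_truth(m)
  expect_equal(truth$surf_om, 6.45, tolerance = 0.001)
  expect_rel_error_lt(surface_area(st, "om"), truth$surf_om, 0.05)
})

test_that("Cavalieri volumes match prisms, padding and the analytic oracle", {
  st <- make_stack(rep(2, 10), a_om = rep(0.25, 10), thickness = 0.04)
  expect_equal(compartment_volume(st, "om"), 0.10)
  # zero-area padding contributes nothing
  pad <- make_stack(c(rep(2, 10), 0, 0), a_om = c(rep(0.25, 10), 0, 0),
                    thickness = 0.04)
  expect_equal(compartment_volume(pad, "om"), 0.10)

  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54)
  st2 <- slice_model(m)
  truth <- analytic_truth(m)
  expect_equal(truth$vol_whole, 0.884, tolerance = 0.001)
  expect_rel_error_lt(compartment_volume(st2, "om"), truth$vol_whole, 0.02)
  expect_rel_error_lt(compartment_volume(st2, "pm"), truth$vol_cytoplasm,
                      0.02)
})

test_that("membrane shell volume is perimeter x thickness x height", {
  st <- make_stack(rep(1.8, 20), thickness = 0.04, om_thickness_nm = 5)
  expect_equal(shell_volume(st, "om"), 1.8 * 0.005 * 0.04 * 20,
               tolerance = 1e-12)
  expect_equal(shell_volume(st, "om", thickness_nm = 0), 0)
  # thin-shell identity: shell ~ surface x mean thickness for constant
  # perimeters (trapezoid surface spans n-1 of the n slabs)
  st_long <- make_stack(rep(1.8, 200), thickness = 0.04, om_thickness_nm = 5)
  expect_rel_error_lt(shell_volume(st_long, "om"),
                      surface_area(st_long, "om") * 0.005, 0.01)
})

test_that("periplasm subtraction reproduces reported rows and clamps at zero", {
  # reported per-cell volume rows are 2-dp rounded, so allow 0.015 fl
  expect_lt(abs(periplasm_volume(1.06, 0.82, 0.01, 0.03) - 0.19), 0.015)
  expect_equal(periplasm_volume(1.07, 0.96, 0.01, 0.03), 0.07,
               tolerance = 1e-12)
  expect_equal(periplasm_volume(1.0, 1.0, 0, 0), 0)
  expect_equal(periplasm_volume(1.06, 0.82, mode = "text_literal"), 0.24,
               tolerance = 1e-12)
  expect_warning(v <- periplasm_volume(1.0, 0.99, 0.02, 0.03), "clamped")
  expect_equal(v, 0)
})

test_that("ribosome totals and densities follow the reporting conventions", {
  st <- make_stack(rep(2, 38), ribosomes = rep(245L, 38))
  expect_equal(ribosome_total(st), 38L * 245L)
  expect_equal(ribosome_total(make_stack(rep(2, 3))), 0L)
  expect_error(make_stack(rep(2, 3), ribosomes = c(1L, -2L, 0L)), "negative")

  # density: total / cytoplasm volume x 0.1, nearest-10 on report
  expect_equal(ribosome_density(8210, 0.58), 8210 / 0.58 * 0.1)
  expect_equal(ribosome_density(8210, 0.58, "nearest_10"), 1420)
  expect_equal(ribosome_density(12930, 1.30, "nearest_10"), 990)
  expect_equal(ribosome_density(0, 0.5), 0)
  expect_error(ribosome_density(100, 0), "positive")
  # per-section mean consistency: 9290 over 38 sections ~ 245/section
  # (reported to the nearest ribosome from unrounded data)
  expect_lt(abs(9290 / 38 - 245), 1)
})

test_that("quantify_cell recovers analytic truth and is internally consistent", {
  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54,
                            ribosome_density = 1170)
  st <- place_ribosomes(m, slice_model(m), seed = 3)
  p <- quantify_cell(st)
  tr <- analytic_truth(m)
  expect_rel_error_lt(p$vol_whole, tr$vol_whole, 0.02)
  expect_rel_error_lt(p$vol_cytoplasm, tr$vol_cytoplasm, 0.02)
  expect_rel_error_lt(p$surf_om, tr$surf_om, 0.05)
  expect_lt(abs(p$diam_om - tr$diam_om), 0.04)
  # conservation: profile total equals the generator's drawn count
  expect_identical(p$ribosomes_total, sum(st$sections$ribosomes))
  # additivity at full precision
  expect_equal(p$vol_whole,
               p$vol_om + p$vol_periplasm + p$vol_pm + p$vol_cytoplasm,
               tolerance = 1e-12)
  # density identity
  expect_equal(p$ribosome_density,
               p$ribosomes_total / p$vol_cytoplasm * 0.1, tolerance = 1e-12)

  # degenerate single-section stack: length and volume still defined,
  # surface area (needs two sections) raises
  one <- make_stack(2, a_om = 0.3, thickness = 0.04)
  expect_equal(cell_length(one), 0.04)
  expect_equal(compartment_volume(one, "om"), 0.3 * 0.04)
  expect_error(quantify_cell(one), "2 sections")
})

test_that("estimators are scale equivariant", {
  set.seed(21)
  for (rep in 1:5) {
    p <- stats::runif(30, 0.5, 2)
    st <- make_stack(p, thickness = 0.04)
    c_scale <- stats::runif(1, 0.5, 3)
    st_c <- make_stack(p * c_scale,
                       a_om = st$sections$a_om_um2 * c_scale^2,
                       p_pm = st$sections$p_pm_um * c_scale,
                       a_pm = st$sections$a_pm_um2 * c_scale^2,
                       thickness = 0.04 * c_scale)
    expect_equal(surface_area(st_c, "om"),
                 surface_area(st, "om") * c_scale^2, tolerance = 1e-10)
    expect_equal(compartment_volume(st_c, "om"),
                 compartment_volume(st, "om") * c_scale^3, tolerance = 1e-10)
    expect_equal(cell_length(st_c), cell_length(st) * c_scale,
                 tolerance = 1e-10)
  }
})

test_that("surface error equals the documented pole-cap bias; volume within 2%", {
  # trapezoid-of-perimeters underestimates each hemispherical cap by a
  # factor pi/4, a relative error of (4 - pi) * r / (2 L); discretization
  # adds less than one percentage point at 40-nm sections
  for (r in c(0.25, 0.35, 0.45)) {
    for (L in c(2, 3.54, 5, 8)) {
      m <- spherocylinder_model("sweep", radius_om = r, length_om = L)
      st <- slice_model(m)
      tr <- analytic_truth(m)
      vol_err <- abs(compartment_volume(st, "om") - tr$vol_whole) /
        tr$vol_whole
      expect_lt(vol_err, 0.02)
      surf_err <- (tr$surf_om - surface_area(st, "om")) / tr$surf_om
      cap_bias <- (4 - pi) * r / (2 * L)
      expect_lt(abs(surf_err - cap_bias), 0.01)
      expect_lt(abs(cell_diameter(st, "om") - 2 * r), st$thickness)
    }
  }
})

test_that("halving section thickness never worsens cylinder volume recovery", {
  for (L in c(1.97, 2.5, 3.54, 5.03)) {
    errs <- vapply(c(0.08, 0.04, 0.02, 0.01), function(t) {
      st <- make_cylinder_stack(L, t, a = 0.25)
      abs(compartment_volume(st, "om") - 0.25 * L)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-12))
  }
})
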