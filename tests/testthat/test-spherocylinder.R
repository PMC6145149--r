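# Synthetic spherocylinder generator: analytic geometry, slicing,
# ribosome placement.

test_that("model construction enforces geometric invariants", {
  expect_s3_class(spherocylinder_model("ok"), "spherocylinder_model")
  expect_error(spherocylinder_model(radius_om = 0.29, length_om = 0.5),
               "twice")
  expect_error(spherocylinder_model(envelope_width = 0.3), "exceed")
  expect_error(spherocylinder_model(envelope_width = 0, pm_thickness = 0),
               "positive")
  expect_error(spherocylinder_model(ribosome_density = -1))
})

test_that("cross sections match exact spherocylinder geometry", {
  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54)
  mid <- cross_section(m, 3.54 / 2)
  expect_equal(mid$r_om, 0.29)
  expect_equal(mid$p_om, 2 * pi * 0.29, tolerance = 1e-12)

  tip <- cross_section(m, 0)
  expect_equal(tip$r_om, 0)
  expect_equal(tip$a_om, 0)
  expect_equal(unlist(cross_section(m, -0.1)[-1]), rep(0, 6),
               ignore_attr = TRUE)
  expect_equal(unlist(cross_section(m, 3.6)[-1]), rep(0, 6),
               ignore_attr = TRUE)

  # inside a cap at distance r/2 from the cap sphere centre: Pythagoras
  z <- 0.29 - 0.29 / 2
  expect_equal(cross_section(m, z)$r_om, 0.29 * sqrt(3) / 2,
               tolerance = 1e-12)
  # numerical cross-check: largest rho with rho^2 + d^2 <= r^2
  d <- 0.29 / 2
  rho_star <- stats::uniroot(function(rho) rho^2 + d^2 - 0.29^2,
                             c(0, 0.29), tol = 1e-12)$root
  expect_equal(cross_section(m, z)$r_om, rho_star, tolerance = 1e-9)

  expect_error(cross_section(m, NaN), "finite")
})

test_that("slicing produces the expected section count and mid-segment", {
  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54)
  st <- slice_model(m, thickness = 0.04, offset = 0, noise_cv = 0)
  expect_equal(nrow(st$sections), ceiling(3.54 / 0.04))  # 89
  # mid-planes falling in the cylindrical segment have constant perimeter
  n_const <- sum(abs(st$sections$p_om_um - 2 * pi * 0.29) < 1e-12)
  expect_equal(n_const, 74)
  # agreement with the analytic cross-section oracle at every mid-plane
  z_mid <- (st$sections$section_index - 0.5) * 0.04
  expect_equal(st$sections$p_om_um, cross_section(m, z_mid)$p_om,
               tolerance = 1e-12)

  expect_error(slice_model(m, thickness = 0), "> 0")
  expect_error(slice_model(m, offset = 0.05), "offset")
})

test_that("slicing is deterministic without noise and seeded with noise", {
  m <- spherocylinder_model("c")
  expect_identical(slice_model(m, noise_cv = 0, seed = 1),
                   slice_model(m, noise_cv = 0, seed = 999))
  s1 <- slice_model(m, noise_cv = 0.05, seed = 42)
  s2 <- slice_model(m, noise_cv = 0.05, seed = 42)
  expect_identical(s1, s2)
  s3 <- slice_model(m, noise_cv = 0.05, seed = 43)
  expect_false(identical(s1$sections$p_om_um, s3$sections$p_om_um))
  expect_true(all(s1$sections$p_om_um >= 0))
})

test_that("ribosome placement is conserved, seeded and Poisson-calibrated", {
  m <- spherocylinder_model("c", ribosome_density = 1170)
  st <- slice_model(m)

  zero <- place_ribosomes(spherocylinder_model("z", ribosome_density = 0), st)
  expect_true(all(zero$sections$ribosomes == 0))

  expect_identical(place_ribosomes(m, st, seed = 7),
                   place_ribosomes(m, st, seed = 7))

  truth <- analytic_truth(m)
  expected_total <- truth$ribosome_density * truth$vol_cytoplasm / 0.1
  totals <- vapply(1:200, function(s) {
    sum(place_ribosomes(m, st, seed = s)$sections$ribosomes)
  }, numeric(1))
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected_total), 3 * se)
})

test_that("equal-volume sections receive exchangeable ribosome counts", {
  m <- spherocylinder_model("c", ribosome_density = 1170)
  st <- slice_model(m)
  n <- nrow(st$sections)
  # mirror-image sections about the cell centre have equal slab volumes
  i <- 10L
  j <- n + 1L - i
  counts <- t(vapply(1:500, function(s) {
    sec <- place_ribosomes(m, st, seed = 1000 + s)$sections$ribosomes
    c(sec[i], sec[j])
  }, numeric(2)))
  chi <- stats::chisq.test(colSums(counts), p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.01)
})

test_that("analytic truth matches the closed forms and a Monte Carlo oracle", {
  m <- spherocylinder_model("c", radius_om = 0.29, length_om = 3.54)
  tr <- analytic_truth(m)
  expect_equal(tr$vol_whole, pi * 0.29^2 * (3.54 - 0.58) +
                 (4 / 3) * pi * 0.29^3, tolerance = 1e-12)
  expect_equal(tr$surf_om, 2 * pi * 0.29 * (3.54 - 0.58) + 4 * pi * 0.29^2,
               tolerance = 1e-12)
  expect_equal(tr$vol_whole,
               tr$vol_om + tr$vol_periplasm + tr$vol_pm + tr$vol_cytoplasm,
               tolerance = 1e-12)

  # sphere limit: L = 2r collapses to a ball
  sph <- analytic_truth(spherocylinder_model("s", radius_om = 0.3,
                                             length_om = 0.6))
  expect_equal(sph$vol_whole, (4 / 3) * pi * 0.3^3, tolerance = 1e-12)
  expect_equal(sph$surf_om, 4 * pi * 0.3^2, tolerance = 1e-12)

  # Monte Carlo volume: uniform points in the bounding box, capsule test
  set.seed(11)
  n_pts <- 2e5
  r <- 0.29
  L <- 3.54
  x <- stats::runif(n_pts, -r, r)
  y <- stats::runif(n_pts, -r, r)
  z <- stats::runif(n_pts, 0, L)
  ax <- pmin(pmax(z, r), L - r)  # nearest point on the cylinder axis segment
  inside <- x^2 + y^2 + (z - ax)^2 <= r^2
  v_mc <- mean(inside) * (2 * r)^2 * L
  expect_rel_error_lt(tr$vol_whole, v_mc, 0.02)
})

test_that("simulate_section_stacks is reproducible per master seed", {
  models <- list(spherocylinder_model("a"),
                 spherocylinder_model("b", radius_om = 0.31, length_om = 4))
  s1 <- simulate_section_stacks(models, seed = 5)
  s2 <- simulate_section_stacks(models, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_section_stacks(models, seed = 6)
  expect_false(identical(s1[[1]]$sections$ribosomes,
                         s3[[1]]$sections$ribosomes))
})
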