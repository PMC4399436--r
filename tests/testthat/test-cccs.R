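test_that("radiological depth: constant, piecewise and dense-sampling oracle", {
  w <- water_grid(n = 41, spacing = 0.5)  # 20.5 cm cube of water
  expect_equal(radiological_depth(w, c(0, 0, -5), c(0, 0, 5)), 10)
  expect_equal(radiological_depth(w, c(0, 0, 0), c(0, 0, 0)), 0)
  # 5 cm water then lung (rho 0.25): 15 cm geometric -> 7.5 cm radiological
  rho <- array(1, c(21, 21, 40))
  rho[, , 1:20] <- 0.25  # low z half is lung
  g <- volume_grid(rho, 0.5, origin_cm = c(-5, -5, -9.75), kind = "density")
  # 5 cm of water (z 5 -> 0) then 10 cm of lung (z 0 -> -10)
  d <- radiological_depth(g, c(0, 0, 5), c(0, 0, -10))
  expect_equal(d, 5 + 10 * 0.25, tolerance = 1e-9)
  expect_error(radiological_depth(w, c(0, 0, NA), c(0, 0, 1)), "non-finite")

  # random oblique rays through a smoothly varying voxelized density
  # vs midpoint-rule fine sampling of the same voxel field
  set.seed(42)
  ax1 <- seq(-4.75, 4.75, by = 0.5)
  dens <- 1 + 0.4 * outer(outer(sin(ax1 / 2), cos(ax1 / 3)), sin(ax1 / 4 + 1))
  lg <- volume_grid(dens, 0.5, kind = "density")
  nray <- 300
  p0 <- cbind(runif(nray, -3, 3), runif(nray, -6, -5), runif(nray, -3, 3))
  p1 <- cbind(runif(nray, -3, 3), runif(nray, 5, 6), runif(nray, -3, 3))
  fast <- radiological_depth(lg, p0, p1)
  step <- 0.001
  oracle <- vapply(seq_len(nray), function(i) {
    L <- sqrt(sum((p1[i, ] - p0[i, ])^2))
    ts <- seq(step / 2, L - step / 2, by = step) / L
    pts <- cbind(p0[i, 1] + ts * (p1[i, 1] - p0[i, 1]),
                 p0[i, 2] + ts * (p1[i, 2] - p0[i, 2]),
                 p0[i, 3] + ts * (p1[i, 3] - p0[i, 3]))
    ix <- round((pts[, 1] - lg$origin_cm[1]) / 0.5) + 1
    iy <- round((pts[, 2] - lg$origin_cm[2]) / 0.5) + 1
    iz <- round((pts[, 3] - lg$origin_cm[3]) / 0.5) + 1
    ok <- ix >= 1 & ix <= 20 & iy >= 1 & iy <= 20 & iz >= 1 & iz <= 20
    sum(dens[cbind(ix[ok], iy[ok], iz[ok])]) * step
  }, numeric(1))
  expect_lt(max(abs(fast - oracle)), 1e-3)
})

test_that("TERMA: vacuum, zero fluence, monoenergetic closed form", {
  att <- attenuation_table(c(0.5, 2, 10), c(0.0968, 0.0494, 0.0222))
  sp <- beam_spectrum(2, 1)
  mu <- 0.0494
  fl <- make_square_fluence(8, spacing_cm = 0.25, extent_cm = 12)
  geom <- beam_geometry(0)
  # vacuum: pure fluence x inverse square x sum w mu
  vac <- volume_grid(array(0, c(11, 11, 21)), 0.5, kind = "density")
  tv <- compute_terma(fl, vac, sp, att, geom)
  ax <- grid_axes(vac)
  a <- 100 - ax$z  # distance from source along the axis
  expect_rel_equal(tv$values[6, 6, ], mu * (100 / a)^2, 1e-9)
  # zero fluence -> zero TERMA
  fl0 <- fluence_map(matrix(0, 21, 21), 0.25)
  expect_equal(max(compute_terma(fl0, vac, sp, att, geom)$values), 0)
  # homogeneous water central axis: T = T0 exp(-mu d) (SSD/(SSD+d))^2
  wat <- volume_grid(array(1, c(21, 21, 41)), 0.25, kind = "density")
  tw <- compute_terma(fl, wat, sp, att, geom)
  surface <- max(grid_axes(wat)$z) + 0.125  # grid top face
  ssd <- 100 - surface
  depth <- surface - grid_axes(wat)$z
  closed <- mu * exp(-mu * depth) * (100 / (ssd + depth))^2
  expect_rel_equal(tw$values[11, 11, ], closed, 1e-4)
})

test_that("brute-force oracle: symmetry and energy conservation", {
  tc <- test_cck()
  w <- water_grid(n = 15, spacing = 1)
  tm <- point_terma(n = 15, spacing = 1)
  d <- point_kernel_superpose_oracle(tm, w, tc$kernel)
  # mirror symmetry about the beam axis (x/y)
  expect_equal(d$values, d$values[15:1, , ], tolerance = 1e-12)
  expect_equal(d$values, aperm(d$values, c(2, 1, 3)), tolerance = 1e-12)
  # spherically banded: forward dose exceeds backward at same radius
  expect_gt(d$values[8, 8, 4], d$values[8, 8, 12])
  # energy conservation on a grid large enough to contain the kernel
  w2 <- water_grid(n = 21, spacing = 1)
  tm2 <- point_terma(n = 21, spacing = 1)
  d2 <- point_kernel_superpose_oracle(tm2, w2, tc$kernel)
  ratio <- sum(d2$values * w2$values) / sum(tm2$values * w2$values)
  expect_lt(abs(ratio - 1), 0.01)
  expect_error(point_kernel_superpose_oracle(
    point_terma(n = 33, spacing = 1), water_grid(n = 33, spacing = 1),
    tc$kernel), "cost guard")
})

test_that("collapsed cone matches the brute-force oracle in water", {
  tc <- test_cck()
  w <- water_grid(n = 21, spacing = 0.25)
  tm <- point_terma(n = 21, spacing = 0.25)
  dc <- collapsed_cone_superpose(tm, w, tc$cck, tc$cones)
  dor <- point_kernel_superpose_oracle(tm, w, tc$kernel)
  expect_equal(max(collapsed_cone_superpose(
    volume_grid(array(0, c(21, 21, 21)), 0.25, kind = "terma"),
    w, tc$cck, tc$cones)$values), 0)  # zero TERMA -> zero dose
  keep <- array(TRUE, c(21, 21, 21))
  keep[11, 11, 11] <- FALSE  # source voxel excluded
  dmax <- max(dor$values)
  diff <- abs(dc$values - dor$values)[keep]
  expect_lt(max(diff) / dmax, 0.03)
  expect_lt(mean(diff) / dmax, 0.01)
})

test_that("uniform rho = 0.5 dose maps onto the water curve (O'Connor)", {
  tc <- test_cck()
  half <- volume_grid(array(0.5, c(21, 21, 21)), 0.5, kind = "density")
  tmh <- point_terma(n = 21, spacing = 0.5)
  dh <- collapsed_cone_superpose(tmh, half, tc$cck, tc$cones)
  # water oracle on the radiologically equivalent lattice (spacing halved)
  wat <- water_grid(n = 21, spacing = 0.25)
  tmw <- point_terma(n = 21, spacing = 0.25)
  dw <- point_kernel_superpose_oracle(tmw, wat, tc$kernel)
  keep <- array(TRUE, c(21, 21, 21))
  keep[11, 11, 11] <- FALSE
  dmax <- max(dw$values)
  diff <- abs(dh$values - dw$values)[keep]
  expect_lt(max(diff) / dmax, 0.03)
  expect_lt(mean(diff) / dmax, 0.01)
})

test_that("plan reconstruction: linearity, symmetry, additivity", {
  tc <- test_cck()
  model <- list(spectrum = beam_spectrum(2, 1),
                attenuation = attenuation_table(c(0.5, 2, 10),
                                                c(0.0968, 0.0494, 0.0222)),
                kernel = tc$kernel, cones = tc$cones, cck = tc$cck)
  w <- water_grid(n = 15, spacing = 0.5)
  fl <- make_square_fluence(3, spacing_cm = 0.25, extent_cm = 8)
  f0 <- list(fluence = fl, gantry_deg = 0)
  f180 <- list(fluence = fl, gantry_deg = 180)
  one <- reconstruct_plan_dose(list(f0), w, model)
  two <- reconstruct_plan_dose(list(f0, f0), w, model)
  expect_identical(two$values, one$values + one$values)  # exact 2x
  # parallel-opposed fields on a symmetric water slab: mid-plane mirror
  pop <- reconstruct_plan_dose(list(f0, f180), w, model)
  expect_equal(pop$values, pop$values[, , 15:1], tolerance = 1e-6)
  # 3-field plan equals the sum of independently computed single fields
  f90 <- list(fluence = fl, gantry_deg = 90)
  plan <- reconstruct_plan_dose(list(f0, f90, f180), w, model)
  singles <- reconstruct_plan_dose(list(f0), w, model)$values +
    reconstruct_plan_dose(list(f90), w, model)$values +
    reconstruct_plan_dose(list(f180), w, model)$values
  expect_identical(plan$values, singles)
  expect_error(reconstruct_plan_dose(list(), w, model), "empty field")
})
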