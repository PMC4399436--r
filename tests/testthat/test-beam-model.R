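test_that("cone set follows the non-uniform zenith banding", {
  cs <- build_cone_set()
  expect_equal(length(cs$zenith_edges_deg) - 1L, 36L)  # 22 + 1 + 9 + 1 + 3
  expect_equal(cs$n_azimuth, 8L)
  expect_equal(nrow(cs$directions), 288L)
  expect_lt(max(abs(sqrt(rowSums(cs$directions^2)) - 1)), 1e-12)
  expect_lt(abs(sum(cs$solid_angle) - 4 * pi), 1e-9)
  # band weights match 2*pi*(cos t1 - cos t2)/8 exactly
  e <- cs$zenith_edges_deg * pi / 180
  expected <- 2 * pi * (cos(e[-37]) - cos(e[-1])) / 8
  expect_equal(unname(cs$solid_angle), expected[cs$band])
  # the five stated bands are present as sub-band boundaries
  expect_true(all(c(0, 44, 50, 95, 120, 180) %in% cs$zenith_edges_deg))
  expect_equal(sum(diff(cs$zenith_edges_deg[1:23])), 44)  # 22 uniform to 44
})

test_that("point kernel is normalized, forward peaked and non-negative", {
  pk <- test_kernel()
  expect_lt(abs(sum(pk$energy_fraction) - 1), 1e-9)
  expect_true(all(pk$energy_fraction >= 0))
  band_mass <- rowSums(pk$energy_fraction)
  expect_gt(sum(band_mass[1:22]), sum(band_mass[23:36]))  # forward peaked
})

test_that("CCK tables conserve energy and are monotone / convex", {
  tc <- test_cck()
  cck <- tc$cck
  expect_lt(abs(sum(cck$K[, ncol(cck$K)]) - 1), 1e-6)
  for (b in c(1, 10, 25, 36)) {
    expect_true(all(diff(cck$K[b, ]) >= -1e-15))          # K monotone
    expect_true(all(diff(diff(cck$C[b, ])) >= -1e-12))    # C convex
    expect_equal(cck$C[b, 1], 0)
  }
  expect_error(build_cck_table(
    structure(list(energy_fraction = tc$kernel$energy_fraction * 2,
                   zenith_edges_deg = tc$kernel$zenith_edges_deg,
                   radial_edges_cm = tc$kernel$radial_edges_cm,
                   band_solid_angle = tc$kernel$band_solid_angle),
              class = "point_kernel"),
    tc$cones), "not normalized")
})

test_that("C matches a 10x-finer trapezoid of the tabulated K", {
  tc <- test_cck()
  cck <- tc$cck
  r <- cck$r_cm
  fine <- seq(0, max(r), by = cck$radial_step_cm / 10)
  node <- seq(1, length(fine), by = 10)  # fine[node] == r
  for (b in c(1, 12, 30)) {
    Kf <- approxfun(r, cck$K[b, ])(fine)
    Cf <- c(0, cumsum((Kf[-1] + Kf[-length(Kf)]) / 2 * diff(fine)))
    Cref <- Cf[node]
    sel <- Cref > 1e-12
    expect_lt(max(abs(cck$C[b, sel] / Cref[sel] - 1)), 1e-6)
  }
})

test_that("finite differences relate k, K and C at the table step", {
  # slowly varying kernel so the tabulation resolves the radial shape
  cones <- build_cone_set()
  pk <- make_point_kernel(a = 0.2, b = 0.05,
                          radial_edges_cm = seq(0, 30, by = 0.05))
  cck <- build_cck_table(pk, cones, radial_step_cm = 0.05, r_max_cm = 30)
  h <- cck$radial_step_cm
  i <- 10:400
  for (b in c(2, 20)) {
    dC <- (cck$C[b, i + 1] - cck$C[b, i - 1]) / (2 * h)
    expect_lt(max(abs(dC / cck$K[b, i] - 1), na.rm = TRUE), 1e-3)
    # forward difference of K recovers the bin density (exact integration)
    dK <- (cck$K[b, i + 1] - cck$K[b, i]) / h
    sel <- cck$k[b, i] > 0
    expect_lt(max(abs(dK[sel] / cck$k[b, i][sel] - 1)), 1e-9)
  }
})

test_that("attenuation lookup: node-exact, log-log consistent, monotone", {
  att <- water_attenuation()
  expect_equal(attenuation_lookup(att, att$energies_MeV),
               att$mu_over_rho_cm2_g)
  # geometric-mean query returns the geometric mean of adjacent values
  e <- att$energies_MeV
  m <- att$mu_over_rho_cm2_g
  gm <- sqrt(e[10] * e[11])
  expect_equal(attenuation_lookup(att, gm), sqrt(m[10] * m[11]),
               tolerance = 1e-12)
  # dense scan is monotone over the monotone part of the table
  scan <- attenuation_lookup(att, exp(seq(log(0.02), log(20),
                                          length.out = 500)))
  expect_true(all(diff(scan) < 0))
  expect_error(attenuation_lookup(att, 50), "range error")
  expect_error(attenuation_lookup(att, 0.001), "range error")
})

test_that("bundled spectra load and validate", {
  for (en in c("6MV", "10MV")) {
    sp <- default_spectrum(en)
    expect_lt(abs(sum(sp$weights) - 1), 1e-9)
    expect_true(all(diff(sp$energies_MeV) > 0))
  }
  expect_gt(sum(default_spectrum("10MV")$energies_MeV *
                default_spectrum("10MV")$weights),
            sum(default_spectrum("6MV")$energies_MeV *
                default_spectrum("6MV")$weights))
  expect_error(beam_spectrum(c(1, 2), c(-1, 2)), "non-negative")
  expect_error(beam_spectrum(c(2, 1), c(1, 1)), "ascending")
})
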