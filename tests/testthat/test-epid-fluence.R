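test_that("scatter kernel evaluates the two-exponential form and normalizes", {
  # raw values at known radii (5x5 grid, 1 cm pitch)
  k <- epid_scatter_kernel(kernel_params(0.5, 0.8, 0.05), c(5, 5), 1,
                           normalize = FALSE)
  expect_equal(k[3, 3], 1.0)                               # d = 0
  expect_equal(k[3, 5], 0.5 * exp(-1.6) + 0.5 * exp(-0.1)) # d = 2 cm
  expect_equal(round(k[3, 5], 4), 0.5534)
  k1 <- epid_scatter_kernel(kernel_params(1, 0.8, 0.05), c(5, 5), 1,
                            normalize = FALSE)
  expect_equal(k1[3, 5], exp(-0.1))                        # single-term limit
  # normalization and symmetry
  kn <- epid_scatter_kernel(kernel_params(), c(31, 31), 0.1)
  expect_lt(abs(sum(kn) - 1), 1e-9)
  expect_equal(kn, kn[31:1, ]) # radial symmetry
  expect_equal(kn, t(kn))
  # errors
  expect_error(epid_scatter_kernel(kernel_params(), c(5, 5), -1), "pitch")
  expect_error(epid_scatter_kernel(kernel_params(), c(4, 5), 0.1), "odd")
})

test_that("epid_image and correction model validate their invariants", {
  expect_error(epid_image(matrix(-1, 2, 2)), "non-negative")
  expect_error(epid_image(matrix(1, 2, 2), pixel_pitch_cm = 0), "pitch")
  expect_error(correction_model(backscatter_sigma_cm = -1), "sigma")
  expect_error(correction_model(displacement_table = data.frame(
    gantry_deg = 0, dx_cm = 0.1, dy_cm = 0)), "gantry 0")
  expect_error(kernel_params(c = 1.5), "c must be")
})

test_that("backscatter correction: zero amplitude, constants, round trip", {
  img <- epid_image(matrix(runif(41 * 41), 41, 41), pixel_pitch_cm = 0.1)
  m0 <- correction_model(backscatter_amplitude = 0)
  expect_equal(correct_backscatter(img, m0)$pixels, img$pixels)
  # unit-sum kernel preserves constants: uniform image scaled by (1 - a)
  uni <- epid_image(matrix(1, 81, 81), pixel_pitch_cm = 0.1)
  mf <- correction_model(backscatter_amplitude = 0.1,
                         backscatter_sigma_cm = 0.3,
                         backscatter_support = "full")
  out <- correct_backscatter(uni, mf)
  ctr <- out$pixels[30:52, 30:52]  # away from edges
  expect_lt(max(abs(ctr - 0.9)), 1e-6)
  # forward-model round trip: ghosted image corrected back to clean
  kp <- kernel_params()
  cm <- correction_model(backscatter_amplitude = 0.04,
                         backscatter_sigma_cm = 1.0, horn_amplitude = 0,
                         noise_filter_range_cm = 0)
  fl <- make_square_fluence(6, spacing_cm = 0.1 / 1.4, extent_cm = 12)
  clean <- simulate_epid_image(fl, kp, cm)
  ghosted <- simulate_epid_image(fl, kp, cm, ghost = TRUE)
  rec <- correct_backscatter(ghosted, cm)
  n <- nrow(rec$pixels)
  infield <- abs((seq_len(n) - (n + 1) / 2) * 0.1) <= 2.5
  expect_lt(max(abs(rec$pixels[infield, infield] -
                    clean$pixels[infield, infield])) / max(clean$pixels),
            0.005)
  # double application is a state error
  expect_error(correct_backscatter(rec, cm), "state error")
})

test_that("gantry displacement: identity, pixel roll, sub-pixel round trip", {
  set.seed(7)
  base <- outer(dnorm(seq(-1.2, 1.2, length.out = 61)),
                dnorm(seq(-1.2, 1.2, length.out = 61)))
  img <- epid_image(base, pixel_pitch_cm = 0.1)
  tab0 <- data.frame(gantry_deg = c(0, 180), dx_cm = c(0, 0), dy_cm = c(0, 0))
  expect_equal(correct_gantry_displacement(img, tab0)$pixels, img$pixels)
  # lattice-commensurate shift = integer roll of the matrix
  img90 <- epid_image(base, pixel_pitch_cm = 0.1, gantry_deg = 90)
  tab1 <- data.frame(gantry_deg = c(0, 90), dx_cm = c(0, 0.1), dy_cm = c(0, 0))
  rolled <- correct_gantry_displacement(img90, tab1)$pixels
  expect_equal(rolled[, 1:60], base[, 2:61])
  # random sub-pixel displacement, then its inverse: interpolation tolerance
  d <- c(0.033, -0.047)
  tab <- data.frame(gantry_deg = c(0, 90), dx_cm = c(0, d[1]),
                    dy_cm = c(0, d[2]))
  shifted <- epidose:::shift_bilinear(base, -d[2] / 0.1, -d[1] / 0.1)
  rec <- correct_gantry_displacement(
    epid_image(pmax(shifted, 0), pixel_pitch_cm = 0.1, gantry_deg = 90), tab)
  interior <- 5:57
  expect_lt(max(abs(rec$pixels[interior, interior] -
                    base[interior, interior])), 1e-3 * max(base))
  expect_error(correct_gantry_displacement(rec, tab), "state error")
})

test_that("deconvolution: delta kernel identity, linearity, round trip", {
  cm <- correction_model(noise_filter_range_cm = 0, c_ad = 2.5)
  flags <- c("backscatter", "displacement")
  img <- epid_image(matrix(runif(51 * 51), 51, 51), pixel_pitch_cm = 0.1,
                    corrected = flags)
  # discrete delta kernel (c = 0, huge mu_s): output = c_ad * P
  delta <- kernel_params(0, 400, 0.1)
  out <- deconvolve_to_fluence(img, delta, cm)
  expect_lt(max(abs(out$values - 2.5 * img$pixels)), 1e-8)
  # zero image -> zero fluence
  z <- epid_image(matrix(0, 31, 31), pixel_pitch_cm = 0.1, corrected = flags)
  expect_equal(max(abs(deconvolve_to_fluence(z, kernel_params(), cm)$values)),
               0)
  # corrections must be flagged first
  raw <- epid_image(matrix(1, 31, 31), pixel_pitch_cm = 0.1)
  expect_error(deconvolve_to_fluence(raw, kernel_params(), cm), "corrections")
  # linearity: doubling P doubles the fluence
  img2 <- epid_image(2 * img$pixels, pixel_pitch_cm = 0.1, corrected = flags)
  expect_equal(deconvolve_to_fluence(img2, kernel_params(), cm)$values,
               2 * deconvolve_to_fluence(img, kernel_params(), cm)$values)
})

test_that("forward simulation inverts: fluence round trip within 1% in-field", {
  kp <- kernel_params()
  cm <- correction_model(noise_filter_range_cm = 0, horn_amplitude = 0)
  fl <- make_square_fluence(6, spacing_cm = 0.1 / 1.4, penumbra_sigma_cm = 0.25,
                            extent_cm = 14)
  img <- simulate_epid_image(fl, kp, cm)
  rec <- epid_to_fluence(img, kp, cm)
  expect_equal(dim(rec$values), dim(fl$values))
  expect_equal(rec$spacing_cm, fl$spacing_cm)
  ax <- fluence_axes(fl)
  infield <- abs(ax$x) <= 2  # >= 1 cm inside the 6 cm field edge
  expect_lt(max(abs(rec$values[infield, infield] -
                    fl$values[infield, infield])) / max(fl$values), 0.01)
})

test_that("horn correction is the stated multiplicative radial map", {
  fl <- make_square_fluence(8, spacing_cm = 0.2, extent_cm = 16)
  m0 <- correction_model(horn_amplitude = 0)
  expect_equal(horn_correct(fl, m0)$values, fl$values)
  m <- correction_model(horn_amplitude = 0.08, horn_sigma_cm = 5)
  out <- horn_correct(fl, m)
  ctr <- (nrow(fl$values) + 1) / 2
  expect_equal(out$values[ctr, ctr], fl$values[ctr, ctr])  # r = 0 unchanged
  # profile with synthetic horns of the same parametric form flattens out
  ax <- fluence_axes(fl)
  r2 <- outer(ax$y^2, ax$x^2, "+")
  horned <- fluence_map(fl$values * (1 + 0.08 * (1 - exp(-r2 / (2 * 25)))),
                        fl$spacing_cm)
  flat <- horn_correct(horned, m)
  infield <- abs(ax$x) < 4
  expect_lt(max(abs(flat$values[infield, infield] -
                    fl$values[infield, infield])), 0.002)
})

test_that("projection to the isocenter plane rescales geometry and intensity", {
  fl <- fluence_map(matrix(1, 11, 11), spacing_cm = 0.04)
  expect_equal(project_to_isocenter(fl, sdd_cm = 100, sad_cm = 100), fl)
  iso <- project_to_isocenter(fl, sdd_cm = 140, sad_cm = 100)
  expect_equal(iso$spacing_cm, 0.04 * 100 / 140, tolerance = 1e-12)
  expect_equal(round(iso$spacing_cm, 6), 0.028571)
  expect_equal(unique(as.numeric(iso$values)), 1.96)
  expect_error(project_to_isocenter(fl, sdd_cm = 90, sad_cm = 100), "sdd")
})
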