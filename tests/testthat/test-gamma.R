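test_that("trilinear resampling: identity, affine exactness, error bound", {
  g <- smooth_field_3d(n = 12, seed = 3, spacing = 0.2)
  expect_equal(resample_trilinear(g, 0.2)$values, g$values, tolerance = 1e-12)
  # linear ramps are reproduced exactly at any spacing
  ax <- grid_axes(g)
  ramp <- volume_grid(outer(outer(2 * ax$x + 1, 0.5 * ax$y, "+"),
                            -ax$z, "+"), 0.2, kind = "generic")
  rs <- resample_trilinear(ramp, 0.07)
  rax <- grid_axes(rs)
  expected <- outer(outer(2 * rax$x + 1, 0.5 * rax$y, "+"), -rax$z, "+")
  expect_equal(rs$values, expected, tolerance = 1e-12)
  # down-then-up stays below a second-difference bound for smooth fields
  down <- resample_trilinear(g, 0.4)
  up <- resample_trilinear(down, 0.2)
  second_diff <- max(abs(diff(g$values, differences = 2)))
  expect_lt(max(abs(up$values - g$values[1:dim(up$values)[1],
                                         1:dim(up$values)[2],
                                         1:dim(up$values)[3]])),
            3 * second_diff)
  expect_error(resample_trilinear(volume_grid(array(1, c(1, 5, 5)), 0.1), 0.05),
               "degenerate")
})

test_that("gamma: identical fields, criterion boundary, threshold handling", {
  f <- flat_top_field(n = 21, spacing = 0.1)
  crit <- gamma_criteria(3, 3, 10)
  same <- gamma_3d(f, f, crit)
  expect_equal(same$pass_rate_pct, 100)
  expect_equal(max(same$gamma$values, na.rm = TRUE), 0)
  expect_equal(same$n_evaluated, sum(!is.na(same$gamma$values)))
  # threshold: voxels at or below 10% of reference max are NA-excluded
  expect_true(all(is.na(same$gamma$values[f$values <= 0.1 * max(f$values)])))
  expect_equal(same$n_evaluated, sum(f$values > 0.1 * max(f$values)))
  # uniform 3% scaling on a flat-topped field: gamma is exactly 1 on the
  # plateau (dose term at criterion, distance 0) and everything passes
  scaled <- volume_grid(f$values * 1.03, f$spacing_cm, f$origin_cm, "dose")
  g <- gamma_3d(f, scaled, crit)
  ctr <- (dim(f$values) + 1) / 2
  expect_equal(g$gamma$values[ctr[1], ctr[2], ctr[3]], 1, tolerance = 1e-9)
  expect_equal(g$pass_rate_pct, 100)  # inclusive gamma <= 1
  expect_error(gamma_3d(f, resample_trilinear(f, 0.05), crit), "lattice")
  tiny <- volume_grid(array(1e-9, c(3, 3, 3)) * 0, 0.1, kind = "dose")
  expect_error(gamma_3d(tiny, tiny, crit), "empty result")
})

test_that("shell search agrees with the exhaustive oracle on random fields", {
  for (seed in 1:3) {
    pair <- perturbed_pair(n = 16, seed = seed)
    crit <- gamma_criteria(3, 3, 10)
    fast <- gamma_3d(pair$ref, pair$ev, crit)
    slow <- gamma_bruteforce_oracle(pair$ref, pair$ev, crit)
    expect_lt(max(abs(fast$gamma$values - slow$gamma$values), na.rm = TRUE),
              0.01)
    expect_equal(fast$pass_rate_pct, slow$pass_rate_pct)
  }
  expect_error(gamma_bruteforce_oracle(smooth_field_3d(n = 30),
                                       smooth_field_3d(n = 30)),
               "cost guard")
})

test_that("loosening criteria never lowers pass status", {
  for (seed in 4:8) {
    pair <- perturbed_pair(n = 14, seed = seed, rel = 0.015, blob_pct = 0.04)
    ref <- pair$ref; ev <- pair$ev
    g33 <- gamma_3d(ref, ev, gamma_criteria(3, 3, 10))
    g22 <- gamma_3d(ref, ev, gamma_criteria(2, 2, 10))
    expect_gte(g33$pass_rate_pct, g22$pass_rate_pct)
    # voxel-wise: gamma under looser criteria is never larger
    expect_true(all(g33$gamma$values <= g22$gamma$values + 1e-12,
                    na.rm = TRUE))
  }
})

test_that("gamma is invariant under a common rigid translation", {
  pair <- perturbed_pair(n = 16, seed = 11)
  ref <- pair$ref; ev <- pair$ev
  g0 <- gamma_3d(ref, ev, gamma_criteria(3, 3, 10))
  shift <- c(0.53, -1.1, 0.2)
  refs <- volume_grid(ref$values, ref$spacing_cm, ref$origin_cm + shift, "dose")
  evs <- volume_grid(ev$values, ev$spacing_cm, ev$origin_cm + shift, "dose")
  gs <- gamma_3d(refs, evs, gamma_criteria(3, 3, 10))
  expect_identical(g0$gamma$values, gs$gamma$values)
  expect_identical(g0$pass_rate_pct, gs$pass_rate_pct)
})

test_that("criteria validation", {
  expect_error(gamma_criteria(0, 3, 10), "positive")
  expect_error(gamma_criteria(3, 3, 10, gamma_cap = 0.5), "gamma_cap")
})
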