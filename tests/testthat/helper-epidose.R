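# Shared fixtures, built in code. Everything is deterministic under the seeds
# set here; nothing is read from disk.

# compact-support point kernel + CCK used by the engine tests: decays within
# ~10 cm so modest grids contain essentially all of the energy
test_kernel <- function(r_max = 15, step = 0.05)
  make_point_kernel(a = 3, b = 0.8, radial_edges_cm = seq(0, r_max, by = step))

test_cck <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cones <- build_cone_set()
      cache <<- list(cones = cones,
                     kernel = test_kernel(),
                     cck = build_cck_table(test_kernel(), cones,
                                           radial_step_cm = 0.05,
                                           r_max_cm = 15))
    }
    cache
  }
})

# uniform grid of relative electron density
water_grid <- function(n = 21, spacing = 0.25, rho = 1)
  volume_grid(array(rho, c(n, n, n)), spacing, kind = "density")

# point-like TERMA at the grid center
point_terma <- function(n = 21, spacing = 0.25, value = 1) {
  tv <- array(0, c(n, n, n))
  tv[(n + 1) / 2, (n + 1) / 2, (n + 1) / 2] <- value
  volume_grid(tv, spacing, kind = "terma")
}

# smooth positive 3D field: plateau plus a few random Gaussian blobs
smooth_field_3d <- function(n = 20, seed = 1, spacing = 0.1, base = 1,
                            n_blobs = 4, amp = 0.5, sig_range = c(0.15, 0.4)) {
  set.seed(seed)
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  v <- array(base, c(n, n, n))
  for (b in seq_len(n_blobs)) {
    ctr <- runif(3, min(ax), max(ax))
    sig <- runif(1, sig_range[1], sig_range[2])
    a <- runif(1, -amp, amp)
    g1 <- exp(-(ax - ctr[1])^2 / (2 * sig^2))
    g2 <- exp(-(ax - ctr[2])^2 / (2 * sig^2))
    g3 <- exp(-(ax - ctr[3])^2 / (2 * sig^2))
    v <- v + a * outer(outer(g1, g2), g3)
  }
  volume_grid(pmax(v, 0), spacing, kind = "dose")
}

# flat-topped separable 3D "field": an exactly flat plateau (half-width
# `plateau` cm) with a cosine taper of width `taper` cm, spacing in cm
flat_top_field <- function(n = 25, spacing = 0.1, plateau = 0.45,
                           taper = 0.5) {
  ax <- abs((seq_len(n) - (n + 1) / 2) * spacing)
  e <- ifelse(ax <= plateau, 1,
              0.5 * (1 + cos(pi * pmin((ax - plateau) / taper, 1))))
  volume_grid(outer(outer(e, e), e), spacing, kind = "dose")
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}

# scaled-down synthetic slab plan for end-to-end pipeline runs: a 10 cm
# muscle/bone/lung stack, 6 cm lateral, two parallel-opposed 4 cm fields.
# Grid sizes are kept small so the full chain (including 1 mm gamma
# resampling) runs in seconds on one CPU.
small_plan_config <- function(perturb = 0.01, blob = 0.03) {
  tc <- test_cck()
  model <- list(spectrum = beam_spectrum(2, 1),
                attenuation = attenuation_table(c(0.5, 2, 10),
                                                c(0.0968, 0.0494, 0.0222)),
                kernel = tc$kernel, cones = tc$cones, cck = tc$cck)
  density <- make_slab_phantom(slab_spec(
    data.frame(material = c("muscle", "bone", "lung", "muscle"),
               thickness_cm = c(2.8, 1.2, 3.2, 2.8)),
    lateral_cm = 6, spacing_cm = 0.4))
  fl <- make_square_fluence(4, spacing_cm = 0.25, penumbra_sigma_cm = 0.2,
                            extent_cm = 7)
  fields <- list(list(fluence = fl, gantry_deg = 0),
                 list(fluence = fl, gantry_deg = 180))
  # deterministic synthetic "planned" dose: the engine's own dose, scaled and
  # locally perturbed so the gamma comparison is non-trivial
  dose <- reconstruct_plan_dose(fields, density, model)
  ax <- grid_axes(dose)
  bump <- outer(outer(exp(-ax$x^2 / 0.5), exp(-ax$y^2 / 0.5)),
                exp(-(ax$z - 1)^2 / 0.5))
  planned <- volume_grid(dose$values * (1 + perturb) + blob * max(dose$values) * bump,
                         dose$spacing_cm, dose$origin_cm, kind = "dose")
  d <- dim(density$values)
  ptv <- array(FALSE, d)
  ptv[8:13, 8:13, 10:16] <- TRUE
  list(energy = "6MV", fields = fields, density = density, planned = planned,
       beam_model = model, prescribed_Gy = 66,
       structures = list(PTV = ptv, BODY = array(TRUE, d)),
       gamma_criteria = list(c(3, 3), c(2, 2)), seed = 1L)
}

# reference/evaluated dose pair that differs the way a QA comparison does:
# a uniform scale error plus smooth local deviations of a few percent of the
# maximum. Gradients stay at clinical scale (a few %/mm at 1 mm resolution).
perturbed_pair <- function(n = 20, seed = 1, spacing = 0.1, rel = 0.01,
                           blob_pct = 0.03) {
  ref <- smooth_field_3d(n, seed, spacing, base = 1, n_blobs = 3, amp = 0.25,
                         sig_range = c(0.8, 1.5))
  dev <- smooth_field_3d(n, seed + 7919, spacing, base = 0, n_blobs = 3,
                         amp = 1, sig_range = c(0.8, 1.5))
  dev <- dev$values / max(abs(dev$values), 1e-12) * blob_pct * max(ref$values)
  ev <- volume_grid(pmax(ref$values * (1 + rel) + dev, 0),
                    spacing, ref$origin_cm, kind = "dose")
  list(ref = ref, ev = ev)
}
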