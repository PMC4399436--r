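#' Beam geometry for a treatment field
#'
#' IEC-style gantry rotation about the isocenter's y axis: at gantry 0 the
#' source sits at `(0, 0, sad)` and the beam travels along `-z`; positive
#' gantry angles rotate the source about y. Collimator and couch rotations
#' are not modeled.
#'
#' @param gantry_deg gantry angle (degrees).
#' @param sad_cm source-to-axis distance (cm), default 100.
#' @param isocenter_cm isocenter position in grid coordinates (cm).
#' @return an object of class `beam_geometry` with the source position and
#'   the beam-frame axes `u` (cross-plane), `v` (in-plane) and `b` (beam
#'   travel direction).
#' @export
beam_geometry <- function(gantry_deg = 0, sad_cm = 100,
                          isocenter_cm = c(0, 0, 0)) {
  if (sad_cm <= 0) stop("invalid argument: sad_cm must be > 0")
  g <- gantry_deg * pi / 180
  Ry <- matrix(c(cos(g), 0, -sin(g),
                 0,      1,  0,
                 sin(g), 0,  cos(g)), 3, 3)
  source <- isocenter_cm + sad_cm * c(sin(g), 0, cos(g))
  structure(list(gantry_deg = gantry_deg, sad_cm = sad_cm,
                 isocenter_cm = isocenter_cm,
                 source_cm = source,
                 u = as.numeric(Ry %*% c(1, 0, 0)),
                 v = c(0, 1, 0),
                 b = as.numeric(Ry %*% c(0, 0, -1)),
                 rotation = Ry),
            class = "beam_geometry")
}

# rotate canonical cone directions (zenith about +z = travel direction) into
# the world frame so the kernel axis follows the beam axis (no per-ray tilt)
rotate_cone_directions <- function(cones, geom) {
  flip <- diag(c(1, -1, -1))  # maps +z onto -z (proper rotation about x)
  M <- geom$rotation %*% flip
  cones$directions %*% t(M)
}

#' Radiological depth along a ray segment
#'
#' Water-equivalent path length `int rho_rel dl` from `source_cm` to
#' `target_cm` through the density grid, computed by exact voxel-boundary
#' traversal; portions of the segment outside the grid contribute zero.
#'
#' @param density a [volume_grid] of relative electron density.
#' @param source_cm,target_cm length-3 points or n x 3 matrices (cm).
#' @return water-equivalent depth(s) in cm.
#' @export
radiological_depth <- function(density, source_cm, target_cm) {
  p0 <- if (is.matrix(source_cm)) source_cm else matrix(source_cm, 1)
  p1 <- if (is.matrix(target_cm)) target_cm else matrix(target_cm, 1)
  if (any(!is.finite(p0)) || any(!is.finite(p1)))
    stop("invalid argument: non-finite coordinates")
  .rad_depth_cpp(density$values, density$spacing_cm, density$origin_cm, p0, p1)
}

#' TERMA by divergent ray tracing
#'
#' Total energy released per unit mass by primary photons: for each voxel one
#' divergent ray is cast from the source through the voxel center (matching
#' the O(N^3) design of the engine). The incident fluence is looked up
#' bilinearly at the ray's crossing of the isocenter plane, scaled by inverse
#' square, and attenuated per spectrum bin:
#' `T = F * (SAD/a)^2 * sum_E w_E (mu/rho)_E exp(-(mu/rho)_E * rho_w * d_rad)`
#' with `d_rad` the radiological depth from the source and `rho_w = 1 g/cm^3`.
#'
#' @param fluence a [fluence_map] at the isocenter plane (beam frame).
#' @param density a [volume_grid] of relative electron density.
#' @param spectrum a [beam_spectrum].
#' @param attenuation an [attenuation_table] covering the spectrum support.
#' @param geom a [beam_geometry].
#' @return a TERMA [volume_grid] on the density lattice.
#' @export
compute_terma <- function(fluence, density, spectrum, attenuation, geom) {
  mu <- attenuation_lookup(attenuation, spectrum$energies_MeV)
  v <- .terma_cpp(density$values, density$spacing_cm, density$origin_cm,
                  fluence$values, rep(fluence$spacing_cm, 2), fluence$origin_cm,
                  geom$source_cm, geom$u, geom$v, geom$b, geom$sad_cm,
                  mu, spectrum$weights)
  volume_grid(v, density$spacing_cm, density$origin_cm, kind = "terma")
}

#' Collapsed-cone superposition of TERMA with CCK transport
#'
#' For each receiving voxel and each cone direction, a ray is marched
#' upstream through the grid by exact voxel-boundary traversal, accumulating
#' energy from TERMA via cumulative-kernel differences evaluated at the
#' density-scaled (radiological) radius; kernels are scaled by the electron
#' densities between interaction and receiving points, and the deposition is
#' averaged over the receiving voxel's radiological chord using the
#' cumulative-cumulative kernel (see [build_cck_table()]). Kernel axes stay
#' aligned with the beam axis (standard collapsed-cone approximation, no
#' divergence tilt).
#'
#' @param terma a TERMA [volume_grid].
#' @param density the co-registered density [volume_grid].
#' @param cck a [cck_table].
#' @param cones the matching [cone_set].
#' @param geom a [beam_geometry] (orients the kernel axis); default gantry 0.
#' @param use_cck logical; `FALSE` falls back to plain cumulative-kernel
#'   point lookup (no receiving-voxel integration).
#' @return a dose [volume_grid] (Gy-proportional).
#' @export
collapsed_cone_superpose <- function(terma, density, cck, cones,
                                     geom = beam_geometry(), use_cck = TRUE) {
  stopifnot_same_lattice(terma, density)
  nb <- nrow(cck$K)
  if (nb != length(cones$zenith_edges_deg) - 1L)
    stop("invalid argument: CCK bands do not match the cone set")
  dirs <- rotate_cone_directions(cones, geom)
  v <- .collapse_cone_cpp(terma$values, density$values, density$spacing_cm,
                          density$origin_cm, dirs, cones$band, cck$K, cck$C,
                          cck$radial_step_cm, max(cck$r_cm),
                          1 / cones$n_azimuth, use_cck)
  volume_grid(v, density$spacing_cm, density$origin_cm, kind = "dose")
}

#' Brute-force point-kernel superposition (test oracle)
#'
#' Exact double sum over (interaction, receiving) voxel pairs with
#' straight-line density scaling of the kernel radius. O(N^6): guarded to
#' grids of at most 31^3 voxels; intended for tests only.
#'
#' @param terma a TERMA [volume_grid].
#' @param density co-registered density [volume_grid].
#' @param kernel a [point_kernel].
#' @param geom a [beam_geometry] (kernel axis orientation).
#' @return a dose [volume_grid].
#' @export
point_kernel_superpose_oracle <- function(terma, density, kernel,
                                          geom = beam_geometry()) {
  stopifnot_same_lattice(terma, density)
  if (prod(dim(density$values)) > 31^3)
    stop("cost guard: oracle restricted to grids <= 31^3 voxels")
  edges <- kernel$radial_edges_cm
  r <- edges  # tabulate k and K at kernel edges (uniform grid required)
  dr <- diff(edges)[1]
  nb <- length(kernel$zenith_edges_deg) - 1L
  ktab <- matrix(0, nb, length(r))
  Ktab <- matrix(0, nb, length(r))
  for (bnd in seq_len(nb)) {
    dens <- kernel$energy_fraction[bnd, ] / diff(edges)
    ktab[bnd, ] <- c(dens, 0)
    Ktab[bnd, ] <- c(0, cumsum(kernel$energy_fraction[bnd, ]))
  }
  v <- .point_kernel_superpose_cpp(terma$values, density$values,
                                   density$spacing_cm, density$origin_cm,
                                   geom$b,  # kernel axis = travel direction
                                   kernel$zenith_edges_deg * pi / 180,
                                   kernel$band_solid_angle, ktab, Ktab, dr)
  volume_grid(v, density$spacing_cm, density$origin_cm, kind = "dose")
}

#' Reconstruct plan dose from per-field fluence maps
#'
#' Runs TERMA + collapsed-cone superposition per field in the gantry-rotated
#' beam frame and sums over fields; absolute scale is carried by the `c_ad`
#' calibration already folded into the fluence maps.
#'
#' @param fields list of `list(fluence = <fluence_map>, gantry_deg = <num>)`.
#' @param density a [volume_grid] of relative electron density.
#' @param model a [beam_model()] list.
#' @param sad_cm source-to-axis distance (cm).
#' @return total dose [volume_grid].
#' @export
reconstruct_plan_dose <- function(fields, density, model, sad_cm = 100) {
  if (!length(fields)) stop("invalid argument: empty field list")
  total <- NULL
  for (fd in fields) {
    geom <- beam_geometry(fd$gantry_deg, sad_cm = sad_cm)
    terma <- compute_terma(fd$fluence, density, model$spectrum,
                           model$attenuation, geom)
    dose <- collapsed_cone_superpose(terma, density, model$cck, model$cones,
                                     geom)
    total <- if (is.null(total)) dose$values else total + dose$values
  }
  volume_grid(total, density$spacing_cm, density$origin_cm, kind = "dose")
}
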