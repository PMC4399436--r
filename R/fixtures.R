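#' Tissue mass densities used by the slab phantom (g/cm^3)
#'
#' Adipose 0.920, muscle 1.040, bone 1.850, lung 0.250 and water 1.000.
#' Fixtures store relative electron density and map these mass densities to
#' it by identity -- an approximation (electron density per gram differs
#' slightly between tissues) that is documented rather than corrected, since
#' engine validation runs against an oracle using the same grids.
#' @export
slab_material_densities <- c(adipose = 0.920, muscle = 1.040, bone = 1.850,
                             lung = 0.250, water = 1.000)

#' Slab-phantom specification
#'
#' @param layers data frame with columns `material` (one of
#'   `r paste(names(slab_material_densities), collapse = ", ")`) and
#'   `thickness_cm` (> 0), ordered from the beam-entry surface inward.
#' @param lateral_cm lateral (x and y) extent (cm).
#' @param spacing_cm isotropic voxel spacing (cm), default 0.3.
#' @return an object of class `slab_spec`.
#' @export
slab_spec <- function(layers, lateral_cm = 30, spacing_cm = 0.3) {
  if (!is.data.frame(layers) || !nrow(layers))
    stop("invalid argument: need at least one layer")
  stopifnot(all(c("material", "thickness_cm") %in% names(layers)))
  if (!all(layers$material %in% names(slab_material_densities)))
    stop("unknown material label")
  if (any(layers$thickness_cm <= 0))
    stop("invalid argument: layer thicknesses must be > 0")
  structure(list(layers = layers, lateral_cm = lateral_cm,
                 spacing_cm = spacing_cm), class = "slab_spec")
}

#' Preset 30 cm heterogeneous slab phantom
#'
#' A muscle / bone / muscle / lung / muscle stack totaling 30 cm -- a
#' plausible arrangement of the published phantom materials (the exact layer
#' geometry is only available graphically and is user-overridable).
#' @param spacing_cm voxel spacing (cm).
#' @param lateral_cm lateral extent (cm).
#' @return a [slab_spec].
#' @export
slab_phantom_preset <- function(spacing_cm = 0.3, lateral_cm = 30) {
  slab_spec(data.frame(
    material = c("muscle", "bone", "muscle", "lung", "muscle"),
    thickness_cm = c(7.2, 3.0, 5.4, 9.0, 5.4)),
    lateral_cm = lateral_cm, spacing_cm = spacing_cm)
}

#' Build a density grid from a slab specification
#'
#' Layers are stacked along z with the first layer at the beam-entry (high z)
#' surface; the grid is centered on the isocenter, so a 30 cm phantom spans
#' z in `[-15, 15]` and a gantry-0 beam at SAD 100 has SSD 85 cm. Layer
#' boundaries that are not commensurate with the voxel spacing snap to the
#' nearest voxel boundary with a warning.
#'
#' @param spec a [slab_spec].
#' @return a density [volume_grid].
#' @export
make_slab_phantom <- function(spec) {
  s <- spec$spacing_cm
  nl <- round(spec$lateral_cm / s)
  total <- sum(spec$layers$thickness_cm)
  nz <- round(total / s)
  cum <- cumsum(spec$layers$thickness_cm)
  bidx <- round(cum / s)
  if (any(abs(cum / s - bidx) > 1e-6))
    warning("layer boundaries snapped to the nearest voxel boundary")
  rho <- array(0, c(nl, nl, nz))
  start <- c(0L, bidx[-length(bidx)])
  for (li in seq_len(nrow(spec$layers))) {
    sl <- (start[li] + 1):bidx[li]
    # first layer occupies the high-z (beam entry) end
    zidx <- nz - sl + 1L
    rho[, , zidx] <- slab_material_densities[[spec$layers$material[li]]]
  }
  volume_grid(rho, s, kind = "density")
}

#' Square field fluence with Gaussian-blurred penumbra
#'
#' Unit-height square field; each edge follows the error-function profile of
#' a step convolved with a Gaussian of `penumbra_sigma_cm`, so the 50% level
#' sits exactly at the field edge for any sigma.
#'
#' @param side_cm field side (cm), > 0.
#' @param spacing_cm map pitch (cm).
#' @param penumbra_sigma_cm Gaussian penumbra sigma (cm); 0 gives an ideal
#'   step field.
#' @param extent_cm full map extent (cm); default `side_cm + 10`.
#' @return a [fluence_map] at the isocenter plane.
#' @export
make_square_fluence <- function(side_cm, spacing_cm = 0.1,
                                penumbra_sigma_cm = 0, extent_cm = NULL) {
  if (side_cm <= 0) stop("invalid argument: side_cm must be > 0")
  if (is.null(extent_cm)) extent_cm <- side_cm + 10
  if (extent_cm < side_cm) stop("invalid argument: side larger than grid")
  n <- 2L * floor(extent_cm / (2 * spacing_cm)) + 1L  # odd, centered on axis
  x <- (seq_len(n) - (n + 1) / 2) * spacing_cm
  edge <- function(x) {
    if (penumbra_sigma_cm == 0) return(as.numeric(abs(x) < side_cm / 2) +
                                         0.5 * (abs(x) == side_cm / 2))
    s <- penumbra_sigma_cm
    pnorm((x + side_cm / 2) / s) - pnorm((x - side_cm / 2) / s)
  }
  fluence_map(outer(edge(x), edge(x)), spacing_cm)
}

#' Forward-simulate an EPID image from an isocenter fluence map
#'
#' Inverts the fluence chain for testing: the fluence is projected to the
#' detector plane, divided by `c_ad`, convolved with the EPID scatter
#' kernel, and optionally degraded with a synthetic backscatter ghost
#' (Gaussian-convolved, arm-side) and Gaussian pixel noise. Deterministic
#' under a fixed `seed`.
#'
#' @param fluence a [fluence_map] at the isocenter plane.
#' @param params a [kernel_params].
#' @param model a [correction_model].
#' @param noise_sd Gaussian pixel-noise standard deviation (>= 0).
#' @param ghost add the synthetic backscatter ghost (logical).
#' @param sdd_cm,sad_cm detector / isocenter plane distances (cm).
#' @param gantry_deg gantry angle stored in the image.
#' @param seed RNG seed for the noise (restores the caller's RNG state).
#' @return an [epid_image]; clean simulations carry the backscatter and
#'   displacement flags (nothing left to correct), ghosted ones only the
#'   displacement flag.
#' @export
simulate_epid_image <- function(fluence, params, model, noise_sd = 0,
                                ghost = FALSE, sdd_cm = 140, sad_cm = 100,
                                gantry_deg = 0, seed = 1L) {
  if (noise_sd < 0) stop("invalid argument: noise_sd must be >= 0")
  m <- sdd_cm / sad_cm
  det <- fluence_map(fluence$values / m^2,
                     spacing_cm = fluence$spacing_cm * m,
                     origin_cm = fluence$origin_cm * m)
  p0 <- det$values / model$c_ad
  kfun <- function(d)
    (1 - params$c) * exp(-params$mu_s * d) + params$c * exp(-params$mu_l * d)
  p <- conv2_radial(p0, kfun, det$spacing_cm)
  corrected <- c("displacement")
  if (ghost) {
    sig <- model$backscatter_sigma_cm
    g <- conv2_radial(p, function(d) exp(-d^2 / (2 * sig^2)), det$spacing_cm)
    half <- ceiling(nrow(p) / 2)
    w <- matrix(0, nrow(p), ncol(p))
    w[(half + 1):nrow(p), ] <- 1
    p <- p + model$backscatter_amplitude * g * w
  } else {
    corrected <- c(corrected, "backscatter")
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    p <- p + matrix(rnorm(length(p), sd = noise_sd), nrow(p))
  }
  epid_image(pmax(p, 0), pixel_pitch_cm = det$spacing_cm, sdd_cm = sdd_cm,
             gantry_deg = gantry_deg, corrected = corrected)
}
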