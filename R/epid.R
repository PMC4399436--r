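#' EPID portal image
#'
#' Container for a (pre-processed) portal image acquired in air. Offset, gain
#' and pixel-map corrections are assumed already applied by the acquisition
#' software; backscatter and gantry-displacement corrections are tracked via
#' `corrected` flags so they cannot be applied twice.
#'
#' @param pixels 2D non-negative numeric matrix of pixel values. Row index is
#'   the in-plane (y, gantry-arm) direction, column index the cross-plane (x)
#'   direction; the beam central axis projects onto the matrix center.
#' @param pixel_pitch_cm pixel pitch at the detector plane (cm); 0.04 cm for
#'   the aS1000 panel.
#' @param sdd_cm source-to-detector distance (cm); 140 cm in the reference
#'   acquisition geometry.
#' @param gantry_deg gantry angle in `[0, 360)`.
#' @param corrected character vector of applied corrections, subset of
#'   `c("backscatter", "displacement")`.
#' @return an object of class `epid_image`.
#' @export
epid_image <- function(pixels, pixel_pitch_cm = 0.04, sdd_cm = 140,
                       gantry_deg = 0, corrected = character()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels < 0)) stop("pixel values must be non-negative")
  if (!is.finite(pixel_pitch_cm) || pixel_pitch_cm <= 0)
    stop("invalid argument: pixel_pitch_cm must be > 0")
  if (!is.finite(sdd_cm) || sdd_cm <= 0)
    stop("invalid argument: sdd_cm must be > 0")
  gantry_deg <- gantry_deg %% 360
  stopifnot(all(corrected %in% c("backscatter", "displacement")))
  structure(list(pixels = pixels, pixel_pitch_cm = pixel_pitch_cm,
                 sdd_cm = sdd_cm, gantry_deg = gantry_deg,
                 corrected = corrected),
            class = "epid_image")
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf("<epid_image> %d x %d px, pitch %.3f cm, SDD %.0f cm, gantry %.1f deg\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_cm, x$sdd_cm,
              x$gantry_deg))
  cat("  corrections applied:",
      if (length(x$corrected)) paste(x$corrected, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Two-exponential EPID scatter-kernel parameters
#'
#' The radial detector scatter kernel is
#' `K(d) = (1 - c) * exp(-mu_s * d) + c * exp(-mu_l * d)`:
#' a short-range primary component (`mu_s`) describing energy spread by
#' charged particles from first photon interactions, plus a long-range
#' component (`mu_l`) from scattered, bremsstrahlung and annihilation photons.
#' Effective attenuation coefficients are fitted per nominal beam energy (see
#' [fit_epid_kernel()]); the defaults here are plausible-scale placeholders,
#' not measured values.
#'
#' @param c mixing fraction of the long-range term, in `[0, 1]`.
#' @param mu_s short-range attenuation coefficient (1/cm), > 0.
#' @param mu_l long-range attenuation coefficient (1/cm), > 0.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(c = 0.05, mu_s = 1.6, mu_l = 0.25) {
  if (!is.finite(c) || c < 0 || c > 1) stop("invalid argument: c must be in [0, 1]")
  if (!is.finite(mu_s) || mu_s <= 0) stop("invalid argument: mu_s must be > 0")
  if (!is.finite(mu_l) || mu_l <= 0) stop("invalid argument: mu_l must be > 0")
  structure(list(c = c, mu_s = mu_s, mu_l = mu_l), class = "kernel_params")
}

#' EPID acquisition correction model
#'
#' Parameters of the acquisition-chain corrections: a radially symmetric
#' Gaussian model for robot-arm backscatter, a gantry-angle-dependent panel
#' displacement table, a Gaussian "horn" (off-axis profile) correction, an
#' exponential noise-suppression kernel for the deconvolution, and the
#' absolute dose-calibration scalar `c_ad` obtained by cross-calibration of
#' the 10 cm x 10 cm reference field. None of the numeric defaults are
#' measured machine values; they must be commissioned per panel.
#'
#' @param backscatter_amplitude unitless amplitude of the backscatter ghost.
#' @param backscatter_sigma_cm Gaussian sigma of the backscatter kernel (cm).
#' @param backscatter_support `"arm"` restricts the correction to the
#'   arm-side half of the panel (rows past the panel mid-line), `"full"`
#'   applies it everywhere.
#' @param horn_amplitude,horn_sigma_cm parameters of the multiplicative horn
#'   correction `1 / (1 + A * (1 - exp(-r^2 / (2 sigma^2))))`.
#' @param noise_filter_range_cm range of the exponential noise-suppression
#'   kernel applied in Fourier space after the deconvolution division; 0
#'   disables it.
#' @param displacement_table data frame with columns `gantry_deg`, `dx_cm`,
#'   `dy_cm`; displacement at 0 degrees must be (0, 0). Linear interpolation
#'   (periodic in angle) is used between tabulated angles.
#' @param c_ad absolute dose-calibration factor (Gy per pixel-value unit).
#' @return an object of class `correction_model`.
#' @export
correction_model <- function(backscatter_amplitude = 0.04,
                             backscatter_sigma_cm = 2.0,
                             backscatter_support = c("arm", "full"),
                             horn_amplitude = 0.06,
                             horn_sigma_cm = 8.0,
                             noise_filter_range_cm = 0.1,
                             displacement_table = data.frame(
                               gantry_deg = c(0, 90, 180, 270),
                               dx_cm = c(0, 0, 0, 0),
                               dy_cm = c(0, 0, 0, 0)),
                             c_ad = 1.0) {
  backscatter_support <- match.arg(backscatter_support)
  if (backscatter_sigma_cm <= 0 || horn_sigma_cm <= 0)
    stop("invalid argument: Gaussian sigmas must be > 0")
  if (noise_filter_range_cm < 0)
    stop("invalid argument: noise_filter_range_cm must be >= 0")
  if (!is.finite(c_ad) || c_ad <= 0) stop("invalid argument: c_ad must be > 0")
  dt <- displacement_table
  stopifnot(is.data.frame(dt), all(c("gantry_deg", "dx_cm", "dy_cm") %in% names(dt)))
  z <- dt[dt$gantry_deg %% 360 == 0, , drop = FALSE]
  if (nrow(z) && any(abs(c(z$dx_cm, z$dy_cm)) > 1e-12))
    stop("displacement at gantry 0 must be (0, 0)")
  structure(list(backscatter_amplitude = backscatter_amplitude,
                 backscatter_sigma_cm = backscatter_sigma_cm,
                 backscatter_support = backscatter_support,
                 horn_amplitude = horn_amplitude,
                 horn_sigma_cm = horn_sigma_cm,
                 noise_filter_range_cm = noise_filter_range_cm,
                 displacement_table = dt[order(dt$gantry_deg), ],
                 c_ad = c_ad),
            class = "correction_model")
}

#' 2D energy-fluence map
#'
#' @param values 2D finite numeric matrix (calibrated energy fluence,
#'   arbitrary units). Rows follow y, columns follow x.
#' @param spacing_cm grid pitch at the map's reference plane (cm).
#' @param origin_cm length-2 position `(x, y)` of the corner pixel
#'   `values[1, 1]` relative to the beam central axis; defaults to a centered
#'   map.
#' @return an object of class `fluence_map`.
#' @export
fluence_map <- function(values, spacing_cm, origin_cm = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("fluence values must be finite")
  if (!is.finite(spacing_cm) || spacing_cm <= 0)
    stop("invalid argument: spacing_cm must be > 0")
  if (is.null(origin_cm))
    origin_cm <- -c(ncol(values) - 1, nrow(values) - 1) / 2 * spacing_cm
  structure(list(values = values, spacing_cm = spacing_cm,
                 origin_cm = as.numeric(origin_cm)),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d, pitch %.4f cm, max %.4g\n",
              nrow(x$values), ncol(x$values), x$spacing_cm, max(x$values)))
  invisible(x)
}

#' Pixel-center coordinates of a fluence map relative to the central axis
#' @param fm a [fluence_map].
#' @return list with numeric vectors `x` (columns) and `y` (rows), in cm.
#' @export
fluence_axes <- function(fm) {
  list(x = fm$origin_cm[1] + (seq_len(ncol(fm$values)) - 1) * fm$spacing_cm,
       y = fm$origin_cm[2] + (seq_len(nrow(fm$values)) - 1) * fm$spacing_cm)
}

#' Evaluate the discrete EPID scatter kernel
#'
#' Evaluates the two-exponential radial kernel on a centered grid and
#' normalizes it to unit sum; the absolute scale of the detector response is
#' carried entirely by `c_ad`, keeping kernel shape and calibration separate.
#'
#' @param params a [kernel_params].
#' @param shape length-2 integer vector (rows, cols), both odd.
#' @param pitch_cm grid pitch (cm), > 0.
#' @param normalize normalize to unit sum (default TRUE).
#' @return numeric matrix.
#' @export
epid_scatter_kernel <- function(params, shape, pitch_cm, normalize = TRUE) {
  if (!is.finite(pitch_cm) || pitch_cm <= 0)
    stop("invalid argument: pitch_cm must be > 0")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L) || any(shape %% 2L == 0L))
    stop("invalid argument: shape must be odd in both dimensions")
  cy <- (shape[1] + 1L) / 2L
  cx <- (shape[2] + 1L) / 2L
  dy <- (seq_len(shape[1]) - cy) * pitch_cm
  dx <- (seq_len(shape[2]) - cx) * pitch_cm
  d <- sqrt(outer(dy^2, dx^2, "+"))
  k <- (1 - params$c) * exp(-params$mu_s * d) + params$c * exp(-params$mu_l * d)
  s <- sum(k)
  if (!is.finite(s) || s <= 0)
    stop("numeric-domain error: kernel evaluates to zero/non-finite")
  if (normalize) k / s else k
}

# circulant kernel evaluation on a padded grid: distances wrap so that the
# kernel center sits at element [1, 1] (ready for FFT products)
circulant_radial <- function(fun, nr, nc, pitch) {
  iy <- pmin(0:(nr - 1), nr - (0:(nr - 1))) * pitch
  ix <- pmin(0:(nc - 1), nc - (0:(nc - 1))) * pitch
  d <- sqrt(outer(iy^2, ix^2, "+"))
  fun(d)
}

# FFT linear convolution of image with a centered radial kernel function,
# zero-padded to twice the image size, cropped back ('same')
conv2_radial <- function(img, kfun, pitch) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- 2L * nr; pc <- 2L * nc
  k <- circulant_radial(kfun, pr, pc, pitch)
  k <- k / sum(k)
  pad <- matrix(0, pr, pc)
  pad[seq_len(nr), seq_len(nc)] <- img
  out <- Re(fft(fft(pad) * fft(k), inverse = TRUE)) / (pr * pc)
  out[seq_len(nr), seq_len(nc)]
}

#' Backscatter correction
#'
#' Subtracts a model of the robot-arm backscatter ghost: the image convolved
#' with a unit-sum radial Gaussian, scaled by `backscatter_amplitude` and
#' (for `backscatter_support = "arm"`) restricted to the arm-side half of the
#' panel (rows past the mid-line). Output pixels are clipped at zero and the
#' `backscatter` flag is set.
#'
#' @param image an [epid_image] without the backscatter flag.
#' @param model a [correction_model].
#' @return corrected [epid_image].
#' @export
correct_backscatter <- function(image, model) {
  if ("backscatter" %in% image$corrected)
    stop("state error: backscatter correction already applied")
  a <- model$backscatter_amplitude
  p <- image$pixels
  if (a != 0) {
    sig <- model$backscatter_sigma_cm
    ghost <- conv2_radial(p, function(d) exp(-d^2 / (2 * sig^2)),
                          image$pixel_pitch_cm)
    w <- matrix(0, nrow(p), ncol(p))
    if (model$backscatter_support == "full") {
      w[] <- 1
    } else {
      half <- ceiling(nrow(p) / 2)
      w[(half + 1):nrow(p), ] <- 1
    }
    p <- pmax(p - a * ghost * w, 0)
  }
  epid_image(p, image$pixel_pitch_cm, image$sdd_cm, image$gantry_deg,
             corrected = union(image$corrected, "backscatter"))
}

# periodic linear interpolation of the displacement table at a gantry angle
lookup_displacement <- function(table, gantry_deg) {
  g <- gantry_deg %% 360
  ang <- table$gantry_deg %% 360
  o <- order(ang)
  ang <- ang[o]
  dx <- table$dx_cm[o]; dy <- table$dy_cm[o]
  # wrap the first point to 360 for periodic interpolation
  ang2 <- c(ang, ang[1] + 360)
  dx2 <- c(dx, dx[1]); dy2 <- c(dy, dy[1])
  if (g < ang2[1]) g <- g + 360
  c(dx = approx(ang2, dx2, xout = g, rule = 2)$y,
    dy = approx(ang2, dy2, xout = g, rule = 2)$y)
}

# bilinear translation of a matrix by (drow, dcol) in pixel units,
# zero outside the original support
shift_bilinear <- function(m, drow, dcol) {
  nr <- nrow(m); nc <- ncol(m)
  r <- seq_len(nr) + drow
  c <- seq_len(nc) + dcol
  r0 <- floor(r); wr <- r - r0
  c0 <- floor(c); wc <- c - c0
  get_rows <- function(idx) {
    out <- matrix(0, nr, nc)
    ok <- idx >= 1 & idx <= nr
    out[ok, ] <- m[idx[ok], , drop = FALSE]
    out
  }
  pick_cols <- function(mm, idx) {
    out <- matrix(0, nr, nc)
    ok <- idx >= 1 & idx <= nc
    out[, ok] <- mm[, idx[ok], drop = FALSE]
    out
  }
  a00 <- pick_cols(get_rows(r0), c0)
  a01 <- pick_cols(get_rows(r0), c0 + 1)
  a10 <- pick_cols(get_rows(r0 + 1), c0)
  a11 <- pick_cols(get_rows(r0 + 1), c0 + 1)
  wrm <- matrix(wr, nr, nc)
  wcm <- matrix(wc, nr, nc, byrow = TRUE)
  a00 * (1 - wrm) * (1 - wcm) + a01 * (1 - wrm) * wcm +
    a10 * wrm * (1 - wcm) + a11 * wrm * wcm
}

#' Gantry-angle panel-displacement correction
#'
#' Translates the image by minus the tabulated panel displacement at the
#' image's gantry angle (bilinear resampling; displacements measured against
#' the 0 degree image of the 10 cm x 10 cm field). The `displacement` flag is
#' set.
#'
#' @param image an [epid_image].
#' @param model a [correction_model] (its `displacement_table` is used), or a
#'   displacement table data frame.
#' @return corrected [epid_image].
#' @export
correct_gantry_displacement <- function(image, model) {
  if ("displacement" %in% image$corrected)
    stop("state error: displacement correction already applied")
  table <- if (inherits(model, "correction_model")) model$displacement_table else model
  d <- lookup_displacement(table, image$gantry_deg)
  p <- shift_bilinear(image$pixels,
                      drow = d[["dy"]] / image$pixel_pitch_cm,
                      dcol = d[["dx"]] / image$pixel_pitch_cm)
  epid_image(pmax(p, 0), image$pixel_pitch_cm, image$sdd_cm, image$gantry_deg,
             corrected = union(image$corrected, "displacement"))
}

#' Deconvolve a corrected portal image into a detector-plane fluence map
#'
#' Inverts `P = (F / c_ad) (x) K_epid` by division in Fourier space on a grid
#' zero-padded to twice the image size (the kernel is evaluated with wrapped
#' distances on the padded grid, so padding covers the kernel support). A
#' unit-sum exponential kernel `exp(-d / range)` is applied as a
#' multiplicative low-pass filter in Fourier space *after* the division to
#' suppress noise amplification. Fourier coefficients of the kernel whose
#' magnitude falls below `1e-6` of the maximum are raised to that floor (with
#' a warning) to regularize the division.
#'
#' @param image an [epid_image] with backscatter and displacement corrections
#'   applied.
#' @param params a [kernel_params].
#' @param model a [correction_model]; supplies `c_ad` and
#'   `noise_filter_range_cm`.
#' @return a [fluence_map] at the detector plane (spacing = pixel pitch).
#' @export
deconvolve_to_fluence <- function(image, params, model) {
  need <- setdiff(c("backscatter", "displacement"), image$corrected)
  if (length(need))
    stop("corrections must be applied before deconvolution: ",
         paste(need, collapse = ", "))
  p <- image$pixels
  pitch <- image$pixel_pitch_cm
  nr <- nrow(p); nc <- ncol(p)
  pr <- 2L * nr; pc <- 2L * nc
  k <- circulant_radial(function(d)
    (1 - params$c) * exp(-params$mu_s * d) + params$c * exp(-params$mu_l * d),
    pr, pc, pitch)
  s <- sum(k)
  if (!is.finite(s) || s <= 0)
    stop("numeric-domain error: degenerate EPID kernel")
  khat <- fft(k / s)
  mag <- Mod(khat)
  floorv <- 1e-6 * max(mag)
  low <- mag < floorv
  pad <- matrix(0, pr, pc)
  pad[seq_len(nr), seq_len(nc)] <- p
  fhat <- fft(pad) / khat
  if (any(low)) {
    # frequencies where the kernel response is below the floor are
    # unrecoverable: dividing there amplifies pixel noise and padding
    # artifacts by >= 1e6, so the inverse response is truncated to zero
    warning(sprintf("kernel spectrum below floor at %d/%d frequencies; band truncated",
                    sum(low), length(low)))
    fhat[low] <- 0
  }
  rng <- model$noise_filter_range_cm
  if (rng > 0) {
    nkern <- circulant_radial(function(d) exp(-d / rng), pr, pc, pitch)
    fhat <- fhat * fft(nkern / sum(nkern))
  }
  f <- Re(fft(fhat, inverse = TRUE)) / (pr * pc)
  fluence_map(model$c_ad * f[seq_len(nr), seq_len(nc)], spacing_cm = pitch)
}

#' Horn (off-axis profile) correction
#'
#' Divides the fluence by `1 + A * (1 - exp(-r^2 / (2 sigma^2)))`, where `r`
#' is the off-axis distance in the map's plane, flattening the "horns" of the
#' beam profile. On-axis values are unchanged.
#'
#' @param fluence a [fluence_map] (normally at the isocenter plane).
#' @param model a [correction_model].
#' @return corrected [fluence_map].
#' @export
horn_correct <- function(fluence, model) {
  a <- model$horn_amplitude
  if (a == 0) return(fluence)
  ax <- fluence_axes(fluence)
  r2 <- outer(ax$y^2, ax$x^2, "+")
  corr <- 1 + a * (1 - exp(-r2 / (2 * model$horn_sigma_cm^2)))
  fluence_map(fluence$values / corr, fluence$spacing_cm, fluence$origin_cm)
}

#' Project a detector-plane map to the isocenter plane
#'
#' Divergent-beam rescaling about the central axis: coordinates shrink by
#' `sad / sdd` (0.04 cm detector pitch at 140 cm becomes 0.028571 cm at
#' SAD 100 cm) and intensity scales by `(sdd / sad)^2` (inverse square).
#'
#' @param fluence a [fluence_map] at the detector plane.
#' @param sdd_cm source-to-detector distance of the input plane (cm).
#' @param sad_cm source-to-axis distance of the target plane (default 100).
#' @return a [fluence_map] at the isocenter plane.
#' @export
project_to_isocenter <- function(fluence, sdd_cm, sad_cm = 100) {
  if (sad_cm <= 0) stop("invalid argument: sad_cm must be > 0")
  if (sdd_cm < sad_cm) stop("invalid argument: sdd_cm must be >= sad_cm")
  m <- sad_cm / sdd_cm
  fluence_map(fluence$values * (sdd_cm / sad_cm)^2,
              spacing_cm = fluence$spacing_cm * m,
              origin_cm = fluence$origin_cm * m)
}

#' Full portal-image to isocenter-fluence chain
#'
#' Applies backscatter and displacement corrections (unless already flagged),
#' deconvolves with the EPID scatter kernel, projects to the isocenter plane
#' and applies the horn correction.
#'
#' @param image an [epid_image].
#' @param params a [kernel_params].
#' @param model a [correction_model].
#' @param sad_cm source-to-axis distance of the output plane (cm).
#' @return a [fluence_map] at the isocenter plane.
#' @export
epid_to_fluence <- function(image, params, model, sad_cm = 100) {
  if (!("backscatter" %in% image$corrected))
    image <- correct_backscatter(image, model)
  if (!("displacement" %in% image$corrected))
    image <- correct_gantry_displacement(image, model)
  f <- deconvolve_to_fluence(image, params, model)
  f <- project_to_isocenter(f, sdd_cm = image$sdd_cm, sad_cm = sad_cm)
  horn_correct(f, model)
}
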