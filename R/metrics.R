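#' Structure mask on a dose lattice
#'
#' @param mask logical (or 0/1) 3D array on the dose lattice.
#' @param name structure label (e.g. `"PTV"`, `"spinal cord"`, `"BODY"`).
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(mask, name = "structure") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  m <- array(as.logical(mask), dim(mask))
  if (any(is.na(m))) stop("mask must not contain NA")
  structure(list(mask = m, name = name), class = "structure_mask")
}

check_mask <- function(grid, mask) {
  m <- if (inherits(mask, "structure_mask")) mask$mask else mask
  if (!identical(dim(m), dim(grid$values)))
    stop("invalid argument: mask is not on the grid lattice")
  m
}

#' Override densities inside the body to water
#'
#' Sets the relative electron density to 1.0 (water) inside the body mask,
#' leaving voxels outside unchanged. Used to exclude dose-algorithm
#' heterogeneity handling from the comparison so that delivery error can be
#' quantified on its own. Idempotent.
#'
#' @param density a density [volume_grid].
#' @param body a [structure_mask] (or logical array) on the density lattice.
#' @return the overridden density [volume_grid].
#' @export
override_to_water <- function(density, body) {
  m <- check_mask(density, body)
  v <- density$values
  v[m] <- 1.0
  volume_grid(v, density$spacing_cm, density$origin_cm, kind = "density")
}

#' Cumulative dose-volume histogram
#'
#' @param dose a dose [volume_grid].
#' @param mask a [structure_mask] on the dose lattice; must be non-empty.
#' @param bin_width_Gy histogram bin width (Gy), default 0.05.
#' @return an object of class `dvh_curve` with `dose_bin_edges_Gy` and
#'   `cumulative_volume_pct` (monotone non-increasing, 100% at zero dose).
#' @export
compute_dvh <- function(dose, mask, bin_width_Gy = 0.05) {
  if (bin_width_Gy <= 0) stop("invalid argument: bin_width_Gy must be > 0")
  m <- check_mask(dose, mask)
  d <- dose$values[m]
  if (!length(d)) stop("empty structure: mask selects no voxels")
  edges <- seq(0, max(d) + bin_width_Gy, by = bin_width_Gy)
  vol <- vapply(edges, function(e) 100 * mean(d >= e), numeric(1))
  structure(list(dose_bin_edges_Gy = edges, cumulative_volume_pct = vol,
                 name = if (inherits(mask, "structure_mask")) mask$name else NA),
            class = "dvh_curve")
}

#' Structure dose-difference metrics
#'
#' Percent differences between reconstructed (EPID-based) and planned (TPS)
#' doses, relative to the prescription:
#' `Diff_mean = (D_mean^EPID - D_mean^TPS) / D_prescribed * 100%` and the
#' analogous `Diff_max` with per-structure voxel maxima (no volume
#' smoothing).
#'
#' @param d_epid,d_tps co-registered dose [volume_grid]s.
#' @param mask a [structure_mask]; must be non-empty.
#' @param prescribed_Gy prescription dose (> 0).
#' @return an object of class `dose_diff_report` with the per-distribution
#'   mean/max doses and the percent differences.
#' @export
dose_difference_metrics <- function(d_epid, d_tps, mask, prescribed_Gy) {
  stopifnot_same_lattice(d_epid, d_tps, "dose grids")
  if (!is.finite(prescribed_Gy) || prescribed_Gy <= 0)
    stop("invalid argument: prescribed_Gy must be > 0")
  m <- check_mask(d_epid, mask)
  if (!any(m)) stop("empty structure: mask selects no voxels")
  de <- d_epid$values[m]
  dt <- d_tps$values[m]
  structure(list(
    name = if (inherits(mask, "structure_mask")) mask$name else NA,
    d_mean_epid = mean(de), d_mean_tps = mean(dt),
    d_max_epid = max(de), d_max_tps = max(dt),
    prescribed_Gy = prescribed_Gy,
    diff_mean_pct = (mean(de) - mean(dt)) / prescribed_Gy * 100,
    diff_max_pct = (max(de) - max(dt)) / prescribed_Gy * 100),
    class = "dose_diff_report")
}

#' @export
print.dose_diff_report <- function(x, ...) {
  cat(sprintf("<dose_diff_report> %s: Diff_mean %+0.2f%%, Diff_max %+0.2f%% (of %.1f Gy)\n",
              x$name, x$diff_mean_pct, x$diff_max_pct, x$prescribed_Gy))
  invisible(x)
}
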