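#' 3D voxel grid container
#'
#' Common container for relative-electron-density, TERMA and dose volumes.
#' `values[i, j, k]` is the voxel whose center sits at
#' `origin_cm + (i-1, j-1, k-1) * spacing_cm`; the isocenter is the coordinate
#' origin. All lengths are centimeters.
#'
#' @param values 3D numeric array of voxel values.
#' @param spacing_cm voxel spacing, scalar (isotropic) or length-3 vector.
#' @param origin_cm position of the center of voxel `[1,1,1]`; defaults to
#'   centering the grid on the isocenter.
#' @param kind one of `"density"`, `"terma"`, `"dose"`, `"generic"`. Density,
#'   TERMA and dose grids must be non-negative and finite.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing_cm, origin_cm = NULL,
                        kind = c("generic", "density", "terma", "dose")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "double"
  if (length(spacing_cm) == 1L) spacing_cm <- rep(spacing_cm, 3L)
  if (length(spacing_cm) != 3L || any(!is.finite(spacing_cm)) || any(spacing_cm <= 0))
    stop("`spacing_cm` must be positive and of length 1 or 3")
  d <- dim(values)
  if (is.null(origin_cm)) origin_cm <- -(d - 1) / 2 * spacing_cm
  if (length(origin_cm) != 3L || any(!is.finite(origin_cm)))
    stop("`origin_cm` must be a finite length-3 vector")
  if (kind != "generic") {
    if (any(!is.finite(values))) stop(kind, " grid values must be finite")
    if (any(values < 0)) stop(kind, " grid values must be non-negative")
  }
  structure(list(values = values, spacing_cm = as.numeric(spacing_cm),
                 origin_cm = as.numeric(origin_cm), kind = kind),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid [%s]> %d x %d x %d voxels, spacing %s cm\n",
              x$kind, d[1], d[2], d[3],
              paste(signif(x$spacing_cm, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) cm, range [%.4g, %.4g]\n",
              paste(signif(x$origin_cm, 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-center coordinates along each axis
#' @param grid a [volume_grid].
#' @return list with numeric vectors `x`, `y`, `z` (cm).
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin_cm[1] + (seq_len(d[1]) - 1) * grid$spacing_cm[1],
       y = grid$origin_cm[2] + (seq_len(d[2]) - 1) * grid$spacing_cm[2],
       z = grid$origin_cm[3] + (seq_len(d[3]) - 1) * grid$spacing_cm[3])
}

#' Test whether two grids share the same voxel lattice
#' @param a,b [volume_grid] objects.
#' @param tol positional tolerance in cm.
#' @return logical scalar.
#' @export
same_lattice <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_cm - b$spacing_cm) <= tol) &&
    all(abs(a$origin_cm - b$origin_cm) <= tol)
}

stopifnot_same_lattice <- function(a, b, what = "grids") {
  if (!same_lattice(a, b)) stop(what, " are not on the same voxel lattice")
  invisible(TRUE)
}

# linear interpolation of a 3D array along one axis onto new coordinates;
# exact on fields affine in the interpolated coordinate
interp_axis <- function(arr, old, new, axis) {
  n <- length(old)
  step <- if (n > 1) old[2] - old[1] else 1
  fi <- (new - old[1]) / step
  i0 <- pmin(pmax(floor(fi), 0), n - 2)
  w <- pmin(pmax(fi - i0, 0), 1)  # clamp fp overshoot at the grid ends
  i0 <- as.integer(i0) + 1L
  i1 <- i0 + 1L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m0 <- a[i0, , , drop = FALSE]
  m1 <- a[i1, , , drop = FALSE]
  out <- sweep(m0, 1, 1 - w, "*") + sweep(m1, 1, w, "*")
  aperm(out, order(perm))
}

#' Trilinear resampling of a volume grid
#'
#' Resamples onto a new uniform lattice spanning the same physical extent;
#' the first voxel center is preserved and subsequent centers are laid out at
#' the new spacing (the far corner is preserved exactly when the extent is a
#' multiple of the new spacing). Exact for fields affine in position.
#'
#' @param grid a [volume_grid].
#' @param new_spacing_cm target spacing, scalar or length-3 (cm).
#' @return a [volume_grid] on the new lattice.
#' @export
resample_trilinear <- function(grid, new_spacing_cm) {
  if (length(new_spacing_cm) == 1L) new_spacing_cm <- rep(new_spacing_cm, 3L)
  if (any(new_spacing_cm <= 0)) stop("new spacing must be positive")
  d <- dim(grid$values)
  if (any(d < 2L)) stop("degenerate axis: need >= 2 voxels per axis")
  ax <- grid_axes(grid)
  newax <- lapply(1:3, function(a)
    seq(ax[[a]][1], ax[[a]][length(ax[[a]])], by = new_spacing_cm[a]))
  v <- grid$values
  v <- interp_axis(v, ax$x, newax[[1]], 1L)
  v <- interp_axis(v, ax$y, newax[[2]], 2L)
  v <- interp_axis(v, ax$z, newax[[3]], 3L)
  volume_grid(v, new_spacing_cm, grid$origin_cm, kind = grid$kind)
}
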