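## Deformation fields, Jacobian-determinant voxel-size maps, and
## relative-voxel-size histograms for geometric distortion.

#' Dense displacement field on a voxel grid
#'
#' The field stores a world-frame displacement `u` (mm) per voxel; the warp
#' maps position `x` to `x + u(x)`, so the zero field is the identity.
#'
#' @param grid a [voxel_grid()].
#' @param displacement numeric array `dims x 3` (mm).
#' @return A `deformation_field`.
#' @export
deformation_field <- function(grid, displacement) {
  .assert(all(dim(displacement) == c(grid$dims, 3)),
          "displacement must be dims x 3")
  .finite_check(displacement, "displacement")
  structure(list(grid = grid, displacement = displacement),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %s, max |u| %.3f mm\n", format(x$grid),
              sqrt(max(rowSums(matrix(x$displacement, ncol = 3)^2)))))
  invisible(x)
}

#' Synthetic low-order polynomial displacement field
#'
#' Evaluates, per component, a 3D polynomial in the offsets from `center`
#' (mm) -- a self-contained stand-in for gradient-coil nonlinearity models,
#' which grow with distance from isocenter.
#'
#' @param grid a [voxel_grid()].
#' @param coefficients list with elements `x`, `y`, `z`; each a data frame
#'   with columns `px`, `py`, `pz` (exponents, total degree <= 5) and `c`
#'   (coefficient, mm per mm^degree). Missing components default to zero.
#' @param center world point (mm) where polynomial offsets are measured.
#' @return A [deformation_field()].
#' @export
polynomial_field <- function(grid, coefficients, center = c(0, 0, 0)) {
  pts <- sweep(voxel_to_world(grid, grid_index_matrix(grid)), 2, center, `-`)
  u <- array(0, c(grid$dims, 3))
  for (k in 1:3) {
    comp <- coefficients[[c("x", "y", "z")[k]]]
    if (is.null(comp) || nrow(comp) == 0) next
    .assert(all(comp$px + comp$py + comp$pz <= 5),
            "polynomial degree must be <= 5")
    acc <- numeric(nrow(pts))
    for (i in seq_len(nrow(comp)))
      acc <- acc + comp$c[i] * pts[, 1]^comp$px[i] * pts[, 2]^comp$py[i] *
        pts[, 3]^comp$pz[i]
    u[, , , k] <- acc
  }
  deformation_field(grid, u)
}

## central differences along one axis of a 3D array, one-sided at borders,
## in units of 1/index
.diff_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n == 1) return(array(0, d))
  ip <- pmin(seq_len(n) + 1, n)
  im <- pmax(seq_len(n) - 1, 1)
  den <- ip - im
  idx <- function(ii) switch(axis, a[ii, , , drop = FALSE],
                             a[, ii, , drop = FALSE], a[, , ii, drop = FALSE])
  den_arr <- array(0, d)
  if (axis == 1) den_arr[] <- den
  if (axis == 2) den_arr[] <- rep(den, each = d[1])
  if (axis == 3) den_arr[] <- rep(den, each = d[1] * d[2])
  (idx(ip) - idx(im)) / den_arr
}

#' Jacobian-determinant voxel-size map of a deformation
#'
#' Computes `det(I + du/dx)` per voxel, with `u` the displacement in mm and
#' gradients taken with respect to world mm (central finite differences,
#' one-sided at the borders). Values below 1 mark compressed (smaller true)
#' voxels, above 1 expanded voxels; any rigid field gives 1 everywhere.
#'
#' @param field a [deformation_field()] with at least 2 voxels per axis.
#' @return A `voxel_size_map` (list with `jacobian_det` [volume()] and grid).
#' @export
jacobian_map <- function(field) {
  g <- field$grid
  .assert(all(g$dims >= 2), "need at least 2 voxels per axis")
  A3 <- g$affine[1:3, 1:3]
  Ainv <- solve(A3) # d(index)/d(world)
  J <- vector("list", 9) # du_i/dx_j
  didx <- vector("list", 3)
  for (i in 1:3) {
    ui <- array(field$displacement[, , , i], g$dims)
    for (ax in 1:3) didx[[ax]] <- .diff_axis(ui, ax) # du_i/d(index_ax)
    for (j in 1:3) {
      acc <- didx[[1]] * Ainv[1, j] + didx[[2]] * Ainv[2, j] +
        didx[[3]] * Ainv[3, j]
      J[[(i - 1) * 3 + j]] <- acc
    }
  }
  F11 <- 1 + J[[1]]; F12 <- J[[2]]; F13 <- J[[3]]
  F21 <- J[[4]]; F22 <- 1 + J[[5]]; F23 <- J[[6]]
  F31 <- J[[7]]; F32 <- J[[8]]; F33 <- 1 + J[[9]]
  det <- F11 * (F22 * F33 - F23 * F32) -
    F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
  structure(list(jacobian_det = volume(det, g, check = FALSE), grid = g),
            class = "voxel_size_map")
}

#' @export
print.voxel_size_map <- function(x, ...) {
  r <- range(x$jacobian_det$data)
  cat(sprintf("<voxel_size_map> %s, relative voxel size %.3f-%.3f\n",
              format(x$grid), r[1], r[2]))
  invisible(x)
}

#' Histogram of relative voxel size
#'
#' @param map a `voxel_size_map` from [jacobian_map()].
#' @param mask logical array / binary [volume()] restricting the summary
#'   (default: everything).
#' @param breaks histogram breaks for the Jacobian determinant; extended
#'   automatically to cover the data.
#' @return A tibble with `bin_lo`, `bin_hi`, `count`; summary statistics
#'   (`min`, `max`, `mean`) in attributes.
#' @export
voxel_size_histogram <- function(map, mask = NULL,
                                 breaks = seq(0.7, 1.3, by = 0.02)) {
  vals <- as.numeric(map$jacobian_det$data)
  if (!is.null(mask)) {
    m <- if (is_volume(mask)) mask$data else mask
    .assert(length(m) == length(vals), "mask must match the grid")
    vals <- vals[as.logical(m)]
  }
  .assert(length(vals) > 0, "empty mask")
  lo <- min(breaks[1], min(vals)); hi <- max(breaks[length(breaks)], max(vals))
  step <- diff(breaks)[1]
  breaks <- seq(lo - step, hi + step, by = step)
  h <- hist(vals, breaks = breaks, plot = FALSE)
  out <- tibble::tibble(bin_lo = head(h$breaks, -1), bin_hi = h$breaks[-1],
                        count = h$counts)
  attr(out, "min") <- min(vals)
  attr(out, "max") <- max(vals)
  attr(out, "mean") <- mean(vals)
  out
}

#' Warp a volume through a deformation field
#'
#' Pull-back warp: the output at voxel centre `x` samples the input at
#' `x + u(x)`.
#'
#' @param v a [volume()].
#' @param field a [deformation_field()] on the output grid.
#' @param method an [interpolant()] or its name.
#' @param fill value outside the field of view.
#' @return The warped [volume()].
#' @export
apply_deformation <- function(v, field, method = "linear", fill = 0) {
  g <- field$grid
  world <- voxel_to_world(g, grid_index_matrix(g))
  u <- matrix(field$displacement, ncol = 3)
  coords <- world_to_voxel_raw(v$grid, world + u)
  vals <- .sample_volume_frames(v, coords, method, fill)
  dims_out <- c(g$dims, if (v$nframes > 1L) v$nframes)
  volume(array(vals, dims_out), g, check = FALSE)
}
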