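## Interpolation kernels, upsampling, rigid resampling, motion correction.

.METHOD_CODES <- c(nearest = 0L, linear = 1L, cubic = 2L, quintic = 3L, sinc = 4L)
.METHOD_SUPPORT <- c(nearest = 0.5, linear = 1, cubic = 2, quintic = 3, sinc = 7)

#' Interpolation kernel specification
#'
#' Available kernels: `nearest` (tie at the half-voxel breaks toward the lower
#' index), `linear` (tent), `cubic` and `quintic` (B-spline interpolation of
#' orders 3/5 with recursive prefiltering, so on-grid samples are reproduced),
#' and `sinc` (Hann-windowed sinc, half-width 7 voxels, weights renormalised
#' to unit sum). All kernels partition unity; outside the field of view a
#' constant fill value is assumed.
#'
#' @param name one of `"nearest"`, `"linear"`, `"cubic"`, `"quintic"`, `"sinc"`.
#' @return An `interpolant` with fields `name`, `support` (kernel half-width,
#'   voxels) and internal code.
#' @export
interpolant <- function(name = c("nearest", "linear", "cubic", "quintic", "sinc")) {
  if (inherits(name, "interpolant")) return(name)
  name <- match.arg(name)
  structure(list(name = name, support = unname(.METHOD_SUPPORT[name]),
                 code = unname(.METHOD_CODES[name])),
            class = "interpolant")
}

## Sample one 3D array at 0-based voxel coords; prefilters for spline methods.
.sample_array3d <- function(arr, coords, method, fill = 0) {
  method <- interpolant(method)
  dims <- dim(arr)[1:3]
  if (method$code %in% c(2L, 3L))
    arr <- array(.bk_bspline_prefilter(as.numeric(arr), as.integer(dims),
                                       if (method$code == 2L) 3L else 5L), dims)
  .bk_sample3d(as.numeric(arr), as.integer(dims), coords, method$code, fill)
}

## Sample all frames of a volume at the same coordinates -> n x nframes matrix
.sample_volume_frames <- function(v, coords, method, fill = 0) {
  method <- interpolant(method)
  dims <- v$grid$dims
  if (v$nframes == 1L)
    return(matrix(.sample_array3d(v$data, coords, method, fill), ncol = 1))
  dat <- v$data
  if (method$code %in% c(2L, 3L)) {
    ord <- if (method$code == 2L) 3L else 5L
    dat <- array(0, dim = dim(v$data))
    for (t in seq_len(v$nframes))
      dat[, , , t] <- array(.bk_bspline_prefilter(as.numeric(v$data[, , , t]),
                                                  as.integer(dims), ord), dims)
  }
  .bk_sample_frames(as.numeric(dat), as.integer(c(dims, v$nframes)),
                    coords, method$code, fill)
}

#' Upsample a volume to a finer grid
#'
#' The output grid has spacing `input spacing / factor` and `prod(factor)`
#' times as many voxels; the affine is adjusted so the output voxel centres
#' tile the same field of view (the first output centre sits at the first
#' input centre minus `spacing_out * (factor - 1) / 2`).
#'
#' @param v a [volume()].
#' @param factor integer upsampling factor, scalar or per axis (>= 1).
#' @param method an [interpolant()] or its name.
#' @return The upsampled [volume()].
#' @export
#' @examples
#' v <- volume(array(1, c(8, 8, 8)), voxel_grid(c(8, 8, 8), 1))
#' u <- upsample(v, 2, "linear")
#' u$grid$dims
upsample <- function(v, factor, method = "cubic") {
  .assert(is_volume(v), "v must be a volume")
  factor <- rep_len(as.integer(round(factor)), 3)
  .assert(all(factor >= 1), "factor must be a positive integer")
  if (all(factor == 1L)) return(v)
  g <- v$grid
  A <- g$affine
  Aout <- A
  Aout[1:3, 1:3] <- sweep(A[1:3, 1:3], 2, factor, `/`)
  Aout[1:3, 4] <- A[1:3, 4] - A[1:3, 1:3] %*% ((factor - 1) / (2 * factor))
  out_grid <- voxel_grid(g$dims * factor, affine = Aout)
  idx <- grid_index_matrix(out_grid)
  coords <- sweep(sweep(idx, 2, (factor - 1) / 2, `-`), 2, factor, `/`)
  vals <- .sample_volume_frames(v, coords, method)
  dims_out <- c(out_grid$dims, if (v$nframes > 1L) v$nframes)
  volume(array(vals, dims_out), out_grid, check = FALSE)
}

#' Resample a volume through a rigid transform
#'
#' The output is sampled at the voxel centres of `out_grid` pulled back
#' through the inverse transform: `out(x) = v(t^-1(x))` in world coordinates,
#' i.e. `t` maps input-space positions to output-space positions. Samples
#' falling outside the input field of view take `fill`. 4D input is resampled
#' frame-wise.
#'
#' @param v a [volume()].
#' @param t a `rigid_transform`.
#' @param out_grid output [voxel_grid()] (default: the input grid).
#' @param method an [interpolant()] or its name.
#' @param fill value assumed outside the field of view.
#' @return The resampled [volume()].
#' @export
resample_rigid <- function(v, t, out_grid = v$grid, method = "linear", fill = 0) {
  .assert(is_volume(v), "v must be a volume")
  .assert(is_rigid(t), "t must be a rigid_transform")
  .assert(abs(det(out_grid$affine)) > 1e-12, "out_grid affine must be invertible")
  idx <- grid_index_matrix(out_grid)
  world <- voxel_to_world(out_grid, idx)
  src_world <- apply_transform(invert_rigid(t), world)
  coords <- world_to_voxel(v$grid, src_world)
  vals <- .sample_volume_frames(v, coords, method, fill)
  dims_out <- c(out_grid$dims, if (v$nframes > 1L) v$nframes)
  volume(array(vals, dims_out), out_grid, check = FALSE)
}

#' Motion-correct a 4D series with a known or estimated trace
#'
#' Every frame is resampled into the reference frame's grid (optionally
#' upsampled first, emulating upsample-then-correct pipelines). The trace
#' holds the forward head motion per frame (reference position `x` is at
#' `T_t(x)` during frame `t`), so correction pulls each frame back through
#' `T_t`.
#'
#' @param series a 4D [volume()].
#' @param trace a [motion_trace()] with one transform per frame.
#' @param method interpolant used for the correction resampling.
#' @param upsample_factor integer; upsample the series onto a finer grid
#'   before applying the transforms (1 = native grid).
#' @param upsample_method interpolant used for the upsampling step.
#' @return The corrected 4D [volume()] (on the possibly upsampled grid).
#' @export
motion_correct <- function(series, trace, method = "linear",
                           upsample_factor = 1, upsample_method = method) {
  .assert(is_volume(series) && series$nframes >= 2, "series must be 4D")
  .assert(inherits(trace, "motion_trace"), "trace must be a motion_trace")
  .assert(length(trace$transforms) == series$nframes,
          "trace length must equal the frame count")
  if (upsample_factor > 1)
    series <- upsample(series, upsample_factor, upsample_method)
  g <- series$grid
  out <- array(0, dim = c(g$dims, series$nframes))
  idx <- grid_index_matrix(g)
  world <- voxel_to_world(g, idx)
  for (t in seq_len(series$nframes)) {
    tr <- trace$transforms[[t]]
    if (max(abs(tr$matrix - diag(4))) < 1e-12) {
      out[, , , t] <- series$data[, , , t]
    } else {
      coords <- world_to_voxel(g, apply_transform(tr, world))
      frame <- array(series$data[, , , t], g$dims)
      out[, , , t] <- .sample_array3d(frame, coords, method)
    }
  }
  volume(out, g, check = FALSE)
}
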