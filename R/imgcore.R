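## Volume/grid data model, NIfTI and affine I/O, rigid-body transforms.

#' Axis-aligned voxel grid with a world affine
#'
#' A `voxel_grid` describes a voxel lattice: integer dimensions, voxel spacing
#' in mm, and a 4x4 affine mapping 0-based voxel indices (voxel centres) to
#' world coordinates in mm (NIfTI convention). By default the grid is centred
#' on the world origin.
#'
#' @param dims integer vector of length 3, voxels per axis.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param origin world position (mm) of voxel (0,0,0); default centres the
#'   field of view on the world origin.
#' @param affine optional full 4x4 affine; overrides `spacing`/`origin`.
#' @return A `voxel_grid` object.
#' @export
#' @examples
#' g <- voxel_grid(c(64, 64, 64), 1)
#' g$spacing
voxel_grid <- function(dims, spacing = 1, origin = NULL, affine = NULL) {
  dims <- as.integer(round(dims))
  .assert(length(dims) == 3 && all(dims >= 1), "dims must be 3 integers >= 1")
  if (is.null(affine)) {
    spacing <- rep_len(as.numeric(spacing), 3)
    .assert(all(spacing > 0), "spacing must be positive")
    if (is.null(origin)) origin <- -(dims - 1) * spacing / 2
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  } else {
    .assert(all(dim(affine) == c(4, 4)), "affine must be 4x4")
    .assert(abs(det(affine)) > 1e-12, "affine must be invertible")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(dims = dims, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...)
  sprintf("%s @ %s mm", paste(x$dims, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) < tol
}

#' Convert between voxel indices and world coordinates
#'
#' @param grid a [voxel_grid()].
#' @param pts n x 3 matrix (world mm for `world_to_voxel`, 0-based voxel
#'   indices for `voxel_to_world`).
#' @return n x 3 matrix of transformed coordinates.
#' @export
voxel_to_world <- function(grid, pts) {
  pts <- rbind(t(matrix(as.numeric(pts), ncol = 3)), 1)
  t(grid$affine %*% pts)[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- rbind(t(matrix(as.numeric(pts), ncol = 3)), 1)
  t(solve(grid$affine) %*% pts)[, 1:3, drop = FALSE]
}

grid_center_world <- function(grid) {
  as.numeric(voxel_to_world(grid, matrix((grid$dims - 1) / 2, 1)))
}

## 0-based voxel index matrix (n x 3) in column-major order, matching the
## storage order of volume data
grid_index_matrix <- function(grid) {
  d <- grid$dims
  cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Scalar volume on a voxel grid
#'
#' Wraps a 3D array (one frame) or 4D array (time series) together with its
#' [voxel_grid()].
#'
#' @param data numeric array, 3D or 4D (x, y, z\[, t\]).
#' @param grid a [voxel_grid()] whose dims match `dim(data)[1:3]`.
#' @param check validate finiteness (disable for large internal temporaries).
#' @return A `bk_volume` object with fields `data`, `grid`, `nframes`.
#' @export
volume <- function(data, grid, check = TRUE) {
  d <- dim(data)
  .assert(length(d) %in% c(3L, 4L), "data must be a 3D or 4D array")
  .assert(all(d[1:3] == grid$dims), "data extent does not match grid dims")
  if (check) .finite_check(data, "volume data")
  structure(list(data = data, grid = grid,
                 nframes = if (length(d) == 4L) d[4] else 1L),
            class = "bk_volume")
}

#' @export
print.bk_volume <- function(x, ...) {
  cat(sprintf("<volume> %s, %d frame(s)\n", format(x$grid), x$nframes))
  invisible(x)
}

is_volume <- function(x) inherits(x, "bk_volume")

#' Read a NIfTI volume
#'
#' Grid affine and spacing are taken from the header; 4D series keep frame
#' order. Payloads written as float32 round-trip bit-exactly.
#'
#' @param path path to a NIfTI-1/2 file (optionally gzipped).
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  d <- dim(img)
  .assert(length(d) %in% c(3L, 4L), "only 3D/4D NIfTI volumes are supported")
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  grid <- voxel_grid(d[1:3], affine = matrix(as.numeric(aff), 4, 4))
  volume(array(as.numeric(img), dim = d), grid)
}

#' Write a volume as NIfTI (float32)
#'
#' @param v a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  .assert(is_volume(v), "v must be a volume")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- if (v$nframes > 1L) c(v$grid$spacing, 1) else
    v$grid$spacing
  RNifti::sform(img) <- structure(v$grid$affine, code = 2L)
  RNifti::qform(img) <- structure(v$grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

## ---- rigid transforms -------------------------------------------------------

rot_roll <- function(a) { # about I-S (z) axis
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_pitch <- function(a) { # about R-L (x) axis
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_yaw <- function(a) { # about A-P (y) axis
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Rigid-body transform from six motion parameters
#'
#' Parameters follow the usual motion-trace convention: rotations roll, pitch
#' and yaw in degrees about the world I-S (z), R-L (x) and A-P (y) axes, and
#' displacements dS, dL, dP in mm along z, x and y. The rotation is composed
#' as roll then pitch then yaw (matrix `Rz %*% Rx %*% Ry`) about a fixed
#' world-space centre, followed by the translation.
#'
#' @param params numeric length 6: `(roll, pitch, yaw, dS, dL, dP)`
#'   (degrees, degrees, degrees, mm, mm, mm).
#' @param center world point (mm) the rotations pivot about; typically the
#'   volume centre. Default origin.
#' @return A `rigid_transform` with fields `params`, `matrix` (4x4 world map)
#'   and `center`.
#' @export
#' @examples
#' t <- rigid_from_params(c(10, 0, 0, 1, 0, 0))
#' rigid_params(t)
rigid_from_params <- function(params, center = c(0, 0, 0)) {
  params <- as.numeric(params)
  .assert(length(params) == 6 && all(is.finite(params)),
          "params must be 6 finite numbers (roll, pitch, yaw, dS, dL, dP)")
  ang <- .deg2rad(params[1:3])
  R <- rot_roll(ang[1]) %*% rot_pitch(ang[2]) %*% rot_yaw(ang[3])
  trans <- params[c(5, 6, 4)] # (dL, dP, dS) -> (x, y, z)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- trans + center - R %*% center
  new_rigid(m, center, params)
}

new_rigid <- function(m, center = c(0, 0, 0), params = NULL) {
  R <- m[1:3, 1:3]
  .assert(max(abs(crossprod(R) - diag(3))) < 1e-8 && det(R) > 0,
          "matrix 3x3 block must be a proper rotation")
  if (is.null(params)) params <- .extract_params(m, center)
  structure(list(params = setNames(params,
                                   c("roll", "pitch", "yaw", "dS", "dL", "dP")),
                 matrix = m, center = as.numeric(center)),
            class = "rigid_transform")
}

.extract_params <- function(m, center) {
  R <- m[1:3, 1:3]
  ## R = Rz(roll) Rx(pitch) Ry(yaw):
  ##   R[3,2] = sin(pitch); R[3,1] = -cos(pitch) sin(yaw); R[1,2] = -sin(roll) cos(pitch)
  pitch <- asin(max(-1, min(1, R[3, 2])))
  if (abs(cos(pitch)) < 1e-8) { # gimbal lock: fold yaw into roll
    yaw <- 0
    roll <- atan2(R[2, 1], R[1, 1])
  } else {
    yaw <- atan2(-R[3, 1], R[3, 3])
    roll <- atan2(-R[1, 2], R[2, 2])
  }
  tvec <- m[1:3, 4] - center + R %*% center
  c(.rad2deg(c(roll, pitch, yaw)), tvec[3], tvec[1], tvec[2])
}

#' @rdname rigid_from_params
#' @param t a `rigid_transform`.
#' @export
rigid_params <- function(t) t$params

#' @rdname rigid_from_params
#' @export
rigid_identity <- function(center = c(0, 0, 0))
  rigid_from_params(rep(0, 6), center)

is_rigid <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$params, 6))
  invisible(x)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse `rigid_transform` (same rotation centre).
#' @export
invert_rigid <- function(t) {
  m <- diag(4)
  R <- t(t$matrix[1:3, 1:3])
  m[1:3, 1:3] <- R
  m[1:3, 4] <- -R %*% t$matrix[1:3, 4]
  new_rigid(m, t$center)
}

#' Apply a rigid transform to world points
#' @param t a `rigid_transform`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], `+`)
}

#' Compose rigid transforms
#'
#' Collapses an ordered chain into a single transform: `chain[[1]]` is applied
#' first. Applying the composed transform to a point is equivalent to applying
#' the chain sequentially.
#'
#' @param chain non-empty list of `rigid_transform` objects.
#' @return A single `rigid_transform`.
#' @export
compose_transforms <- function(chain) {
  if (is_rigid(chain)) chain <- list(chain)
  .assert(is.list(chain) && length(chain) >= 1 && all(vapply(chain, is_rigid, TRUE)),
          "chain must be a non-empty list of rigid transforms")
  m <- Reduce(function(acc, t) t$matrix %*% acc, chain, diag(4))
  new_rigid(m, chain[[1]]$center)
}

#' Read/write a 4x4 affine as whitespace-delimited text (FSL .mat dialect)
#'
#' @param path file path.
#' @return `read_affine`: a 4x4 matrix; `write_affine`: `path` invisibly.
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  .assert(all(dim(m) == c(4, 4)), "affine file must contain a 4x4 matrix")
  dimnames(m) <- NULL
  m
}

#' @rdname read_affine
#' @param m a 4x4 matrix (or `rigid_transform`, whose matrix is written).
#' @export
write_affine <- function(m, path) {
  if (is_rigid(m)) m <- m$matrix
  write.table(format(m, digits = 17), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
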