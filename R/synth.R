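## Synthetic fixtures: folded two-boundary cortical sheets, interdigitated
## stripe phantoms, block-design BOLD runs, motion traces, smooth phantoms.

#' Synthetic folded cortical sheet (white + pial mesh pair)
#'
#' Builds an open, bordered triangulated sheet on a near-equilateral lattice,
#' folded sinusoidally along x (`z = A sin(2 pi u / lambda)`), with vertices
#' spaced by arc length so the mean edge length tracks the requested vertex
#' spacing even on strong folds. A small seeded in-plane jitter makes the
#' triangulation irregular, as cortical reconstructions are. The pial
#' surface is the white surface offset by `thickness` along the vertex
#' normals, so both meshes share topology and the per-vertex white-to-pial
#' distance equals `thickness`.
#'
#' @param extent sheet size in mm (scalar or `c(x, y)`).
#' @param spacing target mean vertex spacing (mm).
#' @param fold_amplitude fold depth A (mm); 0 gives a planar sheet.
#' @param fold_wavelength fold wavelength lambda (mm).
#' @param thickness cortical thickness (mm).
#' @param jitter in-plane jitter as a fraction of `spacing`.
#' @param seed RNG seed for the jitter.
#' @return A `cortical_sheet`: list with `white`, `pial` ([triangle_mesh()]s
#'   sharing topology), and the generating parameters. Vertex sheet
#'   coordinates (arc length u, row coordinate v) are kept in
#'   `attr(, "param_uv")` for stripe labelling.
#' @export
make_cortical_sheet <- function(extent = 40, spacing = 1, fold_amplitude = 1.5,
                                fold_wavelength = 12, thickness = 2,
                                jitter = 0.1, seed = 1) {
  extent <- rep_len(extent, 2)
  .assert(spacing > 0 && all(spacing < extent), "spacing must be positive and below extent")
  .assert(thickness > 0, "thickness must be positive")
  fold <- function(u) fold_amplitude * sin(2 * pi * u / fold_wavelength)
  ## arc-length parameterisation of the fold profile along x
  uu <- seq(0, extent[1], length.out = 4096)
  if (fold_amplitude > 0) {
    du <- diff(uu)
    slopes <- fold_amplitude * (2 * pi / fold_wavelength) *
      cos(2 * pi * (uu[-1] - du / 2) / fold_wavelength)
    arc <- c(0, cumsum(du * sqrt(1 + slopes^2)))
  } else arc <- uu
  total_arc <- max(arc)
  ncol_v <- max(2L, round(total_arc / spacing) + 1L)
  rowh <- spacing * sqrt(3) / 2
  nrow_v <- max(2L, round(extent[2] / rowh) + 1L)
  .with_seed(seed, NULL)
  verts <- matrix(0, nrow_v * ncol_v, 3)
  uv <- matrix(0, nrow_v * ncol_v, 2)
  for (r in seq_len(nrow_v)) {
    offs <- if (r %% 2 == 0) 0.5 else 0
    s_arc <- (seq_len(ncol_v) - 1 + offs) / (ncol_v - 1 + 0.5) * total_arc
    s_arc <- s_arc + runif(ncol_v, -jitter, jitter) * spacing
    s_arc <- pmin(pmax(s_arc, 0), total_arc)
    x <- approx(arc, uu, xout = s_arc, rule = 2)$y
    y <- (r - 1) * rowh + runif(ncol_v, -jitter, jitter) * spacing
    i <- (r - 1) * ncol_v + seq_len(ncol_v)
    verts[i, ] <- cbind(x - extent[1] / 2, y - extent[2] / 2, fold(x))
    uv[i, ] <- cbind(s_arc, y)
  }
  faces <- list()
  for (r in seq_len(nrow_v - 1)) {
    a <- (r - 1) * ncol_v + seq_len(ncol_v - 1) # row r
    b <- a + 1
    c <- a + ncol_v # row r + 1
    d <- c + 1
    if (r %% 2 == 1) {
      faces[[2 * r - 1]] <- cbind(a, b, c)
      faces[[2 * r]] <- cbind(b, d, c)
    } else {
      faces[[2 * r - 1]] <- cbind(a, b, d)
      faces[[2 * r]] <- cbind(a, d, c)
    }
  }
  white <- triangle_mesh(verts, do.call(rbind, faces))
  nrm <- vertex_normals(white)
  flip <- nrm[, 3] < 0
  nrm[flip, ] <- -nrm[flip, ] # orient away from the fold base (+z)
  pial <- triangle_mesh(white$vertices + thickness * nrm, white$faces)
  out <- structure(list(white = white, pial = pial, extent = extent,
                        spacing = spacing, fold_amplitude = fold_amplitude,
                        fold_wavelength = fold_wavelength,
                        thickness = thickness, seed = seed),
                   class = "cortical_sheet")
  attr(out, "param_uv") <- uv
  out
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf(
    "<cortical_sheet> %gx%g mm, %d vertices, thickness %g mm, fold %g/%g mm\n",
    x$extent[1], x$extent[2], nrow(x$white$vertices), x$thickness,
    x$fold_amplitude, x$fold_wavelength))
  invisible(x)
}

#' Interdigitated stripe truth maps on a cortical sheet
#'
#' Labels alternating bands of width `stripe_width` along a sheet coordinate
#' with two systems ("thin"-like and "thick"-like); an optional unlabeled gap
#' fraction separates neighbouring bands. The two label sets are disjoint by
#' construction (ground-truth Dice exactly 0), mimicking columnar systems
#' known to be non-overlapping.
#'
#' @param sheet a [make_cortical_sheet()] result.
#' @param stripe_width band width along the sheet (mm); must be at least
#'   twice the vertex spacing.
#' @param gap_frac fraction of each band left unlabeled at its borders.
#' @param orientation `"u"` (bands across the folds) or `"v"`.
#' @return A `stripe_truth`: list with logical `truth_a`, `truth_b` over
#'   vertices.
#' @export
make_stripe_phantom <- function(sheet, stripe_width = 3, gap_frac = 0,
                                orientation = c("u", "v")) {
  orientation <- match.arg(orientation)
  .assert(stripe_width >= 2 * sheet$spacing,
          "stripe_width must be at least twice the vertex spacing")
  uv <- attr(sheet, "param_uv")
  coord <- uv[, if (orientation == "u") 1 else 2]
  band <- floor(coord / stripe_width)
  frac <- coord / stripe_width - band
  labeled <- frac >= gap_frac / 2 & frac <= 1 - gap_frac / 2
  a <- labeled & band %% 2 == 0
  b <- labeled & band %% 2 == 1
  structure(list(truth_a = a, truth_b = b, stripe_width = stripe_width,
                 gap_frac = gap_frac, orientation = orientation),
            class = "stripe_truth")
}

#' Synthetic block-design BOLD run over a labelled cortical ribbon
#'
#' Voxel time series are `baseline + amplitude * indicator * (boxcar (x) HRF)
#' + noise`, where the indicator marks voxels whose centre lies within half
#' the cortical thickness of a labelled mid-surface vertex; each frame is
#' then warped by the frame's motion transform (identity traces skip the
#' resampling, keeping the noiseless zero-motion run exact).
#'
#' @param sheet a [make_cortical_sheet()] result.
#' @param labels logical vertex labels (one stripe system).
#' @param grid acquisition [voxel_grid()]; must cover the sheet.
#' @param design a [block_design()].
#' @param amplitude response amplitude (signal units).
#' @param noise_sd i.i.d. Gaussian noise sd (signal units).
#' @param trace optional [motion_trace()] (default: no motion).
#' @param baseline baseline intensity.
#' @param delay,dispersion gamma HRF parameters (s).
#' @param seed RNG seed for the noise.
#' @return A 4D [volume()] with `length(design$frame_times)` frames.
#' @export
make_bold_run <- function(sheet, labels, grid, design, amplitude = 2,
                          noise_sd = 1, trace = NULL, baseline = 100,
                          delay = 2.25, dispersion = 1.25, seed = NULL) {
  labels <- as.logical(map_values(labels))
  mid <- (sheet$white$vertices + sheet$pial$vertices) / 2
  fov_lo <- voxel_to_world(grid, matrix(0, 1, 3)) - grid$spacing / 2
  fov_hi <- voxel_to_world(grid, matrix(grid$dims - 1, 1, 3)) + grid$spacing / 2
  .assert(all(sweep(mid, 2, as.numeric(fov_lo), `>=`)) &&
            all(sweep(mid, 2, as.numeric(fov_hi), `<=`)),
          "grid does not cover the sheet")
  pts <- world_to_voxel_raw(grid, mid[labels, , drop = FALSE])
  ind <- array(as.numeric(.bk_mark_near(pts, as.integer(grid$dims),
                                        as.numeric(grid$spacing),
                                        sheet$thickness / 2)),
               grid$dims)
  r <- .task_regressor(design, delay, dispersion)
  nt <- length(r)
  trace <- trace %||% make_motion_trace(nt, amplitudes = 0)
  .assert(length(trace) == nt, "trace length must match the design")
  .with_seed(seed, NULL)
  out <- array(0, c(grid$dims, nt))
  for (t in seq_len(nt)) {
    frame <- baseline + amplitude * r[t] * ind
    if (noise_sd > 0)
      frame <- frame + rnorm(length(frame), 0, noise_sd)
    tr <- trace$transforms[[t]]
    if (max(abs(tr$matrix - diag(4))) > 1e-12) {
      fv <- volume(array(frame, grid$dims), grid, check = FALSE)
      frame <- resample_rigid(fv, tr, method = "linear", fill = baseline)$data
    }
    out[, , , t] <- frame
  }
  volume(out, grid, check = FALSE)
}

#' Synthetic rigid motion trace
#'
#' Sinusoidal or random-walk excursions of the six rigid parameters, zeroed
#' at the (middle) reference frame and scaled so the maximum excursion of
#' each parameter equals its requested amplitude.
#'
#' @param nframes number of frames (>= 1).
#' @param amplitudes per-parameter peak excursions, named
#'   `(roll, pitch, yaw, dS, dL, dP)` in degrees/mm; a scalar is recycled.
#' @param style `"sinusoidal"` or `"random_walk"`.
#' @param cycles sinusoid cycles across the run.
#' @param center rotation centre passed to the transforms.
#' @param seed RNG seed (random-walk style and sinusoid phases).
#' @return A [motion_trace()] with the middle frame as reference.
#' @export
make_motion_trace <- function(nframes, amplitudes = 0.5,
                              style = c("sinusoidal", "random_walk"),
                              cycles = 2, center = c(0, 0, 0), seed = NULL) {
  style <- match.arg(style)
  .assert(nframes >= 1, "nframes must be >= 1")
  amplitudes <- rep_len(as.numeric(amplitudes), 6)
  ref <- (nframes + 1L) %/% 2L
  .with_seed(seed, NULL)
  par <- matrix(0, nframes, 6)
  tt <- seq_len(nframes)
  for (k in 1:6) {
    if (amplitudes[k] <= 0) next
    if (style == "sinusoidal") {
      ph <- runif(1, 0, 2 * pi)
      s <- sin(2 * pi * cycles * (tt - ref) / nframes + ph) -
        sin(ph)
    } else {
      s <- cumsum(rnorm(nframes))
      s <- s - s[ref]
    }
    mx <- max(abs(s))
    par[, k] <- if (mx > 0) amplitudes[k] * s / mx else 0
  }
  trace_from_params(par, ref, center)
}

#' Smooth random Gaussian-blob phantom
#'
#' A structured 3D image (sum of anisotropic Gaussian blobs with random
#' centres, widths and amplitudes) with non-zero intensity gradient over most
#' of the field of view -- the standard target for motion-estimation
#' simulations.
#'
#' @param grid a [voxel_grid()].
#' @param n_blobs number of blobs (>= 1).
#' @param width_range FWHM range of the blobs (mm).
#' @param seed RNG seed.
#' @return A 3D [volume()].
#' @export
make_smooth_phantom <- function(grid, n_blobs = 30, width_range = c(2, 5),
                                seed = NULL) {
  .assert(n_blobs >= 1, "n_blobs must be >= 1")
  .with_seed(seed, NULL)
  pts <- voxel_to_world(grid, grid_index_matrix(grid))
  fov <- grid$dims * grid$spacing
  ctr <- grid_center_world(grid)
  acc <- numeric(nrow(pts))
  for (b in seq_len(n_blobs)) {
    c0 <- ctr + runif(3, -0.4, 0.4) * fov
    sig <- runif(3, width_range[1], width_range[2]) * FWHM_TO_SIGMA
    amp <- runif(1, 0.5, 1.5)
    acc <- acc + amp * exp(-((pts[, 1] - c0[1])^2 / (2 * sig[1]^2) +
                               (pts[, 2] - c0[2])^2 / (2 * sig[2]^2) +
                               (pts[, 3] - c0[3])^2 / (2 * sig[3]^2)))
  }
  volume(array(acc, grid$dims), grid, check = FALSE)
}
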