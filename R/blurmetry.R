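## Monte-Carlo white-noise blur quantification: TSTD <-> FWHM lookup tables
## and voxel-/vertex-wise equivalent-FWHM maps.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Synthetic i.i.d. white-noise 4D series
#'
#' Standard-normal noise per voxel and frame; the long time dimension reduces
#' the across-voxel variance of the temporal standard deviation (TSTD).
#'
#' @param grid a [voxel_grid()].
#' @param nframes number of frames (>= 2).
#' @param seed RNG seed for reproducibility.
#' @return A 4D [volume()].
#' @export
white_noise_series <- function(grid, nframes, seed = NULL) {
  .assert(nframes >= 2, "nframes must be >= 2")
  .with_seed(seed, NULL)
  volume(array(rnorm(prod(grid$dims) * nframes), c(grid$dims, nframes)),
         grid, check = FALSE)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-3) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves each frame with a sampled Gaussian of the requested FWHM (mm,
#' per axis), `sigma = FWHM / (2 sqrt(2 ln 2))`, truncated at 4 sigma and
#' renormalised at the borders so constants are preserved.
#'
#' @param v a [volume()].
#' @param fwhm kernel FWHM in mm (scalar or per axis); 0 is the identity.
#' @return The smoothed [volume()].
#' @export
gaussian_smooth <- function(v, fwhm) {
  .assert(is_volume(v), "v must be a volume")
  fwhm <- rep_len(as.numeric(fwhm), 3)
  .assert(all(fwhm >= 0), "fwhm must be non-negative")
  sig_vox <- fwhm * FWHM_TO_SIGMA / v$grid$spacing
  kerns <- lapply(sig_vox, gaussian_kernel_1d)
  if (all(lengths(kerns) == 1)) return(v)
  d <- v$grid$dims
  out <- v$data
  if (v$nframes == 1L) {
    x <- as.numeric(out)
    for (ax in 0:2)
      if (length(kerns[[ax + 1]]) > 1)
        x <- .bk_conv_axis(x, as.integer(d), kerns[[ax + 1]], ax)
    out <- array(x, d)
  } else {
    for (t in seq_len(v$nframes)) {
      x <- as.numeric(v$data[, , , t])
      for (ax in 0:2)
        if (length(kerns[[ax + 1]]) > 1)
          x <- .bk_conv_axis(x, as.integer(d), kerns[[ax + 1]], ax)
      out[, , , t] <- x
    }
  }
  volume(out, v$grid, check = FALSE)
}

#' Temporal standard deviation map
#'
#' Per-location sample standard deviation over frames (denominator `n - 1`).
#'
#' @param x a 4D [volume()] or a [surface_map()] time series.
#' @return A 3D [volume()] or scalar [surface_map()] of TSTD values.
#' @export
tstd_map <- function(x) {
  if (is_volume(x)) {
    .assert(x$nframes >= 2, "need at least 2 frames")
    m <- x$data
    dim(m) <- c(prod(x$grid$dims), x$nframes)
    out <- volume(array(.row_sds(m), x$grid$dims), x$grid, check = FALSE)
    attr(out, "source_spacing") <- x$grid$spacing
    return(out)
  }
  if (is_surface_map(x)) {
    .assert(is.matrix(x$values) && ncol(x$values) >= 2, "need at least 2 frames")
    return(surface_map(.row_sds(x$values), x$nvert, x$oob))
  }
  stop("x must be a volume or surface_map", call. = FALSE)
}

.row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(0, (rowSums(m * m) - n * mu^2) / (n - 1)))
}

#' Build a TSTD -> FWHM lookup table on a given grid spacing
#'
#' Applies Gaussian kernels of increasing FWHM to one white-noise series and
#' records the mean (and across-voxel spread) of the per-voxel TSTD over an
#' interior mask that excludes a border of three kernel sigmas. For
#' unit-variance input the mean TSTD decreases monotonically with FWHM beyond
#' a sub-voxel plateau whose extent shrinks with finer grid spacing; the
#' table inverts that relationship.
#'
#' @param grid_spacing isotropic voxel size of the table's grid (mm).
#' @param fwhm_grid ascending kernel widths (mm); default 0.1-3.9 in 0.2
#'   steps.
#' @param nframes frames in the calibration noise series (more frames, less
#'   variance); a warning is issued below 50.
#' @param seed RNG seed.
#' @param dim voxels per axis of the calibration grid.
#' @return A `blur_lookup` with fields `fwhm`, `tstd_mean`, `tstd_sd`,
#'   `grid_spacing`, `plateau_edge`.
#' @export
build_lookup <- function(grid_spacing, fwhm_grid = seq(0.1, 3.9, by = 0.2),
                         nframes = 1000, seed = 1, dim = 64) {
  .assert(all(diff(fwhm_grid) > 0), "fwhm_grid must be sorted ascending")
  if (nframes < 50)
    warning("nframes < 50 gives an imprecise lookup table")
  grid <- voxel_grid(rep(dim, 3), grid_spacing)
  noise <- white_noise_series(grid, nframes, seed)
  tmean <- tsd <- numeric(length(fwhm_grid))
  for (i in seq_along(fwhm_grid)) {
    sm <- gaussian_smooth(noise, fwhm_grid[i])
    ts <- tstd_map(sm)
    border <- max(2L, ceiling(3 * fwhm_grid[i] * FWHM_TO_SIGMA / grid_spacing))
    core <- ts$data[(border + 1):(dim - border),
                    (border + 1):(dim - border),
                    (border + 1):(dim - border)]
    tmean[i] <- mean(core)
    tsd[i] <- sd(core)
  }
  new_blur_lookup(fwhm_grid, tmean, tsd, grid_spacing, nframes, seed, dim)
}

new_blur_lookup <- function(fwhm, tstd_mean, tstd_sd, grid_spacing,
                            nframes = NA, seed = NA, dim = NA) {
  ## monotone non-increasing envelope; the inversion starts at the plateau
  ## edge so any TSTD at or above the plateau ceiling maps to the edge (the
  ## minimal detectable blur on this grid)
  m <- cummin(tstd_mean)
  plateau_tol <- 0.003
  edge_idx <- max(which(m >= m[1] - plateau_tol))
  sel <- edge_idx:length(m)
  kp <- !duplicated(m[sel], fromLast = TRUE)
  structure(list(fwhm = fwhm, tstd_mean = tstd_mean, tstd_sd = tstd_sd,
                 grid_spacing = grid_spacing, nframes = nframes, seed = seed,
                 dim = dim,
                 inv_x = m[sel][kp], inv_y = fwhm[sel][kp],
                 plateau_edge = fwhm[edge_idx]),
            class = "blur_lookup")
}

#' @export
print.blur_lookup <- function(x, ...) {
  cat(sprintf(
    "<blur_lookup> %.2g-mm grid, FWHM %.1f-%.1f mm (%d levels), plateau edge %.2f mm\n",
    x$grid_spacing, min(x$fwhm), max(x$fwhm), length(x$fwhm), x$plateau_edge))
  invisible(x)
}

#' @export
tidy.blur_lookup <- function(x, ...)
  tibble::tibble(fwhm = x$fwhm, tstd_mean = x$tstd_mean, tstd_sd = x$tstd_sd)

#' @export
autoplot.blur_lookup <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fwhm, y = .data$tstd_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$tstd_mean - .data$tstd_sd,
                                          ymax = .data$tstd_mean + .data$tstd_sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "applied Gaussian FWHM (mm)",
                  y = "mean TSTD of unit white noise",
                  title = sprintf("TSTD-FWHM transfer function (%g-mm grid)",
                                  object$grid_spacing))
}

#' Plateau edge of a lookup table
#'
#' The largest tabulated FWHM still indistinguishable from no smoothing on
#' this grid (the minimal detectable blur).
#'
#' @param lookup a `blur_lookup`.
#' @return FWHM in mm.
#' @export
plateau_edge <- function(lookup) lookup$plateau_edge

#' Convert a TSTD map to an equivalent-FWHM map
#'
#' Piecewise-linear inversion of the lookup table. TSTD values at or above
#' the plateau ceiling map to the plateau edge; values below the table
#' minimum are clipped to the largest tabulated FWHM and flagged.
#'
#' @param tstd a TSTD [volume()] or [surface_map()] (see [tstd_map()]), or a
#'   plain numeric vector.
#' @param lookup a `blur_lookup` built on the matching grid spacing.
#' @return Same container as `tstd`, holding FWHM in mm; clipped locations
#'   are flagged in `attr(, "clipped_low")`.
#' @export
fwhm_from_tstd <- function(tstd, lookup) {
  vals <- if (is_volume(tstd)) as.numeric(tstd$data) else
    if (is_surface_map(tstd)) tstd$values else as.numeric(tstd)
  if (is_volume(tstd)) {
    sp <- attr(tstd, "source_spacing") %||% tstd$grid$spacing
    .assert(max(abs(sp - lookup$grid_spacing)) < 1e-6,
            "TSTD grid spacing does not match the lookup table")
  }
  x <- rev(lookup$inv_x)
  y <- rev(lookup$inv_y)
  f <- approx(x, y, xout = vals, rule = 2)$y
  clipped <- vals < min(x)
  if (is_volume(tstd)) {
    out <- volume(array(f, tstd$grid$dims), tstd$grid, check = FALSE)
  } else if (is_surface_map(tstd)) {
    out <- surface_map(f, tstd$nvert, tstd$oob)
  } else out <- f
  attr(out, "clipped_low") <- clipped
  out
}

#' Audit the blur introduced by a preprocessing stage
#'
#' The generic "spatial error bar": push a white-noise series through an
#' arbitrary preprocessing pipeline, measure the per-location TSTD of the
#' output, and convert it to the equivalent Gaussian FWHM via the lookup
#' table. Pipelines may return a 4D volume (same or different grid) or a
#' surface-map series.
#'
#' @param pipeline function taking and returning a 4D [volume()] (or
#'   returning a [surface_map()] series).
#' @param grid input [voxel_grid()] for the noise.
#' @param lookup `blur_lookup` matching the *output* grid spacing.
#' @param nframes frames of calibration noise.
#' @param seed RNG seed.
#' @param margin border voxels excluded from volume summaries.
#' @return A `blur_audit` with the FWHM map (`fwhm`), the analysed values
#'   (`fwhm_values`), and summary fields `mean`, `sd`, `n`, `plateau_edge`.
#' @export
blur_audit <- function(pipeline, grid, lookup, nframes = 1000, seed = NULL,
                       margin = 4) {
  noise <- white_noise_series(grid, nframes, seed)
  out <- pipeline(noise)
  rm(noise); gc(FALSE) # long 4D series dominate memory; free eagerly
  ts <- tstd_map(out)
  rm(out); gc(FALSE)
  fw <- fwhm_from_tstd(ts, lookup)
  if (is_volume(fw)) {
    d <- fw$grid$dims
    m <- pmin(margin, (d - 1) %/% 3)
    core <- fw$data[(m[1] + 1):(d[1] - m[1]),
                    (m[2] + 1):(d[2] - m[2]),
                    (m[3] + 1):(d[3] - m[3])]
    vals <- as.numeric(core)
  } else {
    vals <- fw$values[!fw$oob]
  }
  structure(list(fwhm = fw, fwhm_values = vals, mean = mean(vals),
                 sd = sd(vals), n = length(vals),
                 plateau_edge = lookup$plateau_edge),
            class = "blur_audit")
}

#' @export
print.blur_audit <- function(x, ...) {
  cat(sprintf("<blur_audit> mean FWHM %.3f mm (sd %.3f, n %d); plateau edge %.2f mm\n",
              x$mean, x$sd, x$n, x$plateau_edge))
  invisible(x)
}

#' @export
glance.blur_audit <- function(x, ...)
  tibble::tibble(mean_fwhm = x$mean, sd_fwhm = x$sd, n = x$n,
                 plateau_edge = x$plateau_edge,
                 excess_fwhm = x$mean - x$plateau_edge)

#' @export
autoplot.blur_audit <- function(object, ...) {
  ggplot2::ggplot(data.frame(fwhm = object$fwhm_values),
                  ggplot2::aes(x = .data$fwhm)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = object$plateau_edge, linetype = 2) +
    ggplot2::labs(x = "equivalent FWHM (mm)", y = "locations",
                  title = "Blur audit (dashed: lookup plateau edge)")
}

#' Persist / load a lookup table (TSV + JSON metadata)
#'
#' @param lookup a `blur_lookup`.
#' @param path TSV path; metadata goes to `paste0(path, ".json")`.
#' @return `path` / a `blur_lookup`.
#' @export
write_lookup <- function(lookup, path) {
  write.table(data.frame(fwhm = lookup$fwhm, tstd_mean = lookup$tstd_mean,
                         tstd_sd = lookup$tstd_sd),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(grid_spacing = lookup$grid_spacing,
                            nframes = lookup$nframes, seed = lookup$seed,
                            dim = lookup$dim),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_blur_lookup(tab$fwhm, tab$tstd_mean, tab$tstd_sd, meta$grid_spacing,
                  meta$nframes, meta$seed, meta$dim)
}
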