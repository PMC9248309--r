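## Triangle meshes, FreeSurfer surface/curv I/O, midpoint refinement,
## equidistant intracortical surfaces, volume-to-surface projection,
## unique-voxel accounting, radial smoothing, vertex clustering.

#' Triangulated surface mesh in world mm
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  .finite_check(vertices, "vertices")
  .assert(all(faces >= 1) && all(faces <= nrow(vertices)),
          "face indices out of range")
  .assert(!any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
                 faces[, 1] == faces[, 3]),
          "degenerate faces (repeated vertex index)")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

is_mesh <- function(x) inherits(x, "triangle_mesh")

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Unique undirected edges of a mesh
#' @param mesh a [triangle_mesh()].
#' @return 2-column integer matrix of vertex pairs (first index < second).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e[, 1] * (nrow(mesh$vertices) + 1) + e[, 2]), , drop = FALSE]
}

mesh_edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Area-weighted outward vertex normals
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1]) # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, f[, k])
    ids <- as.integer(rownames(acc))
    n[ids, ] <- n[ids, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

## ---- FreeSurfer binary formats ---------------------------------------------

.fs_read_raw <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 16) stop("not a FreeSurfer surface file: ", path,
                                 call. = FALSE)
  readBin(path, "raw", n = sz)
}

#' Read/write FreeSurfer binary triangle surfaces
#'
#' The classic big-endian triangle format (magic `0xFFFFFE`): a creator
#' string terminated by two newlines, vertex and face counts, float32 vertex
#' coordinates and int32 face indices. Round-trips are lossless for float32
#' coordinates.
#'
#' @param path file path.
#' @return `read_surface`: a [triangle_mesh()]; `write_surface`: `path`.
#' @export
read_surface <- function(path) {
  r <- .fs_read_raw(path)
  if (!identical(as.integer(r[1:3]), c(255L, 255L, 254L)))
    stop("bad magic number: not a FreeSurfer triangle surface", call. = FALSE)
  nl <- which(r[-length(r)] == as.raw(10) & r[-1] == as.raw(10))
  .assert(length(nl) >= 1, "corrupt surface header")
  off <- nl[1] + 2 # first byte after the header
  con <- rawConnection(r[off:length(r)])
  on.exit(close(con))
  counts <- readBin(con, "integer", 2, size = 4, endian = "big")
  nv <- counts[1]; nf <- counts[2]
  .assert(nv > 0 && nf >= 0 && length(r) - off + 1 >= 8 + 12 * nv + 12 * nf,
          "truncated surface file")
  vert <- readBin(con, "numeric", 3 * nv, size = 4, endian = "big")
  face <- readBin(con, "integer", 3 * nf, size = 4, endian = "big")
  triangle_mesh(matrix(vert, ncol = 3, byrow = TRUE),
                matrix(face, ncol = 3, byrow = TRUE) + 1L)
}

#' @rdname read_surface
#' @param mesh a [triangle_mesh()].
#' @export
write_surface <- function(mesh, path) {
  .assert(is_mesh(mesh), "mesh must be a triangle_mesh")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 254)), con)
  writeBin(charToRaw("created by blurkit\n\n"), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read/write FreeSurfer "curv" per-vertex scalar files
#'
#' New-format curv (magic `0xFFFFFF`, big-endian float32 values).
#'
#' @param path file path.
#' @return `read_curv`: numeric vector; `write_curv`: `path` invisibly.
#' @export
read_curv <- function(path) {
  r <- .fs_read_raw(path)
  if (!identical(as.integer(r[1:3]), c(255L, 255L, 255L)))
    stop("bad magic number: not a new-format curv file", call. = FALSE)
  con <- rawConnection(r[4:length(r)])
  on.exit(close(con))
  hdr <- readBin(con, "integer", 3, size = 4, endian = "big")
  readBin(con, "numeric", hdr[1] * hdr[3], size = 4, endian = "big")
}

#' @rdname read_curv
#' @param values per-vertex numeric vector.
#' @param nfaces face count recorded in the header (metadata only).
#' @export
write_curv <- function(values, path, nfaces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 255)), con)
  writeBin(as.integer(c(length(values), nfaces, 1L)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

## ---- midpoint refinement ----------------------------------------------------

#' Midpoint ("butterfly"-style) mesh refinement
#'
#' Each iteration inserts a vertex at the midpoint of every edge and splits
#' each triangle into four. The polyhedral geometry and the positions of the
#' original vertices are unchanged; per iteration `V' = V + E` and `F' = 4F`,
#' and every edge length is exactly halved. New vertices are appended after
#' the originals, ordered by their (sorted) parent edge, so the ordering is
#' deterministic. The parent-edge bookkeeping of every iteration is kept in
#' `attr(mesh, "lineage")` for label inheritance (see
#' [inherit_binary_labels()]).
#'
#' @param mesh a [triangle_mesh()]; edges with more than two incident faces
#'   (non-manifold) are rejected.
#' @param iterations number of refinement passes (>= 0).
#' @return The refined [triangle_mesh()].
#' @export
refine_mesh <- function(mesh, iterations = 1) {
  .assert(is_mesh(mesh), "mesh must be a triangle_mesh")
  .assert(iterations >= 0, "iterations must be >= 0")
  lineage <- attr(mesh, "lineage") %||% list()
  for (it in seq_len(iterations)) {
    v <- mesh$vertices
    f <- mesh$faces
    nv <- nrow(v)
    half <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    key <- pmin(half[, 1], half[, 2]) * (nv + 1) + pmax(half[, 1], half[, 2])
    .assert(max(table(key)) <= 2, "non-manifold edge (more than two incident faces)")
    ekey <- sort(unique(key))
    mid_id <- nv + match(key, ekey) # per face-edge midpoint vertex index
    e1 <- ekey %/% (nv + 1) # lower endpoint (1..nv, so the remainder is never 0)
    e2 <- ekey - e1 * (nv + 1)
    mids <- (v[e1, , drop = FALSE] + v[e2, , drop = FALSE]) / 2
    nf <- nrow(f)
    mab <- mid_id[seq_len(nf)]
    mbc <- mid_id[nf + seq_len(nf)]
    mca <- mid_id[2 * nf + seq_len(nf)]
    newf <- rbind(cbind(f[, 1], mab, mca),
                  cbind(mab, f[, 2], mbc),
                  cbind(mca, mbc, f[, 3]),
                  cbind(mab, mbc, mca))
    mesh <- triangle_mesh(rbind(v, mids), newf)
    lineage[[length(lineage) + 1]] <- cbind(parent1 = e1, parent2 = e2)
  }
  attr(mesh, "lineage") <- lineage
  mesh
}

#' Carry binary vertex labels through midpoint refinement
#'
#' A midpoint vertex is labelled only when both parent vertices carry the
#' label, so disjoint label sets stay disjoint under refinement.
#'
#' @param labels logical vector on the unrefined mesh.
#' @param refined_mesh output of [refine_mesh()] (its lineage is used).
#' @return Logical vector on the refined mesh.
#' @export
inherit_binary_labels <- function(labels, refined_mesh) {
  labels <- as.logical(labels)
  for (par in attr(refined_mesh, "lineage") %||% list())
    labels <- c(labels, labels[par[, 1]] & labels[par[, 2]])
  .assert(length(labels) == nrow(refined_mesh$vertices),
          "labels do not match the refinement lineage")
  labels
}

## ---- equidistant surfaces ---------------------------------------------------

#' Family of equidistant intracortical surfaces
#'
#' Linear interpolation between a white-matter surface (depth 0) and a pial
#' surface (depth 1) sharing the same topology: vertex i at depth d is
#' `(1 - d) * white_i + d * pial_i`. A step of 0.1 yields the conventional 11
#' surfaces at 10% thickness intervals.
#'
#' @param white,pial [triangle_mesh()] objects with identical faces.
#' @param step depth step; must divide 1 evenly.
#' @return A `surface_family` with fields `depths` and `meshes`.
#' @export
equidistant_family <- function(white, pial, step = 0.1) {
  .assert(is_mesh(white) && is_mesh(pial), "white/pial must be triangle meshes")
  .assert(nrow(white$vertices) == nrow(pial$vertices) &&
            identical(white$faces, pial$faces),
          "white and pial must share topology")
  n <- 1 / step
  .assert(abs(n - round(n)) < 1e-8, "step must divide 1 evenly")
  depths <- seq(0, 1, by = step)
  meshes <- lapply(depths, function(d)
    triangle_mesh((1 - d) * white$vertices + d * pial$vertices, white$faces))
  structure(list(depths = depths, meshes = meshes), class = "surface_family")
}

#' @export
print.surface_family <- function(x, ...) {
  cat(sprintf("<surface_family> %d surfaces, depths %s..%s, %d vertices\n",
              length(x$depths), min(x$depths), max(x$depths),
              nrow(x$meshes[[1]]$vertices)))
  invisible(x)
}

## ---- volume-to-surface projection ------------------------------------------

#' Per-vertex scalar map (or time series) on a mesh
#'
#' @param values numeric vector (one value per vertex) or matrix
#'   (vertex x frame).
#' @param nvert vertex count of the mesh the map indexes.
#' @param oob logical vector flagging vertices that fell outside the volume
#'   field of view during projection.
#' @return A `surface_map`.
#' @export
surface_map <- function(values, nvert = NULL, oob = NULL) {
  if (is.matrix(values)) n <- nrow(values) else n <- length(values)
  nvert <- nvert %||% n
  .assert(n == nvert, "one value (or series) per vertex required")
  structure(list(values = values, nvert = nvert,
                 oob = oob %||% rep(FALSE, nvert)),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  nf <- if (is.matrix(x$values)) ncol(x$values) else 1L
  cat(sprintf("<surface_map> %d vertices, %d frame(s), %d outside FOV\n",
              x$nvert, nf, sum(x$oob)))
  invisible(x)
}

is_surface_map <- function(x) inherits(x, "surface_map")

map_values <- function(x) if (is_surface_map(x)) x$values else x

#' Project a volume onto a surface mesh
#'
#' Each mesh vertex is carried into the volume's world frame by `reg` and
#' sampled from the voxel grid: `nearest` takes the voxel whose centre is
#' closest to the transformed vertex; `linear` applies trilinear weights over
#' the 8 surrounding voxels. Vertices outside the voxel-centre hull are
#' assigned `fill` and flagged in the map's `oob` field. 4D input yields a
#' per-vertex time series.
#'
#' @param v a [volume()].
#' @param mesh a [triangle_mesh()].
#' @param reg rigid transform taking mesh world coordinates into the volume's
#'   world frame (default identity).
#' @param method `"nearest"` or `"linear"`.
#' @param fill value for out-of-field vertices.
#' @return A [surface_map()].
#' @export
vol2surf <- function(v, mesh, reg = NULL, method = c("nearest", "linear"),
                     fill = 0) {
  method <- match.arg(method)
  .assert(is_volume(v), "v must be a volume")
  .assert(is_mesh(mesh), "mesh must be a triangle_mesh")
  reg <- reg %||% rigid_identity()
  pts <- apply_transform(reg, mesh$vertices)
  coords <- world_to_voxel_raw(v$grid, pts)
  d <- v$grid$dims
  oob <- coords[, 1] < -0.5 | coords[, 1] > d[1] - 0.5 |
    coords[, 2] < -0.5 | coords[, 2] > d[2] - 0.5 |
    coords[, 3] < -0.5 | coords[, 3] > d[3] - 0.5
  vals <- .sample_volume_frames(v, coords, method, fill)
  vals[oob, ] <- fill
  if (ncol(vals) == 1L) vals <- vals[, 1]
  surface_map(vals, nrow(mesh$vertices), oob)
}

#' Single-interpolation projection through composed transforms
#'
#' Projects each frame of a raw (uncorrected) series directly onto the mesh
#' through the composition of the frame's motion transform with the
#' anatomical registration, so the data are interpolated exactly once and no
#' volumetric resampling occurs anywhere on the path.
#'
#' @param raw_series 4D [volume()], uncorrected.
#' @param trace [motion_trace()], one transform per frame (forward motion).
#' @param reg rigid mesh-to-reference-volume registration.
#' @param mesh a [triangle_mesh()].
#' @param method `"nearest"` or `"linear"`.
#' @param fill fill value outside the field of view.
#' @return A [surface_map()] with a vertex x frame series.
#' @export
vol2surf_composed <- function(raw_series, trace, reg = NULL, mesh,
                              method = c("nearest", "linear"), fill = 0) {
  method <- match.arg(method)
  .assert(is_volume(raw_series), "raw_series must be a volume")
  .assert(length(trace) == raw_series$nframes,
          "trace length must equal the frame count")
  reg <- reg %||% rigid_identity()
  g <- raw_series$grid
  d <- g$dims
  nv <- nrow(mesh$vertices)
  nt <- raw_series$nframes
  vals <- matrix(fill, nv, nt)
  oob <- rep(FALSE, nv)
  code <- interpolant(method)$code
  for (t in seq_len(nt)) {
    comp <- compose_transforms(list(reg, trace$transforms[[t]]))
    coords <- world_to_voxel_raw(g, apply_transform(comp, mesh$vertices))
    bad <- coords[, 1] < -0.5 | coords[, 1] > d[1] - 0.5 |
      coords[, 2] < -0.5 | coords[, 2] > d[2] - 0.5 |
      coords[, 3] < -0.5 | coords[, 3] > d[3] - 0.5
    oob <- oob | bad
    frame <- if (nt > 1L) raw_series$data[, , , t] else raw_series$data
    vv <- .bk_sample3d(as.numeric(frame), as.integer(d), coords, code, fill)
    vv[bad] <- fill
    vals[, t] <- vv
  }
  surface_map(vals, nv, oob)
}

## Densify a mesh geometry-preservingly until the longest edge is below
## `target` (mm); returns the vertex set (used for surface-distance queries).
.dense_surface_points <- function(mesh, target, max_iter = 8) {
  for (i in seq_len(max_iter)) {
    if (max(mesh_edge_lengths(mesh)) <= target) break
    mesh <- refine_mesh(mesh, 1)
  }
  mesh$vertices
}

#' Unique-voxel accounting for a surface projection
#'
#' Projects a volume whose voxels carry unique indices onto the mesh with
#' nearest-neighbour interpolation and counts how many distinct voxels are
#' referenced by at least one vertex. The denominator counts the voxels whose
#' centres lie within one voxel diagonal of the surface (measured against a
#' densified copy of `candidate_from`, by default the mesh itself), so the
#' proportion tracks how many of the voxels sampling the surface actually
#' reach a vertex.
#'
#' @param grid a [voxel_grid()].
#' @param mesh a [triangle_mesh()].
#' @param reg rigid mesh-to-volume registration (default identity).
#' @param candidate_from mesh defining the candidate voxel set; pass the
#'   unrefined mesh when comparing refinement iterations so the denominator
#'   stays fixed.
#' @return A `projection_report` with `unique_voxel_count`,
#'   `total_candidate_voxels` and `proportion`.
#' @export
unique_voxel_report <- function(grid, mesh, reg = NULL, candidate_from = mesh) {
  reg <- reg %||% rigid_identity()
  nvox <- prod(grid$dims)
  idxvol <- volume(array(seq_len(nvox), grid$dims), grid, check = FALSE)
  m <- vol2surf(idxvol, mesh, reg, "nearest", fill = NA_real_)
  hit <- m$values[!m$oob & !is.na(m$values)]
  uniq <- length(unique(hit))
  pts <- .dense_surface_points(candidate_from, min(grid$spacing) / 2)
  coords <- world_to_voxel_raw(grid, apply_transform(reg, pts))
  near <- .bk_mark_near(coords, as.integer(grid$dims),
                        as.numeric(grid$spacing),
                        sqrt(sum(grid$spacing^2)))
  total <- sum(near)
  structure(list(unique_voxel_count = uniq,
                 total_candidate_voxels = total,
                 proportion = uniq / max(total, 1)),
            class = "projection_report")
}

#' @export
print.projection_report <- function(x, ...) {
  cat(sprintf("<projection_report> %d of %d candidate voxels reached (%.1f%%)\n",
              x$unique_voxel_count, x$total_candidate_voxels,
              100 * x$proportion))
  invisible(x)
}

#' Unique-voxel proportion across refinement iterations
#'
#' @inheritParams unique_voxel_report
#' @param iterations maximum refinement iteration (0 = original mesh).
#' @return A tibble with `iteration`, `unique_voxels`, `total_candidates`,
#'   `proportion`.
#' @export
unique_voxel_curve <- function(grid, mesh, reg = NULL, iterations = 4) {
  rows <- vector("list", iterations + 1)
  cur <- mesh
  for (i in 0:iterations) {
    rep <- unique_voxel_report(grid, cur, reg, candidate_from = mesh)
    rows[[i + 1]] <- tibble::tibble(iteration = i,
                                    unique_voxels = rep$unique_voxel_count,
                                    total_candidates = rep$total_candidate_voxels,
                                    proportion = rep$proportion)
    if (i < iterations) cur <- refine_mesh(cur, 1)
  }
  dplyr::bind_rows(rows)
}

## ---- intracortical (radial) smoothing --------------------------------------

#' Radial-only intracortical smoothing
#'
#' Averages per-vertex values across cortical-depth surfaces inside
#' `depth_range`, with no tangential (cross-vertex) mixing. The default
#' uniform kernel over depths 0-0.2 follows the conservative deep-cortex
#' window used for columnar mapping.
#'
#' @param maps list of [surface_map()] (or plain vectors/matrices), one per
#'   family depth, aligned with `family$depths`.
#' @param family the [equidistant_family()] the maps were sampled on.
#' @param depth_range inclusive depth interval to average over.
#' @param weights `"uniform"`, `"gaussian"` (over depth, sd =
#'   `gaussian_sd`), or a numeric vector over the included depths.
#' @param gaussian_sd depth-units sd for the Gaussian kernel.
#' @return A [surface_map()] of the radially smoothed values.
#' @export
intracortical_smooth <- function(maps, family, depth_range = c(0, 0.2),
                                 weights = "uniform", gaussian_sd = 0.1) {
  .assert(length(maps) == length(family$depths),
          "need one map per family depth")
  .assert(length(depth_range) == 2 && depth_range[2] >= depth_range[1],
          "depth_range must be an interval")
  sel <- which(family$depths >= depth_range[1] - 1e-9 &
                 family$depths <= depth_range[2] + 1e-9)
  .assert(length(sel) >= 1, "empty depth_range")
  if (is.character(weights)) {
    w <- switch(match.arg(weights, c("uniform", "gaussian")),
                uniform = rep(1, length(sel)),
                gaussian = exp(-(family$depths[sel] - mean(depth_range))^2 /
                                 (2 * gaussian_sd^2)))
  } else {
    .assert(length(weights) == length(sel),
            "weights must match the included depths")
    w <- as.numeric(weights)
  }
  w <- w / sum(w)
  vals <- map_values(maps[[sel[1]]]) * w[1]
  if (length(sel) > 1)
    for (k in 2:length(sel))
      vals <- vals + map_values(maps[[sel[k]]]) * w[k]
  oob <- Reduce(`|`, lapply(maps[sel], function(m)
    if (is_surface_map(m)) m$oob else FALSE))
  surface_map(vals, oob = if (is.logical(oob) && length(oob) > 1) oob else NULL)
}

## ---- vertex clustering ------------------------------------------------------

#' Connected clusters of a binary vertex map
#'
#' Clusters are connected components of the supra-threshold vertex set under
#' mesh edge adjacency.
#'
#' @param mask logical vector (or binary [surface_map()]).
#' @param mesh the [triangle_mesh()] providing adjacency.
#' @return List of integer vectors (vertex indices), largest first.
#' @export
vertex_clusters <- function(mask, mesh) {
  mask <- as.logical(map_values(mask))
  hot <- which(mask)
  if (length(hot) == 0) return(list())
  e <- mesh_edges(mesh)
  e <- e[mask[e[, 1]] & mask[e[, 2]], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(hot)))
  comp <- igraph::components(g)
  ids <- as.integer(igraph::V(g)$name)
  out <- split(ids, comp$membership)
  out <- lapply(out, sort)
  names(out) <- NULL
  out[order(-vapply(out, length, 1L))]
}

#' Remove clusters smaller than a minimum vertex count
#'
#' @inheritParams vertex_clusters
#' @param min_size smallest surviving cluster size (vertices).
#' @return Logical vector with small clusters removed.
#' @export
filter_clusters <- function(mask, mesh, min_size = 2) {
  mask <- as.logical(map_values(mask))
  cl <- vertex_clusters(mask, mesh)
  out <- rep(FALSE, length(mask))
  for (c in cl) if (length(c) >= min_size) out[c] <- TRUE
  out
}
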