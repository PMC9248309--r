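# Mesh model, FreeSurfer I/O, refinement, surface families, projection,
# unique-voxel accounting, radial smoothing, clustering.

test_that("FreeSurfer surface and curv files round-trip losslessly", {
  ico <- icosahedron()
  f <- tempfile()
  write_surface(ico, f)
  r <- read_surface(f)
  # coordinates are float32 on disk; write float32-representable values
  v32 <- matrix(readBin(writeBin(as.numeric(ico$vertices), raw(), size = 4),
                        "numeric", length(ico$vertices), size = 4), ncol = 3)
  write_surface(triangle_mesh(v32, ico$faces), f)
  r <- read_surface(f)
  expect_identical(r$vertices, v32)
  expect_identical(r$faces, ico$faces)

  sheet <- make_cortical_sheet(extent = 20, spacing = 1, seed = 2)
  m32 <- triangle_mesh(
    matrix(readBin(writeBin(as.numeric(sheet$white$vertices), raw(), size = 4),
                   "numeric", length(sheet$white$vertices), size = 4),
           ncol = 3), sheet$white$faces)
  write_surface(m32, f)
  expect_equal(max(abs(read_surface(f)$vertices - m32$vertices)), 0)

  # truncated file and wrong magic raise format errors
  full <- readBin(f, "raw", file.size(f))
  writeBin(full[1:40], f) # header survives, vertex payload cut short
  expect_error(read_surface(f), "truncated")
  writeBin(as.raw(rep(1:4, 10)), f)
  expect_error(read_surface(f), "magic")

  vals <- c(0.5, -1.25, 3, 42)
  fc <- tempfile()
  write_curv(vals, fc, nfaces = 2)
  expect_equal(read_curv(fc), vals)
})

test_that("midpoint refinement follows Euler arithmetic and halves edges", {
  ico <- icosahedron()
  r1 <- refine_mesh(ico, 1)
  expect_equal(nrow(r1$vertices), 42) # V + E = 12 + 30
  expect_equal(nrow(r1$faces), 80)    # 4F
  # original vertex positions unchanged bit-exactly
  expect_identical(r1$vertices[1:12, ], ico$vertices)
  # mean edge length exactly halved (midsegment theorem)
  expect_equal(mean(blurkit:::mesh_edge_lengths(r1)),
               mean(blurkit:::mesh_edge_lengths(ico)) / 2)
  # Euler characteristic preserved for closed meshes
  chi <- function(m) nrow(m$vertices) - nrow(mesh_edges(m)) + nrow(m$faces)
  expect_equal(chi(ico), 2)
  expect_equal(chi(r1), 2)
  # closed genus-0: one iteration takes V to 4V - 6
  r2 <- refine_mesh(r1, 1)
  expect_equal(nrow(r2$vertices), 4 * nrow(r1$vertices) - 6)
  expect_equal(nrow(r2$faces), 4 * nrow(r1$faces))
  expect_identical(refine_mesh(ico, 0)$vertices, ico$vertices)
  # non-manifold input (three faces sharing an edge) is rejected
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                             c(1, 1, 1)),
                       rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(refine_mesh(bad, 1), "non-manifold")
})

test_that("equidistant surface families interpolate white to pial", {
  sheet <- make_cortical_sheet(extent = 15, spacing = 1.5, seed = 3)
  fam <- equidistant_family(sheet$white, sheet$pial, 0.1)
  expect_length(fam$meshes, 11)
  expect_equal(fam$depths, seq(0, 1, 0.1))

  fam3 <- equidistant_family(sheet$white, sheet$pial, 0.5)
  expect_length(fam3$meshes, 3)
  expect_equal(fam3$meshes[[2]]$vertices,
               (sheet$white$vertices + sheet$pial$vertices) / 2)

  fam_id <- equidistant_family(sheet$white, sheet$white, 0.5)
  for (m in fam_id$meshes) expect_identical(m$vertices, sheet$white$vertices)

  expect_error(equidistant_family(sheet$white, refine_mesh(sheet$pial, 1)),
               "topology")
  expect_error(equidistant_family(sheet$white, sheet$pial, 0.3), "step")
})

test_that("vol2surf samples voxel values correctly", {
  g <- voxel_grid(c(6, 6, 6), 1)
  set.seed(9)
  v <- volume(array(rnorm(216), c(6, 6, 6)), g)
  # vertices exactly at voxel centres return those voxels under both methods
  centres <- voxel_to_world(g, rbind(c(1, 2, 3), c(4, 4, 4)))
  mesh <- triangle_mesh(rbind(centres, centres[1, ] + c(0.5, 0, 0)),
                        matrix(c(1, 2, 3), 1))
  for (m in c("nearest", "linear")) {
    sm <- vol2surf(v, mesh, method = m)
    expect_equal(sm$values[1], v$data[2, 3, 4])
    expect_equal(sm$values[2], v$data[5, 5, 5])
  }
  # midpoint between voxel centres along x: trilinear mean of the two
  sm <- vol2surf(v, mesh, method = "linear")
  expect_equal(sm$values[3], mean(v$data[2:3, 3, 4]))
  # constant volume projects to the constant under both methods
  vc <- volume(array(7, c(6, 6, 6)), g)
  for (m in c("nearest", "linear"))
    expect_equal(unique(vol2surf(vc, mesh, method = m)$values), 7)
  # far-outside vertex is flagged and filled
  far <- triangle_mesh(rbind(centres, c(100, 0, 0)), matrix(c(1, 2, 3), 1))
  sm_far <- vol2surf(v, far, method = "nearest", fill = -99)
  expect_true(sm_far$oob[3])
  expect_equal(sm_far$values[3], -99)
})

test_that("composed projection equals per-frame projection for identity motion", {
  g <- voxel_grid(c(8, 8, 8), 1)
  set.seed(10)
  v <- volume(array(rnorm(8^3 * 4), c(8, 8, 8, 4)), g)
  sheet <- make_cortical_sheet(extent = 5, spacing = 1, fold_amplitude = 0.5,
                               seed = 4)
  trace <- make_motion_trace(4, amplitudes = 0)
  reg <- rigid_from_params(c(0, 0, 0, 0.2, -0.3, 0.1))
  for (m in c("nearest", "linear")) {
    comp <- vol2surf_composed(v, trace, reg, sheet$white, m)
    direct <- vol2surf(v, sheet$white, reg, m)
    expect_equal(comp$values, direct$values)
  }
})

test_that("projection of white noise: nearest preserves variance, linear shrinks it", {
  g <- voxel_grid(c(24, 24, 24), 1)
  noise <- white_noise_series(g, 250, seed = 12)
  sheet <- make_cortical_sheet(extent = 16, spacing = 1, seed = 5)
  reg <- rigid_from_params(c(0.5, 0.5, 0.5, 0.3, 0.3, 0.3))
  tn <- tstd_map(vol2surf_composed(noise, make_motion_trace(250, 0), reg,
                                   sheet$white, "nearest"))
  tl <- tstd_map(vol2surf_composed(noise, make_motion_trace(250, 0), reg,
                                   sheet$white, "linear"))
  ok <- !tn$oob
  # nearest: each vertex is one i.i.d. sample stream -> TSTD ~ 1
  expect_lt(abs(mean(tn$values[ok]) - 1), 3 / sqrt(2 * 249))
  # linear: convex weights strictly reduce variance
  expect_lt(mean(tl$values[ok]), mean(tn$values[ok]))
})

test_that("unique-voxel accounting counts distinct source voxels", {
  g <- voxel_grid(c(8, 8, 8), 1)
  # all vertices inside one voxel -> exactly one unique voxel
  one <- triangle_mesh(rbind(c(0.4, 0.4, 0.4), c(0.45, 0.4, 0.4),
                             c(0.4, 0.45, 0.4)),
                       matrix(c(1, 2, 3), 1))
  rep1 <- unique_voxel_report(g, one)
  expect_equal(rep1$unique_voxel_count, 1)
  expect_lte(rep1$unique_voxel_count, rep1$total_candidate_voxels)

  # flat mesh with a vertex at every voxel centre of one slice: that slice
  # is fully recovered
  idx <- as.matrix(expand.grid(x = 0:7, y = 0:7))
  verts <- voxel_to_world(g, cbind(idx, 3))
  faces <- c()
  for (r in 1:7) for (cc in 1:7) {
    a <- (r - 1) * 8 + cc
    faces <- rbind(faces, c(a, a + 1, a + 8), c(a + 1, a + 9, a + 8))
  }
  slice_mesh <- triangle_mesh(verts, faces)
  rep2 <- unique_voxel_report(g, slice_mesh)
  expect_equal(rep2$unique_voxel_count, 64)
})

test_that("unique voxels increase monotonically under refinement to a plateau", {
  sheet <- make_cortical_sheet(extent = 16, spacing = 2, seed = 6)
  g <- voxel_grid(c(22, 22, 12), 1)
  cur <- unique_voxel_curve(g, sheet$white, iterations = 3)
  expect_true(all(diff(cur$unique_voxels) >= 0))
  expect_true(all(diff(cur$proportion) >= -1e-12))
  expect_equal(length(unique(cur$total_candidates)), 1)
})

test_that("radial smoothing averages depths without tangential mixing", {
  sheet <- make_cortical_sheet(extent = 10, spacing = 1, seed = 7)
  fam <- equidistant_family(sheet$white, sheet$pial, 0.1)
  nv <- nrow(sheet$white$vertices)
  set.seed(13)
  maps <- lapply(1:11, function(i) rnorm(nv))
  out <- intracortical_smooth(maps, fam, c(0, 0.2))
  expect_equal(out$values, (maps[[1]] + maps[[2]] + maps[[3]]) / 3)

  # identical maps at all depths pass through unchanged
  same <- lapply(1:11, function(i) maps[[1]])
  expect_equal(intracortical_smooth(same, fam, c(0, 0.3))$values, maps[[1]])

  # a single hot vertex stays confined to that vertex
  hot <- lapply(1:11, function(i) { z <- numeric(nv); z[17] <- 1; z })
  sm <- intracortical_smooth(hot, fam, c(0, 0.2))
  expect_equal(which(sm$values != 0), 17L)

  # consistent per-vertex permutation commutes with the smoothing
  perm <- sample(nv)
  out_perm <- intracortical_smooth(lapply(maps, function(m) m[perm]), fam,
                                   c(0, 0.2))
  expect_equal(out_perm$values, out$values[perm])

  expect_error(intracortical_smooth(maps, fam, c(0.32, 0.34)), "empty")
})

test_that("vertex clustering matches a brute-force flood fill", {
  # 7-vertex path graph as a degenerate strip of triangles, with a mask that
  # removes the bridge vertex
  verts <- cbind(0:6, c(0, 1, 0, 1, 0, 1, 0), 0)
  faces <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6), c(5, 6, 7))
  mesh <- triangle_mesh(verts, faces)
  # removing vertices 3 and 4 severs every bridge between {1,2} and {5,6,7}
  mask <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)

  flood <- function(mask, edges) { # independent oracle
    n <- length(mask)
    comp <- rep(NA_integer_, n)
    k <- 0
    for (s in which(mask)) {
      if (!is.na(comp[s])) next
      k <- k + 1
      queue <- s
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[u])) next
        comp[u] <- k
        nb <- c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1])
        queue <- c(queue, nb[mask[nb] & is.na(comp[nb])])
      }
    }
    unname(lapply(split(which(mask), comp[mask]), sort))
  }
  got <- vertex_clusters(mask, mesh)
  want <- flood(mask, mesh_edges(mesh))
  expect_setequal(lapply(got, identity), want)
  expect_length(got, 2)

  # two isolated hot vertices: two singletons, removed by the size-2 filter
  mask2 <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_length(vertex_clusters(mask2, mesh), 2)
  expect_false(any(filter_clusters(mask2, mesh, 2)))

  # all-hot mesh is a single component of size V
  expect_equal(lengths(vertex_clusters(rep(TRUE, 7), mesh)), 7L)
})
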