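# Synthetic generators: cortical sheets, stripe truths, BOLD runs, motion
# traces, smooth phantoms.

test_that("cortical sheets have the requested geometry", {
  flat <- make_cortical_sheet(extent = 20, spacing = 1, fold_amplitude = 0,
                              thickness = 2, seed = 1)
  expect_equal(range(flat$white$vertices[, 3]), c(0, 0))
  nrm <- vertex_normals(flat$white)
  expect_equal_tol(abs(nrm[, 3]), rep(1, nrow(nrm)), 1e-9) # all parallel

  sheet <- make_cortical_sheet(extent = 40, spacing = 1, seed = 2)
  d <- sqrt(rowSums((sheet$pial$vertices - sheet$white$vertices)^2))
  expect_lt(abs(mean(d) - 2), 0.1)
  # flat sheet: vertex count within 20% of the area/spacing^2 estimate
  nv_flat <- nrow(make_cortical_sheet(extent = 40, spacing = 1,
                                      fold_amplitude = 0,
                                      seed = 2)$white$vertices)
  expect_gt(nv_flat, 1600 * 0.8); expect_lt(nv_flat, 1600 * 1.25)
  # folded sheet: count tracks the (larger) true surface area instead
  nv <- nrow(sheet$white$vertices)
  stretch <- mean(sqrt(1 + (1.5 * 2 * pi / 12)^2 *
                         cos(2 * pi * seq(0, 40, 0.01) / 12)^2))
  expect_lt(abs(nv - 1600 * stretch * 2 / sqrt(3)) / nv, 0.2)
  # mean edge length tracks the requested spacing within 10%
  expect_lt(abs(mean(blurkit:::mesh_edge_lengths(sheet$white)) - 1), 0.1)
  expect_identical(sheet$white$faces, sheet$pial$faces)
  expect_error(make_cortical_sheet(extent = 5, spacing = 10), "spacing")
})

test_that("stripe phantoms are disjoint with the expected band structure", {
  sheet <- make_cortical_sheet(extent = 40, spacing = 1, seed = 3)
  truth <- make_stripe_phantom(sheet, stripe_width = 4)
  expect_equal(dice(truth$truth_a, truth$truth_b)$dice, 0)
  expect_equal(sum(truth$truth_a & truth$truth_b), 0)

  # ~5 bands per system on a 40-mm sheet at 4-mm stripes
  uv <- attr(sheet, "param_uv")
  bands_a <- unique(floor(uv[truth$truth_a, 1] / 4))
  expect_gte(length(bands_a), 4); expect_lte(length(bands_a), 6)

  gap <- make_stripe_phantom(sheet, stripe_width = 4, gap_frac = 0.2)
  unlabeled <- mean(!(gap$truth_a | gap$truth_b))
  expect_gte(unlabeled, 0.1)

  expect_error(make_stripe_phantom(sheet, stripe_width = 0.5), "twice")

  # disjointness survives refinement-based label inheritance
  fam_mid <- triangle_mesh((sheet$white$vertices + sheet$pial$vertices) / 2,
                           sheet$white$faces)
  ref <- refine_mesh(fam_mid, 2)
  a_r <- inherit_binary_labels(truth$truth_a, ref)
  b_r <- inherit_binary_labels(truth$truth_b, ref)
  expect_equal(sum(a_r & b_r), 0)
  expect_gt(sum(a_r), sum(truth$truth_a))
})

test_that("BOLD forward model recovers the amplitude noiselessly", {
  sheet <- make_cortical_sheet(extent = 16, spacing = 1, seed = 4)
  truth <- make_stripe_phantom(sheet, stripe_width = 3)
  grid <- voxel_grid(c(22, 22, 12), 1)
  des <- block_design(seq(0, by = 3, length.out = 30), onsets = 15,
                      durations = 24)
  run <- make_bold_run(sheet, truth$truth_a, grid, des, amplitude = 1.5,
                       noise_sd = 0, seed = 1)
  mid <- triangle_mesh((sheet$white$vertices + sheet$pial$vertices) / 2,
                       sheet$white$faces)
  fit <- fit_glm(vol2surf(run, mid, method = "nearest"), des)
  hot <- truth$truth_a
  expect_equal_tol(fit$beta[hot], rep(1.5, sum(hot)), 1e-6)

  # amplitude 0: pure noise, null calibration holds
  null_run <- make_bold_run(sheet, truth$truth_a, grid, des, amplitude = 0,
                            noise_sd = 1, seed = 2)
  fit0 <- fit_glm(vol2surf(null_run, mid, method = "nearest"), des)
  expect_lt(abs(mean(fit0$p < 0.05) - 0.05),
            4 * sqrt(0.05 * 0.95 / fit0$nvert))

  expect_error(make_bold_run(sheet, truth$truth_a, voxel_grid(c(4, 4, 4), 1),
                             des), "cover")
})

test_that("motion during acquisition reduces uncorrected GLM power", {
  sheet <- make_cortical_sheet(extent = 16, spacing = 1, seed = 5)
  truth <- make_stripe_phantom(sheet, stripe_width = 3)
  grid <- voxel_grid(c(22, 22, 12), 1)
  des <- block_design(seq(0, by = 3, length.out = 30), onsets = 15,
                      durations = 24)
  trace <- make_motion_trace(30, amplitudes = c(0, 0, 0, 1.5, 1.5, 0),
                             seed = 6)
  run <- make_bold_run(sheet, truth$truth_a, grid, des, amplitude = 1,
                       noise_sd = 1, trace = trace, seed = 7)
  mid <- triangle_mesh((sheet$white$vertices + sheet$pial$vertices) / 2,
                       sheet$white$faces)
  raw_fit <- fit_glm(vol2surf(run, mid, method = "linear"), des)
  cor_fit <- fit_glm(vol2surf(motion_correct(run, trace, "linear"), mid,
                              method = "linear"), des)
  hot <- truth$truth_a
  expect_gt(mean(cor_fit$t[hot]), mean(raw_fit$t[hot]))
})

test_that("motion traces honour amplitudes, style and seeds", {
  id <- make_motion_trace(7, amplitudes = 0)
  expect_lt(max(abs(trace_params_matrix(id))), 1e-12)

  tr <- make_motion_trace(20, amplitudes = c(0, 0, 0, 0.5, 0, 0), seed = 8)
  p <- trace_params_matrix(tr)
  expect_equal(max(abs(p[, "dS"])), 0.5)
  expect_equal(max(abs(p[, c("roll", "pitch", "yaw", "dL", "dP")])), 0)
  expect_equal(p[tr$reference_index, "dS"], c(dS = 0))

  rw1 <- make_motion_trace(15, amplitudes = 0.3, style = "random_walk",
                           seed = 9)
  rw2 <- make_motion_trace(15, amplitudes = 0.3, style = "random_walk",
                           seed = 9)
  expect_identical(trace_params_matrix(rw1), trace_params_matrix(rw2))
})

test_that("smooth phantoms are structured, centred and reproducible", {
  g <- voxel_grid(c(20, 20, 20), 1)
  one <- make_smooth_phantom(g, n_blobs = 1, seed = 10)
  # single blob: maximum near its centre, not at the border
  w <- which(one$data == max(one$data), arr.ind = TRUE)
  expect_true(all(w > 2 & w < 19))

  expect_identical(make_smooth_phantom(g, seed = 11)$data,
                   make_smooth_phantom(g, seed = 11)$data)

  ph <- make_smooth_phantom(g, n_blobs = 30, seed = 12)
  gr <- array(0, g$dims)
  gr[2:19, , ] <- abs(ph$data[3:20, , ] - ph$data[1:18, , ])
  expect_gte(mean(gr > 1e-4), 0.5) # gradient structure over most of the FOV
})
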