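# GLM activation mapping, fixed effects, thresholding, Dice.

make_design <- function(nt = 40, TR = 3)
  block_design(seq(0, by = TR, length.out = nt),
               onsets = c(12, 66), durations = 24)

test_that("gamma HRF shape, normalisation and sampling", {
  dt <- 0.01
  h <- gamma_hrf(2.25, 1.25, dt = dt, duration = 30)
  expect_equal(sum(h) * dt, 1, tolerance = 1e-6)
  expect_equal(h[1], 0)
  # analytic mode of the gamma density: (shape - 1) * scale
  shape <- (2.25 / 1.25)^2; scale <- 1.25^2 / 2.25
  t_peak <- (which.max(h) - 1) * dt
  expect_equal(t_peak, (shape - 1) * scale, tolerance = 2 * dt)
  expect_gt(t_peak, 1); expect_lte(t_peak, 2.25)
  # doubling dt halves the sample count without changing the shape
  h2 <- gamma_hrf(2.25, 1.25, dt = 2 * dt, duration = 30)
  expect_equal(length(h) - 1, 2 * (length(h2) - 1))
  # same shape up to the (dt-dependent) normalisation constant
  expect_equal(h2[2], h[3], tolerance = 1e-3)
})

test_that("GLM recovers noiseless betas exactly and is calibrated under the null", {
  des <- make_design()
  r <- blurkit:::.task_regressor(des)
  nv <- 3000
  # noiseless: beta = 1 exactly
  clean <- surface_map(outer(rep(1, 5), 0.3 + 1 * r) +
                         outer(seq_len(5), scale(des$frame_times)[, 1] * 0.01))
  fit0 <- fit_glm(clean, des)
  expect_equal_tol(fit0$beta, rep(1, 5), 1e-6)

  set.seed(30)
  nullmap <- surface_map(matrix(rnorm(nv * 40), nv, 40))
  fit <- fit_glm(nullmap, des)
  frac <- mean(fit$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nv))
  expect_equal(fit$dof, 37L)
})

test_that("detection power rises monotonically with response amplitude", {
  des <- make_design()
  r <- blurkit:::.task_regressor(des)
  set.seed(31)
  nv <- 400
  power_at <- function(amp) {
    y <- outer(rep(amp, nv), r) + matrix(rnorm(nv * 40), nv, 40)
    mean(fit_glm(surface_map(y), des)$p < 0.01)
  }
  p <- vapply(c(0, 0.5, 1, 2), power_at, 1)
  expect_true(all(diff(p) >= 0))
  expect_gt(p[4], 0.9)
})

test_that("fixed-effects combination pools by inverse variance", {
  des <- make_design()
  set.seed(32)
  y <- matrix(rnorm(200 * 40), 200, 40) +
    outer(rep(1, 200), blurkit:::.task_regressor(des))
  m <- fit_glm(surface_map(y), des)

  # combining a map with itself: same beta, double dof, larger |t|
  both <- fixed_effects_combine(list(m, m))
  expect_equal(both$beta, m$beta)
  expect_equal(both$dof, 2L * m$dof)
  expect_true(all(abs(both$t) >= abs(m$t)))

  # equal variances average the betas
  m1 <- blurkit:::new_activation_map(rep(1, 4), rep(0.1, 4), rep(1, 4),
                                     rep(0.5, 4), 10)
  m3 <- blurkit:::new_activation_map(rep(3, 4), rep(0.1, 4), rep(1, 4),
                                     rep(0.5, 4), 10)
  expect_equal(fixed_effects_combine(list(m1, m3))$beta, rep(2, 4))

  # k identical independent runs: t grows ~ sqrt(k)
  seeds <- 1:6
  runs <- lapply(seeds, function(s) {
    set.seed(100 + s)
    yy <- matrix(rnorm(300 * 40), 300, 40) +
      outer(rep(0.8, 300), blurkit:::.task_regressor(des))
    fit_glm(surface_map(yy), des)
  })
  t1 <- mean(abs(runs[[1]]$t))
  t4 <- mean(abs(fixed_effects_combine(runs[1:4])$t))
  expect_equal(t4 / t1, 2, tolerance = 0.25)
})

test_that("binarisation thresholds monotonically and removes singletons", {
  verts <- cbind(0:6, c(0, 1, 0, 1, 0, 1, 0), 0)
  faces <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6), c(5, 6, 7))
  mesh <- triangle_mesh(verts, faces)
  map <- blurkit:::new_activation_map(
    beta = rep(1, 7), variance = rep(1, 7), t = rep(1, 7),
    p = c(0.001, 0.5, 0.5, 0.004, 0.002, 0.5, 0.02), dof = 20)

  # without the cluster filter, stricter masks nest inside looser ones
  loose <- binarize(map, 0.05, min_cluster = 1, mesh = mesh)
  strict <- binarize(map, 0.005, min_cluster = 1, mesh = mesh)
  expect_true(all(which(strict) %in% which(loose)))
  expect_equal(sum(binarize(map, 1 - 1e-12, 1, mesh)), 7)

  # isolated singleton survivors are removed at min_cluster = 2
  filt <- binarize(map, 0.005, min_cluster = 2, mesh = mesh)
  expect_equal(which(filt), 4:5)
})

test_that("dice coefficient handles the standard cases symmetrically", {
  a <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(dice(a, a)$dice, 1)
  expect_equal(dice(a, !a)$dice, 0)
  b <- c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 5))
  d <- dice(a, b)
  expect_equal(d$dice, 0.5) # |A| = |B| = 10, |A n B| = 5
  expect_equal(dice(b, a)$dice, d$dice)
  empty <- dice(logical(8), logical(8))
  expect_equal(empty$dice, 0)
  expect_true(empty$empty_union)
  expect_error(dice(a, logical(3)), "different meshes")
})

test_that("strategy comparison rejects unknown strategies and orders thresholds", {
  sheet <- make_cortical_sheet(extent = 18, spacing = 1, seed = 8)
  truth <- make_stripe_phantom(sheet, stripe_width = 3)
  grid <- voxel_grid(c(24, 24, 12), 1)
  des <- make_design(nt = 30)
  expect_error(strategy_comparison(sheet, truth, grid, des,
                                   strategies = "nope"), "unknown")
  tab <- strategy_comparison(sheet, truth, grid, des, amplitude = 2,
                             noise_sd = 1, strategies = "default",
                             thresholds = c(0.05, 0.001), seeds = 1)
  n05 <- tab$n_intersect[tab$threshold == 0.05]
  n001 <- tab$n_intersect[tab$threshold == 0.001]
  expect_gte(n05, n001) # looser threshold, more overlap
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))
})

test_that("explicit tangential smoothing increases stripe overlap", {
  sheet <- make_cortical_sheet(extent = 18, spacing = 1, seed = 9)
  truth <- make_stripe_phantom(sheet, stripe_width = 3)
  grid <- voxel_grid(c(24, 24, 12), 1)
  des <- make_design(nt = 30)
  tab <- strategy_comparison(sheet, truth, grid, des, amplitude = 2,
                             noise_sd = 1,
                             strategies = c("default", "tangential"),
                             thresholds = 0.01, seeds = 1:3)
  med <- tapply(tab$dice, tab$strategy, median)
  expect_gte(med["tangential"], med["default"])
})
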