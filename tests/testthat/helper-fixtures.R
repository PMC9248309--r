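# Shared fixtures, built in code. The lookup tables are expensive, so they
# are built once per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# TSTD -> FWHM lookup on a 1-mm grid (shared across blurmetry/acceptance tests)
lookup_1mm <- function() fixture("lookup_1mm", function()
  build_lookup(1.0, nframes = 150, seed = 101, dim = 48))

# and on a 0.5-mm grid (finer-grid plateau comparisons)
lookup_05mm <- function() fixture("lookup_05mm", function()
  build_lookup(0.5, nframes = 150, seed = 102, dim = 48))

# closed genus-0 mesh: regular icosahedron with unit circumradius
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  triangle_mesh(v, f)
}

# small smooth phantom for motion tests
motion_phantom <- function(dim = 24, spacing = 1, seed = 4)
  make_smooth_phantom(voxel_grid(rep(dim, 3), spacing), n_blobs = 30,
                      seed = seed)

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
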