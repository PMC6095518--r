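test_that("dome initialization: bulk limits, zero level accuracy, summit height", {
  g <- grid_spec(40, 40, 60)
  p <- mech_params()
  phi <- initialize_domain(g, p)
  expect_lt(phi[1, 1, 55], -0.999)                 # far outside
  expect_gt(phi[20, 20, 3], 0.999)                 # deep inside
  expect_equal(summit_height(phi, g), p$Hz + p$R, tolerance = 0.5)

  # zero level set within half a voxel of the analytic surface
  mesh <- extract_isosurface(phi, 0, g)
  v <- mesh$vertices
  lat <- sqrt((v[, 1] - 20)^2 + (v[, 2] - 20)^2)
  d_analytic <- ifelse(v[, 3] >= p$Hz,
                       sqrt(lat^2 + (v[, 3] - p$Hz)^2) - p$R,
                       lat - p$R)
  expect_lt(max(abs(d_analytic)), 0.5)

  expect_error(initialize_domain(grid_spec(16, 16, 16), p), "fit")
})

test_that("mass source is m u^2 with its trivial limits", {
  g <- tiny_grid(10)
  expect_equal(max(abs(mass_source(scalar_field(0, g), mech_params()))), 0)
  expect_equal(max(abs(mass_source(smooth_field(g), mech_params(m = 0)))), 0)
  a <- mass_source(scalar_field(1, g), mech_params(m = 15))
  expect_equal(as.numeric(a[4, 4, 4]), 15)
})

test_that("tip gaussian: center value, lateral decay, summit tracking", {
  g <- grid_spec(40, 40, 60)
  p <- mech_params()
  phi <- initialize_domain(g, p)
  state <- list(phi = phi, summit_z0 = summit_height(phi, g))
  G <- tip_gaussian(state, p, g)
  summit <- summit_height(phi, g)
  cz <- summit - p$R
  # exact voxel-centre values: amplitude at the centre, e^{-1/2} at one
  # standard deviation of lateral offset
  cc <- grid_coords(g)
  k0 <- which.min(abs(cc$z - cz))
  gauss <- function(i) p$tip_gain *
    exp(-((cc$x[i] - 20)^2 + (cc$y[20] - 20)^2 + (cc$z[k0] - cz)^2) /
          (2 * p$g_width^2))
  expect_equal(G[20, 20, k0], gauss(20), tolerance = 1e-12)
  i_off <- 20L + as.integer(p$g_width)
  expect_equal(G[i_off, 20, k0], gauss(i_off), tolerance = 1e-12)
  expect_equal(gauss(i_off) / gauss(20),
               exp(-((cc$x[i_off] - 20)^2 - (cc$x[20] - 20)^2) / (2 * p$g_width^2)))
  # monotone decay with distance from the center along a ray
  expect_true(all(diff(G[21:40, 20, k0]) < 0))

  # the source centre moves up when the summit rises
  phi_up <- scalar_field(function(x, y, z) {
    lat <- sqrt((x - 20)^2 + (y - 20)^2)
    d <- ifelse(z >= 9, sqrt(lat^2 + (z - 9)^2), lat)
    tanh((10 - d) / sqrt(2))
  }, g)
  G2 <- tip_gaussian(list(phi = phi_up), p, g)
  z_of_max <- function(G) {
    w <- which(G == max(G), arr.ind = TRUE)[1, ]
    w[3]
  }
  expect_gt(z_of_max(G2), z_of_max(G))
})

test_that("primordium sources occupy discrete balls and never double-add", {
  g <- grid_spec(20, 20, 20)
  p <- mech_params(s_phi = 2, s_u = 3, r_p = 2)
  none <- apply_primordium_sources(data.frame(), p, g)
  expect_equal(max(abs(none$s_phi)), 0)
  expect_equal(max(abs(none$s_u)), 0)

  one <- apply_primordium_sources(
    data.frame(x = 10.5, y = 10.5, z = 10.5), p, g)
  cc <- grid_coords(g)
  dm <- c(20, 20, 20)
  X <- array(cc$x, dm); Y <- array(rep(cc$y, each = 20), dm)
  Z <- array(rep(cc$z, each = 400), dm)
  ball <- (X - 10.5)^2 + (Y - 10.5)^2 + (Z - 10.5)^2 <= p$r_p^2
  expect_identical(sum(one$s_u > 0), sum(ball))
  expect_equal(sum(one$s_u) * g$dx^3, p$s_u * sum(ball) * g$dx^3)

  # overlapping balls: pointwise max, not sum
  two <- apply_primordium_sources(
    data.frame(x = c(10.5, 11.5), y = c(10.5, 10.5), z = c(10.5, 10.5)), p, g)
  expect_equal(max(two$s_u), p$s_u)
  expect_equal(max(two$s_phi), p$s_phi)
})

test_that("mechanical equilibrium: homogeneous bulk with all sources off is stationary", {
  g <- tiny_grid(10)
  p <- mech_params(beta = 0, m = 0, kappa = 0)
  for (b in c(-1, 1)) {
    state <- list(phi = scalar_field(b, g), u = scalar_field(0, g),
                  primordia = NULL)
    out <- mech_step(state, p, g, nsteps = 50L, G = FALSE)
    expect_equal(as.numeric(out$phi), rep(b, 1000))
    expect_equal(max(abs(out$u)), 0)
  }
})

test_that("conservation: both field totals are conserved over 1000 steps with sources off", {
  g <- grid_spec(20, 20, 24)
  p <- mech_params(m = 0, kappa = 0, s_phi = 0, s_u = 0)
  phi <- make_fixture("sphere", g, p = p, radius = 7,
                      center = c(10, 10, 12))
  u <- smooth_field(g, seed = 19, amp = 0.3)
  state <- list(phi = phi, u = u, primordia = NULL)
  s_phi0 <- sum(phi) * g$dx^3
  s_u0 <- sum(u) * g$dx^3
  out <- mech_step(state, p, g, nsteps = 1000L, stress_every = 10L, G = FALSE)
  expect_lt(abs(sum(out$phi) * g$dx^3 - s_phi0), 1e-8 * abs(s_phi0))
  expect_lt(abs(sum(out$u) * g$dx^3 - s_u0), 1e-8 * max(abs(s_u0), 1))
})

test_that("interface re-profiling preserves the zero level set and restores width", {
  g <- grid_spec(32, 12, 12, dx = 0.5)
  p <- mech_params(eps = 1)
  # artificially compressed interface
  sharp <- scalar_field(function(x, y, z) tanh((8.2 - x) / (sqrt(2) * 0.4)), g)
  out <- reinit_interface(sharp, p, g)
  m0 <- extract_isosurface(sharp, 0, g)
  m1 <- extract_isosurface(out, 0, g)
  expect_equal(mean(m1$vertices[, 1]), mean(m0$vertices[, 1]), tolerance = 0.05)
  gp <- gradient(out, g)
  peak_slope <- max(abs(gp[, 6, 6, 1]))
  expect_equal(peak_slope, 1 / (sqrt(2) * p$eps), tolerance = 0.1)
})

test_that("trajectories are bit-identical for identical config and seed", {
  cfg <- run_config(eta = 0.3902, seed = 7, grid = grid_spec(24, 24, 28),
                    mech = mech_params(R = 6, Hz = 4, g_width = 3),
                    n_chem_init = 500L, n_chem = 50L, n_mech = 20L,
                    max_cycles = 3L)
  s1 <- run_simulation(cfg, quiet = TRUE)
  s2 <- run_simulation(cfg, quiet = TRUE)
  expect_identical(as.numeric(s1$phi), as.numeric(s2$phi))
  expect_identical(as.numeric(s1$u), as.numeric(s2$u))
  expect_identical(as.numeric(s1$v), as.numeric(s2$v))
  expect_identical(s1$log, s2$log)

  s3 <- run_simulation(run_config(eta = 0.3902, seed = 8,
                                  grid = grid_spec(24, 24, 28),
                                  mech = mech_params(R = 6, Hz = 4, g_width = 3),
                                  n_chem_init = 500L, n_chem = 50L,
                                  n_mech = 20L, max_cycles = 3L), quiet = TRUE)
  expect_false(identical(as.numeric(s1$u), as.numeric(s3$u)))
})

test_that("the time-scale separation of the default grid is 5000", {
  g <- grid_spec()
  expect_identical(g$dt_chem / g$dt_mech, 5000)
})
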