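test_that("reaction kinetics match direct substitution", {
  p <- bvam_params(eta = 0.3902, c = 0.57)
  expect_equal(bvam_reaction(0, 0, p), list(du = 0, dv = 0))

  # hand substitution at (0.1, 0.1)
  r <- bvam_reaction(0.1, 0.1, p)
  du_hand <- 0.3902 * (0.1 + 1.1123 * 0.1 - 0.57 * 0.01 - 0.1 * 0.01)
  dv_hand <- 0.3902 * (-1.0122 * 0.1 - 1 * 0.1 + 0.57 * 0.01 + 0.1 * 0.01)
  expect_equal(r$du, du_hand, tolerance = 1e-12)
  expect_equal(r$dv, dv_hand, tolerance = 1e-12)
  expect_equal(r$du, 0.07981, tolerance = 1e-4)
  expect_equal(r$dv, -0.07590, tolerance = 1e-4)

  p0 <- bvam_params(eta = 0.7, c = 0)
  r0 <- bvam_reaction(1, 0, p0)
  expect_equal(r0$du, p0$eta)
  expect_equal(r0$dv, p0$eta * p0$h)
})

test_that("the homogeneous state is exactly stationary for any parameters", {
  g <- tiny_grid(10)
  u0 <- scalar_field(0, g)
  v0 <- scalar_field(0, g)
  set.seed(5)
  for (rep in 1:5) {
    p <- bvam_params(eta = runif(1, 0.1, 1), a = runif(1, -2, 2),
                     b = runif(1, -2, 0), c = runif(1, 0, 0.57),
                     h = runif(1, -2, 2), D = runif(1, 0.1, 2))
    out <- bvam_step(u0, v0, p, nsteps = 10L)
    expect_identical(max(abs(out$u)), 0)
    expect_identical(max(abs(out$v)), 0)
  }
})

test_that("decoupled linear kinetics follow the exact Euler growth factor", {
  # a = c = h = 0 and the partner morphogen identically zero: each field
  # reduces to diffusion plus a linear reaction, whose grid sum evolves
  # exactly as (1 + dt eta)^n (diffusion conserves the sum)
  g <- tiny_grid(10)
  p <- bvam_params(eta = 0.4, a = 0, b = -1, c = 0, h = 0, D = 1)
  zero <- scalar_field(0, g)
  n <- 200L
  dt <- 5e-2
  u <- smooth_field(g, seed = 2, amp = 0.05)
  out <- bvam_step(u, zero, p, dt = dt, nsteps = n)
  expect_equal(sum(out$u), sum(u) * (1 + dt * p$eta)^n, tolerance = 1e-10)
  expect_equal(max(abs(out$v)), 0)

  v <- smooth_field(g, seed = 3, amp = 0.05)
  out2 <- bvam_step(zero, v, p, dt = dt, nsteps = n)
  expect_equal(sum(out2$v), sum(v) * (1 + dt * p$eta * p$b)^n, tolerance = 1e-10)
})

test_that("a seeded run forms a bounded stationary pattern at pattern-forming parameters", {
  # 16^3 box admits the discrete mode k = 2 pi / 16 inside the Turing band
  g <- grid_spec(16, 16, 16)
  p <- bvam_params(eta = 0.3902, c = 0.57)
  set.seed(9)
  dm <- c(16L, 16L, 16L)
  u <- scalar_field(array(runif(prod(dm), -0.1, 0.1), dm), g)
  v <- scalar_field(array(runif(prod(dm), -0.1, 0.1), dm), g)
  rms0 <- sqrt(mean(u^2))
  out <- bvam_step(u, v, p, nsteps = 40000L)
  rms1 <- sqrt(mean(out$u^2))
  out2 <- bvam_step(out$u, out$v, p, nsteps = 4000L)
  rms2 <- sqrt(mean(out2$u^2))
  expect_gt(rms1, 2 * rms0)          # departed from homogeneity
  expect_lt(max(abs(out2$u)), 5)     # bounded
  # amplitude plateau: successive-difference norm small relative to amplitude
  expect_lt(abs(rms2 - rms1), 0.1 * rms1)

  # equal diffusivities: no Turing instability, the perturbation decays
  pD <- bvam_params(eta = 0.3902, c = 0.57, D = 1)
  outD <- bvam_step(u, v, pD, nsteps = 4000L)
  expect_lt(sqrt(mean(outD$u^2)), 0.5 * rms0)
})

test_that("dispersion relation equals brute-force eigenvalues on random draws", {
  set.seed(1)
  for (rep in 1:100) {
    p <- bvam_params(eta = runif(1, 0.05, 1.5), a = runif(1, -2, 2),
                     b = runif(1, -2, 2), c = runif(1, 0, 0.57),
                     h = runif(1, -2, 2), D = runif(1, 0.05, 3))
    k2 <- runif(1, 0, 3)
    J <- matrix(c(p$eta - p$D * k2, p$eta * p$h,
                  p$eta * p$a, p$eta * p$b - k2), 2, 2)
    brute <- max(Re(eigen(J, only.values = TRUE)$values))
    expect_equal(dispersion_relation(p, k2), brute, tolerance = 1e-10)
  }
})

test_that("dispersion limits: stable homogeneous state, diffusive damping at large k", {
  p <- bvam_params(eta = 0.55)
  expect_lt(dispersion_relation(p, 0), 0)
  expect_lt(dispersion_relation(p, 1e4), dispersion_relation(p, 1e2))
  expect_lt(dispersion_relation(p, 1e4), -100)
})

test_that("turing band: nonempty at used eta, empty at D = 1, endpoints are det roots", {
  p <- bvam_params(eta = 0.3902)
  band <- turing_band(p)
  expect_false(band$empty)
  expect_false(band$homogeneous_unstable)
  expect_gt(band$k2_hi, band$k2_lo)

  # endpoints solve det J(k2) = 0: quadratic D k2^2 - eta (b D + 1) k2 + eta^2 (b - a h)
  roots <- sort(Re(polyroot(c(p$eta^2 * (p$b - p$a * p$h),
                              -p$eta * (p$b * p$D + 1), p$D))))
  expect_equal(band$k2_lo, roots[1], tolerance = 1e-6)
  expect_equal(band$k2_hi, roots[2], tolerance = 1e-6)

  expect_true(turing_band(bvam_params(eta = 0.3902, D = 1))$empty)
})

test_that("sphere mode selection: constructed radius, radius monotonicity, eta separation", {
  p <- bvam_params(eta = 0.3902)
  band <- turing_band(p)
  r3 <- sqrt(3 * 4 / band$k2_peak)     # l (l + 1) / r^2 == k2_peak at l = 3
  expect_identical(predict_sphere_mode(p, r3), 3L)

  radii <- seq(2, 30, by = 1)
  modes <- vapply(radii, function(r) predict_sphere_mode(p, r), integer(1))
  expect_true(all(diff(modes) >= 0))

  expect_gt(predict_sphere_mode(bvam_params(eta = 0.3902), 10),
            predict_sphere_mode(bvam_params(eta = 0.2601), 10))
  expect_error(predict_sphere_mode(bvam_params(eta = 0.39, D = 1), 10), "no Turing band")
})

test_that("masked dynamics freezes the morphogens where the indicator vanishes", {
  g <- tiny_grid(10)
  u <- smooth_field(g, seed = 4, amp = 0.05)
  v <- smooth_field(g, seed = 5, amp = 0.05)
  chi <- scalar_field(0, g)
  out <- bvam_step(u, v, bvam_params(eta = 0.5), nsteps = 50L, chi = chi)
  expect_equal(as.numeric(out$u), as.numeric(u))
  expect_equal(as.numeric(out$v), as.numeric(v))
  # chi == 1 reproduces the unmasked dynamics exactly
  chi1 <- scalar_field(1, g)
  a <- bvam_step(u, v, bvam_params(eta = 0.5), nsteps = 20L)
  b <- bvam_step(u, v, bvam_params(eta = 0.5), nsteps = 20L, chi = chi1)
  expect_equal(as.numeric(a$u), as.numeric(b$u), tolerance = 1e-13)
})
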