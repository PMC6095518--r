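# independent direct-summation reference for the stress tensor, assembled
# term by term from the energy-density partials using only the public
# differential operators
stress_oracle <- function(phi, u, p, g) {
  dm <- c(g$nx, g$ny, g$nz)
  en <- free_energy(phi, u, p, g)
  # pointwise Lagrangian with its explicit gradient dependence
  gphi <- gradient(phi, g)
  gu <- gradient(u, g)
  gp2 <- gphi[, , , 1]^2 + gphi[, , , 2]^2 + gphi[, , , 3]^2
  gu2 <- gu[, , , 1]^2 + gu[, , , 2]^2 + gu[, , , 3]^2
  L <- en$PhiSC^2 - 0.5 * p$rho_phi * gp2 - 0.5 * p$rho_u * gu2
  mu <- en$mu_phi
  gp <- gradient(phi, g)
  gs <- gradient(en$PhiSC, g)
  out <- array(0, c(dm, 3, 3))
  # hessian of phi from nested gradients (same closure, wider stencil)
  hess <- lapply(1:3, function(a) gradient(scalar_field(array(gp[, , , a], c(g$nx, g$ny, g$nz)), g), g))
  for (a in 1:3) for (b in 1:3) {
    term <- p$rho_phi * gp[, , , a] * gp[, , , b] -
      2 * p$eps^2 * gs[, , , b] * gp[, , , a] +
      2 * p$eps^2 * en$PhiSC * hess[[a]][, , , b]
    if (a == b) term <- term + L - phi * mu
    out[, , , a, b] <- term
  }
  out
}

test_that("stress vanishes identically in homogeneous bulk for any parameters", {
  g <- tiny_grid(10)
  set.seed(2)
  for (rep in 1:3) {
    p <- mech_params(beta = runif(1, 0, 2), rho_phi = runif(1, 1, 4),
                     rho_u = runif(1, 0, 1))
    for (b in c(-1, 1)) {
      s <- stress_tensor(scalar_field(b, g), scalar_field(0, g), p)
      expect_equal(max(abs(s)), 0)
    }
  }
})

test_that("homogeneous mid-well state gives a pure hydrostatic (isotropic) stress", {
  g <- tiny_grid(10)
  p <- mech_params()
  s <- stress_tensor(scalar_field(0.5, g), scalar_field(0, g), p)
  d1 <- s[5, 5, 5, 1, 1]
  expect_equal(s[5, 5, 5, 2, 2], d1)
  expect_equal(s[5, 5, 5, 3, 3], d1)
  expect_true(abs(d1) > 0)
  off <- abs(s[5, 5, 5, , ]) * (1 - diag(3))
  expect_equal(max(off), 0)
})

test_that("1D interface stress is anisotropic and matches the term-by-term oracle", {
  g <- grid_spec(32, 10, 10, dx = 0.5)
  p <- mech_params(eps = 1)
  plane <- scalar_field(function(x, y, z) tanh((8 - x) / sqrt(2)), g)
  u0 <- scalar_field(0, g)
  s <- stress_tensor(plane, u0, p, g)
  mid <- which.min(abs(plane[, 5, 5]))
  sxx <- s[mid, 5, 5, 1, 1]
  syy <- s[mid, 5, 5, 2, 2]
  szz <- s[mid, 5, 5, 3, 3]
  expect_equal(syy, szz, tolerance = 1e-10)
  expect_gt(abs(sxx - syy), 0.1 * max(abs(c(sxx, syy))))  # surface-tension anisotropy

  orac <- stress_oracle(plane, u0, p, g)
  ii <- 4:28
  for (a in 1:3) for (b in 1:3) {
    diff <- max(abs(s[ii, 4:7, 4:7, a, b] - orac[ii, 4:7, 4:7, a, b]))
    expect_lt(diff, 0.05 * max(abs(s[, , , 1, 1])) + 1e-8)
  }
})

test_that("interface stress asymmetry is at discretization level on a 1D profile", {
  g <- grid_spec(32, 10, 10, dx = 0.5)
  p <- mech_params(eps = 1)
  plane <- scalar_field(function(x, y, z) tanh((8 - x) / sqrt(2)), g)
  u <- scalar_field(function(x, y, z) 0.2 * exp(-(x - 8)^2 / 8), g)
  s <- stress_tensor(plane, u, p, g)
  asym <- 0
  for (a in 1:3) for (b in 1:3)
    asym <- max(asym, max(abs(s[, , , a, b] - s[, , , b, a])))
  expect_lt(asym, 0.05 * max(abs(s)))
  # symmetrize = TRUE returns an exactly symmetric tensor
  ss <- stress_tensor(plane, u, p, g, symmetrize = TRUE)
  expect_equal(max(abs(ss[, , , 1, 2] - ss[, , , 2, 1])), 0)
})

test_that("fixture curvatures match analytic values within 5 percent", {
  g <- grid_spec(24, 24, 24)
  p <- mech_params()
  sph <- make_fixture("sphere", g, p = p, radius = 8)
  H <- curvature_tensor(sph, p, g)$H
  expect_lt(abs(mean(H, na.rm = TRUE) - 1 / 8), 0.05 / 8)

  cyl <- make_fixture("cylinder", g, p = p, radius = 8)
  Hc <- curvature_tensor(cyl, p, g)$H
  expect_lt(abs(mean(Hc, na.rm = TRUE) - 1 / 16), 0.05 / 16)

  pl <- make_fixture("plane", g, p = p)
  Hp <- curvature_tensor(pl, p, g)$H
  expect_lt(max(abs(Hp), na.rm = TRUE), 1e-6)

  # curvature is masked (NA) off the interface band
  expect_true(is.na(Hp[1, 1, 1]))
})

test_that("sphere curvature error shrinks under grid refinement", {
  p <- mech_params()
  err <- vapply(c(1, 0.5), function(dx) {
    n <- round(24 / dx)
    g <- grid_spec(n, n, n, dx = dx)
    H <- curvature_tensor(make_fixture("sphere", g, p = p, radius = 8), p, g)$H
    abs(mean(H, na.rm = TRUE) - 1 / 8)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("principal stress decomposition: diagonal, isotropic and random tensors", {
  g <- grid_spec(8, 8, 8)
  Td <- tensor_field(diag(c(3, 2, 1)), g)
  ps <- principal_stress(Td, g)
  expect_equal(ps$magnitudes[2, 2, 2, ], c(3, 2, 1))
  expect_equal(abs(ps$directions[2, 2, 2, , 1]), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(ps$directions[2, 2, 2, , 3]), c(0, 0, 1), tolerance = 1e-12)

  iso <- principal_stress(tensor_field(2.2 * diag(3), g), g)
  expect_equal(iso$magnitudes[3, 3, 3, ], rep(2.2, 3))
  V <- iso$directions[3, 3, 3, , ]
  expect_equal(crossprod(V), diag(3), tolerance = 1e-10)

  set.seed(6)
  A <- matrix(rnorm(9), 3, 3); A <- (A + t(A)) / 2
  pr <- principal_stress(tensor_field(A, g), g)
  lam <- pr$magnitudes[4, 4, 4, ]
  expect_true(all(diff(lam) <= 0))
  V <- pr$directions[4, 4, 4, , ]
  recon <- V %*% diag(lam) %*% t(V)
  expect_equal(recon, A, tolerance = 1e-10)
  # deterministic sign: largest-magnitude component positive
  for (r in 1:3) expect_gte(V[which.max(abs(V[, r])), r], 0)
})
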