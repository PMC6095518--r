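test_that("isosurface extraction: sphere radius, topology, empty and dome cases", {
  g <- grid_spec(24, 24, 24)
  p <- mech_params()
  sph <- make_fixture("sphere", g, p = p, radius = 8)
  mesh <- extract_isosurface(sph, 0, g)
  r <- sqrt(rowSums((t(t(mesh$vertices) - c(12, 12, 12)))^2))
  expect_lt(abs(mean(r) - 8), 0.5)
  expect_identical(euler_characteristic(mesh), 2L)

  expect_identical(nrow(extract_isosurface(scalar_field(1, g), 0, g)$vertices), 0L)

  gd <- grid_spec(40, 40, 60)
  dome <- make_fixture("dome", gd, p = mech_params())
  md <- extract_isosurface(dome, 0, gd)
  comp <- phyllodome:::vertex_components(md, rep(TRUE, nrow(md$vertices)))
  expect_identical(length(unique(comp)), 1L)  # single connected component
})

test_that("isosurface extraction is deterministic", {
  g <- grid_spec(16, 16, 16)
  f <- smooth_field(g, seed = 17, amp = 1)
  m1 <- extract_isosurface(f, 0, g)
  m2 <- extract_isosurface(f, 0, g)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})

test_that("surface mean curvature: sphere, plane, and junction gradient on the dome", {
  g <- grid_spec(28, 28, 28)
  p <- mech_params()
  sph <- make_fixture("sphere", g, p = p, radius = 10)
  H <- surface_mean_curvature(sph, p = p, grid = g)
  expect_lt(abs(mean(H, na.rm = TRUE) - 0.1), 0.005)

  pl <- make_fixture("plane", g, p = p)
  Hp <- surface_mean_curvature(pl, p = p, grid = g)
  expect_lt(max(abs(Hp), na.rm = TRUE), 1e-6)

  # |dH/dz| along the dome meridian peaks near the cylinder-cap junction
  gd <- grid_spec(40, 40, 60)
  pd <- mech_params()
  dome <- make_fixture("dome", gd, p = pd)
  mesh <- extract_isosurface(dome, 0, gd)
  Hd <- surface_mean_curvature(dome, mesh = mesh, p = pd, grid = gd)
  z <- mesh$vertices[, 3]
  bands <- cut(z, breaks = seq(0, 16, by = 1))
  bandH <- tapply(Hd, bands, mean, na.rm = TRUE)
  grad <- abs(diff(bandH))
  peak_band <- which.max(grad)
  expect_gt(peak_band, 4)   # junction sits at z = Hz = 6
  expect_lt(peak_band, 9)
})

test_that("bump detection: counts, threshold, merging and summit exclusion", {
  g <- grid_spec(28, 28, 28)
  p <- mech_params(g_width = 3)
  sph <- make_fixture("sphere", g, p = p, radius = 9)
  mesh <- extract_isosurface(sph, 0, g)

  # 5 equatorial bumps -> 5 sites
  bumps <- make_fixture("bumps", g, p = p, radius = 9, z0 = 14, k = 5, bump_width = 1.6)
  mesh$u <- sample_on_mesh(mesh, bumps)
  mesh$grid <- g
  cand <- detect_primordia(mesh, u_threshold = 0.35, p = p)
  expect_identical(nrow(cand), 5L)
  expect_identical(count_symmetry(cand), 5L)

  # uniform field below threshold -> no sites
  mesh$u <- rep(0.1, nrow(mesh$vertices))
  expect_identical(nrow(detect_primordia(mesh, u_threshold = 0.35, p = p)), 0L)

  # wide bumps bridged above a low threshold merge into one cluster
  bumps2 <- make_fixture("bumps", g, p = p, radius = 9, z0 = 14, k = 6, bump_width = 3)
  mesh$u <- sample_on_mesh(mesh, bumps2)
  cand2 <- detect_primordia(mesh, u_threshold = 0.05, p = p)
  expect_identical(nrow(cand2), 1L)

  # a bump at the apex is excluded (summit exclusion)
  apex_bump <- scalar_field(function(x, y, z)
    exp(-((x - 14)^2 + (y - 14)^2 + (z - 23)^2) / (2 * 1.6^2)), g)
  mesh$u <- sample_on_mesh(mesh, apex_bump)
  expect_identical(nrow(detect_primordia(mesh, u_threshold = 0.35, p = p)), 0L)
})

test_that("persistence rule: transient candidates are dropped, persistent ones fix permanently", {
  g <- grid_spec(28, 28, 28)
  p <- mech_params(g_width = 3)
  phi <- make_fixture("sphere", g, p = p, radius = 9)
  bumps <- make_fixture("bumps", g, p = p, radius = 9, z0 = 14, k = 3, bump_width = 1.6)
  quiet <- scalar_field(0, g)

  state <- list(phi = phi, u = bumps, primordia = NULL, T = 0L)
  tracker <- list()
  # candidate present one cycle, then gone: never fixed
  state$T <- 1L
  out <- fix_primordia(state, p, g, tracker, tau = 3L)
  expect_identical(nrow(out$primordia), 0L)
  state$u <- quiet
  state$T <- 2L
  out <- fix_primordia(state, p, g, out$tracker, tau = 3L)
  expect_identical(length(out$tracker), 0L)

  # persisting tau cycles: fixed at the cycle of confirmation, then permanent
  state$u <- bumps
  tracker <- list()
  for (T in 1:3) {
    state$T <- T
    out <- fix_primordia(state, p, g, tracker, tau = 3L)
    tracker <- out$tracker
    state$primordia <- out$primordia
  }
  expect_identical(nrow(state$primordia), 3L)
  expect_true(all(state$primordia$birth_T == 3L))
  # morphogen drops afterwards: the record remains
  state$u <- quiet
  state$T <- 4L
  out <- fix_primordia(state, p, g, tracker, tau = 3L)
  expect_identical(nrow(out$primordia), 3L)
})

test_that("count_symmetry: whorl gap test, Fourier fallback, rotation invariance", {
  expect_identical(count_symmetry(c(0, 90, 180, 270) * pi / 180), 4L)
  set.seed(31)
  jit <- (c(0, 90, 180, 270) + runif(4, -5, 5)) * pi / 180
  expect_identical(count_symmetry(jit), 4L)
  expect_identical(count_symmetry(1.3), 1L)
  expect_error(count_symmetry(numeric()), "empty")

  # Fourier path (forced by a strict gap tolerance) still recovers the fold
  expect_identical(count_symmetry(jit, gap_tol = 1.001), 4L)

  # rotation invariance across folds and offsets
  for (m in 2:6) {
    ang <- 2 * pi * (0:(m - 1)) / m
    for (rot in c(0.3, 1.7, 4.4)) {
      expect_identical(count_symmetry((ang + rot) %% (2 * pi)), as.integer(m))
    }
  }
})

test_that("classify_pattern labels constructed whorled, spiral, ribbed and degenerate cases", {
  mk <- function(angles, births, gens, z_extent = 1, arc_extent = 1) {
    data.frame(x = cos(angles), y = sin(angles), z = 5,
               birth_T = births, angle = angles, generation = gens,
               z_extent = z_extent, arc_extent = arc_extent)
  }
  w <- rbind(mk(2 * pi * (0:3) / 4, 10L, 1L),
             mk(2 * pi * (0:3) / 4 + pi / 4, 40L, 2L))
  cw <- classify_pattern(list(primordia = w))
  expect_identical(cw$label, "whorled")
  expect_identical(cw$fold, 4L)
  expect_identical(cw$generations, 2L)

  golden <- 2.39996
  sp <- mk((golden * (0:7)) %% (2 * pi), seq(5L, 75L, by = 10L),
           rep(1:2, each = 4L))
  cs <- classify_pattern(list(primordia = sp))
  expect_identical(cs$label, "spiral")

  rb <- mk(2 * pi * (0:5) / 6, 10L, 1L, z_extent = 8, arc_extent = 1.5)
  cr <- classify_pattern(list(primordia = rb))
  expect_identical(cr$label, "ribbed")
  expect_identical(cr$fold, 6L)

  expect_identical(classify_pattern(list(primordia = NULL))$label, "none")
})

test_that("mesh_main_component keeps the largest of two disjoint surfaces", {
  g <- grid_spec(40, 20, 20)
  w <- sqrt(2)
  two <- scalar_field(function(x, y, z) {
    d1 <- 7 - sqrt((x - 10)^2 + (y - 10)^2 + (z - 10)^2)
    d2 <- 3.5 - sqrt((x - 30)^2 + (y - 10)^2 + (z - 10)^2)
    tanh(pmax(d1, d2) / w)
  }, g)
  mesh <- extract_isosurface(two, 0, g)
  main <- mesh_main_component(mesh)
  expect_lt(nrow(main$vertices), nrow(mesh$vertices))
  expect_true(all(main$vertices[, 1] < 20))  # the big sphere
  expect_identical(euler_characteristic(main), 2L)
})

test_that("phase_diagram_sweep tabulates calls per cell and records failures", {
  base <- run_config(eta = 0.3902, seed = 1, grid = grid_spec(24, 24, 28),
                     mech = mech_params(R = 6, Hz = 4, g_width = 3),
                     n_chem_init = 300L, n_chem = 30L, n_mech = 10L,
                     max_cycles = 2L)
  tab <- phase_diagram_sweep(base, list(eta = c(0.26, 0.39), gamma = 0.2))
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("eta", "gamma", "label", "fold", "generations",
                    "n_primordia", "error") %in% names(tab)))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$label %in% c("none", "whorled", "spiral", "ribbed", "aberrant")))

  # an invalid cell is recorded as an error and the sweep continues
  tab2 <- phase_diagram_sweep(base, list(c = c(0.9, 0.3)))
  expect_identical(nrow(tab2), 2L)
  expect_false(is.na(tab2$error[1]))
  expect_true(is.na(tab2$error[2]))

  expect_error(phase_diagram_sweep(base, list(bogus = 1)), "unknown sweep axis")
})
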