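# Shared fixtures: small grids and analytic fields used across test files.

tiny_grid <- function(n = 12L) grid_spec(n, n, n)

# smooth pseudo-random scalar field (finite, band-limited so stencils behave)
smooth_field <- function(grid, seed = 1, amp = 0.3) {
  set.seed(seed)
  a <- runif(6, -amp, amp)
  scalar_field(function(x, y, z) {
    L <- grid$nx * grid$dx
    a[1] * sin(2 * pi * x / L) + a[2] * cos(2 * pi * y / L) +
      a[3] * sin(2 * pi * z / L) + a[4] * sin(2 * pi * (x + y) / L) +
      a[5] * cos(2 * pi * (x - z) / L) + a[6]
  }, grid)
}

# interior voxel index helper (strips the boundary shell)
interior <- function(grid, skip = 2L) {
  list(x = (1 + skip):(grid$nx - skip),
       y = (1 + skip):(grid$ny - skip),
       z = (1 + skip):(grid$nz - skip))
}

max_interior_abs <- function(f, grid, skip = 2L) {
  ii <- interior(grid, skip)
  max(abs(f[ii$x, ii$y, ii$z]))
}

# numerical functional derivative of free_energy by central differences at a
# subset of voxels: the independent oracle for dF_dphi / dF_du
numerical_variation <- function(phi, u, p, grid, wrt = c("phi", "u"),
                                voxels, delta = 1e-5) {
  wrt <- match.arg(wrt)
  vapply(seq_len(nrow(voxels)), function(q) {
    i <- voxels[q, 1]; j <- voxels[q, 2]; k <- voxels[q, 3]
    up <- phi; uu <- u
    if (wrt == "phi") {
      up[i, j, k] <- up[i, j, k] + delta
      Fp <- free_energy(up, uu, p, grid)$F
      up[i, j, k] <- up[i, j, k] - 2 * delta
      Fm <- free_energy(up, uu, p, grid)$F
    } else {
      uu[i, j, k] <- uu[i, j, k] + delta
      Fp <- free_energy(up, uu, p, grid)$F
      uu[i, j, k] <- uu[i, j, k] - 2 * delta
      Fm <- free_energy(up, uu, p, grid)$F
    }
    (Fp - Fm) / (2 * delta * grid$dx^3)
  }, numeric(1))
}

# Reference coupled run at the 4-whorl parameter set, shared by the
# acceptance and property tests. Memoized: computed once per test session.
.ref_cache <- new.env(parent = emptyenv())
reference_run <- function() {
  if (is.null(.ref_cache$sim)) {
    cfg <- fold_config(eta = 0.3902, c = 0.57, seed = 1L)
    .ref_cache$cfg <- cfg
    .ref_cache$sim <- run_simulation(cfg, quiet = TRUE)
  }
  .ref_cache$sim
}

# desk-scale configuration for the captioned-fold runs
fold_config <- function(eta, c, seed, kappa = 2, gw_frac = 2, ...) {
  run_config(eta = eta, c = c, seed = seed,
             mech = mech_params(kappa = kappa, g_width = 10 / gw_frac),
             ...)
}
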