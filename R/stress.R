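#' Stress tensor of the phase field
#'
#' The force-flux tensor derived from the free-energy density
#' `L = Phi_SC^2 - (rho_phi/2)|grad phi|^2 - (rho_u/2)|grad u|^2`:
#' \deqn{\sigma_{\alpha\beta} = (L - \phi\,\delta L/\delta\phi)\,
#'   \delta_{\alpha\beta}
#'   - \partial L/\partial(\nabla_\beta\phi)\, \nabla_\alpha\phi
#'   + \nabla_\beta[\partial L/\partial(\nabla^2\phi)]\, \nabla_\alpha\phi
#'   - \partial L/\partial(\nabla^2\phi)\, \nabla_\alpha\nabla_\beta\phi}
#' with the partials expanded for this energy density:
#' `dL/d(grad_b phi) = -rho_phi grad_b phi` and
#' `dL/d(lap phi) = -2 eps^2 Phi_SC`. The diagonal term is the hydrostatic
#' pressure; the gradient terms carry the surface tension and the curvature
#' tensor of the interface. The stress vanishes identically in the homogeneous
#' bulk phases.
#'
#' The raw tensor is not manifestly symmetric; transport uses the symmetrized
#' form (a diffusion mobility must be symmetric for a well-posed flux), which
#' [mech_step()] and [run_simulation()] apply. Set `symmetrize = TRUE` to get
#' it directly; the raw tensor remains available for diagnostics.
#'
#' @param phi,u [scalar_field()]s (phase field and morphogen).
#' @param p a [mech_params()].
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @param symmetrize return `(sigma + t(sigma)) / 2` instead of the raw tensor.
#' @return A `tensor_field3d` `(nx, ny, nz, 3, 3)`.
#' @export
stress_tensor <- function(phi, u, p, grid = NULL, symmetrize = FALSE) {
  g <- field_grid(phi, grid)
  sig <- cpp_stress(as.double(phi), as.double(u), grid_dim(g), g$dx,
                    p$eps, p$beta, p$rho_phi, p$rho_u)
  if (symmetrize) sig <- symmetrize_tensor(sig)
  rewrap(sig, g, "tensor_field3d")
}

symmetrize_tensor <- function(T) {
  out <- T
  for (a in 1:3) for (b in 1:3)
    out[, , , a, b] <- 0.5 * (T[, , , a, b] + T[, , , b, a])
  out
}

#' Curvature tensor and mean curvature of the interface
#'
#' From the outward unit normal `n = -grad(phi)/|grad(phi)|` (the phase
#' convention puts `phi > 0` inside), the projected normal gradient
#' `Q_ab = (delta_ag - n_a n_g) d_g n_b` and the mean curvature
#' `H = trace(Q) / 2` (mean of the principal curvatures). With this convention
#' a sphere of radius `R` enclosing the `phi > 0` phase has `H = +1/R` and a
#' cylinder `H = +1/(2R)`. Curvature is only defined on the interface band
#' `|phi| < band`; voxels outside the band (or with vanishing gradient) are
#' masked with `NA`.
#'
#' @param phi a [scalar_field()].
#' @param p a [mech_params()] (unused numerically; kept for interface
#'   symmetry with the other tensor operations).
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @param band half-width of the interface band in `phi` units.
#' @return A list with `Q` (a `tensor_field3d`, `NA` off the band) and `H`
#'   (a `scalar_field3d`, `NA` off the band).
#' @export
curvature_tensor <- function(phi, p = mech_params(), grid = NULL, band = 0.9) {
  g <- field_grid(phi, grid)
  out <- cpp_curvature(as.double(phi), grid_dim(g), g$dx, band)
  list(Q = rewrap(out$Q, g, "tensor_field3d"),
       H = rewrap(out$H, g))
}

#' Principal stresses and directions
#'
#' Per-voxel eigendecomposition of the symmetrized tensor `(T + t(T)) / 2`.
#' Eigenvalues are sorted descending; each eigenvector is given a
#' deterministic sign by making its largest-magnitude component positive.
#' For a degenerate (isotropic) spectrum any orthonormal frame is valid.
#'
#' @param T a `tensor_field3d`.
#' @param grid the [grid_spec()]; defaults to the grid attached to `T`.
#' @return A list with `magnitudes` (array `(nx, ny, nz, 3)`, descending) and
#'   `directions` (array `(nx, ny, nz, 3, 3)`; `[, , , , r]` is the unit
#'   eigenvector field of the r-th eigenvalue, components in dimension 4).
#' @export
principal_stress <- function(T, grid = NULL) {
  g <- field_grid(T, grid)
  out <- cpp_principal(as.double(T), grid_dim(g))
  dim(out$magnitudes) <- c(grid_dim(g), 3L)
  dim(out$directions) <- c(grid_dim(g), 3L, 3L)
  out
}
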