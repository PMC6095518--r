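#' Mechanical (phase-field) parameters
#'
#' Parameter bundle for the spontaneous-curvature free energy, the
#' stress-directed transport and the growth terms of the mechanical model.
#'
#' The free energy is
#' \deqn{F = \int \left( \Phi_{SC}^2[\phi]
#'   - \tfrac12 \varrho_\phi |\nabla\phi|^2
#'   - \tfrac12 \varrho_u |\nabla u|^2 \right) dV}
#' with \eqn{\Phi_{SC} = \Phi[\phi] - \epsilon C_0[u] (\phi^2 - 1)},
#' \eqn{\Phi[\phi] = -\phi + \phi^3 - \epsilon^2 \nabla^2\phi} and spontaneous
#' curvature \eqn{C_0 = \beta u^2}. Surface is created preferentially where the
#' morphogen is abundant, hence `rho_phi >= rho_u`.
#'
#' @param eps interface width (grid-spacing units). Default 1: the thinnest
#'   interface resolvable at `dx = 1`.
#' @param beta strength of the morphogen's influence on spontaneous curvature.
#' @param gamma coupling of the stress tensor into the morphogen mobility.
#' @param m mass-addition rate of the growth source `m u^2`.
#' @param kappa gain of the tip-growth Gaussian in the phase-field equation.
#' @param D_phi phase-field mobility.
#' @param rho_phi,rho_u surface-tension coefficients of the phase field and
#'   the morphogen (`rho_phi >= rho_u >= 0`).
#' @param R dome radius (cylinder and hemispherical cap).
#' @param Hz initial cylinder height.
#' @param g_width standard deviation of the tip-growth Gaussian; default
#'   `R / 2`.
#' @param tip_gain base amplitude of the tip-growth Gaussian.
#' @param s_phi,s_u source strengths applied inside fixed primordia.
#' @param r_p primordium source-ball radius (in length units); default `2 dx`
#'   on a unit grid.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(eps = 1, beta = 0.5, gamma = 0.2, m = 15, kappa = 2,
                        D_phi = 1, rho_phi = 2.5, rho_u = 0.5,
                        R = 10, Hz = 6, g_width = R / 2, tip_gain = 1,
                        s_phi = 0.5, s_u = 0.5, r_p = 2) {
  if (eps <= 0) stop("'eps' must be positive")
  if (D_phi <= 0) stop("'D_phi' must be positive")
  if (rho_u < 0 || rho_phi < rho_u)
    stop("surface tensions must satisfy rho_phi >= rho_u >= 0")
  structure(list(eps = eps, beta = beta, gamma = gamma, m = m, kappa = kappa,
                 D_phi = D_phi, rho_phi = rho_phi, rho_u = rho_u,
                 R = R, Hz = Hz, g_width = g_width, tip_gain = tip_gain,
                 s_phi = s_phi, s_u = s_u, r_p = r_p),
            class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params>\n")
  cat(sprintf("  interface: eps = %g, rho_phi = %g, rho_u = %g, D_phi = %g\n",
              x$eps, x$rho_phi, x$rho_u, x$D_phi))
  cat(sprintf("  coupling:  beta = %g, gamma = %g\n", x$beta, x$gamma))
  cat(sprintf("  growth:    m = %g, kappa = %g, tip_gain = %g, g_width = %g\n",
              x$m, x$kappa, x$tip_gain, x$g_width))
  cat(sprintf("  geometry:  R = %g, Hz = %g; sources s_phi = %g, s_u = %g, r_p = %g\n",
              x$R, x$Hz, x$s_phi, x$s_u, x$r_p))
  invisible(x)
}

#' Bulk double-well functional of the phase field
#'
#' `Phi = -phi + phi^3 - eps^2 lap(phi)`. Vanishes identically in the bulk
#' phases `phi = +/-1` and along the equilibrium tanh interface profile.
#'
#' @param phi a [scalar_field()] (the phase field).
#' @param p a [mech_params()].
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @return A `scalar_field3d`.
#' @export
phi_functional <- function(phi, p, grid = NULL) {
  g <- field_grid(phi, grid)
  out <- -phi + phi^3 - p$eps^2 * cpp_laplacian(as.double(phi), grid_dim(g), g$dx)
  rewrap(as.array(out), g)
}

#' Spontaneous curvature set by the morphogen
#'
#' `C0 = beta * u^2` pointwise: the preferred interface curvature grows
#' quadratically with the local morphogen concentration, the mechanism by
#' which an auxin maximum softens the surface and lets a primordium bulge out.
#'
#' @param u a [scalar_field()] (morphogen).
#' @param p a [mech_params()].
#' @return A `scalar_field3d` (same grid as `u`).
#' @export
spontaneous_curvature <- function(u, p) {
  g <- field_grid(u)
  rewrap(as.array(p$beta * u^2), g)
}

#' Spontaneous-curvature-augmented functional
#'
#' `Phi_SC = Phi[phi] - eps * C0[u] * (phi^2 - 1)`. The factor `(phi^2 - 1)`
#' acts as a delta function centred at the interface: the curvature coupling
#' is confined to the surface and has no effect in the bulk phases.
#'
#' @inheritParams phi_functional
#' @param u a [scalar_field()] (morphogen).
#' @return A `scalar_field3d`.
#' @export
phi_sc <- function(phi, u, p, grid = NULL) {
  g <- field_grid(phi, grid)
  Phi <- phi_functional(phi, p, g)
  rewrap(as.array(Phi - p$eps * p$beta * u^2 * (phi^2 - 1)), g)
}

#' Free energy of the coupled phase-field/morphogen system
#'
#' Energy density `L = Phi_SC^2 - (rho_phi/2)|grad phi|^2 - (rho_u/2)|grad u|^2`
#' (signs as in the model definition) integrated over the grid, together with
#' both variational derivatives.
#'
#' On the grid the tension terms are discretized in their integrated-by-parts
#' form, `+(rho/2) f lap(f)` (equal to `-(rho/2)|grad f|^2` up to the
#' vanishing zero-flux boundary term): with the symmetric 7-point Laplacian
#' this makes the closed-form variational derivatives [dF_dphi()] and
#' [dF_du()] the *exact* gradients of the implemented `F`, so the numerical
#' perturbation oracle reproduces them to round-off rather than to stencil
#' accuracy.
#'
#' @inheritParams phi_sc
#' @return An object of class `energy_fields`: a list with `Phi`, `PhiSC`,
#'   `density` (scalar fields), `F` (total free energy, grid sum times
#'   `dx^3`), and the variational derivatives `mu_phi`, `mu_u`.
#' @export
free_energy <- function(phi, u, p, grid = NULL) {
  g <- field_grid(phi, grid)
  dm <- grid_dim(g)
  Phi <- phi_functional(phi, p, g)
  PhiSC <- rewrap(as.array(Phi - p$eps * p$beta * u^2 * (phi^2 - 1)), g)
  lphi <- cpp_laplacian(as.double(phi), dm, g$dx)
  lu <- cpp_laplacian(as.double(u), dm, g$dx)
  density <- rewrap(as.array(PhiSC^2 + 0.5 * p$rho_phi * phi * lphi +
                               0.5 * p$rho_u * u * lu), g)
  structure(list(Phi = Phi, PhiSC = PhiSC, density = density,
                 F = sum(density) * g$dx^3,
                 mu_phi = dF_dphi(phi, u, p, g),
                 mu_u = dF_du(phi, u, p, g)),
            class = "energy_fields")
}

#' @export
print.energy_fields <- function(x, ...) {
  cat(sprintf("<energy_fields> F = %.6g\n", x$F))
  invisible(x)
}

#' Variational derivative of the free energy with respect to the phase field
#'
#' `dF/dphi = 2[(3 phi^2 - 1 - 2 phi eps beta u^2) Phi_SC - eps^2 lap(Phi_SC)]
#'  + rho_phi lap(phi)`, implemented exactly in this closed form.
#'
#' @inheritParams phi_sc
#' @return A `scalar_field3d`.
#' @export
dF_dphi <- function(phi, u, p, grid = NULL) {
  g <- field_grid(phi, grid)
  terms <- cpp_energy_terms(as.double(phi), as.double(u), grid_dim(g), g$dx,
                            p$eps, p$beta, p$rho_phi, p$rho_u)
  rewrap(terms$mu_phi, g)
}

#' Variational derivative of the free energy with respect to the morphogen
#'
#' `dF/du = -4 eps (phi^2 - 1) beta u Phi_SC + rho_u lap(u)`. In the bulk
#' phases the coupling term vanishes and only the surface-tension Laplacian
#' survives.
#'
#' @inheritParams phi_sc
#' @return A `scalar_field3d`.
#' @export
dF_du <- function(phi, u, p, grid = NULL) {
  g <- field_grid(phi, grid)
  terms <- cpp_energy_terms(as.double(phi), as.double(u), grid_dim(g), g$dx,
                            p$eps, p$beta, p$rho_phi, p$rho_u)
  rewrap(terms$mu_u, g)
}
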