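#' BVAM reaction-diffusion parameters
#'
#' Kinetic coefficients of the two-morphogen BVAM system in the
#' non-dimensional form
#' \deqn{\partial_t u = D \nabla^2 u + \eta (u + a v - c u v - u v^2)}
#' \deqn{\partial_t v = \nabla^2 v + \eta (b v + h u + c u v + u v^2)}
#' where `u` plays the role of auxin and `v` an antagonistic morphogen.
#' The morphogens are centred on the homogeneous steady state, so `(0, 0)` is
#' always a fixed point. `D` is the diffusivity ratio `D_u / D_v`. The scaling
#' parameter `eta` is the domain-size surrogate of the kinetics: the symmetry
#' of the Turing pattern a given domain supports depends only on `eta` times
#' the squared domain size, which is why it is the main pattern-selection knob.
#' `c` interpolates between stripe-forming (`c = 0`) and spot-forming
#' (`c` near 0.57) kinetics and must lie in `[0, 0.57]`.
#'
#' @param a,b,c,h dimensionless kinetic coefficients.
#' @param D diffusivity ratio `D_u / D_v` (positive).
#' @param eta positive scaling parameter; no default is meaningful, so it must
#'   be supplied.
#' @return An object of class `bvam_params`.
#' @examples
#' p <- bvam_params(eta = 0.3902)
#' bvam_reaction(0.1, 0.1, p)
#' @export
bvam_params <- function(eta, a = 1.1123, b = -1.0122, c = 0.57, h = -1,
                        D = 0.516) {
  if (missing(eta)) stop("'eta' must be supplied (no printed default exists)")
  if (!is.numeric(eta) || eta <= 0) stop("'eta' must be positive")
  if (D <= 0) stop("'D' must be positive")
  if (c < 0 || c > 0.57) stop("'c' must lie in [0, 0.57]")
  structure(list(a = a, b = b, c = c, h = h, D = D, eta = eta),
            class = "bvam_params")
}

#' @export
print.bvam_params <- function(x, ...) {
  cat(sprintf("<bvam_params> a = %g, b = %g, c = %g, h = %g, D = %g, eta = %g\n",
              x$a, x$b, x$c, x$h, x$D, x$eta))
  invisible(x)
}

#' BVAM reaction kinetics
#'
#' The pure reaction part of the BVAM system, evaluated pointwise (vectorized
#' over `u` and `v`):
#' `du = eta (u + a v - c u v - u v^2)`, `dv = eta (b v + h u + c u v + u v^2)`.
#'
#' @param u,v morphogen values (numeric, recycled together).
#' @param p a [bvam_params()].
#' @return A list with components `du` and `dv`.
#' @export
bvam_reaction <- function(u, v, p) {
  stopifnot(inherits(p, "bvam_params"))
  uv <- u * v
  list(du = p$eta * (u + p$a * v - p$c * uv - uv * v),
       dv = p$eta * (p$b * v + p$h * u + p$c * uv + uv * v))
}

#' Advance the BVAM system by explicit Euler steps
#'
#' Explicit Euler update of both morphogen fields:
#' `u <- u + dt (D lap u + f(u, v))`, `v <- v + dt (lap v + g(u, v))`,
#' under the zero-flux boundary closure. The homogeneous state `(0, 0)` is
#' preserved exactly for every parameter set.
#'
#' When a domain indicator `chi` is supplied the dynamics is confined to the
#' tissue by the diffuse-domain method: both diffusive fluxes and kinetics are
#' multiplied by `chi` (in conservative face-flux form), which imposes zero
#' normal flux across the `chi = 0` contour — the realizable reading of
#' zero-flux boundary conditions on the moving tissue surface. With
#' `chi = NULL` the dynamics fills the whole box.
#'
#' @param u,v [scalar_field()]s on a common grid.
#' @param p a [bvam_params()].
#' @param dt time step; defaults to the grid's `dt_chem`.
#' @param nsteps number of steps to take.
#' @param grid the [grid_spec()]; defaults to the grid attached to `u`.
#' @param chi optional domain indicator in `[0, 1]` (e.g.
#'   [domain_indicator()] of the phase field).
#' @return A list with the updated fields `u` and `v`.
#' @export
bvam_step <- function(u, v, p, dt = NULL, nsteps = 1L, grid = NULL, chi = NULL) {
  stopifnot(inherits(p, "bvam_params"))
  g <- field_grid(u, grid)
  if (is.null(dt)) dt <- g$dt_chem
  if (!is.null(chi)) chi <- as.double(chi)
  out <- cpp_bvam_run(as.double(u), as.double(v), grid_dim(g), g$dx,
                      p$a, p$b, p$c, p$h, p$D, p$eta, dt, as.integer(nsteps),
                      chi)
  list(u = rewrap(out$u, g), v = rewrap(out$v, g))
}

#' Smoothed tissue indicator of the phase field
#'
#' `chi = clamp((1 + phi) / 2, 0, 1)`: 1 deep inside the tissue, 0 outside,
#' smooth across the interface. Used to confine the reaction-diffusion
#' dynamics to the tissue (see [bvam_step()]).
#'
#' @param phi a [scalar_field()] phase field.
#' @return A `scalar_field3d` in `[0, 1]`.
#' @export
domain_indicator <- function(phi) {
  g <- field_grid(phi)
  rewrap(array(pmin(pmax((1 + phi) / 2, 0), 1), dim(phi)), g)
}

#' Smoothed interface-shell indicator of the phase field
#'
#' With `eps = NULL`: `1 - phi^2` (clamped to `[0, 1]`), the interface
#' delta-function factor of the spontaneous-curvature coupling, equal to 1 on
#' the surface `phi = 0` and 0 in both bulk phases.
#'
#' With `eps` given, the shell is given a fixed physical width regardless of
#' how steep the evolving phase-field profile has become: each voxel's signed
#' distance to the surface is estimated from the local profile
#' (`d = atanh(phi) (1 - phi^2) / |grad phi|`) and the indicator is
#' `sech^2(d / (sqrt(2) eps))` — identical to `1 - phi^2` for an equilibrium
#' tanh profile of width `eps`, but insensitive to profile compression.
#'
#' Confining the reaction-diffusion dynamics with this weight makes the
#' morphogen pattern live on the tissue surface, the domain on which the
#' spherical-harmonic mode selection ([predict_sphere_mode()]) applies.
#'
#' @param phi a [scalar_field()] phase field.
#' @param eps target shell width; `NULL` for the plain `1 - phi^2` factor.
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @return A `scalar_field3d` in `[0, 1]`.
#' @export
interface_indicator <- function(phi, eps = NULL, grid = NULL) {
  g <- field_grid(phi, grid)
  v <- as.double(phi)
  if (is.null(eps)) {
    out <- pmin(pmax(1 - v^2, 0), 1)
  } else {
    gp <- cpp_gradient(v, grid_dim(g), g$dx)
    n <- prod(grid_dim(g))
    gm <- sqrt(gp[seq_len(n)]^2 + gp[n + seq_len(n)]^2 + gp[2 * n + seq_len(n)]^2)
    out <- numeric(n)  # bulk: 0
    inb <- abs(v) < 0.999 & gm > 1e-8
    d <- atanh(v[inb]) * (1 - v[inb]^2) / gm[inb]
    out[inb] <- 1 / cosh(d / (sqrt(2) * eps))^2
  }
  rewrap(array(out, grid_dim(g)), g)
}

bvam_jacobian <- function(p, k2) {
  matrix(c(p$eta - p$D * k2, p$eta * p$h,
           p$eta * p$a, p$eta * p$b - k2), 2L, 2L)
}

#' Dispersion relation of the linearized BVAM system
#'
#' Largest real part of the eigenvalues of the mode-`k` Jacobian
#' `J(k^2) = [[eta - D k^2, eta a], [eta h, eta b - k^2]]` of the system
#' linearized about the homogeneous state. A Turing instability corresponds to
#' a band of `k^2 > 0` where this growth rate is positive while the
#' homogeneous mode `k^2 = 0` is stable.
#'
#' @param p a [bvam_params()].
#' @param k2 squared wavenumber(s), `>= 0` (vectorized).
#' @return Numeric vector of growth rates, one per element of `k2`.
#' @examples
#' p <- bvam_params(eta = 0.3902)
#' dispersion_relation(p, 0)      # negative: homogeneous state stable
#' dispersion_relation(p, 0.17)   # positive inside the Turing band
#' @export
dispersion_relation <- function(p, k2) {
  stopifnot(inherits(p, "bvam_params"))
  if (any(k2 < 0)) stop("k2 must be >= 0")
  # eigenvalues of the 2x2 Jacobian in closed form
  a11 <- p$eta - p$D * k2
  a22 <- p$eta * p$b - k2
  tr <- a11 + a22
  det <- a11 * a22 - p$eta^2 * p$a * p$h
  disc <- tr^2 / 4 - det
  re <- ifelse(disc >= 0, tr / 2 + sqrt(pmax(disc, 0)), tr / 2)
  as.numeric(re)
}

#' Turing band of unstable wavenumbers
#'
#' Finds the contiguous interval of squared wavenumbers with positive growth
#' rate by a dense scan of [dispersion_relation()] followed by bisection of
#' the endpoints. The band endpoints are roots of `det J(k^2) = 0`.
#'
#' @param p a [bvam_params()].
#' @param n_scan number of scan points.
#' @param tol bisection tolerance on the endpoints.
#' @return A list with elements `k2_lo`, `k2_hi`, `k2_peak` (the fastest
#'   growing squared wavenumber), `empty` (logical) and
#'   `homogeneous_unstable` (logical flag; the band is still returned).
#' @export
turing_band <- function(p, n_scan = 2000L, tol = 1e-8) {
  stopifnot(inherits(p, "bvam_params"))
  hom_unstable <- dispersion_relation(p, 0) > 0
  # scale of the scan: diffusion kills growth for k2 beyond ~eta * O(1)
  k2_max <- 4 * max(p$eta * (1 + abs(p$b)) / min(p$D, 1), 1e-3)
  ks <- seq(0, k2_max, length.out = n_scan)
  lam <- dispersion_relation(p, ks)
  pos <- which(lam > 0 & ks > 0)
  if (!length(pos)) {
    return(list(k2_lo = NA_real_, k2_hi = NA_real_, k2_peak = NA_real_,
                empty = TRUE, homogeneous_unstable = hom_unstable))
  }
  bisect <- function(a, b) {
    fa <- dispersion_relation(p, a) > 0
    for (it in 1:200) {
      if (abs(b - a) < tol) break
      mid <- (a + b) / 2
      if ((dispersion_relation(p, mid) > 0) == fa) a <- mid else b <- mid
    }
    (a + b) / 2
  }
  i_lo <- min(pos); i_hi <- max(pos)
  k2_lo <- if (i_lo > 1) bisect(ks[i_lo - 1], ks[i_lo]) else 0
  k2_hi <- if (i_hi < n_scan) bisect(ks[i_hi + 1], ks[i_hi]) else k2_max
  fine <- seq(k2_lo, k2_hi, length.out = 2000L)
  k2_peak <- fine[which.max(dispersion_relation(p, fine))]
  list(k2_lo = k2_lo, k2_hi = k2_hi, k2_peak = k2_peak,
       empty = FALSE, homogeneous_unstable = hom_unstable)
}

#' Predicted spherical-harmonic degree on a sphere
#'
#' On a sphere of given radius the Laplacian eigenvalues are quantized as
#' `l (l + 1) / radius^2`; the degree whose eigenvalue lies closest to the
#' fastest-growing squared wavenumber of the Turing band is the symmetry the
#' chemistry selects on that domain. Distinct `eta` values therefore map to
#' distinct whorl symmetries at fixed radius.
#'
#' @param p a [bvam_params()].
#' @param radius sphere radius (positive).
#' @return Integer spherical-harmonic degree `l >= 1`.
#' @examples
#' p4 <- bvam_params(eta = 0.3902)
#' p3 <- bvam_params(eta = 0.2601)
#' predict_sphere_mode(p4, 10)  # differs from eta = 0.2601
#' predict_sphere_mode(p3, 10)
#' @export
predict_sphere_mode <- function(p, radius) {
  stopifnot(inherits(p, "bvam_params"), radius > 0)
  band <- turing_band(p)
  if (band$empty)
    stop("no Turing band: the kinetics forms no pattern at these parameters")
  target <- band$k2_peak * radius^2  # l (l + 1) closest to this
  l <- max(1, round((-1 + sqrt(1 + 4 * target)) / 2))
  cand <- unique(pmax(c(l - 1, l, l + 1), 1))
  as.integer(cand[which.min(abs(cand * (cand + 1) - target))])
}
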