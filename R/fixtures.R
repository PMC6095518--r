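#' Analytic test fixtures
#'
#' Constructs the analytic fields used throughout the test-suite and for
#' exploring the operators:
#' \describe{
#'   \item{`sphere`}{tanh interface profile of a sphere (`radius`, `center`;
#'     `phi > 0` inside).}
#'   \item{`cylinder`}{tanh profile of an infinite vertical cylinder
#'     (`radius`).}
#'   \item{`dome`}{the cylinder-plus-hemisphere initial tissue, identical to
#'     [initialize_domain()].}
#'   \item{`plane`}{tanh profile of the horizontal plane `z = z0` (`phi > 0`
#'     below).}
#'   \item{`bumps`}{a surface morphogen field: `k` equally spaced Gaussian
#'     bumps (width `bump_width`) on a ring of given `radius` and height
#'     `z0`, returned as a scalar field to be sampled on a mesh.}
#' }
#'
#' @param kind one of `"sphere"`, `"cylinder"`, `"dome"`, `"plane"`,
#'   `"bumps"`.
#' @param grid a [grid_spec()].
#' @param p a [mech_params()] (supplies `eps` and, for `dome`, `R` and `Hz`).
#' @param radius sphere/cylinder/ring radius.
#' @param center sphere centre (3-vector); defaults to the grid centre.
#' @param z0 plane height / bump-ring height.
#' @param k number of bumps.
#' @param bump_width Gaussian bump standard deviation.
#' @param phase azimuthal phase of the first bump (radians).
#' @return A `scalar_field3d`.
#' @examples
#' g <- grid_spec(24, 24, 24)
#' sph <- make_fixture("sphere", g, radius = 8)
#' @export
make_fixture <- function(kind = c("sphere", "cylinder", "dome", "plane", "bumps"),
                         grid = grid_spec(), p = mech_params(),
                         radius = 8, center = NULL, z0 = NULL, k = 4L,
                         bump_width = 2, phase = 0) {
  kind <- match.arg(kind)
  cx <- grid$nx * grid$dx / 2
  cy <- grid$ny * grid$dx / 2
  cz <- grid$nz * grid$dx / 2
  w <- sqrt(2) * p$eps
  switch(kind,
    sphere = {
      ctr <- if (is.null(center)) c(cx, cy, cz) else center
      scalar_field(function(x, y, z)
        tanh((radius - sqrt((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2)) / w),
        grid)
    },
    cylinder = scalar_field(function(x, y, z)
      tanh((radius - sqrt((x - cx)^2 + (y - cy)^2)) / w), grid),
    dome = initialize_domain(grid, p),
    plane = {
      zz <- if (is.null(z0)) cz else z0
      scalar_field(function(x, y, z) tanh((zz - z) / w), grid)
    },
    bumps = {
      zz <- if (is.null(z0)) cz else z0
      angles <- phase + 2 * pi * (seq_len(k) - 1) / k
      bx <- cx + radius * cos(angles)
      by <- cy + radius * sin(angles)
      scalar_field(function(x, y, z) {
        acc <- 0
        for (q in seq_len(k))
          acc <- acc + exp(-((x - bx[q])^2 + (y - by[q])^2 + (z - zz)^2) /
                             (2 * bump_width^2))
        acc
      }, grid)
    })
}
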