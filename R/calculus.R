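#' Second-order finite-difference operators
#'
#' Standard 7-point/central-difference operators on the regular grid, the
#' numerical substrate of every PDE term in the model. The boundary closure on
#' all six box faces is homogeneous Neumann (zero normal flux), implemented by
#' ghost-cell mirroring: scalars reflect evenly, while the normal component of
#' a flux reflects oddly, which makes the grid sum of any flux divergence
#' vanish to floating precision (discrete conservation).
#'
#' @param f a [scalar_field()] (or bare 3D array with `grid` supplied).
#' @param grid the [grid_spec()]; defaults to the grid attached to the field.
#' @return `laplacian()` and `divergence()` return a `scalar_field3d`;
#'   `gradient()` returns a `vector_field3d`.
#' @examples
#' g <- grid_spec(10, 10, 10)
#' f <- scalar_field(function(x, y, z) x^2 + y^2 + z^2, g)
#' lf <- laplacian(f)
#' lf[5, 5, 5]  # 6, exact for quadratics in the interior
#' @export
laplacian <- function(f, grid = NULL) {
  g <- field_grid(f, grid)
  out <- cpp_laplacian(as.double(f), grid_dim(g), g$dx)
  rewrap(out, g)
}

#' @rdname laplacian
#' @export
gradient <- function(f, grid = NULL) {
  g <- field_grid(f, grid)
  out <- cpp_gradient(as.double(f), grid_dim(g), g$dx)
  rewrap(out, g, "vector_field3d")
}

#' @rdname laplacian
#' @param v a [vector_field()].
#' @export
divergence <- function(v, grid = NULL) {
  g <- field_grid(v, grid)
  out <- cpp_divergence(as.double(v), grid_dim(g), g$dx)
  rewrap(out, g)
}

#' Divergence of an anisotropic flux
#'
#' Computes `div(T grad s)`: the flux `j_a = T_ab d_b s` is formed first, then
#' its divergence is taken under the zero-flux boundary closure. This is the
#' transport operator of the stress-directed morphogen dynamics, where the
#' mobility tensor is the (symmetrized) stress. Reduces to [laplacian()] when
#' `T` is the identity, and its grid sum vanishes for any `T` and `s`.
#'
#' @param T a [tensor_field()] (per-voxel 3x3 mobility).
#' @param s a [scalar_field()].
#' @param grid the [grid_spec()]; defaults to the grid attached to `s`.
#' @return A `scalar_field3d`.
#' @export
anisotropic_flux_divergence <- function(T, s, grid = NULL) {
  g <- field_grid(s, grid)
  out <- cpp_aniso_div(as.double(T), as.double(s), grid_dim(g), g$dx)
  rewrap(out, g)
}
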