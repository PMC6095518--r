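#' Regular 3D grid specification
#'
#' Describes the uniform computational grid on which all fields live, together
#' with the two integration time steps of the model: `dt_chem` for the fast
#' reaction-diffusion dynamics and `dt_mech` for the slow mechanical
#' (phase-field) dynamics. With the defaults the mechanical dynamics is
#' `dt_chem / dt_mech = 5000` times slower than the chemistry.
#'
#' Voxel `(i, j, k)` (1-based) is centred at physical position
#' `((i - 0.5) dx, (j - 0.5) dx, (k - 0.5) dx)`; the z axis is the dome axis.
#'
#' @param nx,ny,nz voxel counts per axis (each at least 8).
#' @param dx uniform grid spacing (dimensionless length).
#' @param dt_chem time step of the chemical (reaction-diffusion) integrator.
#' @param dt_mech time step of the mechanical (phase-field) integrator.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' g$dt_chem / g$dt_mech  # time-scale separation: 5000
#' @export
grid_spec <- function(nx = 40L, ny = 40L, nz = 60L, dx = 1,
                      dt_chem = 5e-2, dt_mech = 1e-5) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 8L))
    stop("grid dimensions must all be >= 8 (stencil support)")
  if (dx <= 0) stop("dx must be positive")
  if (dt_chem <= 0 || dt_mech <= 0) stop("time steps must be positive")
  structure(list(nx = nx, ny = ny, nz = nz, dx = dx,
                 dt_chem = dt_chem, dt_mech = dt_mech),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, dx = %g, dt_chem = %g, dt_mech = %g\n",
              x$nx, x$ny, x$nz, x$dx, x$dt_chem, x$dt_mech))
  invisible(x)
}

grid_dim <- function(grid) c(grid$nx, grid$ny, grid$nz)

#' Voxel-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return A list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates per axis.
#' @export
grid_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$dx,
       y = (seq_len(grid$ny) - 0.5) * grid$dx,
       z = (seq_len(grid$nz) - 0.5) * grid$dx)
}

#' Construct a scalar field on a grid
#'
#' A scalar field is a plain 3D numeric array carrying its [grid_spec()] as an
#' attribute; every model field (the phase field, the two morphogens, energy
#' densities, ...) is represented this way.
#'
#' @param values a numeric 3D array matching the grid, or a single number to
#'   fill the grid with, or a function `f(x, y, z)` of voxel-centre
#'   coordinates.
#' @param grid a [grid_spec()].
#' @return A 3D array of class `scalar_field3d`.
#' @examples
#' g <- grid_spec(8, 8, 8)
#' f <- scalar_field(function(x, y, z) x^2 + y^2 + z^2, g)
#' @export
scalar_field <- function(values, grid) {
  dm <- grid_dim(grid)
  if (is.function(values)) {
    cc <- grid_coords(grid)
    X <- array(cc$x, dm)
    Y <- array(rep(cc$y, each = grid$nx), dm)
    Z <- array(rep(cc$z, each = grid$nx * grid$ny), dm)
    values <- values(X, Y, Z)
  }
  if (length(values) == 1L) values <- array(values, dm)
  values <- as.array(values)
  if (!identical(dim(values), as.integer(dm)))
    stop("field shape does not match grid")
  if (!all(is.finite(values))) stop("scalar field must be finite everywhere")
  structure(values, grid = grid, class = c("scalar_field3d", "array"))
}

#' @export
print.scalar_field3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<scalar_field3d> %d x %d x %d, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

field_grid <- function(f, grid = NULL) {
  g <- attr(f, "grid")
  if (is.null(g)) g <- grid
  if (is.null(g)) stop("field carries no grid and none was supplied")
  g
}

# wrap a bare array as a field of the same grid
rewrap <- function(values, grid, class = "scalar_field3d") {
  structure(values, grid = grid, class = c(class, "array"))
}

#' Construct a vector field on a grid
#'
#' Stored as a 4D array `(nx, ny, nz, 3)` with the last index the Cartesian
#' component.
#'
#' @param x,y,z numeric 3D arrays (or single numbers) for the three components.
#' @param grid a [grid_spec()].
#' @return A 4D array of class `vector_field3d`.
#' @export
vector_field <- function(x, y, z, grid) {
  dm <- grid_dim(grid)
  comp <- lapply(list(x, y, z), function(v) {
    if (length(v) == 1L) v <- array(v, dm)
    if (!identical(dim(v), as.integer(dm))) stop("component shape does not match grid")
    v
  })
  out <- array(c(comp[[1]], comp[[2]], comp[[3]]), c(dm, 3L))
  if (!all(is.finite(out))) stop("vector field must be finite everywhere")
  structure(out, grid = grid, class = c("vector_field3d", "array"))
}

#' Construct a tensor field on a grid
#'
#' Stored as a 5D array `(nx, ny, nz, 3, 3)`; `T[, , , a, b]` is the `(a, b)`
#' tensor component per voxel. Houses the stress tensor, the curvature tensor
#' and tensorial diffusion mobilities.
#'
#' @param values a 5D array `(nx, ny, nz, 3, 3)`, or a 3x3 matrix replicated
#'   over the grid, or a single number times the identity.
#' @param grid a [grid_spec()].
#' @return A 5D array of class `tensor_field3d`.
#' @examples
#' g <- grid_spec(8, 8, 8)
#' id <- tensor_field(diag(3), g)
#' @export
tensor_field <- function(values, grid) {
  dm <- grid_dim(grid)
  if (length(values) == 1L) values <- diag(3) * values
  if (is.matrix(values) && all(dim(values) == c(3L, 3L))) {
    out <- array(0, c(dm, 3L, 3L))
    for (a in 1:3) for (b in 1:3) out[, , , a, b] <- values[a, b]
  } else {
    out <- as.array(values)
    if (!identical(dim(out), as.integer(c(dm, 3L, 3L))))
      stop("tensor field shape does not match grid")
  }
  structure(out, grid = grid, class = c("tensor_field3d", "array"))
}
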