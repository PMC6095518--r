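#' Extract the triangulated isosurface of a field
#'
#' Marching-tetrahedra triangulation of the level set `phi = level`,
#' deterministic for fixed input and watertight for closed isosurfaces.
#' Per-vertex morphogen and mean-curvature samples can be attached by the
#' caller (see [sample_on_mesh()], [surface_mean_curvature()]).
#'
#' @param phi a [scalar_field()].
#' @param level isosurface level (default 0, the tissue surface).
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @return An object of class `surface_mesh`: list with `vertices` (n x 3
#'   matrix of physical coordinates), `faces` (m x 3 integer matrix, 1-based),
#'   and the grid. Empty mesh (0 vertices) if the field never crosses `level`.
#' @export
extract_isosurface <- function(phi, level = 0, grid = NULL) {
  g <- field_grid(phi, grid)
  out <- cpp_isosurface(as.double(phi), grid_dim(g), g$dx, level)
  structure(list(vertices = out$vertices, faces = out$faces,
                 level = level, grid = g),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  extras <- intersect(c("u", "H", "azimuth", "height"), names(x))
  if (length(extras)) cat(" (per-vertex: ", paste(extras, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Euler characteristic of a surface mesh
#'
#' `V - E + F`; equals 2 for a watertight sphere-like surface.
#'
#' @param mesh a `surface_mesh`.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  if (!nrow(f)) return(0L)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

#' Sample a volumetric field on mesh vertices
#'
#' Trilinear interpolation at the vertex positions; `NA` voxels (e.g. the
#' masked region of a curvature field) propagate to the affected vertices.
#'
#' @param mesh a `surface_mesh`.
#' @param field a [scalar_field()] on the mesh's grid.
#' @return Numeric vector, one value per vertex.
#' @export
sample_on_mesh <- function(mesh, field) {
  g <- mesh$grid
  if (!nrow(mesh$vertices)) return(numeric())
  cpp_trilinear(as.double(field), grid_dim(g), g$dx, mesh$vertices)
}

#' Attach morphogen, curvature and cylindrical coordinates to a mesh
#'
#' Convenience wrapper used by the detection pipeline: samples `u` and the
#' mean curvature `H` at the vertices and adds each vertex's azimuth about
#' the dome axis and its height.
#'
#' @param mesh a `surface_mesh`.
#' @param phi,u [scalar_field()]s.
#' @param p a [mech_params()].
#' @return The mesh with per-vertex vectors `u`, `H`, `azimuth` (radians in
#'   `[0, 2 pi)`) and `height`.
#' @export
decorate_mesh <- function(mesh, phi, u, p = mech_params()) {
  g <- mesh$grid
  mesh$u <- sample_on_mesh(mesh, u)
  mesh$H <- surface_mean_curvature(phi, mesh = mesh, p = p)
  cx <- g$nx * g$dx / 2
  cy <- g$ny * g$dx / 2
  ang <- atan2(mesh$vertices[, 2] - cy, mesh$vertices[, 1] - cx)
  mesh$azimuth <- ang %% (2 * pi)
  mesh$height <- mesh$vertices[, 3]
  mesh
}

#' Mean curvature sampled on the surface
#'
#' Samples the mean-curvature field of [curvature_tensor()] at the vertex
#' positions by trilinear interpolation. Vertices whose interpolation stencil
#' leaves the interface band are masked `NA`.
#'
#' @param phi a [scalar_field()] phase field.
#' @param mesh a `surface_mesh` of `phi` (extracted if omitted).
#' @param p a [mech_params()].
#' @param grid the [grid_spec()]; defaults to the grid attached to `phi`.
#' @return Numeric vector of per-vertex `H`.
#' @export
surface_mean_curvature <- function(phi, mesh = NULL, p = mech_params(),
                                   grid = NULL) {
  g <- field_grid(phi, grid)
  if (is.null(mesh)) mesh <- extract_isosurface(phi, 0, g)
  H <- curvature_tensor(phi, p, g)$H
  sample_on_mesh(mesh, H)
}

# connected components of a vertex subset, via union-find over mesh edges
vertex_components <- function(mesh, keep) {
  comp <- cpp_components(mesh$faces, keep)
  comp[comp == 0L] <- NA_integer_
  comp
}

#' Detect candidate primordium sites on the surface
#'
#' Connected clusters of surface vertices whose sampled morphogen exceeds
#' `u_threshold` are reduced to their `u`-weighted centroids. Clusters within
#' `g_width` of the apex are excluded: primordia never appear at the dome
#' summit. The default threshold is adaptive, `mean + 2 sd` of the sampled
#' surface morphogen.
#'
#' @param mesh a decorated `surface_mesh` (per-vertex `u` present; see
#'   [decorate_mesh()]).
#' @param u_threshold detection threshold; `NULL` for the adaptive default.
#' @param p a [mech_params()] (supplies `g_width` for summit exclusion).
#' @param apex apex position (3-vector); computed from the mesh if omitted.
#' @param min_vertices discard clusters smaller than this (noise guard).
#' @param u_abs_min absolute morphogen floor: the adaptive threshold is never
#'   taken below this, so detection waits for a saturated pattern instead of
#'   firing on small-amplitude fluctuations.
#' @param floor_margin vertices within this height of the box floor are
#'   ignored (the open bottom rim of the computational surface is a box
#'   artifact, not tissue).
#' @return A data frame of candidate sites: centroid `x`, `y`, `z`, `angle`,
#'   mean `u`, vertex count `size`, and the cluster's meridional extent
#'   `z_extent` and azimuthal arc length `arc_extent`.
#' @export
detect_primordia <- function(mesh, u_threshold = NULL, p = mech_params(),
                             apex = NULL, min_vertices = 5L,
                             u_abs_min = 0, floor_margin = 0) {
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      angle = numeric(), u = numeric(), size = integer(),
                      z_extent = numeric(), arc_extent = numeric())
  if (is.null(mesh$u)) stop("mesh carries no morphogen samples; see decorate_mesh()")
  if (!length(mesh$u)) return(empty)
  u <- mesh$u
  if (is.null(u_threshold))
    u_threshold <- max(mean(u, na.rm = TRUE) + 2 * sd(u, na.rm = TRUE), u_abs_min)
  keep <- !is.na(u) & u > u_threshold & mesh$vertices[, 3] > floor_margin
  if (!any(keep)) return(empty)
  g <- mesh$grid
  cx <- g$nx * g$dx / 2
  cy <- g$ny * g$dx / 2
  if (is.null(apex)) apex <- c(cx, cy, max(mesh$vertices[, 3]))
  comp <- vertex_components(mesh, keep)
  out <- lapply(split(which(keep), comp[keep]), function(idx) {
    if (length(idx) < min_vertices) return(NULL)
    w <- u[idx] / sum(u[idx])
    ctr <- colSums(mesh$vertices[idx, , drop = FALSE] * w)
    ang <- atan2(ctr[2] - cy, ctr[1] - cx) %% (2 * pi)
    vang <- atan2(mesh$vertices[idx, 2] - cy, mesh$vertices[idx, 1] - cx)
    # angular spread handled circularly (resultant-based)
    Rbar <- sqrt(mean(cos(vang))^2 + mean(sin(vang))^2)
    aspread <- sqrt(pmax(-2 * log(pmax(Rbar, 1e-12)), 0))
    radius <- mean(sqrt((mesh$vertices[idx, 1] - cx)^2 +
                        (mesh$vertices[idx, 2] - cy)^2))
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3], angle = ang,
               u = mean(u[idx]), size = length(idx),
               z_extent = diff(range(mesh$vertices[idx, 3])),
               arc_extent = aspread * radius)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  d_apex <- sqrt((out$x - apex[1])^2 + (out$y - apex[2])^2 + (out$z - apex[3])^2)
  out[d_apex > p$g_width, , drop = FALSE]
}

#' Largest connected component of a surface mesh
#'
#' Restricts a mesh to its largest connected component (by vertex count),
#' reindexing faces and subsetting any per-vertex attributes. The detection
#' pipeline uses this to confine primordium search to the main tissue
#' surface, ignoring any detached satellite isosurfaces.
#'
#' @param mesh a `surface_mesh`.
#' @return A `surface_mesh`.
#' @export
mesh_main_component <- function(mesh) {
  n <- nrow(mesh$vertices)
  if (!n) return(mesh)
  comp <- vertex_components(mesh, rep(TRUE, n))
  main <- as.integer(names(which.max(table(comp))))
  keep <- which(comp == main)
  if (length(keep) == n) return(mesh)
  remap <- rep(NA_integer_, n)
  remap[keep] <- seq_along(keep)
  faces <- mesh$faces[!is.na(remap[mesh$faces[, 1]]), , drop = FALSE]
  faces[] <- remap[faces]
  out <- mesh
  out$vertices <- mesh$vertices[keep, , drop = FALSE]
  out$faces <- faces
  for (nm in intersect(c("u", "H", "azimuth", "height"), names(mesh)))
    out[[nm]] <- mesh[[nm]][keep]
  out
}

# One detection-and-fixation pass, tracking candidate persistence.
# A candidate persisting tau consecutive cycles within match_radius of itself
# becomes a fixed primordium; once fixed, never removed.
detect_and_fix <- function(state, p, grid, tracker, tau = 5L,
                           gen_window = 15L, match_radius = NULL,
                           u_abs_min = 0, floor_margin = 0) {
  if (is.null(match_radius)) match_radius <- 2 * p$r_p
  mesh <- extract_isosurface(state$phi, 0, grid)
  prim <- state$primordia
  if (!nrow(mesh$vertices))
    return(list(tracker = list(), primordia = prim, n_candidates = 0L))
  mesh <- mesh_main_component(mesh)
  mesh <- decorate_mesh(mesh, state$phi, state$u, p)
  apex <- c(grid$nx * grid$dx / 2, grid$ny * grid$dx / 2,
            summit_height(state$phi, grid))
  cand <- detect_primordia(mesh, NULL, p, apex = apex,
                           u_abs_min = u_abs_min, floor_margin = floor_margin)
  new_tracker <- list()
  for (q in seq_len(nrow(cand))) {
    pos <- c(cand$x[q], cand$y[q], cand$z[q])
    hit <- NULL
    for (nm in names(tracker)) {
      tp <- tracker[[nm]]
      if (sqrt(sum((tp$pos - pos)^2)) <= match_radius) { hit <- nm; break }
    }
    entry <- if (!is.null(hit)) tracker[[hit]] else
      list(pos = pos, count = 0L, meta = NULL)
    entry$pos <- pos
    entry$count <- entry$count + 1L
    entry$meta <- cand[q, ]
    if (!is.null(hit)) tracker[[hit]] <- NULL
    new_tracker[[sprintf("c%.1f_%.1f_%.1f", pos[1], pos[2], pos[3])]] <- entry
  }
  tracker <- new_tracker
  # fixation
  for (nm in names(tracker)) {
    entry <- tracker[[nm]]
    if (entry$count < tau) next
    # skip if an already-fixed primordium sits there
    if (nrow(prim) > 0) {
      d <- sqrt((prim$x - entry$pos[1])^2 + (prim$y - entry$pos[2])^2 +
                (prim$z - entry$pos[3])^2)
      if (any(d <= match_radius)) next
    }
    gen <- 1L
    if (nrow(prim) > 0) {
      last_gen <- max(prim$generation)
      first_T <- min(prim$birth_T[prim$generation == last_gen])
      gen <- if (state$T - first_T <= gen_window) last_gen else last_gen + 1L
    }
    prim <- rbind(prim, data.frame(
      x = entry$pos[1], y = entry$pos[2], z = entry$pos[3],
      birth_T = state$T, angle = entry$meta$angle, generation = gen,
      z_extent = entry$meta$z_extent, arc_extent = entry$meta$arc_extent))
  }
  list(tracker = tracker, primordia = prim, n_candidates = nrow(cand))
}

#' Fix persistent candidate sites as primordia
#'
#' The persistence rule in isolation (the scheduler applies it once per
#' cycle): a candidate that has been matched for at least `tau` consecutive
#' cycles within the match radius of itself is fixed as a primordium record;
#' once fixed it is never removed, even if the local morphogen later drops.
#'
#' @param state simulation state list (fields `phi`, `u`, `primordia`, `T`).
#' @param p a [mech_params()].
#' @param grid a [grid_spec()].
#' @param tracker the persistence tracker (list; start with `list()`).
#' @param tau consecutive-cycle persistence required for fixation.
#' @return A list with the updated `tracker`, `primordia` and the candidate
#'   count `n_candidates`.
#' @export
fix_primordia <- function(state, p, grid = NULL, tracker = list(), tau = 5L) {
  g <- if (!is.null(grid)) grid else field_grid(state$phi)
  if (is.null(state$T)) state$T <- 0L
  if (is.null(state$primordia)) state$primordia <- empty_primordia()
  detect_and_fix(state, p, g, tracker, tau = tau)
}

#' Fold symmetry of one generation of primordia
#'
#' Sites sharing an azimuth (within `merge_tol`) are first collapsed to one
#' angular position: spots of one harmonic often stack along a meridian at
#' different heights and count as a single whorl position. If the angular
#' gaps between the distinct positions are uniform (max gap / mean gap below
#' `gap_tol`) the fold is their count (the whorl test); otherwise it is the
#' dominant angular Fourier mode of the site azimuths (modes 1-12, ties
#' broken toward the lower mode). Invariant under global rotation of all
#' azimuths.
#'
#' @param records a data frame with an `angle` column (radians), or a numeric
#'   vector of angles.
#' @param gap_tol whorl-uniformity tolerance on max gap / mean gap.
#' @param max_mode largest Fourier mode considered.
#' @param merge_tol azimuthal separation (radians) below which sites are
#'   merged into one angular position.
#' @return Integer fold (`>= 1`).
#' @export
count_symmetry <- function(records, gap_tol = 1.5, max_mode = 12L,
                           merge_tol = 20 * pi / 180) {
  ang <- if (is.data.frame(records)) records$angle else records
  ang <- sort(ang %% (2 * pi))
  n <- length(ang)
  if (!n) stop("cannot count the symmetry of an empty generation")
  if (n == 1L) return(1L)
  # collapse azimuthal duplicates (circularly)
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  grp <- cumsum(c(TRUE, head(gaps, -1) > merge_tol))
  if (gaps[n] <= merge_tol && max(grp) > 1L) grp[grp == max(grp)] <- 1L
  pos <- sort(vapply(split(ang, grp), function(a) {
    atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)
  }, numeric(1)))
  k <- length(pos)
  if (k == 1L) return(1L)
  gaps <- diff(c(pos, pos[1] + 2 * pi))
  if (max(gaps) / mean(gaps) < gap_tol) return(k)
  power <- vapply(seq_len(max_mode), function(m) Mod(sum(exp(1i * m * pos))), numeric(1))
  as.integer(which.max(power))  # which.max takes the first (lowest) on ties
}

#' Azimuthal fold of a surface morphogen pattern
#'
#' Field-level symmetry counter used for ribbed (stripe) patterns, where
#' discrete sites under-describe the pattern: the dominant angular Fourier
#' mode of the above-threshold surface morphogen on the dome flank, each
#' vertex weighted by its excess over the threshold.
#'
#' @param mesh a decorated `surface_mesh`.
#' @param u_threshold threshold; `NULL` for the adaptive `mean + 1 sd`.
#' @param p a [mech_params()] (summit exclusion).
#' @param apex apex position; defaults to the topmost vertex on the axis.
#' @param max_mode largest Fourier mode considered.
#' @return Integer fold.
#' @export
field_fold <- function(mesh, u_threshold = NULL, p = mech_params(),
                       apex = NULL, max_mode = 12L) {
  u <- mesh$u
  if (is.null(u)) stop("mesh carries no morphogen samples")
  g <- mesh$grid
  cx <- g$nx * g$dx / 2
  cy <- g$ny * g$dx / 2
  if (is.null(apex)) apex <- c(cx, cy, max(mesh$vertices[, 3]))
  if (is.null(u_threshold)) u_threshold <- mean(u, na.rm = TRUE) + sd(u, na.rm = TRUE)
  d_apex <- sqrt((mesh$vertices[, 1] - apex[1])^2 +
                 (mesh$vertices[, 2] - apex[2])^2 +
                 (mesh$vertices[, 3] - apex[3])^2)
  keep <- !is.na(u) & u > u_threshold & d_apex > p$g_width
  if (!any(keep)) return(0L)
  w <- u[keep] - u_threshold
  ang <- mesh$azimuth[keep]
  power <- vapply(seq_len(max_mode), function(m)
    Mod(sum(w * exp(1i * m * ang))), numeric(1))
  as.integer(which.max(power))
}

#' Classify the pattern of a completed trajectory
#'
#' Labels the trajectory as `whorled` (generations of near-simultaneous,
#' uniformly spaced rings), `spiral` (staggered births with a persistent
#' azimuthal offset between successive sites: parastichy packing), `ribbed`
#' (sites elongated into meridional stripes, the stripe-kinetics regime),
#' `aberrant` (primordia present but with inconsistent ring structure), or
#' `none` (no fixed primordia).
#'
#' @param sim a `phyllo_sim` (or a list with `primordia` and, for the ribbed
#'   call, `phi`/`u` fields).
#' @param gen_sync maximum birth spread (cycles) for a ring to count as
#'   simultaneous.
#' @param rib_aspect minimum meridional-to-azimuthal extent ratio for a site
#'   to count as a rib stripe.
#' @param gap_tol whorl-uniformity tolerance (see [count_symmetry()]).
#' @return An object of class `pattern_call`: list with `label`, `fold` and
#'   `generations`.
#' @export
classify_pattern <- function(sim, gen_sync = 3L, rib_aspect = 2,
                             gap_tol = 1.5) {
  prim <- sim$primordia
  call <- function(label, fold, generations)
    structure(list(label = label, fold = as.integer(fold),
                   generations = as.integer(generations)), class = "pattern_call")
  if (is.null(prim) || nrow(prim) == 0) return(call("none", 0L, 0L))
  gens <- sort(unique(prim$generation))
  n_gen <- length(gens)
  first <- prim[prim$generation == gens[1], ]

  # ribbed: elongated meridional stripes
  aspect <- prim$z_extent / pmax(prim$arc_extent, 1e-6)
  if (median(aspect) > rib_aspect) {
    fold <- NA_integer_
    if (!is.null(sim$phi) && !is.null(sim$u)) {
      g <- field_grid(sim$phi)
      p <- if (!is.null(sim$config)) sim$config$mech else mech_params()
      mesh <- decorate_mesh(extract_isosurface(sim$phi, 0, g), sim$phi, sim$u, p)
      fold <- field_fold(mesh, NULL, p,
                         apex = c(g$nx * g$dx / 2, g$ny * g$dx / 2,
                                  summit_height(sim$phi, g)))
    }
    if (is.na(fold) || fold < 1) fold <- count_symmetry(first, gap_tol)
    return(call("ribbed", fold, n_gen))
  }

  per_gen <- lapply(gens, function(gg) prim[prim$generation == gg, ])
  spread <- vapply(per_gen, function(s) diff(range(s$birth_T)), numeric(1))
  uniform <- vapply(per_gen, function(s) {
    if (nrow(s) < 2) return(TRUE)
    ang <- sort(s$angle)
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    max(gaps) / mean(gaps) < gap_tol
  }, logical(1))
  folds <- vapply(per_gen, count_symmetry, integer(1), gap_tol = gap_tol)

  complete <- vapply(seq_along(per_gen), function(ii)
    nrow(per_gen[[ii]]) >= folds[1] || ii == length(per_gen), logical(1))
  if (all(spread[complete] <= gen_sync) && all(uniform[complete])) {
    consistent <- length(unique(folds[complete & vapply(per_gen, nrow, integer(1)) >= folds[1]])) <= 1
    if (consistent) return(call("whorled", folds[1], n_gen))
    return(call("aberrant", folds[1], n_gen))
  }

  # spiral: staggered births with a persistent divergence angle
  ord <- prim[order(prim$birth_T), ]
  if (nrow(ord) >= 3) {
    dang <- diff(ord$angle) %% (2 * pi)
    Rbar <- Mod(mean(exp(1i * dang)))
    if (Rbar > 0.6 && max(spread) > gen_sync)
      return(call("spiral", count_symmetry(prim, gap_tol), n_gen))
  }
  if (any(!uniform[complete])) return(call("aberrant", folds[1], n_gen))
  call("spiral", folds[1], n_gen)
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> %s, fold %d, %d generation(s)\n",
              x$label, x$fold, x$generations))
  invisible(x)
}

#' Sweep a parameter grid and tabulate pattern calls
#'
#' Runs one simulation per cell of a parameter grid (e.g. over `eta` and
#' `gamma`, or `beta` and `gamma`) and tabulates the [classify_pattern()]
#' call per cell. Per-cell failures are recorded and the sweep continues.
#' Reduced grids and horizons for desk-scale sweeps are supported through the
#' base configuration.
#'
#' @param base_config a [run_config()] used for every cell.
#' @param axes named list of parameter vectors, e.g.
#'   `list(eta = c(0.26, 0.39), gamma = c(0.2, 1))`. Names must be fields of
#'   the BVAM, mechanical or scheduler parameter sets, or `seed`.
#' @param quiet passed to [run_simulation()].
#' @return A data frame with one row per cell: the axis values, `label`,
#'   `fold`, `generations`, `n_primordia` and `error` (NA on success).
#' @export
phase_diagram_sweep <- function(base_config, axes, quiet = TRUE) {
  stopifnot(is.list(axes), length(axes) >= 1, !is.null(names(axes)))
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (nm in names(cells)) {
    known <- c(names(base_config$bvam), names(base_config$mech),
               names(base_config$sched), "seed")
    if (!nm %in% known) stop(sprintf("unknown sweep axis '%s'", nm))
  }
  for (q in seq_len(nrow(cells))) {
    res <- tryCatch({
      cfg <- base_config
      for (nm in names(cells)) {
        val <- cells[q, nm]
        if (nm %in% names(cfg$bvam)) {
          # rebuild through the constructor so per-cell range checks apply
          cfg$bvam <- do.call(bvam_params,
                              modifyList(unclass(cfg$bvam),
                                         setNames(list(val), nm)))
        } else if (nm %in% names(cfg$mech)) {
          cfg$mech <- do.call(mech_params,
                              modifyList(unclass(cfg$mech),
                                         setNames(list(val), nm)))
        } else if (nm %in% names(cfg$sched)) cfg$sched[[nm]] <- val
        else cfg$seed <- val
      }
      sim <- run_simulation(cfg, quiet = quiet)
      pc <- classify_pattern(sim)
      data.frame(cells[q, , drop = FALSE], label = pc$label, fold = pc$fold,
                 generations = pc$generations,
                 n_primordia = nrow(sim$primordia), error = NA_character_)
    }, error = function(e) {
      data.frame(cells[q, , drop = FALSE], label = NA_character_,
                 fold = NA_integer_, generations = NA_integer_,
                 n_primordia = NA_integer_, error = conditionMessage(e))
    })
    rows[[q]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
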