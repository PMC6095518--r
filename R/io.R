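#' Persist and restore simulation states
#'
#' Snapshots hold the three fields, the fixed primordia, the cycle counter and
#' the seed, versioned and written via R's native serialization. The round
#' trip is lossless: a run resumed from a snapshot at a cycle boundary is
#' bit-identical to the uninterrupted run.
#'
#' @param state a list with fields `phi`, `u`, `v` and optionally `primordia`,
#'   `T`, `summit_z0`, `config` (a `phyllo_sim` works).
#' @param path file path.
#' @return `load_snapshot()` returns the state list; `save_snapshot()` returns
#'   `path` invisibly.
#' @export
save_snapshot <- function(state, path) {
  obj <- list(format = "phyllodome-snapshot", version = 1L,
              phi = state$phi, u = state$u, v = state$v,
              primordia = state$primordia, T = state$T,
              summit_z0 = state$summit_z0,
              tracker = state$tracker,
              seed = if (!is.null(state$config)) state$config$seed else state$seed,
              config = state$config)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read snapshot: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "phyllodome-snapshot"))
    stop("not a phyllodome snapshot file")
  if (!identical(obj$version, 1L))
    stop(sprintf("snapshot version mismatch: got %s, expected 1",
                 as.character(obj$version)))
  obj$format <- NULL
  obj$version <- NULL
  obj
}

#' Export fields as a legacy-VTK structured grid
#'
#' Writes one or more scalar fields on a common grid as a legacy ASCII VTK
#' `STRUCTURED_POINTS` dataset (point data, one array per field), readable by
#' standard viewers.
#'
#' @param fields a named list of [scalar_field()]s (or a single field, named
#'   `field`).
#' @param path output file path (`.vtk`).
#' @param grid the [grid_spec()]; defaults to the grid of the first field.
#' @return `path`, invisibly.
#' @export
export_fields <- function(fields, path, grid = NULL) {
  if (!is.list(fields)) fields <- list(field = fields)
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    stop("fields must be named")
  g <- field_grid(fields[[1]], grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "phyllodome fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g$nx, g$ny, g$nz),
               sprintf("ORIGIN %g %g %g", 0.5 * g$dx, 0.5 * g$dx, 0.5 * g$dx),
               sprintf("SPACING %g %g %g", g$dx, g$dx, g$dx),
               sprintf("POINT_DATA %d", g$nx * g$ny * g$nz)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(as.double(fields[[nm]]), format = "g", digits = 9), con)
  }
  invisible(path)
}

#' Export a surface mesh (VTK polydata or PLY)
#'
#' Writes the triangulated isosurface as legacy ASCII VTK `POLYDATA` or ASCII
#' PLY, chosen by the file extension (`.vtk` / `.ply`). Per-vertex attributes
#' attached to the mesh (`u`, `H`) are included (VTK point data / PLY vertex
#' properties).
#'
#' @param mesh a `surface_mesh`.
#' @param path output path ending in `.vtk` or `.ply`.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  extras <- intersect(c("u", "H"), names(mesh))
  con <- file(path, "w")
  on.exit(close(con))
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nv),
             "property float x", "property float y", "property float z",
             sprintf("property float %s", extras),
             sprintf("element face %d", nf),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    vdat <- mesh$vertices
    for (nm in extras) vdat <- cbind(vdat, ifelse(is.na(mesh[[nm]]), 0, mesh[[nm]]))
    writeLines(apply(vdat, 1, function(r) paste(formatC(r, format = "g", digits = 7),
                                                collapse = " ")), con)
    writeLines(apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
  } else {
    writeLines(c("# vtk DataFile Version 3.0", "phyllodome mesh", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d double", nv)), con)
    writeLines(apply(mesh$vertices, 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
    writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
    writeLines(apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
    if (length(extras)) {
      writeLines(sprintf("POINT_DATA %d", nv), con)
      for (nm in extras) {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(formatC(ifelse(is.na(mesh[[nm]]), 0, mesh[[nm]]),
                           format = "g", digits = 9), con)
      }
    }
  }
  invisible(path)
}

#' Export the primordium log as CSV
#'
#' Fixed column schema (header row): `x`, `y`, `z`, `birth_T`, `angle`,
#' `generation`, `z_extent`, `arc_extent`.
#'
#' @param sim a `phyllo_sim` (or a primordium data frame).
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
export_primordia <- function(sim, path) {
  prim <- if (is.data.frame(sim)) sim else sim$primordia
  write.csv(prim, path, row.names = FALSE)
  invisible(path)
}
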