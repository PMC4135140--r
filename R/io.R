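# Configuration, reports, trajectories and mesh export.
#
# Formats: YAML for configuration, JSON for reports, CSV for trajectories
# and traces, ASCII STL/OBJ for surfaces and legacy ASCII VTK for image
# (SDF) data. File-level lengths are millimetres; in-memory scene state is
# SI.

REPORT_SCHEMA_VERSION <- "1.0"

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates every key against the defaults
#' (unknown keys are an error naming the key), fills unset values with their
#' defaults and echoes the result to the log.
#'
#' @param path YAML file.
#' @param quiet suppress the configuration echo.
#' @return the fully defaulted configuration list.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(scene_config(), user)
  validate_config(cfg)
  if (!quiet) {
    message("configuration (defaults materialized):")
    message(paste(utils::capture.output(utils::str(cfg, give.head = FALSE)),
                  collapse = "\n"))
  }
  cfg
}

#' Write a configuration to YAML
#'
#' @param config configuration list.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a procedure report to JSON
#'
#' Full-precision JSON round trip with an embedded schema version. Reports
#' containing non-finite trace values are rejected.
#'
#' @param report a `procedure_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "procedure_report")) stop("write_report: not a procedure_report")
  num <- unlist(lapply(report, function(x) {
    if (is.data.frame(x)) unlist(x, use.names = FALSE)
    else if (is.numeric(x)) as.numeric(x) else numeric(0)
  }), use.names = FALSE)
  if (any(!is.finite(num))) stop("write_report: non-finite values in report")
  payload <- report
  class(payload) <- NULL
  # sdf grids do not belong in a report file
  payload$carved_sdf <- NULL
  # keep the names of named vectors (peaks, damage flags) through JSON
  for (nm in names(payload)) {
    x <- payload[[nm]]
    if (is.atomic(x) && !is.null(names(x))) payload[[nm]] <- as.list(x)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a procedure report from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return a `procedure_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      !identical(obj$schema_version, REPORT_SCHEMA_VERSION))
    stop("read_report: schema version mismatch (file: ",
         if (is.null(obj$schema_version)) "<none>" else obj$schema_version,
         ", supported: ", REPORT_SCHEMA_VERSION, ")")
  for (nm in names(obj)) {
    if (is.data.frame(obj[[nm]])) next
    if (is.list(obj[[nm]]) && all(vapply(obj[[nm]], is.numeric, TRUE)) &&
        length(obj[[nm]]) > 0 &&
        length(unique(vapply(obj[[nm]], length, 1L))) == 1 &&
        vapply(obj[[nm]], length, 1L)[1] > 1) {
      obj[[nm]] <- as.data.frame(obj[[nm]])
    }
  }
  # restore named numeric vectors flattened by JSON
  for (nm in c("incus_peak_mm", "damage")) {
    if (!is.null(obj[[nm]]) && is.list(obj[[nm]]))
      obj[[nm]] <- unlist(obj[[nm]])
  }
  structure(obj, class = "procedure_report")
}

#' Read / write tool trajectories as CSV
#'
#' CSV columns `t, x, y, z, qw, qx, qy, qz[, drill][, tool_id]` with
#' positions in millimetres; converted to metres on read.
#'
#' @param path CSV file.
#' @param ... passed to [tool_trajectory()] (e.g. homothetic factors).
#' @export
read_trajectory_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  for (cc in c("x", "y", "z")) df[[cc]] <- df[[cc]] * 1e-3
  tool_trajectory(df, ...)
}

#' @rdname read_trajectory_csv
#' @param traj a [tool_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- traj$df
  for (cc in c("x", "y", "z")) df[[cc]] <- df[[cc]] * 1e3
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a triangle surface to ASCII STL
#'
#' @param mesh a `tri_shell` (or any list with `nodes` and `triangles`).
#' @param path output file.
#' @param name solid name.
#' @export
write_stl <- function(mesh, path, name = "otosim") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  V <- mesh$nodes; Tm <- mesh$triangles
  for (i in seq_len(nrow(Tm))) {
    p <- V[Tm[i, ], , drop = FALSE]
    n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Export a mesh to Wavefront OBJ
#'
#' @inheritParams write_stl
#' @export
write_obj <- function(mesh, path) {
  V <- mesh$nodes
  Tm <- if (!is.null(mesh$triangles)) mesh$triangles else NULL
  lines <- sprintf("v %g %g %g", V[, 1], V[, 2], V[, 3])
  if (!is.null(Tm)) lines <- c(lines, sprintf("f %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Save / load an SDF grid as legacy ASCII VTK structured points
#'
#' @param g an [sdf_grid()].
#' @param path .vtk file.
#' @export
write_vtk_image <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "otosim signed distance field",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g$dims[1], g$dims[2], g$dims[3]),
               sprintf("ORIGIN %.17g %.17g %.17g", g$origin[1], g$origin[2],
                       g$origin[3]),
               sprintf("SPACING %.17g %.17g %.17g", g$spacing, g$spacing,
                       g$spacing),
               sprintf("POINT_DATA %d", prod(g$dims)),
               "SCALARS distance double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.17g", as.numeric(g$values)), con)
  invisible(path)
}

#' @rdname write_vtk_image
#' @export
read_vtk_image <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", ln[grep("^DIMENSIONS", ln)])), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "", ln[grep("^ORIGIN", ln)])), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "", ln[grep("^SPACING", ln)])), "\\s+")[[1]])[1]
  start <- grep("^LOOKUP_TABLE", ln) + 1L
  vals <- as.numeric(ln[start:(start + prod(dims) - 1L)])
  sdf_grid(origin, spacing, dims, array(vals, dim = dims))
}
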