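#' Export mesh and fields in legacy VTK structured-grid format
#'
#' ASCII legacy VTK (`DATASET STRUCTURED_GRID`) with the axisymmetric plane
#' as a `(ni+1) x (nj+1) x 1` point lattice and cell data for the solved
#' fields, for inspection in ParaView or similar viewers.
#'
#' @param mesh a [build_mesh()] result.
#' @param path output `.vtk` path.
#' @param state optional [solve_flow()] result; when given, `u`, `v`, `p`,
#'   `k`, `omega` and `mu_t` are written as CELL_DATA.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, state = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- (mesh$ni + 1) * (mesh$nj + 1)
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric airway flow", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$ni + 1, mesh$nj + 1),
               sprintf("POINTS %d double", np)), con)
  pts <- cbind(as.vector(mesh$xn), as.vector(mesh$rn), 0)
  write(t(pts), con, ncolumns = 3)
  if (!is.null(state)) {
    nc <- mesh$ni * mesh$nj
    writeLines(sprintf("CELL_DATA %d", nc), con)
    for (nm in c("u", "v", "p", "k", "omega", "mu_t")) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      write(as.vector(state[[nm]]), con, ncolumns = 6)
    }
  }
  invisible(path)
}

#' Export the revolved lumen surface as STL
#'
#' Triangulates the surface of revolution of the lumen profile. Both STL
#' dialects are supported; binary is the common interchange default, ASCII is
#' human-readable.
#'
#' @param profile an [axi_profile()].
#' @param path output `.stl` path.
#' @param n_theta azimuthal facets per ring.
#' @param binary write the binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(profile, path, n_theta = 64L, binary = TRUE) {
  s <- profile$s; R <- profile$R
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)
  tri <- list()
  for (i in seq_len(length(s) - 1L)) {
    for (j in seq_len(n_theta)) {
      p1 <- c(s[i], R[i] * cos(th[j]), R[i] * sin(th[j]))
      p2 <- c(s[i + 1], R[i + 1] * cos(th[j]), R[i + 1] * sin(th[j]))
      p3 <- c(s[i + 1], R[i + 1] * cos(th[j + 1]), R[i + 1] * sin(th[j + 1]))
      p4 <- c(s[i], R[i] * cos(th[j + 1]), R[i] * sin(th[j + 1]))
      tri[[length(tri) + 1L]] <- rbind(p1, p2, p3)
      tri[[length(tri) + 1L]] <- rbind(p1, p3, p4)
    }
  }
  normal <- function(t_) {
    n <- c(
      (t_[2, 2] - t_[1, 2]) * (t_[3, 3] - t_[1, 3]) -
        (t_[2, 3] - t_[1, 3]) * (t_[3, 2] - t_[1, 2]),
      (t_[2, 3] - t_[1, 3]) * (t_[3, 1] - t_[1, 1]) -
        (t_[2, 1] - t_[1, 1]) * (t_[3, 3] - t_[1, 3]),
      (t_[2, 1] - t_[1, 1]) * (t_[3, 2] - t_[1, 2]) -
        (t_[2, 2] - t_[1, 2]) * (t_[3, 1] - t_[1, 1]))
    m <- sqrt(sum(n^2))
    if (m > 0) n / m else c(0, 0, 0)
  }
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(length(tri)), con, size = 4, endian = "little")
    for (t_ in tri) {
      writeBin(as.numeric(c(normal(t_), t(t_))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid airway", con)
    for (t_ in tri) {
      n <- normal(t_)
      writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %g %g %g", t_[, 1], t_[, 2], t_[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid airway", con)
  }
  invisible(path)
}

#' Write metrics reports to CSV and JSON
#'
#' One row per case with the column set
#' `case, dP_S1_Pa, dP_S2_Pa, wss_max_S1_Pa, wss_max_S2_Pa, EL_W, lambda,
#' Re_S1, Re_S2` (region names follow the stenosis ids actually present).
#'
#' @param reports a [flow_metrics()] report or list of them.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return the combined data frame, invisibly.
#' @export
write_metrics <- function(reports, csv = NULL, json = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(tab, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(tab)
}
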