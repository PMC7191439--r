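#' Mesh parameters for the axisymmetric structured grid
#'
#' Controls the wall-clustered finite-volume grid built by [build_mesh()]:
#' a geometric stack of `n_bl_layers` boundary-layer cells grows from
#' `first_layer_height` at the wall by `growth_ratio` per layer, and the
#' remaining interior cells are smoothly graded down to the axis. The same
#' first-layer/growth-ratio mechanism used for wall-resolving prism layers in
#' 3D airway meshes, reduced to a structured axisymmetric grid.
#'
#' @param n_axial cells along the axis across the anatomical segment (inlet
#'   and outlet extensions receive additional, geometrically stretched cells).
#' @param n_radial cells across the radius, boundary layers included.
#' @param first_layer_height wall-adjacent cell thickness (m).
#' @param growth_ratio successive boundary-layer expansion ratio (`>= 1`).
#' @param n_bl_layers number of clustered wall layers.
#' @param ext_stretch axial stretching ratio applied in the domain extensions.
#' @param ext_max_ratio cap on extension cell size as a multiple of the
#'   anatomical axial spacing.
#' @return An object of class `mesh_params`.
#' @export
mesh_params <- function(n_axial = 90L, n_radial = 30L,
                        first_layer_height = 1e-5, growth_ratio = 1.2,
                        n_bl_layers = 3L, ext_stretch = 1.15,
                        ext_max_ratio = 8) {
  stopifnot(n_axial >= 4L, n_radial >= 4L, first_layer_height > 0,
            growth_ratio >= 1, n_bl_layers >= 1L,
            n_radial > n_bl_layers + 1L, ext_stretch >= 1, ext_max_ratio >= 1)
  structure(list(n_axial = as.integer(n_axial), n_radial = as.integer(n_radial),
                 first_layer_height = first_layer_height,
                 growth_ratio = growth_ratio,
                 n_bl_layers = as.integer(n_bl_layers),
                 ext_stretch = ext_stretch, ext_max_ratio = ext_max_ratio),
            class = "mesh_params")
}

#' Refine mesh parameters for a grid-sensitivity study
#'
#' Multiplies the axial and radial cell counts by `factor` and divides the
#' first-layer height by `factor`, so successive levels halve (or better) every
#' grid spacing, as required for Richardson analysis of observed convergence
#' order.
#'
#' @param params a [mesh_params()].
#' @param factor integer refinement factor, `>= 2`.
#' @return refined `mesh_params`.
#' @export
refine_mesh <- function(params, factor) {
  stopifnot(inherits(params, "mesh_params"))
  if (factor < 2 || factor != round(factor))
    stop("refinement factor must be an integer >= 2")
  params$n_axial <- as.integer(params$n_axial * factor)
  params$n_radial <- as.integer(params$n_radial * factor)
  params$first_layer_height <- params$first_layer_height / factor
  params
}

# geometric wall stack + smoothly graded interior, from the axis (0) to R;
# returns radial node positions of length n_radial + 1
radial_nodes <- function(R, nr, h1, g, nbl, station = NA) {
  stack <- h1 * g^(0:(nbl - 1L))
  if (sum(stack) >= 0.9 * R)
    stop(sprintf(paste0("boundary-layer stack (%.3g m) too thick for local ",
                        "radius %.3g m at axial station %s"),
                 sum(stack), R, format(station)))
  n_int <- nr - nbl
  h_last <- stack[nbl]
  target <- R - sum(stack)
  f <- function(q) sum(h_last * q^(1:n_int)) - target
  # bracket the grading ratio
  lo <- 1e-3; hi <- 1.0
  while (f(hi) < 0) hi <- hi * 1.5
  q <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  thick <- c(stack, h_last * q^(1:n_int))  # wall -> axis
  r <- R - cumsum(c(0, thick))
  r[length(r)] <- 0
  rev(r)
}

# cumulative axial spacings covering length L, starting at dx0 and stretching
# geometrically (capped), rescaled to fit L exactly
stretched_spacings <- function(L, dx0, ratio, cap) {
  if (L <= 0) return(numeric(0))
  dx <- dx0
  out <- numeric(0)
  while (sum(out) < L) {
    out <- c(out, dx)
    dx <- min(dx * ratio, cap * dx0)
    if (length(out) > 1e5) stop("extension meshing failed to terminate")
  }
  out * (L / sum(out))
}

#' Build a wall-clustered axisymmetric structured mesh
#'
#' Discretizes the revolved lumen of an [axi_profile()] into an
#' `(n_axial + extensions) x n_radial` finite-volume grid. Radial node
#' distributions follow the local lumen radius `R(s)` with a geometric
#' boundary-layer stack at the wall (thickness `first_layer_height`, expansion
#' `growth_ratio`); cell volumes and face area vectors carry the full
#' 2*pi-revolution metric (Pappus volumes, conical face areas), so the mesh is
#' exactly conservative for the revolved solid.
#'
#' @param profile an [axi_profile()] (typically extended via [extend_domain()]).
#' @param params a [mesh_params()].
#' @return An object of class `structured_mesh` with node lattices `xn`, `rn`,
#'   cell centroids/volumes, face area vectors, interpolation weights, wall
#'   spacing, and the generating profile attached.
#' @export
build_mesh <- function(profile, params) {
  stopifnot(inherits(profile, "axi_profile"), inherits(params, "mesh_params"))
  a0 <- profile$anat[1]; a1 <- profile$anat[2]
  dx0 <- (a1 - a0) / params$n_axial
  x_anat <- seq(a0, a1, length.out = params$n_axial + 1L)
  lin <- a0 - min(profile$s)
  lout <- max(profile$s) - a1
  x_in <- if (lin > 0) {
    sp <- stretched_spacings(lin, dx0, params$ext_stretch, params$ext_max_ratio)
    a0 - rev(cumsum(sp))
  } else numeric(0)
  x_out <- if (lout > 0) {
    sp <- stretched_spacings(lout, dx0, params$ext_stretch, params$ext_max_ratio)
    a1 + cumsum(sp)
  } else numeric(0)
  x <- c(x_in, x_anat, x_out)
  ni <- length(x) - 1L
  nj <- params$n_radial

  Rw <- profile_radius(profile, x)
  rn <- matrix(0, ni + 1L, nj + 1L)
  for (i in seq_len(ni + 1L)) {
    rn[i, ] <- radial_nodes(Rw[i], nj, params$first_layer_height,
                            params$growth_ratio, params$n_bl_layers,
                            station = signif(x[i], 6))
  }
  xn <- matrix(x, ni + 1L, nj + 1L)

  geo <- mesh_geometry(xn, rn)
  mesh <- structure(c(list(ni = ni, nj = nj, xn = xn, rn = rn,
                           profile = profile, params = params,
                           i_anat = range(which(x >= a0 - 1e-12 & x <= a1 + 1e-12))),
                      geo),
                    class = "structured_mesh")
  if (any(mesh$vol <= 0)) stop("mesh contains non-positive cell volumes")
  mesh
}

# cell centroids/volumes and axisymmetric face area vectors from node lattices
mesh_geometry <- function(xn, rn) {
  ni <- nrow(xn) - 1L; nj <- ncol(xn) - 1L
  ii <- seq_len(ni); jj <- seq_len(nj)
  # corners: a=(i,j) b=(i+1,j) c=(i+1,j+1) d=(i,j+1), counterclockwise
  xa <- xn[ii, jj, drop = FALSE];     ra <- rn[ii, jj, drop = FALSE]
  xb <- xn[ii + 1L, jj, drop = FALSE]; rb <- rn[ii + 1L, jj, drop = FALSE]
  xc_ <- xn[ii + 1L, jj + 1L, drop = FALSE]; rc_ <- rn[ii + 1L, jj + 1L, drop = FALSE]
  xd <- xn[ii, jj + 1L, drop = FALSE]; rd <- rn[ii, jj + 1L, drop = FALSE]
  cr1 <- xa * rb - xb * ra; cr2 <- xb * rc_ - xc_ * rb
  cr3 <- xc_ * rd - xd * rc_; cr4 <- xd * ra - xa * rd
  A2 <- 0.5 * (cr1 + cr2 + cr3 + cr4)
  cx <- ((xa + xb) * cr1 + (xb + xc_) * cr2 + (xc_ + xd) * cr3 +
           (xd + xa) * cr4) / (6 * A2)
  cr <- ((ra + rb) * cr1 + (rb + rc_) * cr2 + (rc_ + rd) * cr3 +
           (rd + ra) * cr4) / (6 * A2)
  vol <- 2 * pi * cr * A2

  # east-direction faces (constant-i lines), (ni+1) x nj, normal -> +i
  ie <- seq_len(ni + 1L)
  x1 <- xn[ie, jj, drop = FALSE]; r1 <- rn[ie, jj, drop = FALSE]
  x2 <- xn[ie, jj + 1L, drop = FALSE]; r2 <- rn[ie, jj + 1L, drop = FALSE]
  rme <- 0.5 * (r1 + r2)
  Se_x <- 2 * pi * rme * (r2 - r1)
  Se_r <- -2 * pi * rme * (x2 - x1)
  xfe <- 0.5 * (x1 + x2); rfe <- rme

  # north-direction faces (constant-j lines), ni x (nj+1), normal -> +j
  jn <- seq_len(nj + 1L)
  x1 <- xn[ii, jn, drop = FALSE]; r1 <- rn[ii, jn, drop = FALSE]
  x2 <- xn[ii + 1L, jn, drop = FALSE]; r2 <- rn[ii + 1L, jn, drop = FALSE]
  rmn <- 0.5 * (r1 + r2)
  Sn_x <- -2 * pi * rmn * (r2 - r1)
  Sn_r <- 2 * pi * rmn * (x2 - x1)
  xfn <- 0.5 * (x1 + x2); rfn <- rmn

  # outward face-vector sums per cell (Green-Gauss metric correction)
  sumS_x <- Se_x[ii + 1L, jj, drop = FALSE] - Se_x[ii, jj, drop = FALSE] +
    Sn_x[, jj + 1L, drop = FALSE] - Sn_x[, jj, drop = FALSE]
  sumS_r <- Se_r[ii + 1L, jj, drop = FALSE] - Se_r[ii, jj, drop = FALSE] +
    Sn_r[, jj + 1L, drop = FALSE] - Sn_r[, jj, drop = FALSE]

  # distance from wall-adjacent centroid to the wall face, per axial cell
  nwx <- Sn_x[, nj + 1L]; nwr <- Sn_r[, nj + 1L]
  nmag <- sqrt(nwx^2 + nwr^2)
  wall_y <- ((xfn[, nj + 1L] - cx[, nj]) * nwx +
               (rfn[, nj + 1L] - cr[, nj]) * nwr) / nmag

  list(xc = cx, rc = cr, vol = vol,
       Se_x = Se_x, Se_r = Se_r, xfe = xfe, rfe = rfe,
       Sn_x = Sn_x, Sn_r = Sn_r, xfn = xfn, rfn = rfn,
       sumS_x = sumS_x, sumS_r = sumS_r, wall_y = wall_y)
}

#' @export
print.structured_mesh <- function(x, ...) {
  cat("Axisymmetric structured mesh\n")
  cat(sprintf("  %d x %d cells (%d total), volume %.4g m^3\n",
              x$ni, x$nj, x$ni * x$nj, sum(x$vol)))
  cat(sprintf("  wall spacing: min %.3g m, max %.3g m\n",
              min(x$wall_y), max(x$wall_y)))
  invisible(x)
}

#' Exact volume of the revolved profile
#'
#' Solid-of-revolution volume `pi * integral R(s)^2 ds` of the piecewise-linear
#' lumen profile, evaluated exactly per segment. Used as the analytic oracle
#' for geometric conservation of the mesh.
#'
#' @param profile an [axi_profile()].
#' @return volume (m^3).
#' @export
revolved_volume <- function(profile) {
  h <- diff(profile$s)
  r1 <- profile$R[-length(profile$R)]
  r2 <- profile$R[-1]
  sum(pi * h * (r1^2 + r1 * r2 + r2^2) / 3)
}

#' Mesh quality summary
#'
#' Reports minimal cell volume, maximal cell aspect ratio and maximal
#' neighbor size jump; flags cells beyond conventional thresholds.
#'
#' @param mesh a [build_mesh()] result.
#' @param max_aspect,max_jump flag thresholds.
#' @return list with fields `min_volume`, `max_aspect`, `max_jump`, `flags`.
#' @export
mesh_quality <- function(mesh, max_aspect = 2000, max_jump = 3) {
  dx <- diff(mesh$xn[, 1])
  dr <- t(diff(t(mesh$rn)))      # (ni+1) x nj radial spacings at stations
  drc <- 0.5 * (dr[-nrow(dr), , drop = FALSE] + dr[-1, , drop = FALSE])
  aspect <- sweep(1 / drc, 1, dx, "*")
  jump_r <- drc[, -1, drop = FALSE] / drc[, -ncol(drc), drop = FALSE]
  jump_r <- pmax(jump_r, 1 / jump_r)
  jump_x <- outer(pmax(dx[-1] / dx[-length(dx)], dx[-length(dx)] / dx[-1]),
                  rep(1, mesh$nj))
  list(min_volume = min(mesh$vol),
       max_aspect = max(aspect),
       max_jump = max(max(jump_r), max(jump_x)),
       flags = list(aspect = sum(aspect > max_aspect),
                    jump = sum(jump_r > max_jump) + sum(jump_x > max_jump),
                    nonpositive_volume = sum(mesh$vol <= 0)))
}
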