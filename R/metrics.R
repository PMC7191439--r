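#' Wall shear stress along the duct
#'
#' Magnitude of the viscous tangential stress exerted on the wall,
#' `tau_wall = mu * d(u_t)/dn` evaluated at the wall from the wall-adjacent
#' cells. The default uses a one-sided quadratic fit through the first two
#' cell centers (second-order accurate in the near-wall spacing); `"linear"`
#' uses the first-layer cell only.
#'
#' @param state a converged [solve_flow()] result.
#' @param mesh the mesh the state lives on.
#' @param method gradient evaluation at the wall.
#' @return data frame with wall-face axial position `s` (m) and stress `tau`
#'   (Pa, nonnegative). If the state did not converge a warning is attached.
#' @export
wall_shear_stress <- function(state, mesh, method = c("quadratic", "linear")) {
  method <- match.arg(method)
  if (!isTRUE(state$converged))
    warning("wall shear stress evaluated on an unconverged state")
  ni <- mesh$ni; nj <- mesh$nj
  mu <- state$fluid$mu
  wall_Ax <- mesh$Sn_x[, nj + 1]; wall_Ar <- mesh$Sn_r[, nj + 1]
  Aw <- sqrt(wall_Ax^2 + wall_Ar^2)
  nxh <- wall_Ax / Aw; nrh <- wall_Ar / Aw
  # tangential unit vector along the wall (normal rotated by 90 degrees)
  txh <- nrh; trh <- -nxh
  ut1 <- state$u[, nj] * txh + state$v[, nj] * trh
  y1 <- mesh$wall_y
  if (method == "linear" || nj < 3) {
    grad <- ut1 / y1
  } else {
    ut2 <- state$u[, nj - 1] * txh + state$v[, nj - 1] * trh
    y2 <- (mesh$xfn[, nj + 1] - mesh$xc[, nj - 1]) * nxh +
      (mesh$rfn[, nj + 1] - mesh$rc[, nj - 1]) * nrh
    grad <- (ut1 * y2^2 - ut2 * y1^2) / (y1 * y2 * (y2 - y1))
  }
  data.frame(s = mesh$xfn[, nj + 1], tau = abs(mu * grad))
}

# volume-weighted (equivalently area-weighted) column average of a cell field,
# linearly interpolated to axial position s
column_average <- function(field, mesh, s) {
  colavg <- rowSums(field * mesh$vol) / rowSums(mesh$vol)
  approx(mesh$xc[, 1], colavg, xout = s, rule = 2)$y
}

#' Static pressure drop between two cross-sections
#'
#' Area-averaged static pressure at `s_up` minus at `s_down`. Total-pressure
#' drop (mass-flux-averaged `p + 1/2 rho |u|^2`) is available via
#' `type = "total"`; static is the primary definition of the stenotic
#' pressure drop.
#'
#' @param state a [solve_flow()] result.
#' @param mesh the mesh.
#' @param s_up,s_down axial stations (m), `s_up < s_down`, both inside the
#'   anatomical region.
#' @param type `"static"` or `"total"`.
#' @return pressure drop (Pa).
#' @export
pressure_drop <- function(state, mesh, s_up, s_down,
                          type = c("static", "total")) {
  type <- match.arg(type)
  anat <- mesh$profile$anat
  if (s_up >= s_down) stop("s_up must lie upstream of s_down")
  if (s_up < anat[1] - 1e-12 || s_down > anat[2] + 1e-12)
    stop("measurement stations must lie inside the anatomical region")
  if (type == "static") {
    column_average(state$p, mesh, s_up) - column_average(state$p, mesh, s_down)
  } else {
    Q <- state$Q
    (energy_flux(state, mesh, s_up) - energy_flux(state, mesh, s_down)) / Q
  }
}

#' Mechanical energy flux through a cross-section
#'
#' Discrete cross-section integral of `(p + 1/2 rho |u|^2)` carried by the
#' conservative face volume fluxes, `sum_j (p_f + 1/2 rho |u_f|^2) * Q_f`,
#' evaluated at the face column nearest to `s`.
#'
#' @param state a [solve_flow()] result.
#' @param mesh the mesh.
#' @param s axial station (m) within the domain.
#' @return energy flux (W), positive in the downstream direction.
#' @export
energy_flux <- function(state, mesh, s) {
  if (s < min(mesh$xn[, 1]) - 1e-12 || s > max(mesh$xn[, 1]) + 1e-12)
    stop("axial position outside the mesh")
  i <- which.min(abs(mesh$xfe[, 1] - s))
  ni <- mesh$ni
  rho <- state$fluid$rho
  face_val <- function(field, inlet_val, outlet_val = field[ni, ]) {
    if (i == 1) return(inlet_val)
    if (i == ni + 1) return(outlet_val)
    0.5 * (field[i - 1, ] + field[i, ])
  }
  # static pressure: linear extrapolation at the inlet face, Dirichlet datum
  # at the outlet face
  xf <- mesh$xfe[i, 1]
  p_in <- state$p[1, ] + (state$p[1, ] - state$p[2, ]) *
    (mesh$xc[1, 1] - xf) / (mesh$xc[2, 1] - mesh$xc[1, 1])
  pf <- face_val(state$p, p_in, rep(0, mesh$nj))
  uf <- face_val(state$u, state$u_in)
  vf <- face_val(state$v, rep(0, mesh$nj))
  qf <- state$me[i, ] / rho
  sum((pf + 0.5 * rho * (uf^2 + vf^2)) * qf)
}

#' Energy-loss rate
#'
#' The normalized mechanical energy dissipated between inlet and outlet,
#' `lambda = 1 - E_outlet / E_inlet`.
#'
#' @param E_inlet inlet energy flux (W), `> 0`.
#' @param E_outlet outlet energy flux (W).
#' @return dimensionless loss rate.
#' @export
energy_loss_rate <- function(E_inlet, E_outlet) {
  if (E_inlet <= 0) stop("inlet energy flux must be positive")
  1 - E_outlet / E_inlet
}

#' Aerodynamic metrics report for one case
#'
#' Computes the full read-out set from a converged state: static pressure
#' drop across each stenotic region (stations one reference diameter upstream
#' and downstream of the region, clamped to the anatomical segment), maximum
#' wall shear stress per region and globally, inlet/outlet mechanical energy
#' fluxes over the anatomical segment, energy loss and loss rate, and the
#' throat Reynolds number per region.
#'
#' Regions default to the stenoses recorded in the mesh's profile; for
#' virtually corrected cases pass the uncorrected case's extents so residual
#' drops at former stenotic sites are still reported.
#'
#' @param state a [solve_flow()] result.
#' @param mesh the mesh.
#' @param regions named list of axial extents `c(s_start, s_end)` (m); default
#'   taken from the profile's stenosis specs.
#' @param label case label (e.g. `"M1"`).
#' @return object of class `metrics_report`.
#' @export
flow_metrics <- function(state, mesh, regions = NULL, label = "case") {
  prof <- mesh$profile
  anat <- prof$anat
  if (is.null(regions)) {
    regions <- lapply(prof$stenoses, stenosis_extent)
    names(regions) <- vapply(prof$stenoses, `[[`, "", "id")
  }
  fluid <- state$fluid
  Q <- state$Q
  wss <- wall_shear_stress(state, mesh)
  in_anat <- wss$s >= anat[1] & wss$s <= anat[2]
  D0 <- 2 * prof$R0

  dP <- wss_max <- Re <- setNames(numeric(length(regions)), names(regions))
  for (nm in names(regions)) {
    ext <- regions[[nm]]
    s_up <- max(ext[1] - D0, anat[1])
    s_down <- min(ext[2] + D0, anat[2])
    dP[nm] <- pressure_drop(state, mesh, s_up, s_down)
    sel <- wss$s >= ext[1] & wss$s <= ext[2]
    wss_max[nm] <- if (any(sel)) max(wss$tau[sel]) else NA_real_
    ii <- which(mesh$xn[, 1] >= ext[1] & mesh$xn[, 1] <= ext[2])
    R_throat <- min(mesh$rn[ii, mesh$nj + 1])
    U_throat <- Q / (pi * R_throat^2)
    Re[nm] <- reynolds_number(fluid, U_throat, 2 * R_throat)
  }
  E_in <- energy_flux(state, mesh, anat[1])
  E_out <- energy_flux(state, mesh, anat[2])
  EL <- E_in - E_out
  structure(list(
    case = label,
    pressure_drop = dP,
    dP_total = pressure_drop(state, mesh, anat[1], anat[2], type = "total"),
    wss_max = wss_max,
    wss_max_global = if (any(in_anat)) max(wss$tau[in_anat]) else NA_real_,
    E_inlet = E_in, E_outlet = E_out, EL = EL,
    lambda = energy_loss_rate(E_in, E_out),
    Re_throat = Re,
    Q_L_min = Q * 60000,
    converged = isTRUE(state$converged)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report [%s]%s\n", x$case,
              if (x$converged) "" else " (UNCONVERGED)"))
  for (nm in names(x$pressure_drop))
    cat(sprintf("  %s: dP = %.3f Pa, max WSS = %.3f Pa, Re_throat = %.0f\n",
                nm, x$pressure_drop[nm], x$wss_max[nm], x$Re_throat[nm]))
  cat(sprintf("  E_in = %.4g W, E_out = %.4g W, EL = %.4g W, lambda = %.4f\n",
              x$E_inlet, x$E_outlet, x$EL, x$lambda))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  row <- data.frame(case = x$case, stringsAsFactors = FALSE)
  for (nm in names(x$pressure_drop))
    row[[paste0("dP_", nm, "_Pa")]] <- unname(x$pressure_drop[nm])
  for (nm in names(x$wss_max))
    row[[paste0("wss_max_", nm, "_Pa")]] <- unname(x$wss_max[nm])
  row$EL_W <- x$EL
  row$lambda <- x$lambda
  for (nm in names(x$Re_throat))
    row[[paste0("Re_", nm)]] <- unname(x$Re_throat[nm])
  row
}
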