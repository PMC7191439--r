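#' Bronchial branch
#'
#' One conduit of the reduced-order bronchial tree: a laminar Poiseuille
#' resistance plus a quadratic minor-loss term,
#' `dP = 128 mu L / (pi D^4) * Q + K * 1/2 rho (Q/A)^2`.
#'
#' @param id branch label (e.g. `"LMB"`, `"RSL"`).
#' @param length conduit length (m).
#' @param diameter conduit diameter (m).
#' @param K dimensionless minor-loss coefficient (`>= 0`).
#' @return object of class `airway_branch`.
#' @export
airway_branch <- function(id, length, diameter, K = 0) {
  stopifnot(is.character(id), length > 0, diameter > 0, K >= 0)
  structure(list(id = id, length = length, diameter = diameter, K = K),
            class = "airway_branch")
}

#' Flow-dependent branch resistance
#'
#' `R(Q) = 128 mu L / (pi D^4) + K rho Q / (2 A^2)` in Pa/(m^3/s), so that
#' `dP = R(Q) * Q` combines the laminar and minor-loss contributions.
#'
#' @param branch an [airway_branch()].
#' @param Q volumetric flow through the branch (m^3/s, `>= 0`).
#' @param fluid a [fluid_properties()].
#' @return resistance in Pa s/m^3 (positive).
#' @export
branch_resistance <- function(branch, Q, fluid) {
  stopifnot(Q >= 0)
  A <- pi * branch$diameter^2 / 4
  128 * fluid$mu * branch$length / (pi * branch$diameter^4) +
    branch$K * fluid$rho * Q / (2 * A^2)
}

#' Bronchial resistance tree
#'
#' Tree-structured network rooted at the trachea. Branches with no children
#' are outlets held at zero gauge pressure.
#'
#' @param branches list of [airway_branch()] objects.
#' @param parent named character vector mapping each branch id to its parent
#'   id, with the root mapped to `NA`.
#' @return object of class `airway_tree`.
#' @export
airway_tree <- function(branches, parent) {
  ids <- vapply(branches, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("branch ids must be unique")
  stopifnot(setequal(names(parent), ids))
  root <- names(parent)[is.na(parent)]
  if (length(root) != 1) stop("the tree must have exactly one root")
  if (!all(parent[!is.na(parent)] %in% ids))
    stop("every parent must name an existing branch")
  # detect cycles / disconnection by walking up from every node
  for (id in ids) {
    seen <- character(); cur <- id
    while (!is.na(parent[cur])) {
      if (cur %in% seen) stop("connectivity is not a tree (cycle detected)")
      seen <- c(seen, cur); cur <- parent[[cur]]
    }
  }
  names(branches) <- ids
  children <- lapply(ids, function(id) ids[!is.na(parent) & parent == id])
  names(children) <- ids
  structure(list(branches = branches, parent = parent, children = children,
                 root = root,
                 outlets = ids[vapply(children, length, 0L) == 0]),
            class = "airway_tree")
}

#' Solve the bronchial resistance network
#'
#' Fixed-point iteration over the flow-dependent branch resistances: at each
#' pass, equivalent resistances are reduced leaf-to-root (series branch plus
#' parallel children) and flows distributed root-to-leaf in inverse proportion
#' to the children's equivalent resistances, so flow conservation at every
#' junction holds exactly by construction. Iteration stops when the relative
#' flow change is below `1e-12`.
#'
#' @param tree an [airway_tree()].
#' @param Q_in inlet volumetric flow (L/min, `> 0`).
#' @param fluid a [fluid_properties()].
#' @param root_resistance extra series resistance at the root (Pa s/m^3),
#'   e.g. the tracheal secant resistance `dP/Q` taken from the CFD solution.
#' @return object of class `network_solution`: per-branch flows (L/min),
#'   outlet shares (percent), the right:left split, and outlet pressures.
#' @export
solve_network <- function(tree, Q_in, fluid = fluid_properties(),
                          root_resistance = 0) {
  stopifnot(inherits(tree, "airway_tree"), Q_in > 0, root_resistance >= 0)
  Q_si <- Q_in / 60000
  ids <- names(tree$branches)
  Q <- setNames(rep(Q_si / max(length(tree$outlets), 1), length(ids)), ids)
  Q[tree$root] <- Q_si
  Req <- setNames(numeric(length(ids)), ids)

  reduce <- function(id) {
    ch <- tree$children[[id]]
    Rb <- branch_resistance(tree$branches[[id]], Q[[id]], fluid)
    if (length(ch)) {
      for (c_ in ch) reduce(c_)
      Rb <- Rb + 1 / sum(1 / Req[ch])
    }
    Req[[id]] <<- Rb
    invisible(NULL)
  }
  distribute <- function(id) {
    ch <- tree$children[[id]]
    if (!length(ch)) return(invisible(NULL))
    g <- 1 / Req[ch]
    for (c_ in ch) {
      Q[[c_]] <<- Q[[id]] * (1 / Req[[c_]]) / sum(g)
      distribute(c_)
    }
    invisible(NULL)
  }

  it <- 0; converged <- FALSE
  trace <- numeric(0)
  repeat {
    it <- it + 1
    Q_old <- Q
    reduce(tree$root)
    Q[tree$root] <- Q_si
    distribute(tree$root)
    delta <- max(abs(Q - Q_old) / Q_si)
    trace <- c(trace, delta)
    if (delta < 1e-12) { converged <- TRUE; break }
    if (it >= 200) break
  }
  if (!converged)
    stop(paste0("bronchial network failed to converge; relative changes: ",
                paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))

  # outlet pressures: walk down from the root accumulating dP
  p_node <- setNames(numeric(length(ids)), ids)
  p_root_in <- Req[[tree$root]] * Q_si + root_resistance * Q_si
  acc <- function(id, p_up) {
    dp <- branch_resistance(tree$branches[[id]], Q[[id]], fluid) * Q[[id]]
    p_node[[id]] <<- p_up - dp
    for (c_ in tree$children[[id]]) acc(c_, p_node[[id]])
  }
  acc(tree$root, p_root_in)

  out <- tree$outlets
  share <- 100 * Q[out] / Q_si
  side <- substr(out, 1, 1)
  split <- c(right = sum(share[side == "R"]), left = sum(share[side == "L"]))
  structure(list(
    flow_L_min = Q * 60000,
    share_percent = share,
    split = split,
    outlet_pressure = p_node[out],
    inlet_pressure = p_root_in,
    Req = Req, iterations = it, converged = converged
  ), class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat("Bronchial network solution\n")
  for (nm in names(x$share_percent))
    cat(sprintf("  %s: %.3f L/min (%.2f%%)\n", nm,
                x$flow_L_min[nm], x$share_percent[nm]))
  cat(sprintf("  right:left split = %.1f : %.1f\n",
              x$split["right"], x$split["left"]))
  invisible(x)
}

#' Default bronchial trees
#'
#' Reduced-order branch dimensions standing in for the patient's bronchial
#' anatomy. The `"right_dominant"` preset is calibrated (not measured) so the
#' uncorrected patient-like case distributes close to 7:3 right:left,
#' emulating the C-shaped trachea of a left pulmonary artery sling that
#' favors right-lung ventilation; `"healthy"` is calibrated to the
#' 56.57:43.43 right:left reference reported for healthy infants. The outlet
#' label set (LSL, LML, LIL, RSL, RML, RIL below the two main bronchi)
#' follows the configurable seven-label outlet convention.
#'
#' @param preset `"right_dominant"` or `"healthy"`.
#' @return an [airway_tree()].
#' @export
default_bronchial_tree <- function(preset = c("right_dominant", "healthy")) {
  preset <- match.arg(preset)
  dims <- switch(preset,
    right_dominant = list(
      LMB = c(0.026, 0.0031), RMB = c(0.006, 0.0042),
      LSL = c(0.009, 0.0026), LML = c(0.009, 0.0022), LIL = c(0.010, 0.0030),
      RSL = c(0.008, 0.0028), RML = c(0.009, 0.0024), RIL = c(0.010, 0.0032)),
    healthy = list(
      LMB = c(0.016, 0.0040), RMB = c(0.006, 0.0042),
      LSL = c(0.009, 0.0026), LML = c(0.009, 0.0022), LIL = c(0.010, 0.0030),
      RSL = c(0.008, 0.0028), RML = c(0.009, 0.0024), RIL = c(0.010, 0.0032)))
  branches <- lapply(names(dims), function(nm)
    airway_branch(nm, dims[[nm]][1], dims[[nm]][2],
                  K = if (nm %in% c("LMB", "RMB")) 0.5 else 1))
  parent <- c(LMB = "trachea", RMB = "trachea",
              LSL = "LMB", LML = "LMB", LIL = "LMB",
              RSL = "RMB", RML = "RMB", RIL = "RMB",
              trachea = NA)
  branches <- c(branches, list(airway_branch("trachea", 0.002, 0.006, K = 0)))
  airway_tree(branches, parent)
}

#' Mirror-symmetric test tree
#'
#' Left and right subtrees with identical dimensions; the solved split is
#' exactly 50:50, which anchors the network solver's symmetry property.
#'
#' @return an [airway_tree()].
#' @export
symmetric_bronchial_tree <- function() {
  b <- function(id, L, D, K = 1) airway_branch(id, L, D, K)
  branches <- list(
    b("trachea", 0.002, 0.006, 0),
    b("LMB", 0.010, 0.0038, 0.5), b("RMB", 0.010, 0.0038, 0.5),
    b("LSL", 0.009, 0.0026), b("LIL", 0.010, 0.0030),
    b("RSL", 0.009, 0.0026), b("RIL", 0.010, 0.0030))
  parent <- c(trachea = NA, LMB = "trachea", RMB = "trachea",
              LSL = "LMB", LIL = "LMB", RSL = "RMB", RIL = "RMB")
  airway_tree(branches, parent)
}
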