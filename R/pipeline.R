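#' Run a single case end to end
#'
#' Geometry, mesh, steady RANS solve, and metrics for one [case_spec()].
#' Metrics are evaluated over the stenotic regions of the *uncorrected*
#' pathology, so corrected cases still report residual pressure drops and
#' wall shear at the former stenotic sites.
#'
#' @param case a [case_spec()].
#' @param keep_state return the full flow state and mesh along with metrics.
#' @return list with `metrics` (a [flow_metrics()] report) and, when
#'   `keep_state`, `state` and `mesh`.
#' @export
run_case <- function(case, keep_state = TRUE) {
  prof <- case_profile(case)
  mesh <- build_mesh(prof, case$mesh)
  state <- solve_flow(mesh, case$bc, case$fluid, case$settings)
  regions <- lapply(case$stenoses, stenosis_extent)
  names(regions) <- vapply(case$stenoses, `[[`, "", "id")
  metrics <- flow_metrics(state, mesh, regions = regions, label = case$label)
  if (keep_state) list(metrics = metrics, state = state, mesh = mesh)
  else list(metrics = metrics)
}

#' Compare surgical variants end to end
#'
#' Runs every case of a suite (geometry, mesh, solve, metrics, bronchial
#' network), assembles the per-case metrics table, and summarizes the
#' cross-stenosis interaction: how correcting one segment shifts the pressure
#' drop at the other, the ordering of energy-loss rates, and the left/right
#' flow distribution. A case that fails to converge is marked failed and the
#' comparison continues.
#'
#' @param cases named list of [case_spec()]s, e.g.
#'   [make_patient_like_suite()].
#' @param tree bronchial resistance tree for the flow split; default the
#'   right-dominant preset.
#' @param outdir optional directory; when given, per-case metrics (CSV and
#'   JSON), network shares (CSV) and the interaction summary (JSON) are
#'   written there.
#' @param keep_states retain full flow states in the returned object.
#' @return object of class `comparison_report` with fields `table`
#'   (data.frame of per-case metrics and splits), `deltas`, `interaction`
#'   (named logical flags), `network`, `failed`, and optionally `runs`.
#' @export
run_comparison <- function(cases = make_patient_like_suite(),
                           tree = default_bronchial_tree(),
                           outdir = NULL, keep_states = FALSE) {
  runs <- list(); nets <- list(); failed <- character()
  for (lbl in names(cases)) {
    res <- tryCatch(run_case(cases[[lbl]]), error = function(e) e)
    if (inherits(res, "error") || !res$metrics$converged) {
      failed <- c(failed, lbl)
      if (inherits(res, "error")) {
        warning(sprintf("case %s failed: %s", lbl, conditionMessage(res)))
        next
      }
    }
    # tracheal contribution enters the network as a secant resistance dP/Q
    R_tr <- max(res$metrics$dP_total, 0) / res$state$Q
    nets[[lbl]] <- solve_network(tree, cases[[lbl]]$bc$inlet_flow,
                                 cases[[lbl]]$fluid, root_resistance = R_tr)
    runs[[lbl]] <- if (keep_states) res else list(metrics = res$metrics)
  }
  if (!length(runs)) stop("no case completed")

  tab <- do.call(rbind, lapply(names(runs), function(lbl) {
    df <- as.data.frame(runs[[lbl]]$metrics)
    df$right_share_pct <- unname(nets[[lbl]]$split["right"])
    df$left_share_pct <- unname(nets[[lbl]]$split["left"])
    df$failed <- lbl %in% failed
    df
  }))

  deltas <- NULL; interaction <- NULL
  want <- c("M1", "M2", "M3", "M4")
  if (all(want %in% tab$case) && all(c("dP_S1_Pa", "dP_S2_Pa") %in% names(tab))) {
    g <- function(col, lbl) tab[tab$case == lbl, col]
    deltas <- data.frame(
      comparison = c("M2 vs M1 at S2", "M3 vs M1 at S1",
                     "lambda M2 / M1", "lambda M3 / M1", "lambda M4 / M1"),
      value = c(g("dP_S2_Pa", "M2") - g("dP_S2_Pa", "M1"),
                g("dP_S1_Pa", "M3") - g("dP_S1_Pa", "M1"),
                g("lambda", "M2") / g("lambda", "M1"),
                g("lambda", "M3") / g("lambda", "M1"),
                g("lambda", "M4") / g("lambda", "M1")))
    lam <- setNames(tab$lambda, tab$case)[want]
    splits <- setNames(tab$right_share_pct, tab$case)[want]
    interaction <- c(
      correcting_S1_raises_dP_S2 = g("dP_S2_Pa", "M2") > g("dP_S2_Pa", "M1"),
      correcting_S2_lowers_dP_S1 = g("dP_S1_Pa", "M3") < g("dP_S1_Pa", "M1"),
      lambda_min_is_M4 = unname(lam["M4"] == min(lam)),
      lambda_M3_below_M2 = unname(lam["M3"] < lam["M2"]),
      lambda_M2_close_to_M1 = unname(abs(lam["M2"] - lam["M1"]) <
                                       0.35 * lam["M1"]),
      wss_S2_exceeds_S1_in_M1 =
        g("wss_max_S2_Pa", "M1") > g("wss_max_S1_Pa", "M1"),
      split_stable_across_cases = diff(range(splits)) < 5)
  }

  rep_ <- structure(list(table = tab, deltas = deltas,
                         interaction = interaction, network = nets,
                         failed = failed,
                         runs = if (keep_states) runs else NULL),
                    class = "comparison_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(outdir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(tab, file.path(outdir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    net_tab <- do.call(rbind, lapply(names(nets), function(lbl) {
      fl <- nets[[lbl]]$flow_L_min
      sh <- nets[[lbl]]$share_percent
      data.frame(case = lbl, branch = names(fl), flow_L_min = unname(fl),
                 share_percent = unname(sh[names(fl)]))
    }))
    write.csv(net_tab, file.path(outdir, "network.csv"), row.names = FALSE)
    if (!is.null(interaction))
      jsonlite::write_json(as.list(interaction),
                           file.path(outdir, "interaction.json"),
                           auto_unbox = TRUE)
  }
  rep_
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Surgical-scheme comparison\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$interaction)) {
    cat("interaction summary:\n")
    for (nm in names(x$interaction))
      cat(sprintf("  %-28s %s\n", nm, x$interaction[[nm]]))
  }
  if (length(x$failed)) cat("failed cases:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Grid-sensitivity study
#'
#' Re-runs a case on successively refined meshes (axial and radial counts
#' multiplied, first-layer height divided), tabulates a scalar metric per
#' level, and estimates the observed convergence order by Richardson analysis
#' of the last three levels. A level is recommended once the successive
#' relative change drops below `1%`.
#'
#' @param case a [case_spec()].
#' @param levels number of refinement levels (`>= 3`).
#' @param factor refinement factor between levels.
#' @param metric function mapping a [run_case()] result (fields `metrics`,
#'   `state`, `mesh`) to a scalar; default the static pressure drop over the
#'   central 80% of the anatomical segment (interior stations avoid
#'   boundary-interpolation bias, so the error sequence is clean enough for
#'   Richardson analysis).
#' @return list with the per-level `table`, the `observed_order`, and the
#'   `recommended` level (NA when no level meets the 1% criterion).
#' @export
grid_sensitivity <- function(case, levels = 3, factor = 2,
                             metric = NULL) {
  if (is.null(metric))
    metric <- function(run) {
      anat <- run$mesh$profile$anat
      La <- diff(anat)
      pressure_drop(run$state, run$mesh, anat[1] + 0.1 * La,
                    anat[2] - 0.1 * La)
    }
  if (levels < 3) stop("a grid study needs at least 3 levels")
  mp <- case$mesh
  vals <- numeric(0); cells <- integer(0)
  for (l in seq_len(levels)) {
    c_l <- case
    c_l$mesh <- mp
    res <- run_case(c_l, keep_state = TRUE)
    if (!res$metrics$converged)
      stop(sprintf("level %d failed to converge; study incomplete", l))
    vals <- c(vals, metric(res))
    cells <- c(cells, res$mesh$ni * res$mesh$nj)
    if (l < levels) mp <- refine_mesh(mp, factor)
  }
  n <- length(vals)
  d1 <- vals[n - 1] - vals[n - 2]
  d2 <- vals[n] - vals[n - 1]
  order_obs <- if (d2 != 0 && d1 / d2 > 0) log(d1 / d2) / log(factor) else NA
  rel_change <- c(NA, abs(diff(vals)) / abs(vals[-1]))
  tab <- data.frame(level = seq_len(n), cells = cells, value = vals,
                    rel_change = rel_change)
  rec <- which(rel_change < 0.01)[1]
  list(table = tab, observed_order = order_obs,
       recommended = if (is.na(rec)) NA_integer_ else as.integer(rec))
}
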