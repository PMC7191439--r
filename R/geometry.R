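#' Parametric axisymmetric airway lumen profile
#'
#' Constructs an arc-length-parameterized description of an airway lumen:
#' radius `R(s)` sampled on a strictly increasing axial coordinate `s`. The
#' profile is the parametric stand-in for a reconstructed 3D tracheal surface;
#' stenoses are applied to it as smooth (raised-cosine) constrictions and can
#' later be virtually corrected, emulating staged surgical repair.
#'
#' @param length axial length of the anatomical segment (m).
#' @param radius reference (healthy) lumen radius `R0` (m).
#' @param n number of axial samples across the anatomical segment.
#' @return An object of class `axi_profile` with fields `s` (axial samples, m),
#'   `R` (lumen radius per sample, m), `R0` (reference radius, m), `stenoses`
#'   (list of applied [stenosis_spec()] objects), `anat` (axial range of the
#'   anatomical segment) and `extension` (inlet/outlet extension lengths, m).
#' @examples
#' prof <- axi_profile(length = 0.045, radius = 0.003)
#' cross_section_area(prof, 0.02)
#' @export
axi_profile <- function(length = 0.045, radius = 0.003, n = 1201L) {
  stopifnot(length > 0, radius > 0, n >= 11L)
  s <- seq(0, length, length.out = n)
  prof <- structure(list(
    s = s,
    R = rep(radius, n),
    R0 = radius,
    stenoses = list(),
    anat = c(0, length),
    extension = c(inlet = 0, outlet = 0)
  ), class = "axi_profile")
  validate_profile(prof)
  prof
}

#' Stenosis specification
#'
#' Describes one stenotic segment: its axial placement and a target stenosis
#' ratio `r` defined as the fractional cross-sectional area reduction relative
#' to the tracheal entrance, `(S_TE - S_SP) / S_TE`. The constriction
#' shape is a raised-cosine radius dip, C1-smooth at both ends, with its
#' minimum lumen at `center` chosen so the area there satisfies the requested
#' severity: `R_min = R0 * sqrt(1 - severity)`.
#'
#' @param id label, e.g. `"S1"`.
#' @param center axial position of the throat (m).
#' @param length axial extent of the constriction (m).
#' @param severity target area-reduction ratio in `[0, 1)`.
#' @param shape constriction profile family; only `"cosine"` is implemented.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(id, center, length, severity, shape = "cosine") {
  stopifnot(is.character(id), nchar(id) > 0, length > 0,
            severity >= 0, severity < 1)
  shape <- match.arg(shape, "cosine")
  structure(list(id = id, center = center, length = length,
                 severity = severity, shape = shape),
            class = "stenosis_spec")
}

# radius reduction of a spec evaluated at axial positions s, for reference R0
stenosis_dip <- function(spec, s, R0) {
  depth <- R0 * (1 - sqrt(1 - spec$severity))
  dip <- numeric(length(s))
  inside <- abs(s - spec$center) <= spec$length / 2
  dip[inside] <- 0.5 * depth *
    (1 + cos(2 * pi * (s[inside] - spec$center) / spec$length))
  dip
}

stenosis_extent <- function(spec) {
  spec$center + c(-0.5, 0.5) * spec$length
}

validate_profile <- function(prof) {
  stopifnot(inherits(prof, "axi_profile"))
  if (any(diff(prof$s) <= 0)) stop("profile axial samples must be strictly increasing")
  if (any(prof$R <= 0)) stop("profile radius must be positive everywhere")
  slope <- abs(diff(prof$R) / diff(prof$s))
  if (max(slope) > 10)
    warning("profile slope |dR/ds| exceeds 10; mesh may not resolve it")
  invisible(prof)
}

#' @export
print.axi_profile <- function(x, ...) {
  cat("Axisymmetric airway profile\n")
  cat(sprintf("  anatomical segment: [%.4f, %.4f] m, R0 = %.4f m\n",
              x$anat[1], x$anat[2], x$R0))
  cat(sprintf("  domain: [%.4f, %.4f] m (%d samples)\n",
              min(x$s), max(x$s), length(x$s)))
  if (length(x$stenoses)) {
    for (sp in x$stenoses)
      cat(sprintf("  stenosis %s: center %.4f m, length %.4f m, ratio %.1f%%\n",
                  sp$id, sp$center, sp$length, 100 * sp$severity))
  } else cat("  no stenoses\n")
  invisible(x)
}

# linear interpolation of the lumen radius
profile_radius <- function(prof, s) {
  if (any(s < min(prof$s) - 1e-12 | s > max(prof$s) + 1e-12))
    stop("axial position outside profile extent")
  approx(prof$s, prof$R, xout = s, rule = 2)$y
}

#' Cross-sectional lumen area
#'
#' Area of the circular cross-section at axial position `s`, `pi * R(s)^2`.
#'
#' @param profile an [axi_profile()].
#' @param s axial position(s) (m) within the profile extent.
#' @return area(s) in m^2.
#' @export
cross_section_area <- function(profile, s) {
  pi * profile_radius(profile, s)^2
}

#' Stenosis ratio of an applied stenosis
#'
#' The severity of a narrowed segment as the fractional area reduction
#' relative to the tracheal entrance, reported in percent:
#' `(S_TE - S_SP) / S_TE * 100` percent, where `S_TE` is the cross-sectional area
#' at the anatomical inlet and `S_SP` the minimal area within the stenotic
#' extent.
#'
#' @param profile an [axi_profile()].
#' @param stenosis_id label of a stenosis present in the profile.
#' @return severity in percent, in `[0, 100)`.
#' @export
stenosis_ratio <- function(profile, stenosis_id) {
  spec <- find_stenosis(profile, stenosis_id)
  s_te <- cross_section_area(profile, profile$anat[1])
  ext <- stenosis_extent(spec)
  inside <- profile$s >= ext[1] & profile$s <= ext[2]
  s_sp <- pi * min(profile$R[inside])^2
  (s_te - s_sp) / s_te * 100
}

find_stenosis <- function(profile, id) {
  for (sp in profile$stenoses) if (sp$id == id) return(sp)
  stop(sprintf("no stenosis with id '%s' in profile", id))
}

#' Apply a stenosis to a profile
#'
#' Subtracts the spec's raised-cosine radius dip from the lumen so that the
#' minimal cross-sectional area in the extent matches the requested severity;
#' the radius returns smoothly (C1) to the incoming lumen at both ends of the
#' extent.
#'
#' @param profile an [axi_profile()].
#' @param spec a [stenosis_spec()]; its extent must lie inside the anatomical
#'   segment and must not overlap a previously applied stenosis.
#' @return the modified profile, with `spec` recorded.
#' @export
apply_stenosis <- function(profile, spec) {
  stopifnot(inherits(spec, "stenosis_spec"))
  ext <- stenosis_extent(spec)
  if (ext[1] < profile$anat[1] - 1e-12 || ext[2] > profile$anat[2] + 1e-12)
    stop("stenosis extent outside the anatomical segment")
  for (sp in profile$stenoses) {
    other <- stenosis_extent(sp)
    if (ext[1] < other[2] && other[1] < ext[2])
      stop(sprintf("stenosis '%s' overlaps existing stenosis '%s'",
                   spec$id, sp$id))
    if (sp$id == spec$id)
      stop(sprintf("stenosis id '%s' already present", spec$id))
  }
  if (spec$severity == 0) {
    profile$stenoses <- c(profile$stenoses, list(spec))
    return(profile)
  }
  # densify the sample grid across the extent (throat sample included exactly)
  s_add <- seq(ext[1], ext[2], length.out = 201L)
  s_add <- sort(unique(c(s_add, spec$center)))
  s_new <- sort(unique(c(profile$s, s_add)))
  R_new <- approx(profile$s, profile$R, xout = s_new)$y
  R_new <- R_new - stenosis_dip(spec, s_new, profile$R0)
  if (any(R_new <= 0)) stop("stenosis would close the lumen")
  profile$s <- s_new
  profile$R <- R_new
  profile$stenoses <- c(profile$stenoses, list(spec))
  validate_profile(profile)
  profile
}

#' Virtually correct a stenosis
#'
#' Restores the lumen over the stenotic extent to the profile it had before
#' the stenosis was applied (the reference caliber for a profile built from a
#' healthy lumen), leaving every other stenosis untouched. This is the
#' computational analogue of surgically repairing one narrowed segment.
#'
#' @param profile an [axi_profile()].
#' @param stenosis_id label of the stenosis to correct.
#' @return the corrected profile; the spec is removed from its record.
#' @export
correct_stenosis <- function(profile, stenosis_id) {
  spec <- find_stenosis(profile, stenosis_id)
  profile$R <- profile$R + stenosis_dip(spec, profile$s, profile$R0)
  profile$stenoses <-
    Filter(function(sp) sp$id != stenosis_id, profile$stenoses)
  validate_profile(profile)
  profile
}

#' Extend the computational domain with straight inlet/outlet ducts
#'
#' Prepends and appends constant-radius extensions of length
#' `factor * local diameter`, so the flow entering the anatomical segment is
#' developed and the outlet pressure boundary sits far from the region of
#' interest. The anatomical range is preserved so metrics are evaluated only
#' on the airway itself.
#'
#' @param profile an [axi_profile()].
#' @param inlet_factor,outlet_factor extension lengths in local diameters
#'   (dimensionless, `>= 0`); defaults follow common practice of 20 upstream
#'   and 40 downstream diameters.
#' @return the extended profile.
#' @export
extend_domain <- function(profile, inlet_factor = 20, outlet_factor = 40) {
  if (inlet_factor < 0 || outlet_factor < 0)
    stop("extension factors must be nonnegative")
  if (inlet_factor == 0 && outlet_factor == 0) return(profile)
  n0 <- length(profile$s)
  if (inlet_factor > 0) {
    r_in <- profile$R[1]
    l_in <- inlet_factor * 2 * r_in
    s_pre <- seq(profile$s[1] - l_in, profile$s[1], length.out = 33L)
    profile$s <- c(s_pre[-33L], profile$s)
    profile$R <- c(rep(r_in, 32L), profile$R)
    profile$extension["inlet"] <- profile$extension["inlet"] + l_in
  }
  if (outlet_factor > 0) {
    n <- length(profile$s)
    r_out <- profile$R[n]
    l_out <- outlet_factor * 2 * r_out
    s_post <- seq(profile$s[n], profile$s[n] + l_out, length.out = 33L)
    profile$s <- c(profile$s, s_post[-1L])
    profile$R <- c(profile$R, rep(r_out, 32L))
    profile$extension["outlet"] <- profile$extension["outlet"] + l_out
  }
  validate_profile(profile)
  profile
}

#' Surgical scheme: which stenoses are corrected
#'
#' The four subsets of a two-stenosis trachea map one-to-one onto the model
#' labels used throughout: M1 corrects nothing (the original pathology), M2
#' corrects S1 only, M3 corrects S2 only, and M4 corrects both.
#'
#' @param corrected character vector of stenosis ids to correct.
#' @return An object of class `surgical_scheme`.
#' @export
surgical_scheme <- function(corrected = character()) {
  stopifnot(is.character(corrected), !anyDuplicated(corrected))
  structure(list(corrected = corrected), class = "surgical_scheme")
}

#' @export
print.surgical_scheme <- function(x, ...) {
  cat(sprintf("Surgical scheme %s: corrects {%s}\n", scheme_label(x),
              paste(x$corrected, collapse = ", ")))
  invisible(x)
}

#' Model label of a surgical scheme
#'
#' @param scheme a [surgical_scheme()].
#' @return `"M1"`..`"M4"` for the subsets of `{S1, S2}`, otherwise `"custom"`.
#' @export
scheme_label <- function(scheme) {
  ids <- sort(scheme$corrected)
  if (identical(ids, character(0))) return("M1")
  if (identical(ids, "S1")) return("M2")
  if (identical(ids, "S2")) return("M3")
  if (identical(ids, c("S1", "S2"))) return("M4")
  "custom"
}

#' Apply a surgical scheme to a profile
#'
#' Corrects, in order, every stenosis named by the scheme. Corrections
#' commute, so the order is immaterial.
#'
#' @param profile an [axi_profile()].
#' @param scheme a [surgical_scheme()]; all ids must exist in the profile.
#' @return the corrected profile.
#' @export
apply_scheme <- function(profile, scheme) {
  stopifnot(inherits(scheme, "surgical_scheme"))
  for (id in scheme$corrected) profile <- correct_stenosis(profile, id)
  profile
}
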