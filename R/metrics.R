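# Beam QA metrics: field centre, FWHM, 20-80% penumbra, relative output
# factor.  Levels are referenced to the profile maximum (small fields have
# no flat plateau to fit); crossings are searched walking outward from the
# global maximum, which is robust to noise-induced extra crossings far from
# the field.

# first crossing of `level` on one side of the peak, by linear interpolation
.crossing <- function(x, y, level, side = c("right", "left")) {
  side <- match.arg(side)
  imax <- which.max(y)
  idx <- if (side == "right") seq(imax, length(y)) else seq(imax, 1L)
  yy <- y[idx]
  below <- which(yy < level)
  if (length(below) == 0 || below[1] == 1L)
    stop("profile does not cross the ", signif(level, 3),
         " level on the ", side, " side")
  i2 <- below[1]
  i1 <- i2 - 1L
  x1 <- x[idx[i1]]; x2 <- x[idx[i2]]
  y1 <- yy[i1]; y2 <- yy[i2]
  x1 + (level - y1) * (x2 - x1) / (y2 - y1)
}

#' Field centre from a projected profile
#'
#' Intensity-weighted centroid (centre of gravity) of the projected dose
#' profile, computed over samples at or above a threshold fraction of the
#' maximum so that out-of-field noise carries no weight.  The disk centre of
#' the reconstruction is placed at this position.
#'
#' @param profile a `projected_profile` (background-subtracted).
#' @param threshold inclusion level as a fraction of the maximum.
#' @return centre position, mm.
#' @export
field_center <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "projected_profile"),
            threshold >= 0, threshold < 1)
  p <- profile$p
  if (max(p) <= 0) stop("cannot locate the centre of an all-zero profile")
  keep <- p >= threshold * max(p)
  sum(profile$x[keep] * p[keep]) / sum(p[keep])
}

#' Full width at half maximum
#'
#' Distance between the two 50%-of-maximum crossings, each located by
#' linear interpolation between bracketing samples.  For radial (half)
#' profiles the one-sided axis-to-crossing distance is doubled.
#'
#' @param profile a `projected_profile`, a `radial_profile`, or a plain
#'   list/data frame with fields `x`/`p` (lateral) or `r`/`d` (radial).
#' @param level crossing level as a fraction of the maximum (0.5 for FWHM).
#' @return width, mm.
#' @export
fwhm <- function(profile, level = 0.5) UseMethod("fwhm")

#' @export
fwhm.projected_profile <- function(profile, level = 0.5) {
  lev <- level * max(profile$p)
  .crossing(profile$x, profile$p, lev, "right") -
    .crossing(profile$x, profile$p, lev, "left")
}

#' @export
fwhm.radial_profile <- function(profile, level = 0.5) {
  2 * .crossing(profile$r, profile$d, level * max(profile$d), "right")
}

#' @export
fwhm.default <- function(profile, level = 0.5) {
  if (!is.null(profile$r))
    fwhm.radial_profile(list(r = profile$r, d = profile$d), level)
  else
    fwhm.projected_profile(list(x = profile$x, p = profile$p), level)
}

#' 20--80% penumbra width
#'
#' Lateral distance over which the profile climbs from 20% to 80% of its
#' maximum, averaged over the ascending and descending field edges (for a
#' radial profile the single edge is reported; the two lateral edges of the
#' revolution-symmetric field are identical).
#'
#' @param profile as in [fwhm()].
#' @param levels the two fractional levels.
#' @return penumbra width, mm.
#' @export
penumbra_20_80 <- function(profile, levels = c(0.2, 0.8)) {
  lo <- min(levels); hi <- max(levels)
  if (!is.null(profile$r)) {
    d <- profile$d
    return(.crossing(profile$r, d, lo * max(d), "right") -
             .crossing(profile$r, d, hi * max(d), "right"))
  }
  p <- profile$p
  right <- .crossing(profile$x, p, lo * max(p), "right") -
    .crossing(profile$x, p, hi * max(p), "right")
  left <- .crossing(profile$x, p, hi * max(p), "left") -
    .crossing(profile$x, p, lo * max(p), "left")
  (right + left) / 2
}

# on-axis dose of a reconstruction (disk stack or sampled radial profile)
.on_axis <- function(obj) {
  if (inherits(obj, "disk_stack")) return(dose_profile(obj, 0))
  if (!is.null(obj$r)) return(obj$d[which.min(obj$r)])
  stop("need a disk_stack or radial_profile to read the on-axis dose")
}

#' Relative output factor
#'
#' Ratio of the on-axis reconstructed dose of a field to that of a named
#' reference field (conventionally the 15 mm cone).  Both reconstructions
#' must come from the same signal-calibration chain; if both carry a
#' `calibration` attribute the values are compared and a mismatch warns.
#'
#' @param profile reconstruction of the field of interest (`disk_stack` or
#'   `radial_profile`).
#' @param reference reconstruction of the reference field.
#' @return dimensionless output factor.
#' @export
output_factor <- function(profile, reference) {
  cal_p <- attr(profile, "calibration")
  cal_r <- attr(reference, "calibration")
  if (!is.null(cal_p) && !is.null(cal_r) && !identical(cal_p, cal_r))
    warning("calibration metadata differ between field and reference; ",
            "the output factor may not be meaningful")
  d0 <- .on_axis(profile)
  dref <- .on_axis(reference)
  if (dref <= 0) stop("reference field has zero on-axis dose")
  d0 / dref
}

#' Beam-metrics table for a set of reconstructed fields
#'
#' Assembles one row per field: FWHM, 20--80% penumbra, on-axis dose and
#' (when the reference is present) the relative output factor.
#'
#' @param profiles named list of reconstructions (`disk_stack` or
#'   `radial_profile`), one per field.
#' @param reference name of the reference field for output factors; if
#'   absent from `profiles` the output-factor column is omitted with a
#'   warning.
#' @param centers optional named numeric vector of field-centre positions
#'   (mm) to carry into the table.
#' @return a `data.frame` with columns `field`, `center` (if given),
#'   `fwhm_mm`, `penumbra_20_80_mm`, `on_axis_dose`, `output_factor`.
#' @export
metrics_report <- function(profiles, reference = NULL, centers = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1,
            !is.null(names(profiles)), all(nzchar(names(profiles))))
  rad <- lapply(profiles, function(p)
    if (inherits(p, "disk_stack")) sample_profile(p) else p)
  tab <- data.frame(
    field = names(profiles),
    fwhm_mm = vapply(rad, fwhm, numeric(1)),
    penumbra_20_80_mm = vapply(rad, penumbra_20_80, numeric(1)),
    on_axis_dose = vapply(profiles, .on_axis, numeric(1)),
    row.names = NULL)
  if (!is.null(centers))
    tab$center_mm <- unname(centers[tab$field])
  if (!is.null(reference)) {
    if (!reference %in% names(profiles)) {
      warning("reference field '", reference,
              "' not found; output-factor column omitted")
    } else {
      dref <- .on_axis(profiles[[reference]])
      tab$output_factor <- tab$on_axis_dose / dref
    }
  }
  tab
}
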