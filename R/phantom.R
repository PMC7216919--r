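#' Regular 2D grid specification for dose fields
#'
#' Defines the sampling lattice on which ground-truth dose fields are
#' evaluated.  Coordinates follow the DICOM-style convention used throughout
#' the package: `x` runs across the fiber ribbon (the reconstruction axis),
#' `z` runs along the second in-plane axis (parallel to the fibers).
#'
#' @param spacing grid spacing in mm (isotropic).
#' @param half_width half-extent in mm; the grid spans `[-half_width,
#'   half_width]` in both `x` and `z`, centred on the origin.
#' @return a list with elements `spacing`, `x`, `z` (sample-centre
#'   coordinates in mm).
#' @export
field_grid <- function(spacing = 0.05, half_width = 15) {
  stopifnot(spacing > 0, half_width > spacing)
  n <- floor(half_width / spacing)
  ax <- spacing * seq(-n, n)
  list(spacing = spacing, x = ax, z = ax)
}

#' Construct a dose field from a value matrix
#'
#' Low-level constructor for arbitrary (e.g. Gaussian or measured) fields;
#' [cone_dose_field()] and [square_dose_field()] cover the standard shapes.
#'
#' @param values non-negative matrix, rows indexed by `grid$x`, columns by
#'   `grid$z`.
#' @param grid a [field_grid()].
#' @return a `dose_field` object.
#' @export
dose_field <- function(values, grid) new_dose_field(values, grid)

new_dose_field <- function(values, grid) {
  stopifnot(is.matrix(values), nrow(values) == length(grid$x),
            ncol(values) == length(grid$z), all(values >= 0))
  structure(list(values = values, x = grid$x, z = grid$z,
                 spacing = grid$spacing),
            class = "dose_field")
}

#' @export
print.dose_field <- function(x, ...) {
  cat(sprintf("<dose_field> %d x %d grid, spacing %.4g mm, peak %.4g a.u.\n",
              length(x$x), length(x$z), x$spacing, max(x$values)))
  invisible(x)
}

#' Radial dose model of a circular (cone-collimated) field
#'
#' Flat-top field with an error-function penumbra:
#' `D(r) = peak_dose * pnorm((diameter/2 - r) / penumbra_sigma)`.
#' This is the analytic ground truth that [cone_dose_field()] rasterises;
#' it is exported so that downstream checks can compare reconstructions
#' against the generating model.
#'
#' @param r radial distance(s) from the field centre, mm.
#' @param diameter nominal field diameter, mm.
#' @param peak_dose flat-top dose, arbitrary units.
#' @param penumbra_sigma Gaussian penumbra width parameter, mm.
#' @return dose values, same length as `r`.
#' @export
cone_radial_dose <- function(r, diameter, peak_dose = 1, penumbra_sigma = 0.8) {
  peak_dose * stats::pnorm((diameter / 2 - r) / penumbra_sigma)
}

#' Synthesise a circular cone field on a 2D grid
#'
#' @param diameter nominal field diameter, mm (clinical cones: 4--15 mm).
#' @param peak_dose flat-top dose in arbitrary units.
#' @param penumbra_sigma penumbra width parameter, mm.
#' @param center `(x, z)` field centre in mm.
#' @param grid a [field_grid()] specification; must contain the field
#'   footprint (`center` plus `diameter/2 + 4 * penumbra_sigma`).
#' @return a `dose_field` object.
#' @export
cone_dose_field <- function(diameter, peak_dose = 1, penumbra_sigma = 0.8,
                            center = c(0, 0), grid = field_grid()) {
  stopifnot(diameter > 0, penumbra_sigma > 0, peak_dose >= 0)
  foot <- diameter / 2 + 4 * penumbra_sigma
  if (center[1] - foot < min(grid$x) || center[1] + foot > max(grid$x) ||
      center[2] - foot < min(grid$z) || center[2] + foot > max(grid$z))
    stop("grid does not contain the field footprint (centre +/- ",
         sprintf("%.2f", foot), " mm); enlarge `half_width`")
  r <- sqrt(outer((grid$x - center[1])^2, (grid$z - center[2])^2, "+"))
  new_dose_field(cone_radial_dose(r, diameter, peak_dose, penumbra_sigma),
                 grid)
}

# 1D edge profile of a side-s strip convolved with a Gaussian of width sigma;
# sigma = 0 degenerates to the sharp indicator.
.edge_pair <- function(t, s, sigma) {
  if (sigma <= 0) return(0 + (abs(t) <= s / 2))
  stats::pnorm((s / 2 - t) / sigma) - stats::pnorm((-s / 2 - t) / sigma)
}

#' Synthesise a rotated square field on a 2D grid
#'
#' Exact 2D convolution of a square indicator with an isotropic Gaussian:
#' the dose factorises into two error-function edge pairs in the rotated
#' frame.
#'
#' @param side side length, mm.
#' @param angle rotation about the field centre, degrees in `[0, 360)`.
#' @param peak_dose flat-top dose, arbitrary units.
#' @param penumbra_sigma edge blur, mm; `0` gives sharp edges.
#' @param center `(x, z)` field centre, mm.
#' @param grid a [field_grid()]; must contain the rotated footprint.
#' @return a `dose_field` object.
#' @export
square_dose_field <- function(side, angle = 0, peak_dose = 1,
                              penumbra_sigma = 0, center = c(0, 0),
                              grid = field_grid()) {
  stopifnot(side > 0, angle >= 0, angle < 360, penumbra_sigma >= 0)
  foot <- side / sqrt(2) + 4 * penumbra_sigma
  if (center[1] - foot < min(grid$x) || center[1] + foot > max(grid$x) ||
      center[2] - foot < min(grid$z) || center[2] + foot > max(grid$z))
    stop("grid does not contain the rotated square footprint; ",
         "enlarge `half_width`")
  th <- angle * pi / 180
  xs <- grid$x - center[1]
  zs <- grid$z - center[2]
  # rotated coordinates u, v for every grid node
  u <- outer(xs * cos(th), zs * sin(th), "+")
  v <- outer(-xs * sin(th), zs * cos(th), "+")
  vals <- peak_dose * .edge_pair(u, side, penumbra_sigma) *
    .edge_pair(v, side, penumbra_sigma)
  new_dose_field(vals, grid)
}

#' SciFi ribbon detector geometry
#'
#' Describes the staggered multi-layer scintillating-fiber ribbon.  With the
#' defaults (275 um layer pitch, 6 layers, half-pitch stagger) the union of
#' fiber centres across layers samples the `x` axis every 137.5 um.
#'
#' @param fiber_diameter fiber diameter, mm.
#' @param layer_pitch centre-to-centre fiber pitch within one layer, mm.
#' @param n_layers number of stacked layers.
#' @param layer_stagger lateral shift between adjacent layers, as a fraction
#'   of `layer_pitch`.
#' @param ribbon_length fiber length (along the fiber axis), mm.
#' @param ribbon_width ribbon extent across fibers, mm.
#' @return a `detector_geometry` object.
#' @export
detector_geometry <- function(fiber_diameter = 0.250, layer_pitch = 0.275,
                              n_layers = 6, layer_stagger = 0.5,
                              ribbon_length = 400, ribbon_width = 130) {
  stopifnot(fiber_diameter > 0, layer_pitch > 0, n_layers >= 1,
            layer_stagger >= 0, layer_stagger < 1,
            ribbon_length > 0, ribbon_width > 0)
  structure(list(fiber_diameter = fiber_diameter, layer_pitch = layer_pitch,
                 n_layers = n_layers, layer_stagger = layer_stagger,
                 ribbon_length = ribbon_length, ribbon_width = ribbon_width),
            class = "detector_geometry")
}

#' Union of fiber-centre positions across layers
#'
#' Adjacent layers are shifted by `layer_stagger * layer_pitch`; the union of
#' centres over all layers forms the effective sampling comb.  Dose is
#' assumed equal in every layer, so the layers collapse into this single
#' interleaved set.
#'
#' @param geometry a [detector_geometry()].
#' @param xlim optional `c(min, max)` in mm to clip the returned positions
#'   (e.g. the extent of a simulated field grid).
#' @return sorted numeric vector of fiber-centre x positions, mm, centred on
#'   the ribbon midline (x = 0 is a fiber centre of layer 1).
#' @export
fiber_positions <- function(geometry = detector_geometry(), xlim = NULL) {
  p <- geometry$layer_pitch
  offs <- sort(unique(round(((seq_len(geometry$n_layers) - 1) *
                               geometry$layer_stagger) %% 1, 9)) * p)
  half <- geometry$ribbon_width / 2
  pos <- sort(unique(round(as.vector(
    outer(p * seq(-ceiling(half / p), ceiling(half / p)), offs, "+")), 9)))
  pos <- pos[pos >= -half & pos <= half]
  if (!is.null(xlim)) pos <- pos[pos >= xlim[1] & pos <= xlim[2]]
  pos
}

new_fiber_signals <- function(fiber_x, signal) {
  stopifnot(length(fiber_x) == length(signal), !is.unsorted(fiber_x),
            all(diff(fiber_x) > 0), all(signal >= 0))
  structure(list(fiber_x = fiber_x, signal = signal), class = "fiber_signals")
}

#' Forward-project a dose field onto the fiber ribbon
#'
#' Each fiber integrates the dose along its length (the `z` axis), so the
#' ribbon output is the 1D projection of the 2D field -- for a radially
#' symmetric field, its Abel transform.  The integral is evaluated by
#' rectangle quadrature on the field grid, with the dose linearly
#' interpolated across `x` at each fiber centre.
#'
#' @param field a `dose_field`.
#' @param geometry a [detector_geometry()].
#' @param cross_section `"line"` treats the fiber as a line through its
#'   centre; `"tophat"` averages the dose over the fiber diameter (volume
#'   averaging across the 0.25 mm cross-section).
#' @return a `fiber_signals` object (positions mm, signals in dose x mm).
#' @export
project_field <- function(field, geometry = detector_geometry(),
                          cross_section = c("line", "tophat")) {
  cross_section <- match.arg(cross_section)
  stopifnot(inherits(field, "dose_field"))
  fx <- fiber_positions(geometry, xlim = range(field$x))
  if (length(fx) == 0)
    stop("no overlap between the field grid and the fiber ribbon")
  sub <- if (cross_section == "line") 0 else
    geometry$fiber_diameter * seq(-0.4, 0.4, by = 0.2)
  sig <- numeric(length(fx))
  for (dx in sub) {
    xq <- pmin(pmax(fx + dx, min(field$x)), max(field$x))
    i <- pmin(findInterval(xq, field$x), length(field$x) - 1L)
    w <- (xq - field$x[i]) / field$spacing
    lines <- (1 - w) * field$values[i, , drop = FALSE] +
      w * field$values[i + 1L, , drop = FALSE]
    sig <- sig + rowSums(lines) * field$spacing / length(sub)
  }
  new_fiber_signals(fx, pmax(sig, 0))
}

#' Camera model for rendering the ribbon output
#'
#' @param pixel_pitch mm per pixel at the detector plane.  The default
#'   resolves the 137.5 um effective fiber comb with 5 pixels per fiber.
#' @param n_rows number of image rows (the fiber axis maps to rows).
#' @param stripe_sigma Gaussian cross-profile width of one fiber's stripe on
#'   the image, mm.  The fiber-to-pixel point-spread width is a free
#'   parameter of the rendering; the default keeps neighbouring fibers
#'   clearly resolved.
#' @param margin dark border added on each side of the outermost fiber, mm.
#' @return a `camera_spec` list.
#' @export
camera_spec <- function(pixel_pitch = 0.0275, n_rows = 64,
                        stripe_sigma = 0.02, margin = 1.155) {
  stopifnot(pixel_pitch > 0, n_rows >= 1, stripe_sigma > 0, margin >= 0)
  structure(list(pixel_pitch = pixel_pitch, n_rows = n_rows,
                 stripe_sigma = stripe_sigma, margin = margin),
            class = "camera_spec")
}

#' Construct a detector image from a pixel matrix
#'
#' Low-level constructor for images not produced by the renderer (external
#' data, synthetic noise studies).  Rows index the fiber axis (y), columns
#' index the across-fiber axis (x).
#'
#' @param pixels non-negative numeric matrix.
#' @param pixel_pitch mm per pixel.
#' @param x0 x coordinate of the centre of column 1, mm.
#' @param orientation `"rows_y"` (the only supported layout).
#' @return a `detector_image`.
#' @export
detector_image <- function(pixels, pixel_pitch, x0 = 0,
                           orientation = "rows_y")
  new_detector_image(pixels, pixel_pitch, x0, orientation)

new_detector_image <- function(pixels, pixel_pitch, x0 = 0,
                               orientation = "rows_y") {
  stopifnot(is.matrix(pixels), all(pixels >= 0), pixel_pitch > 0)
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch, x0 = x0,
                 orientation = orientation),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %d x %d px, pitch %.4g mm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch))
  invisible(x)
}

#' Render fiber signals to a camera image
#'
#' Each fiber is drawn as a vertical stripe (uniform along rows) whose
#' cross-profile is a discrete Gaussian normalised to unit mass, so the
#' integrated intensity of a stripe equals the fiber signal and the total
#' image intensity equals the total signal.  Rendering is linear in the
#' signals.
#'
#' @param signals a `fiber_signals` object.
#' @param camera a [camera_spec()].
#' @return a `detector_image`; rows index the fiber axis (y), columns index
#'   x, with `x0` the x coordinate of column 1.
#' @export
render_detector_image <- function(signals, camera = camera_spec()) {
  stopifnot(inherits(signals, "fiber_signals"))
  fx <- signals$fiber_x
  pitch <- camera$pixel_pitch
  eff <- min(diff(fx))
  if (pitch > eff / 2)
    warning("pixel pitch ", pitch, " mm does not resolve the ", eff,
            " mm fiber spacing (need >= 2 px/fiber)")
  x0 <- fx[1] - camera$margin
  ncol <- ceiling((fx[length(fx)] + camera$margin - x0) / pitch) + 1L
  xc <- x0 + (seq_len(ncol) - 1L) * pitch
  colint <- numeric(ncol)
  hw <- ceiling(4 * camera$stripe_sigma / pitch)
  for (k in seq_along(fx)) {
    c0 <- round((fx[k] - x0) / pitch) + 1L
    idx <- max(1L, c0 - hw):min(ncol, c0 + hw)
    kern <- exp(-0.5 * ((xc[idx] - fx[k]) / camera$stripe_sigma)^2)
    colint[idx] <- colint[idx] + signals$signal[k] * kern / sum(kern)
  }
  pixels <- matrix(colint / camera$n_rows, nrow = camera$n_rows,
                   ncol = ncol, byrow = TRUE)
  new_detector_image(pixels, pitch, x0 = x0)
}

#' Camera noise model
#'
#' Gaussian read noise on every pixel plus sparse radiation-induced impulse
#' noise: transient spikes that hit isolated pixels while the camera sits in
#' the treatment vault.
#'
#' @param gaussian_sigma read-noise standard deviation, a.u.
#' @param impulse_rate per-pixel probability of an impulse.
#' @param impulse_amplitude amplitude added to an impulse-hit pixel, a.u.
#' @param seed integer seed; the noise draw is fully determined by it.
#' @return a `noise_model` list.
#' @export
noise_model <- function(gaussian_sigma = 0, impulse_rate = 0,
                        impulse_amplitude = 0, seed = 1L) {
  stopifnot(gaussian_sigma >= 0, impulse_rate >= 0, impulse_rate <= 1,
            impulse_amplitude >= 0)
  structure(list(gaussian_sigma = gaussian_sigma, impulse_rate = impulse_rate,
                 impulse_amplitude = impulse_amplitude,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Inject noise into a detector image
#'
#' Deterministic for a fixed seed; the global RNG state is restored on exit.
#' Pixel values are clamped at zero after the Gaussian component (a camera
#' cannot report negative intensity).
#'
#' @param image a `detector_image`.
#' @param model a [noise_model()].
#' @return a new `detector_image`.
#' @export
add_noise <- function(image, model) {
  stopifnot(inherits(image, "detector_image"), inherits(model, "noise_model"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(model$seed)
  px <- image$pixels
  if (model$gaussian_sigma > 0)
    px <- px + stats::rnorm(length(px), sd = model$gaussian_sigma)
  if (model$impulse_rate > 0) {
    hit <- stats::runif(length(px)) < model$impulse_rate
    px[hit] <- px[hit] + model$impulse_amplitude
  }
  out <- image
  out$pixels <- matrix(pmax(px, 0), nrow = nrow(image$pixels))
  out
}
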