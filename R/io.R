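# File formats: single-channel TIFF images with a JSON sidecar carrying the
# physical metadata (TIFF tags do not round-trip pixel pitch reliably across
# readers), CSV profiles and disk stacks, YAML configuration.

#' Write a detector image as TIFF + JSON sidecar
#'
#' Pixels are stored as 32-bit float TIFF normalised to `[0, 1]`; the
#' normalisation scale, pixel pitch, column-1 x position and orientation go
#' into the sidecar so that [read_detector_image()] restores the image
#' exactly.
#'
#' @param image a `detector_image`.
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path (default `path` + `.json`).
#' @return `path`, invisibly.
#' @export
write_detector_image <- function(image, path,
                                 sidecar = paste0(path, ".json")) {
  stopifnot(inherits(image, "detector_image"))
  scale <- max(image$pixels)
  px <- if (scale > 0) image$pixels / scale else image$pixels
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_pitch_mm = image$pixel_pitch, x0_mm = image$x0,
         orientation = image$orientation, intensity_scale = scale),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detector image from TIFF (+ sidecar)
#'
#' @param path single-channel TIFF or PNG path.
#' @param sidecar JSON sidecar path; looked for at `path` + `.json` when
#'   `NULL`.
#' @param pixel_pitch pixel pitch in mm/px, used when no sidecar exists.
#' @return a `detector_image`.
#' @export
read_detector_image <- function(path, sidecar = NULL, pixel_pitch = NULL) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L)
      stop("multi-channel image not supported; supply a single-channel ",
           "grayscale TIFF/PNG")
    px <- px[, , 1L]
  }
  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar) else NULL
  pitch <- if (!is.null(meta$pixel_pitch_mm)) meta$pixel_pitch_mm
           else pixel_pitch
  if (is.null(pitch))
    stop("pixel pitch unknown: provide a JSON sidecar with ",
         "`pixel_pitch_mm` or pass `pixel_pitch=`")
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  new_detector_image(px * scale, pitch,
                     x0 = if (!is.null(meta$x0_mm)) meta$x0_mm else 0,
                     orientation = if (!is.null(meta$orientation))
                       meta$orientation else "rows_y")
}

#' Profile CSV input/output
#'
#' Two-column CSV (`position_mm`, `value`) for projected profiles, folded
#' half-profiles and fiber-signal vectors.
#'
#' @param x a `projected_profile`, `half_profile` or `fiber_signals`.
#' @param path CSV path.
#' @return for the writer, `path` invisibly; for the reader, a
#'   `projected_profile` (spacing inferred from the positions, which must be
#'   uniform).
#' @export
write_profile_csv <- function(x, path) {
  df <- if (inherits(x, "half_profile"))
    data.frame(position_mm = x$x, value = x$S)
  else if (inherits(x, "fiber_signals"))
    data.frame(position_mm = x$fiber_x, value = x$signal)
  else data.frame(position_mm = x$x, value = x$p)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("position_mm", "value") %in% names(df)))
  d <- diff(df$position_mm)
  if (any(abs(d - d[1]) > 1e-9 * max(abs(d))))
    stop("profile positions in ", path, " are not uniformly spaced")
  new_projected_profile(df$position_mm, df$value, d[1])
}

#' Disk-stack CSV input/output
#'
#' @param stack a `disk_stack`.
#' @param path CSV path with columns `R_mm`, `beta`.
#' @return `path` invisibly (writer); a reduced `disk_stack` (reader).
#' @export
write_disk_stack_csv <- function(stack, path) {
  utils::write.csv(data.frame(R_mm = stack$R, beta = stack$beta), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_disk_stack_csv
#' @export
read_disk_stack_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("R_mm", "beta") %in% names(df)), all(df$beta >= 0))
  structure(list(beta = df$beta, R = df$R_mm, n_iter = NA_integer_,
                 residual_history = NULL),
            class = "disk_stack")
}
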