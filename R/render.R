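#' Plot specification for repetition images
#'
#' Fixed rendering conventions for the six-panel repetition images: panel
#' order and per-panel symmetric y-limits are pinned so that absolute
#' amplitude is preserved across images (values outside a panel's limits are
#' clipped to its border, never rescaled). Defaults follow the study
#' conventions: panels `gyro_x` (+-250 deg/s), `gyro_y`, `gyro_z`
#' (+-100 deg/s), `acc_x` (+-3 m/s^2), `acc_y`, `acc_z` (+-15 m/s^2), stacked
#' vertically with no axes, ticks or labels, saved as 470x470 JPEG files.
#'
#' @param image_side Image side in pixels (>= 64, default 470).
#' @param format `"jpeg"` (default, quality 0.95) or `"png"`.
#' @param line_rgb Line colour as length-3 RGB in `[0, 1]` (default blue).
#' @param line_px Line thickness in pixels (default 2).
#' @param background_rgb Background colour (default white).
#' @param ylim Named numeric vector of positive half-ranges per panel channel,
#'   in panel order.
#' @return Object of class `plot_spec`.
#' @export
plot_spec <- function(image_side = 470L, format = c("jpeg", "png"),
                      line_rgb = c(0, 0, 1), line_px = 2L,
                      background_rgb = c(1, 1, 1),
                      ylim = c(gyro_x = 250, gyro_y = 100, gyro_z = 100,
                               acc_x = 3, acc_y = 15, acc_z = 15)) {
  format <- match.arg(format)
  stopifnot(image_side >= 64, all(ylim > 0), length(line_rgb) == 3,
            length(background_rgb) == 3, line_px >= 1)
  structure(list(image_side = as.integer(image_side), format = format,
                 line_rgb = line_rgb, line_px = as.integer(line_px),
                 background_rgb = background_rgb, ylim = ylim),
            class = "plot_spec")
}

#' Render a repetition as a six-panel image
#'
#' Draws each panel channel as a connected polyline at its fixed y-limits into
#' an `image_side x image_side x 3` pixel array (values in `[0, 1]`), panels
#' stacked top to bottom in spec order with zero padding, no axes and no
#' labels. Rendering is a pure function of the epoch values and the spec:
#' identical inputs give bit-identical pixel arrays. Out-of-range values are
#' clipped to the panel border.
#'
#' @param rep An `imu_repetition` carrying the six panel channels (normally
#'   resampled to a fixed length first).
#' @param spec A [plot_spec()].
#' @return Object of class `repetition_image` with fields `pixels` (array),
#'   `label`, `subject_id`, `rep_index`.
#' @export
render_repetition <- function(rep, spec = plot_spec()) {
  stopifnot(inherits(rep, "imu_repetition"), inherits(spec, "plot_spec"))
  chans <- names(spec$ylim)
  missing <- setdiff(chans, names(rep$channels))
  if (length(missing))
    stop("repetition is missing panel channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  side <- spec$image_side
  pix <- array(rep(spec$background_rgb, each = side * side),
               dim = c(side, side, 3))
  bounds <- floor(seq_len(length(chans)) * side / length(chans))
  top <- c(0L, bounds[-length(bounds)]) + 1L
  for (i in seq_along(chans)) {
    v <- rep$channels[[chans[i]]]
    r <- spec$ylim[[i]]
    v <- pmin(pmax(v, -r), r)
    h <- bounds[i] - top[i] + 1L
    ## +limit -> top row of the panel, -limit -> bottom row
    rowpos <- top[i] + (r - v) / (2 * r) * (h - 1L)
    cols <- seq(1, side, length.out = length(v))
    yc <- round(stats::approx(cols, rowpos, xout = seq_len(side))$y)
    for (cc in seq_len(side)) {
      lo <- if (cc == 1L) yc[1L] else min(yc[cc - 1L], yc[cc])
      hi <- if (cc == 1L) yc[1L] else max(yc[cc - 1L], yc[cc])
      rows <- lo:min(hi + spec$line_px - 1L, bounds[i])
      pix[rows, cc, 1L] <- spec$line_rgb[1L]
      pix[rows, cc, 2L] <- spec$line_rgb[2L]
      pix[rows, cc, 3L] <- spec$line_rgb[3L]
    }
  }
  structure(list(pixels = pix, label = rep$exercise_label,
                 subject_id = rep$subject_id, rep_index = rep$rep_index),
            class = "repetition_image")
}

#' @export
print.repetition_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<repetition_image> %s/%s rep %s, %dx%d px\n",
              x$subject_id, x$label, x$rep_index, d[1L], d[2L]))
  invisible(x)
}

.image_filename <- function(img, format) {
  sprintf("%s_rep%03d.%s", img$subject_id, img$rep_index,
          switch(format, jpeg = "jpg", png = "png"))
}

#' Parse subject and repetition index from an image filename
#'
#' Inverse of the naming scheme used by [write_image_dataset()]
#' (`<subject>_rep<index>.<ext>`).
#'
#' @param filename Image file name (with or without directory).
#' @return List with `subject_id` and `rep_index`.
#' @export
parse_image_filename <- function(filename) {
  b <- basename(filename)
  m <- regmatches(b, regexec("^(.+)_rep([0-9]+)\\.(jpg|jpeg|png)$", b))[[1L]]
  if (!length(m)) stop("unparseable image filename: ", b, call. = FALSE)
  list(subject_id = m[2L], rep_index = as.integer(m[3L]))
}

#' Write a labeled image dataset (folder per class)
#'
#' Writes every rendered repetition under `out_dir/<label>/`, the layout an
#' image-retraining workflow expects: one folder per class, holding that
#' class's training images. Filenames encode subject and repetition index.
#'
#' @param images List of `repetition_image` objects (or of `imu_repetition`
#'   objects, which are rendered with `spec` first).
#' @param out_dir Output directory root.
#' @param spec A [plot_spec()]; also decides the file format.
#' @return Invisibly, a `data.frame` of `label`, `subject_id`, `rep_index`,
#'   `path`.
#' @export
write_image_dataset <- function(images, out_dir, spec = plot_spec()) {
  if (!length(images)) stop("no images to write", call. = FALSE)
  images <- lapply(images, function(x)
    if (inherits(x, "imu_repetition")) render_repetition(x, spec) else x)
  stopifnot(all(vapply(images, inherits, logical(1), "repetition_image")))
  rows <- lapply(images, function(img) {
    d <- file.path(out_dir, img$label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(d, .image_filename(img, spec$format))
    if (spec$format == "png") png::writePNG(img$pixels, path)
    else jpeg::writeJPEG(img$pixels, path, quality = 0.95)
    data.frame(label = img$label, subject_id = img$subject_id,
               rep_index = img$rep_index, path = path, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}

#' Read an image file as a pixel array
#'
#' @param path PNG or JPEG file.
#' @return `height x width x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
        else jpeg::readJPEG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}
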