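#' Gray-scale frame sequences
#'
#' A `frame_sequence` is the package's container for an ordered gray-scale
#' image sequence: a numeric `rows x cols x T` array with luminance values in
#' `[0, value_scale]` (8-bit scale, 0-255, by default). All model and noise
#' functions consume and return this class.
#'
#' @param x A numeric 3-D array (`rows x cols x frames`), or a list of equally
#'   sized numeric matrices.
#' @param value_scale Nominal maximum luminance (default 255).
#' @return An object of class `"frame_sequence"`.
#' @examples
#' fs <- frame_sequence(array(128, dim = c(4, 4, 3)))
#' dim(fs)
#' @export
frame_sequence <- function(x, value_scale = 255) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (is.null(d) || !all(vapply(x, function(m) identical(dim(m), d), TRUE)))
      stop("all frames must be matrices with identical dimensions")
    x <- array(unlist(x, use.names = FALSE), dim = c(d, length(x)))
  }
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'x' must be a rows x cols x frames array or a list of matrices")
  if (dim(x)[3] < 2L)
    stop("a frame sequence needs at least 2 frames")
  storage.mode(x) <- "double"
  if (anyNA(x) || min(x) < 0 || max(x) > value_scale)
    stop("luminance values must lie in [0, value_scale]")
  structure(x, value_scale = value_scale, class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Gray-scale frame sequence: %d x %d pixels, %d frames (scale 0-%g)\n",
              d[1], d[2], d[3], attr(x, "value_scale")))
  cat(sprintf("  luminance range observed: [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' Extract one frame as a matrix
#'
#' @param x A `frame_sequence`.
#' @param t Frame index.
#' @return A numeric matrix.
#' @export
get_frame <- function(x, t) {
  stopifnot(inherits(x, "frame_sequence"), t >= 1, t <= dim(x)[3])
  x[, , t, drop = TRUE]
}

#' Number of frames in a sequence
#' @param x A `frame_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x)[3]

#' @export
plot.frame_sequence <- function(x, t = dim(x)[3], ...) {
  m <- get_frame(x, t) / attr(x, "value_scale")
  graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(m) / ncol(m),
                  main = sprintf("frame %d", t), ...)
  invisible(x)
}

#' Convert a colour (or gray) pixel array to 8-bit gray-scale
#'
#' Colour input is reduced with the Rec. 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); values on the [0, 1] scale (as returned by
#' PNG readers) are rescaled to 0-255.
#'
#' @param img A matrix (already gray) or a `rows x cols x 3`/`x 4` array.
#' @return A numeric matrix on the 0-255 scale.
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  if (max(img) <= 1) img <- img * 255
  pmin(pmax(img, 0), 255)
}

#' Load an image directory as a frame sequence
#'
#' Reads every PNG (and, when the tiff package is available, TIFF) file in a
#' directory, in natural sort order, converts each to 8-bit gray-scale and
#' stacks them into a [frame_sequence()].
#'
#' @param path Directory containing the frames.
#' @param pattern Regular expression selecting frame files.
#' @return A `frame_sequence`.
#' @export
load_frames <- function(path, pattern = "\\.(png|tif|tiff)$") {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) < 2L) stop("need at least 2 frame files in ", path)
  # natural sort: order by the last embedded integer, then by name
  num <- lapply(regmatches(basename(files), gregexpr("\\d+", basename(files))),
                as.numeric)
  ord <- order(vapply(num, function(v) if (length(v)) v[length(v)] else NA_real_, 0),
               basename(files), na.last = TRUE)
  files <- files[ord]
  read1 <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      to_grayscale(png::readPNG(f))
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is needed to read TIFF frames")
      to_grayscale(tiff::readTIFF(f))
    }
  }
  frames <- lapply(files, read1)
  frame_sequence(frames)
}

#' Write a frame sequence as numbered PNG files
#'
#' The inverse of [load_frames()]: writes each frame as an 8-bit gray PNG
#' (`frame_0001.png`, ...) so generated or corrupted datasets can be
#' inspected and reloaded losslessly after rounding to integer levels.
#'
#' @param x A `frame_sequence`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(x, dir) {
  stopifnot(inherits(x, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vs <- attr(x, "value_scale")
  paths <- character(n_frames(x))
  for (t in seq_len(n_frames(x))) {
    paths[t] <- file.path(dir, sprintf("frame_%04d.png", t))
    png::writePNG(round(get_frame(x, t)) / vs, paths[t])
  }
  invisible(paths)
}
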