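#' Synthetic looming stimulus: a disc expanding toward collision
#'
#' Generates a gray-scale sequence of a centred disc growing until it fills
#' the visual field at the collision frame, emulating a recorded approach of
#' a dark (or light) ball toward the camera. Under the perspective growth law
#' the retinal radius grows as \eqn{1/(t_c - t)}, the image of an object
#' approaching at constant speed; a linear law is also available. The
#' rendering uses exactly two luminance levels, so the only temporal signal
#' is the moving disc edge.
#'
#' @param rows,cols Frame dimensions in pixels.
#' @param frames Total number of frames T.
#' @param collision_frame Frame `tc` at which the disc covers the whole
#'   field (it stays full from `tc` to T). Must satisfy `2 <= tc <= T`.
#' @param polarity `"dark"` (dark disc on light background) or `"light"`.
#' @param object_level,background_level Luminance of disc and background on
#'   the 0-255 scale; for `polarity = "light"` the two are swapped.
#' @param r0 Initial disc radius as a fraction of `min(rows, cols) / 2`.
#' @param growth `"perspective"` (radius proportional to `1 / (tc - t)`,
#'   constant-velocity approach) or `"linear"`.
#' @param texture_sd If positive, a static Gaussian texture with this
#'   standard deviation is superimposed on the background (fixed across
#'   frames, so it only enters the model where the disc edge sweeps it).
#' @param texture_seed Seed fixing the texture pattern.
#' @return A [frame_sequence()].
#' @examples
#' fs <- looming_sequence(rows = 50, cols = 50, frames = 40, collision_frame = 36)
#' fs
#' @export
looming_sequence <- function(rows = 100, cols = 100, frames = 60,
                             collision_frame = 55,
                             polarity = c("dark", "light"),
                             object_level = 30, background_level = 200,
                             r0 = 0.05,
                             growth = c("perspective", "linear"),
                             texture_sd = 0, texture_seed = 1L) {
  polarity <- match.arg(polarity)
  growth <- match.arg(growth)
  if (rows < 3 || cols < 3) stop("degenerate frame dimensions")
  if (collision_frame < 2 || collision_frame > frames)
    stop("'collision_frame' must lie in [2, frames]")
  if (r0 <= 0 || r0 > 1) stop("'r0' must lie in (0, 1]")

  fg <- if (polarity == "dark") object_level else background_level
  bg <- if (polarity == "dark") background_level else object_level

  r0px <- r0 * min(rows, cols) / 2
  rmax <- sqrt((rows / 2)^2 + (cols / 2)^2) + 1  # full coverage
  # Perspective law: retinal radius a / (t* - t), the image of an object
  # approaching at constant speed with collision epoch t* just past the
  # collision frame. a and t* are solved so the disc starts at r0px and
  # reaches full coverage exactly at the collision frame:
  # r(1) = r0px, r(tc) = rmax.
  tc <- collision_frame
  b <- r0px * (tc - 1) / (rmax - r0px)
  if (!is.finite(b) || b <= 0) b <- 0  # degenerate r0; pure 1/(tc - t)
  a <- rmax * b
  radius <- function(t) {
    if (t >= tc) return(rmax)
    r <- switch(growth,
      perspective = a / (tc + b - t),
      linear = r0px + (rmax - r0px) * (t - 1) / (tc - 1))
    min(r, rmax)
  }

  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  dist2 <- outer((seq_len(rows) - cy)^2, (seq_len(cols) - cx)^2, `+`)

  base_bg <- matrix(bg, rows, cols)
  if (texture_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    set.seed(texture_seed)
    base_bg <- base_bg + matrix(stats::rnorm(rows * cols, sd = texture_sd),
                                rows, cols)
    base_bg <- pmin(pmax(base_bg, 0), 255)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  arr <- array(0, c(rows, cols, frames))
  for (t in seq_len(frames)) {
    f <- base_bg
    f[dist2 <= radius(t)^2] <- fg
    arr[, , t] <- f
  }
  frame_sequence(arr)
}

restore_rng <- function(seed) {
  # returns an exit handler restoring the caller's RNG state
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() assign(".Random.seed", old, envir = globalenv())
}

#' Corrupt a sequence with salt-and-pepper (impulse) noise
#'
#' Independently in every frame, each pixel is corrupted with probability
#' `pnr` (the pepper-noise ratio: the expected fraction of corrupted pixels
#' per frame); a corrupted pixel is set to 0 or to the full luminance scale
#' with equal probability. Other pixels are untouched; dimensions and frame
#' count never change.
#'
#' @param frames A [frame_sequence()].
#' @param pnr Fraction of pixels corrupted per frame, in \[0, 1\].
#' @param seed Optional seed (RNG state restored on exit).
#' @return The corrupted `frame_sequence`.
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 20, collision_frame = 18)
#' noisy <- add_salt_pepper(fs, pnr = 0.01, seed = 7)
#' @export
add_salt_pepper <- function(frames, pnr, seed = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (!is.numeric(pnr) || pnr < 0 || pnr > 1)
    stop("'pnr' must lie in [0, 1]")
  restore <- restore_rng(seed)
  if (is.function(restore)) on.exit(restore())
  vs <- attr(frames, "value_scale")
  n <- length(frames)
  hit <- stats::runif(n) < pnr
  val <- ifelse(stats::runif(n) < 0.5, 0, vs)
  out <- unclass(frames)
  out[hit] <- val[hit]
  frame_sequence(out, value_scale = vs)
}

#' Corrupt a sequence with additive Gaussian noise
#'
#' Adds independent zero-mean Gaussian noise to every pixel of every frame.
#' The variance `gnv` is specified on the normalised \[0, 1\] intensity scale
#' (the convention of image-processing toolboxes), so draws are scaled by the
#' luminance scale before addition; the result is clipped to
#' `[0, value_scale]`.
#'
#' @param frames A [frame_sequence()].
#' @param gnv Noise variance on the \[0, 1\] scale (non-negative).
#' @param seed Optional seed (RNG state restored on exit).
#' @return The corrupted `frame_sequence`.
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 20, collision_frame = 18)
#' noisy <- add_gaussian_noise(fs, gnv = 0.007, seed = 7)
#' @export
add_gaussian_noise <- function(frames, gnv, seed = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (!is.numeric(gnv) || gnv < 0) stop("'gnv' must be non-negative")
  restore <- restore_rng(seed)
  if (is.function(restore)) on.exit(restore())
  vs <- attr(frames, "value_scale")
  out <- unclass(frames) + stats::rnorm(length(frames), sd = sqrt(gnv)) * vs
  frame_sequence(pmin(pmax(out, 0), vs), value_scale = vs)
}
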