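#' Engineering pre-filters for noisy input sequences
#'
#' Per-frame 2-D median or Gaussian smoothing, the standard engineering
#' answer to impulse and additive noise respectively. Frames are padded by
#' edge replication before filtering so dimensions and borders are
#' preserved; values stay on the original luminance scale.
#'
#' @param frames A [frame_sequence()].
#' @param kind `"median"` or `"gaussian"`.
#' @param window Odd window size (>= 3) for the median filter.
#' @param sigma Standard deviation (pixels) of the Gaussian kernel.
#' @param kernel_size Odd side length of the Gaussian kernel.
#' @return The filtered `frame_sequence`.
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 20, collision_frame = 18)
#' smooth <- prefilter(add_salt_pepper(fs, 0.01, seed = 1), "median")
#' @export
prefilter <- function(frames, kind = c("median", "gaussian"),
                      window = 3L, sigma = 1.0, kernel_size = 5L) {
  stopifnot(inherits(frames, "frame_sequence"))
  kind <- match.arg(kind)
  vs <- attr(frames, "value_scale")
  d <- dim(frames)
  if (kind == "median") {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
      stop("'window' must be an odd integer >= 3")
    half <- window %/% 2L
  } else {
    if (sigma <= 0) stop("'sigma' must be positive")
    kernel_size <- as.integer(kernel_size)
    if (kernel_size < 3L || kernel_size %% 2L == 0L)
      stop("'kernel_size' must be an odd integer >= 3")
    half <- kernel_size %/% 2L
    brush <- EBImage::makeBrush(kernel_size, shape = "Gaussian", sigma = sigma)
  }
  ridx <- c(rep(1L, half), seq_len(d[1]), rep(d[1], half))
  cidx <- c(rep(1L, half), seq_len(d[2]), rep(d[2], half))
  keep_r <- (half + 1L):(half + d[1]); keep_c <- (half + 1L):(half + d[2])
  out <- array(0, d)
  for (t in seq_len(d[3])) {
    padded <- frames[ridx, cidx, t] / vs
    f <- if (kind == "median") {
      EBImage::medianFilter(padded, half)
    } else {
      EBImage::filter2(padded, brush, boundary = "replicate")
    }
    out[, , t] <- pmin(pmax(f[keep_r, keep_c] * vs, 0), vs)
  }
  frame_sequence(out, value_scale = vs)
}

#' Pre-filter comparative baselines
#'
#' The two engineering reference methods the probabilistic model is compared
#' against: pre-filter the input sequence, then run the deterministic classic
#' LGMD on it. By convention the median filter is paired with impulse
#' (salt-and-pepper) noise and the Gaussian filter with Gaussian noise, but
#' either can be applied to any input.
#'
#' @param frames A [frame_sequence()] (typically noisy).
#' @param noise_kind `"salt_pepper"` (median pre-filter) or `"gaussian"`
#'   (Gaussian pre-filter).
#' @param params An [lgmd_params()] object for the deterministic run.
#' @param ... Passed to [prefilter()] (window, sigma, kernel_size).
#' @return An `"lgmd"` trace of the deterministic model on the filtered
#'   input; the filter specification is attached as attribute `"prefilter"`.
#' @export
comparative_method <- function(frames, noise_kind = c("salt_pepper", "gaussian"),
                               params = lgmd_params(prob = 1), ...) {
  noise_kind <- match.arg(noise_kind)
  kind <- if (noise_kind == "salt_pepper") "median" else "gaussian"
  fit <- deterministic_lgmd(prefilter(frames, kind, ...), params)
  attr(fit, "prefilter") <- kind
  fit
}
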