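#' Distinct ratio: peak-versus-background separation of a response trace
#'
#' The distinct ratio of a membrane-potential output trace is
#' \deqn{DR = \kappa_{max} - \frac{\sum_i \kappa(i) - \kappa_{max}}{T - 1},}
#' the peak output minus the mean of all non-peak outputs. A detector that
#' responds sharply at the collision moment and stays quiet otherwise has a
#' high DR; a constant trace has DR = 0. When the maximum is attained at
#' several frames the first occurrence is reported as the peak and one copy
#' of the maximum is excluded from the background mean.
#'
#' @param trace A numeric vector of \eqn{\kappa} values, or an `"lgmd"`
#'   object.
#' @return An object of class `"dr_result"`: list with `dr`, `kappa_max`,
#'   `peak_frame` and `n_frames`.
#' @examples
#' distinct_ratio(c(0.5, 0.5, 1.0))  # DR = 0.5
#' @export
distinct_ratio <- function(trace) {
  if (inherits(trace, "lgmd")) trace <- trace$kappa
  trace <- as.numeric(trace)
  T <- length(trace)
  if (T < 2L) stop("need a trace of at least 2 frames")
  kmax <- max(trace)
  structure(
    list(dr = kmax - (sum(trace) - kmax) / (T - 1),
         kappa_max = kmax,
         peak_frame = which.max(trace),
         n_frames = T),
    class = "dr_result")
}

#' @export
print.dr_result <- function(x, ...) {
  cat(sprintf("DR = %.4f (peak kappa %.4f at frame %d of %d)\n",
              x$dr, x$kappa_max, x$peak_frame, x$n_frames))
  invisible(x)
}

#' Signed offset between response peak and collision frame
#'
#' A collision-perceiving run should peak at (or just before) the true
#' collision moment; large offsets indicate premature or missed responses.
#'
#' @param trace A numeric \eqn{\kappa} trace or `"lgmd"` object.
#' @param collision_frame Ground-truth collision frame.
#' @return Integer `which.max(trace) - collision_frame`.
#' @export
peak_alignment <- function(trace, collision_frame) {
  if (inherits(trace, "lgmd")) trace <- trace$kappa
  if (collision_frame < 1 || collision_frame > length(trace))
    stop("'collision_frame' outside the trace")
  which.max(trace) - as.integer(collision_frame)
}

#' Replicate trials of the probabilistic model on one input
#'
#' Runs the gated network `n` times on the same input with independent
#' derived seeds and aggregates the traces: per-frame mean and sample
#' variance, per-trial distinct ratios, and their mean and sample standard
#' deviation. This is the repeated-presentation protocol used to report the
#' stochastic model's behaviour (default 20 replicates).
#'
#' @param frames A [frame_sequence()].
#' @param params An [lgmd_params()] object.
#' @param n Number of replicate trials.
#' @param seed Master seed; each trial receives an independent substream
#'   seed derived from it. Same master seed, same ensemble.
#' @param layer_noise Optional intermediate-layer noise, passed to [lgmd()].
#' @param deterministic If `TRUE`, runs the classic baseline in every trial
#'   (traces then coincide unless `layer_noise` is stochastic).
#' @return An object of class `"lgmd_ensemble"`: list with `traces`
#'   (T x n matrix of kappa), `mean`, `var` (per-frame), `dr` (per-trial),
#'   `dr_mean`, `dr_sd`, `n`, `params`, `seed`.
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 30, collision_frame = 27)
#' ens <- run_trials(fs, lgmd_params(prob = 0.5), n = 5, seed = 1)
#' ens
#' @export
run_trials <- function(frames, params = lgmd_params(), n = 20, seed = NULL,
                       layer_noise = NULL, deterministic = FALSE) {
  stopifnot(n >= 1)
  restore <- restore_rng(seed)
  if (is.function(restore)) on.exit(restore())
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
  T <- n_frames(frames)
  traces <- matrix(0, T, n)
  for (k in seq_len(n)) {
    traces[, k] <- lgmd(frames, params, deterministic = deterministic,
                        seed = trial_seeds[k],
                        layer_noise = layer_noise)$kappa
  }
  drs <- apply(traces, 2, function(tr) distinct_ratio(tr)$dr)
  structure(
    list(traces = traces,
         mean = rowMeans(traces),
         # single-trial ensembles have no spread by definition
         var = if (n > 1) apply(traces, 1, stats::var) else rep(0, T),
         dr = drs,
         dr_mean = mean(drs),
         dr_sd = if (n > 1) stats::sd(drs) else 0,
         n = n, params = params, seed = seed,
         trial_seeds = trial_seeds),
    class = "lgmd_ensemble")
}

#' @export
print.lgmd_ensemble <- function(x, ...) {
  cat(sprintf("LGMD replicate ensemble: %d trials, %d frames, prob = %g\n",
              x$n, nrow(x$traces), x$params$prob))
  cat(sprintf("  DR = %.4f +/- %.4f (mean +/- sd over trials)\n",
              x$dr_mean, if (x$n > 1) x$dr_sd else 0))
  invisible(x)
}

#' @export
plot.lgmd_ensemble <- function(x, ..., collision_frame = NULL) {
  T <- nrow(x$traces)
  sd_band <- sqrt(x$var)
  graphics::plot(seq_len(T), x$mean, type = "n",
                 ylim = range(c(x$mean - sd_band, x$mean + sd_band, 0.5, 1)),
                 xlab = "frame", ylab = expression(kappa[t]), ...)
  graphics::polygon(c(seq_len(T), rev(seq_len(T))),
                    c(x$mean - sd_band, rev(x$mean + sd_band)),
                    col = "grey85", border = NA)
  graphics::lines(seq_len(T), x$mean, lwd = 2, col = "steelblue")
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  if (!is.null(collision_frame))
    graphics::abline(v = collision_frame, lty = 2, col = "red")
  invisible(x)
}

#' Sweep the transmission probability and measure the distinct ratio
#'
#' Runs a replicate ensemble at each probability on the grid, on the same
#' input, and tabulates the distinct-ratio mean and standard deviation. On
#' noisy inputs the DR-versus-prob curve is typically unimodal with an
#' interior maximum (around 0.5), reflecting the trade-off between noise
#' rejection (low prob drops noise impulses) and signal transmission (high
#' prob preserves the looming edge).
#'
#' @param frames A [frame_sequence()].
#' @param params An [lgmd_params()] object; its `prob` is overridden by each
#'   grid value in turn.
#' @param probs Probability grid, values in (0, 1].
#' @param n Replicate trials per grid value.
#' @param seed Master seed; each grid value receives an independent derived
#'   ensemble seed.
#' @param layer_noise Optional intermediate-layer noise, passed through.
#' @return An object of classes `"lgmd_sweep"` and `"data.frame"` with
#'   columns `prob`, `dr_mean`, `dr_sd`, `n`; the per-prob ensembles are
#'   attached as attribute `"ensembles"`.
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 30, collision_frame = 27)
#' sw <- prob_sweep(fs, probs = c(0.5, 1), n = 3, seed = 1)
#' sw
#' @export
prob_sweep <- function(frames, params = lgmd_params(),
                       probs = seq(0.1, 1, by = 0.1), n = 20, seed = NULL,
                       layer_noise = NULL) {
  if (any(probs <= 0 | probs > 1)) stop("grid values must lie in (0, 1]")
  probs <- sort(probs)
  restore <- restore_rng(seed)
  if (is.function(restore)) on.exit(restore())
  ens_seeds <- sample.int(.Machine$integer.max - 1L, length(probs))
  ensembles <- vector("list", length(probs))
  for (i in seq_along(probs)) {
    p <- params; p$prob <- probs[i]
    ensembles[[i]] <- run_trials(frames, p, n = n, seed = ens_seeds[i],
                                 layer_noise = layer_noise)
  }
  out <- data.frame(
    prob = probs,
    dr_mean = vapply(ensembles, `[[`, 0, "dr_mean"),
    dr_sd = vapply(ensembles, function(e) if (e$n > 1) e$dr_sd else 0, 0),
    n = n)
  attr(out, "ensembles") <- ensembles
  class(out) <- c("lgmd_sweep", "data.frame")
  out
}

#' @export
print.lgmd_sweep <- function(x, ...) {
  cat("Distinct ratio vs transmission probability\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  best <- x$prob[which.max(x$dr_mean)]
  cat(sprintf("  best prob on grid: %g (DR = %.4f)\n", best, max(x$dr_mean)))
  invisible(x)
}

#' @export
plot.lgmd_sweep <- function(x, ...) {
  graphics::plot(x$prob, x$dr_mean, type = "b", pch = 19,
                 ylim = range(c(x$dr_mean - x$dr_sd, x$dr_mean + x$dr_sd)),
                 xlab = "transmission probability", ylab = "distinct ratio",
                 ...)
  graphics::arrows(x$prob, x$dr_mean - x$dr_sd, x$prob, x$dr_mean + x$dr_sd,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  invisible(x)
}
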