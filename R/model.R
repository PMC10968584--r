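#' Run the probabilistic LGMD network on an image sequence
#'
#' Applies the four-layered looming-detector network frame by frame:
#' photoreceptor luminance change with persistence, Bernoulli-gated
#' excitation, one-frame-delayed kernel-spread gated inhibition, gated
#' excitation/inhibition summation, passing-coefficient modulation with
#' thresholding, and gated integration into the output cell's membrane
#' potential \eqn{K_t}, reported through a sigmoid as \eqn{\kappa_t}.
#'
#' Five gate families (P-to-E, P-to-I per kernel tap, E-to-S, I-to-S,
#' S-to-output) are resampled independently at every frame and every pixel
#' from Bernoulli(`prob`). With `prob = 1` all gates are surely 1 and the
#' output equals the deterministic classic model exactly. The first frame has
#' no predecessor, so its photoreceptor field is zero and
#' \eqn{\kappa_1 = 0.5}; no gates are consumed there.
#'
#' Reproducibility: for a given `seed`, gate fields are consumed in a fixed
#' order per frame (P-to-E; the nine P-to-I taps in column order of the
#' kernel; E-to-S; I-to-S; S-to-output). Any `layer_noise` draws are
#' pre-generated from the stream before gate sampling starts, so a
#' deterministic and a gated run sharing one seed receive identical injected
#' noise.
#'
#' @param frames A [frame_sequence()] (or 3-D array coercible to one).
#' @param params An [lgmd_params()] object; `params$prob` sets the gate
#'   probability.
#' @param deterministic If `TRUE`, all gates are fixed to 1 and no gate
#'   randomness is consumed: the classic LGMD baseline.
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @param capture_layers If `TRUE`, per-frame intermediate fields
#'   (P, E, I, S, Ce, omega, S_tilde) are kept in the result for inspection.
#' @param layer_noise Optional noise injected into an intermediate layer:
#'   a list with `layer` (`"P"`, `"E"`, `"I"` or `"S"`), `kind`
#'   (`"salt_pepper"` or `"gaussian"`), and `ratio` (fraction of entries
#'   replaced) or `variance` (relative to the field's maximum magnitude).
#'   Noise injected at P feeds everything downstream, including the
#'   persistence history and the delayed inhibition.
#'
#' @return An object of class `"lgmd"`: a list with `kappa` and `K` (length-T
#'   numeric traces), `params`, `deterministic`, `seed`, `n_frames`, `dims`,
#'   the input `frames`, and (optionally) `layers`.
#'
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 30, collision_frame = 27)
#' fit <- lgmd(fs, lgmd_params(prob = 0.5), seed = 1)
#' fit
#' @seealso [deterministic_lgmd()], [run_trials()], [distinct_ratio()]
#' @export
lgmd <- function(frames, params = lgmd_params(), deterministic = FALSE,
                 seed = NULL, capture_layers = FALSE, layer_noise = NULL) {
  if (!inherits(frames, "frame_sequence")) frames <- frame_sequence(frames)
  stopifnot(inherits(params, "lgmd_params"))
  d <- dim(frames)
  R <- d[1]; C <- d[2]; T <- d[3]
  if (T < 2L) stop("need at least 2 frames")
  ncell <- R * C

  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }

  noise <- check_layer_noise(layer_noise)
  noise_plan <- if (!is.null(noise)) pregen_noise(noise, R, C, T) else NULL

  coeffs <- persistence_coefficients(params$u, params$np)
  kappa <- numeric(T); K <- numeric(T)
  kappa[1] <- 0.5
  layers <- if (capture_layers)
    list(P = vector("list", T), E = vector("list", T), I = vector("list", T),
         S = vector("list", T), Ce = vector("list", T), omega = numeric(T),
         S_tilde = vector("list", T))

  zero <- matrix(0, R, C)
  P_prev <- zero
  P_hist <- list()

  for (t in 2:T) {
    P <- photoreceptor_update(frames[, , t], frames[, , t - 1L],
                              P_hist, coeffs)
    if (!is.null(noise) && noise$layer == "P")
      P <- apply_noise_plan(P, noise, noise_plan, t)

    if (deterministic) {
      gPE <- gPI <- gES <- gIS <- gSL <- NULL
    } else {
      gPE <- sample_gate_field(R, C, params$prob)
      gPI <- sample_gate_field(R, C, params$prob, taps = 9L)
      gES <- sample_gate_field(R, C, params$prob)
      gIS <- sample_gate_field(R, C, params$prob)
      gSL <- sample_gate_field(R, C, params$prob)
    }

    E <- excitation_layer(P, gPE)
    if (!is.null(noise) && noise$layer == "E")
      E <- apply_noise_plan(E, noise, noise_plan, t)
    I <- inhibition_layer(P_prev, gPI, params$inhibition_kernel)
    if (!is.null(noise) && noise$layer == "I")
      I <- apply_noise_plan(I, noise, noise_plan, t)
    S <- summation_layer(E, I, params$WI, gES, gIS)
    if (!is.null(noise) && noise$layer == "S")
      S <- apply_noise_plan(S, noise, noise_plan, t)

    Ce <- passing_coefficient(S)
    omega <- scale_factor(Ce, params$Cw)
    St <- grouping_threshold(S, Ce, omega, params$Ts)
    K[t] <- membrane_potential(St, gSL)
    kappa[t] <- neuron_output(K[t], ncell)

    if (capture_layers) {
      layers$P[[t]] <- P; layers$E[[t]] <- E; layers$I[[t]] <- I
      layers$S[[t]] <- S; layers$Ce[[t]] <- Ce; layers$omega[t] <- omega
      layers$S_tilde[[t]] <- St
    }

    P_prev <- P
    if (params$np > 0L) P_hist <- c(list(P), P_hist)[seq_len(min(
      length(P_hist) + 1L, params$np))]
  }

  structure(
    list(kappa = kappa, K = K, params = params,
         deterministic = deterministic, seed = seed,
         layer_noise = layer_noise, n_frames = T, dims = c(R, C),
         frames = frames, layers = layers),
    class = "lgmd")
}

#' Deterministic classic-LGMD baseline
#'
#' The `prob = 1` limit of the gated network: every synaptic gate is fixed to
#' 1, no randomness is consumed, and the same input always yields bitwise the
#' same trace. This is the classic four-layered LGMD model that the
#' probabilistic variant generalises, and the oracle that a `prob = 1` gated
#' run must match exactly.
#'
#' @inheritParams lgmd
#' @return An object of class `"lgmd"` (with `deterministic = TRUE`).
#' @examples
#' fs <- looming_sequence(rows = 40, cols = 40, frames = 30, collision_frame = 27)
#' det <- deterministic_lgmd(fs)
#' which.max(det$kappa)
#' @export
deterministic_lgmd <- function(frames, params = lgmd_params(prob = 1),
                               capture_layers = FALSE, layer_noise = NULL,
                               seed = NULL) {
  lgmd(frames, params, deterministic = TRUE, seed = seed,
       capture_layers = capture_layers, layer_noise = layer_noise)
}

check_layer_noise <- function(x) {
  if (is.null(x)) return(NULL)
  stopifnot(is.list(x), !is.null(x$layer), !is.null(x$kind))
  x$layer <- match.arg(x$layer, c("P", "E", "I", "S"))
  x$kind <- match.arg(x$kind, c("salt_pepper", "gaussian"))
  if (x$kind == "salt_pepper") {
    if (is.null(x$ratio) || x$ratio < 0 || x$ratio > 1)
      stop("salt_pepper layer noise needs 'ratio' in [0, 1]")
  } else {
    if (is.null(x$variance) || x$variance < 0)
      stop("gaussian layer noise needs non-negative 'variance'")
  }
  x
}

# Draw all layer-noise randomness up front (frames 2..T) so that gated and
# deterministic runs sharing a seed see identical injected noise.
pregen_noise <- function(noise, R, C, T) {
  n <- R * C * (T - 1L)
  if (noise$kind == "salt_pepper") {
    list(u_hit = array(stats::runif(n), c(R, C, T - 1L)),
         u_val = array(stats::runif(n), c(R, C, T - 1L)))
  } else {
    list(z = array(stats::rnorm(n), c(R, C, T - 1L)))
  }
}

apply_noise_plan <- function(field, noise, plan, t) {
  m <- max(abs(field))
  if (noise$kind == "salt_pepper") {
    hit <- plan$u_hit[, , t - 1L] < noise$ratio
    v <- plan$u_val[, , t - 1L]
    repl <- ifelse(v < 0.5, 0, ifelse(v < 0.75, m, -m))
    field[hit] <- repl[hit]
    field
  } else {
    field + plan$z[, , t - 1L] * sqrt(noise$variance) * m
  }
}

#' Inject noise into an intermediate layer field
#'
#' Corrupts a single intermediate field (P, E, I or S output) with either
#' impulse ("salt-and-pepper") or additive Gaussian noise, emulating noise
#' arising inside neural signal transmission rather than in the stimulus.
#' Intermediate fields are signed and unbounded, so amplitudes are taken
#' relative to the field's maximum magnitude and no clipping is applied:
#' impulse noise replaces a fraction `ratio` of entries with 0 (half the
#' time) or with the field's maximum magnitude carrying a random sign;
#' Gaussian noise adds draws with standard deviation
#' `sqrt(variance) * max(abs(field))`.
#'
#' @param field A numeric matrix (an intermediate layer output).
#' @param kind `"salt_pepper"` or `"gaussian"`.
#' @param ratio Fraction of entries replaced (salt-and-pepper).
#' @param variance Relative variance of the additive draws (Gaussian).
#' @return The corrupted field (same dimensions).
#' @export
inject_layer_noise <- function(field, kind = c("salt_pepper", "gaussian"),
                               ratio = 0, variance = 0) {
  kind <- match.arg(kind)
  noise <- check_layer_noise(list(layer = "P", kind = kind, ratio = ratio,
                                  variance = variance))
  R <- nrow(field); C <- ncol(field)
  plan <- pregen_noise(noise, R, C, 2L)
  apply_noise_plan(field, noise, plan, 2L)
}

#' @export
print.lgmd <- function(x, ...) {
  dr <- distinct_ratio(x$kappa)
  cat(sprintf("%s LGMD response trace\n",
              if (x$deterministic) "Deterministic" else
                sprintf("Probabilistic (prob = %g)", x$params$prob)))
  cat(sprintf("  input: %d x %d pixels, %d frames\n",
              x$dims[1], x$dims[2], x$n_frames))
  cat(sprintf("  peak output kappa = %.4f at frame %d; distinct ratio = %.4f\n",
              dr$kappa_max, dr$peak_frame, dr$dr))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
summary.lgmd <- function(object, ...) {
  dr <- distinct_ratio(object$kappa)
  structure(list(trace = object, dr = dr), class = "summary.lgmd")
}

#' @export
print.summary.lgmd <- function(x, ...) {
  print(x$trace)
  k <- x$trace$kappa
  cat(sprintf("  kappa: min %.4f, median %.4f, max %.4f\n",
              min(k), stats::median(k), max(k)))
  cat(sprintf("  background mean (non-peak frames): %.4f\n",
              (sum(k) - x$dr$kappa_max) / (length(k) - 1)))
  invisible(x)
}

#' @export
as.data.frame.lgmd <- function(x, ...) {
  data.frame(frame = seq_len(x$n_frames), K = x$K, kappa = x$kappa)
}

#' @export
plot.lgmd <- function(x, ..., collision_frame = NULL) {
  graphics::plot(seq_len(x$n_frames), x$kappa, type = "l", lwd = 2,
                 xlab = "frame", ylab = expression(kappa[t]),
                 ylim = c(0.45, 1), ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  if (!is.null(collision_frame))
    graphics::abline(v = collision_frame, lty = 2, col = "red")
  invisible(x)
}

#' Simulate replicate response traces from a fitted LGMD run
#'
#' Re-runs the gated network on the stored input with `nsim` independent
#' seeds, mirroring repeated presentations of the same stimulus to a
#' stochastic neuron.
#'
#' @param object An `"lgmd"` object.
#' @param nsim Number of replicate traces.
#' @param seed Master seed for the replicate seeds.
#' @param ... Unused.
#' @return An `"lgmd_ensemble"` (see [run_trials()]).
#' @export
simulate.lgmd <- function(object, nsim = 20, seed = NULL, ...) {
  run_trials(object$frames, object$params, n = nsim, seed = seed,
             layer_noise = object$layer_noise)
}
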