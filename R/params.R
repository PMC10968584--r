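#' Network parameters for the (probabilistic) LGMD model
#'
#' Bundles every constant of the four-layered LGMD network: the persistence
#' depth and shape of the photoreceptor layer, the inhibition weight, the
#' S-layer threshold and scale constant, the synaptic transmission
#' probability, and the two fixed 3x3 kernels (lateral inhibition spread and
#' the passing-coefficient averaging mask).
#'
#' @param np Integer persistence depth of the photoreceptor layer, i.e. how
#'   many past luminance-change frames decay into the current one. Allowed
#'   values are 0, 1 or 2.
#' @param u Real shape parameter of the persistence coefficients
#'   \eqn{p_i = (1 + e^{u i})^{-1}}. Larger `u` means faster decay of past
#'   luminance changes.
#' @param WI Inhibition weight applied when the I layer is subtracted from the
#'   E layer at the summation stage.
#' @param Ts Positive S-layer threshold: modulated summation values below `Ts`
#'   are zeroed before integration.
#' @param Cw Positive scale constant used when normalising the passing
#'   coefficient into the per-frame scale \eqn{\omega}.
#' @param prob Synaptic transmission probability in (0, 1]; every inter-layer
#'   connection is gated by an independent Bernoulli(`prob`) draw. `prob = 1`
#'   recovers the deterministic classic LGMD.
#'
#' @return An object of class `"lgmd_params"`: a list with the scalar
#'   parameters above plus `inhibition_kernel` (corners 0.125, edges 0.25,
#'   centre 0) and `passing_kernel` (all 1/9).
#'
#' @examples
#' p <- lgmd_params(prob = 0.5)
#' p
#' @export
lgmd_params <- function(np = 1, u = 1.0, WI = 0.3, Ts = 30, Cw = 4,
                        prob = 0.5) {
  np <- as.integer(np)
  if (length(np) != 1L || is.na(np) || !np %in% 0:2)
    stop("'np' must be 0, 1 or 2")
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u))
  if (!is.numeric(WI) || length(WI) != 1L || WI < 0)
    stop("'WI' must be a non-negative number")
  if (!is.numeric(Ts) || length(Ts) != 1L || Ts <= 0)
    stop("'Ts' must be positive")
  if (!is.numeric(Cw) || length(Cw) != 1L || Cw <= 0)
    stop("'Cw' must be positive")
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob > 1)
    stop("'prob' must lie in (0, 1]")

  ki <- inhibition_kernel()
  kp <- passing_kernel()
  # kernel mass is part of the model contract, not a tunable
  stopifnot(abs(sum(ki) - 1.5) < 1e-12, abs(sum(kp) - 1) < 1e-12)

  structure(
    list(np = np, u = u, WI = WI, Ts = Ts, Cw = Cw, prob = prob,
         inhibition_kernel = ki, passing_kernel = kp),
    class = "lgmd_params")
}

#' Lateral inhibition kernel
#'
#' The fixed 3x3 spread of delayed inhibition from a photoreceptor cell onto
#' its retinotopic neighbours: 0.25 to the four edge neighbours, 0.125 to the
#' four diagonal neighbours, nothing to the cell itself. Entries sum to 1.5.
#'
#' @return A 3x3 numeric matrix.
#' @export
inhibition_kernel <- function() {
  matrix(c(0.125, 0.25, 0.125,
           0.25,  0,    0.25,
           0.125, 0.25, 0.125), 3, 3, byrow = TRUE)
}

#' Passing-coefficient kernel
#'
#' The 3x3 uniform averaging mask (all entries 1/9) used to compute the
#' passing coefficient, i.e. the neighbourhood mean of the summation layer
#' that suppresses isolated excitations.
#'
#' @return A 3x3 numeric matrix summing to 1.
#' @export
passing_kernel <- function() {
  matrix(1 / 9, 3, 3)
}

#' @export
print.lgmd_params <- function(x, ...) {
  cat("LGMD network parameters\n")
  cat(sprintf("  np   (persistence depth)       %d\n", x$np))
  cat(sprintf("  u    (persistence shape)       %g\n", x$u))
  cat(sprintf("  WI   (inhibition weight)       %g\n", x$WI))
  cat(sprintf("  Ts   (S-layer threshold)       %g\n", x$Ts))
  cat(sprintf("  Cw   (scale constant)          %g\n", x$Cw))
  cat(sprintf("  prob (transmission probability) %g%s\n", x$prob,
              if (x$prob == 1) "  [deterministic limit]" else ""))
  invisible(x)
}

#' Persistence coefficients of the photoreceptor layer
#'
#' Computes \eqn{p_i = (1 + e^{u i})^{-1}} for \eqn{i = 1, \dots, np}: the
#' weights with which past luminance-change fields persist into the current
#' photoreceptor output. Each coefficient lies in (0, 1) and decays with lag.
#'
#' @param u Real shape parameter.
#' @param np Non-negative integer persistence depth.
#' @return Numeric vector of length `np` (length 0 when `np = 0`).
#' @examples
#' persistence_coefficients(u = 0, np = 2)  # both 0.5
#' @export
persistence_coefficients <- function(u, np) {
  np <- as.integer(np)
  if (np < 0) stop("'np' must be non-negative")
  if (np == 0L) return(numeric(0))
  1 / (1 + exp(u * seq_len(np)))
}
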