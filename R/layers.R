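#' Single-stage operations of the LGMD network
#'
#' These functions expose each stage of the four-layered network on plain
#' numeric matrices, exactly as composed frame-by-frame by [lgmd()]. They are
#' mainly useful for testing and for inspecting intermediate fields; gate
#' arguments default to `NULL`, meaning an ungated (all-ones, deterministic)
#' stage.
#'
#' @name lgmd-layers
NULL

pad0 <- function(m) {
  # zero padding: out-of-frame neighbours contribute no signal
  r <- nrow(m); c <- ncol(m)
  p <- matrix(0, r + 2L, c + 2L)
  p[2:(r + 1L), 2:(c + 1L)] <- m
  p
}

check_dims <- function(a, b, what) {
  if (!identical(dim(a), dim(b)))
    stop("dimension mismatch in ", what)
}

#' Photoreceptor layer: luminance change with persistence
#'
#' Computes the photoreceptor output
#' \eqn{P_t = \sum_i p_i P_{t-i} + L_t - L_{t-1}}: the frame difference plus
#' a decaying memory of past changes. At the start of a sequence the history
#' is zero-padded, so the first frame's P field is all zero.
#'
#' @param cur_L,prev_L Current and previous luminance frames (matrices).
#' @param P_history List of previous P fields, most recent first; shorter
#'   histories than `length(coeffs)` are treated as zero-padded.
#' @param coeffs Persistence coefficients from [persistence_coefficients()].
#' @return The P field (matrix, same dims, may be negative).
#' @rdname lgmd-layers
#' @export
photoreceptor_update <- function(cur_L, prev_L, P_history = list(),
                                 coeffs = numeric(0)) {
  check_dims(cur_L, prev_L, "photoreceptor_update")
  P <- cur_L - prev_L
  nh <- min(length(coeffs), length(P_history))
  for (i in seq_len(nh)) {
    check_dims(P_history[[i]], cur_L, "photoreceptor_update history")
    P <- P + coeffs[i] * P_history[[i]]
  }
  P
}

#' Sample a Bernoulli gate field
#'
#' Draws an i.i.d. 0/1 field from the current RNG stream, one draw per pixel
#' (and per kernel tap when `taps > 1`, as used by the P-to-I connection).
#' Gate fields multiply the transmitted signal, modelling stochastic synaptic
#' transmission.
#'
#' @param nrow,ncol Field dimensions.
#' @param prob Transmission probability in (0, 1].
#' @param taps Number of independent gate layers (1, or 9 for P-to-I).
#' @return A `nrow x ncol` matrix (or `nrow x ncol x taps` array) of 0/1.
#' @rdname lgmd-layers
#' @export
sample_gate_field <- function(nrow, ncol, prob, taps = 1L) {
  if (!is.numeric(prob) || prob <= 0 || prob > 1)
    stop("'prob' must lie in (0, 1]")
  n <- nrow * ncol * taps
  g <- as.double(stats::runif(n) < prob)
  if (taps == 1L) matrix(g, nrow, ncol) else array(g, c(nrow, ncol, taps))
}

#' Excitatory layer: gated copy of the photoreceptor field
#'
#' @param P Photoreceptor field.
#' @param gate 0/1 gate matrix (`NULL` = all ones).
#' @return The E field: `P * gate`.
#' @rdname lgmd-layers
#' @export
excitation_layer <- function(P, gate = NULL) {
  if (is.null(gate)) return(P)
  check_dims(P, gate, "excitation_layer")
  P * gate
}

#' Inhibitory layer: delayed, kernel-weighted, gated spread
#'
#' Each pixel receives the previous frame's photoreceptor output of its eight
#' neighbours, weighted by the lateral [inhibition_kernel()], each tap gated
#' independently. Out-of-frame neighbours contribute zero.
#'
#' @param P_prev Previous frame's P field (all-zero at sequence start).
#' @param gates `rows x cols x 9` 0/1 array, tap-major in column order of the
#'   3x3 kernel (`NULL` = ungated).
#' @param kernel 3x3 inhibition weights.
#' @return The I field.
#' @rdname lgmd-layers
#' @export
inhibition_layer <- function(P_prev, gates = NULL,
                             kernel = inhibition_kernel()) {
  r <- nrow(P_prev); c <- ncol(P_prev)
  if (!is.null(gates)) {
    if (!identical(dim(gates), c(r, c, 9L)))
      stop("dimension mismatch in inhibition_layer gates")
  }
  Pp <- pad0(P_prev)
  I <- matrix(0, r, c)
  tap <- 0L
  for (dj in -1:1) for (di in -1:1) {
    tap <- tap + 1L
    w <- kernel[di + 2L, dj + 2L]
    if (w == 0) next
    shifted <- Pp[(2L + di):(r + 1L + di), (2L + dj):(c + 1L + dj)]
    I <- I + if (is.null(gates)) w * shifted else w * shifted * gates[, , tap]
  }
  I
}

#' Summation layer: gated excitation minus weighted gated inhibition
#'
#' @param E,I Excitatory and inhibitory fields.
#' @param WI Inhibition weight.
#' @param gate_e,gate_i 0/1 gate matrices (`NULL` = ungated).
#' @return The S field (`E * gate_e - I * gate_i * WI`; may be negative).
#' @rdname lgmd-layers
#' @export
summation_layer <- function(E, I, WI, gate_e = NULL, gate_i = NULL) {
  check_dims(E, I, "summation_layer")
  if (!is.null(gate_e)) { check_dims(E, gate_e, "summation_layer"); E <- E * gate_e }
  if (!is.null(gate_i)) { check_dims(I, gate_i, "summation_layer"); I <- I * gate_i }
  E - I * WI
}

#' Passing coefficient: 3x3 neighbourhood mean of the summation layer
#'
#' Convolves S with the uniform [passing_kernel()] under zero padding, giving
#' each pixel the mean activity of its 3x3 neighbourhood. Isolated
#' excitations (noise) produce small passing coefficients and are suppressed
#' by the subsequent modulation.
#'
#' @param S Summation-layer field.
#' @return The Ce field.
#' @rdname lgmd-layers
#' @export
passing_coefficient <- function(S) {
  r <- nrow(S); c <- ncol(S)
  Sp <- pad0(S)
  Ce <- matrix(0, r, c)
  for (dj in -1:1) for (di in -1:1)
    Ce <- Ce + Sp[(2L + di):(r + 1L + di), (2L + dj):(c + 1L + dj)]
  Ce / 9
}

#' Per-frame scale of the passing coefficient
#'
#' \eqn{\omega = \max |Ce| / C_\omega + 0.01}. The absolute value keeps
#' \eqn{\omega} strictly positive, so the modulation in
#' [grouping_threshold()] never flips sign on an all-negative frame; the
#' 0.01 floor guards the all-zero frame.
#'
#' @param Ce Passing-coefficient field.
#' @param Cw Positive scale constant.
#' @return Scalar \eqn{\omega > 0}.
#' @rdname lgmd-layers
#' @export
scale_factor <- function(Ce, Cw) {
  max(abs(Ce)) / Cw + 0.01
}

#' Modulation and thresholding of the summation layer
#'
#' Forms \eqn{\tilde S = S \cdot Ce / \omega} and zeroes every entry below
#' the threshold `Ts` (the comparison is inclusive: entries equal to `Ts`
#' survive). Surviving entries are therefore all `>= Ts > 0`.
#'
#' @param S,Ce Summation and passing-coefficient fields.
#' @param omega Per-frame scale from [scale_factor()].
#' @param Ts Positive threshold.
#' @return The thresholded \eqn{\tilde S} field.
#' @rdname lgmd-layers
#' @export
grouping_threshold <- function(S, Ce, omega, Ts) {
  check_dims(S, Ce, "grouping_threshold")
  St <- S * Ce / omega
  St[St < Ts] <- 0
  St
}

#' Membrane potential: gated integration over the dendritic field
#'
#' @param S_tilde Thresholded summation field.
#' @param gate 0/1 gate matrix (`NULL` = ungated).
#' @return Scalar membrane potential \eqn{K_t \ge 0}.
#' @rdname lgmd-layers
#' @export
membrane_potential <- function(S_tilde, gate = NULL) {
  if (!is.null(gate)) {
    check_dims(S_tilde, gate, "membrane_potential")
    S_tilde <- S_tilde * gate
  }
  sum(S_tilde)
}

#' Sigmoid output of the LGMD cell
#'
#' \eqn{\kappa_t = (1 + e^{-K_t / n_{cell}})^{-1}}, where `ncell` is the
#' number of photoreceptor cells. Since \eqn{K_t \ge 0}, the output lives in
#' `[0.5, 1)`; 0.5 is the quiescent level.
#'
#' @param K Membrane potential (scalar or vector).
#' @param ncell Number of cells (rows * cols).
#' @return \eqn{\kappa} value(s).
#' @rdname lgmd-layers
#' @export
neuron_output <- function(K, ncell) {
  stopifnot(ncell > 0)
  1 / (1 + exp(-K / ncell))
}
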