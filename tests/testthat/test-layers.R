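test_that("photoreceptor output is the frame difference plus persistence", {
  L0 <- matrix(100, 5, 5)
  # constant luminance, empty history: all-zero P
  expect_equal(photoreceptor_update(L0, L0), matrix(0, 5, 5))
  # pure frame difference at one pixel when np = 0
  L1 <- L0; L1[2, 3] <- 110
  P <- photoreceptor_update(L1, L0)
  expect_equal(P[2, 3], 10)
  expect_equal(sum(P != 0), 1)
  # persistence: prev P = 10 at a pixel, zero current difference, u = 1
  hist <- list(matrix(0, 5, 5)); hist[[1]][4, 4] <- 10
  P2 <- photoreceptor_update(L0, L0, hist, persistence_coefficients(1, 1))
  expect_equal(P2[4, 4], 2.68941421369995, tolerance = 1e-12)
  expect_error(photoreceptor_update(L0, matrix(0, 4, 4)), "dimension")
})

test_that("excitation layer is an elementwise gate mask", {
  P <- matrix(rnorm(25), 5, 5)
  expect_identical(excitation_layer(P, matrix(1, 5, 5)), P)
  expect_equal(excitation_layer(P, matrix(0, 5, 5)), matrix(0, 5, 5))
  g <- matrix(0, 5, 5); g[3, 2] <- 1
  P7 <- matrix(0, 5, 5); P7[3, 2] <- 7
  E <- excitation_layer(P7, g)
  expect_equal(E[3, 2], 7)
  expect_equal(sum(E), 7)
})

test_that("inhibition layer matches a brute-force zero-padded convolution", {
  # uniform field: interior pixels get 1.5x the field (kernel mass)
  Pu <- matrix(2, 6, 6)
  I <- inhibition_layer(Pu)
  expect_equal(I[3, 3], 3)
  # impulse: centre gets nothing, 4-neighbours 0.25A, diagonals 0.125A
  Pi <- matrix(0, 5, 5); Pi[3, 3] <- 8
  I2 <- inhibition_layer(Pi)
  expect_equal(I2[3, 3], 0)
  expect_equal(I2[2, 3], 2)
  expect_equal(I2[2, 2], 1)
  # random fields against the independent loop oracle
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(rnorm(48), 6, 8)
    expect_equal(inhibition_layer(m), brute_conv3(m, inhibition_kernel()),
                 tolerance = 1e-12)
  }
  # all gates zero kill the inhibition
  expect_equal(inhibition_layer(Pu, array(0, c(6, 6, 9))), matrix(0, 6, 6))
  # per-tap gating: gate exactly one tap open everywhere
  g <- array(0, c(5, 5, 9)); g[, , 2] <- 1  # tap 2 = (di = 0, dj = -1), w = .25
  I3 <- inhibition_layer(Pi, g)
  expect_equal(sum(I3), 2)
})

test_that("summation combines gated excitation and weighted inhibition", {
  E <- matrix(10, 3, 3); I <- matrix(10, 3, 3)
  S <- summation_layer(E, I, WI = 0.3)
  expect_equal(S, matrix(7, 3, 3))
  # excitation gate closed, inhibition open: negative values allowed
  S2 <- summation_layer(E, I, WI = 0.3,
                        gate_e = matrix(0, 3, 3), gate_i = matrix(1, 3, 3))
  expect_equal(S2, matrix(-3, 3, 3))
  S3 <- summation_layer(E, I, WI = 0.3,
                        gate_e = matrix(0, 3, 3), gate_i = matrix(0, 3, 3))
  expect_equal(S3, matrix(0, 3, 3))
})

test_that("passing coefficient is the zero-padded neighbourhood mean", {
  Su <- matrix(3, 6, 6)
  Ce <- passing_coefficient(Su)
  expect_equal(Ce[3, 3], 3)              # interior: kernel sums to 1
  expect_equal(Ce[1, 1], 3 * 4 / 9)      # corner: 4 in-frame taps
  Si <- matrix(0, 5, 5); Si[3, 3] <- 9
  Ci <- passing_coefficient(Si)
  expect_true(all(Ci[2:4, 2:4] == 1))
  expect_equal(sum(Ci), 9)
  set.seed(4)
  m <- matrix(rnorm(35), 5, 7)
  expect_equal(passing_coefficient(m), brute_conv3(m, passing_kernel()),
               tolerance = 1e-12)
})

test_that("scale factor is positive and homogeneous in the field", {
  expect_equal(scale_factor(matrix(c(-4, 2), 1, 2), Cw = 4), 1.01)
  expect_equal(scale_factor(matrix(0, 3, 3), Cw = 4), 0.01)
  Ce <- matrix(rnorm(9), 3, 3)
  expect_equal(scale_factor(3 * Ce, 4) - 0.01,
               3 * (scale_factor(Ce, 4) - 0.01), tolerance = 1e-12)
})

test_that("grouping threshold zeroes sub-threshold modulated values inclusively", {
  S <- matrix(1, 2, 2)
  # modulated values chosen around Ts = 30 via Ce with omega = 1
  Ce <- matrix(c(29.9, 30, 31, -5), 2, 2)
  St <- grouping_threshold(S, Ce, omega = 1, Ts = 30)
  expect_equal(as.vector(St), c(0, 30, 31, 0))  # boundary kept, negatives zeroed
  expect_true(all(St == 0 | St >= 30))
})

test_that("membrane potential and sigmoid output behave at the limits", {
  St <- matrix(0, 4, 4)
  expect_equal(membrane_potential(St), 0)
  St[2, 2] <- 40; St[3, 3] <- 35
  expect_equal(membrane_potential(St), 75)
  expect_equal(membrane_potential(St, matrix(0, 4, 4)), 0)
  expect_equal(neuron_output(0, 100), 0.5)
  expect_equal(neuron_output(100, 100), 1 / (1 + exp(-1)))
  expect_equal(neuron_output(1e9, 100), 1)
  expect_true(all(diff(neuron_output(seq(0, 500, 50), 100)) > 0))
})

test_that("gate fields have the right statistics and degenerate limits", {
  set.seed(99)
  expect_true(all(sample_gate_field(20, 20, prob = 1) == 1))
  g <- sample_gate_field(200, 200, prob = 0.5)
  expect_true(all(g %in% c(0, 1)))
  se <- sqrt(0.25 / 40000)
  expect_lt(abs(mean(g) - 0.5), 4 * se)
  g9 <- sample_gate_field(10, 10, prob = 0.3, taps = 9)
  expect_identical(dim(g9), c(10L, 10L, 9L))
  expect_error(sample_gate_field(5, 5, prob = 0), "prob")
})
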