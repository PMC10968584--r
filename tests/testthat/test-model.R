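test_that("prob = 1 run equals the deterministic baseline exactly", {
  for (s in 1:3) {
    fs <- random_sequence(rows = 15, cols = 12, frames = 8, seed = s)
    gated <- lgmd(fs, lgmd_params(prob = 1), seed = s)
    det <- deterministic_lgmd(fs)
    expect_identical(gated$kappa, det$kappa)
    expect_identical(gated$K, det$K)
  }
})

test_that("constant-luminance input is a fixed point at kappa = 0.5", {
  fs <- frame_sequence(array(128, c(10, 10, 6)))
  for (p in c(0.3, 0.7, 1)) {
    out <- lgmd(fs, lgmd_params(prob = p), seed = 1, capture_layers = TRUE)
    expect_equal(out$kappa, rep(0.5, 6))
    expect_equal(out$K, rep(0, 6))
    expect_equal(out$layers$P[[4]], matrix(0, 10, 10))
    expect_equal(out$layers$S[[4]], matrix(0, 10, 10))
  }
})

test_that("output is bounded in [0.5, 1) and the first frame is quiescent", {
  fs <- random_sequence(rows = 12, cols = 12, frames = 10, seed = 7)
  out <- lgmd(fs, lgmd_params(prob = 0.6), seed = 2)
  expect_equal(out$kappa[1], 0.5)
  expect_true(all(out$kappa >= 0.5 & out$kappa < 1 + 1e-15))
  expect_true(all(out$K >= 0))
})

test_that("identical seed and input reproduce bitwise-identical traces", {
  fs <- random_sequence(rows = 12, cols = 12, frames = 8, seed = 3)
  a <- lgmd(fs, lgmd_params(prob = 0.4), seed = 11, capture_layers = TRUE)
  b <- lgmd(fs, lgmd_params(prob = 0.4), seed = 11, capture_layers = TRUE)
  expect_identical(a$kappa, b$kappa)
  expect_identical(a$layers$E, b$layers$E)
  c <- lgmd(fs, lgmd_params(prob = 0.4), seed = 12)
  expect_false(identical(a$kappa, c$kappa))
})

test_that("running with a seed leaves the caller's RNG state untouched", {
  fs <- random_sequence(rows = 8, cols = 8, frames = 5, seed = 4)
  set.seed(123)
  before <- .Random.seed
  invisible(lgmd(fs, lgmd_params(prob = 0.5), seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("trial-mean excitation converges to prob * P (gating expectation)", {
  set.seed(42)
  P <- matrix(runif(64, -50, 50), 8, 8)
  n <- 500; prob <- 0.5
  acc <- matrix(0, 8, 8)
  for (k in seq_len(n)) acc <- acc + excitation_layer(P, sample_gate_field(8, 8, prob))
  emp <- acc / n
  se <- abs(P) * sqrt(prob * (1 - prob) / n)
  ok <- abs(emp - prob * P) <= 4 * se
  expect_gte(mean(ok), 0.99)
})

test_that("layer noise hooks corrupt the requested layer reproducibly", {
  fs <- small_looming(rows = 24, cols = 24, frames = 15, collision_frame = 13)
  ln <- list(layer = "P", kind = "salt_pepper", ratio = 0.05)
  a <- lgmd(fs, lgmd_params(prob = 0.5), seed = 5, layer_noise = ln)
  b <- lgmd(fs, lgmd_params(prob = 0.5), seed = 5, layer_noise = ln)
  expect_identical(a$kappa, b$kappa)
  # deterministic and gated runs with one seed receive identical injected noise
  da <- deterministic_lgmd(fs, layer_noise = ln, seed = 5, capture_layers = TRUE)
  ga <- lgmd(fs, lgmd_params(prob = 0.5), seed = 5, layer_noise = ln,
             capture_layers = TRUE)
  expect_identical(da$layers$P, ga$layers$P)
  # gaussian layer noise accepted on any layer
  for (ly in c("E", "I", "S")) {
    out <- lgmd(fs, lgmd_params(prob = 0.8), seed = 2,
                layer_noise = list(layer = ly, kind = "gaussian",
                                   variance = 0.01))
    expect_true(all(is.finite(out$kappa)))
  }
  expect_error(lgmd(fs, layer_noise = list(layer = "P", kind = "salt_pepper")),
               "ratio")
})

test_that("inject_layer_noise respects intensity limits and magnitudes", {
  f <- matrix(rnorm(100, sd = 10), 10, 10)
  set.seed(1)
  expect_identical(inject_layer_noise(f, "salt_pepper", ratio = 0), f)
  expect_identical(inject_layer_noise(f, "gaussian", variance = 0), f)
  set.seed(2)
  full <- inject_layer_noise(f, "salt_pepper", ratio = 1)
  m <- max(abs(f))
  expect_true(all(full %in% c(0, m, -m)))
})

test_that("simulate() re-runs the stored input as a replicate ensemble", {
  fs <- small_looming(rows = 20, cols = 20, frames = 12, collision_frame = 10)
  fit <- lgmd(fs, lgmd_params(prob = 0.5), seed = 1)
  ens <- simulate(fit, nsim = 4, seed = 3)
  expect_s3_class(ens, "lgmd_ensemble")
  expect_equal(ncol(ens$traces), 4)
  expect_equal(nrow(ens$traces), n_frames(fs))
})
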