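test_that("looming disc starts at r0 and fills the frame at collision", {
  fs <- looming_sequence(rows = 60, cols = 60, frames = 40,
                         collision_frame = 35, r0 = 0.1,
                         object_level = 0, background_level = 255)
  f1 <- get_frame(fs, 1)
  # initial disc radius r0 * min(R,C)/2 = 3 px: area close to pi * 9
  expect_equal(sum(f1 == 0), sum(outer((1:60 - 30.5)^2, (1:60 - 30.5)^2, `+`) <= 9))
  expect_gt(sum(f1 == 0), 20)
  # disc area is non-decreasing
  areas <- vapply(1:40, function(t) sum(get_frame(fs, t) == 0), 0)
  expect_true(all(diff(areas) >= 0))
  # full coverage from the collision frame on
  expect_gte(areas[35] / 3600, 0.95)
  expect_equal(areas[35], 3600)
  # exactly two luminance levels
  expect_true(all(unlist(fs) %in% c(0, 255)))
  expect_error(looming_sequence(frames = 10, collision_frame = 12), "collision_frame")
  expect_error(looming_sequence(rows = 2, cols = 2), "degenerate")
})

test_that("a frozen-geometry disc elicits no response after frame 2", {
  one <- get_frame(looming_sequence(rows = 30, cols = 30, frames = 20,
                                    collision_frame = 18), 10)
  frozen <- frame_sequence(array(one, c(30, 30, 8)))
  out <- lgmd(frozen, lgmd_params(prob = 0.7), seed = 1)
  expect_equal(out$kappa, rep(0.5, 8))
})

test_that("polarity swap preserves frame-difference magnitudes", {
  dark <- looming_sequence(rows = 30, cols = 30, frames = 15,
                           collision_frame = 13, polarity = "dark")
  light <- looming_sequence(rows = 30, cols = 30, frames = 15,
                            collision_frame = 13, polarity = "light")
  for (t in 2:15) {
    dd <- get_frame(dark, t) - get_frame(dark, t - 1)
    dl <- get_frame(light, t) - get_frame(light, t - 1)
    expect_equal(abs(dd), abs(dl))
  }
})

test_that("salt-and-pepper corruption hits the expected pixel fraction", {
  fs <- frame_sequence(array(128, c(100, 100, 3)))
  expect_identical(unclass(add_salt_pepper(fs, 0)), unclass(fs))
  all_noise <- add_salt_pepper(fs, 1, seed = 1)
  expect_true(all(all_noise %in% c(0, 255)))
  noisy <- add_salt_pepper(fs, 0.01, seed = 2)
  count <- sum(get_frame(noisy, 1) != 128)
  expect_lt(abs(count - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # dims and frame count preserved; frames corrupted independently
  expect_identical(dim(noisy), dim(fs))
  expect_false(identical(get_frame(noisy, 1), get_frame(noisy, 2)))
  expect_error(add_salt_pepper(fs, 1.5), "pnr")
})

test_that("gaussian corruption has the nominal variance and clips to range", {
  fs <- frame_sequence(array(128, c(200, 200, 3)))
  expect_identical(unclass(add_gaussian_noise(fs, 0)), unclass(fs))
  noisy <- add_gaussian_noise(fs, 0.007, seed = 3)
  expect_true(min(noisy) >= 0 && max(noisy) <= 255)
  # mid-gray: clipping is negligible, sample variance near 0.007 * 255^2
  v <- var(as.vector(unclass(noisy) - 128))
  expect_lt(abs(v - 0.007 * 255^2) / (0.007 * 255^2), 0.1)
  expect_error(add_gaussian_noise(fs, -1), "gnv")
})

test_that("noise operators are reproducible under a fixed seed", {
  fs <- small_looming(rows = 20, cols = 20, frames = 10, collision_frame = 9)
  expect_identical(unclass(add_salt_pepper(fs, 0.05, seed = 7)),
                   unclass(add_salt_pepper(fs, 0.05, seed = 7)))
  expect_identical(unclass(add_gaussian_noise(fs, 0.01, seed = 7)),
                   unclass(add_gaussian_noise(fs, 0.01, seed = 7)))
})

test_that("frame I/O round-trips integer-valued sequences", {
  fs <- small_looming(rows = 16, cols = 16, frames = 5, collision_frame = 4)
  d <- tempfile("frames")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  write_frames(fs, d)
  expect_length(list.files(d, pattern = "\\.png$"), 5)
  back <- load_frames(d)
  expect_equal(unclass(back), unclass(fs), ignore_attr = TRUE)
  # gray conversion: R=G=B input maps to the channel value
  rgb <- array(0.5, c(4, 4, 3))
  expect_equal(to_grayscale(rgb), matrix(127.5, 4, 4))
})
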