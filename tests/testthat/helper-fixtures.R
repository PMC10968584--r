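# Shared fixtures: all inputs are generated in code at test time.

# A small random gray-scale sequence (values 0-255), reproducible.
random_sequence <- function(rows = 20, cols = 20, frames = 10, seed = 1) {
  set.seed(seed)
  frame_sequence(array(runif(rows * cols * frames, 0, 255),
                       c(rows, cols, frames)))
}

# A small clean looming stimulus used across tests.
small_looming <- function(rows = 40, cols = 40, frames = 30,
                          collision_frame = 27, ...) {
  looming_sequence(rows = rows, cols = cols, frames = frames,
                   collision_frame = collision_frame, ...)
}

# Independent brute-force 3x3 convolution with zero padding, used as the
# oracle for the inhibition and passing-coefficient stages.
brute_conv3 <- function(m, kernel) {
  r <- nrow(m); c <- ncol(m)
  out <- matrix(0, r, c)
  for (i in seq_len(r)) for (j in seq_len(c)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= r && jj >= 1 && jj <= c)
        acc <- acc + m[ii, jj] * kernel[di + 2, dj + 2]
    }
    out[i, j] <- acc
  }
  out
}

# Independent distinct-ratio evaluation: explicit loop, one copy of the
# maximum excluded from the background mean.
brute_dr <- function(kappa) {
  kmax <- -Inf
  for (v in kappa) if (v > kmax) kmax <- v
  bg <- 0
  for (v in kappa) bg <- bg + v
  kmax - (bg - kmax) / (length(kappa) - 1)
}

# Independent per-pixel median with edge replication on a small frame.
brute_median3 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  out <- matrix(0, r, c)
  for (i in seq_len(r)) for (j in seq_len(c)) {
    ii <- pmin(pmax(i + (-1:1), 1), r)
    jj <- pmin(pmax(j + (-1:1), 1), c)
    out[i, j] <- median(m[ii, jj])
  }
  out
}
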