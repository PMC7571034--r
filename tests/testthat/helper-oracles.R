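# Independent brute-force oracles used to check the implementation.
# Each oracle is written from the mathematical definition, not from the
# package code paths it validates.

# Centred moving average by direct summation.
oracle_moving_average <- function(v, width) {
  half <- (width - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    sum(v[idx]) / length(idx)
  }, numeric(1))
}

# Sub-sample-and-smoothen by direct summation of the defining window.
oracle_subsample <- function(v, m) {
  n <- length(v)
  sr <- n %/% m
  out <- numeric(m)
  for (k in 0:(m - 1L)) {
    acc <- 0; cnt <- 0L
    for (i in -sr:sr) {
      j <- k * sr + i
      j <- min(max(j, 0L), n - 1L)
      acc <- acc + v[j + 1L]
      cnt <- cnt + 1L
    }
    out[k + 1L] <- acc / cnt
  }
  out
}

# O(N^2) discrete Fourier transform magnitudes.
oracle_dft_mod <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1L)) / n)))
  }, numeric(1))
}

# Textbook single-level Haar analysis filter bank (low-pass branch):
# convolve with (1/sqrt2, 1/sqrt2) and downsample by 2.
oracle_haar_a1 <- function(x) {
  h <- c(1, 1) / sqrt(2)
  n <- length(x)
  vapply(seq_len(n / 2), function(k) {
    sum(h * x[(2L * k - 1L):(2L * k)])
  }, numeric(1))
}

# Hand-rolled forward pass on explicit loops (no matrix ops shared with the
# implementation).
oracle_forward <- function(x, weights) {
  h <- x
  L <- length(weights)
  for (l in seq_len(L)) {
    w <- weights[[l]]
    n_out <- ncol(w)
    z <- numeric(n_out)
    inp <- c(h, 1)
    for (j in seq_len(n_out)) z[j] <- sum(inp * w[, j])
    h <- if (l < L) pmax(z, 0) else z
  }
  e <- exp(h - max(h))
  e / sum(e)
}

# Central-difference gradient of log pi(action) with respect to the output
# weight matrix.
oracle_logpi_grad <- function(h2, theta, action, eps = 1e-6) {
  logpi <- function(th) {
    z <- drop(c(h2, 1) %*% th)
    z <- z - max(z)
    z[action] - log(sum(exp(z)))
  }
  g <- matrix(0, nrow(theta), ncol(theta))
  for (j in seq_len(nrow(theta))) for (i in seq_len(ncol(theta))) {
    tp <- theta; tp[j, i] <- tp[j, i] + eps
    tm <- theta; tm[j, i] <- tm[j, i] - eps
    g[j, i] <- (logpi(tp) - logpi(tm)) / (2 * eps)
  }
  g
}

# Random small fitted-network stand-in for online-update tests: a valid
# har_mlp-shaped object without running the trainer.
random_small_net <- function(seed = 1, n_in = 6L, hidden = c(4L, 5L),
                             n_out = 8L) {
  set.seed(seed)
  sizes <- c(n_in, hidden, n_out)
  w <- lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(rnorm((sizes[l] + 1L) * sizes[l + 1L], sd = 0.5),
           sizes[l] + 1L, sizes[l + 1L]))
  structure(list(weights = w, hidden = hidden,
                 classes = har_activities()[seq_len(n_out)],
                 normalizer = NULL),
            class = "har_mlp")
}

# A tiny synthetic segment pair for feature tests.
make_test_segment <- function(seed = 1, n_stretch = 40L, n_accel = 400L,
                              label = "walk") {
  set.seed(seed)
  t_s <- seq(0, by = 0.04, length.out = n_stretch)
  t_a <- seq(0, by = 0.004, length.out = n_accel)
  har_segment(start = 0, end = n_stretch * 0.04,
              stretch = sample_series(t_s, 1 + 0.3 * sin(2 * pi * t_s) +
                                        rnorm(n_stretch, 0, 0.01)),
              accel = data.frame(time = t_a,
                                 ax = rnorm(n_accel, 0, 0.05),
                                 ay = rnorm(n_accel, 0, 0.05),
                                 az = 1 + rnorm(n_accel, 0, 0.05)),
              label = label)
}
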