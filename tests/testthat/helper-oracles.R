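# independent brute-force MSD: explicit double loop over all ordered pairs
brute_msd <- function(track, max_lag) {
  n <- length(track$t)
  vapply(seq_len(max_lag), function(k) {
    acc <- 0
    for (i in 1:(n - k))
      acc <- acc + (track$x[i + k] - track$x[i])^2 +
        (track$y[i + k] - track$y[i])^2
    acc / (n - k)
  }, numeric(1))
}

# pure 2D random walk with diffusion coefficient D
brownian_track <- function(id, D, dt, n) {
  s <- sqrt(2 * D * dt)
  gc_track(id, t = (0:(n - 1)) * dt,
           x = cumsum(c(0, rnorm(n - 1, 0, s))),
           y = cumsum(c(0, rnorm(n - 1, 0, s))))
}

linear_track <- function(id, v, dt, n, x0 = 0, y0 = 0, angle = 0) {
  t <- (0:(n - 1)) * dt
  gc_track(id, t = t, x = x0 + v * cos(angle) * t,
           y = y0 + v * sin(angle) * t)
}

# rasterized shapes for morphometry
disk_mask <- function(r, n = 2 * r + 20) {
  c0 <- n / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

ellipse_mask <- function(a, b, n = 2 * a + 40) {
  c0 <- n / 2
  outer(1:n, 1:n, function(i, j) ((i - c0) / a)^2 + ((j - c0) / b)^2 <= 1)
}

# isotropic Gaussian localization cluster
gauss_cluster <- function(n, cx, cy, sigma) {
  data.frame(x = rnorm(n, cx, sigma), y = rnorm(n, cy, sigma))
}
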