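# Independent oracles and tiny fixture builders used across the test files.
# These deliberately use naive loops / direct formulas, not the package's
# vectorized implementations.

# Pearson correlation by direct summation.
naive_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Least-squares line fit by solving the 2x2 normal equations directly,
# returning the residual.
naive_detrend <- function(ts) {
  n <- length(ts)
  t_idx <- seq_len(n) - 1
  A <- rbind(c(n, sum(t_idx)), c(sum(t_idx), sum(t_idx^2)))
  b <- c(sum(ts), sum(t_idx * ts))
  coefs <- solve(A, b)
  ts - coefs[1] - coefs[2] * t_idx
}

# A small 4D image filled from a fixed-seed normal draw.
random_image <- function(dims = c(6, 6, 4, 20), tr_s = 2.8, seed = 1) {
  set.seed(seed)
  image_4d(array(rnorm(prod(dims)), dim = dims), tr_s = tr_s)
}

full_mask <- function(img_or_dims) {
  d <- if (inherits(img_or_dims, "image_4d")) dim(img_or_dims$data)[1:3] else img_or_dims
  array(TRUE, dim = d)
}

# Sinusoid image at an exact DFT bin j (0-based), constant over space.
bin_sinusoid_image <- function(dims3 = c(4, 4, 2), n_t = 132, tr_s = 2.8, bin_j = 7,
                               amplitude = 1) {
  t_idx <- seq_len(n_t) - 1
  f <- bin_j / (n_t * tr_s)
  ts <- amplitude * sin(2 * pi * f * t_idx * tr_s + 0.3)
  arr <- array(rep(ts, each = prod(dims3)), dim = c(dims3, n_t))
  list(img = image_4d(arr, tr_s = tr_s), freq_hz = f, ts = ts)
}

# Total temporal power (sum of squared values) of an image.
image_power <- function(img) sum(img$data^2)

extdata <- function(name) system.file("extdata", name, package = "seedconn")
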