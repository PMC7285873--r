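# Gaussian kernel density models used for read-length quantities.
#
# The models deliberately store their training points (plus a Scott's-rule
# bandwidth) rather than a gridded density: sampling is then exact
# smoothed-bootstrap sampling from the fitted KDE -- resample a training
# point uniformly (or kernel-weighted, for conditional draws) and add
# Gaussian jitter at the bandwidth.  Marginalized over the training set this
# reproduces the KDE density exactly, and it is cheap per draw.

scott_bandwidth <- function(x, d = 1L) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- 1e-6
  bw <- s * n^(-1 / (d + 4))
  max(bw, 1e-9)
}

# One-dimensional KDE: points on a declared scale ("identity", "log10",
# "log1p"); sampling jitters on that scale and back-transforms.
fit_kde1d <- function(x, scale = c("identity", "log10", "log1p")) {
  scale <- match.arg(scale)
  tx <- switch(scale, identity = x, log10 = log10(x), log1p = log1p(x))
  structure(list(points = tx, bw = scott_bandwidth(tx), scale = scale,
                 n = length(x)),
            class = "nanotx_kde1d")
}

sample_kde1d <- function(kde, n) {
  if (kde$n == 0L) stopf("cannot sample from an empty KDE")
  idx <- sample.int(kde$n, n, replace = TRUE)
  z <- kde$points[idx] + stats::rnorm(n, 0, kde$bw)
  switch(kde$scale, identity = z, log10 = 10^z, log1p = expm1(z))
}

# Two-dimensional KDE with a diagonal Scott bandwidth matrix.
fit_kde2d <- function(x, y) {
  stopifnot(length(x) == length(y))
  structure(list(x = x, y = y,
                 bw_x = scott_bandwidth(x, d = 2L),
                 bw_y = scott_bandwidth(y, d = 2L),
                 n = length(x)),
            class = "nanotx_kde2d")
}

# Joint draw from a 2D KDE (both coordinates jittered).
sample_kde2d <- function(kde, n) {
  idx <- sample.int(kde$n, n, replace = TRUE)
  cbind(kde$x[idx] + stats::rnorm(n, 0, kde$bw_x),
        kde$y[idx] + stats::rnorm(n, 0, kde$bw_y))
}

# Conditional draw of y | x = x0 from a 2D KDE: training points are
# resampled with Gaussian kernel weights in the x dimension, then jittered
# in y.  `x0` may be a vector; to keep the weight computation affordable for
# large batches, x0 values are grouped on a fine grid (resolution bw_x/20,
# far below the kernel scale, so the approximation is negligible).
sample_kde2d_conditional <- function(kde, x0) {
  n <- length(x0)
  res <- kde$bw_x / 20
  key <- round(x0 / res)
  out <- numeric(n)
  for (k in unique(key)) {
    sel <- which(key == k)
    xc <- k * res
    w <- stats::dnorm(kde$x, xc, kde$bw_x)
    if (sum(w) <= 0) w <- rep(1, kde$n)
    idx <- sample.int(kde$n, length(sel), replace = TRUE, prob = w)
    out[sel] <- kde$y[idx] + stats::rnorm(length(sel), 0, kde$bw_y)
  }
  out
}
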