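# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive three-point neighbour scan for strict local extrema
# (no plateau handling; used on continuous random data where ties have
# probability zero).
brute_extrema <- function(x) {
  mx <- integer(0); mn <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- c(mx, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- c(mn, i)
  }
  list(maxima = mx, minima = mn)
}

# Natural cubic spline through (xi, yi) evaluated at xout, by direct
# solution of the second-derivative tridiagonal system.
natural_spline_eval <- function(xi, yi, xout) {
  n <- length(xi)
  h <- diff(xi)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((yi[i + 1] - yi[i]) / h[i] - (yi[i] - yi[i - 1]) / h[i - 1])
  }
  m <- solve(A, b)   # second derivatives at knots
  vapply(xout, function(x) {
    j <- max(which(xi <= x)); j <- min(j, n - 1)
    dx <- x - xi[j]; hj <- h[j]
    yi[j] + dx * ((yi[j + 1] - yi[j]) / hj - hj / 6 * (2 * m[j] + m[j + 1])) +
      dx^2 * m[j] / 2 + dx^3 * (m[j + 1] - m[j]) / (6 * hj)
  }, numeric(1))
}

# Zero-crossing count ignoring exact zeros.
zc_count <- function(x) {
  s <- sign(x); s <- s[s != 0]
  if (length(s) < 2) 0L else sum(diff(s) != 0)
}

imf_property_holds <- function(im) {
  ex <- find_extrema(im)
  abs(length(ex$maxima) + length(ex$minima) - zc_count(im)) <= 1
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# Small cached synthetic dataset shared by selection/feature tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(generator_config(n_subjects = 1, seed = 42))
    cache
  }
})

small_decomps <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(small_dataset(),
                       function(s) emd(as.vector(s$data[1, ])))
    cache
  }
})
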