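#' Sifting configuration for EMD and EEMD
#'
#' @param max_imfs maximum number of intrinsic mode functions to extract.
#'   The default of 16 matches the deepest decompositions seen on
#'   one-minute 100 Hz EEG epochs.
#' @param max_sift_iterations cap on sifting iterations per IMF.
#' @param sd_threshold Cauchy-type stopping threshold: sifting of one IMF
#'   stops once `sum((h_prev - h)^2) / sum(h_prev^2)` falls below this
#'   value *and* the candidate satisfies the IMF extrema/zero-crossing
#'   condition.
#' @param ensemble_size number of noise-perturbed ensemble members (EEMD).
#' @param noise_fraction standard deviation of the added Gaussian noise as
#'   a fraction of the signal standard deviation (EEMD).
#' @param seed integer seed for the EEMD noise draws.
#' @return an object of class `sift_config`.
#' @export
sift_config <- function(max_imfs = 16, max_sift_iterations = 30,
                        sd_threshold = 0.2, ensemble_size = 100,
                        noise_fraction = 0.2, seed = 1) {
  stopifnot(max_imfs >= 1, max_sift_iterations >= 1, sd_threshold > 0,
            ensemble_size >= 1, noise_fraction > 0)
  structure(list(max_imfs = as.integer(max_imfs),
                 max_sift_iterations = as.integer(max_sift_iterations),
                 sd_threshold = sd_threshold,
                 ensemble_size = as.integer(ensemble_size),
                 noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "sift_config")
}

#' Locate strict local extrema of a series
#'
#' Plateaus (runs of equal values) are collapsed to a single point at the
#' plateau midpoint before the three-point neighbour comparison, so a flat
#' crest counts as one maximum.
#'
#' @param x numeric vector of length >= 3.
#' @return list with integer vectors `maxima` and `minima` (indices
#'   into `x`).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) stop("series must have length >= 3")
  r <- rle(as.vector(x))
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) %/% 2L
  m <- length(v)
  if (m < 3)
    return(list(maxima = integer(0), minima = integer(0)))
  core <- 2:(m - 1)
  is_max <- v[core] > v[core - 1] & v[core] > v[core + 1]
  is_min <- v[core] < v[core - 1] & v[core] < v[core + 1]
  list(maxima = mid[core][is_max], minima = mid[core][is_min])
}

# Count sign changes, ignoring exact zeros.
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# IMF condition: numbers of extrema and zero crossings equal or differ by 1.
imf_condition_ok <- function(h) {
  ex <- find_extrema(h)
  n_ext <- length(ex$maxima) + length(ex$minima)
  abs(n_ext - count_zero_crossings(h)) <= 1L
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' Natural cubic splines are fitted through the maxima (upper envelope)
#' and minima (lower envelope). Before fitting, the two extrema nearest
#' each edge are mirrored beyond the signal boundary, which suppresses
#' end swings of the spline.
#'
#' @param x numeric vector.
#' @param maxima,minima integer index vectors as returned by
#'   [find_extrema()]; each must contain at least 2 points.
#' @return numeric vector, the pointwise mean envelope.
#' @export
envelope_mean <- function(x, maxima, minima) {
  n <- length(x)
  if (length(maxima) < 2 || length(minima) < 2)
    stop("need at least 2 maxima and 2 minima to form envelopes")
  mirror <- function(idx) {
    val <- x[idx]
    k <- min(2L, length(idx))
    left <- 2L - idx[seq_len(k)]                         # reflect about 1
    right <- 2L * n - idx[length(idx) - seq_len(k) + 1L] # reflect about n
    xi <- c(left, idx, right)
    yi <- c(val[seq_len(k)], val, val[length(val) - seq_len(k) + 1L])
    keep <- !duplicated(xi)
    o <- order(xi[keep])
    list(xi = xi[keep][o], yi = yi[keep][o])
  }
  up <- mirror(maxima)
  lo <- mirror(minima)
  eu <- stats::spline(up$xi, up$yi, xout = seq_len(n), method = "natural")$y
  el <- stats::spline(lo$xi, lo$yi, xout = seq_len(n), method = "natural")$y
  (eu + el) / 2
}

#' Empirical mode decomposition by sifting
#'
#' Iteratively subtracts the cubic-spline envelope mean from the current
#' component until the Cauchy stopping criterion falls below
#' `sd_threshold` and the extrema/zero-crossing IMF condition holds (or
#' `max_sift_iterations` is reached), then removes the converged IMF and
#' repeats on the remainder. Extraction stops when the residue is
#' monotone (fewer than 2 maxima or 2 minima) or `max_imfs` IMFs have
#' been extracted. The decomposition is exactly additive: the IMFs and
#' residue sum back to the input up to floating-point error.
#'
#' @param x finite numeric vector, length >= 4.
#' @param config a [sift_config()].
#' @return an object of class `imf_set`: list with `imfs` (list of
#'   numeric vectors, highest frequency first), `residue`, and
#'   `source_length`.
#' @export
#' @examples
#' t <- seq(0, 6, by = 0.01)
#' x <- sin(2 * pi * 8 * t) + sin(2 * pi * 0.5 * t)
#' d <- emd(x)
#' length(d$imfs)
emd <- function(x, config = sift_config()) {
  x <- as.vector(x)
  stopifnot_finite(x, "signal")
  if (length(x) < 4) stop("signal must have length >= 4")
  imfs <- list()
  r <- x
  for (k in seq_len(config$max_imfs)) {
    ex <- find_extrema(r)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    h <- r
    for (it in seq_len(config$max_sift_iterations)) {
      ex <- find_extrema(h)
      if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
      m <- envelope_mean(h, ex$maxima, ex$minima)
      h_new <- h - m
      denom <- sum(h^2)
      sd_k <- if (denom > 0) sum((h - h_new)^2) / denom else 0
      h <- h_new
      if (sd_k < config$sd_threshold && imf_condition_ok(h)) break
    }
    imfs[[k]] <- h
    r <- r - h
  }
  imf_set(imfs, residue = r, source_length = length(x))
}

imf_set <- function(imfs, residue, source_length) {
  structure(list(imfs = imfs, residue = residue,
                 source_length = as.integer(source_length)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residue, %d samples\n",
              length(x$imfs), x$source_length))
  invisible(x)
}

#' Number of IMFs in a decomposition
#' @param x an `imf_set`.
#' @export
n_imfs <- function(x) length(x$imfs)

#' Reconstruct the signal from an IMF set
#' @param x an `imf_set`.
#' @param with_residue add the residue (default `TRUE`).
#' @return numeric vector of length `source_length`.
#' @export
reconstruct <- function(x, with_residue = TRUE) {
  out <- if (length(x$imfs)) Reduce(`+`, x$imfs) else numeric(x$source_length)
  if (with_residue) out <- out + x$residue
  out
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` copies of the signal, each perturbed
#' with fresh Gaussian white noise of standard deviation
#' `noise_fraction * sd(x)`, and averages the IMFs index-wise across
#' members. Members with fewer IMFs than the deepest member are padded
#' with zero series before averaging, so the output IMF count equals the
#' maximum member count. The residue is defined as the input minus the
#' sum of the averaged IMFs. Fully reproducible from `config$seed`.
#'
#' @inheritParams emd
#' @return an `imf_set`; note that unlike plain EMD the averaged IMFs do
#'   not sum exactly to the input (the gap shrinks roughly as
#'   1/sqrt(ensemble_size)).
#' @export
eemd <- function(x, config = sift_config()) {
  x <- as.vector(x)
  stopifnot_finite(x, "signal")
  noise_sd <- config$noise_fraction * stats::sd(x)
  n <- length(x)
  member_imfs <- vector("list", config$ensemble_size)
  for (e in seq_len(config$ensemble_size)) {
    set.seed(child_seed(config$seed, e))
    member_imfs[[e]] <- emd(x + stats::rnorm(n, sd = noise_sd), config)$imfs
  }
  L <- max(vapply(member_imfs, length, integer(1)))
  if (L == 0) return(imf_set(list(), residue = x, source_length = n))
  zero <- numeric(n)
  imfs <- lapply(seq_len(L), function(i) {
    acc <- zero
    for (m in member_imfs) acc <- acc + (if (i <= length(m)) m[[i]] else zero)
    acc / config$ensemble_size
  })
  imf_set(imfs, residue = x - Reduce(`+`, imfs), source_length = n)
}
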