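# Daubechies-4 (four vanishing moments, 8-tap) scaling filter.
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)
# Quadrature-mirror wavelet filter g[k] = (-1)^k h[L-1-k].
DB4_G <- rev(DB4_H) * (-1)^(seq_along(DB4_H) - 1)

# One level of the periodized decimated wavelet transform.
dwt_step <- function(x, h = DB4_H, g = DB4_G) {
  n <- length(x)
  L <- length(h)
  idx <- outer(seq(1L, n, by = 2L), 0:(L - 1), `+`)
  idx <- (idx - 1L) %% n + 1L
  xm <- matrix(x[idx], ncol = L)
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

idwt_step <- function(a, d, h = DB4_H, g = DB4_G) {
  n2 <- 2L * length(a)
  L <- length(h)
  x <- numeric(n2)
  for (k in seq_along(a)) {
    pos <- ((2L * (k - 1L) + 0:(L - 1)) %% n2) + 1L
    x[pos] <- x[pos] + a[k] * h + d[k] * g
  }
  x
}

#' Three-level db4 wavelet subband decomposition
#'
#' The discrete-wavelet baseline against which the EMD/EEMD approaches
#' are compared: a 3-level periodized pyramid with the Daubechies-4 (db4)
#' mother wavelet. Features are computed on the coefficient vectors of
#' the three detail subbands D1-D3 and the level-3 approximation A3.
#' The transform is orthogonal, so the coefficients conserve energy and
#' [idwt_subbands()] reconstructs the input to floating-point accuracy.
#'
#' @param x numeric vector; length must be divisible by 8 (three halvings)
#'   and at least 8 samples per retained subband.
#' @return an object of class `subband_set`: list with `details` (list
#'   D1, D2, D3), `approximation` (A3), `wavelet_name`, `source_length`.
#' @export
#' @examples
#' x <- rnorm(256)
#' sb <- dwt_subbands(x)
#' sum(sapply(sb$details, function(d) sum(d^2))) +
#'   sum(sb$approximation^2) - sum(x^2)  # ~ 0, orthogonality
dwt_subbands <- function(x) {
  x <- as.vector(x)
  n <- length(x)
  if (n %% 8L != 0L || n < 64L)
    stop("series length must be a multiple of 8 and >= 64 for 3 levels")
  details <- vector("list", 3L)
  a <- x
  for (lev in 1:3) {
    s <- dwt_step(a)
    details[[lev]] <- s$d
    a <- s$a
  }
  names(details) <- c("D1", "D2", "D3")
  structure(list(details = details, approximation = a,
                 wavelet_name = "db4", source_length = n),
            class = "subband_set")
}

#' Inverse of [dwt_subbands()]
#' @param sb a `subband_set`.
#' @return the reconstructed series.
#' @export
idwt_subbands <- function(sb) {
  a <- sb$approximation
  for (lev in 3:1) a <- idwt_step(a, sb$details[[lev]])
  a
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %s, D1-D3 + A3 from %d samples\n",
              x$wavelet_name, x$source_length))
  invisible(x)
}

# Uniform access to the component list of a decomposition.
decomposition_components <- function(obj) {
  if (inherits(obj, "imf_set")) {
    comps <- obj$imfs
    names(comps) <- paste0("IMF", seq_along(comps))
  } else if (inherits(obj, "subband_set")) {
    comps <- c(list(A3 = obj$approximation), obj$details)
  } else stop("unsupported decomposition object")
  comps
}
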