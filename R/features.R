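#' Time-domain features
#'
#' Energy, mean, skewness and kurtosis of a series. Moments are
#' population moments (divisor N); skewness is `m3 / m2^(3/2)` and
#' kurtosis `m4 / m2^2` (not excess, so a Gaussian gives ~3).
#'
#' @param x numeric vector, length >= 2.
#' @return named numeric vector `c(energy, mean, skewness, kurtosis)`;
#'   skewness and kurtosis are `NA` for a zero-variance series.
#' @export
#' @examples
#' time_features(c(1, 2, 3, 4))
time_features <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  out <- c(energy = sum(abs(x)^2), mean = mu,
           skewness = NA_real_, kurtosis = NA_real_)
  if (m2 > 0) {
    out["skewness"] <- mean((x - mu)^3) / m2^1.5
    out["kurtosis"] <- mean((x - mu)^4) / m2^2
  }
  out
}

#' Two-sided periodogram
#'
#' Power spectral density estimate `S(w_k) = |X(w_k)|^2 / N` on the full
#' DFT grid `w_k = 2*pi*k/N`, `k = 0..N-1`, rectangular window. By
#' Parseval's theorem the total power equals the time-domain energy.
#'
#' @param x numeric vector, length >= 2.
#' @return object of class `spectrum_est`: list with `power`, `omega`
#'   (radians/sample) and `total`.
#' @export
periodogram <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  p <- Mod(stats::fft(x))^2 / n
  structure(list(power = p, omega = 2 * pi * (0:(n - 1)) / n,
                 total = sum(p)),
            class = "spectrum_est")
}

#' @export
print.spectrum_est <- function(x, ...) {
  cat(sprintf("<spectrum_est> %d bins, total power %.6g\n",
              length(x$power), x$total))
  invisible(x)
}

# Mean power of the two-sided periodogram inside a frequency band [lo, hi] Hz.
band_power <- function(x, fs, lo, hi) {
  sp <- periodogram(x)
  f <- sp$omega / (2 * pi) * fs
  f <- pmin(f, fs - f)                 # fold to physical frequency
  sel <- f >= lo & f <= hi
  mean(sp$power[sel])
}

#' Spectral features
#'
#' Total power, first three spectral moments and spectral entropy of the
#' two-sided periodogram. The moments are `M_j = sum(w_k^j * S(w_k))`;
#' the entropy is the Shannon entropy (bits) of the normalized power
#' distribution `P(w_k) = S(w_k)/S_T`, with `0*log(0)` taken as 0.
#'
#' @param x numeric vector.
#' @return named numeric vector
#'   `c(total_power, moment1, moment2, moment3, spectral_entropy)`;
#'   entropy is `NA` for an all-zero series.
#' @export
spectral_features <- function(x) {
  sp <- periodogram(x)
  st <- sp$total
  mj <- vapply(1:3, function(j) sum(sp$omega^j * sp$power), numeric(1))
  h <- NA_real_
  if (st > 0) {
    p <- sp$power / st
    nz <- p > 0
    h <- -sum(p[nz] * log2(p[nz]))
  }
  c(total_power = st, moment1 = mj[1], moment2 = mj[2], moment3 = mj[3],
    spectral_entropy = h)
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Classic Hurst analysis: for each of about `n_scales` logarithmically
#' spaced window sizes m between `min_window` and N/2, the series is cut
#' into non-overlapping windows; in each window the range of the
#' cumulative deviations from the window mean is divided by the window
#' standard deviation (divisor m), and the mean of log(R/S) across
#' windows is regressed on log(m). The slope is the Hurst exponent:
#' ~0.5 for uncorrelated noise, above 0.5 for persistent (long-range
#' correlated) series, below 0.5 for anti-persistent series.
#'
#' @param x numeric vector, length >= 64.
#' @param n_scales target number of window sizes.
#' @param min_window smallest window size.
#' @return the estimated Hurst exponent (`NA` if fewer than 3 usable
#'   scales survive, e.g. for a constant series).
#' @export
hurst_exponent <- function(x, n_scales = 10, min_window = 8) {
  n <- length(x)
  if (n < 64) stop("need at least 64 samples")
  ms <- unique(round(exp(seq(log(min_window), log(n / 2),
                             length.out = n_scales))))
  log_rs <- rep(NA_real_, length(ms))
  for (i in seq_along(ms)) {
    m <- ms[i]
    k <- floor(n / m)
    vals <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      w <- x[((j - 1) * m + 1):(j * m)]
      mu <- mean(w)
      s <- sqrt(mean((w - mu)^2))
      if (s == 0) next
      xa <- cumsum(w - mu)
      vals[j] <- (max(xa) - min(xa)) / s
    }
    if (any(!is.na(vals))) log_rs[i] <- mean(log(vals), na.rm = TRUE)
  }
  ok <- !is.na(log_rs)
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(stats::lm(log_rs[ok] ~ log(ms[ok])))[2])
}

#' Higuchi fractal dimension
#'
#' Builds, for every lag k = 1..`k_max` and offset m = 1..k, the
#' decimated subseries X[m], X[m+k], X[m+2k], ... and its normalized
#' curve length
#' `L[m,k] = (sum |X[m+ik] - X[m+(i-1)k]|) * (N-1) / (floor((N-m)/k) * k^2)`,
#' averages over offsets to get L[k], and returns the slope of
#' log(L[k]) versus log(1/k). Smooth curves give ~1, Brownian paths
#' ~1.5, uncorrelated noise ~2.
#'
#' @param x numeric vector with `length(x) > 2 * k_max`.
#' @param k_max largest lag; 30 is where the estimate saturates on
#'   one-minute 100 Hz EEG segments.
#' @return the estimated fractal dimension.
#' @export
higuchi_fd <- function(x, k_max = 30) {
  n <- length(x)
  if (k_max < 2) stop("k_max must be >= 2")
  if (n <= 2 * k_max) stop("series too short for this k_max")
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lmk <- numeric(k)
    for (m in seq_len(k)) {
      i_max <- floor((n - m) / k)
      if (i_max < 1) { lmk[m] <- NA_real_; next }
      idx <- m + (0:i_max) * k
      lmk[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (i_max * k) / k
    }
    lk[k] <- mean(lmk, na.rm = TRUE)
  }
  unname(coef(stats::lm(log(lk) ~ log(1 / seq_len(k_max))))[2])
}

# Feature-group extractors keyed by group name.
feature_group_funs <- list(
  time = function(x) time_features(x),
  spectral = function(x) spectral_features(x),
  nonlinear = function(x) c(hurst = hurst_exponent(x),
                            higuchi_fd = higuchi_fd(x))
)

#' Assemble a labeled feature table
#'
#' Computes the requested feature groups on the chosen components of
#' every segment and binds them into a segments x features matrix with
#' component-major, feature-minor column order. Components may be
#' selected IMFs of a per-segment decomposition, the four db4 subbands,
#' or the raw segment itself.
#'
#' @param segments list of single-channel [eeg_epoch()] objects.
#' @param components `"imf"`, `"dwt"` or `"raw"`.
#' @param groups character subset of `c("time", "spectral", "nonlinear")`.
#' @param decompositions for `components = "imf"`: list of `imf_set`
#'   objects parallel to `segments` (precomputed, so selection and
#'   feature extraction reuse one decomposition run).
#' @param selected integer vector of IMF indices (priority order) for
#'   `components = "imf"`.
#' @return object of class `feature_table`: list with `values` (numeric
#'   matrix), `feature_names`, `labels`, `row_meta`, and `dropped`
#'   (indices of segments excluded because a feature was undefined or a
#'   selected component was missing).
#' @export
build_feature_table <- function(segments,
                                components = c("imf", "dwt", "raw"),
                                groups = c("time", "spectral", "nonlinear"),
                                decompositions = NULL, selected = 1:3) {
  components <- match.arg(components)
  groups <- match.arg(groups, c("time", "spectral", "nonlinear"),
                      several.ok = TRUE)
  if (components == "imf") {
    if (is.null(decompositions) || length(decompositions) != length(segments))
      stop("components = 'imf' needs one precomputed decomposition per segment")
  }
  rows <- vector("list", length(segments))
  meta <- vector("list", length(segments))
  dropped <- integer(0)
  feature_names <- NULL
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    x <- as.vector(seg$data[1, ])
    comps <- switch(components,
      raw = list(EEG = x),
      dwt = decomposition_components(dwt_subbands(x)),
      imf = {
        imfs <- decompositions[[si]]$imfs
        if (max(selected) > length(imfs)) {
          warning(sprintf("segment %d has %d IMFs; selected index %d missing - row dropped",
                          si, length(imfs), max(selected)))
          dropped <- c(dropped, si)
          next
        }
        stats::setNames(imfs[selected], paste0("IMF", selected))
      })
    vals <- unlist(lapply(names(comps), function(cn) {
      v <- unlist(lapply(groups, function(g) feature_group_funs[[g]](comps[[cn]])))
      stats::setNames(v, paste(cn, names(v), sep = "_"))
    }))
    if (anyNA(vals)) {
      warning(sprintf("segment %d has undefined features - row dropped", si))
      dropped <- c(dropped, si)
      next
    }
    rows[[si]] <- vals
    if (is.null(feature_names)) feature_names <- names(vals)
    meta[[si]] <- data.frame(subject = seg$subject_id, channel = seg$channel_names[1],
                             epoch = seg$label, stringsAsFactors = FALSE)
  }
  keep <- setdiff(seq_along(segments), dropped)
  values <- do.call(rbind, rows[keep])
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = vapply(segments[keep], function(s) s$label, ""),
                 row_meta = do.call(rbind, meta[keep]),
                 dropped = dropped),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d segments x %d features (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  invisible(x)
}
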