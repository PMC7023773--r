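#' Generator configuration for synthetic epileptic EEG
#'
#' Bundles the dimensions and class-separation settings of the synthetic
#' pre-seizure/seizure EEG generator. The defaults emulate the clinical
#' recording setup the package targets: 16 subjects, the 10 temporal- and
#' frontal-lobe-weighted bipolar channels, 100 Hz sampling and one-minute
#' epochs.
#'
#' `effect_size` scales the amplitude of the seizure-band (3-5 Hz) rhythmic
#' component added to seizure epochs; at 0 the two classes are drawn from
#' identical distributions.
#'
#' @param n_subjects number of simulated subjects (>= 1).
#' @param n_channels number of EEG channels per epoch.
#' @param fs sampling rate in Hz.
#' @param duration epoch length in seconds.
#' @param effect_size nonnegative multiplier on the seizure-band amplitude.
#' @param seed master integer seed; all randomness derives from it.
#' @return an object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 2, seed = 1)
#' epoch <- generate_epoch("seizure", cfg, subject_index = 1)
#' dim(epoch$data)
generator_config <- function(n_subjects = 16, n_channels = 10, fs = 100,
                             duration = 60, effect_size = 3, seed = 1) {
  stopifnot(n_subjects >= 1, n_channels >= 1, fs > 0, duration > 0,
            effect_size >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 fs = fs, duration = duration,
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "generator_config")
}

#' Standard channel names of the ten-channel montage
#'
#' The ten temporal- and frontal-lobe-weighted bipolar derivations used
#' throughout: five left-hemisphere channels followed by five
#' right-hemisphere channels. Beyond 10 channels, generic `chNN` names are
#' appended.
#'
#' @param n number of channel names wanted.
#' @return character vector of length `n`.
#' @export
eeg_channel_names <- function(n = 10) {
  full <- c("Fp1-F7", "F7-T1", "T1-T3", "T3-T5", "Fp1-F3",
            "Fp2-F8", "F8-T2", "T2-T4", "T4-T6", "Fp2-F4")
  if (n <= 10) full[seq_len(n)] else c(full, paste0("ch", 11:n))
}

#' Construct a labeled EEG epoch
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate (Hz).
#' @param label class label, `"pre_seizure"` or `"seizure"`.
#' @param subject_id subject identifier token.
#' @param channel_names character vector, one name per row of `data`.
#' @return an object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, label, subject_id = "S1",
                      channel_names = NULL) {
  data <- rbind(data)
  label <- match.arg(label, c("pre_seizure", "seizure"))
  if (fs <= 0) stop("fs must be positive")
  stopifnot_finite(data, "epoch data")
  channel_names <- channel_names %||% eeg_channel_names(nrow(data))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal the number of channels")
  structure(list(data = data, fs = fs, label = label,
                 subject_id = subject_id, channel_names = channel_names),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s, subject %s: %d channel(s) x %d samples @ %g Hz\n",
              x$label, x$subject_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# 1/f-shaped background noise via spectral shaping of white noise
# (amplitude ~ f^(-exponent/2), i.e. power ~ 1/f), unit standard deviation.
pink_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)          # two-sided frequency index
  shape <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic multichannel EEG epoch
#'
#' Pre-seizure epochs are 1/f-shaped broadband background plus a 10 Hz
#' alpha oscillation. Seizure epochs share the same background and alpha
#' content and add a high-amplitude rhythmic 4 Hz component with an 8 Hz
#' harmonic, scaled by `config$effect_size`. Each channel receives an
#' independent amplitude jitter and phase so channels are distinct but
#' class-consistent.
#'
#' @param label `"pre_seizure"` or `"seizure"`.
#' @param config a [generator_config()].
#' @param subject_index 1-based subject number.
#' @param epoch_seed optional integer seed overriding the seed derived
#'   from `config$seed` and `subject_index`.
#' @return an [eeg_epoch()] with `n_channels x fs*duration` data.
#' @export
generate_epoch <- function(label, config, subject_index = 1,
                           epoch_seed = NULL) {
  label <- match.arg(label, c("pre_seizure", "seizure"))
  stopifnot(inherits(config, "generator_config"))
  n <- round(config$fs * config$duration)
  tt <- (seq_len(n) - 1) / config$fs
  label_code <- if (label == "seizure") 2L else 1L
  base_seed <- epoch_seed %||%
    child_seed(config$seed, subject_index, label_code)
  data <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    set.seed(child_seed(base_seed, ch))
    bg <- 20 * pink_noise(n)
    jit <- stats::runif(1, 0.8, 1.2)
    alpha <- 10 * jit * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
    x <- bg + alpha
    if (label == "seizure") {
      amp <- 10 * config$effect_size * stats::runif(1, 0.8, 1.2)
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + amp * sin(2 * pi * 4 * tt + ph) +
        0.5 * amp * sin(2 * pi * 8 * tt + 2 * ph)
    }
    data[ch, ] <- x
  }
  eeg_epoch(data, config$fs, label,
            subject_id = sprintf("S%02d", subject_index),
            channel_names = eeg_channel_names(config$n_channels))
}

#' Generate the full synthetic pre-seizure/seizure dataset
#'
#' Produces one pre-seizure and one seizure epoch per subject and flattens
#' every channel into an independent labeled single-channel segment, the
#' unit on which decomposition, IMF selection and classification operate.
#' With the default configuration (16 subjects, 10 channels) this yields
#' 320 segments, 160 per class.
#'
#' @param config a [generator_config()].
#' @return list of single-channel [eeg_epoch()] segments; each retains its
#'   subject and channel identity for the hemisphere summary.
#' @export
#' @examples
#' segs <- generate_dataset(generator_config(n_subjects = 1, seed = 7))
#' length(segs)  # 1 subject x 10 channels x 2 classes = 20
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  segments <- vector("list", config$n_subjects * config$n_channels * 2L)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (label in c("pre_seizure", "seizure")) {
      ep <- generate_epoch(label, config, subject_index = s)
      for (ch in seq_len(config$n_channels)) {
        i <- i + 1L
        segments[[i]] <- eeg_epoch(ep$data[ch, , drop = FALSE], ep$fs, label,
                                   subject_id = ep$subject_id,
                                   channel_names = ep$channel_names[ch])
      }
    }
  }
  segments
}

# Autocovariance of fractional Gaussian noise with Hurst index H at lag h.
fgn_acov <- function(h, hurst) {
  0.5 * (abs(h + 1)^(2 * hurst) - 2 * abs(h)^(2 * hurst) +
           abs(h - 1)^(2 * hurst))
}

#' Generate exact fractional Gaussian noise
#'
#' Circulant-embedding (Davies-Harte) synthesis: the target autocovariance
#' sequence is embedded in a circulant matrix whose eigenvalues are
#' obtained by FFT, so the sample paths have exactly the fGn second-order
#' structure. `hurst = 0.5` degenerates to i.i.d. Gaussian white noise.
#' Used as the reference process when validating the rescaled-range Hurst
#' estimator.
#'
#' @param hurst Hurst index, strictly between 0 and 1.
#' @param n series length (>= 2).
#' @param seed integer seed.
#' @return numeric vector of length `n`, zero mean and unit variance in
#'   distribution.
#' @export
generate_fgn <- function(hurst, n, seed = 1) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie strictly in (0, 1)")
  if (n < 2) stop("n must be >= 2")
  set.seed(as.integer(seed))
  m <- 2L * n
  g <- fgn_acov(0:n, hurst)
  circ <- c(g[1:n], g[n + 1], rev(g[2:n]))
  lam <- Re(stats::fft(circ))
  lam[lam < 0] <- 0            # guard tiny negative rounding
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  w <- stats::fft(sqrt(lam) * z)
  Re(w[1:n]) / sqrt(m)
}
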