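test_that("time-domain features match hand-computed population moments", {
  f <- time_features(c(1, 2, 3, 4))
  expect_equal(unname(f["energy"]), 30)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 2.5625 / 1.25^2)  # m4 / m2^2 = 1.64
  fc <- time_features(rep(3, 10))
  expect_equal(unname(fc["energy"]), 90)
  expect_equal(unname(fc["mean"]), 3)
  expect_true(is.na(fc["skewness"]) && is.na(fc["kurtosis"]))
})

test_that("periodogram satisfies Parseval and known closed forms", {
  # constant series: all power at DC
  p <- periodogram(rep(2, 16))
  expect_equal(p$power[1], 16 * 4)
  expect_lt(max(p$power[-1]), 1e-12)
  # on-grid cosine splits power between conjugate bins
  n <- 64; k0 <- 5
  x <- cos(2 * pi * k0 * (0:(n - 1)) / n)
  p2 <- periodogram(x)
  expect_equal(p2$power[k0 + 1], p2$power[n - k0 + 1], tolerance = 1e-9)
  expect_equal(sum(p2$power[c(k0 + 1, n - k0 + 1)]), p2$total,
               tolerance = 1e-9)
  # Parseval on random data
  set.seed(2)
  xr <- rnorm(100)
  expect_equal(periodogram(xr)$total, sum(xr^2), tolerance = 1e-8)
})

test_that("spectral features match a direct bin-loop oracle", {
  # constant: zero moments and zero entropy
  s <- spectral_features(rep(1, 32))
  expect_equal(unname(s[c("moment1", "moment2", "moment3")]), c(0, 0, 0))
  expect_equal(unname(s["spectral_entropy"]), 0)
  # on-grid cosine: two equal masses, one bit of entropy
  n <- 64
  x <- cos(2 * pi * 5 * (0:(n - 1)) / n)
  expect_equal(unname(spectral_features(x)["spectral_entropy"]), 1,
               tolerance = 1e-9)
  # random series vs independent loop
  set.seed(4)
  xr <- rnorm(64)
  X <- fft(xr)
  S <- Mod(X)^2 / 64
  w <- 2 * pi * (0:63) / 64
  st <- 0; m <- c(0, 0, 0); h <- 0
  for (k in 1:64) st <- st + S[k]
  for (j in 1:3) for (k in 1:64) m[j] <- m[j] + w[k]^j * S[k]
  for (k in 1:64) if (S[k] > 0) h <- h - S[k] / st * log2(S[k] / st)
  got <- spectral_features(xr)
  expect_equal(unname(got), c(st, m, h), tolerance = 1e-9)
})

test_that("entropy is bounded and scale behaviour is as expected", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(128)
    h <- spectral_features(x)["spectral_entropy"]
    expect_gte(unname(h), 0)
    expect_lte(unname(h), log2(128))
  }
  x <- rnorm(512)
  c_ <- 2.3
  expect_equal(time_features(c_ * x)["energy"],
               c_^2 * time_features(x)["energy"])
  expect_equal(spectral_features(c_ * x)["total_power"],
               c_^2 * spectral_features(x)["total_power"])
  expect_equal(time_features(c_ * x)[c("skewness", "kurtosis")],
               time_features(x)[c("skewness", "kurtosis")], tolerance = 1e-10)
  expect_equal(hurst_exponent(c_ * x), hurst_exponent(x), tolerance = 1e-9)
  expect_equal(higuchi_fd(c_ * x), higuchi_fd(x), tolerance = 1e-9)
})

test_that("the Hurst estimator recovers known exponents", {
  he_wn <- mean(vapply(1:10, function(s) {
    set.seed(s); hurst_exponent(rnorm(6000))
  }, numeric(1)))
  expect_lt(abs(he_wn - 0.5), 0.05)
  he_fgn <- mean(vapply(1:10, function(s)
    hurst_exponent(generate_fgn(0.8, 4096, s)), numeric(1)))
  expect_lt(abs(he_fgn - 0.8), 0.1)
  expect_gte(hurst_exponent(seq_len(2000) + 0), 0.9)
  # strictly increasing in the generator's H
  means <- vapply(c(0.2, 0.5, 0.8), function(H)
    mean(vapply(1:10, function(s) hurst_exponent(generate_fgn(H, 2048, s)),
                numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(is.na(hurst_exponent(rep(1, 128))))
})

test_that("Higuchi dimension hits the known limits", {
  expect_equal(higuchi_fd(seq_len(2000) * 1.0), 1, tolerance = 0.05)
  fd_wn <- mean(vapply(1:10, function(s) {
    set.seed(s); higuchi_fd(rnorm(2000))
  }, numeric(1)))
  expect_gte(fd_wn, 1.9); expect_lte(fd_wn, 2.05)
  fd_rw <- mean(vapply(1:10, function(s) {
    set.seed(s); higuchi_fd(cumsum(rnorm(2000)))
  }, numeric(1)))
  expect_lt(abs(fd_rw - 1.5), 0.1)
  expect_error(higuchi_fd(rnorm(50), k_max = 30))
})

test_that("feature tables have the documented shapes", {
  segs <- small_dataset()[1:4]
  decs <- small_decomps()[1:4]
  ft_t <- build_feature_table(segs, "imf", "time", decompositions = decs)
  expect_equal(dim(ft_t$values), c(4, 12))    # 3 IMFs x 4 features
  ft_s <- build_feature_table(segs, "imf", "spectral", decompositions = decs)
  expect_equal(ncol(ft_s$values), 15)
  ft_n <- build_feature_table(segs, "imf", "nonlinear", decompositions = decs)
  expect_equal(ncol(ft_n$values), 6)
  ft_d <- build_feature_table(segs, "dwt", "spectral")
  expect_equal(ncol(ft_d$values), 20)         # 4 subbands x 5 features
  ft_r <- build_feature_table(segs[1], "raw", "nonlinear")
  expect_equal(dim(ft_r$values), c(1, 2))
  # Parseval ties the time-domain energy to the spectral total power
  expect_equal(unname(ft_s$values[, "IMF1_total_power"]),
               unname(ft_t$values[, "IMF1_energy"]), tolerance = 1e-8)
  # column order is component-major
  expect_equal(ft_t$feature_names[1:4],
               paste0("IMF1_", c("energy", "mean", "skewness", "kurtosis")))
})

test_that("segments with missing selected IMFs are dropped with a warning", {
  segs <- small_dataset()[1:3]
  decs <- small_decomps()[1:3]
  # request an IMF index beyond what any segment produced
  too_deep <- max(vapply(decs, n_imfs, integer(1))) + 1L
  expect_warning(build_feature_table(segs[1], "imf", "time",
                                     decompositions = decs[1],
                                     selected = c(1, too_deep)))
  ft <- suppressWarnings(
    build_feature_table(segs, "imf", "time", decompositions = decs,
                        selected = c(1, too_deep)))
  expect_equal(length(ft$dropped), 3)
})
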