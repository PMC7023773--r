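test_that("selection metrics reproduce their defining formulas", {
  expect_equal(imf_energy(c(1, 2, 3)), 14)
  expect_equal(imf_energy(numeric(5)), 0)
  set.seed(1)
  x <- rnorm(100)
  expect_equal(imf_energy(x), sum(x * x))

  expect_equal(imf_correlation(x, x), 1)
  expect_equal(imf_correlation(x, -x), -1)
  y <- rnorm(100)
  # two-pass cross-covariance / (sd * sd) oracle
  oracle <- mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(imf_correlation(x, y), oracle, tolerance = 1e-12)
  expect_warning(v <- imf_correlation(x, rep(1, 100)))
  expect_identical(v, -Inf)

  expect_equal(psd_distance(x, x), 0)
  # halving the IMF scales its PSD by 1/4 in every bin: distance = N ln 4
  expect_equal(psd_distance(x, x / 2), 100 * log(4), tolerance = 1e-9)
  # bin-by-bin oracle on a random pair
  x128 <- rnorm(128); y128 <- rnorm(128)
  sx <- periodogram(x128)$power; sy <- periodogram(y128)$power
  dis <- sum(log(pmax(sx, 1e-12 * max(sx)) / pmax(sy, 1e-12 * max(sy))))
  expect_equal(psd_distance(x128, y128), dis, tolerance = 1e-9)

  # t statistic on a fixed 5-point series, hand computation
  s5 <- c(0.3, -0.1, 0.4, 0.2, -0.2)
  tstat <- mean(s5) / (sd(s5) / sqrt(5))
  expect_equal(as.numeric(imf_pvalue(s5)), 2 * pt(-abs(tstat), df = 4),
               tolerance = 1e-12)
  expect_lt(as.numeric(imf_pvalue(rnorm(200) + 5)), 1e-6)
})

test_that("null-distribution of the IMF p-value is approximately uniform", {
  set.seed(7)
  ps <- vapply(1:200, function(i) as.numeric(imf_pvalue(rnorm(1000))),
               numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})

test_that("rank_components sorts stably with lower-index tie-breaks", {
  expect_equal(rank_components(c(4, 1, 9), "descending")$order, c(3, 1, 2))
  expect_equal(rank_components(rep(2, 5), "descending")$order, 1:5)
  expect_equal(rank_components(rep(2, 5), "ascending")$order, 1:5)
  set.seed(3)
  sc <- rnorm(12)
  expect_equal(rank_components(sc, "descending")$order, order(-sc))
  expect_equal(rank_components(sc, "ascending")$order, order(sc))
})

test_that("ranking matrix has 4 padded rows per segment and correct counts", {
  segs <- small_dataset()          # 1 subject x 10 channels x 2 epochs
  rm_ <- build_ranking_matrix(segs, "emd", decompositions = small_decomps())
  expect_equal(dim(rm_$rows), c(80, 16))  # 40 metric rows per epoch pair
  expect_equal(unname(table(rm_$row_meta$metric)), array(rep(20L, 4)))
  # per-row padding: sentinel zeros only after a permutation prefix
  for (r in sample(nrow(rm_$rows), 10)) {
    row <- rm_$rows[r, ]
    L <- sum(row != 0)
    expect_setequal(row[seq_len(L)], seq_len(L))
    expect_true(all(row[-seq_len(L)] == 0))
  }
})

test_that("consensus_select counts first-priority indices exactly", {
  fake <- structure(list(rows = cbind(c(1, 1, 3, 2, 1, 3),
                                      matrix(0, 6, 15))),
                    class = "ranking_matrix")
  sel <- consensus_select(fake, k = 3)
  expect_equal(sel$selected, c(1, 3, 2))
  expect_equal(unname(sel$histogram), c(3L, 1L, 2L))
  expect_equal(sum(sel$histogram), 6)
  # all rows starting with the same index
  fake1 <- structure(list(rows = cbind(rep(1, 4), matrix(0, 4, 15))),
                     class = "ranking_matrix")
  expect_equal(consensus_select(fake1, k = 1)$selected, 1)
  # exhaustive counting oracle on a random first column
  set.seed(5)
  col <- sample(1:6, 200, replace = TRUE)
  fake2 <- structure(list(rows = cbind(col, matrix(0, 200, 15))),
                     class = "ranking_matrix")
  sel2 <- consensus_select(fake2, k = 3)
  counts <- sapply(1:6, function(i) sum(col == i))
  expect_equal(sel2$selected, order(-counts, 1:6)[1:3])
  expect_warning(consensus_select(fake1, k = 5))
})

test_that("rankings are equivariant under IMF permutation and amplitude scale", {
  set.seed(9)
  x <- rnorm(256)
  d <- emd(x)
  L <- n_imfs(d)
  skip_if(L < 3)
  perm <- sample(L)
  score_sets <- function(imfs) list(
    e = vapply(imfs, imf_energy, numeric(1)),
    r = vapply(imfs, function(im) imf_correlation(x, im), numeric(1)),
    d = vapply(imfs, function(im) psd_distance(x, im), numeric(1)),
    p = vapply(imfs, function(im) as.numeric(imf_pvalue(im)), numeric(1)))
  s0 <- score_sets(d$imfs)
  s1 <- score_sets(d$imfs[perm])
  for (nm in names(s0)) expect_equal(s1[[nm]], s0[[nm]][perm])
  # scaling signal and IMFs jointly: correlation/p-value/psd unchanged,
  # energies scale by c^2 so the energy ranking is unchanged
  c_ <- 3.7
  xs <- c_ * x
  imfs_s <- lapply(d$imfs, function(im) c_ * im)
  expect_equal(vapply(imfs_s, function(im) imf_correlation(xs, im), numeric(1)),
               s0$r, tolerance = 1e-10)
  expect_equal(vapply(imfs_s, function(im) psd_distance(xs, im), numeric(1)),
               s0$d, tolerance = 1e-8)
  expect_equal(vapply(imfs_s, function(im) as.numeric(imf_pvalue(im)), numeric(1)),
               s0$p, tolerance = 1e-10)
  expect_equal(rank_components(vapply(imfs_s, imf_energy, numeric(1)),
                               "descending")$order,
               rank_components(s0$e, "descending")$order)
})

test_that("the selector returns three distinct IMFs deterministically", {
  segs <- small_dataset()
  rm_ <- build_ranking_matrix(segs, "emd", decompositions = small_decomps())
  sel1 <- consensus_select(rm_, k = 3)
  sel2 <- consensus_select(rm_, k = 3)
  expect_identical(sel1, sel2)
  expect_length(unique(sel1$selected), 3)
})
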