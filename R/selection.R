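#' Per-IMF selection metrics
#'
#' The four metrics of the hybrid IMF-selection procedure. Each scores a
#' candidate IMF against the signal it was extracted from:
#'
#' * `imf_energy()`: sum of squared samples; high energy ranks first.
#' * `imf_correlation()`: Pearson correlation with the source signal;
#'   high correlation ranks first.
#' * `psd_distance()`: Kullback-Leibler-style log-ratio distance between
#'   the periodogram of the signal and that of the IMF, summed over the
#'   full two-sided frequency grid; low distance ranks first.
#' * `imf_pvalue()`: two-sided one-sample t-test p-value of mean zero
#'   (IMFs are nominally zero-mean oscillations); high p-value ranks
#'   first.
#'
#' @param imf numeric vector, one intrinsic mode function.
#' @param x numeric vector, the source signal (same length as `imf`).
#' @return a single numeric score.
#' @name imf_metrics
NULL

#' @rdname imf_metrics
#' @export
imf_energy <- function(imf) sum(abs(imf)^2)

#' @rdname imf_metrics
#' @export
imf_correlation <- function(x, imf) {
  stopifnot(length(x) == length(imf))
  if (stats::sd(x) == 0 || stats::sd(imf) == 0) {
    warning("zero-variance input; correlation undefined, returning -Inf sentinel")
    return(-Inf)
  }
  stats::cor(x, imf)
}

#' @rdname imf_metrics
#' @param epsilon_factor floor applied to each periodogram, as a fraction
#'   of its maximum, before the bin-wise ratio.
#' @param symmetric if `TRUE`, use the standard spectrum-weighted
#'   symmetrized KL divergence instead of the plain log-ratio sum.
#' @export
psd_distance <- function(x, imf, epsilon_factor = 1e-12, symmetric = FALSE) {
  stopifnot(length(x) == length(imf))
  sx <- periodogram(x)$power
  si <- periodogram(imf)$power
  sx <- pmax(sx, epsilon_factor * max(sx))
  si <- pmax(si, epsilon_factor * max(si))
  if (symmetric) {
    px <- sx / sum(sx); pi_ <- si / sum(si)
    return(sum(px * log(px / pi_)) + sum(pi_ * log(pi_ / px)))
  }
  sum(log(sx / si))
}

#' @rdname imf_metrics
#' @param alpha significance level for the recorded h-value.
#' @export
imf_pvalue <- function(imf, alpha = 0.05) {
  if (length(imf) < 2) stop("need at least 2 samples for the t-test")
  if (stats::sd(imf) == 0) {
    warning("zero-variance IMF; p-value undefined, returning 0 sentinel")
    p <- 0
  } else {
    p <- stats::t.test(imf, mu = 0)$p.value
  }
  structure(p, h = as.integer(p < alpha))
}

#' Rank components by a score vector
#'
#' Stable ordering with ties broken in favour of the lower component
#' index, so equal scores keep natural IMF order.
#'
#' @param scores numeric vector, one score per component.
#' @param direction `"descending"` (energy, correlation, p-value) or
#'   `"ascending"` (PSD distance).
#' @param metric_name token recorded with the ranking.
#' @return object of class `imf_ranking`: list with `order` (component
#'   indices, best first), `scores`, `metric_name`.
#' @export
#' @examples
#' rank_components(c(4, 1, 9), "descending")$order  # 3 1 2
rank_components <- function(scores, direction = c("descending", "ascending"),
                            metric_name = "score") {
  direction <- match.arg(direction)
  stopifnot(length(scores) >= 1)
  key <- if (direction == "descending") -xtfrm(scores) else xtfrm(scores)
  ord <- order(key, seq_along(scores))
  structure(list(order = ord, scores = scores, metric_name = metric_name,
                 direction = direction),
            class = "imf_ranking")
}

# The four rankings of one decomposed segment, in fixed metric order.
rank_imf_set <- function(x, decomp) {
  comps <- decomp$imfs
  if (length(comps) == 0) stop("decomposition produced no IMFs")
  e <- vapply(comps, imf_energy, numeric(1))
  r <- vapply(comps, function(im) suppressWarnings(imf_correlation(x, im)),
              numeric(1))
  d <- vapply(comps, function(im) psd_distance(x, im), numeric(1))
  p <- vapply(comps, function(im) as.numeric(suppressWarnings(imf_pvalue(im))),
              numeric(1))
  list(energy = rank_components(e, "descending", "energy"),
       correlation = rank_components(r, "descending", "correlation"),
       psd_distance = rank_components(d, "ascending", "psd_distance"),
       p_value = rank_components(p, "descending", "p_value"))
}

#' Build the combined IMF ranking matrix of a dataset
#'
#' Decomposes every labeled segment, computes the four metric rankings
#' and stacks their order vectors as rows, padded to `config$max_imfs`
#' columns with the sentinel 0 where a segment produced fewer IMFs.
#' With 16 subjects, 10 channels and 2 epochs this yields the
#' 1280 x 16 ranking matrix (4 metric rows per segment).
#'
#' @param segments list of single-channel [eeg_epoch()] objects, e.g.
#'   from [generate_dataset()].
#' @param decomposer `"emd"` or `"eemd"`.
#' @param config a [sift_config()].
#' @param decompositions optional list of precomputed `imf_set` objects
#'   parallel to `segments`, to avoid decomposing twice when the same
#'   IMFs also feed feature extraction.
#' @return object of class `ranking_matrix`: list with `rows` (integer
#'   matrix), `row_meta` (data.frame subject, epoch, channel, metric).
#' @export
build_ranking_matrix <- function(segments, decomposer = c("emd", "eemd"),
                                 config = sift_config(),
                                 decompositions = NULL) {
  decomposer <- match.arg(decomposer)
  dec_fun <- if (decomposer == "emd") emd else eemd
  rows <- matrix(0L, nrow = 4L * length(segments), ncol = config$max_imfs)
  meta <- vector("list", 4L * length(segments))
  metric_names <- c("energy", "correlation", "psd_distance", "p_value")
  ri <- 0L
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    x <- as.vector(seg$data[1, ])
    dec <- if (!is.null(decompositions)) decompositions[[si]] else
      tryCatch(dec_fun(x, config), error = function(e)
      stop(sprintf("decomposition failed on segment %d (%s/%s): %s",
                   si, seg$subject_id, seg$channel_names[1],
                   conditionMessage(e))))
    rks <- rank_imf_set(x, dec)
    for (mn in metric_names) {
      ri <- ri + 1L
      ord <- rks[[mn]]$order
      rows[ri, seq_along(ord)] <- ord
      meta[[ri]] <- data.frame(subject = seg$subject_id, epoch = seg$label,
                               channel = seg$channel_names[1], metric = mn,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(rows = rows, row_meta = do.call(rbind, meta)),
            class = "ranking_matrix")
}

#' @export
print.ranking_matrix <- function(x, ...) {
  cat(sprintf("<ranking_matrix> %d rows x %d columns (4 metric rows per segment)\n",
              nrow(x$rows), ncol(x$rows)))
  invisible(x)
}

#' Histogram-consensus IMF selection
#'
#' Counts which IMF index each ranking row puts in first priority (the
#' first column of the ranking matrix) and selects the `k` most frequent
#' indices, ordered by descending count with ties broken by the lower
#' index. Padding sentinels (0) are ignored.
#'
#' @param matrix a `ranking_matrix` from [build_ranking_matrix()].
#' @param k number of IMFs to select (default 3).
#' @return object of class `selection_result`: list with `selected`
#'   (indices in priority order) and `histogram` (named count vector).
#' @export
consensus_select <- function(matrix, k = 3) {
  first <- matrix$rows[, 1]
  first <- first[first != 0L]
  counts <- table(factor(first, levels = sort(unique(first))))
  idx <- as.integer(names(counts))
  ord <- order(-as.integer(counts), idx)
  if (k > length(idx)) {
    warning(sprintf("only %d distinct first-priority IMFs observed; returning all",
                    length(idx)))
    k <- length(idx)
  }
  structure(list(selected = idx[ord][seq_len(k)],
                 histogram = stats::setNames(as.integer(counts),
                                             as.character(idx))),
            class = "selection_result")
}

#' Borda-count consensus over all ranking columns
#'
#' Alternative consensus that scores every column (a component in rank
#' position j contributes `max_imfs - j + 1` points), rather than only
#' the first-priority column. Off the default path; provided for
#' comparison.
#'
#' @inheritParams consensus_select
#' @export
borda_select <- function(matrix, k = 3) {
  w <- ncol(matrix$rows)
  scores <- numeric(max(matrix$rows))
  for (j in seq_len(w)) {
    col <- matrix$rows[, j]
    col <- col[col != 0L]
    for (i in col) scores[i] <- scores[i] + (w - j + 1)
  }
  ord <- order(-scores, seq_along(scores))
  structure(list(selected = ord[seq_len(min(k, sum(scores > 0)))],
                 histogram = stats::setNames(scores, seq_along(scores))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> selected IMFs (priority order):",
      paste0("IMF", x$selected, collapse = ", "), "\n")
  invisible(x)
}
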