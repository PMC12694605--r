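#' Graded ranking metrics at depth k
#'
#' `dcg_at_k()` computes the discounted cumulative gain
#' \eqn{\sum_{i=1}^{\min(k,n)} g_i / \log_2(i+1)} of gains taken in predicted
#' order (1-based ranks). `ndcg_at_k()` normalizes by the ideal DCG at the
#' same depth, computed over the full candidate list sorted by gain.
#' `recall_at_k()` is the fraction of relevant items (gain > 0) retrieved in
#' the top k; `precision_at_k()` is the fraction of the top k that is
#' relevant, where "relevant" means gain > 0 by default or gain = 2 only
#' (exact known pairs) with `relevant = "exact"`.
#'
#' @param g_ranked Gain vector in predicted rank order.
#' @param k Depth (>= 1).
#' @param relevant For `precision_at_k`: `"positive"` (gain > 0, default) or
#'   `"exact"` (gain = 2 only).
#' @return A scalar; NDCG, recall and precision lie in \[0, 1\].
#' @export
dcg_at_k <- function(g_ranked, k) {
  if (k < 1) abort("k must be >= 1")
  dcg_trunc(g_ranked, k)
}

#' @rdname dcg_at_k
#' @export
ndcg_at_k <- function(g_ranked, k) {
  idcg <- dcg_trunc(sort(g_ranked, decreasing = TRUE), k)
  if (idcg == 0) {
    abort("IDCG is zero (no positive gain): query must be excluded upstream")
  }
  dcg_trunc(g_ranked, k) / idcg
}

#' @rdname dcg_at_k
#' @export
recall_at_k <- function(g_ranked, k) {
  n_rel <- sum(g_ranked > 0)
  if (n_rel == 0) abort("no relevant item in candidate list")
  sum(g_ranked[seq_len(min(k, length(g_ranked)))] > 0) / n_rel
}

#' @rdname dcg_at_k
#' @export
precision_at_k <- function(g_ranked, k, relevant = c("positive", "exact")) {
  if (k < 1) abort("k must be >= 1")
  relevant <- match.arg(relevant)
  thr <- if (relevant == "exact") 2 else 1
  sum(g_ranked[seq_len(min(k, length(g_ranked)))] >= thr) / k
}

#' Per-disease metrics from ranked lists
#'
#' Computes NDCG@k, Recall@k and Precision@k for every disease in a rankings
#' table, at each requested depth.
#'
#' @param rankings Tibble with columns `disease_id`, `rank`, `adjuvant_id`.
#' @param queries A [query_set()] supplying graded gains.
#' @param k Integer vector of depths (default `c(5, 10)`).
#' @return Tibble with columns `disease_id`, `k`, `ndcg`, `recall`,
#'   `precision`.
#' @export
per_disease_metrics <- function(rankings, queries, k = c(5, 10)) {
  joined <- left_join(as_tibble(rankings), as_tibble(queries),
                      by = c("disease_id", "adjuvant_id"))
  if (any(is.na(joined$gain))) {
    abort("rankings contain candidates absent from the query set")
  }
  joined <- arrange(joined, .data$disease_id, .data$rank)
  gl <- split(joined$gain, joined$disease_id)
  purrr::map(names(gl), function(d) {
    g <- gl[[d]]
    tibble(disease_id = d, k = k,
           ndcg = vapply(k, function(kk) ndcg_at_k(g, kk), numeric(1)),
           recall = vapply(k, function(kk) recall_at_k(g, kk), numeric(1)),
           precision = vapply(k, function(kk) precision_at_k(g, kk), numeric(1)))
  }) %>% bind_rows()
}

#' Macro-average per-disease metrics
#'
#' Unweighted arithmetic mean over diseases (each disease is one independent
#' query, regardless of candidate-list size).
#'
#' @param per_disease Output of [per_disease_metrics()].
#' @return Tibble with one row per `(metric, k)`: columns `metric`, `k`,
#'   `mean`, `n`.
#' @export
macro_average <- function(per_disease) {
  if (!nrow(per_disease)) abort("no diseases to average")
  per_disease %>%
    tidyr::pivot_longer(c("ndcg", "recall", "precision"),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$metric, .data$k) %>%
    summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
}

#' Percentile bootstrap confidence interval for a macro-averaged metric
#'
#' Resamples diseases with replacement `B` times, recomputes the macro mean
#' each time, and returns the empirical percentiles of the `B` means.
#'
#' @param values Per-disease metric values (length >= 2).
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the interval is a pure function of
#'   `(values, seed)`.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, B = 1000, level = 0.95, seed = 1) {
  n <- length(values)
  if (n < 2) abort("bootstrap_ci needs at least 2 values")
  set.seed(seed)
  draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  means <- rowMeans(matrix(values[draws], nrow = B))
  a <- (1 - level) / 2
  q <- unname(quantile(means, c(a, 1 - a), type = 7))
  c(lo = q[1], hi = q[2])
}

#' Two-sided paired randomization test for per-disease metrics
#'
#' Tests the null of no difference between two rankers evaluated on the same
#' diseases. The statistic is the mean paired difference; the null
#' distribution is built by independent random sign flips of each difference.
#' For n <= 12 all \eqn{2^n} sign patterns are enumerated exactly; otherwise
#' `n_perm` random flips are drawn and the p-value uses add-one smoothing.
#'
#' @param values_a,values_b Paired per-disease metric values (equal length
#'   >= 2, same disease order).
#' @param n_perm Number of random sign assignments when not exhaustive
#'   (default 10000).
#' @param seed Integer seed (ignored in the exhaustive case).
#' @return Two-sided p-value.
#' @export
paired_randomization_test <- function(values_a, values_b, n_perm = 10000,
                                      seed = 1) {
  n <- length(values_a)
  if (length(values_b) != n) {
    abort(sprintf("length mismatch: %d vs %d", n, length(values_b)))
  }
  if (n < 2) abort("need at least 2 paired values")
  d <- values_a - values_b
  obs <- abs(mean(d))
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_stats <- abs(as.vector(signs %*% d) / n)
    mean(null_stats >= obs - 1e-12)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
    null_stats <- abs(as.vector(signs %*% d) / n)
    (sum(null_stats >= obs - 1e-12) + 1) / (n_perm + 1)
  }
}

#' Reliability diagram bins and expected calibration error
#'
#' Converts raw scores to confidences with a sigmoid, bins them into
#' `n_bins` equal-width bins on \[0, 1\], and compares each bin's mean
#' confidence with its empirical precision (positive fraction). The expected
#' calibration error is the bin-size-weighted mean absolute gap:
#' \deqn{\mathrm{ECE} = \sum_b \frac{n_b}{N} \lvert \overline{conf}_b - prec_b \rvert.}
#' Empty bins are skipped.
#'
#' @param scores Raw real-valued scores.
#' @param relevance Binary (0/1) relevance per item.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `bins` (tibble: `bin`, `lo`, `hi`, `n`, `confidence`,
#'   `precision`) and scalar `ece`.
#' @export
reliability_and_ece <- function(scores, relevance, n_bins = 10) {
  if (!length(scores)) abort("empty input")
  if (length(relevance) != length(scores)) abort("scores/relevance length mismatch")
  if (!all(relevance %in% c(0, 1))) abort("relevance must be binary 0/1")
  conf <- sigmoid(scores)
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  bins <- tibble(bin = seq_len(n_bins),
                 lo = (seq_len(n_bins) - 1) / n_bins,
                 hi = seq_len(n_bins) / n_bins)
  agg <- tibble(bin = bin, conf = conf, rel = relevance) %>%
    group_by(.data$bin) %>%
    summarise(n = dplyr::n(), confidence = mean(.data$conf),
              precision = mean(.data$rel), .groups = "drop")
  bins <- left_join(bins, agg, by = "bin") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  occ <- bins$n > 0
  ece <- sum(bins$n[occ] / length(scores) *
               abs(bins$confidence[occ] - bins$precision[occ]))
  list(bins = bins, ece = ece)
}

#' Rank-swap analysis between two rankings
#'
#' For each candidate, the rank delta
#' `delta = rank_ablated - rank_full` (positive = promoted by the full
#' model), sorted by absolute delta descending. Deltas always sum to zero
#' over the shared candidate set.
#'
#' @param ranking_full,ranking_ablated Ranking tibbles for the same disease
#'   and identical candidate sets (columns `rank`, `adjuvant_id`).
#' @return Tibble with `adjuvant_id`, `rank_full`, `rank_ablated`, `delta`.
#' @export
rank_swap <- function(ranking_full, ranking_ablated) {
  a <- as_tibble(ranking_full)
  b <- as_tibble(ranking_ablated)
  sym <- union(setdiff(a$adjuvant_id, b$adjuvant_id),
               setdiff(b$adjuvant_id, a$adjuvant_id))
  if (length(sym)) {
    abort(sprintf("candidate sets differ: %s", paste(dQuote(sym), collapse = ", ")))
  }
  out <- left_join(select(a, adjuvant_id = "adjuvant_id", rank_full = "rank"),
                   select(b, adjuvant_id = "adjuvant_id", rank_ablated = "rank"),
                   by = "adjuvant_id") %>%
    mutate(delta = .data$rank_ablated - .data$rank_full) %>%
    arrange(dplyr::desc(abs(.data$delta)), .data$adjuvant_id)
  out
}

#' Cumulative DCG and ideal DCG curves
#'
#' Rank-by-rank cumulative gain curves for case-study plots.
#'
#' @param g_ranked Gain vector in predicted order.
#' @return Tibble with columns `rank`, `dcg`, `idcg`.
#' @export
dcg_curve <- function(g_ranked) {
  n <- length(g_ranked)
  disc <- 1 / log2(seq_len(n) + 1)
  tibble(rank = seq_len(n),
         dcg = cumsum(g_ranked * disc),
         idcg = cumsum(sort(g_ranked, decreasing = TRUE) * disc))
}
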