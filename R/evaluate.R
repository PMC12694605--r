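#' Rank all candidates for many diseases
#'
#' @param model A fitted `adjuvant_ranker`.
#' @param diseases Character vector of disease ids.
#' @param candidates Adjuvant ids (default: all in the graph).
#' @return One concatenated rankings tibble.
#' @export
rank_all <- function(model, diseases, candidates = NULL) {
  bind_rows(purrr::map(diseases, function(d) {
    rank_candidates(model, d, candidates)
  }))
}

#' Evaluate a rankings table against graded labels
#'
#' Computes per-disease NDCG@k, Recall@k and Precision@k, macro-averages
#' them, and attaches disease-level percentile-bootstrap confidence
#' intervals.
#'
#' @param rankings Rankings tibble (`disease_id`, `rank`, `adjuvant_id`).
#' @param queries A [query_set()] with graded gains.
#' @param k Depths (default `c(5, 10)`).
#' @param B Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @param split Tag recorded in the report (`"transductive"`, `"inductive"`,
#'   or any label).
#' @return An `eval_report`: list with `split`, `per_disease`, `summary`
#'   (columns `split`, `metric`, `k`, `mean`, `ci_lo`, `ci_hi`, `n`), `B`,
#'   `level`, `seed`.
#' @export
evaluate_rankings <- function(rankings, queries, k = c(5, 10), B = 1000,
                              level = 0.95, seed = 1, split = "unspecified") {
  per_disease <- per_disease_metrics(rankings, queries, k)
  if (!nrow(per_disease)) abort("no evaluable diseases in this split")
  macro <- macro_average(per_disease)
  long <- tidyr::pivot_longer(per_disease, c("ndcg", "recall", "precision"),
                              names_to = "metric", values_to = "value")
  cis <- long %>%
    group_by(.data$metric, .data$k) %>%
    summarise(ci = list(if (dplyr::n() >= 2) {
      bootstrap_ci(.data$value, B = B, level = level, seed = seed)
    } else c(lo = mean(.data$value), hi = mean(.data$value))),
    .groups = "drop") %>%
    mutate(ci_lo = purrr::map_dbl(.data$ci, 1),
           ci_hi = purrr::map_dbl(.data$ci, 2)) %>%
    select(-"ci")
  summary <- left_join(macro, cis, by = c("metric", "k")) %>%
    mutate(split = split) %>%
    select("split", "metric", "k", "mean", "ci_lo", "ci_hi", "n")
  structure(list(split = split, per_disease = per_disease, summary = summary,
                 B = B, level = level, seed = seed),
            class = "eval_report")
}

#' Evaluate a fitted ranker on a data split
#'
#' Ranks every evaluable disease of the requested split (diseases with at
#' least one positive) over all adjuvants and scores the rankings with the
#' graded evaluation suite.
#'
#' @param model A fitted `adjuvant_ranker`.
#' @param data The [ranker_data()] bundle.
#' @param split `"transductive"` or `"inductive"`.
#' @inheritParams evaluate_rankings
#' @return An `eval_report`.
#' @export
evaluate_ranker <- function(model, data, split = c("transductive", "inductive"),
                            k = c(5, 10), B = 1000, level = 0.95, seed = 1) {
  split <- match.arg(split)
  diseases <- split_diseases(data, split)
  if (!length(diseases)) abort(sprintf("no evaluable diseases in %s split", split))
  rankings <- rank_all(model, diseases)
  evaluate_rankings(rankings, data$queries, k = k, B = B, level = level,
                    seed = seed, split = split)
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> split = %s, n = %d diseases, B = %d\n",
              x$split, length(unique(x$per_disease$disease_id)), x$B))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s@%-2d  %.3f  [%.3f, %.3f]\n", s$metric[i], s$k[i],
                s$mean[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}

#' Compare two evaluation reports with a paired randomization test
#'
#' Pairs per-disease values of the chosen metric by disease id and applies
#' the two-sided paired randomization test.
#'
#' @param report_a,report_b `eval_report`s over the same diseases.
#' @param metric `"ndcg"`, `"recall"` or `"precision"`.
#' @param k Depth.
#' @param n_perm,seed Randomization-test controls.
#' @return Tibble with one row: `metric`, `k`, `mean_a`, `mean_b`, `diff`,
#'   `p_value`, `n`.
#' @export
compare_evals <- function(report_a, report_b, metric = "ndcg", k = 10,
                          n_perm = 10000, seed = 1) {
  va <- filter(report_a$per_disease, .data$k == !!k)
  vb <- filter(report_b$per_disease, .data$k == !!k)
  j <- left_join(select(va, "disease_id", a = dplyr::all_of(metric)),
                 select(vb, "disease_id", b = dplyr::all_of(metric)),
                 by = "disease_id")
  if (any(is.na(j$b))) abort("reports cover different diseases")
  p <- paired_randomization_test(j$a, j$b, n_perm = n_perm, seed = seed)
  tibble(metric = metric, k = k, mean_a = mean(j$a), mean_b = mean(j$b),
         diff = mean(j$a - j$b), p_value = p, n = nrow(j))
}

#' Write an evaluation report to JSON / Markdown
#'
#' The Markdown layout has one row per (split, metric, depth) with columns
#' Split, Metric, Mean, 95% CI, n.
#'
#' @param reports An `eval_report` or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(reports, path) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  payload <- purrr::map(reports, function(r) {
    list(split = r$split, B = r$B, level = r$level,
         n_diseases = length(unique(r$per_disease$disease_id)),
         summary = r$summary, per_disease = r$per_disease)
  })
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_md <- function(reports, path) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  lines <- c("| Split | Metric | Mean | 95% CI | n |",
             "|---|---|---|---|---|")
  for (r in reports) {
    s <- r$summary
    lines <- c(lines, sprintf("| %s | %s@%d | %.3f | [%.3f, %.3f] | %d |",
                              s$split, s$metric, s$k, s$mean, s$ci_lo,
                              s$ci_hi, s$n))
  }
  writeLines(lines, path)
  invisible(path)
}
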