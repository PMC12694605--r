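#' Tidy a fitted adjuvant ranker
#'
#' One row per parameter block with its dimensions and L2 norm.
#'
#' @param x An `adjuvant_ranker`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `rows`, `cols`, `l2_norm`.
#' @export
tidy.adjuvant_ranker <- function(x, ...) {
  p <- x$params
  blocks <- list(Wf = p$theta$Wf, bf = matrix(p$theta$bf, nrow = 1),
                 W = p$W, Wm = p$Wm)
  bind_rows(purrr::imap(blocks, function(m, nm) {
    tibble(term = nm, rows = nrow(m), cols = ncol(m),
           l2_norm = sqrt(sum(m^2)))
  }))
}

#' Glance at a fitted adjuvant ranker
#'
#' @param x An `adjuvant_ranker`.
#' @param ... Unused.
#' @return One-row tibble with the key hyperparameters, final training loss
#'   and last logged validation NDCG.
#' @export
glance.adjuvant_ranker <- function(x, ...) {
  vn <- x$history$val_ndcg[!is.na(x$history$val_ndcg)]
  cfg <- x$config
  tibble(dim = cfg$dim, alpha = cfg$alpha, K = cfg$K, gamma = cfg$gamma,
         lambda = cfg$lambda, mix_w = cfg$mix_w, gains = cfg$gains,
         epochs = cfg$epochs, seed = cfg$seed,
         final_loss = x$history$loss[nrow(x$history)],
         val_ndcg = if (length(vn)) vn[length(vn)] else NA_real_)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-disease metric tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_disease

#' Glance at an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble: split, n, B, and macro means at the largest depth.
#' @export
glance.eval_report <- function(x, ...) {
  kk <- max(x$summary$k)
  s <- filter(x$summary, .data$k == kk)
  tibble(split = x$split, n_diseases = s$n[1], B = x$B, k = kk,
         ndcg = s$mean[s$metric == "ndcg"],
         recall = s$mean[s$metric == "recall"],
         precision = s$mean[s$metric == "precision"])
}

#' Plot an evaluation report
#'
#' Macro means with bootstrap confidence intervals, one panel per metric.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$k), y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "depth k", y = "macro mean",
                  title = sprintf("Ranking quality (%s split)", object$split)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Reliability diagram
#'
#' Per-bin mean confidence vs empirical precision, with the diagonal of
#' perfect calibration; the subtitle reports the expected calibration error.
#'
#' @param rel Output of [reliability_and_ece()].
#' @return A ggplot object.
#' @export
plot_reliability <- function(rel) {
  occ <- filter(rel$bins, .data$n > 0)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$confidence, y = .data$precision)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean confidence", y = "empirical precision",
                  title = "Reliability diagram",
                  subtitle = sprintf("ECE = %.3f", rel$ece)) +
    ggplot2::theme_minimal()
}

#' Cumulative DCG / ideal DCG curves
#'
#' @param curve Output of [dcg_curve()].
#' @return A ggplot object.
#' @export
plot_dcg_curve <- function(curve) {
  long <- tidyr::pivot_longer(curve, c("dcg", "idcg"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank", y = "cumulative discounted gain",
                  title = "DCG vs ideal DCG") +
    ggplot2::theme_minimal()
}

#' Rank-swap plot
#'
#' Horizontal bars of per-candidate rank deltas (positive = promoted by the
#' full model relative to the ablated one).
#'
#' @param swap Output of [rank_swap()].
#' @param top_n Show the `top_n` largest absolute deltas (default 15).
#' @return A ggplot object.
#' @export
plot_rank_swap <- function(swap, top_n = 15) {
  top <- head(swap, top_n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$delta,
    y = stats::reorder(.data$adjuvant_id, abs(.data$delta))
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "rank delta (ablated - full; >0 promoted by full model)",
                  y = NULL, title = "Rank-swap analysis") +
    ggplot2::theme_minimal()
}
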