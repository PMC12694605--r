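# Exact DCG of gains taken in the given order, truncated at depth k.
dcg_trunc <- function(g, k) {
  n <- min(length(g), k)
  if (n < 1) return(0)
  i <- seq_len(n)
  sum(g[i] / log2(i + 1))
}

#' Smooth NDCG surrogate loss (ApproxNDCG)
#'
#' Differentiable surrogate for \eqn{1 - \mathrm{NDCG}@k}. Hard ranks are
#' replaced by smooth ranks
#' \deqn{\hat r_i = 1 + \sum_{j \ne i} \sigma\!\big((s_j - s_i)/\tau\big),}
#' the top-k truncation by the smooth indicator
#' \eqn{t_i = \sigma((k + 0.5 - \hat r_i)/\tau)}, and the loss is
#' \deqn{1 - \frac{1}{\mathrm{IDCG}@k} \sum_i \frac{g_i\, t_i}{\log_2(\hat r_i + 1)}.}
#' As \eqn{\tau \to 0} with untied scores the loss converges to
#' \eqn{1 - \mathrm{NDCG}@k} exactly.
#'
#' @param s Numeric score vector (length >= 2).
#' @param g Non-negative gain vector, same length; at least one positive.
#' @param k Truncation depth (default: full list length).
#' @param tau Temperature > 0 (default 1).
#' @param return_grad If `TRUE`, return `list(loss, grad)` with the gradient
#'   with respect to `s`.
#' @return Scalar loss, or a list when `return_grad = TRUE`.
#' @export
approx_ndcg_loss <- function(s, g, k = length(s), tau = 1, return_grad = FALSE) {
  n <- length(s)
  if (n < 2 || length(g) != n) abort("need |s| = |g| >= 2")
  if (tau <= 0) abort("tau must be > 0")
  if (all(g == 0)) abort("all gains are zero: query must be filtered upstream")
  idcg <- dcg_trunc(sort(g, decreasing = TRUE), k)

  Dlt <- outer(s, s, function(a, b) b - a)  # Dlt[i, j] = s_j - s_i
  S <- sigmoid(Dlt / tau)
  diag(S) <- 0
  rhat <- 1 + rowSums(S)
  tk <- sigmoid((k + 0.5 - rhat) / tau)
  L <- log2(rhat + 1)
  loss <- 1 - sum(g * tk / L) / idcg
  if (!return_grad) return(loss)

  # d(num_i)/d(rhat_i), then chain through the smooth ranks.
  dtk <- -dsigmoid((k + 0.5 - rhat) / tau) / tau
  dL <- 1 / ((rhat + 1) * log(2))
  dnum_drhat <- g * (dtk * L - tk * dL) / L^2
  ci <- -dnum_drhat / idcg            # d loss / d rhat_i
  P <- dsigmoid(Dlt / tau) / tau      # symmetric since sigma' is even
  diag(P) <- 0
  grad <- as.vector(P %*% ci) - ci * rowSums(P)
  list(loss = loss, grad = grad)
}

#' ListNet loss (top-one variant)
#'
#' Cross-entropy between the softmax of the gains (target distribution) and
#' the softmax of the scores:
#' \deqn{\ell = -\sum_i \mathrm{softmax}(g)_i \log \mathrm{softmax}(s)_i.}
#' Invariant to any constant shift of `s`; minimized when `s` induces the same
#' softmax as `g`. All-zero gains give a uniform target.
#'
#' @inheritParams approx_ndcg_loss
#' @return Scalar loss, or `list(loss, grad)` when `return_grad = TRUE`
#'   (gradient w.r.t. `s` is `softmax(s) - softmax(g)`).
#' @export
listnet_loss <- function(s, g, return_grad = FALSE) {
  n <- length(s)
  if (n < 2 || length(g) != n) abort("need |s| = |g| >= 2")
  p <- softmax(g)
  logq <- s - logsumexp(s)
  loss <- -sum(p * logq)
  if (!return_grad) return(loss)
  list(loss = loss, grad = exp(logq) - p)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
logsumexp <- function(x) max(x) + log(sum(exp(x - max(x))))

# Mixed per-query listwise loss w * ApproxNDCG + (1 - w) * ListNet.
mixed_list_loss <- function(s, g, k, tau, mix_w, return_grad = FALSE) {
  if (mix_w > 0) a <- approx_ndcg_loss(s, g, k, tau, return_grad)
  if (mix_w < 1) l <- listnet_loss(s, g, return_grad)
  if (mix_w == 1) return(a)
  if (mix_w == 0) return(l)
  if (!return_grad) return(mix_w * a + (1 - mix_w) * l)
  list(loss = mix_w * a$loss + (1 - mix_w) * l$loss,
       grad = mix_w * a$grad + (1 - mix_w) * l$grad)
}

#' Combined training objective over a batch of queries
#'
#' Sums the mixed listwise loss over queries and adds the L2 penalty
#' \eqn{\lambda \lVert \theta \rVert_2^2} over the trainable parameters
#' (encoder weights, bilinear `W`, mechanism projection `Wm`; the prior
#' weight `gamma` is a tuned hyperparameter, not trained, so it is not
#' penalized).
#'
#' @param batch List of query items, each a list with numeric `s` (scores) and
#'   `g` (gains), optionally `disease_id` for error reporting.
#' @param params Ranker parameters (list with `theta$Wf`, `theta$bf`, `W`,
#'   `Wm`); may be `NULL` when `lambda = 0`.
#' @param cfg List with `tau`, `mix_w`, `lambda`, and optional `k`.
#' @return Scalar loss.
#' @export
combined_loss <- function(batch, params = NULL, cfg = list()) {
  if (!length(batch)) abort("batch must be nonempty")
  tau <- cfg$tau %||% 1
  mix_w <- cfg$mix_w %||% 0.5
  lambda <- cfg$lambda %||% 0
  total <- 0
  for (item in batch) {
    k <- cfg$k %||% length(item$s)
    total <- total + tryCatch(
      mixed_list_loss(item$s, item$g, k, tau, mix_w),
      error = function(e) {
        abort(sprintf("query %s: %s", item$disease_id %||% "<unnamed>",
                      conditionMessage(e)))
      }
    )
  }
  if (lambda > 0) {
    total <- total + lambda * param_sq_norm(params)
  }
  total
}

param_sq_norm <- function(params) {
  sum(params$theta$Wf^2) + sum(params$theta$bf^2) +
    sum(params$W^2) + sum(params$Wm^2)
}

#' Sample negative adjuvants for a disease
#'
#' Draws `n_neg` adjuvants uniformly without replacement from the non-positive
#' candidates (all of them if fewer than `n_neg`). Uses the current RNG state,
#' so results are reproducible under `set.seed()`.
#'
#' @param all_adjuvants Character vector of candidate adjuvant ids.
#' @param positives_of_d Adjuvant ids that are positives for this disease.
#' @param n_neg Number of negatives to draw (>= 1).
#' @return Character vector of sampled negative ids.
#' @export
sample_negatives <- function(all_adjuvants, positives_of_d, n_neg) {
  pool <- setdiff(all_adjuvants, positives_of_d)
  if (!length(pool)) {
    abort("no negative candidates: every adjuvant is a positive for this disease")
  }
  if (n_neg < 1) abort("n_neg must be >= 1")
  if (length(pool) <= n_neg) return(pool)
  sample(pool, n_neg)
}
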