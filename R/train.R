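# Propagation without input validation; M may be the transposed adjacency
# (the adjoint of the forward propagation, used for backpropagation).
# Isolated nodes (pure self-loop rows) are exact fixed points of the
# recurrence; their rows are preserved bit for bit rather than left to
# accumulate rounding from (1-a)*x + a*x.
appnp_raw <- function(Z, M, alpha, K) {
  Z <- as.matrix(Z)
  H <- Z
  if (K == 0) return(H)
  for (k in seq_len(K)) H <- (1 - alpha) * as.matrix(M %*% H) + alpha * Z
  iso <- which(Matrix::diag(M) == 1)
  if (length(iso)) H[iso, ] <- Z[iso, ]
  H
}

#' Assemble a training/evaluation data bundle
#'
#' Validates and packages the knowledge graph, graded query lists, mechanism
#' cues and the transductive/inductive disease split into one object consumed
#' by [train_ranker()] and [evaluate_ranker()].
#'
#' @param graph A [hetero_graph()].
#' @param positives Data frame `disease_id`, `adjuvant_id`.
#' @param classes Data frame `adjuvant_id`, `class_label`.
#' @param cues Data frame `adjuvant_id`, `pathway_token`.
#' @param splits Data frame `disease_id`, `split` with split in
#'   `"transductive"` / `"inductive"`.
#' @param vocab Pathway vocabulary (default [default_pathway_vocab()]).
#' @return An object of class `ranker_data`.
#' @export
ranker_data <- function(graph, positives, classes, cues, splits,
                        vocab = default_pathway_vocab()) {
  stopifnot(inherits(graph, "hetero_graph"))
  splits <- as_tibble(splits)
  if (!all(c("disease_id", "split") %in% names(splits))) {
    abort("splits must have columns disease_id, split")
  }
  bad <- setdiff(unique(splits$split), c("transductive", "inductive"))
  if (length(bad)) {
    abort(sprintf("unknown split label(s): %s", paste(dQuote(bad), collapse = ", ")))
  }
  queries <- query_set(graph, positives, classes)
  adjuvant_ids <- sort(graph$nodes$node_id[graph$nodes$node_type == "Adjuvant"],
                       method = "radix")
  Phi <- build_cues(cues, vocab, adjuvant_ids)
  structure(list(
    graph = graph, positives = as_tibble(positives),
    classes = as_tibble(classes), cues = as_tibble(cues),
    splits = splits, vocab = vocab, queries = queries,
    adjuvant_ids = adjuvant_ids, Phi = Phi
  ), class = "ranker_data")
}

split_diseases <- function(data, split) {
  evaluable <- unique(data$queries$disease_id)
  sort(intersect(data$splits$disease_id[data$splits$split == split], evaluable),
       method = "radix")
}

#' Train the graph-propagated adjuvant ranker
#'
#' Fits the full model end to end: text features are encoded with the
#' hashing encoder, mapped by the affine base encoder, smoothed over the
#' training graph with APPNP (inductive diseases are isolated -- all their
#' edges removed -- so they never leak into training), and scored by the
#' bilinear + mechanism-prior scorer. Parameters \eqn{(\theta_f, W, W_m)}
#' minimize the hybrid listwise objective
#' \eqn{\sum_d [w\,\ell_{ApproxNDCG} + (1-w)\,\ell_{ListNet}] + \lambda\lVert\theta\rVert_2^2}
#' over positives plus freshly resampled negatives each epoch, using Adam
#' with analytically derived gradients (backpropagated through all K
#' propagation steps via the adjoint recurrence). The prior weight `gamma` is
#' a fixed hyperparameter here; see [tune_gamma()] for validation-grid
#' selection.
#'
#' @param data A [ranker_data()] bundle.
#' @param dim Embedding width D (default 64).
#' @param d_in Hashing feature width (default 256).
#' @param alpha,K APPNP teleport and step count (defaults 0.5, 10; the larger
#'   teleport keeps more of each node's own text signal, which matters when
#'   rankings must transfer to edgeless zero-shot diseases).
#' @param gamma Mechanism-prior weight (default 2, the validation-grid choice
#'   on the default synthetic benchmark; see [tune_gamma()]).
#' @param lambda L2 coefficient (default 0.2). The penalty on the bilinear
#'   block shrinks toward a scaled identity (dot-product similarity), not the
#'   zero matrix, so strong regularization trades memorization for
#'   generalization rather than for a degenerate scorer.
#' @param tau ApproxNDCG temperature (default 1).
#' @param mix_w Weight of ApproxNDCG vs ListNet in \[0, 1\] (default 0.5;
#'   0 = ListNet only, the "base loss" ablation).
#' @param n_neg Negatives sampled per query per epoch (default 20).
#' @param lr Adam learning rate (default 1e-2).
#' @param epochs Training epochs (default 200).
#' @param ndcg_k Depth of the surrogate's smooth truncation and of validation
#'   NDCG (default 10).
#' @param gains `"graded"` (default) or `"binary"` (collapse gains 2 -> 1,
#'   1 -> 0 in the training targets; evaluation is always graded).
#' @param p_cold Cold-start augmentation probability (default 1): per query
#'   and epoch, with this probability the disease is scored from its
#'   unpropagated embedding `z_d` instead of `h_d`, exactly the condition a
#'   zero-shot (edgeless) disease is scored under at inference. Set to 0 to
#'   train purely warm.
#' @param val_frac Fraction of transductive queries held out for validation
#'   logging / gamma tuning (default 0.2).
#' @param seed Root seed; init, negative sampling and all downstream
#'   randomness derive from it.
#' @param verbose Print per-epoch progress (default FALSE).
#' @return An object of class `adjuvant_ranker`.
#' @export
train_ranker <- function(data, dim = 64, d_in = 256, alpha = 0.5, K = 10,
                         gamma = 2, lambda = 0.2, tau = 1, mix_w = 0.5,
                         n_neg = 20, lr = 1e-2, epochs = 200, ndcg_k = 10,
                         gains = c("graded", "binary"), p_cold = 1,
                         val_frac = 0.2, seed = 1, verbose = FALSE) {
  stopifnot(inherits(data, "ranker_data"))
  gains <- match.arg(gains)
  seeds <- derive_seeds(seed)

  g <- data$graph
  X <- encode_nodes(g, backend = "hashing", dim = d_in)
  inductive <- data$splits$disease_id[data$splits$split == "inductive"]
  A_hat <- normalized_adjacency(g, drop_edges_of = inductive)
  At <- Matrix::t(A_hat)
  idx <- g$index
  n_nodes <- nrow(g$nodes)

  trans <- split_diseases(data, "transductive")
  if (!length(trans)) abort("no evaluable transductive diseases to train on")
  set.seed(seeds[["init"]])
  n_val <- floor(val_frac * length(trans))
  val_d <- sort(if (n_val > 0) sample(trans, n_val) else character(0))
  train_d <- setdiff(trans, val_d)
  if (!length(train_d)) abort("validation fraction leaves no training queries")

  # per-disease gain vectors over all adjuvants (stable adjuvant order)
  qgain <- split(data$queries$gain, data$queries$disease_id)
  adj <- data$adjuvant_ids
  pos_of <- split(data$positives$adjuvant_id, data$positives$disease_id)

  # Bilinear interaction parameterized as W = c I + V: the L2 penalty then
  # shrinks toward a scaled dot-product similarity (which generalizes to
  # unseen diseases) rather than toward the zero matrix, while V keeps the
  # full unconstrained D x D capacity.
  params <- list(
    theta = init_encoder(d_in, dim, seed = seeds[["init"]]),
    c_bilinear = 1,
    V = matrix(rnorm(dim * dim, sd = 0.1 / sqrt(dim)), dim, dim),
    Wm = matrix(rnorm(ncol(data$Phi) * dim, sd = 0.1 / sqrt(dim)),
                ncol(data$Phi), dim),
    gamma = gamma, lambda = lambda
  )
  params$W <- params$c_bilinear * diag(dim) + params$V
  adam <- adam_init(list(Wf = params$theta$Wf, bf = params$theta$bf,
                         c_bilinear = params$c_bilinear, V = params$V,
                         Wm = params$Wm))

  collapse <- function(gv) if (gains == "binary") as.integer(gv == 2L) else gv
  history <- vector("list", epochs)
  set.seed(seeds[["negatives"]])

  for (ep in seq_len(epochs)) {
    Z <- base_encode(X, params$theta)
    H <- appnp_raw(Z, A_hat, alpha, K)
    G_H <- matrix(0, n_nodes, dim)
    G_Z_direct <- matrix(0, n_nodes, dim)  # gradient into cold z_d rows
    gW <- matrix(0, dim, dim)
    gWm <- matrix(0, nrow(params$Wm), dim)
    loss <- 0

    for (d in train_d) {
      pos <- unique(pos_of[[d]])
      negs <- sample_negatives(adj, pos, n_neg)
      cold <- runif(1) < p_cold
      cand <- c(pos, negs)
      gq <- collapse(qgain[[d]][match(cand, adj)])
      if (all(gq == 0)) next
      idx_d <- idx[[d]]
      idx_a <- unname(idx[cand])
      Phi_c <- data$Phi[cand, , drop = FALSE]
      h_d <- if (cold) Z[idx_d, ] else H[idx_d, ]
      Ha <- H[idx_a, , drop = FALSE]
      tWh <- as.vector(crossprod(params$W, h_d))
      u <- as.vector(params$Wm %*% h_d)
      align <- as.vector(Phi_c %*% u)
      mvec <- sigmoid(align)
      s <- as.vector(Ha %*% tWh) + gamma * mvec

      res <- mixed_list_loss(s, gq, ndcg_k, tau, mix_w, return_grad = TRUE)
      loss <- loss + res$loss
      ds <- res$grad

      ha_ds <- as.vector(crossprod(Ha, ds))
      gW <- gW + outer(h_d, ha_ds)
      dm <- gamma * ds * mvec * (1 - mvec)
      du <- as.vector(crossprod(Phi_c, dm))
      gWm <- gWm + outer(du, h_d)
      g_hd <- as.vector(params$W %*% ha_ds) + as.vector(crossprod(params$Wm, du))
      if (cold) {
        G_Z_direct[idx_d, ] <- G_Z_direct[idx_d, ] + g_hd
      } else {
        G_H[idx_d, ] <- G_H[idx_d, ] + g_hd
      }
      G_H[idx_a, ] <- G_H[idx_a, ] + outer(ds, tWh)
    }

    G_Z <- appnp_raw(G_H, At, alpha, K) + G_Z_direct
    grads <- list(
      Wf = crossprod(X, G_Z) + 2 * lambda * params$theta$Wf,
      bf = colSums(G_Z) + 2 * lambda * params$theta$bf,
      c_bilinear = sum(diag(gW)) + 2 * lambda * params$c_bilinear,
      V = gW + 2 * lambda * params$V,
      Wm = gWm + 2 * lambda * params$Wm
    )
    loss <- loss + lambda *
      (sum(params$theta$Wf^2) + sum(params$theta$bf^2) +
         params$c_bilinear^2 + sum(params$V^2) + sum(params$Wm^2))
    if (!is.finite(loss)) {
      abort(sprintf("non-finite loss at epoch %d: check learning rate / inputs", ep))
    }

    cur <- list(Wf = params$theta$Wf, bf = params$theta$bf,
                c_bilinear = params$c_bilinear, V = params$V, Wm = params$Wm)
    upd <- adam_step(adam, grads, lr, cur)
    adam <- upd$state
    params$theta$Wf <- upd$values$Wf
    params$theta$bf <- upd$values$bf
    params$c_bilinear <- upd$values$c_bilinear
    params$V <- upd$values$V
    params$Wm <- upd$values$Wm
    params$W <- params$c_bilinear * diag(dim) + params$V

    val_ndcg <- NA_real_
    if (length(val_d) && (ep %% 10 == 0 || ep == epochs)) {
      val_ndcg <- validation_ndcg(params, X, A_hat, alpha, K, idx, adj,
                                  data$Phi, qgain, val_d, ndcg_k)
    }
    history[[ep]] <- tibble(epoch = ep, loss = loss, val_ndcg = val_ndcg)
    if (verbose && (ep %% 10 == 0 || ep == 1)) {
      message(sprintf("epoch %3d  loss %.4f  val NDCG@%d %s", ep, loss, ndcg_k,
                      ifelse(is.na(val_ndcg), "-", sprintf("%.3f", val_ndcg))))
    }
  }

  Z <- base_encode(X, params$theta)
  H <- appnp_raw(Z, A_hat, alpha, K)
  structure(list(
    params = params, H = H, X = X, A_hat = A_hat, index = idx,
    adjuvant_ids = adj, Phi = data$Phi, vocab = data$vocab,
    history = bind_rows(history), val_diseases = val_d,
    encoder_tag = attr(X, "encoder_tag"),
    config = list(dim = dim, d_in = d_in, alpha = alpha, K = K, gamma = gamma,
                  lambda = lambda, tau = tau, mix_w = mix_w, n_neg = n_neg,
                  lr = lr, epochs = epochs, ndcg_k = ndcg_k, gains = gains,
                  p_cold = p_cold, val_frac = val_frac, seed = seed)
  ), class = "adjuvant_ranker")
}

# Validation NDCG with diseases scored cold (their unpropagated embedding
# z_d), the condition hyperparameters are tuned for.
validation_ndcg <- function(params, X, A_hat, alpha, K, idx, adj, Phi, qgain,
                            diseases, k) {
  Z <- base_encode(X, params$theta)
  H <- appnp_raw(Z, A_hat, alpha, K)
  idx_a <- unname(idx[adj])
  vals <- vapply(diseases, function(d) {
    h_d <- Z[idx[[d]], ]
    s <- as.vector(H[idx_a, , drop = FALSE] %*%
                     as.vector(crossprod(params$W, h_d))) +
      params$gamma * mechanism_match(h_d, Phi, params$Wm)
    ord <- order(-s, adj, method = "radix")
    ndcg_at_k(qgain[[d]][ord], k)
  }, numeric(1))
  mean(vals)
}

adam_init <- function(values) {
  list(t = 0,
       m = purrr::map(values, ~ .x * 0),
       v = purrr::map(values, ~ .x * 0))
}

adam_step <- function(state, grads, lr, values,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    values[[nm]] <- values[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, values = values)
}

#' @exportS3Method base::print
print.adjuvant_ranker <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<adjuvant_ranker> D=%d, alpha=%.2f, K=%d, gamma=%g, %s gains, %d epochs (seed %d)\n",
    cfg$dim, cfg$alpha, cfg$K, cfg$gamma, cfg$gains, cfg$epochs, cfg$seed))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final loss %.4f", last$loss))
  vn <- x$history$val_ndcg[!is.na(x$history$val_ndcg)]
  if (length(vn)) cat(sprintf(", val NDCG@%d %.3f", cfg$ndcg_k, vn[length(vn)]))
  cat("\n")
  invisible(x)
}
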