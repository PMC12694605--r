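#' Mechanism-matching prior
#'
#' Projects the disease embedding into a "mechanism-demand" space and scores
#' its alignment with an adjuvant's pathway cues:
#' \deqn{m(d,a) = \sigma\left((W_m h_d)^\top \phi(a)\right),}
#' a single sigmoid of the scalar alignment, so \eqn{m \in (0,1)} always. An
#' all-zero cue vector (unknown mechanism) gives \eqn{m = \sigma(0) = 0.5}.
#'
#' @param h_d Disease embedding (length `D`).
#' @param phi Cue vector (length `P`) or a cue matrix (`n x P`) for many
#'   adjuvants at once.
#' @param Wm Mechanism projection matrix (`P x D`).
#' @return Scalar (or vector of length `n`) in (0, 1).
#' @export
mechanism_match <- function(h_d, phi, Wm) {
  u <- as.vector(Wm %*% h_d)  # mechanism demand, length P
  if (is.matrix(phi)) {
    sigmoid(as.vector(phi %*% u))
  } else {
    sigmoid(sum(u * phi))
  }
}

#' Disease-adjuvant compatibility score
#'
#' Combines a bilinear interaction term with the mechanism-matching prior:
#' \deqn{s(d,a) = h_d^\top W h_a + \gamma\, m(d,a).}
#' With `gamma = 0` the score is purely bilinear; the score is monotone
#' increasing in `gamma` for fixed positive `m`.
#'
#' @param h_d Disease embedding (length `D`).
#' @param h_a Adjuvant embedding (length `D`) or matrix (`n x D`).
#' @param phi_a Cue vector (length `P`) or matrix (`n x P`).
#' @param params Ranker parameters: list with `W` (`D x D`), `Wm` (`P x D`)
#'   and non-negative scalar `gamma`.
#' @return Scalar score (or vector of length `n`).
#' @export
score_pair <- function(h_d, h_a, phi_a, params) {
  tWh <- as.vector(crossprod(params$W, h_d))  # W^T h_d
  inter <- if (is.matrix(h_a)) as.vector(h_a %*% tWh) else sum(h_a * tWh)
  inter + params$gamma * mechanism_match(h_d, phi_a, params$Wm)
}

# Scores for one disease over a set of adjuvant rows; internal fast path.
score_candidates <- function(H, idx_d, idx_a, Phi_a, params) {
  h_d <- H[idx_d, ]
  Ha <- H[idx_a, , drop = FALSE]
  as.vector(Ha %*% as.vector(crossprod(params$W, h_d))) +
    params$gamma * mechanism_match(h_d, Phi_a, params$Wm)
}

#' Rank candidate adjuvants for a disease
#'
#' Scores every candidate with the fitted ranker and sorts in descending
#' score order; ties are broken deterministically by adjuvant id ascending,
#' so the output never depends on candidate input order.
#'
#' @param model A fitted `adjuvant_ranker` (see [train_ranker()]).
#' @param disease_id Disease node id present in the model's graph.
#' @param candidates Character vector of adjuvant ids; default all adjuvants
#'   in the graph.
#' @return A tibble with columns `disease_id`, `rank`, `adjuvant_id`, `score`.
#' @export
rank_candidates <- function(model, disease_id, candidates = NULL) {
  stopifnot(inherits(model, "adjuvant_ranker"))
  idx <- model$index
  if (!disease_id %in% names(idx)) {
    abort(sprintf("unknown disease id %s (for out-of-graph diseases use rank_new_disease())",
                  dQuote(disease_id)))
  }
  candidates <- candidates %||% model$adjuvant_ids
  missing <- setdiff(candidates, model$adjuvant_ids)
  if (length(missing)) {
    abort(sprintf("unknown adjuvant id(s): %s", paste(dQuote(missing), collapse = ", ")))
  }
  s <- score_candidates(model$H, idx[[disease_id]], idx[candidates],
                        model$Phi[candidates, , drop = FALSE], model$params)
  ord <- order(-s, candidates, method = "radix")
  tibble(disease_id = disease_id,
         rank = seq_along(candidates),
         adjuvant_id = candidates[ord],
         score = s[ord])
}

#' Rank adjuvants for a disease not present in the training graph
#'
#' Inductive (zero-shot) inference: the new disease is represented by the
#' encoding of its text alone. With no edges its propagated embedding equals
#' its encoded embedding, so the score uses \eqn{h_d = f_\theta(x_d)}.
#'
#' @param model A fitted `adjuvant_ranker`.
#' @param disease_text Free text describing the disease.
#' @param candidates Adjuvant ids; default all adjuvants in the graph.
#' @return A tibble as in [rank_candidates()] with `disease_id = "<new>"`.
#' @export
rank_new_disease <- function(model, disease_text, candidates = NULL) {
  stopifnot(inherits(model, "adjuvant_ranker"))
  candidates <- candidates %||% model$adjuvant_ids
  x <- encode_text_row(disease_text, ncol(model$X))
  h_d <- as.vector(base_encode(matrix(x, 1), model$params$theta))
  Ha <- model$H[model$index[candidates], , drop = FALSE]
  s <- as.vector(Ha %*% as.vector(crossprod(model$params$W, h_d))) +
    model$params$gamma *
      mechanism_match(h_d, model$Phi[candidates, , drop = FALSE], model$params$Wm)
  ord <- order(-s, candidates, method = "radix")
  tibble(disease_id = "<new>", rank = seq_along(candidates),
         adjuvant_id = candidates[ord], score = s[ord])
}

# Hash-encode one text into a feature row (same scheme as encode_nodes).
encode_text_row <- function(text, dim) {
  x <- numeric(dim)
  toks <- tokenize_text(text)
  if (length(toks)) {
    idx <- str_hash(toks, 31) %% dim + 1
    sgn <- ifelse(str_hash(toks, 131) %% 2 == 0, 1, -1)
    for (t in seq_along(toks)) x[idx[t]] <- x[idx[t]] + sgn[t]
    nrm <- sqrt(sum(x^2))
    if (nrm > 0) x <- x / nrm
  }
  x
}

#' Write rankings to a TSV file
#'
#' Output columns: `disease_id`, `rank`, `adjuvant_id`, `score`, and `gain`
#' when graded labels are supplied.
#'
#' @param rankings Tibble of rankings (possibly several diseases).
#' @param path Output path.
#' @param queries Optional [query_set()] to attach gains.
#' @return `rankings` (with gains if attached), invisibly.
#' @export
write_rankings <- function(rankings, path, queries = NULL) {
  if (!is.null(queries)) {
    rankings <- left_join(rankings, as_tibble(queries),
                          by = c("disease_id", "adjuvant_id"))
  }
  write_tsv_plain(rankings, path)
  invisible(rankings)
}
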