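#' Random-selection baseline ranker
#'
#' Ranks the candidates as a uniform random permutation, reproducible by
#' seed. Reads no edges, cues or learned parameters.
#'
#' @param candidates Character vector of adjuvant ids.
#' @param seed Integer seed.
#' @param disease_id Optional id recorded in the output.
#' @return Tibble with columns `disease_id`, `rank`, `adjuvant_id`.
#' @export
random_ranker <- function(candidates, seed, disease_id = NA_character_) {
  if (!length(candidates)) abort("candidates must be nonempty")
  set.seed(seed)
  perm <- sample(candidates)
  tibble(disease_id = disease_id, rank = seq_along(perm), adjuvant_id = perm)
}

#' Text-similarity baseline ranker
#'
#' Ranks candidates by cosine similarity between the disease's and each
#' adjuvant's raw text feature vectors -- no graph, no mechanism cues, no
#' learned weights. Ties break by adjuvant id ascending; zero-norm candidate
#' vectors (cosine undefined) rank last, deterministically.
#'
#' @param disease_id Disease node id (must have a feature row).
#' @param candidates Character vector of adjuvant ids.
#' @param features Feature matrix from [encode_nodes()] (rownames = node ids).
#' @return Tibble with columns `disease_id`, `rank`, `adjuvant_id`,
#'   `similarity`.
#' @export
text_similarity_ranker <- function(disease_id, candidates, features) {
  need <- c(disease_id, candidates)
  missing <- setdiff(need, rownames(features))
  if (length(missing)) {
    abort(sprintf("no feature row for: %s", paste(dQuote(missing), collapse = ", ")))
  }
  x_d <- features[disease_id, ]
  Xa <- features[candidates, , drop = FALSE]
  nd <- sqrt(sum(x_d^2))
  na_ <- sqrt(rowSums(Xa^2))
  sim <- as.vector(Xa %*% x_d)
  denom <- nd * na_
  sim <- ifelse(denom > 0, sim / denom, -Inf)  # 0/0 never selected
  ord <- order(-sim, candidates, method = "radix")
  tibble(disease_id = disease_id, rank = seq_along(candidates),
         adjuvant_id = candidates[ord], similarity = sim[ord])
}

#' Rankings for a baseline over a set of diseases
#'
#' Convenience wrapper producing one concatenated rankings table in the same
#' format as the learned ranker. The random baseline derives one
#' reproducible sub-seed per disease from `seed`; the text baseline uses the
#' same feature backend as the model for fairness.
#'
#' @param kind `"random"` or `"text_similarity"`.
#' @param diseases Character vector of disease ids.
#' @param candidates Character vector of adjuvant ids (shared candidate set).
#' @param features Feature matrix (required for `"text_similarity"`).
#' @param seed Integer seed (required for `"random"`).
#' @return Tibble with columns `disease_id`, `rank`, `adjuvant_id` (plus
#'   `similarity` for the text baseline), attribute `baseline_kind`.
#' @export
baseline_rankings <- function(kind = c("random", "text_similarity"), diseases,
                              candidates, features = NULL, seed = 1) {
  kind <- match.arg(kind)
  out <- if (kind == "random") {
    set.seed(seed)
    sub <- sample.int(.Machine$integer.max - 1L, length(diseases))
    purrr::map2(diseases, sub, function(d, s) random_ranker(candidates, s, d))
  } else {
    if (is.null(features)) abort("text_similarity baseline needs `features`")
    purrr::map(diseases, function(d) text_similarity_ranker(d, candidates, features))
  }
  out <- bind_rows(out)
  attr(out, "baseline_kind") <- kind
  out
}
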