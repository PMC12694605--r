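# Deterministic polynomial rolling hashes over UTF-8 bytes, exact in double
# arithmetic (all intermediates < 2^53). Two independent multipliers give the
# bucket index and the sign for the hashing trick.
str_hash <- function(strings, mult) {
  vapply(strings, function(s) {
    b <- utf8ToInt(s)
    h <- 0
    for (x in b) h <- (h * mult + x) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9_]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) > 1) {
    bigrams <- paste(toks[-length(toks)], toks[-1], sep = "_")
    toks <- c(toks, bigrams)
  }
  toks
}

#' Encode node text into initial feature vectors
#'
#' Default backend is an offline, fully deterministic signed feature-hashing
#' encoder: word unigrams and bigrams of each node's text are hashed into
#' `dim` buckets with a random-sign convention, and each row is
#' L2-normalized (rows with empty text stay zero). A pretrained biomedical
#' text-embedding backend can be plugged in behind the same interface but is
#' not bundled; requesting it without supplying an encoder function is an
#' explicit error, never a silent substitution.
#'
#' @param g A [hetero_graph()].
#' @param backend `"hashing"` (default) or `"pretrained"`.
#' @param dim Output dimensionality of the hashing encoder (default 256).
#' @param encoder_fn For `backend = "pretrained"`: a function
#'   `character -> numeric matrix` supplying the embeddings.
#' @return A numeric matrix, one row per node in the graph's stable order,
#'   rownames = node ids, with attribute `encoder_tag`.
#' @export
encode_nodes <- function(g, backend = c("hashing", "pretrained"), dim = 256,
                         encoder_fn = NULL) {
  stopifnot(inherits(g, "hetero_graph"))
  backend <- match.arg(backend)
  if (backend == "pretrained") {
    if (is.null(encoder_fn)) {
      abort(paste(
        "the pretrained biomedical encoder backend requires model weights",
        "that are not bundled with this package; pass `encoder_fn` or use",
        "backend = 'hashing' (the offline default)"
      ))
    }
    X <- encoder_fn(g$nodes$text)
    if (!is.matrix(X) || nrow(X) != nrow(g$nodes)) {
      abort("encoder_fn must return a numeric matrix with one row per node")
    }
    tag <- "pretrained"
  } else {
    X <- matrix(0, nrow(g$nodes), dim)
    for (v in seq_len(nrow(g$nodes))) {
      toks <- tokenize_text(g$nodes$text[v])
      if (!length(toks)) next
      idx <- str_hash(toks, 31) %% dim + 1
      sgn <- ifelse(str_hash(toks, 131) %% 2 == 0, 1, -1)
      for (t in seq_along(toks)) X[v, idx[t]] <- X[v, idx[t]] + sgn[t]
      nrm <- sqrt(sum(X[v, ]^2))
      if (nrm > 0) X[v, ] <- X[v, ] / nrm
    }
    tag <- sprintf("hashing-%d", dim)
  }
  if (any(!is.finite(X))) abort("feature matrix contains non-finite entries")
  rownames(X) <- g$nodes$node_id
  attr(X, "encoder_tag") <- tag
  X
}

#' Build the adjuvant mechanism-cue matrix
#'
#' Encodes each adjuvant's known innate-immune pathway engagements (e.g. CpG
#' oligodeoxynucleotides -> TLR9, MPLA -> TLR4) as a multi-hot binary vector
#' over a fixed pathway vocabulary. Adjuvants absent from the cue table get an
#' all-zero row (mechanism unknown); duplicate rows are idempotent.
#'
#' @param cue_table Data frame with columns `adjuvant_id`, `pathway_token`.
#' @param vocab Ordered character vector of pathway tokens; every token in
#'   `cue_table` must be in `vocab`.
#' @param adjuvant_ids Character vector of adjuvant ids defining the rows (in
#'   this order).
#' @return Binary matrix `length(adjuvant_ids) x length(vocab)` with dimnames.
#' @export
build_cues <- function(cue_table, vocab, adjuvant_ids) {
  cue_table <- as_tibble(cue_table)
  stopifnot(all(c("adjuvant_id", "pathway_token") %in% names(cue_table)))
  unknown <- setdiff(cue_table$pathway_token, vocab)
  if (length(unknown)) {
    abort(sprintf("pathway token(s) not in vocabulary: %s",
                  paste(dQuote(unknown), collapse = ", ")))
  }
  Phi <- matrix(0L, length(adjuvant_ids), length(vocab),
                dimnames = list(adjuvant_ids, vocab))
  keep <- cue_table$adjuvant_id %in% adjuvant_ids
  if (any(keep)) {
    Phi[cbind(cue_table$adjuvant_id[keep], cue_table$pathway_token[keep])] <- 1L
  }
  Phi
}

#' Default innate-immune pathway vocabulary
#'
#' A small curated list of pattern-recognition pathway tokens used as the
#' default mechanism-cue vocabulary. Editable: pass your own vector (or a
#' YAML list in the run config) to [build_cues()].
#'
#' @return Character vector of pathway tokens.
#' @export
default_pathway_vocab <- function() {
  c("TLR9", "TLR4", "TLR7", "STING", "NLRP3", "CLEC7A")
}
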