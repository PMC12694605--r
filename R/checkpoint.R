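CHECKPOINT_VERSION <- "1.0"

#' Save / load a trained ranker checkpoint
#'
#' Checkpoints are a single versioned JSON file (text, full double
#' precision) holding the encoder weights, bilinear interaction `W`,
#' mechanism projection `Wm`, the prior weight `gamma`, the regularization
#' coefficient, the full run configuration, the pathway vocabulary and the
#' training history. Identical configuration and seed produce byte-identical
#' checkpoints. Loading re-derives features, adjacency and propagated
#' embeddings deterministically from the accompanying data bundle.
#'
#' @param model A fitted `adjuvant_ranker`.
#' @param path Checkpoint file path (`.json`).
#' @return `write_checkpoint`: the path, invisibly. `read_checkpoint`: the
#'   reconstructed `adjuvant_ranker`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "adjuvant_ranker"))
  payload <- list(
    format = "adjuvantrank-checkpoint",
    version = CHECKPOINT_VERSION,
    config = model$config,
    vocab = model$vocab,
    encoder_tag = model$encoder_tag,
    history = model$history,
    params = list(
      Wf = model$params$theta$Wf, bf = model$params$theta$bf,
      W = model$params$W, Wm = model$params$Wm,
      gamma = model$params$gamma, lambda = model$params$lambda
    )
  )
  jsonlite::write_json(payload, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_checkpoint
#' @param data The [ranker_data()] bundle the model was trained on (supplies
#'   the graph, cues and splits needed to rebuild embeddings).
#' @export
read_checkpoint <- function(path, data) {
  stopifnot(inherits(data, "ranker_data"))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "adjuvantrank-checkpoint")) {
    abort(sprintf("%s is not an adjuvantrank checkpoint", path))
  }
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    abort(sprintf("checkpoint version %s not supported (expected %s)",
                  obj$version, CHECKPOINT_VERSION))
  }
  cfg <- obj$config
  params <- list(
    theta = list(Wf = as.matrix(obj$params$Wf), bf = as.numeric(obj$params$bf)),
    W = as.matrix(obj$params$W), Wm = as.matrix(obj$params$Wm),
    gamma = obj$params$gamma, lambda = obj$params$lambda
  )
  X <- encode_nodes(data$graph, backend = "hashing", dim = cfg$d_in)
  inductive <- data$splits$disease_id[data$splits$split == "inductive"]
  A_hat <- normalized_adjacency(data$graph, drop_edges_of = inductive)
  H <- appnp_raw(base_encode(X, params$theta), A_hat, cfg$alpha, cfg$K)
  structure(list(
    params = params, H = H, X = X, A_hat = A_hat, index = data$graph$index,
    adjuvant_ids = data$adjuvant_ids, Phi = data$Phi, vocab = obj$vocab,
    history = as_tibble(obj$history), val_diseases = character(0),
    encoder_tag = obj$encoder_tag, config = cfg
  ), class = "adjuvant_ranker")
}

#' Select the mechanism-prior weight on a validation grid
#'
#' The prior weight \eqn{\gamma} is a tuned hyperparameter, not a trained
#' one: the model is trained once per grid value and the value with the best
#' validation NDCG@k is kept.
#'
#' @param data A [ranker_data()] bundle.
#' @param grid Candidate gamma values (default `c(0, 0.5, 1, 2)`).
#' @param ... Passed to [train_ranker()] (must include a positive
#'   `val_frac`).
#' @return List with `model` (best fit), `gamma` (selected value), and
#'   `grid_results` (tibble `gamma`, `val_ndcg`).
#' @export
tune_gamma <- function(data, grid = c(0, 0.5, 1, 2), ...) {
  fits <- purrr::map(grid, function(gm) train_ranker(data, gamma = gm, ...))
  val <- vapply(fits, function(m) {
    vn <- m$history$val_ndcg[!is.na(m$history$val_ndcg)]
    if (!length(vn)) abort("tune_gamma requires val_frac > 0")
    vn[length(vn)]
  }, numeric(1))
  best <- which.max(val)
  list(model = fits[[best]], gamma = grid[best],
       grid_results = tibble(gamma = grid, val_ndcg = val))
}
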