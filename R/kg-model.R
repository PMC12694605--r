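#' Construct a heterogeneous vaccine knowledge graph
#'
#' Builds a typed graph over four node types -- `Disease`, `Vaccine`,
#' `Adjuvant`, `Platform` -- from a node table and an edge list. Adjuvants are
#' anchored by their Vaccine Ontology identifiers and diseases by name
#' strings; both are treated as opaque ids. Nodes are stored in a stable
#' lexicographic order by `(node_type, node_id)` (C collation) so that all
#' matrix views are bit-reproducible across runs.
#'
#' @param nodes A data frame with columns `node_id`, `node_type`, `text`.
#' @param edges A data frame with columns `src`, `edge_type`, `dst`.
#' @return An object of class `hetero_graph`: a list with tibbles `nodes` and
#'   `edges` and an integer `index` mapping `node_id` to row position.
#' @examples
#' g <- hetero_graph(
#'   nodes = tibble::tibble(
#'     node_id = c("brucellosis", "VO_0001", "vax1", "subunit"),
#'     node_type = c("Disease", "Adjuvant", "Vaccine", "Platform"),
#'     text = c("brucellosis intracellular", "CpG ODN TLR9", "vaccine 1", "subunit")
#'   ),
#'   edges = tibble::tibble(
#'     src = c("vax1", "vax1", "vax1"),
#'     edge_type = c("vaccine-targets-disease", "vaccine-uses-adjuvant", "vaccine-on-platform"),
#'     dst = c("brucellosis", "VO_0001", "subunit")
#'   )
#' )
#' g
#' @export
hetero_graph <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  req_n <- c("node_id", "node_type", "text")
  req_e <- c("src", "edge_type", "dst")
  if (!all(req_n %in% names(nodes))) {
    abort(paste0("node table must have columns: ", paste(req_n, collapse = ", ")))
  }
  if (!all(req_e %in% names(edges))) {
    abort(paste0("edge table must have columns: ", paste(req_e, collapse = ", ")))
  }
  nodes <- nodes[, req_n]
  edges <- edges[, req_e]

  bad_type <- which(!nodes$node_type %in% NODE_TYPES)
  if (length(bad_type)) {
    abort(sprintf(
      "unknown node_type %s at node-table row %d (expected one of: %s)",
      dQuote(nodes$node_type[bad_type[1]]), bad_type[1],
      paste(NODE_TYPES, collapse = ", ")
    ))
  }
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1]
    abort(sprintf("duplicate node_id %s", dQuote(dup)))
  }
  missing_ep <- setdiff(c(edges$src, edges$dst), nodes$node_id)
  if (length(missing_ep)) {
    abort(sprintf(
      "edge endpoint(s) not present in node table: %s",
      paste(dQuote(missing_ep), collapse = ", ")
    ))
  }
  if (any(edges$src == edges$dst)) {
    abort("self-edges are not allowed in input (self-loops are added by normalization)")
  }

  ord <- order(nodes$node_type, nodes$node_id, method = "radix")
  nodes <- nodes[ord, ]
  index <- setNames(seq_len(nrow(nodes)), nodes$node_id)
  structure(list(nodes = nodes, edges = edges, index = index),
            class = "hetero_graph")
}

#' @exportS3Method base::print
print.hetero_graph <- function(x, ...) {
  cnt <- table(factor(x$nodes$node_type, levels = NODE_TYPES))
  cat(sprintf(
    "<hetero_graph> %d nodes (%s), %d edges\n",
    nrow(x$nodes),
    paste(sprintf("%d %s", as.integer(cnt), names(cnt)), collapse = ", "),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Read a knowledge graph from TSV files
#'
#' Reads `nodes.tsv` (columns `node_id`, `node_type`, `text`) and `edges.tsv`
#' (columns `src`, `edge_type`, `dst`), both tab-separated UTF-8 with a header
#' row, and assembles a [hetero_graph()]. Parse errors report the offending
#' file line; edges referencing absent nodes report the missing id.
#'
#' @param edge_path Path to the edge TSV.
#' @param node_path Path to the node TSV.
#' @return A `hetero_graph`.
#' @export
read_graph <- function(edge_path, node_path) {
  nodes <- read_tsv_checked(node_path, c("node_id", "node_type", "text"))
  edges <- read_tsv_checked(edge_path, c("src", "edge_type", "dst"))
  bad <- which(!nodes$node_type %in% NODE_TYPES)
  if (length(bad)) {
    # +1: header occupies file line 1
    abort(sprintf(
      "%s line %d: unknown node_type %s (expected one of: %s)",
      node_path, bad[1] + 1L, dQuote(nodes$node_type[bad[1]]),
      paste(NODE_TYPES, collapse = ", ")
    ))
  }
  hetero_graph(nodes, edges)
}

read_tsv_checked <- function(path, cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", check.names = FALSE,
                   encoding = "UTF-8", blank.lines.skip = FALSE)
  if (!all(cols %in% names(df))) {
    abort(sprintf("%s: expected columns %s, found %s", path,
                  paste(cols, collapse = ", "), paste(names(df), collapse = ", ")))
  }
  as_tibble(df[, cols, drop = FALSE])
}

#' Write a knowledge graph to TSV files
#'
#' Inverse of [read_graph()]: round-tripping reproduces the input files up to
#' record ordering (nodes are written in the graph's stable order).
#'
#' @param g A `hetero_graph`.
#' @param edge_path,node_path Output paths.
#' @return `g`, invisibly.
#' @export
write_graph <- function(g, edge_path, node_path) {
  stopifnot(inherits(g, "hetero_graph"))
  write_tsv_plain(g$nodes, node_path)
  write_tsv_plain(g$edges, edge_path)
  invisible(g)
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

#' Serialize a graph to/from a single JSON file
#'
#' Convenience single-file serialization for fixtures; equivalent to the pair
#' of TSVs used by [read_graph()].
#'
#' @param g A `hetero_graph`.
#' @param path JSON file path.
#' @return For `write_graph_json`, `g` invisibly; for `read_graph_json`, a
#'   `hetero_graph`.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "hetero_graph"))
  jsonlite::write_json(
    list(nodes = g$nodes, edges = g$edges),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(g)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hetero_graph(as_tibble(obj$nodes), as_tibble(obj$edges))
}

#' Row-normalized adjacency with self-loops
#'
#' Treats the heterogeneous graph as a single undirected graph (edge types are
#' metadata only) and returns \eqn{\hat A = D^{-1}(A + I)} over the stable
#' node ordering, where \eqn{A} is the symmetric binary adjacency and \eqn{D}
#' the degree matrix of \eqn{A + I}. Every row sums to exactly 1; an isolated
#' node's row is its own self-loop.
#'
#' @param g A `hetero_graph`, or one with a subset of edges.
#' @param drop_edges_of Optional character vector of node ids whose incident
#'   edges are removed before normalization (the nodes themselves are kept,
#'   becoming isolated). Used to hold out inductive diseases: with a
#'   row-normalized self-looped adjacency, isolating a node leaves every other
#'   row identical to physically removing it.
#' @return A sparse row-stochastic `dgCMatrix` with dimnames = node ids.
#' @export
normalized_adjacency <- function(g, drop_edges_of = NULL) {
  stopifnot(inherits(g, "hetero_graph"))
  n <- nrow(g$nodes)
  if (n == 0) abort("graph has no nodes")
  edges <- g$edges
  if (!is.null(drop_edges_of)) {
    keep <- !(edges$src %in% drop_edges_of | edges$dst %in% drop_edges_of)
    edges <- edges[keep, , drop = FALSE]
  }
  i <- unname(g$index[edges$src])
  j <- unname(g$index[edges$dst])
  A <- sparseMatrix(i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
                    x = 1, dims = c(n, n))
  A@x[] <- 1  # binarize duplicated records
  d <- Matrix::rowSums(A)
  Ahat <- Diagonal(x = 1 / d) %*% A
  dimnames(Ahat) <- list(g$nodes$node_id, g$nodes$node_id)
  methods::as(Ahat, "CsparseMatrix")
}

#' Build graded-relevance query lists for every disease
#'
#' For each disease with at least one known positive adjuvant, the candidate
#' set is every `Adjuvant` node in the graph, with graded gains: 2 for an
#' exact known disease-adjuvant pair, 1 for an adjuvant sharing a functional
#' class with any positive of that disease, 0 otherwise. Diseases with zero
#' positives are excluded (their ideal DCG is zero, so ranking metrics are
#' undefined) with a warning.
#'
#' @param g A `hetero_graph`.
#' @param positives Data frame with columns `disease_id`, `adjuvant_id`.
#' @param classes Data frame with columns `adjuvant_id`, `class_label`, one
#'   row per class membership.
#' @return A tibble with columns `disease_id`, `adjuvant_id`, `gain`
#'   (class `query_set`), one row per disease x candidate adjuvant.
#' @export
query_set <- function(g, positives, classes) {
  stopifnot(inherits(g, "hetero_graph"))
  positives <- as_tibble(positives)
  classes <- as_tibble(classes)
  adjuvants <- g$nodes$node_id[g$nodes$node_type == "Adjuvant"]
  diseases <- g$nodes$node_id[g$nodes$node_type == "Disease"]

  bad_adj <- setdiff(positives$adjuvant_id, adjuvants)
  if (length(bad_adj)) {
    abort(sprintf("positives reference unknown adjuvant(s): %s",
                  paste(dQuote(bad_adj), collapse = ", ")))
  }
  bad_dis <- setdiff(positives$disease_id, diseases)
  if (length(bad_dis)) {
    abort(sprintf("positives reference unknown disease(s): %s",
                  paste(dQuote(bad_dis), collapse = ", ")))
  }

  no_pos <- setdiff(diseases, unique(positives$disease_id))
  if (length(no_pos)) {
    warn(sprintf("excluding %d disease(s) with zero positives from queries: %s",
                 length(no_pos), paste(head(no_pos, 5), collapse = ", ")))
  }
  qd <- sort(intersect(diseases, unique(positives$disease_id)), method = "radix")
  adjuvants <- sort(adjuvants, method = "radix")

  cls_of <- split(classes$class_label, classes$adjuvant_id)
  pos_of <- split(positives$adjuvant_id, positives$disease_id)

  out <- purrr::map(qd, function(d) {
    pos <- unique(pos_of[[d]])
    pos_cls <- unique(unlist(cls_of[pos], use.names = FALSE))
    gain <- integer(length(adjuvants))
    if (length(pos_cls)) {
      shares <- vapply(adjuvants, function(a) {
        cl <- cls_of[[a]]
        !is.null(cl) && any(cl %in% pos_cls)
      }, logical(1))
      gain[shares] <- 1L
    }
    gain[adjuvants %in% pos] <- 2L
    tibble(disease_id = d, adjuvant_id = adjuvants, gain = as.integer(gain))
  })
  out <- bind_rows(out)
  class(out) <- c("query_set", class(out))
  out
}
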