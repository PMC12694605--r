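# Brute-force metric oracles, written independently of the package
# implementations (plain loops, no shared helpers).

oracle_dcg <- function(g, k) {
  total <- 0
  for (i in seq_len(min(k, length(g)))) {
    total <- total + g[i] / (log(i + 1) / log(2))
  }
  total
}

oracle_ndcg <- function(g, k) {
  ideal <- g[order(g, decreasing = TRUE)]
  oracle_dcg(g, k) / oracle_dcg(ideal, k)
}

oracle_recall <- function(g, k) {
  found <- 0
  for (i in seq_len(min(k, length(g)))) if (g[i] > 0) found <- found + 1
  found / sum(g > 0)
}

oracle_precision <- function(g, k) {
  found <- 0
  for (i in seq_len(min(k, length(g)))) if (g[i] > 0) found <- found + 1
  found / k
}

# Central-difference numerical gradient of scalar f at x (vector or matrix).
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Hand-checkable 4-node toy graph (1 of each node type, 3 edges).
toy_nodes <- function() {
  tibble::tibble(
    node_id = c("brucellosis", "VO_0001", "vax1", "subunit"),
    node_type = c("Disease", "Adjuvant", "Vaccine", "Platform"),
    text = c("brucellosis intracellular th1", "cpg odn TLR9 agonist",
             "brucellosis vaccine", "subunit platform")
  )
}

toy_edges <- function() {
  tibble::tibble(
    src = c("vax1", "vax1", "vax1"),
    edge_type = c("vaccine-targets-disease", "vaccine-uses-adjuvant",
                  "vaccine-on-platform"),
    dst = c("brucellosis", "VO_0001", "subunit")
  )
}

toy_graph <- function() hetero_graph(toy_nodes(), toy_edges())

# Small but non-trivial bundle for training tests.
small_bundle <- function(seed = 11) {
  cfg <- synth_config(n_disease = 12, n_adjuvant = 16, n_platform = 2,
                      n_pathways = 4, n_classes = 4, beta = 6,
                      positives_per_disease = 2, text_noise = 0.2,
                      n_inductive = 4, seed = seed)
  as_ranker_data(generate_synth(cfg))
}

random_gain_list <- function(n) sample(0:2, n, replace = TRUE)
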