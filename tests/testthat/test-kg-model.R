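test_that("TSV round-trip parses the toy graph and reproduces its files", {
  dir <- withr::local_tempdir()
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  g0 <- toy_graph()
  write_graph(g0, ep, np)
  g <- read_graph(ep, np)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 3)
  # stable ordering: lexicographic by (node_type, node_id)
  expect_equal(g$nodes$node_type, c("Adjuvant", "Disease", "Platform", "Vaccine"))
  # round-trip up to record ordering
  dir2 <- withr::local_tempdir()
  write_graph(g, file.path(dir2, "e.tsv"), file.path(dir2, "n.tsv"))
  g2 <- read_graph(file.path(dir2, "e.tsv"), file.path(dir2, "n.tsv"))
  expect_identical(g$nodes, g2$nodes)
  expect_identical(dplyr::arrange(g$edges, src, dst),
                   dplyr::arrange(g2$edges, src, dst))
})

test_that("JSON serialization is equivalent to the TSV pair", {
  path <- withr::local_tempfile(fileext = ".json")
  g <- toy_graph()
  write_graph_json(g, path)
  g2 <- read_graph_json(path)
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})

test_that("degenerate and malformed inputs are handled per contract", {
  dir <- withr::local_tempdir()
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  # empty edge file, nonempty node file -> all nodes isolated
  writeLines(c("node_id\tnode_type\ttext", "d1\tDisease\tfoo", "a1\tAdjuvant\tbar"), np)
  writeLines("src\tedge_type\tdst", ep)
  g <- read_graph(ep, np)
  expect_equal(nrow(g$edges), 0)
  expect_equal(nrow(g$nodes), 2)
  # edge referencing an absent node names that id
  writeLines(c("src\tedge_type\tdst", "d1\ttargets\tmissing_node"), ep)
  expect_error(read_graph(ep, np), "missing_node")
  # unknown node_type reports the file line
  writeLines(c("node_id\tnode_type\ttext", "d1\tDisease\tfoo", "x1\tGene\tbar"), np)
  writeLines("src\tedge_type\tdst", ep)
  expect_error(read_graph(ep, np), "line 3.*Gene")
  # self-edges rejected
  expect_error(
    hetero_graph(toy_nodes(),
                 tibble::tibble(src = "vax1", edge_type = "e", dst = "vax1")),
    "self-edge"
  )
  expect_error(
    hetero_graph(dplyr::bind_rows(toy_nodes(), toy_nodes()[1, ]), toy_edges()),
    "duplicate"
  )
})

test_that("normalized adjacency is D^-1 (A + I) with exact row sums", {
  # two nodes joined by one edge: each row [0.5, 0.5]
  g <- hetero_graph(
    tibble::tibble(node_id = c("d1", "v1"), node_type = c("Disease", "Vaccine"),
                   text = c("a", "b")),
    tibble::tibble(src = "v1", edge_type = "targets", dst = "d1")
  )
  A <- as.matrix(normalized_adjacency(g))
  expect_equal(unname(A), matrix(0.5, 2, 2))
  # single isolated node: [[1]]
  g1 <- hetero_graph(
    tibble::tibble(node_id = "d1", node_type = "Disease", text = "a"),
    tibble::tibble(src = character(), edge_type = character(), dst = character())
  )
  expect_equal(as.matrix(normalized_adjacency(g1)), matrix(1, 1, 1),
               ignore_attr = TRUE)
  # any graph: rows sum to 1 within 1e-12 (including isolated nodes)
  synth <- generate_synth(synth_config(n_disease = 8, n_adjuvant = 10,
                                       n_inductive = 2, seed = 3))
  gs <- hetero_graph(synth$nodes, synth$edges)
  As <- normalized_adjacency(gs)
  expect_lt(max(abs(Matrix::rowSums(As) - 1)), 1e-12)
  # isolating a node leaves other rows equal to physically removing it
  d_iso <- synth$splits$disease_id[synth$splits$split == "inductive"][1]
  A_iso <- normalized_adjacency(gs, drop_edges_of = d_iso)
  keep <- setdiff(rownames(A_iso), d_iso)
  gs_rm <- hetero_graph(synth$nodes[synth$nodes$node_id != d_iso, ],
                        synth$edges[synth$edges$src != d_iso &
                                    synth$edges$dst != d_iso, ])
  A_rm <- normalized_adjacency(gs_rm)
  expect_equal(as.matrix(A_iso[keep, keep]), as.matrix(A_rm[keep, keep]))
})

test_that("graded gains are assigned 2/1/0 and depend only on inputs", {
  nodes <- tibble::tibble(
    node_id = c("d1", "d2", "a1", "a2", "a3", "a4"),
    node_type = c("Disease", "Disease", rep("Adjuvant", 4)),
    text = letters[1:6]
  )
  edges <- tibble::tibble(src = character(), edge_type = character(),
                          dst = character())
  g <- hetero_graph(nodes, edges)
  positives <- tibble::tibble(disease_id = "d1", adjuvant_id = "a1")
  classes <- tibble::tibble(adjuvant_id = c("a1", "a2", "a3"),
                            class_label = c("emulsion", "emulsion", "tlr_agonist"))
  expect_warning(q <- query_set(g, positives, classes), "zero positives")
  q1 <- dplyr::filter(q, disease_id == "d1")
  expect_equal(q1$gain[q1$adjuvant_id == "a1"], 2L)  # exact positive
  expect_equal(q1$gain[q1$adjuvant_id == "a2"], 1L)  # shares class with a positive
  expect_equal(q1$gain[q1$adjuvant_id == "a3"], 0L)  # unrelated class
  expect_equal(q1$gain[q1$adjuvant_id == "a4"], 0L)  # no class at all
  # d2 (zero positives) excluded
  expect_false("d2" %in% q$disease_id)
  # permutation of input row order never changes gains
  suppressWarnings({
    q_perm <- query_set(g, positives[sample(nrow(positives)), , drop = FALSE],
                        classes[rev(seq_len(nrow(classes))), ])
  })
  expect_identical(as.data.frame(q), as.data.frame(q_perm))
  # unknown adjuvant in positives errors with its id
  expect_error(query_set(g, tibble::tibble(disease_id = "d1",
                                           adjuvant_id = "nope"), classes),
               "nope")
})
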