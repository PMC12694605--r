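#' Configuration for the synthetic knowledge-graph generator
#'
#' Defines the study conditions the generator emulates: a sparse curated
#' snapshot of disease-adjuvant positives over a four-type knowledge graph,
#' class-structured adjuvants whose functional class correlates with their
#' mechanism cues, and planted mechanism-aligned signal -- the probability
#' that a disease-adjuvant pair is positive increases with the alignment
#' between the disease's latent pathway demand and the adjuvant's cue vector
#' through a logistic link \eqn{P(pos) = \sigma(\beta z + b)}, with `b`
#' calibrated so the expected number of positives per disease hits the
#' target.
#'
#' @param n_disease,n_adjuvant,n_platform Node counts. Vaccines are derived,
#'   one per positive pair, so that every positive is connected
#'   disease--vaccine--adjuvant.
#' @param n_pathways Number of innate-immune pathway tokens P.
#' @param n_classes Number of adjuvant functional classes.
#' @param beta Signal strength \eqn{\beta \ge 0}: alignment -> positive
#'   log-odds. `beta = 0` is the null model (positives independent of
#'   mechanism).
#' @param positives_per_disease Target expected positives per disease; every
#'   disease is additionally guaranteed at least one positive (curated
#'   snapshots only contain diseases with a known adjuvant).
#' @param text_noise Fraction of filler tokens in generated node text, in
#'   \[0, 1\]; higher = weaker text signal.
#' @param n_inductive Number of diseases held out as the inductive
#'   (zero-shot) split.
#' @param seed Root seed; generation is bitwise reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_disease = 89, n_adjuvant = 120, n_platform = 4,
                         n_pathways = 6, n_classes = 6, beta = 4,
                         positives_per_disease = 3, text_noise = 0.5,
                         n_inductive = 41, seed = 7) {
  stopifnot(n_disease >= 1, n_adjuvant >= 1, n_platform >= 1,
            n_pathways >= 1, n_classes >= 1, beta >= 0,
            positives_per_disease >= 1, text_noise >= 0, text_noise <= 1,
            n_inductive >= 0, n_inductive < n_disease)
  if (positives_per_disease > n_adjuvant) {
    abort("positives_per_disease cannot exceed n_adjuvant")
  }
  structure(as.list(environment()), class = "synth_config")
}

filler_words <- function() {
  c("immune", "response", "antigen", "formulation", "dose", "clinical",
    "trial", "protective", "efficacy", "murine", "model", "humoral",
    "cellular", "serum", "titer", "challenge", "strain", "pathogen",
    "infection", "chronic", "acute", "mucosal", "systemic", "injection",
    "emulsion", "particle", "stability", "cohort", "study", "phase",
    "adult", "pediatric", "booster", "prime", "schedule", "safety",
    "tolerability", "endemic", "outbreak", "surveillance")
}

pathway_tokens <- function(P) {
  base <- default_pathway_vocab()
  if (P <= length(base)) base[seq_len(P)] else c(base, sprintf("PW%02d", seq_len(P - length(base))))
}

#' Generate a synthetic ontology-shaped knowledge graph with planted signal
#'
#' See [synth_config()] for the generative model. Returns every artifact a
#' run needs (graph, cue table, positives, classes, split assignment) plus
#' the latent truth (demand vectors, alignments, sampling probabilities) for
#' oracle checks.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_data` list with elements `nodes`, `edges`, `positives`,
#'   `classes`, `cues`, `splits`, `vocab`, `latent`, `config`.
#' @export
generate_synth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  P <- cfg$n_pathways
  vocab <- pathway_tokens(P)
  fill <- filler_words()

  disease_ids <- sprintf("disease_%03d", seq_len(cfg$n_disease))
  adjuvant_ids <- sprintf("VO_%04d", seq_len(cfg$n_adjuvant))
  platform_ids <- sprintf("platform_%02d", seq_len(cfg$n_platform))

  # latent pathway demand per disease: one dominant pathway plus noise
  dom_d <- sample.int(P, cfg$n_disease, replace = TRUE)
  demand <- t(vapply(seq_len(cfg$n_disease), function(i) {
    raw <- rgamma(P, shape = 0.5)
    raw[dom_d[i]] <- raw[dom_d[i]] + 3
    raw / sum(raw)
  }, numeric(P)))

  # multi-hot cues per adjuvant; class label = class of the dominant cue
  # pathway, with label noise (all-zero cue rows = unknown mechanism)
  dom_a <- sample.int(P, cfg$n_adjuvant, replace = TRUE)
  Cue <- matrix(0L, cfg$n_adjuvant, P, dimnames = list(adjuvant_ids, vocab))
  for (i in seq_len(cfg$n_adjuvant)) {
    Cue[i, dom_a[i]] <- as.integer(runif(1) < 0.9)
    others <- setdiff(seq_len(P), dom_a[i])
    Cue[i, others] <- as.integer(runif(length(others)) < 0.15)
  }
  class_of_pathway <- ((seq_len(P) - 1) %% cfg$n_classes) + 1
  class_id <- vapply(seq_len(cfg$n_adjuvant), function(i) {
    if (sum(Cue[i, ]) == 0 || runif(1) > 0.85) {
      sample.int(cfg$n_classes, 1)
    } else {
      as.integer(class_of_pathway[which.max(Cue[i, ])])
    }
  }, integer(1))
  classes <- tibble(adjuvant_id = adjuvant_ids,
                    class_label = sprintf("class_%02d", class_id))

  # logistic planted-signal sampling of positives
  align <- demand %*% Matrix::t(Cue)
  align <- as.matrix(align)
  sdv <- stats::sd(as.vector(align))
  z <- if (sdv > 0) (align - mean(align)) / sdv else align * 0
  target_rate <- cfg$positives_per_disease / cfg$n_adjuvant
  b <- uniroot(function(bb) mean(sigmoid(cfg$beta * z + bb)) - target_rate,
               c(-30, 30))$root
  prob <- sigmoid(cfg$beta * z + b)
  pos_mat <- matrix(runif(length(prob)) < prob, nrow = cfg$n_disease)
  for (i in seq_len(cfg$n_disease)) {        # curated diseases have >= 1 positive
    if (!any(pos_mat[i, ])) {
      pos_mat[i, sample.int(cfg$n_adjuvant, 1, prob = prob[i, ])] <- TRUE
    }
  }
  pos_idx <- which(pos_mat, arr.ind = TRUE)
  positives <- tibble(disease_id = disease_ids[pos_idx[, 1]],
                      adjuvant_id = adjuvant_ids[pos_idx[, 2]]) %>%
    arrange(.data$disease_id, .data$adjuvant_id)

  # one vaccine per positive pair; each vaccine sits on a platform
  n_vac <- nrow(positives)
  vaccine_ids <- sprintf("vaccine_%04d", seq_len(n_vac))
  vac_platform <- platform_ids[sample.int(cfg$n_platform, n_vac, replace = TRUE)]
  edges <- bind_rows(
    tibble(src = vaccine_ids, edge_type = "vaccine-targets-disease",
           dst = positives$disease_id),
    tibble(src = vaccine_ids, edge_type = "vaccine-uses-adjuvant",
           dst = positives$adjuvant_id),
    tibble(src = vaccine_ids, edge_type = "vaccine-on-platform",
           dst = vac_platform)
  )

  # node text: pathway/class tokens plus filler so the text-similarity
  # baseline carries partial (but not full) signal
  sample_tokens <- function(n, signal_tokens, signal_prob) {
    vapply(seq_len(n), function(j) {
      if (length(signal_tokens) && runif(1) > cfg$text_noise) {
        sample(signal_tokens, 1, prob = signal_prob)
      } else {
        sample(fill, 1)
      }
    }, character(1))
  }
  disease_text <- vapply(seq_len(cfg$n_disease), function(i) {
    paste(c("disease", disease_ids[i],
            sample_tokens(8, vocab, demand[i, ])), collapse = " ")
  }, character(1))
  adjuvant_text <- vapply(seq_len(cfg$n_adjuvant), function(i) {
    cues_i <- vocab[Cue[i, ] == 1]
    paste(c("adjuvant", adjuvant_ids[i], cues_i,
            sprintf("class_%02d", class_id[i]),
            sample_tokens(4, cues_i, rep(1, length(cues_i)))),
          collapse = " ")
  }, character(1))
  platform_names <- c("subunit", "mrna", "inactivated", "live_attenuated",
                      "viral_vector", "conjugate", "dna", "protein")
  platform_text <- sprintf("platform %s", platform_names[
    ((seq_len(cfg$n_platform) - 1) %% length(platform_names)) + 1])
  vaccine_text <- sprintf("vaccine candidate against %s with %s",
                          positives$disease_id, positives$adjuvant_id)

  nodes <- bind_rows(
    tibble(node_id = disease_ids, node_type = "Disease", text = disease_text),
    tibble(node_id = adjuvant_ids, node_type = "Adjuvant", text = adjuvant_text),
    tibble(node_id = vaccine_ids, node_type = "Vaccine", text = vaccine_text),
    tibble(node_id = platform_ids, node_type = "Platform", text = platform_text)
  )

  cue_idx <- which(Cue == 1L, arr.ind = TRUE)
  cues <- tibble(adjuvant_id = adjuvant_ids[cue_idx[, 1]],
                 pathway_token = vocab[cue_idx[, 2]]) %>%
    arrange(.data$adjuvant_id, .data$pathway_token)

  inductive <- sort(sample(disease_ids, cfg$n_inductive))
  splits <- tibble(
    disease_id = disease_ids,
    split = ifelse(disease_ids %in% inductive, "inductive", "transductive")
  )

  structure(list(
    nodes = nodes, edges = edges, positives = positives, classes = classes,
    cues = cues, splits = splits, vocab = vocab,
    latent = list(demand = demand, cue = Cue, alignment = align, z = z,
                  prob = prob, intercept = b, dominant_disease = dom_d,
                  dominant_adjuvant = dom_a),
    config = cfg
  ), class = "synth_data")
}

#' Assemble a generated dataset into a ranker_data bundle
#'
#' @param synth A `synth_data` object from [generate_synth()].
#' @return A [ranker_data()] bundle.
#' @export
as_ranker_data <- function(synth) {
  stopifnot(inherits(synth, "synth_data"))
  g <- hetero_graph(synth$nodes, synth$edges)
  ranker_data(g, synth$positives, synth$classes, synth$cues, synth$splits,
              vocab = synth$vocab)
}

#' Named fixture presets
#'
#' `tiny` is a hand-checkable graph (a dozen-odd nodes); `default` mirrors a
#' curated-snapshot scale with 48 transductive / 41 inductive evaluable
#' diseases and planted signal `beta = 4`; `null` is the same scale with
#' `beta = 0` (no mechanism signal).
#'
#' @param name `"tiny"`, `"default"` or `"null"`.
#' @param seed Root seed (default 7).
#' @return A [synth_config()].
#' @export
preset_config <- function(name = c("tiny", "default", "null"), seed = 7) {
  name <- match.arg(name)
  switch(name,
    tiny = synth_config(n_disease = 2, n_adjuvant = 4, n_platform = 1,
                        n_pathways = 3, n_classes = 3, beta = 4,
                        positives_per_disease = 1, text_noise = 0.3,
                        n_inductive = 1, seed = seed),
    default = synth_config(seed = seed),
    null = synth_config(beta = 0, seed = seed)
  )
}

#' Write a fixture bundle to a directory
#'
#' Writes `nodes.tsv`, `edges.tsv`, `cues.tsv`, `positives.tsv`,
#' `classes.tsv`, `splits.tsv` and `vocab.yaml`; the files round-trip
#' through [read_fixture()] / [read_graph()] without warnings.
#'
#' @param name Preset name (see [preset_config()]) or a `synth_config`.
#' @param dir Output directory (created if absent).
#' @param seed Root seed used when `name` is a preset name.
#' @return The directory path, invisibly.
#' @export
make_fixture <- function(name, dir, seed = 7) {
  cfg <- if (inherits(name, "synth_config")) name else preset_config(name, seed)
  synth <- generate_synth(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_plain(synth$nodes, file.path(dir, "nodes.tsv"))
  write_tsv_plain(synth$edges, file.path(dir, "edges.tsv"))
  write_tsv_plain(synth$cues, file.path(dir, "cues.tsv"))
  write_tsv_plain(synth$positives, file.path(dir, "positives.tsv"))
  write_tsv_plain(synth$classes, file.path(dir, "classes.tsv"))
  write_tsv_plain(synth$splits, file.path(dir, "splits.tsv"))
  yaml::write_yaml(list(pathway_vocab = synth$vocab), file.path(dir, "vocab.yaml"))
  invisible(dir)
}

#' Read a fixture directory into a ranker_data bundle
#'
#' @param dir Directory written by [make_fixture()] (or hand-assembled with
#'   the same file layout).
#' @return A [ranker_data()] bundle.
#' @export
read_fixture <- function(dir) {
  g <- read_graph(file.path(dir, "edges.tsv"), file.path(dir, "nodes.tsv"))
  vocab_path <- file.path(dir, "vocab.yaml")
  vocab <- if (file.exists(vocab_path)) {
    unlist(yaml::read_yaml(vocab_path)$pathway_vocab)
  } else {
    default_pathway_vocab()
  }
  ranker_data(
    g,
    positives = read_tsv_checked(file.path(dir, "positives.tsv"),
                                 c("disease_id", "adjuvant_id")),
    classes = read_tsv_checked(file.path(dir, "classes.tsv"),
                               c("adjuvant_id", "class_label")),
    cues = read_tsv_checked(file.path(dir, "cues.tsv"),
                            c("adjuvant_id", "pathway_token")),
    splits = read_tsv_checked(file.path(dir, "splits.tsv"),
                              c("disease_id", "split")),
    vocab = vocab
  )
}
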