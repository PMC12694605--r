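test_that("graded metrics match their hand-evaluated examples", {
  expect_equal(dcg_at_k(c(2, 1, 0), 3), 2 + 1 / log2(3))
  expect_equal(round(dcg_at_k(c(2, 1, 0), 3), 5), 2.63093)
  expect_equal(dcg_at_k(c(0, 0, 0), 3), 0)
  expect_equal(dcg_at_k(c(1.7, 5), 1), 1.7)  # first-rank discount is 1

  expect_equal(round(ndcg_at_k(c(1, 2), 2), 5), 0.85972)
  expect_equal(ndcg_at_k(c(2, 1, 1, 0), 4), 1)  # ideal order
  expect_error(ndcg_at_k(c(0, 0), 2), "IDCG")

  expect_equal(recall_at_k(c(2, 0, 1, 0, 1), 2), 1 / 3)
  expect_equal(recall_at_k(c(1, 2, 0, 0), 2), 1)
  # monotone non-decreasing in k
  g <- c(0, 2, 0, 1, 1, 0)
  rec <- sapply(1:6, function(k) recall_at_k(g, k))
  expect_true(all(diff(rec) >= 0))

  expect_equal(precision_at_k(c(2, 1, 1, 1, 0), 5), 0.8)
  expect_equal(precision_at_k(c(0, 0, 0), 3), 0)
  expect_equal(precision_at_k(c(2, 0), 1), 1)
  # exact-positives-only threshold is a switch
  expect_equal(precision_at_k(c(2, 1, 1, 1, 0), 5, relevant = "exact"), 0.2)
})

test_that("metrics agree with brute-force oracles on random graded lists", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    g <- random_gain_list(n)
    if (all(g == 0)) g[sample(n, 1)] <- sample(1:2, 1)
    k <- sample(1:n, 1)
    expect_equal(dcg_at_k(g, k), oracle_dcg(g, k), tolerance = 1e-10)
    expect_equal(ndcg_at_k(g, k), oracle_ndcg(g, k), tolerance = 1e-10)
    expect_equal(recall_at_k(g, k), oracle_recall(g, k), tolerance = 1e-10)
    expect_equal(precision_at_k(g, k), oracle_precision(g, k), tolerance = 1e-10)
    expect_true(ndcg_at_k(g, k) >= 0 && ndcg_at_k(g, k) <= 1)
  }
})

test_that("macro average is the unweighted mean over diseases", {
  pd <- tibble::tibble(disease_id = c("d1", "d2"), k = 10,
                       ndcg = c(0.2, 0.8), recall = c(1, 0), precision = c(0.5, 0.1))
  m <- macro_average(pd)
  expect_equal(m$mean[m$metric == "ndcg"], 0.5)
  expect_equal(m$mean[m$metric == "recall"], 0.5)
  expect_identical(macro_average(pd[2:1, ]), m)
  # single disease: its own values
  m1 <- macro_average(pd[1, ])
  expect_equal(m1$mean[m1$metric == "ndcg"], 0.2)
  expect_equal(m1$mean[m1$metric == "recall"], 1)
})

test_that("percentile bootstrap is degenerate-safe and seed-pure", {
  expect_equal(unname(bootstrap_ci(rep(0.4, 10), B = 200, seed = 5)),
               c(0.4, 0.4))
  # same values + same seed -> identical interval regardless of RNG state
  set.seed(31); v <- rnorm(15)
  a <- bootstrap_ci(v, B = 300, seed = 77)
  set.seed(999); runif(10)
  b <- bootstrap_ci(v, B = 300, seed = 77)
  expect_identical(a, b)
  expect_true(a["lo"] <= mean(v) && mean(v) <= a["hi"])
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("paired randomization test is exact for small n and symmetric", {
  # identical inputs: p = 1
  v <- c(0.1, 0.5, 0.9)
  expect_equal(paired_randomization_test(v, v), 1)
  # n = 3, all differences +0.1: exhaustive two-sided p = 2/8
  a <- c(0.5, 0.6, 0.7); b <- a - 0.1
  expect_equal(paired_randomization_test(a, b), 0.25)
  expect_equal(paired_randomization_test(b, a), 0.25)  # two-sidedness
  # Monte-Carlo branch is seed-pure and symmetric
  set.seed(50)
  x <- rnorm(20); y <- rnorm(20, mean = 0.3)
  p1 <- paired_randomization_test(x, y, n_perm = 2000, seed = 3)
  p2 <- paired_randomization_test(y, x, n_perm = 2000, seed = 3)
  expect_equal(p1, p2)
  expect_error(paired_randomization_test(1:3, 1:4), "mismatch")
})

test_that("reliability bins and ECE match the hand-built example", {
  # 2 occupied bins: (conf .2, prec .5) and (conf .9, prec .5), 2 items each
  scores <- qlogis(c(0.2, 0.2, 0.9, 0.9))
  rel <- c(1, 0, 1, 0)
  out <- reliability_and_ece(scores, rel, n_bins = 2)
  expect_equal(out$ece, 0.5 * 0.3 + 0.5 * 0.4)
  occ <- out$bins[out$bins$n > 0, ]
  expect_equal(occ$confidence, c(0.2, 0.9), tolerance = 1e-12)
  expect_equal(occ$precision, c(0.5, 0.5))
  # perfectly calibrated bins give ECE 0
  s2 <- qlogis(c(0.25, 0.25, 0.25, 0.25, 0.75, 0.75, 0.75, 0.75))
  r2 <- c(1, 0, 0, 0, 1, 1, 1, 0)
  expect_equal(reliability_and_ece(s2, r2, n_bins = 2)$ece, 0)
  # bounded in [0, 1]
  set.seed(14)
  for (i in 1:10) {
    e <- reliability_and_ece(rnorm(30, sd = 3), sample(0:1, 30, TRUE))$ece
    expect_true(e >= 0 && e <= 1)
  }
  expect_error(reliability_and_ece(numeric(0), numeric(0)), "empty")
})

test_that("rank-swap deltas are conserved and ordered by magnitude", {
  full <- tibble::tibble(rank = 1:4, adjuvant_id = c("a", "b", "c", "d"))
  same <- rank_swap(full, full)
  expect_true(all(same$delta == 0))
  # candidate moving from rank 9 to rank 3 has delta +6
  f2 <- tibble::tibble(rank = 1:9, adjuvant_id = c(letters[1:2], "cpg", letters[3:8]))
  a2 <- tibble::tibble(rank = 1:9, adjuvant_id = c(letters[1:8], "cpg"))
  sw <- rank_swap(f2, a2)
  expect_equal(sw$delta[sw$adjuvant_id == "cpg"], 6)
  expect_equal(sum(sw$delta), 0)
  expect_equal(sw$delta, sw$delta[order(-abs(sw$delta))])
  expect_error(rank_swap(full, f2[1:4, ]), "differ")
})

test_that("cumulative gain curves track DCG and its ideal", {
  g <- c(0, 2, 1, 0, 1)
  cv <- dcg_curve(g)
  expect_equal(cv$dcg[5], dcg_at_k(g, 5))
  expect_equal(cv$idcg[5], dcg_at_k(sort(g, decreasing = TRUE), 5))
  expect_true(all(cv$idcg - cv$dcg >= -1e-12))
  expect_true(all(diff(cv$dcg) >= 0))
})
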