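test_that("ListNet top-one loss matches hand evaluation and its invariances", {
  # g=[1,0], s=[0,0]: cross-entropy of uniform prediction = ln 2
  expect_equal(listnet_loss(c(0, 0), c(1, 0)), log(2), tolerance = 1e-12)
  # shift invariance
  s <- c(0.3, -1.2, 2.2); g <- c(2, 0, 1)
  expect_equal(listnet_loss(s + 17.5, g), listnet_loss(s, g))
  # s proportional to g attains the minimum (entropy of softmax(g))
  p <- exp(g - max(g)) / sum(exp(g - max(g)))
  expect_equal(listnet_loss(g, g), -sum(p * log(p)))
  set.seed(3)
  for (i in 1:10) {
    expect_gte(listnet_loss(g + rnorm(3, sd = 0.5), g), listnet_loss(g, g))
  }
  # gradient is softmax(s) - softmax(g)
  res <- listnet_loss(s, g, return_grad = TRUE)
  expect_equal(res$grad, num_grad(function(x) listnet_loss(x, g), s),
               tolerance = 1e-6)
})

test_that("smooth-rank surrogate behaves per the closed-form small cases", {
  # two candidates, tied scores: both smooth ranks are 1.5, loss finite,
  # gradient pushes the relevant score up and the irrelevant one down
  res <- approx_ndcg_loss(c(0, 0), c(1, 0), k = 2, tau = 1, return_grad = TRUE)
  expect_true(is.finite(res$loss))
  expect_lt(res$grad[1], 0)
  expect_gt(res$grad[2], 0)
  # gradient matches finite differences
  set.seed(6)
  s <- rnorm(5); g <- c(2, 0, 1, 0, 1)
  res2 <- approx_ndcg_loss(s, g, k = 3, tau = 0.7, return_grad = TRUE)
  expect_equal(res2$grad,
               num_grad(function(x) approx_ndcg_loss(x, g, k = 3, tau = 0.7), s),
               tolerance = 1e-5)
  # ideally ordered scores at tiny temperature: loss ~ 0
  expect_lt(approx_ndcg_loss(c(3, 2, 1), c(2, 1, 0), k = 3, tau = 1e-4), 1e-3)
  # all-zero gains must have been filtered upstream
  expect_error(approx_ndcg_loss(c(1, 0), c(0, 0)), "filtered upstream")
})

test_that("surrogate at tiny temperature equals 1 - exact NDCG", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    g <- random_gain_list(n)
    if (all(g == 0)) g[1] <- 1
    s <- sample(seq_len(n))  # untied scores
    k <- sample(1:n, 1)
    ord <- order(-s)
    expect_equal(approx_ndcg_loss(s, g, k = k, tau = 1e-4),
                 1 - oracle_ndcg(g[ord], k), tolerance = 1e-3)
  }
})

test_that("both listwise losses are invariant to candidate permutation", {
  set.seed(12)
  s <- rnorm(6); g <- c(2, 1, 0, 0, 1, 0)
  for (i in 1:5) {
    p <- sample(6)
    expect_equal(listnet_loss(s[p], g[p]), listnet_loss(s, g))
    expect_equal(approx_ndcg_loss(s[p], g[p], k = 4, tau = 0.5),
                 approx_ndcg_loss(s, g, k = 4, tau = 0.5))
  }
})

test_that("combined objective mixes components and adds the exact L2 penalty", {
  set.seed(9)
  batch <- list(list(disease_id = "d1", s = rnorm(4), g = c(2, 0, 1, 0)),
                list(disease_id = "d2", s = rnorm(3), g = c(1, 0, 0)))
  params <- list(theta = list(Wf = matrix(rnorm(6), 2), bf = rnorm(3)),
                 W = matrix(rnorm(9), 3), Wm = matrix(rnorm(6), 2))
  # endpoints equal the component losses exactly
  expect_identical(combined_loss(batch, cfg = list(mix_w = 1, tau = 0.5)),
                   sum(sapply(batch, function(b)
                     approx_ndcg_loss(b$s, b$g, length(b$s), 0.5))))
  expect_identical(combined_loss(batch, cfg = list(mix_w = 0)),
                   sum(sapply(batch, function(b) listnet_loss(b$s, b$g))))
  # lambda adds exactly lambda * ||theta||^2 for fixed theta
  sq <- sum(params$theta$Wf^2) + sum(params$theta$bf^2) +
    sum(params$W^2) + sum(params$Wm^2)
  l0 <- combined_loss(batch, params, list(lambda = 0))
  l1 <- combined_loss(batch, params, list(lambda = 0.3))
  expect_equal(l1 - l0, 0.3 * sq)
  expect_equal(combined_loss(batch, params, list(lambda = 0.6)) - l0, 0.6 * sq)
  # per-query failures carry the disease id
  bad <- list(list(disease_id = "dX", s = c(0, 0), g = c(0, 0)))
  expect_error(combined_loss(bad, cfg = list(mix_w = 1)), "dX")
  expect_error(combined_loss(list()), "nonempty")
})

test_that("one gradient step separates a positive from a negative for any mix", {
  for (w in c(0, 0.5, 1)) {
    res <- adjuvantrank:::mixed_list_loss(c(0, 0), c(1, 0), k = 2, tau = 1,
                                          mix_w = w, return_grad = TRUE)
    s_new <- c(0, 0) - 0.1 * res$grad
    expect_gt(s_new[1] - s_new[2], 0)
  }
})

test_that("negative sampling is uniform without replacement and reproducible", {
  adj <- sprintf("a%02d", 1:10)
  pos <- c("a01", "a02")
  # exhaustion: returns every non-positive exactly once
  set.seed(1)
  expect_setequal(sample_negatives(adj, pos, 8), setdiff(adj, pos))
  expect_setequal(sample_negatives(adj, pos, 50), setdiff(adj, pos))
  # reproducible under the same seed
  set.seed(42); s1 <- sample_negatives(adj, pos, 3)
  set.seed(42); s2 <- sample_negatives(adj, pos, 3)
  expect_identical(s1, s2)
  # uniformity: 10,000 single draws within 3-sigma binomial bounds
  set.seed(7)
  draws <- replicate(10000, sample_negatives(adj, pos, 1))
  counts <- table(factor(draws, levels = setdiff(adj, pos)))
  p <- 1 / 8
  bound <- 3 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) <= bound))
  # every adjuvant positive -> error
  expect_error(sample_negatives(pos, pos, 1), "every adjuvant")
})
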