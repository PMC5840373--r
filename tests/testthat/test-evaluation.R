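make_design <- function(n_topics, n_passages, n_sentences) {
  g <- expand.grid(s = seq_len(n_sentences), p = seq_len(n_passages),
                   t = seq_len(n_topics))
  design_spec(sprintf("t%dp%ds%d", g$t, g$p, g$s),
              topic = paste0("T", g$t),
              passage = paste0("T", g$t, "P", g$p))
}

test_that("pairwise classification follows the four-correlation rule", {
  set.seed(1)
  truth <- matrix(rnorm(10 * 20), 10, 20)
  pairs <- t(combn(10, 2))

  # perfect decoding
  expect_equal(pairwise_accuracy(truth, truth, pairs)$accuracy, 1)

  # adversarial swap of two stimuli
  dec <- truth[c(2, 1), ]
  expect_equal(pairwise_accuracy(dec, truth[1:2, ],
                                 matrix(c(1, 2), 1))$accuracy, 0)

  # constant vectors are excluded, not scored
  dec2 <- truth
  dec2[3, ] <- 5
  pr <- pairwise_accuracy(dec2, truth, pairs)
  expect_equal(pr$n_excluded, 9L)          # the 9 pairs touching stimulus 3
  expect_equal(pr$n_pairs, 36L)
})

test_that("independent decoded vectors score at chance", {
  accs <- sapply(1:5, function(s) {
    set.seed(s)
    dec <- matrix(rnorm(200 * 50), 200, 50)
    tru <- matrix(rnorm(200 * 50), 200, 50)
    pairs <- cbind(sample(200, 2000, TRUE), sample(200, 2000, TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairwise_accuracy(dec, tru, pairs)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("pair enumeration is exhaustive per task", {
  d <- make_design(2, 1, 2)   # 2 topics x 1 passage x 2 sentences
  expect_equal(nrow(enumerate_pairs(d, "cross_topic")), 4L)
  expect_equal(nrow(enumerate_pairs(d, "within_passage")), 2L)
  expect_error(enumerate_pairs(d, "within_topic_cross_passage"),
               "no eligible pairs")

  w <- design_spec(sprintf("w%03d", 1:180), kind = "word")
  expect_equal(nrow(enumerate_pairs(w, "all_pairs")), choose(180, 2))

  # brute-force check of the task predicates on a richer design
  d2 <- make_design(3, 2, 2)
  for (task in c("cross_topic", "within_topic_cross_passage",
                 "within_passage")) {
    pr <- enumerate_pairs(d2, task)
    same_topic <- d2$topic[pr[, 1]] == d2$topic[pr[, 2]]
    same_pass <- d2$passage[pr[, 1]] == d2$passage[pr[, 2]]
    switch(task,
      cross_topic = expect_true(all(!same_topic)),
      within_topic_cross_passage = expect_true(all(same_topic & !same_pass)),
      within_passage = expect_true(all(same_pass)))
  }
  n_all <- sum(sapply(c("cross_topic", "within_topic_cross_passage",
                        "within_passage"),
                      function(tk) nrow(enumerate_pairs(d2, tk))))
  expect_equal(n_all, choose(nrow(d2), 2))
})

test_that("conservative independent-pair counts implement the printed rules", {
  w <- design_spec(sprintf("w%03d", 1:180), kind = "word")
  expect_equal(conservative_count(w, "all_pairs"), 180L)

  d <- make_design(2, 2, 3)   # 2 topics x 2 passages x 3 sentences
  # (iii) the number of sentences
  expect_equal(conservative_count(d, "within_passage"), 12L)
  # (i) cross-topic passage pairs (2x2 = 4) x min sentences (3)
  expect_equal(conservative_count(d, "cross_topic"), 12L)
  # (ii) within-topic passage pairs (1 per topic x 2 topics) x min sentences
  expect_equal(conservative_count(d, "within_topic_cross_passage"), 6L)
})

test_that("the conservative binomial test is exact and monotone", {
  expect_equal(binomial_pvalue(180, 180), 0.5^180)
  # sum of the upper binomial tail from 5 of 10
  expect_equal(binomial_pvalue(5, 10),
               sum(choose(10, 5:10)) / 2^10, tolerance = 1e-12)
  expect_equal(binomial_pvalue(5, 10), 0.623, tolerance = 1e-3)
  ps <- sapply(0:10, binomial_pvalue, n_independent = 10)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  # accuracy rescaling to the conservative count
  expect_equal(binomial_pvalue(n_independent = 10, accuracy = 0.52),
               binomial_pvalue(5, 10))
})

test_that("rank accuracy hits its endpoints and midpoint exactly", {
  set.seed(2)
  cand <- matrix(rnorm(180 * 30), 180, 30)
  # decoded equals a candidate: top of the ranking
  expect_equal(rank_accuracy(cand[7, ], cand, 7)$score, 1)
  # worst candidate: anti-correlated with the decoded vector
  dec <- cand[1, ]
  worst <- rbind(cand[1:180, ])
  worst[50, ] <- -dec
  expect_equal(rank_accuracy(dec, worst, 50)$score, 0)
  # midpoint: rank 91 of 181
  expect_equal(rank_accuracy(dec, worst, 50)$rank, 180)

  # exact mid-rank case: correlations graded by angle, true item 91st of 181
  base <- scale(rnorm(30))[, 1]
  orth <- scale(residuals(lm(rnorm(30) ~ base)))[, 1]
  theta <- seq(0, pi, length.out = 181)
  cands <- outer(cos(theta), base) + outer(sin(theta), orth)
  expect_equal(rank_accuracy(base, cands, 91)$score, 0.5, tolerance = 1e-6)

  expect_error(rank_accuracy(rep(1, 30), cand, 1), "constant")
  expect_error(rank_accuracy(cand[1, ], cand[1, , drop = FALSE], 1),
               "at least 2")
})

test_that("random rankings average to rank accuracy 0.5", {
  set.seed(3)
  scores <- sapply(1:1000, function(i) {
    dec <- rnorm(25)
    cand <- matrix(rnorm(40 * 25), 40, 25)
    rank_accuracy(dec, cand, sample(40, 1))$score
  })
  expect_lt(abs(mean(scores) - 0.5), 0.02)
})

test_that("the normal rank null uses the printed variance", {
  # variance (R+1)/(12(R-1)T) with R = 3, T = 12 is 4/288
  expect_equal(rank_null_pvalue(0.5 + sqrt(4 / 288), 3, 12),
               pnorm(1, lower.tail = FALSE))
  expect_equal(rank_null_pvalue(0.5, 3, 12), 0.5)
  ms <- seq(0.4, 0.9, by = 0.1)
  ps <- sapply(ms, rank_null_pvalue, n_candidates = 100, n_tests = 24)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("word spotting scores the best-ranked sentence word", {
  set.seed(4)
  vocab <- word_vector_table(sprintf("v%04d", 1:500),
                             matrix(rnorm(500 * 20), 500, 20))
  # decoded vector equal to a vocabulary word's own vector tops the ranking
  ws <- word_spotting(vocab$vectors[17, ], vocab, c("v0017", "v0200"))
  expect_equal(ws$score, 1)
  expect_equal(unname(ws$word_scores["v0017"]), 1)

  # score follows the rank-accuracy formula for known ranks
  dec <- rnorm(20)
  cs <- cor(t(vocab$vectors), dec)
  rk <- rank(-cs)
  words <- c("v0003", "v0101")
  expected <- max(1 - (rk[c(3, 101)] - 1) / (500 - 1))
  expect_equal(word_spotting(dec, vocab, words)$score, expected)

  expect_error(word_spotting(dec, vocab, character(0)), "empty")
  expect_error(word_spotting(dec, vocab, "nope"), "not in vocabulary")
})

test_that("the word-spotting null matches its closed-form median", {
  for (k in c(1, 3, 6, 10)) {
    null <- word_spotting_null(rep(k, 50), vocab_size = 30000,
                               n_runs = 1000, seed = k)
    expect_lt(abs(null$median - 0.5^(1 / k)), 0.01)
  }
  # single-draw null is approximately uniform
  null1 <- word_spotting_null(rep(1, 100), 30000, n_runs = 200, seed = 1)
  expect_lt(abs(mean(null1$scores) - 0.5), 0.02)
  expect_equal(sum(null1$mean_counts), 100)  # bins partition the sentences
  # determinism
  n2 <- word_spotting_null(rep(3, 10), 1000, n_runs = 5, seed = 9)
  n3 <- word_spotting_null(rep(3, 10), 1000, n_runs = 5, seed = 9)
  expect_identical(n2$scores, n3$scores)
})

test_that("KS comparison is calibrated under the null and powerful off it", {
  null <- word_spotting_null(rep(4, 60), 5000, n_runs = 200, seed = 5)
  ps <- sapply(1:100, function(s) {
    obs <- word_spotting_null(rep(4, 60), 5000, n_runs = 1, seed = 1000 + s)
    ks_compare(as.vector(obs$scores), null)$p_value
  })
  expect_gte(sum(ps > 0.01), 95)

  # maximal separation
  expect_lt(ks_compare(rep(1, 60), null)$p_value, 1e-6)
  # identical samples give statistic 0
  expect_equal(ks_compare(null$scores[1, ], null$scores[1, ])$statistic, 0)
})

test_that("similarity structure correlation behaves at its endpoints", {
  set.seed(6)
  truth <- matrix(rnorm(30 * 15), 30, 15)
  expect_equal(similarity_structure(truth, truth), 1)
  indep <- matrix(rnorm(30 * 15), 30, 15)
  expect_lt(abs(similarity_structure(indep, truth,
                                     include_diagonal = FALSE)), 0.15)
  expect_error(similarity_structure(truth[1:2, ], truth[1:2, ]), "at least 3")
  bad <- truth
  bad[4, ] <- 1
  expect_error(similarity_structure(bad, truth), "constant")
})

test_that("restriction comparisons use the paired t and sign tests", {
  set.seed(7)
  b <- runif(100)
  expect_lt(compare_restrictions(b + 0.1 + rnorm(100, sd = 1e-3), b), 1e-10)
  # equal samples: statistic 0, one-sided p at the 0.5 boundary
  expect_equal(compare_restrictions(b, b), 0.5)
  a2 <- b + rnorm(100, sd = 1e-8)
  expect_gt(compare_restrictions(a2, b), 0.05)

  expect_equal(sign_test(1:6 + 0.5, 1:6), 0.5^6)
  expect_equal(sign_test(c(1, 2), c(1, 2)), 1)
  expect_error(compare_restrictions(1:3, 1:4), "length")

  expect_equal(bonferroni(0.001, 40), 0.04)
  expect_equal(bonferroni(0.5, 16), 1)
})

test_that("evaluation measures are invariant to common stimulus permutation", {
  set.seed(8)
  n <- 24
  dec <- matrix(rnorm(n * 10), n, 10)
  tru <- dec + matrix(rnorm(n * 10, sd = 0.5), n, 10)
  d <- make_design(2, 2, 6)
  perm <- sample(n)
  for (task in c("cross_topic", "within_passage")) {
    p1 <- pairwise_accuracy(dec, tru, enumerate_pairs(d, task))
    dperm <- design_spec(d$id[perm], topic = d$topic[perm],
                         passage = d$passage[perm])
    p2 <- pairwise_accuracy(dec[perm, ], tru[perm, ],
                            enumerate_pairs(dperm, task))
    expect_equal(p1$accuracy, p2$accuracy)
  }
  r1 <- mean(sapply(1:n, function(i) rank_accuracy(dec[i, ], tru, i)$score))
  r2 <- mean(sapply(1:n, function(i) {
    rank_accuracy(dec[perm, ][i, ], tru[perm, ], i)$score
  }))
  expect_equal(r1, r2)
})

test_that("the evaluation report assembles tasks, counts and p-values", {
  set.seed(9)
  d <- make_design(3, 2, 3)
  n <- nrow(d)
  tru <- matrix(rnorm(n * 12), n, 12)
  dec <- tru + matrix(rnorm(n * 12, sd = 0.3), n, 12)
  rep_ <- evaluate_decoding(dec, tru, d, bonferroni_factor = 8)
  expect_equal(nrow(rep_$pairwise), 3L)
  expect_true(all(rep_$pairwise$p_corrected >= rep_$pairwise$p_raw))
  expect_true(all(rep_$pairwise$p_corrected <= 1))
  expect_equal(rep_$rank$n_tests, 6L)  # conservative: passages, not sentences
  expect_gt(rep_$rank$mean_score, 0.9)
})
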