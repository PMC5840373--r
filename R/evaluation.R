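# Row-standardize a matrix so that the dot product of two standardized rows
# equals their Pearson correlation. Constant rows come back as all-zero and
# are flagged.
row_standardize <- function(x) {
  x <- as.matrix(x)
  xc <- x - rowMeans(x)
  nrm <- sqrt(rowSums(xc^2))
  bad <- nrm == 0
  nrm[bad] <- 1
  list(values = xc / nrm, constant = bad)
}

#' Experimental design specification
#'
#' Per-stimulus labels defining the hierarchical sentence designs (sentences
#' nested in passages nested in topics) or a flat word design. The hierarchy
#' determines which stimulus pairs belong to each pairwise classification
#' task and the conservative independent-pair counts for the binomial test.
#'
#' @param ids unique stimulus ids.
#' @param topic,passage per-stimulus topic and passage labels (ignored for
#'   word designs). Every passage must belong to exactly one topic.
#' @param kind \code{"sentence"} or \code{"word"}.
#' @param experiment optional experiment name.
#' @return Object of class \code{design_spec} (a data frame).
#' @export
design_spec <- function(ids, topic = NULL, passage = NULL,
                        kind = c("sentence", "word"), experiment = "") {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_semdec("duplicate stimulus ids in design")
  n <- length(ids)
  if (kind == "sentence") {
    if (is.null(topic) || is.null(passage)) {
      stop_semdec("sentence designs need `topic` and `passage` labels")
    }
    topic <- as.character(topic)
    passage <- as.character(passage)
    if (length(topic) != n || length(passage) != n) {
      stop_semdec("label lengths do not match the number of stimuli")
    }
    # a passage may not span topics
    pt <- unique(data.frame(passage, topic))
    if (anyDuplicated(pt$passage)) {
      stop_semdec("passage(s) assigned to more than one topic")
    }
  } else {
    topic <- rep(NA_character_, n)
    passage <- rep(NA_character_, n)
  }
  df <- data.frame(id = ids, topic = topic, passage = passage,
                   stringsAsFactors = FALSE)
  attr(df, "kind") <- kind
  attr(df, "experiment") <- experiment
  class(df) <- c("design_spec", "data.frame")
  df
}

#' Enumerate stimulus pairs for a pairwise classification task
#'
#' The three sentence tasks grade difficulty: pairs of sentences from
#' different topics are easiest to tell apart, pairs from different passages
#' within a topic harder, and pairs from the same passage hardest.
#'
#' @param design a [design_spec()].
#' @param task one of \code{"all_pairs"}, \code{"cross_topic"},
#'   \code{"within_topic_cross_passage"}, \code{"within_passage"}.
#' @return Two-column integer matrix of row-index pairs (i < j).
#' @export
enumerate_pairs <- function(design,
                            task = c("all_pairs", "cross_topic",
                                     "within_topic_cross_passage",
                                     "within_passage")) {
  task <- match.arg(task)
  stopifnot(inherits(design, "design_spec"))
  n <- nrow(design)
  if (n < 2L) stop_semdec("need at least 2 stimuli to form pairs")
  idx <- utils::combn(n, 2L)
  keep <- switch(task,
    all_pairs = rep(TRUE, ncol(idx)),
    cross_topic = design$topic[idx[1L, ]] != design$topic[idx[2L, ]],
    within_topic_cross_passage =
      design$topic[idx[1L, ]] == design$topic[idx[2L, ]] &
      design$passage[idx[1L, ]] != design$passage[idx[2L, ]],
    within_passage = design$passage[idx[1L, ]] == design$passage[idx[2L, ]]
  )
  if (task != "all_pairs" && attr(design, "kind") == "word") {
    stop_semdec("hierarchical tasks are undefined for word designs")
  }
  keep[is.na(keep)] <- FALSE
  out <- t(idx[, keep, drop = FALSE])
  if (nrow(out) == 0L) stop_semdec("no eligible pairs for task '", task, "'")
  colnames(out) <- c("i", "j")
  out
}

#' Conservative independent-pair count for the binomial test
#'
#' Pairwise results are correlated across all pairs sharing a decoded
#' vector, so the binomial test uses deliberately conservative counts
#' instead of the raw number of pairs: for word designs, the number of
#' distinct words; for sentence designs, (i) cross-topic — the number of
#' passage pairs in different topics times the minimum number of sentences
#' per passage, (ii) within-topic cross-passage — the number of within-topic
#' passage pairs (summed over topics) times the minimum sentences per
#' passage, (iii) within-passage — the number of sentences.
#'
#' @inheritParams enumerate_pairs
#' @return Integer count.
#' @export
conservative_count <- function(design,
                               task = c("all_pairs", "cross_topic",
                                        "within_topic_cross_passage",
                                        "within_passage")) {
  task <- match.arg(task)
  stopifnot(inherits(design, "design_spec"))
  if (attr(design, "kind") == "word") return(nrow(design))
  if (task == "all_pairs") return(nrow(design))
  if (task == "within_passage") return(nrow(design))
  pass <- unique(design[, c("passage", "topic")])
  min_sent <- min(table(design$passage))
  if (task == "cross_topic") {
    pp <- utils::combn(nrow(pass), 2L)
    n_cross <- sum(pass$topic[pp[1L, ]] != pass$topic[pp[2L, ]])
    return(as.integer(n_cross * min_sent))
  }
  # within_topic_cross_passage
  n_within <- sum(vapply(split(pass$passage, pass$topic),
                         function(p) choose(length(p), 2L), numeric(1)))
  as.integer(n_within * min_sent)
}

#' Pairwise classification accuracy
#'
#' For each pair of stimuli, computes the four Pearson correlations between
#' the two decoded vectors and the two text-derived vectors; the pair is
#' classified correctly when the highest of the four is a matched one
#' (decoded vector with its own text vector). Pairs involving a constant
#' (correlation-undefined) vector are skipped and reported in the exclusion
#' tally.
#'
#' @param decoded matrix of decoded vectors (stimuli x dimensions).
#' @param truth matrix of text-derived vectors, rows aligned with
#'   \code{decoded}.
#' @param pairs two-column index matrix as from [enumerate_pairs()].
#' @return List of class \code{pairwise_result}: \code{accuracy},
#'   \code{n_pairs} (scored), \code{n_correct}, \code{n_excluded}.
#' @export
pairwise_accuracy <- function(decoded, truth, pairs) {
  decoded <- as.matrix(decoded)
  truth <- as.matrix(truth)
  if (!all(dim(decoded) == dim(truth))) {
    stop_semdec("`decoded` and `truth` must have identical shapes")
  }
  pairs <- as.matrix(pairs)
  ds <- row_standardize(decoded)
  ts <- row_standardize(truth)
  i <- pairs[, 1L]
  j <- pairs[, 2L]
  bad <- ds$constant[i] | ds$constant[j] | ts$constant[i] | ts$constant[j]
  c11 <- rowSums(ds$values[i, , drop = FALSE] * ts$values[i, , drop = FALSE])
  c22 <- rowSums(ds$values[j, , drop = FALSE] * ts$values[j, , drop = FALSE])
  c12 <- rowSums(ds$values[i, , drop = FALSE] * ts$values[j, , drop = FALSE])
  c21 <- rowSums(ds$values[j, , drop = FALSE] * ts$values[i, , drop = FALSE])
  correct <- pmax(c11, c22) > pmax(c12, c21)
  correct <- correct[!bad]
  structure(list(accuracy = mean(correct), n_pairs = length(correct),
                 n_correct = sum(correct), n_excluded = sum(bad)),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("Pairwise accuracy: %.3f (%d/%d pairs", x$accuracy,
              x$n_correct, x$n_pairs))
  if (x$n_excluded > 0) cat(sprintf(", %d excluded", x$n_excluded))
  cat(")\n")
  invisible(x)
}

#' Conservative binomial p-value for pairwise accuracy
#'
#' Exact upper-tail binomial probability
#' \eqn{P(X \ge n_{correct} \mid H_0: \mathrm{chance})} at rate 0.5, with
#' the observed accuracy rescaled to a conservative independent-trial count
#' ([conservative_count()]); \code{n_correct = round(accuracy * n_independent)}.
#'
#' @param n_correct number of correct trials (or see \code{accuracy}).
#' @param n_independent conservative number of independent trials.
#' @param accuracy alternatively, give the raw accuracy and let the function
#'   rescale it.
#' @return p-value in (0, 1].
#' @export
binomial_pvalue <- function(n_correct = NULL, n_independent, accuracy = NULL) {
  n_independent <- check_count(n_independent, "n_independent")
  if (is.null(n_correct)) {
    if (is.null(accuracy)) stop_semdec("give `n_correct` or `accuracy`")
    n_correct <- round(accuracy * n_independent)
  }
  if (n_correct < 0 || n_correct > n_independent) {
    stop_semdec("`n_correct` must be between 0 and `n_independent`")
  }
  stats::pbinom(n_correct - 1L, n_independent, 0.5, lower.tail = FALSE)
}

#' Rank accuracy of a decoded vector against a candidate set
#'
#' Candidates are ranked by Pearson correlation with the decoded vector
#' (descending); the score of the true candidate is
#' \eqn{1 - (\mathrm{rank} - 1)/(n - 1)}: 1 at the top of the ranking, 0 at
#' the bottom, 0.5 at chance. Ties receive average ranks, so a tie spanning
#' the true candidate scores at the tie's average position.
#'
#' @param decoded_row decoded vector.
#' @param candidates matrix of candidate vectors (rows).
#' @param true_index row index of the correct candidate.
#' @return List of class \code{rank_result}: \code{score}, \code{rank},
#'   \code{n_candidates}.
#' @export
rank_accuracy <- function(decoded_row, candidates, true_index) {
  candidates <- as.matrix(candidates)
  n <- nrow(candidates)
  if (n < 2L) stop_semdec("need at least 2 candidates")
  if (true_index < 1L || true_index > n) stop_semdec("invalid `true_index`")
  if (stats::sd(decoded_row) == 0) {
    stop_semdec("decoded vector is constant; correlation ranking undefined")
  }
  cs <- row_standardize(candidates)
  dstd <- (decoded_row - mean(decoded_row))
  dstd <- dstd / sqrt(sum(dstd^2))
  r <- drop(cs$values %*% dstd)
  r[cs$constant] <- -Inf
  rk <- rank(-r, ties.method = "average")[true_index]
  structure(list(score = 1 - (rk - 1) / (n - 1), rank = rk,
                 n_candidates = n),
            class = "rank_result")
}

#' Normal-approximation p-value for mean rank accuracy
#'
#' Under the null, each ranking is a uniform multinomial outcome normalized
#' to a rank-accuracy score; by the central limit theorem the mean of
#' \code{n_tests} scores is approximately normal with mean 0.5 and variance
#' \deqn{\frac{R + 1}{12 (R - 1)\, T}}
#' where \eqn{R} is the number of candidate vectors in the range and
#' \eqn{T} the number of tests. Because scores of sentences in the same
#' passage can be correlated, a conservative \eqn{T} (e.g., the number of
#' passages rather than sentences) is appropriate.
#'
#' @param mean_rank_accuracy observed mean score.
#' @param n_candidates number of candidate vectors in the decoding range.
#' @param n_tests (conservative) number of averaged tests.
#' @return One-sided upper-tail p-value.
#' @export
rank_null_pvalue <- function(mean_rank_accuracy, n_candidates, n_tests) {
  n_candidates <- check_count(n_candidates, "n_candidates", min = 2L)
  n_tests <- check_count(n_tests, "n_tests")
  v <- (n_candidates + 1) / (12 * (n_candidates - 1) * n_tests)
  stats::pnorm(mean_rank_accuracy, mean = 0.5, sd = sqrt(v),
               lower.tail = FALSE)
}

#' Word-spotting score of a decoded vector
#'
#' Ranks the entire vocabulary by correlation with the decoded vector and
#' scores the sentence by the best rank accuracy achieved by any of its
#' words. This open-ended task measures how much usable information the
#' decoded vector carries when no closed candidate set exists; synonyms and
#' related words compete with — and may outrank — the sentence's actual
#' words, which is why even good decoders rarely hit 1.0.
#'
#' @param decoded_row decoded vector.
#' @param vocab a [word_vector_table()] (the basic vocabulary, ~30,000
#'   words at reference scale).
#' @param sentence_words the sentence's (in-vocabulary) words.
#' @return List of class \code{word_spot_result}: \code{score}, plus
#'   \code{word_scores} (per-word rank accuracies, named).
#' @export
word_spotting <- function(decoded_row, vocab, sentence_words) {
  stopifnot(inherits(vocab, "word_vectors"))
  if (length(sentence_words) == 0L) stop_semdec("empty sentence word list")
  widx <- match(sentence_words, vocab$words)
  if (anyNA(widx)) {
    stop_semdec("word(s) not in vocabulary: ",
                paste(sentence_words[is.na(widx)], collapse = ", "))
  }
  if (stats::sd(decoded_row) == 0) stop_semdec("decoded vector is constant")
  vs <- row_standardize(vocab$vectors)
  dstd <- decoded_row - mean(decoded_row)
  dstd <- dstd / sqrt(sum(dstd^2))
  r <- drop(vs$values %*% dstd)
  r[vs$constant] <- -Inf
  rk <- rank(-r, ties.method = "average")
  n <- length(r)
  scores <- 1 - (rk[widx] - 1) / (n - 1)
  names(scores) <- sentence_words
  structure(list(score = max(scores), word_scores = scores),
            class = "word_spot_result")
}

#' Simulated null distribution for word-spotting scores
#'
#' Under the null, a sentence with \eqn{k} (in-vocabulary) words receives
#' \eqn{k} uniformly random ranks in \eqn{\{1, \ldots, V\}}; each is
#' normalized to a rank accuracy and the sentence scores the maximum. Each
#' simulation run produces one score per sentence; scores are binned and the
#' bin frequencies averaged across runs. The median of the max of \eqn{k}
#' uniforms is \eqn{0.5^{1/k}}, so sentences with more words push the null
#' median well above 0.5.
#'
#' @param word_counts per-sentence word counts (all \eqn{\ge} 1).
#' @param vocab_size vocabulary size (\eqn{\ge} 2).
#' @param n_runs simulation runs (1000 at reference scale).
#' @param seed RNG seed.
#' @param n_bins histogram bins on \eqn{[0, 1]}.
#' @return Object of class \code{word_spot_null}: \code{breaks},
#'   \code{mean_counts} (per-bin frequencies averaged over runs),
#'   \code{scores} (runs x sentences matrix), \code{median}.
#' @export
word_spotting_null <- function(word_counts, vocab_size, n_runs = 1000L,
                               seed = 1L, n_bins = 20L) {
  word_counts <- as.integer(word_counts)
  if (any(word_counts < 1L)) stop_semdec("word counts must be >= 1")
  vocab_size <- check_count(vocab_size, "vocab_size", min = 2L)
  n_runs <- check_count(n_runs, "n_runs")
  ns <- length(word_counts)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  scores <- with_seed(seed, {
    out <- matrix(NA_real_, n_runs, ns)
    for (r in seq_len(n_runs)) {
      draws <- sample.int(vocab_size, sum(word_counts), replace = TRUE)
      acc <- 1 - (draws - 1) / (vocab_size - 1)
      grp <- rep.int(seq_len(ns), word_counts)
      out[r, ] <- vapply(split(acc, grp), max, numeric(1))
    }
    out
  })
  counts <- matrix(0, n_runs, n_bins)
  for (r in seq_len(n_runs)) {
    counts[r, ] <- graphics::hist(scores[r, ], breaks = breaks,
                                  plot = FALSE)$counts
  }
  structure(list(breaks = breaks, mean_counts = colMeans(counts),
                 scores = scores, median = stats::median(scores)),
            class = "word_spot_null")
}

#' @export
print.word_spot_null <- function(x, ...) {
  cat(sprintf("Word-spotting null: %d runs x %d sentences, median %.3f\n",
              nrow(x$scores), ncol(x$scores), x$median))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of observed scores against a null
#'
#' Two-sided two-sample KS test between the observed word-spotting scores
#' and the simulated null distribution (pooled across runs).
#'
#' @param observed_scores numeric vector of observed scores.
#' @param null a [word_spotting_null()] object or a numeric vector of null
#'   scores.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
ks_compare <- function(observed_scores, null) {
  if (inherits(null, "word_spot_null")) null <- as.vector(null$scores)
  if (length(observed_scores) == 0L || length(null) == 0L) {
    stop_semdec("empty inputs")
  }
  kt <- suppressWarnings(
    stats::ks.test(observed_scores, null, alternative = "two.sided",
                   exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Correlation of similarity structures
#'
#' Builds the stimulus-by-stimulus correlation matrix of the text-derived
#' vectors (text/text) and the matrix of correlations between decoded and
#' text vectors (decoded/text), and returns the Pearson correlation between
#' corresponding entries. A high value means the decoder preserves the
#' relational geometry of the semantic space even when individual vectors
#' are noisy. The diagonal is included by default (it carries the
#' decoded-to-own-text correlations, which are informative); set
#' \code{include_diagonal = FALSE} for the off-diagonal-only variant.
#'
#' @param decoded,truth aligned stimulus x dimension matrices (>= 3
#'   stimuli).
#' @param include_diagonal include the matrix diagonals in the comparison.
#' @return Pearson correlation between the two similarity structures.
#' @export
similarity_structure <- function(decoded, truth, include_diagonal = TRUE) {
  decoded <- as.matrix(decoded)
  truth <- as.matrix(truth)
  if (!all(dim(decoded) == dim(truth))) stop_semdec("shape mismatch")
  if (nrow(decoded) < 3L) stop_semdec("need at least 3 stimuli")
  ds <- row_standardize(decoded)
  ts <- row_standardize(truth)
  if (any(ds$constant) || any(ts$constant)) {
    stop_semdec("constant row(s); similarity undefined")
  }
  tt <- tcrossprod(ts$values)
  dt <- tcrossprod(ds$values, ts$values)
  if (include_diagonal) {
    stats::cor(as.vector(tt), as.vector(dt))
  } else {
    off <- row(tt) != col(tt)
    stats::cor(tt[off], dt[off])
  }
}

#' Compare voxel-restriction conditions
#'
#' \code{compare_restrictions()} runs the one-sided paired t-test for
#' pairwise accuracy, with each sample containing the average accuracy of
#' pairs involving each sentence (alternative: condition A better than B).
#' \code{sign_test()} is the companion test for per-subject rank accuracies:
#' the exact binomial probability of at least the observed number of
#' positive differences among the non-zero ones.
#'
#' @param a,b paired per-sentence accuracy vectors (t-test) or paired
#'   per-subject rank accuracies (sign test).
#' @return p-value.
#' @export
compare_restrictions <- function(a, b) {
  if (length(a) != length(b)) stop_semdec("paired samples differ in length")
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate differences: the t statistic is 0 (p = 0.5) or +/- infinite
    return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  tt$p.value
}

#' @rdname compare_restrictions
#' @export
sign_test <- function(a, b) {
  if (length(a) != length(b)) stop_semdec("paired samples differ in length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  stats::pbinom(sum(d > 0) - 1L, length(d), 0.5, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies raw p-values by the number of comparisons (subjects x tasks,
#' or tasks x networks x experiments in the restriction analyses) and caps
#' at 1.
#'
#' @param p raw p-value(s).
#' @param factor number of comparisons.
#' @return Corrected p-value(s).
#' @export
bonferroni <- function(p, factor) {
  factor <- check_count(factor, "factor")
  pmin(1, p * factor)
}

#' Evaluate decoded vectors across pairwise tasks
#'
#' Convenience wrapper running [pairwise_accuracy()] for each requested
#' task with its [conservative_count()] and [binomial_pvalue()], plus the
#' overall rank accuracy with its normal null.
#'
#' @param decoded,truth aligned stimulus x dimension matrices.
#' @param design a [design_spec()].
#' @param tasks pairwise tasks to run (defaults depend on design kind).
#' @param bonferroni_factor multiplier for the corrected p-values.
#' @param rank_n_tests conservative number of tests for the rank-accuracy
#'   null; defaults to the number of passages (sentence designs) or
#'   stimuli (word designs).
#' @return Object of class \code{evaluation_report}: data frame
#'   \code{pairwise} (task, accuracy, n_pairs, n_independent, p_raw,
#'   p_corrected) and list \code{rank} (mean score, p-values).
#' @export
evaluate_decoding <- function(decoded, truth, design, tasks = NULL,
                              bonferroni_factor = 1L, rank_n_tests = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(tasks)) {
    tasks <- if (attr(design, "kind") == "word") "all_pairs" else
      c("cross_topic", "within_topic_cross_passage", "within_passage")
  }
  rows <- lapply(tasks, function(tk) {
    pr <- pairwise_accuracy(decoded, truth, enumerate_pairs(design, tk))
    ni <- conservative_count(design, tk)
    p <- binomial_pvalue(n_independent = ni, accuracy = pr$accuracy)
    data.frame(task = tk, accuracy = pr$accuracy, n_pairs = pr$n_pairs,
               n_independent = ni, p_raw = p,
               p_corrected = bonferroni(p, bonferroni_factor))
  })
  n <- nrow(decoded)
  rk <- vapply(seq_len(n), function(i) {
    rank_accuracy(decoded[i, ], truth, i)$score
  }, numeric(1))
  if (is.null(rank_n_tests)) {
    rank_n_tests <- if (attr(design, "kind") == "word") n else
      length(unique(design$passage))
  }
  p_rank <- rank_null_pvalue(mean(rk), n, rank_n_tests)
  structure(list(pairwise = do.call(rbind, rows),
                 rank = list(mean_score = mean(rk), scores = rk,
                             n_candidates = n, n_tests = rank_n_tests,
                             p_raw = p_rank,
                             p_corrected = bonferroni(p_rank,
                                                      bonferroni_factor))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Pairwise classification:\n")
  print(x$pairwise, row.names = FALSE)
  cat(sprintf("Rank accuracy: %.3f over %d candidates (p = %.3g, corrected %.3g)\n",
              x$rank$mean_score, x$rank$n_candidates, x$rank$p_raw,
              x$rank$p_corrected))
  invisible(x)
}
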