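#' Cosine similarity matrix of a semantic space
#'
#' Computes the n-by-n matrix of cosine similarities between all pairs of
#' word vectors. This is the first step of the spectral-clustering pipeline:
#' cosine similarity between embedding vectors tracks semantic relatedness,
#' so the similarity matrix defines the graph on which words are clustered.
#'
#' @param table a [word_vector_table()].
#' @return A square numeric matrix with class attribute
#'   \code{similarity_matrix} and \code{stage = "raw_cosine"}: symmetric,
#'   entries in \eqn{[-1, 1]}, unit diagonal.
#' @export
cosine_similarity_matrix <- function(table) {
  stopifnot(inherits(table, "word_vectors"))
  v <- table$vectors
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) {
    stop_semdec("zero-norm embedding row(s): ",
                paste(table$words[nrm == 0], collapse = ", "))
  }
  u <- v / nrm
  s <- tcrossprod(u)
  # clamp tiny numerical overshoot, force exact unit diagonal
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  attr(s, "stage") <- "raw_cosine"
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Row-stochastic normalization of a cosine similarity matrix
#'
#' Maps raw cosine similarities through \eqn{(C + 1)/2} so all entries lie in
#' \eqn{[0, 1]}, zeroes the diagonal (a word should not vote for itself), and
#' divides each row by its sum so rows form probability distributions. The
#' result is the transition matrix whose leading eigenvectors define the
#' spectral embedding.
#'
#' @param sim a \code{similarity_matrix} at stage \code{"raw_cosine"}.
#' @return The row-stochastic matrix (stage \code{"row_stochastic"}).
#' @export
normalize_similarity <- function(sim) {
  if (!identical(attr(sim, "stage"), "raw_cosine")) {
    stop_semdec("`sim` must be a raw cosine similarity matrix")
  }
  if (nrow(sim) < 2L) {
    stop_semdec("need at least 2 words to build a row-stochastic matrix")
  }
  s <- (unclass(sim) + 1) / 2
  diag(s) <- 0
  rs <- rowSums(s)
  if (any(rs == 0)) {
    stop_semdec("row(s) with zero total similarity after zeroing the diagonal")
  }
  s <- s / rs
  attr(s, "stage") <- "row_stochastic"
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Spectral embedding of a row-stochastic similarity matrix
#'
#' Eigendecomposes the (non-symmetric) row-stochastic matrix and keeps the
#' \code{n_eig} eigenvectors with the largest real eigenvalue parts. Real
#' parts are taken and each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive, making the embedding reproducible
#' across LAPACK builds. The leading eigenvector of a connected
#' row-stochastic matrix is constant (eigenvalue 1); it is kept, carrying no
#' cluster information but doing no harm to k-means.
#'
#' @param sim row-stochastic \code{similarity_matrix}.
#' @param n_eig number of eigenvectors to keep.
#' @return List with \code{coords} (n_words x n_eig) and \code{eigenvalues}
#'   (sorted descending by real part), class \code{spectral_embedding}.
#' @export
spectral_embedding <- function(sim, n_eig) {
  if (!identical(attr(sim, "stage"), "row_stochastic")) {
    stop_semdec("`sim` must be row-stochastic; call normalize_similarity() first")
  }
  n_eig <- check_count(n_eig, "n_eig")
  if (n_eig > nrow(sim)) stop_semdec("n_eig exceeds the number of words")
  e <- eigen(unclass(sim), symmetric = FALSE)
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(n_eig)]
  vals <- Re(e$values[ord])
  vecs <- Re(e$vectors[, ord, drop = FALSE])
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(coords = vecs, eigenvalues = vals),
            class = "spectral_embedding")
}

# k-means++ seeding: D^2-weighted sampling of initial centers.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1L) {
    for (j in 2L:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1L, prob = probs)
      nd <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  x[centers, , drop = FALSE]
}

#' Spectral clustering of a semantic space
#'
#' Clusters the vocabulary by (1) computing pairwise cosine similarities,
#' (2) rescaling them to \eqn{[0,1]} and zeroing the diagonal, (3) row
#' normalizing to a stochastic matrix, (4) taking its leading \code{n_eig}
#' eigenvectors as an embedding, and (5) running k-means (squared Euclidean
#' distance, k-means++ seeding, \code{n_restarts} restarts keeping the best
#' within-cluster sum of squares) on the embedding. Words with the same
#' profile of similarity to all other words land close together in the
#' spectral embedding, which is more robust than clustering the raw vectors.
#'
#' For a ~30,000-word vocabulary the reference configuration is
#' \code{k = 200}, \code{n_eig = 100}.
#'
#' @param table a [word_vector_table()].
#' @param k number of clusters.
#' @param n_eig embedding dimensionality.
#' @param seed integer seed making the k-means stage reproducible.
#' @param n_restarts k-means restarts (best solution kept).
#' @return Object of class \code{cluster_assignment}: list with
#'   \code{labels} (integers in \code{1:k}, named by word), \code{k},
#'   \code{seed}, \code{sizes} (per-cluster word counts), and
#'   \code{embedding} (the [spectral_embedding()]).
#' @export
spectral_cluster <- function(table, k, n_eig = min(100L, length(table$words)),
                             seed = 1L, n_restarts = 10L) {
  stopifnot(inherits(table, "word_vectors"))
  k <- check_count(k, "k")
  n <- length(table$words)
  if (k > n) stop_semdec("k exceeds the number of words")
  emb <- spectral_embedding(normalize_similarity(cosine_similarity_matrix(table)),
                            n_eig)
  x <- emb$coords
  labels <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cen <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = cen, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best$cluster
  })
  names(labels) <- table$words
  structure(list(labels = labels, k = k, seed = seed,
                 sizes = tabulate(labels, nbins = k), embedding = emb),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d words in %d clusters (seed %d)\n",
              length(x$labels), x$k, x$seed))
  cat("Cluster sizes: ")
  cat(paste(utils::head(x$sizes, 10L), collapse = ", "))
  if (x$k > 10L) cat(", ...")
  cat("\n")
  invisible(x)
}

#' Write a cluster assignment as TSV
#'
#' Two columns: \code{word}, \code{cluster_id} (1-based).
#'
#' @param assignment a \code{cluster_assignment}.
#' @param path output path.
#' @export
write_clusters <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  utils::write.table(
    data.frame(word = names(assignment$labels),
               cluster_id = unname(assignment$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dimension usage of a stimulus word set
#'
#' A dimension is "represented" by a selected word if that word's absolute
#' value on the dimension is in the top \code{quantile} fraction of absolute
#' values across the whole vocabulary on that dimension. The per-dimension
#' count of representing words diagnoses how well a stimulus set spans the
#' semantic space: dimensions with few representatives are poorly probed by
#' the experiment.
#'
#' @param table a [word_vector_table()] for the full vocabulary.
#' @param selected_words tokens of the stimulus set (subset of the
#'   vocabulary).
#' @param quantile top fraction of magnitude that counts as representing
#'   (default 0.10).
#' @return List of class \code{dimension_usage} with \code{counts} (one
#'   integer per dimension) and \code{quantile}.
#' @export
dimension_usage <- function(table, selected_words, quantile = 0.10) {
  stopifnot(inherits(table, "word_vectors"))
  if (quantile <= 0 || quantile > 1) stop_semdec("`quantile` must be in (0, 1]")
  sel <- lookup_vectors(table, selected_words)
  a <- abs(table$vectors)
  thresh <- apply(a, 2L, stats::quantile, probs = 1 - quantile, names = FALSE)
  counts <- colSums(abs(sel) >= rep(thresh, each = nrow(sel)))
  structure(list(counts = as.integer(counts), quantile = quantile),
            class = "dimension_usage")
}
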