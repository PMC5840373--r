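#' Configuration for the synthetic-data generator
#'
#' The generator instantiates the pipeline's data-generating assumptions
#' with known ground truth: a clustered semantic space on the unit sphere, a
#' sparse linear encoding of semantic dimensions into spatially contiguous
#' voxel blobs on a 3D grid, and i.i.d. Gaussian measurement noise (the
#' inputs represent deconvolved per-stimulus estimates, so no temporal
#' autocorrelation is modeled).
#'
#' \code{noise_sd} is expressed relative to the signal: the encoding matrix
#' is rescaled so the average signal standard deviation across informative
#' voxels is 1, and noise with standard deviation \code{noise_sd} is then
#' added — \code{noise_sd = 1} therefore means per-voxel SNR of about 1,
#' and \code{noise_sd = 0} a noiseless forward model.
#'
#' @param n_words vocabulary size.
#' @param n_dims semantic dimensions (kept well below the 300 of production
#'   embeddings so simulations stay fast).
#' @param n_clusters planted clusters in the semantic space.
#' @param grid_shape 3D voxel grid (mask = whole grid).
#' @param n_informative voxels carrying signal.
#' @param noise_sd noise level relative to unit signal SD.
#' @param n_topics,n_passages,n_sentences hierarchical sentence design:
#'   topics x passages per topic x sentences per passage;
#'   \code{n_sentences} may be a vector (recycled over passages) for mixed
#'   designs.
#' @param words_per_sentence content words drawn per sentence.
#' @param jitter within-cluster angular spread of word vectors.
#' @param min_cos_sep maximum allowed cosine between cluster centers
#'   (centers are redrawn until all pairs are at least this separated).
#' @param seed master seed; each generator stage derives its own stream.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_words = 120L, n_dims = 50L, n_clusters = 24L,
                             grid_shape = c(20L, 10L, 10L),
                             n_informative = 50L, noise_sd = 1,
                             n_topics = 24L, n_passages = 4L,
                             n_sentences = 4L, words_per_sentence = 4L,
                             jitter = 0.05, min_cos_sep = 0.5, seed = 1L) {
  cfg <- list(n_words = check_count(n_words, "n_words"),
              n_dims = check_count(n_dims, "n_dims"),
              n_clusters = check_count(n_clusters, "n_clusters"),
              grid_shape = as.integer(grid_shape),
              n_informative = check_count(n_informative, "n_informative",
                                          min = 0L),
              noise_sd = noise_sd,
              n_topics = check_count(n_topics, "n_topics"),
              n_passages = check_count(n_passages, "n_passages"),
              n_sentences = as.integer(n_sentences),
              words_per_sentence = check_count(words_per_sentence,
                                               "words_per_sentence"),
              jitter = jitter, min_cos_sep = min_cos_sep,
              seed = as.integer(seed))
  if (cfg$n_clusters > cfg$n_words) stop_semdec("more clusters than words")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L)) {
    stop_semdec("`grid_shape` must be 3 positive integers")
  }
  if (cfg$n_informative > prod(cfg$grid_shape)) {
    stop_semdec("more informative voxels than grid voxels")
  }
  if (cfg$noise_sd < 0) stop_semdec("`noise_sd` must be >= 0")
  if (length(cfg$n_sentences) < 1L || any(cfg$n_sentences < 1L)) {
    stop_semdec("`n_sentences` must be positive (a count, or one per passage)")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Named sub-streams derived from the master seed keep the generator stages
# independently replayable.
sub_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 1009 + offset) %% 2147483647)
}

#' Generate a clustered semantic space
#'
#' Cluster centers are drawn on the unit sphere and redrawn until every pair
#' is separated by cosine at most \code{min_cos_sep}; words are assigned to
#' clusters round-robin and placed at their center plus isotropic Gaussian
#' jitter, then renormalized to the sphere. The result mimics regions of
#' related words in an embedding space.
#'
#' @param cfg a [synthetic_config()].
#' @return List with \code{table} (a [word_vector_table()], words
#'   \code{w0001, ...}) and \code{labels} (planted cluster of each word).
#' @export
make_semantic_space <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(sub_seed(cfg, 1L), {
    k <- cfg$n_clusters
    d <- cfg$n_dims
    centers <- NULL
    for (try in seq_len(200L)) {
      cand <- matrix(stats::rnorm(k * d), k, d)
      cand <- cand / sqrt(rowSums(cand^2))
      cc <- tcrossprod(cand)
      if (k == 1L || max(cc[upper.tri(cc)]) <= cfg$min_cos_sep) {
        centers <- cand
        break
      }
    }
    if (is.null(centers)) {
      stop_semdec("could not place ", k, " cluster centers at cosine <= ",
                  cfg$min_cos_sep, " in ", d, " dimensions")
    }
    labels <- rep_len(seq_len(k), cfg$n_words)
    v <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_words * d, sd = cfg$jitter), cfg$n_words, d)
    v <- v / sqrt(rowSums(v^2))
    words <- sprintf("w%04d", seq_len(cfg$n_words))
    list(table = word_vector_table(words, v), labels = labels)
  })
}

#' Generate a sparse linear forward model
#'
#' Chooses the informative voxels as spatially contiguous blobs (seed voxels
#' grown through their 3D neighborhoods), so that neighborhood-based
#' informativeness scoring sees realistic local structure, and draws their
#' encoding weights i.i.d. normal; all other voxels encode nothing. The
#' encoding matrix is rescaled at simulation time so informative voxels have
#' unit signal SD (see [synthetic_config()]).
#'
#' @param cfg a [synthetic_config()].
#' @return List of class \code{synthetic_ground_truth}: \code{encoding}
#'   (voxels x dimensions, zero rows outside the informative set),
#'   \code{informative}, \code{geometry}.
#' @export
make_forward_model <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  geom <- volume_geometry(cfg$grid_shape, seq_len(prod(cfg$grid_shape)))
  nv <- n_voxels(geom)
  informative <- integer(0)
  if (cfg$n_informative > 0L) {
    informative <- with_seed(sub_seed(cfg, 2L), {
      chosen <- integer(0)
      for (try in seq_len(1000L)) {
        seed_vox <- sample.int(nv, 1L)
        blob <- neighborhood(geom, seed_vox)
        chosen <- union(chosen, blob)
        if (length(chosen) >= cfg$n_informative) break
      }
      if (length(chosen) < cfg$n_informative) {
        stop_semdec("failed to place informative blobs")
      }
      sort(chosen[seq_len(cfg$n_informative)])
    })
  }
  a <- matrix(0, nv, cfg$n_dims)
  if (length(informative) > 0L) {
    a[informative, ] <- with_seed(sub_seed(cfg, 3L), {
      matrix(stats::rnorm(length(informative) * cfg$n_dims),
             length(informative), cfg$n_dims)
    })
  }
  structure(list(encoding = a, informative = informative, geometry = geom),
            class = "synthetic_ground_truth")
}

#' Simulate a decoding experiment with known ground truth
#'
#' Generates a semantic space, a forward model, and a stimulus set, then
#' produces brain data as \eqn{X = Z A^\top + \varepsilon}: semantic vectors
#' pushed through the sparse linear encoding plus Gaussian noise.
#'
#' Word experiments use single-word stimuli (one per vocabulary word, up to
#' \code{n_stimuli}); sentence experiments build the hierarchical
#' topic/passage/sentence design, with each topic tied to one planted
#' cluster and each sentence averaging content words drawn from that
#' cluster's vocabulary. The reference sentence designs are 24 topics x 4
#' passages x 4 sentences (384) and 24 topics x 3-4 passages mixed (243).
#'
#' @param cfg a [synthetic_config()].
#' @param kind \code{"words"} or \code{"sentences"}.
#' @param n_stimuli for word experiments, how many words to present
#'   (default: all).
#' @return List of class \code{synthetic_experiment}: \code{examples}
#'   (an [example_matrix()]), \code{stimuli} (a [stimulus_table()] with
#'   vectors attached), \code{Z} (true semantic vectors), \code{design}
#'   (a [design_spec()]), \code{space}, \code{labels} (planted clusters),
#'   \code{ground_truth} (encoding as used, informative set, geometry).
#' @export
simulate_experiment <- function(cfg, kind = c("words", "sentences"),
                                n_stimuli = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  kind <- match.arg(kind)
  space <- make_semantic_space(cfg)
  fwd <- make_forward_model(cfg)
  if (kind == "words") {
    n_st <- if (is.null(n_stimuli)) cfg$n_words else
      check_count(n_stimuli, "n_stimuli")
    if (n_st > cfg$n_words) stop_semdec("more stimuli than vocabulary words")
    widx <- seq_len(n_st)
    ids <- sprintf("stim_%04d", widx)
    st <- stimulus_table(ids, rep("word", n_st), space$table$words[widx],
                         as.list(space$table$words[widx]))
    design <- design_spec(ids, kind = "word", experiment = "synthetic-words")
  } else {
    if (cfg$n_topics > cfg$n_clusters) {
      stop_semdec("sentence designs need n_topics <= n_clusters")
    }
    cluster_words <- split(space$table$words, space$labels)
    small <- lengths(cluster_words[seq_len(cfg$n_topics)]) <
      cfg$words_per_sentence
    if (any(small)) {
      stop_semdec("cluster vocabulary too small for ",
                  cfg$words_per_sentence, " words per sentence")
    }
    pg <- expand.grid(passage = seq_len(cfg$n_passages),
                      topic = seq_len(cfg$n_topics))
    sent_counts <- rep_len(cfg$n_sentences, nrow(pg))
    grid <- data.frame(topic = rep(pg$topic, sent_counts),
                       passage = rep(pg$passage, sent_counts),
                       sentence = unlist(lapply(sent_counts, seq_len)))
    ids <- sprintf("t%02dp%02ds%02d", grid$topic, grid$passage, grid$sentence)
    content <- with_seed(sub_seed(cfg, 4L), {
      lapply(grid$topic, function(tp) {
        sample(cluster_words[[tp]], cfg$words_per_sentence)
      })
    })
    st <- stimulus_table(ids, rep("sentence", nrow(grid)),
                         vapply(content, paste, character(1), collapse = " "),
                         content)
    design <- design_spec(ids,
                          topic = sprintf("topic%02d", grid$topic),
                          passage = sprintf("t%02dp%02d", grid$topic,
                                            grid$passage),
                          kind = "sentence", experiment = "synthetic-sentences")
  }
  st <- attach_vectors(st, space$table)
  z <- semantic_vectors(st)
  a <- fwd$encoding
  signal <- z %*% t(a)
  if (length(fwd$informative) > 0L) {
    sig_sd <- mean(apply(signal[, fwd$informative, drop = FALSE], 2L,
                         stats::sd))
    if (sig_sd > 0) {
      a <- a / sig_sd
      signal <- signal / sig_sd
    }
  }
  x <- signal
  if (cfg$noise_sd > 0) {
    x <- x + with_seed(sub_seed(cfg, 5L), {
      matrix(stats::rnorm(length(signal), sd = cfg$noise_sd),
             nrow(signal), ncol(signal))
    })
  }
  em <- example_matrix(x, st$id, fwd$geometry)
  structure(list(examples = em, stimuli = st, Z = z, design = design,
                 space = space$table, labels = space$labels,
                 ground_truth = structure(
                   list(encoding = a, informative = fwd$informative,
                        geometry = fwd$geometry),
                   class = "synthetic_ground_truth")),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment: %d stimuli (%s), %d voxels, %d dims, %d informative\n",
              nrow(x$examples$values), attr(x$design, "experiment"),
              ncol(x$examples$values), ncol(x$Z),
              length(x$ground_truth$informative)))
  invisible(x)
}
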