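#' Construct a word-vector table
#'
#' A word-vector table holds a vocabulary together with its embedding matrix
#' (one row per word). It is the package's representation of a semantic
#' space: every downstream stage — clustering, sentence composition,
#' decoding, word spotting — looks words up in one of these.
#'
#' Token matching is exact and case-sensitive; lowercase your stimuli
#' upstream if the embedding vocabulary is lowercase.
#'
#' @param words character vector of unique tokens.
#' @param vectors numeric matrix, \code{length(words)} rows; columns are
#'   embedding dimensions.
#' @return An object of class \code{word_vectors} with elements
#'   \code{words} and \code{vectors} (rownames set to the words).
#' @seealso [read_word_vectors()] to load a GloVe-style text file,
#'   [sentence_vector()], [spectral_cluster()].
#' @export
word_vector_table <- function(words, vectors) {
  words <- as.character(words)
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(words) != nrow(vectors)) {
    stop_semdec("`words` and `vectors` disagree on the number of words")
  }
  if (anyDuplicated(words)) {
    stop_semdec("duplicate tokens in vocabulary: ",
                paste(unique(words[duplicated(words)]), collapse = ", "))
  }
  if (ncol(vectors) < 1L) stop_semdec("embeddings need at least one dimension")
  check_finite_matrix(vectors, "vectors")
  rownames(vectors) <- words
  structure(list(words = words, vectors = vectors), class = "word_vectors")
}

#' @export
print.word_vectors <- function(x, ...) {
  cat(sprintf("Word-vector table: %d words x %d dimensions\n",
              length(x$words), ncol(x$vectors)))
  invisible(x)
}

#' Read word embeddings from a GloVe-style text file
#'
#' Each line holds a token followed by the embedding values, separated by
#' whitespace. Gzipped files are read transparently.
#'
#' @param path path to the embedding file (\code{.txt} or \code{.txt.gz}).
#' @param n_max maximum number of lines to read (\code{Inf} for all); handy
#'   for working with the head of a large vocabulary file.
#' @return A [word_vector_table()].
#' @export
read_word_vectors <- function(path, n_max = Inf) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, n = if (is.finite(n_max)) n_max else -1L)
  if (length(lines) == 0L) stop_semdec("empty embedding file: ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nfield <- lengths(parts)
  if (length(unique(nfield)) != 1L) {
    stop_semdec("inconsistent field counts in embedding file (lines differ in dimension)")
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1L]),
                 numeric(nfield[1L] - 1L))
  vectors <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  word_vector_table(words, vectors)
}

# Row lookup with an informative error naming the missing token(s).
lookup_vectors <- function(table, tokens, context = NULL) {
  stopifnot(inherits(table, "word_vectors"))
  idx <- match(tokens, table$words)
  if (anyNA(idx)) {
    missing <- unique(tokens[is.na(idx)])
    where <- if (is.null(context)) "" else sprintf(" (stimulus '%s')", context)
    stop_semdec("token(s) not in vocabulary", where, ": ",
                paste(missing, collapse = ", "))
  }
  table$vectors[idx, , drop = FALSE]
}

#' Compose a sentence vector by averaging content-word vectors
#'
#' The semantic vector of a sentence is the arithmetic mean of the embedding
#' vectors of its content words. Function words carry little lexical
#' semantics and are assumed to have been stripped when the stimulus table
#' was authored.
#'
#' @param content_words non-empty character vector of tokens, all present in
#'   \code{table}.
#' @param table a [word_vector_table()].
#' @return Numeric vector of length \code{ncol(table$vectors)}.
#' @export
sentence_vector <- function(content_words, table) {
  if (length(content_words) == 0L) {
    stop_semdec("cannot build a sentence vector from an empty content-word list")
  }
  v <- lookup_vectors(table, content_words)
  colMeans(v)
}
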