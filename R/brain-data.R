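#' Construct an example matrix
#'
#' The example matrix is the decoding pipeline's data container: one row per
#' stimulus (a deconvolved per-stimulus activation image), one column per
#' in-mask voxel, tied to a [volume_geometry()].
#'
#' @param values numeric matrix, stimuli x in-mask voxels.
#' @param stimulus_ids unique ids, one per row.
#' @param geometry a [volume_geometry()] with as many voxels as columns.
#' @return Object of class \code{example_matrix}.
#' @export
example_matrix <- function(values, stimulus_ids, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  values <- check_finite_matrix(as.matrix(values), "values")
  storage.mode(values) <- "double"
  stimulus_ids <- as.character(stimulus_ids)
  if (nrow(values) != length(stimulus_ids)) {
    stop_semdec("row count does not match number of stimulus ids")
  }
  if (anyDuplicated(stimulus_ids)) stop_semdec("duplicate stimulus ids")
  if (ncol(values) != n_voxels(geometry)) {
    stop_semdec("column count does not match the mask size")
  }
  rownames(values) <- stimulus_ids
  structure(list(values = values, stimulus_ids = stimulus_ids,
                 geometry = geometry),
            class = "example_matrix")
}

#' @export
print.example_matrix <- function(x, ...) {
  cat(sprintf("Example matrix: %d stimuli x %d voxels (%s grid)\n",
              nrow(x$values), ncol(x$values),
              paste(x$geometry$grid_shape, collapse = " x ")))
  invisible(x)
}

#' Read per-stimulus brain images into an example matrix
#'
#' Loads a 4D NIfTI of per-stimulus activation images and a 3D mask sharing
#' its grid, flattens each volume to the in-mask voxels (column-major voxel
#' order), and labels rows with the supplied stimulus ids. The mask is
#' binarized at 0.5 so probabilistic gray-matter masks are tolerated.
#'
#' Inputs are assumed fully preprocessed (motion-corrected, registered,
#' deconvolved); no further spatial processing is applied.
#'
#' @param volume_file path to a 4D NIfTI (4th axis = stimuli).
#' @param mask_file path to a 3D NIfTI mask on the same grid.
#' @param ids stimulus ids, length equal to the 4th-axis extent.
#' @return An [example_matrix()].
#' @export
read_examples <- function(volume_file, mask_file, ids) {
  vol <- RNifti::readNifti(volume_file)
  msk <- RNifti::readNifti(mask_file)
  dv <- dim(vol)
  dm <- dim(msk)
  if (length(dv) != 4L) stop_semdec("volume file must be 4D")
  if (length(dm) != 3L || any(dv[1:3] != dm)) {
    stop_semdec("mask grid does not match volume grid")
  }
  if (dv[4L] != length(ids)) {
    stop_semdec(sprintf("4th-axis length (%d) does not match id count (%d)",
                        dv[4L], length(ids)))
  }
  mask_idx <- which(as.vector(msk) >= 0.5)
  if (length(mask_idx) == 0L) stop_semdec("mask is empty")
  geom <- volume_geometry(dm, mask_idx)
  flat <- matrix(as.vector(vol), nrow = prod(dm), ncol = dv[4L])
  example_matrix(t(flat[mask_idx, , drop = FALSE]), ids, geom)
}

#' Write an example matrix back to NIfTI
#'
#' Inverse of [read_examples()]: reconstitutes one 3D volume per stimulus
#' (out-of-mask voxels set to 0) and writes the 4D stack plus the binary
#' mask. Values round-trip exactly for 64-bit floats.
#'
#' @param em an [example_matrix()].
#' @param volume_file,mask_file output paths.
#' @return Invisibly, \code{c(volume_file, mask_file)}.
#' @export
write_examples <- function(em, volume_file, mask_file) {
  stopifnot(inherits(em, "example_matrix"))
  gs <- em$geometry$grid_shape
  n <- nrow(em$values)
  arr <- array(0, dim = c(gs, n))
  flat <- matrix(0, prod(gs), n)
  flat[em$geometry$mask_indices, ] <- t(em$values)
  arr[] <- flat
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), volume_file)
  msk <- array(0, dim = gs)
  msk[em$geometry$mask_indices] <- 1
  RNifti::writeNifti(RNifti::asNifti(msk, datatype = "double"), mask_file)
  invisible(c(volume_file, mask_file))
}

#' Read a stimulus table
#'
#' Tab-separated file with header columns \code{id}, \code{kind}
#' (\code{word} or \code{sentence}), \code{text}, and \code{content_words}
#' (tokens separated by \code{|}).
#'
#' @param path TSV path.
#' @return Object of class \code{stimulus_table}: data frame with list
#'   column \code{content_words}; \code{semantic_vectors} attribute absent
#'   until [attach_vectors()] is called.
#' @export
read_stimuli <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("id", "kind", "text", "content_words")
  if (!all(req %in% names(df))) {
    stop_semdec("stimulus table must have columns: ", paste(req, collapse = ", "))
  }
  stimulus_table(df$id, df$kind, df$text,
                 strsplit(df$content_words, "|", fixed = TRUE))
}

#' Construct a stimulus table in code
#'
#' @param ids unique stimulus ids.
#' @param kind \code{"word"} or \code{"sentence"}, per row.
#' @param text raw stimulus text.
#' @param content_words list of token vectors, one per row.
#' @return Object of class \code{stimulus_table}.
#' @export
stimulus_table <- function(ids, kind, text, content_words) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop_semdec("duplicate stimulus id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(kind %in% c("word", "sentence"))) {
    stop_semdec("`kind` must be 'word' or 'sentence'")
  }
  if (any(lengths(content_words) == 0L)) {
    stop_semdec("empty content-word list for stimulus: ",
                paste(ids[lengths(content_words) == 0L], collapse = ", "))
  }
  df <- data.frame(id = ids, kind = kind, text = as.character(text),
                   stringsAsFactors = FALSE)
  df$content_words <- content_words
  class(df) <- c("stimulus_table", "data.frame")
  df
}

#' Attach text-derived semantic vectors to a stimulus table
#'
#' Computes one semantic vector per stimulus as the mean of its
#' content-word vectors ([sentence_vector()]); a single-word stimulus gets
#' that word's vector. The vectors become the decoding targets (the Z
#' matrix).
#'
#' @param st a [stimulus_table()].
#' @param table a [word_vector_table()].
#' @return The stimulus table with a \code{semantic_vectors} attribute
#'   (matrix, stimuli x dimensions, rownames = ids).
#' @export
attach_vectors <- function(st, table) {
  stopifnot(inherits(st, "stimulus_table"), inherits(table, "word_vectors"))
  z <- matrix(NA_real_, nrow(st), ncol(table$vectors),
              dimnames = list(st$id, NULL))
  for (i in seq_len(nrow(st))) {
    v <- tryCatch(lookup_vectors(table, st$content_words[[i]], context = st$id[i]),
                  error = function(e) stop_semdec(conditionMessage(e)))
    z[i, ] <- colMeans(v)
  }
  attr(st, "semantic_vectors") <- z
  st
}

#' Extract the semantic-vector matrix from a stimulus table
#' @param st a [stimulus_table()] after [attach_vectors()].
#' @return Matrix of stimuli x dimensions.
#' @export
semantic_vectors <- function(st) {
  z <- attr(st, "semantic_vectors")
  if (is.null(z)) stop_semdec("no semantic vectors attached; call attach_vectors()")
  z
}
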