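# Columnwise Pearson correlation between two matrices of equal shape;
# NA where either column is constant.
colwise_cor <- function(a, b) {
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  sa <- sqrt(colSums(a^2))
  sb <- sqrt(colSums(b^2))
  out <- colSums(a * b) / (sa * sb)
  out[sa == 0 | sb == 0] <- NA_real_
  out
}

# Contiguous-block fold assignment (optionally shuffled).
make_folds <- function(n, folds, shuffle = FALSE, seed = NULL) {
  idx <- seq_len(n)
  if (shuffle) idx <- with_seed(seed, sample(idx))
  split(idx, cut(seq_len(n), folds, labels = FALSE))
}

#' Voxel informativeness map
#'
#' Scores every in-mask voxel by how well a ridge regression on the voxel
#' and its 26 adjacent 3D neighbors predicts the semantic dimensions of the
#' training stimuli. For each voxel, a ridge model (fixed penalty
#' \code{ridge_lambda}, default 1, with intercept) is fit from the
#' neighborhood columns to each semantic dimension inside k-fold
#' cross-validation; the held-out predictions are concatenated across folds
#' and correlated with the true dimension values; the voxel's score is the
#' maximum correlation across dimensions.
#'
#' The score asks "does the local pattern around this voxel carry
#' information about any semantic dimension?", which is what makes it a
#' sensible criterion for reducing ~50,000 gray-matter voxels to the few
#' thousand that feed the decoder.
#'
#' @param X an [example_matrix()] (training stimuli only; using test rows
#'   here would leak information into voxel selection).
#' @param Z numeric matrix of semantic vectors, rows aligned with \code{X}.
#' @param folds number of cross-validation folds (contiguous blocks of
#'   stimuli by default).
#' @param ridge_lambda fixed ridge penalty for the neighborhood models.
#' @param shuffle,seed optionally shuffle stimuli before folding,
#'   reproducibly.
#' @return Object of class \code{informativeness_map}: list with
#'   \code{scores} (one per mask position, in \eqn{[-1, 1]}) and
#'   \code{folds}.
#' @export
informativeness <- function(X, Z, folds = 10L, ridge_lambda = 1,
                            shuffle = FALSE, seed = NULL) {
  stopifnot(inherits(X, "example_matrix"))
  Z <- check_finite_matrix(as.matrix(Z), "Z")
  xm <- X$values
  n <- nrow(xm)
  if (nrow(Z) != n) stop_semdec("X and Z disagree on the number of stimuli")
  folds <- check_count(folds, "folds", min = 2L)
  if (n < folds) stop_semdec("fewer stimuli than folds")
  dim_sd <- apply(Z, 2L, stats::sd)
  if (all(dim_sd == 0)) stop_semdec("all semantic dimensions are constant")
  if (all(apply(xm, 2L, stats::sd) == 0)) {
    stop_semdec("imaging data are identical across stimuli (no variance)")
  }
  fold_idx <- make_folds(n, folds, shuffle = shuffle, seed = seed)
  nbs <- all_neighborhoods(X$geometry)
  nv <- n_voxels(X$geometry)
  d <- ncol(Z)
  scores <- numeric(nv)
  # per-fold training means of Z, reused by every voxel
  ztr_means <- lapply(fold_idx, function(te) colMeans(Z[-te, , drop = FALSE]))
  ztr_c <- lapply(seq_along(fold_idx), function(f) {
    te <- fold_idx[[f]]
    sweep(Z[-te, , drop = FALSE], 2L, ztr_means[[f]])
  })
  for (v in seq_len(nv)) {
    nb <- nbs[[v]]
    xn <- xm[, nb, drop = FALSE]
    pred <- matrix(NA_real_, n, d)
    for (f in seq_along(fold_idx)) {
      te <- fold_idx[[f]]
      xtr <- xn[-te, , drop = FALSE]
      mu <- colMeans(xtr)
      xtr <- sweep(xtr, 2L, mu)
      g <- crossprod(xtr)
      diag(g) <- diag(g) + ridge_lambda
      b <- solve(g, crossprod(xtr, ztr_c[[f]]))
      xte <- sweep(xn[te, , drop = FALSE], 2L, mu)
      pred[te, ] <- xte %*% b +
        rep(ztr_means[[f]], each = length(te))
    }
    r <- colwise_cor(pred, Z)
    r[dim_sd == 0] <- NA_real_
    scores[v] <- if (all(is.na(r))) -1 else max(r, na.rm = TRUE)
  }
  structure(list(scores = scores, folds = folds),
            class = "informativeness_map")
}

#' Select the most informative voxels
#'
#' Returns the mask positions of the \code{n} highest informativeness
#' scores, optionally restricting candidates to a sub-mask (e.g., a brain
#' network). If fewer candidates exist than requested, all of them are
#' returned with a warning — small restriction masks simply contribute all
#' their voxels. Ties at the selection boundary are broken by lower mask
#' position, so selection is deterministic.
#'
#' @param map an [informativeness()] map.
#' @param n number of voxels requested (the reference pipeline uses 5000,
#'   roughly 10\% of a cortical mask).
#' @param restrict optional restriction: logical vector over mask positions,
#'   or integer mask positions.
#' @return Object of class \code{voxel_selection}: list with \code{indices}
#'   (mask positions, in decreasing score order), \code{n_requested},
#'   \code{restriction}.
#' @export
select_top <- function(map, n, restrict = NULL) {
  stopifnot(inherits(map, "informativeness_map"))
  n <- check_count(n, "n")
  nv <- length(map$scores)
  cand <- seq_len(nv)
  restriction <- NULL
  if (!is.null(restrict)) {
    if (is.logical(restrict)) {
      if (length(restrict) != nv) {
        stop_semdec("logical `restrict` must cover every mask position")
      }
      cand <- which(restrict)
    } else {
      cand <- sort(unique(as.integer(restrict)))
      if (any(cand < 1L | cand > nv)) {
        stop_semdec("`restrict` contains invalid mask positions")
      }
    }
    restriction <- deparse(substitute(restrict))
  }
  if (length(cand) == 0L) stop_semdec("empty candidate set after restriction")
  if (length(cand) < n) {
    warning(sprintf("only %d candidate voxels available; returning all of them",
                    length(cand)), call. = FALSE)
  }
  ord <- cand[order(-map$scores[cand], cand)]
  structure(list(indices = ord[seq_len(min(n, length(ord)))],
                 n_requested = n, restriction = restriction),
            class = "voxel_selection")
}

#' Export an informativeness map as a 3D NIfTI volume
#'
#' Out-of-mask voxels are written as 0; thresholding and averaging such maps
#' across subjects yields fraction-of-subjects consistency maps.
#'
#' @param map an [informativeness()] map.
#' @param geometry the [volume_geometry()] the map was computed on.
#' @param path output NIfTI path.
#' @export
write_informativeness_map <- function(map, geometry, path) {
  stopifnot(inherits(map, "informativeness_map"),
            inherits(geometry, "volume_geometry"))
  if (length(map$scores) != n_voxels(geometry)) {
    stop_semdec("map length does not match geometry")
  }
  vol <- array(0, dim = geometry$grid_shape)
  vol[geometry$mask_indices] <- map$scores
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), path)
  invisible(path)
}
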