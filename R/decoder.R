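#' Default ridge penalty grid
#'
#' 20 points log-spaced between 1e-3 and 1e6, covering effectively
#' unregularized through near-constant fits.
#' @return Numeric vector of candidate penalties.
#' @export
default_lambda_grid <- function() {
  exp(seq(log(1e-3), log(1e6), length.out = 20L))
}

# GCV scores for every lambda on pre-centered data, from a shared SVD.
# sv: svd(Xc); zc: centered response; n: number of rows.
# GCV(lambda) = ||(I - H)zc||^2 / (n (1 - tr(H)/n)^2), H the ridge smoother.
gcv_scores_svd <- function(sv, zc, n, lambda_grid) {
  a <- drop(crossprod(sv$u, zc))
  d2 <- sv$d^2
  zz <- sum(zc^2)
  vapply(lambda_grid, function(lam) {
    s <- d2 / (d2 + lam)
    rss <- zz - sum(a^2) + sum(((1 - s) * a)^2)
    trh <- sum(s)
    if (trh >= n) return(NA_real_)
    rss / (n * (1 - trh / n)^2)
  }, numeric(1))
}

#' Ridge regression with penalty chosen by generalized cross-validation
#'
#' Fits \eqn{\min_b \|Xb + b_0 - z\|_2^2 + \lambda \|b\|_2^2}, choosing
#' \eqn{\lambda} from a grid by the GCV criterion
#' \deqn{GCV(\lambda) = \frac{\|(I - H_\lambda)\tilde z\|^2}{n\,(1 -
#'   \mathrm{tr}(H_\lambda)/n)^2}}
#' evaluated on mean-centered data, where \eqn{H_\lambda} is the ridge
#' smoother matrix. GCV is a rotation-invariant approximation to
#' leave-one-out cross-validation that needs no refitting per left-out
#' point; the SVD of the centered design is computed once and shared across
#' the whole grid.
#'
#' @param X numeric matrix of predictors (rows = observations).
#' @param z numeric response vector.
#' @param lambda_grid positive candidate penalties.
#' @return List with \code{b} (coefficients), \code{b0} (intercept),
#'   \code{lambda} (selected penalty) and \code{gcv} (data frame of
#'   \code{lambda}, \code{score} over the grid; \code{NA} score = skipped).
#' @export
fit_ridge_gcv <- function(X, z, lambda_grid = default_lambda_grid()) {
  X <- check_finite_matrix(as.matrix(X), "X")
  z <- as.numeric(z)
  n <- nrow(X)
  if (length(z) != n) stop_semdec("X and z disagree on the number of rows")
  if (n < 3L) stop_semdec("need at least 3 observations")
  if (length(lambda_grid) == 0L || any(lambda_grid <= 0)) {
    stop_semdec("`lambda_grid` must be non-empty and strictly positive")
  }
  xm <- colMeans(X)
  zm <- mean(z)
  xc <- sweep(X, 2L, xm)
  zc <- z - zm
  if (all(zc == 0)) {
    # constant response: zero coefficients at any penalty
    return(list(b = numeric(ncol(X)), b0 = zm, lambda = lambda_grid[1L],
                gcv = data.frame(lambda = lambda_grid, score = 0)))
  }
  sv <- svd(xc)
  keep <- sv$d > max(sv$d) * 1e-12
  sv$d <- sv$d[keep]
  sv$u <- sv$u[, keep, drop = FALSE]
  sv$v <- sv$v[, keep, drop = FALSE]
  scores <- gcv_scores_svd(sv, zc, n, lambda_grid)
  if (all(is.na(scores))) stop_semdec("GCV criterion undefined at every grid point")
  lam <- lambda_grid[which.min(scores)]
  a <- drop(crossprod(sv$u, zc))
  b <- drop(sv$v %*% (sv$d / (sv$d^2 + lam) * a))
  list(b = b, b0 = zm - sum(xm * b), lambda = lam,
       gcv = data.frame(lambda = lambda_grid, score = scores))
}

#' Fit a semantic decoder
#'
#' Trains one ridge regression per semantic dimension, mapping activation
#' patterns over the selected voxels to that dimension, with the penalty
#' chosen independently per dimension by generalized cross-validation
#' ([fit_ridge_gcv()]). Each voxel is mean-normalized across training
#' stimuli, as is each semantic dimension; the training means are stored in
#' the model so that test images are normalized with statistics derived
#' purely from the training set.
#'
#' The SVD of the centered training matrix is computed once and shared by
#' all dimensions' GCV paths, which is mathematically identical to
#' per-dimension smoother matrices but far cheaper.
#'
#' @param X an [example_matrix()] of training stimuli, or a plain numeric
#'   matrix (stimuli x voxels).
#' @param Z semantic-vector matrix, rows aligned with \code{X}.
#' @param voxels a [select_top()] selection, integer mask positions, or
#'   \code{NULL} for all voxels.
#' @param lambda_grid candidate ridge penalties.
#' @return Object of class \code{semantic_decoder}: coefficients
#'   (selected voxels x dimensions), intercepts, per-dimension lambdas,
#'   voxel indices, training voxel means and dimension means, and the
#'   geometry fingerprint of the training data.
#' @seealso [predict.semantic_decoder()], [crossval_decode()],
#'   [write_decoder()].
#' @export
semantic_decoder <- function(X, Z, voxels = NULL,
                             lambda_grid = default_lambda_grid()) {
  geom <- NULL
  ids <- NULL
  if (inherits(X, "example_matrix")) {
    geom <- X$geometry
    ids <- X$stimulus_ids
    xm <- X$values
  } else {
    xm <- check_finite_matrix(as.matrix(X), "X")
  }
  Z <- check_finite_matrix(as.matrix(Z), "Z")
  n <- nrow(xm)
  if (nrow(Z) != n) stop_semdec("X and Z disagree on the number of stimuli")
  if (n < 3L) stop_semdec("need at least 3 training stimuli")
  sel <- if (is.null(voxels)) {
    seq_len(ncol(xm))
  } else if (inherits(voxels, "voxel_selection")) {
    voxels$indices
  } else {
    as.integer(voxels)
  }
  if (any(sel < 1L | sel > ncol(xm))) stop_semdec("invalid voxel indices")
  xs <- xm[, sel, drop = FALSE]
  voxel_means <- colMeans(xs)
  dim_means <- colMeans(Z)
  xc <- sweep(xs, 2L, voxel_means)
  zc <- sweep(Z, 2L, dim_means)
  zero_var <- apply(xs, 2L, stats::sd) == 0
  if (any(zero_var)) {
    message(sum(zero_var), " selected voxel(s) have zero training variance; ",
            "ridge shrinks their coefficients to zero")
  }
  sv <- svd(xc)
  keep <- sv$d > max(sv$d, 0) * 1e-12
  sv$d <- sv$d[keep]
  sv$u <- sv$u[, keep, drop = FALSE]
  sv$v <- sv$v[, keep, drop = FALSE]
  d <- ncol(Z)
  coefs <- matrix(0, length(sel), d)
  lambdas <- numeric(d)
  degenerate <- logical(d)
  for (j in seq_len(d)) {
    zj <- zc[, j]
    if (all(zj == 0)) {
      degenerate[j] <- TRUE
      lambdas[j] <- lambda_grid[1L]
      next
    }
    scores <- gcv_scores_svd(sv, zj, n, lambda_grid)
    if (all(is.na(scores))) stop_semdec("GCV undefined for dimension ", j)
    lam <- lambda_grid[which.min(scores)]
    a <- drop(crossprod(sv$u, zj))
    coefs[, j] <- drop(sv$v %*% (sv$d / (sv$d^2 + lam) * a))
    lambdas[j] <- lam
  }
  if (any(degenerate)) {
    message(sum(degenerate), " semantic dimension(s) constant in training; ",
            "decoded as their mean")
  }
  intercepts <- dim_means - drop(crossprod(coefs, voxel_means))
  structure(list(coefficients = coefs, intercepts = intercepts,
                 lambdas = lambdas, voxel_indices = sel,
                 voxel_means = voxel_means, dim_means = dim_means,
                 degenerate_dims = which(degenerate),
                 geometry = geom, stimulus_ids = ids,
                 lambda_grid = lambda_grid, n_train = n),
            class = "semantic_decoder")
}

#' @export
print.semantic_decoder <- function(x, ...) {
  cat(sprintf("Semantic decoder: %d voxels -> %d dimensions (n_train = %d)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$n_train))
  cat(sprintf("Ridge penalties (GCV-selected): median %.3g, range [%.3g, %.3g]\n",
              stats::median(x$lambdas), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' @export
summary.semantic_decoder <- function(object, ...) {
  out <- list(
    n_voxels = nrow(object$coefficients),
    n_dims = ncol(object$coefficients),
    n_train = object$n_train,
    lambda_summary = summary(object$lambdas),
    coef_norms = sqrt(colSums(object$coefficients^2)),
    degenerate_dims = object$degenerate_dims
  )
  class(out) <- "summary.semantic_decoder"
  out
}

#' @export
print.summary.semantic_decoder <- function(x, ...) {
  cat(sprintf("Semantic decoder fitted on %d stimuli\n", x$n_train))
  cat(sprintf("  voxels: %d   dimensions: %d\n", x$n_voxels, x$n_dims))
  cat("  GCV-selected lambda:\n")
  print(x$lambda_summary)
  cat(sprintf("  coefficient norms: median %.3g\n",
              stats::median(x$coef_norms)))
  if (length(x$degenerate_dims)) {
    cat("  degenerate dimensions:", paste(x$degenerate_dims, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.semantic_decoder <- function(object, ...) {
  rbind(`(Intercept)` = object$intercepts, object$coefficients)
}

#' Decode semantic vectors from new activation patterns
#'
#' Applies a fitted decoder to new images: the stored training voxel means
#' are subtracted from the selected columns, the per-dimension coefficients
#' and intercepts applied, and the stored training dimension means restored,
#' so decoded vectors live on the same scale as the text-derived vectors.
#' Decoding the training-set mean image returns exactly the dimension means.
#'
#' @param object a fitted [semantic_decoder()].
#' @param newdata an [example_matrix()] (geometry must match the training
#'   geometry) or a plain matrix with the same columns as the training data.
#' @param ... unused.
#' @return Matrix of decoded vectors (stimuli x dimensions), rownames =
#'   stimulus ids where available.
#' @export
predict.semantic_decoder <- function(object, newdata, ...) {
  if (inherits(newdata, "example_matrix")) {
    if (!is.null(object$geometry)) {
      g1 <- object$geometry
      g2 <- newdata$geometry
      if (!identical(g1$grid_shape, g2$grid_shape) ||
          !identical(g1$mask_indices, g2$mask_indices)) {
        stop_semdec("geometry of `newdata` does not match the training geometry")
      }
    }
    xm <- newdata$values
  } else {
    xm <- check_finite_matrix(as.matrix(newdata), "newdata")
  }
  xs <- xm[, object$voxel_indices, drop = FALSE]
  out <- xs %*% object$coefficients +
    rep(object$intercepts, each = nrow(xs))
  out
}

#' Leave-k-out cross-validated decoding
#'
#' Partitions the stimuli into folds of size \code{k}, and in each fold
#' selects voxels ([informativeness()] + [select_top()]), trains a decoder,
#' and decodes the held-out stimuli — all using training rows only, so no
#' test information leaks into selection, normalization, or the GCV choice
#' of penalty. The reference word-decoding design uses 180 stimuli in folds
#' of 10, i.e., 18 folds, with per-fold voxel selection.
#'
#' @param X an [example_matrix()].
#' @param Z semantic matrix aligned with \code{X}.
#' @param k held-out stimuli per fold.
#' @param n_select number of voxels to select per fold.
#' @param lambda_grid candidate ridge penalties.
#' @param inner_folds folds for the informativeness score's internal CV.
#' @param restrict optional restriction mask passed to [select_top()].
#' @param shuffle,seed optionally shuffle the stimulus order before folding.
#' @return List of class \code{crossval_decoding}: \code{decoded} (matrix
#'   covering every stimulus, original order), \code{fold_assignment},
#'   \code{selections} (per-fold [select_top()] results), \code{lambdas}
#'   (per-fold per-dimension penalties).
#' @export
crossval_decode <- function(X, Z, k = 10L, n_select = 5000L,
                            lambda_grid = default_lambda_grid(),
                            inner_folds = 10L, restrict = NULL,
                            shuffle = FALSE, seed = NULL) {
  stopifnot(inherits(X, "example_matrix"))
  Z <- check_finite_matrix(as.matrix(Z), "Z")
  n <- nrow(X$values)
  if (nrow(Z) != n) stop_semdec("X and Z disagree on the number of stimuli")
  k <- check_count(k, "k")
  n_folds <- ceiling(n / k)
  order_idx <- if (shuffle) with_seed(seed, sample(seq_len(n))) else seq_len(n)
  fold_of <- integer(n)
  fold_of[order_idx] <- rep(seq_len(n_folds), each = k, length.out = n)
  decoded <- matrix(NA_real_, n, ncol(Z))
  rownames(decoded) <- X$stimulus_ids
  selections <- vector("list", n_folds)
  lambdas <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- which(fold_of == f)
    tr <- setdiff(seq_len(n), te)
    if (length(tr) < 3L) stop_semdec("fold with fewer than 3 training stimuli")
    xtr <- example_matrix(X$values[tr, , drop = FALSE],
                          X$stimulus_ids[tr], X$geometry)
    imap <- informativeness(xtr, Z[tr, , drop = FALSE], folds = inner_folds)
    sel <- select_top(imap, n_select, restrict = restrict)
    model <- semantic_decoder(xtr, Z[tr, , drop = FALSE], voxels = sel,
                              lambda_grid = lambda_grid)
    decoded[te, ] <- predict(model, X$values[te, , drop = FALSE])
    selections[[f]] <- sel
    lambdas[[f]] <- model$lambdas
  }
  structure(list(decoded = decoded, fold_assignment = fold_of,
                 selections = selections, lambdas = lambdas),
            class = "crossval_decoding")
}

#' @export
print.crossval_decoding <- function(x, ...) {
  cat(sprintf("Cross-validated decoding: %d stimuli, %d folds, %d dimensions\n",
              nrow(x$decoded), length(x$selections), ncol(x$decoded)))
  invisible(x)
}

#' Save / load a decoder model
#'
#' The container stores every model field (coefficients, intercepts,
#' penalties, voxel indices, normalization means, geometry) with a format
#' version, using R's native serialization; \code{read_decoder()} restores
#' a model that decodes bit-identically.
#'
#' @param model a [semantic_decoder()].
#' @param path file path.
#' @return \code{write_decoder}: the path, invisibly. \code{read_decoder}:
#'   the model.
#' @export
write_decoder <- function(model, path) {
  stopifnot(inherits(model, "semantic_decoder"))
  payload <- unclass(model)
  payload$format_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$format_version)) stop_semdec("not a decoder model file")
  payload$format_version <- NULL
  structure(payload, class = "semantic_decoder")
}
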