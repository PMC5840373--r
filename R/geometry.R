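#' Volume geometry: a 3D grid plus an analysis mask
#'
#' Ties a flat example matrix (stimuli x voxels) to the 3D voxel grid it was
#' sampled from. Columns of the example matrix correspond, in order, to the
#' in-mask voxels; \code{mask_indices} stores their linear indices into the
#' grid using R's column-major convention (first axis fastest-varying),
#' 1-based. Serializing the geometry with a decoder model makes the model
#' portable across sessions.
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param mask_indices strictly increasing 1-based linear indices of in-mask
#'   voxels.
#' @return Object of class \code{volume_geometry}.
#' @export
volume_geometry <- function(grid_shape, mask_indices) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop_semdec("`grid_shape` must be 3 positive integers")
  }
  mask_indices <- as.integer(mask_indices)
  if (length(mask_indices) == 0L) stop_semdec("mask is empty")
  if (is.unsorted(mask_indices, strictly = TRUE)) {
    stop_semdec("`mask_indices` must be strictly increasing")
  }
  if (mask_indices[1L] < 1L || mask_indices[length(mask_indices)] > prod(grid_shape)) {
    stop_semdec("mask indices fall outside the grid")
  }
  structure(list(grid_shape = grid_shape, mask_indices = mask_indices),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("Volume geometry: %s grid, %d in-mask voxels\n",
              paste(x$grid_shape, collapse = " x "), length(x$mask_indices)))
  invisible(x)
}

#' Number of in-mask voxels
#' @param geometry a [volume_geometry()].
#' @return Integer count.
#' @export
n_voxels <- function(geometry) length(geometry$mask_indices)

# 3D coordinates (n x 3 matrix, 1-based) of each in-mask voxel, mask order.
mask_coordinates <- function(geometry) {
  arrayInd(geometry$mask_indices, .dim = geometry$grid_shape)
}

# linear grid index -> mask position (NA outside mask)
mask_position_lookup <- function(geometry) {
  lut <- rep(NA_integer_, prod(geometry$grid_shape))
  lut[geometry$mask_indices] <- seq_along(geometry$mask_indices)
  lut
}

#' 3D neighborhood of a voxel within the mask
#'
#' Returns the mask positions of the voxel itself plus every in-grid,
#' in-mask voxel at Chebyshev distance 1 (the 26 adjacent neighbors in 3D),
#' so at most 27 positions. Voxels at the grid or mask boundary simply have
#' fewer neighbors; no padding is applied, since padded values would
#' fabricate signal.
#'
#' @param geometry a [volume_geometry()].
#' @param voxel mask position (1-based index into the in-mask voxel list).
#' @return Sorted integer vector of mask positions (includes \code{voxel}).
#' @export
neighborhood <- function(geometry, voxel) {
  stopifnot(inherits(geometry, "volume_geometry"))
  nv <- n_voxels(geometry)
  if (length(voxel) != 1L || voxel < 1L || voxel > nv) {
    stop_semdec("`voxel` is not a valid mask position")
  }
  co <- arrayInd(geometry$mask_indices[voxel], .dim = geometry$grid_shape)[1L, ]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cand <- sweep(offs, 2L, co, `+`)
  gs <- geometry$grid_shape
  keep <- cand[, 1L] >= 1L & cand[, 1L] <= gs[1L] &
          cand[, 2L] >= 1L & cand[, 2L] <= gs[2L] &
          cand[, 3L] >= 1L & cand[, 3L] <= gs[3L]
  cand <- cand[keep, , drop = FALSE]
  lin <- cand[, 1L] + (cand[, 2L] - 1L) * gs[1L] +
    (cand[, 3L] - 1L) * gs[1L] * gs[2L]
  pos <- mask_position_lookup(geometry)[lin]
  sort(pos[!is.na(pos)])
}

# All neighborhoods at once; returns a list indexed by mask position.
# Vectorized over the 27 offsets to avoid a per-voxel R loop.
all_neighborhoods <- function(geometry) {
  gs <- geometry$grid_shape
  co <- mask_coordinates(geometry)
  nv <- nrow(co)
  lut <- mask_position_lookup(geometry)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- matrix(NA_integer_, nv, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    x <- co[, 1L] + offs[j, 1L]
    y <- co[, 2L] + offs[j, 2L]
    z <- co[, 3L] + offs[j, 3L]
    ok <- x >= 1L & x <= gs[1L] & y >= 1L & y <= gs[2L] & z >= 1L & z <= gs[3L]
    lin <- x + (y - 1L) * gs[1L] + (z - 1L) * gs[1L] * gs[2L]
    nb[ok, j] <- lut[lin[ok]]
  }
  lapply(seq_len(nv), function(i) {
    v <- nb[i, ]
    sort(v[!is.na(v)])
  })
}
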