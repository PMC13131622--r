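#' Scale-space configuration for 3D keypoint detection
#'
#' Defaults follow the classic SIFT lineage: Gaussian scales
#' sigma = 1.0, 1.6, 2.2, 3.0 voxels repeated over three octaves (each
#' octave halves the grid), a contrast threshold of 0.01 on the
#' \[0, 1\]-normalized intensity scale, and a Hessian eigenvalue anisotropy
#' ratio of 10 for edge suppression. Sigmas are isotropic in voxel units;
#' anisotropic acquisitions are handled by the same detector (scale space is
#' not spacing-corrected).
#'
#' @param sigmas strictly increasing Gaussian scales, in voxels.
#' @param n_octaves number of octaves (>= 1).
#' @param contrast_thresh minimum absolute DoG response of a keypoint.
#' @param edge_ratio_thresh maximum |lambda_max| / |lambda_min| Hessian
#'   eigenvalue ratio; larger (more plate/edge-like) candidates are dropped.
#' @return list of class `bovw_scale_space_config`.
#' @export
scale_space_config <- function(sigmas = c(1.0, 1.6, 2.2, 3.0), n_octaves = 3L,
                               contrast_thresh = 0.01, edge_ratio_thresh = 10) {
  stopifnot(length(sigmas) >= 2, all(diff(sigmas) > 0), n_octaves >= 1,
            contrast_thresh >= 0, edge_ratio_thresh > 1)
  structure(list(sigmas = as.numeric(sigmas), n_octaves = as.integer(n_octaves),
                 contrast_thresh = contrast_thresh,
                 edge_ratio_thresh = edge_ratio_thresh),
            class = "bovw_scale_space_config")
}

# 1D Gaussian kernel matrix with half-sample mirror ("reflect") boundaries,
# applied along one axis by matrix multiplication.
gaussian_band_matrix <- function(n, sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect <- function(j, n) {
    # 0-based half-sample mirror: ... 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
    while (any(bad <- j < 0 | j >= n)) {
      j[j < 0] <- -1 - j[j < 0]
      j[j >= n] <- 2 * n - 1 - j[j >= n]
    }
    j
  }
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (t in seq_along(k)) {
    off <- t - (r + 1L)
    j <- reflect(i - 1L + off, n) + 1L
    K[cbind(i, j)] <- K[cbind(i, j)] + k[t]
  }
  K
}

# Separable convolution: multiply along the requested axis.
conv_axis <- function(a, K, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  res <- array(m, dim(ap))
  aperm(res, order(perm))
}

#' Separable 3D Gaussian blur
#'
#' @param a 3D numeric array.
#' @param sigma isotropic Gaussian standard deviation in voxels.
#' @param truncate kernel support radius in units of sigma.
#' @return blurred array, same shape. Boundaries use half-sample mirroring.
#' @export
gaussian_blur3d <- function(a, sigma, truncate = 4) {
  stopifnot(length(dim(a)) == 3, sigma > 0)
  d <- dim(a)
  for (axis in 1:3) {
    a <- conv_axis(a, gaussian_band_matrix(d[axis], sigma, truncate), axis)
  }
  a
}

downsample2 <- function(a) {
  d <- dim(a)
  a[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2), drop = FALSE]
}

#' Build a 3D difference-of-Gaussians pyramid
#'
#' For each octave the volume is blurred at every configured sigma and
#' consecutive blurred copies are differenced,
#' `DoG[i] = G(sigma[i+1]) - G(sigma[i])`, approximating the
#' Laplacian-of-Gaussian. The next octave restarts from the most-blurred
#' level of the previous one, downsampled by taking every second voxel.
#' Octaves whose grid falls below the minimal 5-voxel support for extremum
#' and Hessian stencils are skipped with a warning.
#'
#' @param v a normalized [new_volume()] (or plain 3D array).
#' @param cfg a [scale_space_config()].
#' @return object of class `bovw_dog_pyramid`: per retained octave, the list
#'   of DoG arrays tagged with `(octave, level)` where level i pairs
#'   `sigmas[i]` and `sigmas[i+1]`.
#' @export
build_dog_pyramid <- function(v, cfg = scale_space_config()) {
  a <- if (inherits(v, "bovw_volume")) v$data else v
  stopifnot(length(dim(a)) == 3)
  octaves <- list()
  base <- a
  for (o in seq_len(cfg$n_octaves) - 1L) {
    if (any(dim(base) < 5L)) {
      warning("octave ", o, " skipped: grid ", paste(dim(base), collapse = "x"),
              " is below the minimal 5-voxel stencil support")
      break
    }
    gaussians <- lapply(cfg$sigmas, function(s) gaussian_blur3d(base, s))
    dogs <- lapply(seq_len(length(cfg$sigmas) - 1L), function(i) {
      gaussians[[i + 1L]] - gaussians[[i]]
    })
    octaves[[length(octaves) + 1L]] <- list(
      octave = o, dogs = dogs,
      sigmas = cfg$sigmas, dim = dim(base)
    )
    base <- downsample2(gaussians[[length(gaussians)]])
  }
  structure(list(octaves = octaves, config = cfg), class = "bovw_dog_pyramid")
}

# 26-neighborhood offsets (excluding the center).
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Strict local extrema of a 3D array over the 26-neighborhood. Border voxels
# (incomplete neighborhoods) are never extrema. Returns logical arrays.
local_extrema_26 <- function(d) {
  dims <- dim(d)
  padmax <- array(-Inf, dims + 2L)
  padmax[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- d
  padmin <- array(Inf, dims + 2L)
  padmin[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- d
  nbr_max <- array(-Inf, dims)
  nbr_min <- array(Inf, dims)
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    dz <- offs[r, 1]; dy <- offs[r, 2]; dx <- offs[r, 3]
    sl <- padmax[(2:(dims[1] + 1)) + dz, (2:(dims[2] + 1)) + dy,
                 (2:(dims[3] + 1)) + dx, drop = FALSE]
    nbr_max <- pmax(nbr_max, sl)
    sl <- padmin[(2:(dims[1] + 1)) + dz, (2:(dims[2] + 1)) + dy,
                 (2:(dims[3] + 1)) + dx, drop = FALSE]
    nbr_min <- pmin(nbr_min, sl)
  }
  interior <- array(FALSE, dims)
  interior[2:(dims[1] - 1), 2:(dims[2] - 1), 2:(dims[3] - 1)] <- TRUE
  list(maxima = (d > nbr_max) & interior, minima = (d < nbr_min) & interior)
}

empty_keypoints <- function() {
  data.frame(z = integer(0), y = integer(0), x = integer(0),
             z_oct = integer(0), y_oct = integer(0), x_oct = integer(0),
             octave = integer(0), level = integer(0), sigma = numeric(0),
             response = numeric(0), polarity = character(0),
             stringsAsFactors = FALSE)
}

#' Detect contrast-thresholded 3x3x3 DoG extrema
#'
#' A candidate keypoint is a voxel that is a strict extremum among its (up
#' to 26) within-volume neighbors in one DoG volume, with absolute response
#' above `contrast_thresh`. With the convention DoG = more blurred minus
#' less blurred, bright blobs are DoG minima (`polarity = "bright"`) and
#' dark blobs DoG maxima (`polarity = "dark"`). Octave coordinates are
#' mapped to the original grid via `(c - 1) * 2^octave + 1` (the 1-based
#' equivalent of multiplying 0-based coordinates by `2^octave`).
#'
#' @param pyr a [build_dog_pyramid()] result.
#' @param contrast_thresh minimum |DoG| response; defaults to the pyramid's
#'   configured value.
#' @return data.frame with columns `z, y, x` (original resolution, 1-based),
#'   `z_oct, y_oct, x_oct` (octave grid), `octave` (0-based), `level`
#'   (index of the lower sigma of the differenced pair), `sigma`,
#'   `response`, `polarity`.
#' @export
detect_extrema <- function(pyr, contrast_thresh = NULL) {
  stopifnot(inherits(pyr, "bovw_dog_pyramid"))
  thr <- contrast_thresh %||% pyr$config$contrast_thresh
  out <- list()
  for (oct in pyr$octaves) {
    scale <- 2L^oct$octave
    for (lev in seq_along(oct$dogs)) {
      d <- oct$dogs[[lev]]
      ex <- local_extrema_26(d)
      keep <- (ex$maxima | ex$minima) & (abs(d) > thr)
      if (!any(keep)) next
      idx <- which(keep, arr.ind = TRUE)
      ord <- order(idx[, 3], idx[, 2], idx[, 1])  # deterministic scan order
      idx <- idx[ord, , drop = FALSE]
      resp <- d[keep][ord]
      out[[length(out) + 1L]] <- data.frame(
        z = (idx[, 1] - 1L) * scale + 1L,
        y = (idx[, 2] - 1L) * scale + 1L,
        x = (idx[, 3] - 1L) * scale + 1L,
        z_oct = idx[, 1], y_oct = idx[, 2], x_oct = idx[, 3],
        octave = oct$octave, level = lev, sigma = oct$sigmas[lev],
        response = resp,
        polarity = ifelse(resp < 0, "bright", "dark"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty_keypoints())
  do.call(rbind, out)
}

# 3x3 Hessian of a 3D array at one interior voxel, central differences.
hessian_at <- function(d, z, y, x) {
  H <- matrix(0, 3, 3)
  c0 <- d[z, y, x]
  H[1, 1] <- d[z + 1, y, x] - 2 * c0 + d[z - 1, y, x]
  H[2, 2] <- d[z, y + 1, x] - 2 * c0 + d[z, y - 1, x]
  H[3, 3] <- d[z, y, x + 1] - 2 * c0 + d[z, y, x - 1]
  H[1, 2] <- H[2, 1] <- (d[z + 1, y + 1, x] - d[z + 1, y - 1, x] -
                           d[z - 1, y + 1, x] + d[z - 1, y - 1, x]) / 4
  H[1, 3] <- H[3, 1] <- (d[z + 1, y, x + 1] - d[z + 1, y, x - 1] -
                           d[z - 1, y, x + 1] + d[z - 1, y, x - 1]) / 4
  H[2, 3] <- H[3, 2] <- (d[z, y + 1, x + 1] - d[z, y + 1, x - 1] -
                           d[z, y - 1, x + 1] + d[z, y - 1, x - 1]) / 4
  H
}

#' Suppress edge- and plate-like keypoints via the DoG Hessian
#'
#' The 3x3 Hessian of the DoG response is estimated at each keypoint by
#' central differences on its octave grid; keypoints whose eigenvalue
#' anisotropy `|lambda_max| / |lambda_min|` exceeds `edge_ratio_thresh`
#' (including a vanishing smallest eigenvalue) are discarded, as are
#' keypoints whose stencil does not fit inside the DoG volume. Input order
#' is preserved.
#'
#' @param pyr the pyramid the keypoints came from.
#' @param kps keypoint data.frame from [detect_extrema()].
#' @param edge_ratio_thresh maximum eigenvalue ratio; defaults to the
#'   pyramid's configured value.
#' @return filtered keypoint data.frame.
#' @export
edge_filter <- function(pyr, kps, edge_ratio_thresh = NULL) {
  stopifnot(inherits(pyr, "bovw_dog_pyramid"))
  thr <- edge_ratio_thresh %||% pyr$config$edge_ratio_thresh
  if (nrow(kps) == 0) return(kps)
  oct_index <- vapply(pyr$octaves, function(o) o$octave, integer(1))
  keep <- logical(nrow(kps))
  for (i in seq_len(nrow(kps))) {
    oi <- match(kps$octave[i], oct_index)
    d <- pyr$octaves[[oi]]$dogs[[kps$level[i]]]
    dims <- dim(d)
    z <- kps$z_oct[i]; y <- kps$y_oct[i]; x <- kps$x_oct[i]
    if (z < 2 || y < 2 || x < 2 || z > dims[1] - 1 || y > dims[2] - 1 || x > dims[3] - 1) {
      next  # stencil does not fit: unreliable, drop
    }
    ev <- abs(eigen(hessian_at(d, z, y, x), symmetric = TRUE, only.values = TRUE)$values)
    lo <- min(ev)
    keep[i] <- lo > 0 && max(ev) / lo <= thr
  }
  kps[keep, , drop = FALSE]
}

#' Detect multiscale 3D keypoints
#'
#' Composite detector: DoG pyramid, 3x3x3 extremum detection with contrast
#' threshold, then Hessian edge filtering. Deterministic for a given volume
#' and configuration.
#'
#' @inheritParams build_dog_pyramid
#' @return keypoint data.frame (see [detect_extrema()]).
#' @export
detect_keypoints <- function(v, cfg = scale_space_config()) {
  pyr <- build_dog_pyramid(v, cfg)
  kps <- detect_extrema(pyr, cfg$contrast_thresh)
  edge_filter(pyr, kps, cfg$edge_ratio_thresh)
}
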