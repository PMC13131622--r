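# Quantification of high-attention regions: global thresholding, 3D
# connected-component blob statistics, and 3D Haralick co-occurrence
# texture features (13-feature set, distance 1, zeros ignored, averaged
# over directions).

#' Threshold an attention map into a high-attention mask
#'
#' One global threshold, chosen once for the whole dataset (see
#' [attention_threshold_value()] for the default percentile rule), is
#' applied uniformly to every image.
#'
#' @param map a [render_attention()] result or plain 3D array.
#' @param thresh scalar threshold; voxels with value `> thresh` are kept.
#' @param which for attention-map objects, threshold the `"rescaled"`
#'   (default) or signed `"render"` array.
#' @return logical 3D array.
#' @export
threshold_attention <- function(map, thresh, which = c("rescaled", "render")) {
  which <- match.arg(which)
  a <- if (inherits(map, "bovw_attention_map")) map[[which]] else map
  stopifnot(length(dim(a)) == 3)
  a > thresh
}

#' Default global attention threshold
#'
#' The q-th percentile of min-max-rescaled attention values, pooled over all
#' voxels with positive signed attention across the dataset. A percentile
#' rule makes the "empirically chosen" global threshold reproducible.
#'
#' @param maps list of [render_attention()] results.
#' @param pct percentile (default 90).
#' @return scalar threshold on the rescaled maps.
#' @export
attention_threshold_value <- function(maps, pct = 90) {
  vals <- unlist(lapply(maps, function(m) m$rescaled[m$render > 0]))
  if (length(vals) == 0) stop("no positive attention voxels in the dataset")
  stats::quantile(vals, pct / 100, names = FALSE, type = 7)
}

connectivity_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 `6` = rowSums(abs(g)) == 1,
                 `18` = rowSums(g^2) <= 2,
                 `26` = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' 3D connected-component blob statistics
#'
#' Labels the connected components of a binary mask (26-connectivity by
#' default; 6 and 18 available) and reports their count and voxel volumes.
#' Components are numbered in deterministic scan order (by the linear array
#' index of their first voxel).
#'
#' @param mask logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return list of class `bovw_blob_stats`: `n_blobs`, `blob_volumes`
#'   (voxel counts, one per blob), `labels` (integer 3D array, 0 =
#'   background) and `connectivity`.
#' @export
blob_analysis <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3)
  d <- dim(mask)
  m <- mask > 0
  vox <- which(m)  # linear indices, ascending = scan order
  labels <- array(0L, d)
  if (length(vox) == 0) {
    return(structure(list(n_blobs = 0L, blob_volumes = integer(0),
                          labels = labels, connectivity = connectivity),
                     class = "bovw_blob_stats"))
  }
  rank_of <- array(0L, d)
  rank_of[vox] <- seq_along(vox)
  offs <- connectivity_offsets(connectivity)
  # keep only "positive" offset directions; edges are undirected
  offs <- offs[apply(offs, 1, function(o) o[which(o != 0)[1]] > 0), , drop = FALSE]
  coords <- which(m, arr.ind = TRUE)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    nb_rank <- rank_of[nb_lin]
    src <- which(ok)[nb_rank > 0]
    if (length(src)) {
      edges[[length(edges) + 1L]] <- cbind(src, nb_rank[nb_rank > 0])
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(t(em)))
  }
  comp <- igraph::components(g)$membership
  # relabel so components appear in scan order of their first voxel
  first_seen <- unique(comp)
  relabel <- integer(max(comp))
  relabel[first_seen] <- seq_along(first_seen)
  comp <- relabel[comp]
  labels[vox] <- comp
  vols <- tabulate(comp)
  structure(list(n_blobs = length(vols), blob_volumes = as.integer(vols),
                 labels = labels, connectivity = connectivity),
            class = "bovw_blob_stats")
}

#' Quantize a masked volume to discrete gray levels for texture analysis
#'
#' In-mask intensities are clipped to the `lo_pct`/`hi_pct` percentiles
#' (computed over in-mask voxels), normalized to `[0, 1]` and quantized to
#' levels `1..n_levels`; background voxels are set to level 0, which the
#' co-occurrence statistics ignore. A constant in-mask signal maps to level
#' 1 everywhere with a warning.
#'
#' @param v a [new_volume()] with a mask (without one, all voxels are
#'   treated as foreground).
#' @param n_levels number of gray levels (default 32).
#' @param lo_pct,hi_pct clip percentiles (defaults 1 and 99).
#' @return integer 3D array of levels `0..n_levels`.
#' @export
quantize_for_texture <- function(v, n_levels = 32L, lo_pct = 1, hi_pct = 99) {
  stopifnot(inherits(v, "bovw_volume"))
  ml <- mask_logical(v) %||% array(TRUE, dim(v$data))
  vals <- v$data[ml]
  qs <- stats::quantile(vals, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  out <- array(0L, dim(v$data))
  if (qs[2] <= qs[1]) {
    warning("constant in-mask signal; all foreground quantized to level 1")
    out[ml] <- 1L
    return(out)
  }
  u <- (pmin(pmax(v$data[ml], qs[1]), qs[2]) - qs[1]) / (qs[2] - qs[1])
  out[ml] <- pmin(as.integer(floor(u * n_levels)) + 1L, n_levels)
  out
}

# The 13 unique 3D direction offsets at distance 1 (half of the 26).
haralick_offsets <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g[apply(g, 1, function(o) o[which(o != 0)[1]] > 0), , drop = FALSE]
}

# Symmetric, normalized GLCM of a quantized array for one offset.
# Pairs touching level 0 are excluded. Returns NULL if no valid pair.
glcm_3d <- function(q, offset, n_levels) {
  d <- dim(q)
  pz <- max(1, 1 - offset[1]):min(d[1], d[1] - offset[1])
  py <- max(1, 1 - offset[2]):min(d[2], d[2] - offset[2])
  px <- max(1, 1 - offset[3]):min(d[3], d[3] - offset[3])
  if (length(pz) < 1 || length(py) < 1 || length(px) < 1) return(NULL)
  a <- q[pz, py, px]
  b <- q[pz + offset[1], py + offset[2], px + offset[3]]
  ok <- a > 0 & b > 0
  if (!any(ok)) return(NULL)
  a <- a[ok]; b <- b[ok]
  counts <- matrix(0, n_levels, n_levels)
  t1 <- tabulate((a - 1L) * n_levels + b, nbins = n_levels^2)
  counts <- matrix(t1, n_levels, n_levels, byrow = TRUE)
  counts <- counts + t(counts)  # symmetrize
  counts / sum(counts)
}

# The 13 Haralick statistics of one normalized GLCM. Natural logs; on a
# zero-variance matrix, correlation and both information measures are
# defined as 0 and the result is flagged via attr "degenerate".
haralick_features_from_glcm <- function(P) {
  ng <- nrow(P)
  i <- seq_len(ng)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(i * px)
  muy <- sum(i * py)
  sigx <- sqrt(sum((i - mux)^2 * px))
  sigy <- sqrt(sum((i - muy)^2 * py))
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  dmat <- ii - jj
  asm <- sum(P^2)
  contrast <- sum(dmat^2 * P)
  degenerate <- sigx == 0 || sigy == 0
  correlation <- if (degenerate) 0 else (sum(ii * jj * P) - mux * muy) / (sigx * sigy)
  variance <- sum((ii - mux)^2 * P)
  idm <- sum(P / (1 + dmat^2))
  # p_{x+y} over k = 2..2*ng and p_{x-y} over k = 0..ng-1
  ks <- 2:(2 * ng)
  pxy_sum <- vapply(ks, function(k) sum(P[ii + jj == k]), numeric(1))
  kd <- 0:(ng - 1)
  pxy_diff <- vapply(kd, function(k) sum(P[abs(dmat) == k]), numeric(1))
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_entropy <- -sum(plogp(pxy_sum))
  entropy <- -sum(plogp(P))
  diff_mean <- sum(kd * pxy_diff)
  diff_var <- sum((kd - diff_mean)^2 * pxy_diff)
  diff_entropy <- -sum(plogp(pxy_diff))
  pxpy <- outer(px, py)
  hxy1 <- -sum(xlogy(P, pxpy))
  hxy2 <- -sum(plogp(pxpy))
  hx <- -sum(plogp(px))
  hy <- -sum(plogp(py))
  imc1 <- if (degenerate || max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- if (degenerate) 0 else sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  out <- c(
    angular_second_moment = asm, contrast = contrast,
    correlation = correlation, sum_of_squares_variance = variance,
    inverse_difference_moment = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = diff_var, difference_entropy = diff_entropy,
    info_measure_corr_1 = imc1, info_measure_corr_2 = imc2
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' 3D Haralick texture features of a quantized patch
#'
#' Gray-level co-occurrence matrices are built for the 13 unique distance-1
#' 3D directions, excluding any pair that touches background (level 0),
#' symmetrized and normalized to sum 1. The standard 13 Haralick statistics
#' are computed per direction and averaged over the directions that contain
#' at least one valid pair. Natural logarithms are used for the entropy
#' terms; correlation and the information measures of correlation are
#' defined as 0 on zero-variance (single-level) input.
#'
#' @param qpatch integer 3D array of gray levels `0..n_levels` (0 =
#'   background, ignored).
#' @param n_levels number of foreground gray levels.
#' @return named numeric vector of the 13 features, or `NULL` when no
#'   direction contains a valid co-occurring pair (patch flagged invalid).
#' @export
haralick_patch <- function(qpatch, n_levels = 32L) {
  stopifnot(length(dim(qpatch)) == 3)
  offs <- haralick_offsets()
  acc <- NULL
  n_valid <- 0L
  for (r in seq_len(nrow(offs))) {
    P <- glcm_3d(qpatch, offs[r, ], n_levels)
    if (is.null(P)) next
    f <- haralick_features_from_glcm(P)
    acc <- if (is.null(acc)) f else acc + f
    n_valid <- n_valid + 1L
  }
  if (n_valid == 0L) return(NULL)
  out <- acc / n_valid
  attr(out, "n_directions") <- n_valid
  out
}

#' Pool patch-level Haralick features per image and per condition
#'
#' Per-image means of every feature over that image's valid high-attention
#' patches, and per-condition kernel density estimates of the pooled
#' patch-level values (Gaussian KDE, Scott's rule-of-thumb bandwidth).
#' Images without a single valid patch are excluded with a message.
#'
#' @param features data.frame with `image_id`, `condition` and the 13
#'   feature columns (one row per patch).
#' @param kde_n number of KDE grid points per feature.
#' @return list with `per_image` (one row per image: condition + 13 means)
#'   and `kde` (long data.frame: condition, feature, x, density).
#' @export
pool_texture <- function(features, kde_n = 512L) {
  feat_cols <- setdiff(names(features), c("image_id", "condition"))
  split_img <- split(features, features$image_id)
  rows <- lapply(split_img, function(df) {
    data.frame(image_id = df$image_id[1], condition = df$condition[1],
               n_patches = nrow(df),
               as.list(colMeans(df[feat_cols])),
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  kde <- list()
  for (cond in unique(features$condition)) {
    sub <- features[features$condition == cond, , drop = FALSE]
    for (fc in feat_cols) {
      vals <- sub[[fc]]
      if (length(vals) < 2 || stats::sd(vals) == 0) next
      dens <- stats::density(vals, bw = "nrd", n = kde_n)
      kde[[length(kde) + 1L]] <- data.frame(
        condition = cond, feature = fc, x = dens$x, density = dens$y,
        stringsAsFactors = FALSE
      )
    }
  }
  kde <- if (length(kde)) do.call(rbind, kde) else
    data.frame(condition = character(0), feature = character(0),
               x = numeric(0), density = numeric(0))
  list(per_image = per_image, kde = kde)
}
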