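#' 3D intensity gradients in Cartesian and spherical form
#'
#' Finite differences of the normalized intensity: central differences in
#' the interior, one-sided at the borders. Each voxel gets the gradient
#' components `(g_z, g_y, g_x)`, the magnitude, the polar angle
#' `theta = acos(g_z / |g|)` in `[0, pi]` and the azimuth
#' `phi = atan2(g_y, g_x)` in `[-pi, pi)`. Zero gradients get
#' `theta = phi = 0`. The field is computed once per volume at the original
#' resolution and shared by all octaves.
#'
#' @param v a [new_volume()] or plain 3D array.
#' @return list of class `bovw_gradients` with 3D arrays `gz, gy, gx, mag,
#'   theta, phi`.
#' @export
compute_gradients <- function(v) {
  a <- if (inherits(v, "bovw_volume")) v$data else v
  stopifnot(length(dim(a)) == 3)
  diff_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    g <- matrix(0, nrow = n, ncol = ncol(m))
    if (n >= 3) g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    if (n >= 2) {
      g[1, ] <- m[2, ] - m[1, ]
      g[n, ] <- m[n, ] - m[n - 1, ]
    }
    aperm(array(g, dim(ap)), order(perm))
  }
  gz <- diff_axis(a, 1)
  gy <- diff_axis(a, 2)
  gx <- diff_axis(a, 3)
  mag <- sqrt(gz^2 + gy^2 + gx^2)
  theta <- array(0, dim(a))
  pos <- mag > 0
  theta[pos] <- acos(pmin(pmax(gz[pos] / mag[pos], -1), 1))
  phi <- atan2(gy, gx)
  phi[!pos] <- 0
  structure(list(gz = gz, gy = gy, gx = gx, mag = mag, theta = theta, phi = phi),
            class = "bovw_gradients")
}

#' Extract the cubic descriptor patch for a keypoint
#'
#' The patch is a cube centered on the keypoint with odd edge length
#' `round_to_odd(5 * sigma_eff)` voxels, where
#' `sigma_eff = sigma * 2^octave` is the keypoint's scale at original
#' resolution. A patch is rejected (not padded) when the cube exceeds the
#' volume bounds or when less than `min_mask_frac` of its voxels lie inside
#' the mask; without a mask the in-mask fraction is 1.
#'
#' @param v a [new_volume()] object.
#' @param kp one keypoint: a one-row data.frame (or list) with `z, y, x,
#'   sigma, octave`.
#' @param min_mask_frac minimum fraction of patch voxels inside the mask.
#' @return list of class `bovw_patch` with `accepted` (logical), and for
#'   accepted patches `center`, `edge_len`, `ranges` (per-axis index
#'   vectors) and `in_mask_fraction`; rejected patches carry a `reason`.
#' @export
extract_patch <- function(v, kp, min_mask_frac = 0.5) {
  stopifnot(inherits(v, "bovw_volume"))
  sigma_eff <- kp$sigma * 2^kp$octave
  edge <- round_to_odd(5 * sigma_eff)
  half <- (edge - 1L) %/% 2L
  ctr <- c(kp$z, kp$y, kp$x)
  d <- dim(v$data)
  lo <- ctr - half
  hi <- ctr + half
  reject <- function(reason) {
    structure(list(accepted = FALSE, reason = reason, center = ctr,
                   edge_len = edge), class = "bovw_patch")
  }
  if (any(lo < 1) || any(hi > d)) return(reject("out_of_bounds"))
  ranges <- lapply(1:3, function(k) lo[k]:hi[k])
  frac <- 1
  ml <- mask_logical(v)
  if (!is.null(ml)) {
    frac <- mean(ml[ranges[[1]], ranges[[2]], ranges[[3]]])
    if (frac < min_mask_frac) return(reject("mask_fraction"))
  }
  structure(list(accepted = TRUE, center = ctr, edge_len = edge,
                 ranges = ranges, in_mask_fraction = frac),
            class = "bovw_patch")
}

#' Rotationally robust 3D HOG descriptor for one patch
#'
#' Instead of absolute gradient orientations, every in-patch (and in-mask)
#' voxel `p` is compared with each of its in-patch 26-neighbors `q`: the
#' relative orientation differences `dtheta = |theta_p - theta_q|` (in
#' `[0, pi]`) and `dphi = phi_p - phi_q` wrapped to `[-pi, pi)` select a
#' `(dtheta, dphi)` histogram bin into which the relative magnitude ratio
#' `m_q / (m_p + eps)` is accumulated. Voxels with `m_p < eps` contribute
#' nothing. Because both angles and magnitudes are relative to the local
#' neighborhood, the histogram is approximately invariant to rigid rotations
#' of the patch and exactly invariant to intensity scaling (after the final
#' per-patch L2 normalization; an all-zero histogram is left as zeros).
#'
#' @param patch an accepted [extract_patch()] result.
#' @param grad a [compute_gradients()] field for the same volume.
#' @param mask optional logical 3D array (same grid as the volume);
#'   restricts the central voxels `p` to the mask.
#' @param n_theta,n_phi number of polar / azimuthal difference bins
#'   (descriptor length `n_theta * n_phi`).
#' @param eps magnitude floor in the ratio denominator.
#' @return numeric descriptor of length `n_theta * n_phi`, L2-normalized.
#' @export
rihog_descriptor <- function(patch, grad, mask = NULL, n_theta = 4L, n_phi = 8L,
                             eps = 1e-8) {
  stopifnot(inherits(patch, "bovw_patch"), isTRUE(patch$accepted),
            inherits(grad, "bovw_gradients"))
  rg <- patch$ranges
  th <- grad$theta[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  ph <- grad$phi[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  mg <- grad$mag[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  mk <- if (is.null(mask)) NULL else mask[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  e <- dim(th)
  nbins <- n_theta * n_phi
  acc <- numeric(nbins)
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    dz <- offs[r, 1]; dy <- offs[r, 2]; dx <- offs[r, 3]
    pz <- max(1, 1 - dz):min(e[1], e[1] - dz)
    py <- max(1, 1 - dy):min(e[2], e[2] - dy)
    px <- max(1, 1 - dx):min(e[3], e[3] - dx)
    thp <- th[pz, py, px]; thq <- th[pz + dz, py + dy, px + dx]
    php <- ph[pz, py, px]; phq <- ph[pz + dz, py + dy, px + dx]
    mgp <- mg[pz, py, px]; mgq <- mg[pz + dz, py + dy, px + dx]
    ok <- mgp >= eps
    if (!is.null(mk)) ok <- ok & mk[pz, py, px]
    if (!any(ok)) next
    dth <- abs(thp[ok] - thq[ok])
    dph <- wrap_to_pi(php[ok] - phq[ok])
    w <- mgq[ok] / (mgp[ok] + eps)
    it <- pmin(floor(dth / (pi / n_theta)), n_theta - 1L)
    ip <- pmin(floor((dph + pi) / (2 * pi / n_phi)), n_phi - 1L)
    bin <- it * n_phi + ip + 1L
    s <- rowsum(w, bin)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  l2_normalize(acc)
}

#' Compute descriptors for all keypoints of a volume
#'
#' Convenience wrapper: extracts a patch per keypoint, drops rejected ones,
#' and stacks the descriptors of the survivors.
#'
#' @param v a normalized [new_volume()].
#' @param kps keypoint data.frame from [detect_keypoints()].
#' @param grad optional precomputed [compute_gradients()] field.
#' @param min_mask_frac,n_theta,n_phi,eps see [extract_patch()] and
#'   [rihog_descriptor()].
#' @return list with `descriptors` (matrix, one row per accepted keypoint)
#'   and `keypoints` (the accepted subset, with `edge_len` and
#'   `in_mask_fraction` columns added).
#' @export
compute_descriptors <- function(v, kps, grad = NULL, min_mask_frac = 0.5,
                                n_theta = 4L, n_phi = 8L, eps = 1e-8) {
  if (is.null(grad)) grad <- compute_gradients(v)
  ml <- mask_logical(v)
  n <- nrow(kps)
  keep <- logical(n)
  edge_len <- integer(n)
  frac <- numeric(n)
  desc <- vector("list", n)
  for (i in seq_len(n)) {
    p <- extract_patch(v, kps[i, ], min_mask_frac = min_mask_frac)
    edge_len[i] <- p$edge_len
    if (!p$accepted) next
    keep[i] <- TRUE
    frac[i] <- p$in_mask_fraction
    desc[[i]] <- rihog_descriptor(p, grad, mask = ml,
                                  n_theta = n_theta, n_phi = n_phi, eps = eps)
  }
  kept <- kps[keep, , drop = FALSE]
  kept$edge_len <- edge_len[keep]
  kept$in_mask_fraction <- frac[keep]
  mat <- if (any(keep)) do.call(rbind, desc[keep]) else
    matrix(numeric(0), 0, n_theta * n_phi)
  rownames(mat) <- NULL
  list(descriptors = mat, keypoints = kept)
}
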