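# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results with the simplest possible code (triple
# loops, BFS, explicit pair counting) so the fast implementations are
# checked against an unrelated computation path.

# Exhaustive 3x3x3 strict-extremum scan of one 3D array. Border voxels are
# excluded (incomplete neighborhoods). Returns a data.frame of (z, y, x,
# value, type).
oracle_extrema_scan <- function(d) {
  dims <- dim(d)
  out <- list()
  for (z in 2:(dims[1] - 1)) for (y in 2:(dims[2] - 1)) for (x in 2:(dims[3] - 1)) {
    nb <- d[(z - 1):(z + 1), (y - 1):(y + 1), (x - 1):(x + 1)]
    v <- d[z, y, x]
    others <- nb[-14]  # center is element 14 of the 3x3x3 block
    if (all(v > others)) {
      out[[length(out) + 1]] <- data.frame(z = z, y = y, x = x, value = v, type = "max")
    } else if (all(v < others)) {
      out[[length(out) + 1]] <- data.frame(z = z, y = y, x = x, value = v, type = "min")
    }
  }
  if (length(out) == 0) {
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      value = numeric(0), type = character(0)))
  }
  do.call(rbind, out)
}

# Breadth-first flood fill connected-component labeling of a binary mask.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 `6` = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 `18` = offs[rowSums(offs^2) <= 2, , drop = FALSE],
                 `26` = offs)
  labels <- array(0L, d)
  lab <- 0L
  todo <- which(mask > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    p <- todo[r, ]
    if (labels[p[1], p[2], p[3]] != 0L) next
    lab <- lab + 1L
    queue <- list(p)
    labels[p[1], p[2], p[3]] <- lab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- cur + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] > 0 && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- lab
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  labels
}

# Brute-force 13-feature Haralick vector by explicit pair counting and
# elementwise feature sums (independent of the package's vectorized GLCM).
oracle_haralick <- function(q, n_levels) {
  d <- dim(q)
  dirs <- list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
               c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1),
               c(1,-1,1), c(1,-1,-1))
  feats <- NULL
  n_valid <- 0
  for (dir in dirs) {
    cnt <- matrix(0, n_levels, n_levels)
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      q2 <- c(z, y, x) + dir
      if (any(q2 < 1) || any(q2 > d)) next
      a <- q[z, y, x]; b <- q[q2[1], q2[2], q2[3]]
      if (a == 0 || b == 0) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) == 0) next
    P <- cnt / sum(cnt)
    f <- oracle_haralick_features(P)
    feats <- if (is.null(feats)) f else feats + f
    n_valid <- n_valid + 1
  }
  if (n_valid == 0) return(NULL)
  feats / n_valid
}

# Feature formulas written as explicit loops over GLCM cells.
oracle_haralick_features <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sigx <- sqrt(sum(((1:ng) - mux)^2 * px))
  sigy <- sqrt(sum(((1:ng) - muy)^2 * py))
  asm <- 0; contrast <- 0; corr_num <- 0; varia <- 0; idm <- 0; entropy <- 0
  hxy1 <- 0
  pxy_sum <- numeric(2 * ng); pxy_diff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    corr_num <- corr_num + i * j * p
    varia <- varia + (i - mux)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) entropy <- entropy - p * log(p)
    if (p > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - p * log(px[i] * py[j])
    pxy_sum[i + j] <- pxy_sum[i + j] + p
    pxy_diff[abs(i - j) + 1] <- pxy_diff[abs(i - j) + 1] + p
  }
  degen <- sigx == 0 || sigy == 0
  correlation <- if (degen) 0 else (corr_num - mux * muy) / (sigx * sigy)
  ks <- seq_along(pxy_sum)
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  sum_entropy <- ent(pxy_sum)
  kd <- seq_along(pxy_diff) - 1
  diff_mean <- sum(kd * pxy_diff)
  diff_var <- sum((kd - diff_mean)^2 * pxy_diff)
  diff_entropy <- ent(pxy_diff)
  hx <- ent(px); hy <- ent(py)
  hxy2 <- ent(outer(px, py))
  imc1 <- if (degen || max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- if (degen) 0 else sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(angular_second_moment = asm, contrast = contrast,
    correlation = correlation, sum_of_squares_variance = varia,
    inverse_difference_moment = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = diff_var, difference_entropy = diff_entropy,
    info_measure_corr_1 = imc1, info_measure_corr_2 = imc2)
}

# Volume with isotropic Gaussian blobs at given (z,y,x) centers.
blob_volume <- function(shape, centers, sigma = 1.6, amplitude = 1) {
  a <- array(0, shape)
  g <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]), x = seq_len(shape[3]))
  for (r in seq_len(nrow(centers))) {
    a[] <- a + amplitude * exp(-((g$z - centers[r, 1])^2 + (g$y - centers[r, 2])^2 +
                                   (g$x - centers[r, 3])^2) / (2 * sigma^2))
  }
  a
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Smooth random test patch: a few Gaussian blobs inside a cube.
smooth_random_patch <- function(n = 17, n_blobs = 6, seed = 7) {
  set.seed(seed)
  centers <- matrix(runif(n_blobs * 3, n * 0.3, n * 0.75), n_blobs, 3)
  sig <- runif(n_blobs, 1.5, 3)
  a <- array(0, c(n, n, n))
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  for (i in seq_len(n_blobs)) {
    a[] <- a + runif(1, 0.5, 1) * exp(-((g$z - centers[i, 1])^2 +
                                          (g$y - centers[i, 2])^2 +
                                          (g$x - centers[i, 3])^2) / (2 * sig[i]^2))
  }
  a
}

# Descriptor of a standalone cubic array, centered patch covering most of it.
descriptor_of_cube <- function(a, edge = dim(a)[1] - 2, ...) {
  v <- new_volume(a)
  grad <- compute_gradients(v)
  ctr <- (dim(a)[1] + 1) %/% 2
  kp <- list(z = ctr, y = ctr, x = ctr, sigma = edge / 5, octave = 0)
  p <- extract_patch(v, kp, min_mask_frac = 0)
  stopifnot(p$accepted)
  rihog_descriptor(p, grad, ...)
}
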