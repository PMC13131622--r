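# Visual-word encoding: sparse dictionary learning, soft assignment,
# per-image pooling and TF-IDF + L2 image vectors.
#
# The sparse coder is orthogonal matching pursuit (OMP) with a fixed
# nonzero budget; the dictionary update is the method-of-optimal-directions
# (MOD) least-squares step with atom renormalization and seeded replacement
# of dead atoms. No installed R package provides mini-batch dictionary
# learning, so the alternation is implemented here directly.

# OMP-encode rows of x (n x d) against unit-norm atoms (K x d).
# Returns n x K coefficients; descriptors may receive negative weights.
omp_encode <- function(atoms, x, sparsity = 5L, tol = 1e-10) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  K <- nrow(atoms)
  n <- nrow(x)
  s_max <- min(sparsity, K, ncol(x))
  coeffs <- matrix(0, n, K)
  At <- t(atoms)  # d x K
  for (i in seq_len(n)) {
    xi <- x[i, ]
    nrm2 <- sum(xi^2)
    if (nrm2 <= tol) next
    r <- xi
    active <- integer(0)
    cf <- NULL
    for (s in seq_len(s_max)) {
      corr <- abs(drop(r %*% At))
      corr[active] <- -Inf
      j <- which.max(corr)
      if (corr[j] < 1e-12) break
      active <- c(active, j)
      B <- At[, active, drop = FALSE]           # d x |A|
      cf <- qr.solve(B, xi)
      r <- xi - drop(B %*% cf)
      if (sum(r^2) <= tol * nrm2) break
    }
    if (length(active)) coeffs[i, active] <- cf
  }
  coeffs
}

#' Learn a sparse visual-word codebook
#'
#' Alternates OMP sparse coding with a method-of-optimal-directions
#' least-squares dictionary update on (a seeded subsample of) the pooled
#' descriptors. Atoms are unit-L2-normalized after every update; atoms that
#' no descriptor uses are reseeded from random training descriptors. The
#' result is deterministic for a given seed. Descriptors should be pooled
#' across all images of the dataset before learning.
#'
#' @param descriptors matrix, one descriptor per row (>= K rows).
#' @param K codebook size; 200 visual words by default.
#' @param seed RNG seed controlling initialization and subsampling.
#' @param sparsity OMP nonzero budget per descriptor during learning and
#'   encoding.
#' @param n_iter coding/update alternations.
#' @param max_train at most this many (seeded-subsampled) descriptors are
#'   used per alternation.
#' @return object of class `bovw_codebook` with the `K x D` atom matrix and
#'   the training metadata.
#' @export
learn_codebook <- function(descriptors, K = 200L, seed = 1L, sparsity = 5L,
                           n_iter = 10L, max_train = 5000L) {
  x <- as.matrix(descriptors)
  n <- nrow(x)
  if (n < K) {
    stop("need at least K = ", K, " descriptors to learn the codebook, got ",
         n, "; use a smaller K")
  }
  nz <- which(rowSums(x^2) > 0)
  if (length(nz) < K) stop("fewer than K nonzero descriptors; use a smaller K")
  with_seed(seed, {
    init <- sample(nz, K)
    atoms <- x[init, , drop = FALSE]
    atoms <- atoms / sqrt(rowSums(atoms^2))
    for (it in seq_len(n_iter)) {
      batch <- if (n > max_train) x[sample.int(n, max_train), , drop = FALSE] else x
      C <- omp_encode(atoms, batch, sparsity = sparsity)
      usage <- colSums(abs(C))
      G <- crossprod(C) + diag(1e-8, K)
      atoms_new <- solve(G, crossprod(C, batch))
      nrm <- sqrt(rowSums(atoms_new^2))
      dead <- usage <= 1e-12 | nrm <= 1e-12
      if (any(dead)) {
        atoms_new[dead, ] <- batch[sample(which(rowSums(batch^2) > 0),
                                          sum(dead), replace = TRUE), , drop = FALSE]
        nrm <- sqrt(rowSums(atoms_new^2))
      }
      atoms <- atoms_new / nrm
    }
    structure(list(atoms = atoms, K = as.integer(K), D = ncol(x),
                   seed = as.integer(seed), sparsity = as.integer(sparsity),
                   n_iter = as.integer(n_iter)),
              class = "bovw_codebook")
  })
}

#' Soft-assign descriptors to the codebook
#'
#' Each descriptor is encoded as a sparse coefficient vector over the whole
#' dictionary (OMP with the codebook's nonzero budget); coefficients may be
#' negative, and a zero descriptor encodes to all-zero coefficients.
#'
#' @param cb a [learn_codebook()] result.
#' @param descriptors matrix (rows) or a single descriptor vector.
#' @return `n x K` coefficient matrix, rows in input order.
#' @export
encode_descriptors <- function(cb, descriptors) {
  stopifnot(inherits(cb, "bovw_codebook"))
  x <- if (is.null(dim(descriptors))) matrix(descriptors, nrow = 1) else as.matrix(descriptors)
  if (ncol(x) != cb$D) {
    stop("descriptor length ", ncol(x), " does not match codebook atom length ", cb$D)
  }
  omp_encode(cb$atoms, x, sparsity = cb$sparsity)
}

#' Pool patch encodings into an image-level word-usage vector
#'
#' Word usage is the per-word sum of absolute coefficients over the image's
#' patches. Absolute values make usage non-negative, which the TF-IDF
#' weighting and the attention redistribution both presuppose; set
#' `absolute = FALSE` for plain signed sums.
#'
#' @param coeffs `P x K` coefficient matrix of one image's patches.
#' @param absolute pool `|coefficients|` (default) or raw coefficients.
#' @return length-K usage vector; an image with zero patches yields the
#'   zero vector with a warning.
#' @export
pool_image <- function(coeffs, absolute = TRUE) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1)
  if (nrow(coeffs) == 0) {
    warning("image has no accepted patches; returning zero usage vector")
    return(numeric(ncol(coeffs)))
  }
  if (absolute) colSums(abs(coeffs)) else colSums(coeffs)
}

#' Fit the smoothed inverse-document-frequency model
#'
#' With N images and `df_k` the number of images whose usage of word k
#' exceeds the presence threshold, `idf_k = ln((1 + N) / (1 + df_k)) + 1`.
#' A word present in every image gets idf 1 (maximal down-weighting); a word
#' absent everywhere gets the finite `ln(1 + N) + 1`.
#'
#' @param usage `N x K` matrix of raw usage vectors (N >= 2 images).
#' @param eps presence threshold on usage.
#' @return object of class `bovw_tfidf` storing `idf`, `n_documents`, `eps`.
#' @export
fit_tfidf <- function(usage, eps = 1e-8) {
  usage <- as.matrix(usage)
  n <- nrow(usage)
  if (n < 2) stop("TF-IDF needs at least 2 images")
  df <- colSums(usage > eps)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(idf = idf, n_documents = n, eps = eps), class = "bovw_tfidf")
}

#' Apply TF-IDF weighting and L2 normalization to usage vectors
#'
#' `tfidf_k = usage_k * idf_k`, then each image vector is scaled to unit L2
#' norm (an all-zero vector stays zero). The normalization removes the
#' dependence on the number of keypoints per image.
#'
#' @param model a [fit_tfidf()] result.
#' @param usage usage vector or `N x K` matrix.
#' @return list of class `bovw_image_vectors` with matrices `raw_usage`,
#'   `tfidf` and `normalized` (one row per image).
#' @export
apply_tfidf_l2 <- function(model, usage) {
  stopifnot(inherits(model, "bovw_tfidf"))
  u <- if (is.null(dim(usage))) matrix(usage, nrow = 1) else as.matrix(usage)
  if (ncol(u) != length(model$idf)) stop("usage length does not match fitted idf")
  tf <- sweep(u, 2, model$idf, `*`)
  nrm <- sqrt(rowSums(tf^2))
  nrm[nrm == 0] <- 1
  structure(list(raw_usage = u, tfidf = tf, normalized = tf / nrm),
            class = "bovw_image_vectors")
}

#' 2D embedding of image vectors for visualization
#'
#' UMAP (via \pkg{uwot}, single-threaded for reproducibility) of the
#' normalized image vectors; `method = "pca"` gives a deterministic linear
#' alternative. The embedding is presentation-layer only: nothing downstream
#' consumes it.
#'
#' @param x `N x K` matrix of normalized image vectors (N >= 4).
#' @param seed RNG seed.
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors UMAP neighborhood size (capped at N - 1).
#' @return `N x 2` coordinate matrix.
#' @export
embed_2d <- function(x, seed = 42L, method = c("umap", "pca"), n_neighbors = 15L) {
  x <- as.matrix(x)
  method <- match.arg(method)
  if (nrow(x) < 4) stop("need at least 4 images to embed, got ", nrow(x))
  if (method == "pca") {
    sc <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x
    if (ncol(sc) < 2) sc <- cbind(sc, 0)
    return(sc[, 1:2, drop = FALSE])
  }
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("package 'uwot' is required for method = \"umap\"")
  }
  with_seed(seed, {
    uwot::umap(x, n_neighbors = min(n_neighbors, nrow(x) - 1),
               n_threads = 1, n_sgd_threads = 0, batch = FALSE)
  })
}
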