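make_prototype_corpus <- function(n = 300, noise = 0.02, seed = 1) {
  set.seed(seed)
  proto <- diag(1, 3, 32)
  idx <- sample(1:3, n, replace = TRUE)
  proto[idx, ] + matrix(rnorm(n * 32, 0, noise), n)
}

test_that("codebook learning beats a random codebook and is deterministic", {
  X <- make_prototype_corpus(seed = 1)
  held <- make_prototype_corpus(n = 100, seed = 2)
  cb <- learn_codebook(X, K = 3, seed = 5, sparsity = 2, n_iter = 8)
  expect_equal(dim(cb$atoms), c(3, 32))
  expect_equal(sqrt(rowSums(cb$atoms^2)), rep(1, 3))

  resid <- function(atoms) {
    co <- bovw3d:::omp_encode(atoms, held, sparsity = 2)
    mean(sqrt(rowSums((held - co %*% atoms)^2)))
  }
  set.seed(99)
  random_atoms <- matrix(rnorm(3 * 32), 3)
  random_atoms <- random_atoms / sqrt(rowSums(random_atoms^2))
  expect_lt(resid(cb$atoms), resid(random_atoms))

  cb2 <- learn_codebook(X, K = 3, seed = 5, sparsity = 2, n_iter = 8)
  expect_identical(cb$atoms, cb2$atoms)
  expect_error(learn_codebook(X[1:2, ], K = 3), "smaller K")
})

test_that("a 200-word codebook yields 200 unit-norm atoms", {
  set.seed(4)
  X <- matrix(abs(rnorm(600 * 32)), 600)
  cb <- learn_codebook(X, K = 200, seed = 1, n_iter = 3)
  expect_equal(dim(cb$atoms), c(200, 32))
  expect_equal(sqrt(rowSums(cb$atoms^2)), rep(1, 200), tolerance = 1e-12)
})

test_that("soft assignment encodes over the whole dictionary", {
  X <- make_prototype_corpus(seed = 3)
  cb <- learn_codebook(X, K = 3, seed = 1, sparsity = 2, n_iter = 8)
  # a descriptor equal to an atom is encoded almost entirely by that atom
  co <- encode_descriptors(cb, cb$atoms[2, ])
  expect_gte(abs(co[2]) / sum(abs(co)), 0.9)
  expect_true(all(encode_descriptors(cb, rep(0, 32)) == 0))
  # batch encoding preserves order
  batch <- encode_descriptors(cb, X[1:10, ])
  expect_equal(dim(batch), c(10, 3))
  for (i in c(1, 7)) {
    expect_equal(batch[i, ], as.vector(encode_descriptors(cb, X[i, ])))
  }
  expect_error(encode_descriptors(cb, rep(0, 31)), "does not match")
})

test_that("image pooling sums absolute coefficients", {
  co <- rbind(c(1, 0, 0), c(0, 2, 0))
  expect_equal(pool_image(co), c(1, 2, 0))
  expect_equal(pool_image(matrix(c(-1, 0, 0), 1)), c(1, 0, 0))
  expect_equal(pool_image(matrix(c(-1, 0, 0), 1), absolute = FALSE), c(-1, 0, 0))
  one <- matrix(c(0.5, -0.25, 0), 1)
  expect_equal(pool_image(one[rep(1, 7), ]), 7 * pool_image(one))
  expect_warning(z <- pool_image(matrix(numeric(0), 0, 3)), "no accepted patches")
  expect_equal(z, c(0, 0, 0))
})

test_that("idf matches the smoothed closed form", {
  usage <- rbind(c(1, 0, 0.5), c(2, 0, 0), c(3, 0, 1))
  m <- fit_tfidf(usage)
  n <- 3
  expect_equal(m$idf[1], log((1 + n) / (1 + 3)) + 1)  # ubiquitous word -> 1
  expect_equal(m$idf[1], 1)
  expect_equal(m$idf[2], log(1 + n) + 1)              # absent word, finite
  expect_equal(m$idf[3], log((1 + n) / (1 + 2)) + 1)  # hand calculation
  expect_error(fit_tfidf(usage[1, , drop = FALSE]), "at least 2")
})

test_that("tf-idf + L2 matches hand calculation and its invariances", {
  usage <- rbind(c(2, 1, 0), c(1, 1, 1))
  m <- fit_tfidf(usage)
  iv <- apply_tfidf_l2(m, usage[1, ])
  hand <- usage[1, ] * m$idf
  expect_equal(iv$tfidf[1, ], hand)
  expect_equal(iv$normalized[1, ], hand / sqrt(sum(hand^2)))
  expect_equal(sqrt(sum(iv$normalized[1, ]^2)), 1)
  # doubling usage leaves the normalized vector unchanged
  expect_equal(apply_tfidf_l2(m, 2 * usage[1, ])$normalized, iv$normalized)
  # uniform usage with uniform idf embeds to the uniform unit vector
  mu <- fit_tfidf(rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(apply_tfidf_l2(mu, c(3, 3, 3))$normalized[1, ], rep(1 / sqrt(3), 3))
  # all-zero usage stays all-zero
  expect_equal(apply_tfidf_l2(m, c(0, 0, 0))$normalized[1, ], c(0, 0, 0))
})

test_that("fit/transform on the same corpus is self-consistent", {
  set.seed(8)
  usage <- matrix(rexp(6 * 10), 6)
  m <- fit_tfidf(usage)
  v1 <- apply_tfidf_l2(m, usage)
  v2 <- apply_tfidf_l2(m, usage)
  expect_identical(v1$normalized, v2$normalized)
  # conservation identity consumed by the attention decomposition
  coeffs <- matrix(rnorm(5 * 10), 5)
  expect_identical(sum(pool_image(coeffs)), sum(abs(coeffs)))
})

test_that("replicating every patch leaves the normalized vector unchanged", {
  set.seed(10)
  coeffs <- matrix(rnorm(8 * 6), 8)
  corpus <- rbind(pool_image(coeffs), matrix(rexp(3 * 6), 3))
  m <- fit_tfidf(corpus)
  v1 <- apply_tfidf_l2(m, pool_image(coeffs))$normalized
  for (times in c(2, 5)) {
    rep_coeffs <- coeffs[rep(seq_len(nrow(coeffs)), times), ]
    v2 <- apply_tfidf_l2(m, pool_image(rep_coeffs))$normalized
    expect_equal(v1, v2, tolerance = 1e-10)
  }
})

test_that("2D embeddings separate well-separated classes", {
  set.seed(21)
  x <- rbind(matrix(rnorm(10 * 8, 0, 0.1), 10),
             matrix(rnorm(10 * 8, 2, 0.1), 10))
  em <- embed_2d(x, method = "pca")
  lab <- rep(1:2, each = 10)
  centroids <- rbind(colMeans(em[lab == 1, ]), colMeans(em[lab == 2, ]))
  spread <- mean(c(apply(em[lab == 1, ], 1, function(p) sqrt(sum((p - centroids[1, ])^2))),
                   apply(em[lab == 2, ], 1, function(p) sqrt(sum((p - centroids[2, ])^2)))))
  expect_gt(sqrt(sum((centroids[1, ] - centroids[2, ])^2)), spread)
  # duplicates map together; PCA is deterministic
  xd <- x[c(1, 1, 5, 9), ]
  emd <- embed_2d(xd, method = "pca")
  expect_equal(emd[1, ], emd[2, ])
  expect_identical(embed_2d(x, method = "pca"), em)
  expect_error(embed_2d(x[1:3, ]), "at least 4")
})

test_that("UMAP embedding is available and well-formed", {
  set.seed(22)
  x <- rbind(matrix(rnorm(8 * 6, 0, 0.1), 8), matrix(rnorm(8 * 6, 3, 0.1), 8))
  em <- embed_2d(x, seed = 7, method = "umap", n_neighbors = 5)
  expect_equal(dim(em), c(16, 2))
  expect_true(all(is.finite(em)))
})
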