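# Separable toy corpus: classes differ only in the usage of one word.
word7_corpus <- function(n_per_class = 12, K = 10, seed = 5) {
  set.seed(seed)
  base <- matrix(abs(rnorm(2 * n_per_class * K, 1, 0.1)), 2 * n_per_class)
  base[seq_len(n_per_class), 7] <- base[seq_len(n_per_class), 7] + 2
  x <- base / sqrt(rowSums(base^2))
  list(x = x, y = factor(rep(c("hi7", "lo7"), each = n_per_class),
                         levels = c("lo7", "hi7")))
}

test_that("logistic regression finds the discriminative word", {
  d <- word7_corpus()
  model <- train_classifier(d$x, d$y, C = 1)
  expect_equal(which.max(abs(model$weights[, 1])), 7)
  # hi7 is the positive (second) level and uses more of word 7
  expect_gt(model$weights[7, 1], 0)
  model2 <- train_classifier(d$x, d$y, C = 1)
  expect_identical(model$weights, model2$weights)
  expect_error(train_classifier(d$x, rep("one", nrow(d$x))), "2 classes")
})

test_that("cross-validation on permuted labels is at chance", {
  d <- word7_corpus(n_per_class = 20)
  expect_gte(evaluate_auc(d$x, d$y, n_folds = 5, seed = 1)$auc, 0.95)
  set.seed(123)
  yp <- sample(d$y)
  auc_null <- evaluate_auc(d$x, yp, n_folds = 5, seed = 1)$auc
  expect_gt(auc_null, 0.25)
  expect_lt(auc_null, 0.75)
})

test_that("rank AUC matches exhaustive pair counting", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 1.0)
  # one discordant pair out of nine
  expect_equal(auc_score(c(0.9, 0.8, 0.6, 0.7, 0.4, 0.2),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 8 / 9)
  expect_equal(auc_score(rep(0.5, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  # oracle: explicit loop over all positive/negative pairs with tie = 1/2
  set.seed(2)
  s <- round(runif(20), 1)
  lab <- rep(c(TRUE, FALSE), 10)
  pairs <- 0
  for (i in which(lab)) for (j in which(!lab)) {
    pairs <- pairs + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(auc_score(s, lab), pairs / (10 * 10))
})

test_that("attention decomposition reproduces the worked example", {
  # one word spread equally over 10 patches, contributing 10 units
  coeffs <- matrix(0, 10, 2); coeffs[, 1] <- 0.5
  corpus <- rbind(pool_image(coeffs), c(2, 1))
  tm <- fit_tfidf(corpus)
  x1 <- apply_tfidf_l2(tm, corpus[1, ])$normalized[1, ]
  w <- c(10 / x1[1], 0)  # calibrate so word 1 contributes exactly 10 units
  model <- structure(list(weights = matrix(w, ncol = 1, dimnames = list(NULL, "B")),
                          intercepts = c(B = 0.7), levels = c("A", "B"),
                          binary = TRUE, C = 1), class = "bovw_classifier")
  att <- attention_scores(model, tm, coeffs)
  expect_equal(att$patch_scores, rep(1, 10))
  expect_equal(sum(att$patch_scores), 10)
  expect_equal(att$decision, 10)
})

test_that("patch scores match a brute-force word-by-patch double loop", {
  set.seed(14)
  for (rep in 1:5) {
    P <- 5; K <- 4
    coeffs <- matrix(rnorm(P * K), P)
    corpus <- rbind(pool_image(coeffs), matrix(rexp(2 * K), 2))
    tm <- fit_tfidf(corpus)
    x <- apply_tfidf_l2(tm, corpus[1, ])$normalized[1, ]
    w <- rnorm(K)
    model <- structure(list(weights = matrix(w, ncol = 1, dimnames = list(NULL, "B")),
                            intercepts = c(B = 0), levels = c("A", "B"),
                            binary = TRUE, C = 1), class = "bovw_classifier")
    att <- attention_scores(model, tm, coeffs, x = x)
    oracle <- numeric(P)
    for (p in 1:P) for (k in 1:K) {
      tot <- sum(abs(coeffs[, k]))
      if (tot > 0) oracle[p] <- oracle[p] + w[k] * x[k] * abs(coeffs[p, k]) / tot
    }
    expect_equal(att$patch_scores, oracle, tolerance = 1e-12)
    expect_equal(sum(att$patch_scores), sum(w * x), tolerance = 1e-10)
    # single-patch image: the whole linear term lands on that patch
    single <- coeffs[1, , drop = FALSE]
    tm1 <- fit_tfidf(rbind(pool_image(single), corpus[2, ]))
    att1 <- attention_scores(model, tm1, single)
    expect_equal(att1$patch_scores, att1$decision)
  }
})

test_that("provenance mismatches are refused", {
  coeffs <- matrix(rnorm(6 * 3), 6)
  tm <- fit_tfidf(rbind(pool_image(coeffs), c(1, 2, 3)))
  model <- structure(list(weights = matrix(rnorm(3), ncol = 1,
                                           dimnames = list(NULL, "B")),
                          intercepts = c(B = 0), levels = c("A", "B"),
                          binary = TRUE, C = 1), class = "bovw_classifier")
  x_wrong <- l2 <- apply_tfidf_l2(tm, c(9, 1, 1))$normalized[1, ]
  expect_error(attention_scores(model, tm, coeffs, x = x_wrong),
               "provenance mismatch")
})

test_that("relabeling a binary problem negates all patch scores", {
  d <- word7_corpus(n_per_class = 10)
  m1 <- train_classifier(d$x, d$y)
  m2 <- train_classifier(d$x, factor(d$y, levels = rev(levels(d$y))))
  expect_equal(m1$weights[, 1], -m2$weights[, 1], tolerance = 1e-4)
  coeffs <- matrix(abs(rnorm(5 * 10)), 5)
  tm <- fit_tfidf(rbind(pool_image(coeffs), matrix(rexp(2 * 10), 2)))
  a1 <- attention_scores(m1, tm, coeffs)
  a2 <- attention_scores(m2, tm, coeffs)
  expect_equal(a1$patch_scores, -a2$patch_scores, tolerance = 1e-4)
})

test_that("rendering spreads, accumulates and rescales as specified", {
  patches <- data.frame(z = 5, y = 5, x = 5, edge_len = 5)
  am <- render_attention(c(10, 10, 10), patches, 2.5)
  expect_equal(sum(am$render), 2.5, tolerance = 1e-12)
  expect_equal(unique(am$render[am$render != 0]), 2.5 / 125)
  expect_equal(sum(am$render != 0), 125)

  # overlapping patches: voxelwise oracle on a 10^3 grid
  patches2 <- data.frame(z = c(4, 6), y = c(4, 6), x = c(4, 6),
                         edge_len = c(5, 5))
  s <- c(1.0, -0.5)
  am2 <- render_attention(c(10, 10, 10), patches2, s)
  oracle <- array(0, c(10, 10, 10))
  for (i in 1:2) {
    rng <- lapply(c(patches2$z[i], patches2$y[i], patches2$x[i]),
                  function(c0) (c0 - 2):(c0 + 2))
    oracle[rng[[1]], rng[[2]], rng[[3]]] <-
      oracle[rng[[1]], rng[[2]], rng[[3]]] + s[i] / 125
  }
  expect_equal(am2$render, oracle, tolerance = 1e-12)
  expect_equal(sum(am2$render), sum(s), tolerance = 1e-12)

  # constant map rescales to zeros with a warning
  expect_warning(am3 <- render_attention(c(4, 4, 4),
                                         data.frame(z = 2, y = 2, x = 2, edge_len = 1)[0, ],
                                         numeric(0)), "constant")
  expect_true(all(am3$rescaled == 0))
  # positive-only mode drops negative patches
  am4 <- render_attention(c(10, 10, 10), patches2, s, positive_only = TRUE)
  expect_equal(sum(am4$render), 1.0, tolerance = 1e-12)
  # gaussian mode still conserves each patch's score
  am5 <- render_attention(c(10, 10, 10), patches2, s, mode = "gaussian")
  expect_equal(sum(am5$render), sum(s), tolerance = 1e-12)
  expect_error(render_attention(c(6, 6, 6), patches, 1), "outside")
})

test_that("multiclass evaluation returns a full confusion matrix", {
  set.seed(31)
  K <- 6
  x <- do.call(rbind, lapply(1:4, function(c0) {
    matrix(rnorm(8 * K, 0, 0.15), 8) + matrix(rep(c(rep(0, c0 - 1), 2, rep(0, 4 - c0), 0, 0)[1:K], each = 8), 8)
  }))
  y <- factor(rep(paste0("c", 1:4), each = 8))
  ev <- evaluate_auc(x, y, n_folds = 4, seed = 2)
  expect_equal(dim(ev$confusion), c(4, 4))
  expect_equal(sum(ev$confusion), 32)
  expect_gte(sum(diag(ev$confusion)) / 32, 0.9)
  # multiclass attention needs an explicit class and conserves per class
  model <- train_classifier(x, y)
  coeffs <- matrix(abs(rnorm(5 * K)), 5)
  tm <- fit_tfidf(rbind(pool_image(coeffs), matrix(rexp(2 * K), 2)))
  att <- attention_scores(model, tm, coeffs, class = "c2")
  xv <- apply_tfidf_l2(tm, pool_image(coeffs))$normalized[1, ]
  expect_equal(sum(att$patch_scores), sum(model$weights[, "c2"] * xv),
               tolerance = 1e-10)
  expect_error(attention_scores(model, tm, coeffs), "specify 'class'")
})
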