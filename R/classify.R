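# L2-regularized logistic regression on image vectors, AUC-ROC scoring,
# and the decomposition of decision values into per-patch attention.

#' Train an L2-regularized logistic regression on image vectors
#'
#' Fits ridge-penalized logistic regression (via \pkg{glmnet}, `alpha = 0`,
#' a single penalty `lambda = 1 / (n * C)` so `C` plays the usual inverse
#' regularization role) on normalized image vectors. Two classes give one
#' weight vector (scores favor the second factor level); more classes give
#' a multinomial model with one weight vector per class. The fit is
#' deterministic: the solver is run to a tight tolerance and uses no
#' randomness.
#'
#' @param x `N x K` matrix of normalized image vectors.
#' @param y class labels (coerced to factor; >= 2 levels, >= 2 samples per
#'   level).
#' @param C inverse regularization strength (larger = weaker penalty).
#' @return object of class `bovw_classifier` with `weights` (`K x n_class`
#'   matrix; one column named after the positive class for binary models),
#'   `intercepts` and `levels`.
#' @export
train_classifier <- function(x, y, C = 1.0) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  n <- nrow(x)
  lambda <- 1 / (n * C)
  binary <- nlevels(y) == 2
  fit <- glmnet::glmnet(
    x, y, family = if (binary) "binomial" else "multinomial",
    alpha = 0, lambda = lambda, standardize = FALSE, thresh = 1e-12,
    maxit = 1e6
  )
  if (binary) {
    co <- as.matrix(stats::coef(fit))
    weights <- matrix(co[-1, 1], ncol = 1,
                      dimnames = list(colnames(x), levels(y)[2]))
    intercepts <- stats::setNames(co[1, 1], levels(y)[2])
  } else {
    cl <- stats::coef(fit)
    weights <- do.call(cbind, lapply(cl, function(m) as.matrix(m)[-1, 1]))
    colnames(weights) <- levels(y)
    intercepts <- vapply(cl, function(m) as.matrix(m)[1, 1], numeric(1))
    names(intercepts) <- levels(y)
  }
  structure(list(weights = weights, intercepts = intercepts,
                 levels = levels(y), C = C, binary = binary),
            class = "bovw_classifier")
}

#' Linear decision values of a fitted classifier
#'
#' @param model a [train_classifier()] result.
#' @param x image vector matrix (or single vector).
#' @return `N x n_class` matrix of `x %*% w + b` scores (one column for
#'   binary models).
#' @export
decision_values <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(x %*% model$weights, 2, model$intercepts, `+`)
}

predict_proba <- function(model, x) {
  dv <- decision_values(model, x)
  if (model$binary) {
    p <- 1 / (1 + exp(-dv[, 1]))
    cbind(stats::setNames(data.frame(1 - p, p), model$levels))
  } else {
    e <- exp(dv - apply(dv, 1, max))
    as.data.frame(e / rowSums(e))
  }
}

#' Rank-based AUC-ROC
#'
#' Midrank (tie-aware) Mann-Whitney formulation: perfectly separated scores
#' give 1, constant scores give 0.5.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels logical or two-level factor; the second level (or `TRUE`)
#'   is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (!is.logical(labels)) {
    labels <- factor(labels)
    if (nlevels(labels) != 2) stop("AUC needs exactly 2 classes")
    labels <- labels == levels(labels)[2]
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Cross-validated classifier evaluation
#'
#' Stratified k-fold cross-validation with a fixed seed. Binary problems
#' return the AUC-ROC pooled over out-of-fold predicted probabilities;
#' multiclass problems return the confusion matrix of out-of-fold predicted
#' classes (rows = truth). `n_folds = 0` evaluates in-sample on a single fit
#' instead.
#'
#' @param x image vector matrix.
#' @param y class labels.
#' @param n_folds folds (default 5), or 0 for in-sample evaluation.
#' @param C,seed see [train_classifier()]; the seed only drives fold
#'   assignment.
#' @return list with `auc` (binary) or `confusion` (multiclass), plus the
#'   per-sample `scores` data.frame.
#' @export
evaluate_auc <- function(x, y, n_folds = 5L, C = 1.0, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  binary <- nlevels(y) == 2
  if (n_folds == 0) {
    model <- train_classifier(x, y, C = C)
    prob <- predict_proba(model, x)
  } else {
    if (min(table(y)) < n_folds) {
      stop("each class needs at least n_folds = ", n_folds, " samples")
    }
    fold <- stratified_folds(y, n_folds, seed)
    prob <- as.data.frame(matrix(NA_real_, nrow(x), nlevels(y)))
    names(prob) <- levels(y)
    for (f in seq_len(n_folds)) {
      test <- fold == f
      if (nlevels(droplevels(y[!test])) < nlevels(y)) {
        stop("a class is absent from the training split of fold ", f)
      }
      model <- train_classifier(x[!test, , drop = FALSE], y[!test], C = C)
      prob[test, ] <- predict_proba(model, x[test, , drop = FALSE])
    }
  }
  pred <- factor(levels(y)[max.col(as.matrix(prob), ties.method = "first")],
                 levels = levels(y))
  out <- list(scores = cbind(data.frame(label = y, predicted = pred), prob))
  if (binary) {
    out$auc <- auc_score(prob[[levels(y)[2]]], y)
  } else {
    out$confusion <- table(truth = y, predicted = pred)
  }
  out
}

#' Decompose an image's decision value into per-patch attention scores
#'
#' The linear decision value (excluding the intercept, which has no spatial
#' support) is `sum_k w_k x_k` over visual words, where `x_k` is the
#' TF-IDF + L2-normalized usage of word k. Each word contribution
#' `c_k = w_k x_k` is redistributed to the image's patches in proportion to
#' each patch's absolute usage of that word; words with zero total usage
#' contribute nothing. Patch scores therefore sum exactly (to float
#' precision) to the linear decision term, giving a conservative spatial
#' decomposition.
#'
#' The normalized vector is reconstructed here from `coeffs` through the
#' stored TF-IDF model; if a reference vector `x` is supplied and disagrees,
#' the call aborts (provenance mismatch between encodings and vector).
#'
#' @param model a [train_classifier()] result.
#' @param tfidf the [fit_tfidf()] model used for the image vectors.
#' @param coeffs `P x K` patch coefficient matrix of one image.
#' @param x optional reference normalized image vector to validate against.
#' @param class which class's weight vector to use (default: the positive
#'   class for binary models; must be named for multiclass models).
#' @return list with `patch_scores` (length P), `word_contrib` (length K)
#'   and `decision` (their common sum).
#' @export
attention_scores <- function(model, tfidf, coeffs, x = NULL, class = NULL) {
  stopifnot(inherits(model, "bovw_classifier"), inherits(tfidf, "bovw_tfidf"))
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1)
  usage <- colSums(abs(coeffs))
  xv <- apply_tfidf_l2(tfidf, usage)$normalized[1, ]
  if (!is.null(x)) {
    if (max(abs(x - xv)) > 1e-6) {
      stop("provenance mismatch: supplied image vector was not produced ",
           "from these patch encodings via the stored TF-IDF model")
    }
  }
  if (is.null(class)) {
    class <- colnames(model$weights)[if (model$binary) 1 else stop(
      "multiclass model: specify 'class' for the decomposition")]
  }
  w <- model$weights[, class]
  contrib <- w * xv
  share <- abs(coeffs)
  tot <- colSums(share)
  active <- tot > 0
  patch_scores <- as.vector(
    share[, active, drop = FALSE] %*% (contrib[active] / tot[active])
  )
  list(patch_scores = patch_scores, word_contrib = contrib,
       decision = sum(contrib), class = class)
}

#' Render patch attention scores into a volumetric attention map
#'
#' Each patch's scalar score is spread over its cubic support (uniformly by
#' default, so voxel values sum exactly to the patch score; optional
#' isotropic Gaussian weighting, still normalized to conserve the score).
#' Overlapping patches accumulate additively. The `rescaled` copy is the
#' per-image min-max normalization of the rendered map to `[0, 1]`; a
#' constant rendered map rescales to all zeros with a warning.
#'
#' @param volume_shape integer length-3 `(z, y, x)` grid shape.
#' @param patches data.frame with patch geometry columns `z, y, x,
#'   edge_len` (as produced by [compute_descriptors()]).
#' @param patch_scores numeric vector, one score per patch row.
#' @param mode `"uniform"` or `"gaussian"` within-patch weighting.
#' @param positive_only drop patches with non-positive scores before
#'   rendering (the "positive attention" display convention).
#' @return list of class `bovw_attention_map` with 3D arrays `render` and
#'   `rescaled`, plus the inputs' bookkeeping.
#' @export
render_attention <- function(volume_shape, patches, patch_scores,
                             mode = c("uniform", "gaussian"),
                             positive_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(nrow(patches) == length(patch_scores))
  d <- as.integer(volume_shape)
  acc <- array(0, d)
  idx <- seq_len(nrow(patches))
  if (positive_only) idx <- idx[patch_scores > 0]
  for (i in idx) {
    e <- patches$edge_len[i]
    half <- (e - 1L) %/% 2L
    lo <- c(patches$z[i], patches$y[i], patches$x[i]) - half
    hi <- lo + e - 1L
    if (any(lo < 1) || any(hi > d)) {
      stop("patch ", i, " extends outside the volume")
    }
    w <- if (mode == "uniform") {
      array(1 / e^3, rep(e, 3))
    } else {
      s <- e / 5  # one SIFT scale unit
      g1 <- exp(-((1:e) - (half + 1))^2 / (2 * s^2))
      w3 <- outer(outer(g1, g1), g1)
      w3 / sum(w3)
    }
    acc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      acc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + patch_scores[i] * w
  }
  rng <- range(acc)
  if (rng[2] > rng[1]) {
    rescaled <- (acc - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("attention map is constant; min-max rescaled map set to zeros")
    rescaled <- array(0, d)
  }
  structure(list(render = acc, rescaled = rescaled, mode = mode,
                 positive_only = positive_only),
            class = "bovw_attention_map")
}
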