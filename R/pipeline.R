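#' Full pipeline configuration
#'
#' One schema-versioned bundle of every tunable parameter, with the package
#' defaults. Round-trips through JSON unchanged (see [read_config()]).
#'
#' @param norm_lo_pct,norm_hi_pct intensity normalization clip percentiles.
#' @param sigmas,n_octaves,contrast_thresh,edge_ratio_thresh scale-space
#'   parameters, see [scale_space_config()].
#' @param min_mask_frac minimum in-mask patch fraction, see
#'   [extract_patch()].
#' @param n_theta,n_phi descriptor orientation-difference bins.
#' @param K codebook size (visual words).
#' @param sparsity,dict_iter,max_train sparse-coding / dictionary-learning
#'   settings, see [learn_codebook()].
#' @param pool_absolute pool absolute coefficients (see [pool_image()]).
#' @param C,n_folds classifier inverse regularization and CV folds
#'   (`n_folds = 0` evaluates in-sample).
#' @param attention_mode,attention_positive within-patch spreading and
#'   positive-only rendering, see [render_attention()].
#' @param threshold_pct percentile rule for the global attention threshold.
#' @param connectivity blob connectivity (6, 18 or 26).
#' @param quant_levels gray levels for texture quantization.
#' @param embed_method `"umap"`, `"pca"` or `"none"`.
#' @param seed master seed for codebook learning, fold assignment and the
#'   embedding.
#' @return list of class `bovw_config`.
#' @export
pipeline_config <- function(norm_lo_pct = 5, norm_hi_pct = 95,
                            sigmas = c(1.0, 1.6, 2.2, 3.0), n_octaves = 3L,
                            contrast_thresh = 0.01, edge_ratio_thresh = 10,
                            min_mask_frac = 0.5, n_theta = 4L, n_phi = 8L,
                            K = 200L, sparsity = 5L, dict_iter = 10L,
                            max_train = 5000L, pool_absolute = TRUE,
                            C = 1.0, n_folds = 5L,
                            attention_mode = "uniform", attention_positive = TRUE,
                            threshold_pct = 90, connectivity = 26L,
                            quant_levels = 32L, embed_method = "umap",
                            seed = 1L) {
  cfg <- list(schema_version = "1.0",
              norm_lo_pct = norm_lo_pct, norm_hi_pct = norm_hi_pct,
              sigmas = sigmas, n_octaves = as.integer(n_octaves),
              contrast_thresh = contrast_thresh,
              edge_ratio_thresh = edge_ratio_thresh,
              min_mask_frac = min_mask_frac,
              n_theta = as.integer(n_theta), n_phi = as.integer(n_phi),
              K = as.integer(K), sparsity = as.integer(sparsity),
              dict_iter = as.integer(dict_iter), max_train = as.integer(max_train),
              pool_absolute = pool_absolute, C = C, n_folds = as.integer(n_folds),
              attention_mode = attention_mode,
              attention_positive = attention_positive,
              threshold_pct = threshold_pct,
              connectivity = as.integer(connectivity),
              quant_levels = as.integer(quant_levels),
              embed_method = embed_method, seed = as.integer(seed))
  class(cfg) <- "bovw_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "schema_version")])
  if (!identical(raw$schema_version, cfg$schema_version)) {
    stop("config schema version ", raw$schema_version,
         " does not match supported version ", cfg$schema_version)
  }
  cfg
}

#' Size-stratified subset of a dataset
#'
#' Keeps perturbed-class images whose nuclear volume is above their
#' condition's median, and control images below their condition's median;
#' images exactly at the median are excluded. This enriches the perturbed
#' class for the most-affected (enlarged) nuclei while removing the
#' size-driven overlap from the control side.
#'
#' @param manifest data.frame with columns `label` and `nuclear_volume`.
#' @param control_label,perturbed_label the two condition labels.
#' @return the subset manifest (possibly empty, with a warning when all
#'   volumes tie at the median).
#' @export
stratify_by_volume <- function(manifest, control_label, perturbed_label) {
  stopifnot(all(c("label", "nuclear_volume") %in% names(manifest)))
  if (any(is.na(manifest$nuclear_volume))) stop("missing nuclear volumes (no masks?)")
  keep <- logical(nrow(manifest))
  for (lab in c(control_label, perturbed_label)) {
    sel <- manifest$label == lab
    med <- stats::median(manifest$nuclear_volume[sel])
    keep[sel] <- if (lab == perturbed_label) {
      manifest$nuclear_volume[sel] > med
    } else {
      manifest$nuclear_volume[sel] < med
    }
  }
  out <- manifest[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("size stratification kept no images (all volumes at the median?)")
  out
}

#' Run the full analysis pipeline
#'
#' Executes, for a list of volumes with labels: percentile normalization,
#' multiscale keypoint detection, rotation-robust descriptor extraction,
#' codebook learning on the pooled descriptors, per-patch soft assignment,
#' per-image pooling, TF-IDF + L2 image vectors, optional 2D embedding,
#' cross-validated classification (AUC-ROC for two classes, confusion
#' matrix otherwise), attention decomposition and rendering with an
#' in-sample final model, global-threshold blob statistics, and Haralick
#' texture analysis of high-attention patches. Fully reproducible given the
#' configuration seed.
#'
#' @param records either a `make_dataset()` result, a list of
#'   `bovw_fixture_record` / [new_volume()] objects, or a manifest
#'   data.frame with `image_path` / `mask_path` columns to read from disk.
#' @param labels per-image condition labels; taken from the records or
#'   manifest when omitted.
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list of class `bovw_pipeline_result`; see the elements
#'   `vectors`, `evaluation`, `attention`, `blobs`, `texture`.
#' @export
run_pipeline <- function(records, labels = NULL, config = pipeline_config(),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  # -- resolve inputs ------------------------------------------------------
  if (is.list(records) && !is.null(records$records)) {
    if (is.null(labels)) labels <- records$manifest$label
    records <- records$records
  }
  if (is.data.frame(records)) {
    manifest <- records
    if (is.null(labels)) labels <- manifest$label
    records <- lapply(seq_len(nrow(manifest)), function(i) {
      read_volume(manifest$image_path[i],
                  mask_path = if (nzchar(manifest$mask_path[i] %||% "")) {
                    manifest$mask_path[i]
                  } else NULL)
    })
  }
  vols <- lapply(records, function(r) if (inherits(r, "bovw_fixture_record")) r$volume else r)
  n_img <- length(vols)
  if (is.null(labels)) {
    labels <- vapply(records, function(r) r$class %||% stop("labels missing"), character(1))
  }
  stopifnot(length(labels) == n_img)
  labels <- factor(labels)
  image_ids <- names(vols) %||% sprintf("img_%03d", seq_len(n_img))

  cfg <- config
  ss_cfg <- scale_space_config(cfg$sigmas, cfg$n_octaves, cfg$contrast_thresh,
                               cfg$edge_ratio_thresh)

  # -- per-image feature extraction ---------------------------------------
  say("normalizing %d volumes and extracting descriptors", n_img)
  per_image <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    v <- normalize_volume(vols[[i]], cfg$norm_lo_pct, cfg$norm_hi_pct)
    kps <- detect_keypoints(v, ss_cfg)
    de <- compute_descriptors(v, kps, min_mask_frac = cfg$min_mask_frac,
                              n_theta = cfg$n_theta, n_phi = cfg$n_phi)
    per_image[[i]] <- list(volume = v, keypoints = de$keypoints,
                           descriptors = de$descriptors)
  }
  n_desc <- vapply(per_image, function(p) nrow(p$descriptors), integer(1))
  say("descriptors per image: median %d (range %d-%d)",
      as.integer(stats::median(n_desc)), min(n_desc), max(n_desc))

  # -- codebook + encoding -------------------------------------------------
  pooled <- do.call(rbind, lapply(per_image, `[[`, "descriptors"))
  say("learning %d-word codebook on %d pooled descriptors", cfg$K, nrow(pooled))
  codebook <- learn_codebook(pooled, K = cfg$K, seed = cfg$seed,
                             sparsity = cfg$sparsity, n_iter = cfg$dict_iter,
                             max_train = cfg$max_train)
  usage <- matrix(0, n_img, cfg$K)
  encodings <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    co <- encode_descriptors(codebook, per_image[[i]]$descriptors)
    encodings[[i]] <- co
    usage[i, ] <- pool_image(co, absolute = cfg$pool_absolute)
  }
  tfidf <- fit_tfidf(usage)
  vectors <- apply_tfidf_l2(tfidf, usage)
  rownames(vectors$normalized) <- image_ids

  embedding <- NULL
  if (cfg$embed_method != "none" && n_img >= 4) {
    say("embedding image vectors (%s)", cfg$embed_method)
    embedding <- embed_2d(vectors$normalized, seed = cfg$seed,
                          method = cfg$embed_method)
  }

  # -- classification ------------------------------------------------------
  say("evaluating classifier (%s)",
      if (cfg$n_folds > 0) sprintf("%d-fold CV", cfg$n_folds) else "in-sample")
  evaluation <- evaluate_auc(vectors$normalized, labels, n_folds = cfg$n_folds,
                             C = cfg$C, seed = cfg$seed)
  final_model <- train_classifier(vectors$normalized, labels, C = cfg$C)

  # -- attention -----------------------------------------------------------
  say("rendering attention maps")
  attention <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    cls <- if (final_model$binary) NULL else as.character(labels[i])
    att <- attention_scores(final_model, tfidf, encodings[[i]],
                            x = vectors$normalized[i, ], class = cls)
    amap <- render_attention(dim(per_image[[i]]$volume$data),
                             per_image[[i]]$keypoints, att$patch_scores,
                             mode = cfg$attention_mode,
                             positive_only = cfg$attention_positive)
    attention[[i]] <- list(scores = att, map = amap)
  }
  thresh <- attention_threshold_value(lapply(attention, `[[`, "map"),
                                      pct = cfg$threshold_pct)

  # -- blobs + texture -----------------------------------------------------
  say("blob and texture analysis (global threshold %.4f)", thresh)
  blob_rows <- vector("list", n_img)
  tex_rows <- list()
  for (i in seq_len(n_img)) {
    hi <- threshold_attention(attention[[i]]$map, thresh)
    bs <- blob_analysis(hi, connectivity = cfg$connectivity)
    blob_rows[[i]] <- data.frame(
      image_id = image_ids[i], label = as.character(labels[i]),
      n_blobs = bs$n_blobs,
      total_volume = sum(bs$blob_volumes),
      mean_volume = if (bs$n_blobs > 0) mean(bs$blob_volumes) else NA_real_,
      stringsAsFactors = FALSE
    )
    q <- quantize_for_texture(per_image[[i]]$volume, n_levels = cfg$quant_levels)
    kp <- per_image[[i]]$keypoints
    if (nrow(kp) == 0) next
    in_hi <- hi[cbind(kp$z, kp$y, kp$x)]
    for (j in which(in_hi)) {
      half <- (kp$edge_len[j] - 1L) %/% 2L
      lo <- c(kp$z[j], kp$y[j], kp$x[j]) - half
      hi_c <- lo + kp$edge_len[j] - 1L
      f <- haralick_patch(q[lo[1]:hi_c[1], lo[2]:hi_c[2], lo[3]:hi_c[3], drop = FALSE],
                          n_levels = cfg$quant_levels)
      if (is.null(f)) next
      tex_rows[[length(tex_rows) + 1L]] <- data.frame(
        image_id = image_ids[i], condition = as.character(labels[i]),
        as.list(f), stringsAsFactors = FALSE
      )
    }
  }
  blobs <- do.call(rbind, blob_rows)
  texture <- NULL
  if (length(tex_rows)) {
    tex_df <- do.call(rbind, tex_rows)
    texture <- pool_texture(tex_df)
    texture$per_patch <- tex_df
  }

  structure(list(
    config = cfg, image_ids = image_ids, labels = labels,
    keypoints = lapply(per_image, `[[`, "keypoints"),
    codebook = codebook, encodings = encodings, tfidf = tfidf,
    vectors = vectors, embedding = embedding,
    evaluation = evaluation, model = final_model,
    attention = attention, attention_threshold = thresh,
    blobs = blobs, texture = texture
  ), class = "bovw_pipeline_result")
}

#' @export
print.bovw_pipeline_result <- function(x, ...) {
  cat("<bovw_pipeline_result>\n")
  cat(sprintf("  images: %d (%s)\n", length(x$image_ids),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  cat(sprintf("  codebook: %d words x %d dims\n", x$codebook$K, x$codebook$D))
  if (!is.null(x$evaluation$auc)) {
    cat(sprintf("  AUC-ROC (%s): %.3f\n",
                if (x$config$n_folds > 0) sprintf("%d-fold CV", x$config$n_folds)
                else "in-sample", x$evaluation$auc))
  }
  if (!is.null(x$evaluation$confusion)) {
    cat("  confusion matrix:\n")
    print(x$evaluation$confusion)
  }
  cat(sprintf("  attention threshold: %.4f; mean blobs/image: %.1f\n",
              x$attention_threshold, mean(x$blobs$n_blobs)))
  invisible(x)
}
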