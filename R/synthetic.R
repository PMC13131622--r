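# Synthetic volumetric fixtures: masked ellipsoidal "nuclei" whose interior
# texture differs between two classes (punctate high-frequency blobs versus
# smooth low-frequency signal), plus an anisotropic whole-field "timelapse"
# mode with many overlapping cells and no masks. Every draw is fully
# determined by the seed, and ground truth (blob centers, scales, nucleus
# volume) is always recorded so localization and trend-recovery tests can
# assert against it.

#' Specification of the synthetic two-class nucleus dataset
#'
#' Class A emulates punctate, high-frequency chromatin-like texture (many
#' small bright foci); class B emulates the smoother, more homogeneous
#' signal of a perturbed condition (few broad blobs), with an optional
#' nuclear volume shift mimicking loss-of-function nuclear enlargement.
#'
#' @param n_per_class images per class.
#' @param shape `(z, y, x)` grid shape in voxels.
#' @param radius_mean,radius_sd nucleus ellipsoid mean radius and s.d.
#'   (voxels); per-axis radii are additionally jittered by up to
#'   `axis_jitter` (relative).
#' @param class_a,class_b texture parameters per class: `n_blobs`,
#'   `blob_sigma` (voxels) and `amplitude`.
#' @param base_level diffuse interior intensity common to both classes.
#' @param noise_sd additive Gaussian noise s.d.
#' @param volume_shift multiplicative nuclear volume factor for class B
#'   (radius scales with its cube root).
#' @param anisotropy axial downsampling factor for the timelapse mode.
#' @param seed master seed; fully determines the dataset.
#' @return list of class `bovw_fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = 20L,
                         shape = c(40L, 40L, 40L),
                         radius_mean = 13, radius_sd = 1, axis_jitter = 0.12,
                         class_a = list(n_blobs = 25L, blob_sigma = 1.5, amplitude = 1.0),
                         class_b = list(n_blobs = 4L, blob_sigma = 5.0, amplitude = 1.0),
                         base_level = 0.15, noise_sd = 0.05,
                         volume_shift = 1.3, anisotropy = 4L, seed = 1L) {
  stopifnot(n_per_class >= 1, all(shape >= 8), radius_mean > 0,
            class_a$n_blobs >= 1, class_b$n_blobs >= 1,
            noise_sd >= 0, volume_shift > 0, anisotropy >= 1)
  structure(list(n_per_class = as.integer(n_per_class), shape = as.integer(shape),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 axis_jitter = axis_jitter, class_a = class_a, class_b = class_b,
                 base_level = base_level, noise_sd = noise_sd,
                 volume_shift = volume_shift, anisotropy = as.integer(anisotropy),
                 seed = as.integer(seed)),
            class = "bovw_fixture_spec")
}

# Add an isotropic Gaussian blob in place, evaluated on a +-4 sigma subgrid.
add_blob <- function(a, center, sigma, amplitude) {
  d <- dim(a)
  r <- ceiling(4 * sigma)
  lo <- pmax(round(center) - r, 1)
  hi <- pmin(round(center) + r, d)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  gz <- exp(-(zs - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(ys - center[2])^2 / (2 * sigma^2))
  gx <- exp(-(xs - center[3])^2 / (2 * sigma^2))
  a[zs, ys, xs] <- a[zs, ys, xs] + amplitude * outer(outer(gz, gy), gx)
  a
}

ellipsoid_mask <- function(shape, center, radii) {
  zs <- (seq_len(shape[1]) - center[1]) / radii[1]
  ys <- (seq_len(shape[2]) - center[2]) / radii[2]
  xs <- (seq_len(shape[3]) - center[3]) / radii[3]
  outer(outer(zs^2, ys^2, `+`), xs^2, `+`) <= 1
}

#' Generate one synthetic nucleus
#'
#' An ellipsoidal mask centered near the grid center, with interior
#' intensity = diffuse base level + the class's sum of Gaussian blobs +
#' Gaussian noise, clipped at zero; background is zero. Blob centers are
#' sampled uniformly inside 80% of the ellipsoid so every recorded center
#' lies strictly inside the mask.
#'
#' @param spec a [fixture_spec()].
#' @param class_id `"A"` (punctate) or `"B"` (smooth).
#' @param seed per-image seed (bit-identical output for equal seeds).
#' @return list of class `bovw_fixture_record` with `volume` (a
#'   [new_volume()] with binary mask), `class`, and `ground_truth`
#'   (`blob_centers` matrix, `blob_sigma`, `radii`, `nucleus_volume`).
#' @export
make_nucleus <- function(spec, class_id = c("A", "B"), seed = 1L) {
  class_id <- match.arg(class_id)
  pars <- if (class_id == "A") spec$class_a else spec$class_b
  shape <- spec$shape
  with_seed(seed, {
    r0 <- max(2, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
    if (class_id == "B") r0 <- r0 * spec$volume_shift^(1 / 3)
    radii <- r0 * (1 + stats::runif(3, -spec$axis_jitter, spec$axis_jitter))
    center <- (shape + 1) / 2 + stats::runif(3, -1, 1)
    radii <- pmin(radii, (shape - 3) / 2)  # keep the nucleus inside the grid
    mask <- ellipsoid_mask(shape, center, radii)
    # uniform sampling inside the shrunken ellipsoid, by rejection
    n_blobs <- pars$n_blobs
    centers <- matrix(0, n_blobs, 3, dimnames = list(NULL, c("z", "y", "x")))
    got <- 0L
    tries <- 0L
    while (got < n_blobs) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place ", n_blobs, " blobs inside the mask")
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      got <- got + 1L
      centers[got, ] <- center + u * 0.8 * radii
    }
    a <- array(0, shape)
    for (b in seq_len(n_blobs)) {
      a <- add_blob(a, centers[b, ], pars$blob_sigma, pars$amplitude)
    }
    a <- a + spec$base_level
    if (spec$noise_sd > 0) a <- a + stats::rnorm(length(a), 0, spec$noise_sd)
    a <- pmax(a, 0)
    a[!mask] <- 0
    structure(list(
      volume = new_volume(array(a, shape), mask = mask),
      class = class_id,
      ground_truth = list(blob_centers = centers, blob_sigma = pars$blob_sigma,
                          radii = radii, center = center,
                          nucleus_volume = sum(mask))
    ), class = "bovw_fixture_record")
  })
}

timelapse_class_params <- function() {
  # 2x2 design: control / polarity-OE x pre- / post-ligand. Ligand drives
  # clustering (diffuse signal condenses into many compact puncta); the
  # overexpression coarsens clusters (fewer, larger, brighter).
  list(
    ctrl_pre  = list(n_blobs = 8L,  blob_sigma = 3.5, amplitude = 0.5),
    ctrl_post = list(n_blobs = 30L, blob_sigma = 1.2, amplitude = 1.0),
    oe_pre    = list(n_blobs = 8L,  blob_sigma = 4.5, amplitude = 0.6),
    oe_post   = list(n_blobs = 18L, blob_sigma = 2.2, amplitude = 1.2)
  )
}

make_timelapse_frame <- function(spec, pars, seed) {
  lat <- max(spec$shape[2:3])
  full <- c(lat, lat, lat)
  with_seed(seed, {
    a <- array(0, full)
    n_cells <- 5L
    cell_centers <- matrix(stats::runif(n_cells * 3, lat * 0.15, lat * 0.85),
                           n_cells, 3)
    centers_all <- NULL
    for (ci in seq_len(n_cells)) {
      for (b in seq_len(pars$n_blobs)) {
        ctr <- cell_centers[ci, ] + stats::rnorm(3, 0, lat * 0.08)
        ctr <- pmin(pmax(ctr, 2), lat - 1)
        a <- add_blob(a, ctr, pars$blob_sigma, pars$amplitude)
        centers_all <- rbind(centers_all, ctr)
      }
    }
    a <- a + spec$base_level / 2
    if (spec$noise_sd > 0) a <- a + stats::rnorm(length(a), 0, spec$noise_sd)
    a <- pmax(a, 0)
    # emulate coarse axial sampling: keep every anisotropy-th z-plane
    a <- a[seq(1, lat, by = spec$anisotropy), , , drop = FALSE]
    structure(list(
      volume = new_volume(a, spacing = c(spec$anisotropy, 1, 1)),
      ground_truth = list(blob_centers = centers_all,
                          blob_sigma = pars$blob_sigma)
    ), class = "bovw_fixture_record")
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' In `"nuclei"` mode, `n_per_class` masked single-nucleus volumes per class
#' (A punctate, B smooth). In `"timelapse"` mode, whole-field anisotropic
#' frames without masks for the four conditions
#' `ctrl_pre / ctrl_post / oe_pre / oe_post` (z extent = lateral extent /
#' `anisotropy`). Per-image seeds are drawn deterministically from the
#' spec's master seed. When `dir` is given, volumes (and masks) are written
#' as TIFF with a CSV manifest and JSON ground-truth sidecars.
#'
#' @param spec a [fixture_spec()].
#' @param mode `"nuclei"` or `"timelapse"`.
#' @param dir optional output directory.
#' @return list with `records` (list of `bovw_fixture_record`) and
#'   `manifest` (data.frame: image_id, label, nuclear_volume, paths when
#'   written).
#' @export
make_dataset <- function(spec, mode = c("nuclei", "timelapse"), dir = NULL) {
  mode <- match.arg(mode)
  classes <- if (mode == "nuclei") c("A", "B") else names(timelapse_class_params())
  n_total <- spec$n_per_class * length(classes)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n_total))
  records <- vector("list", n_total)
  ids <- character(n_total)
  labels <- character(n_total)
  k <- 0L
  tl_pars <- timelapse_class_params()
  for (cl in classes) {
    for (i in seq_len(spec$n_per_class)) {
      k <- k + 1L
      records[[k]] <- if (mode == "nuclei") {
        make_nucleus(spec, cl, seed = seeds[k])
      } else {
        rec <- make_timelapse_frame(spec, tl_pars[[cl]], seed = seeds[k])
        rec$class <- cl
        rec
      }
      ids[k] <- sprintf("%s_%03d", cl, i)
      labels[k] <- cl
    }
  }
  manifest <- data.frame(
    image_id = ids, image_path = "", mask_path = "", label = labels,
    channel = "synthetic",
    nuclear_volume = vapply(records, function(r) {
      if (is.null(r$volume$mask)) NA_real_ else sum(r$volume$mask > 0)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n_total)) {
      ip <- file.path(dir, paste0(ids[k], ".tif"))
      mp <- if (!is.null(records[[k]]$volume$mask)) {
        file.path(dir, paste0(ids[k], "_mask.tif"))
      } else ""
      write_volume(records[[k]]$volume, ip,
                   mask_path = if (nzchar(mp)) mp else NULL)
      gt <- records[[k]]$ground_truth
      jsonlite::write_json(gt, file.path(dir, paste0(ids[k], "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
      manifest$image_path[k] <- ip
      manifest$mask_path[k] <- mp
    }
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(records = records, manifest = manifest)
}
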