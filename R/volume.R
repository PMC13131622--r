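#' Construct a volumetric image
#'
#' A volume is a 3D scalar intensity grid in `(z, y, x)` axis order with
#' optional physical voxel spacing and an optional label/binary mask on the
#' same grid. Voxel coordinates are 1-based array indices throughout the
#' package.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param spacing numeric length-3 physical voxel size per axis
#'   (micrometres), `(z, y, x)`. Defaults to unit spacing.
#' @param mask optional 3D array of the same shape: 0 = background,
#'   positive integers = object labels (or logical for a binary mask).
#' @param offset integer length-3 voxel offset (0-based) of this volume's
#'   origin inside a parent volume; set by [crop_to_label()] so cropped
#'   coordinates can be mapped back.
#' @return object of class `bovw_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), mask = NULL,
                       offset = c(0L, 0L, 0L)) {
  if (length(dim(data)) != 3) {
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimension(s)")
  }
  if (!is.null(mask)) {
    if (is.logical(mask)) mask <- array(as.integer(mask), dim(mask))
    if (!identical(dim(mask), dim(data))) {
      stop("mask shape (", paste(dim(mask), collapse = "x"),
           ") does not match data shape (", paste(dim(data), collapse = "x"), ")")
    }
  }
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(
    list(data = data, spacing = as.numeric(spacing), mask = mask,
         offset = as.integer(offset)),
    class = "bovw_volume"
  )
}

#' @export
print.bovw_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bovw_volume> %d x %d x %d (z,y,x), spacing %s um%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "/"),
              if (!is.null(x$mask)) sprintf(", mask with %d label(s)",
                                            length(setdiff(unique(as.vector(x$mask)), 0)))
              else ""))
  invisible(x)
}

#' Read a volume from a multi-page TIFF stack
#'
#' Pages are stacked along z, giving `(z, y, x)` axis order. Voxel spacing is
#' recovered from a JSON `{"spacing": [z, y, x]}` payload in the
#' ImageDescription tag when present (as written by [write_volume()]);
#' otherwise unit spacing is assumed. Single-page (2D) files are rejected.
#'
#' @param path TIFF file with >= 2 pages.
#' @param mask_path optional TIFF holding an integer label mask of the same
#'   shape.
#' @return a [new_volume()] object.
#' @export
read_volume <- function(path, mask_path = NULL) {
  st <- read_tiff_stack(path)
  if (dim(st$data)[1] < 2) {
    stop("expected a 3D stack but '", path, "' holds a single 2D page")
  }
  spacing <- c(1, 1, 1)
  if (!is.null(st$description)) {
    meta <- tryCatch(jsonlite::fromJSON(st$description), error = function(e) NULL)
    if (!is.null(meta$spacing) && length(meta$spacing) == 3) {
      spacing <- as.numeric(meta$spacing)
    }
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    ms <- read_tiff_stack(mask_path)
    mask <- array(as.integer(round(ms$data)), dim(ms$data))
  }
  new_volume(st$data, spacing = spacing, mask = mask)
}

#' Write a volume (and optionally its mask) as multi-page TIFF
#'
#' Intensities are stored as 32-bit float, masks as unsigned 16-bit
#' integers. Spacing is embedded in the ImageDescription tag so that
#' [read_volume()] round-trips it.
#'
#' @param v a [new_volume()] object.
#' @param path output TIFF path for the intensity data.
#' @param mask_path optional output path for the mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, mask_path = NULL) {
  stopifnot(inherits(v, "bovw_volume"))
  desc <- as.character(jsonlite::toJSON(list(spacing = v$spacing), auto_unbox = FALSE, digits = NA))
  write_tiff_stack(v$data, path, sample_format = "float", description = desc)
  if (!is.null(mask_path)) {
    if (is.null(v$mask)) stop("volume has no mask to write")
    write_tiff_stack(v$mask, mask_path, sample_format = "uint16", description = desc)
  }
  invisible(path)
}

mask_logical <- function(v) {
  if (is.null(v$mask)) NULL else v$mask > 0
}

#' Percentile-normalize a volume to [0, 1]
#'
#' Intensities are clipped to the `lo_pct`/`hi_pct` percentiles and affinely
#' rescaled so that the low percentile maps to 0 and the high percentile to
#' 1. When the volume carries a mask the percentiles are computed over
#' in-mask voxels only (per-nucleus normalization); background voxels are
#' still transformed with the same affine map and clipped. A constant region
#' (equal percentiles) yields an all-zero volume with a warning rather than
#' an error, so batch runs survive degenerate crops.
#'
#' @param v a [new_volume()] object with finite data.
#' @param lo_pct,hi_pct clip percentiles, `0 <= lo_pct < hi_pct <= 100`.
#' @return normalized volume (mask and spacing carried over).
#' @export
normalize_volume <- function(v, lo_pct = 5, hi_pct = 95) {
  stopifnot(inherits(v, "bovw_volume"))
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100)) {
    stop("need 0 <= lo_pct < hi_pct <= 100")
  }
  if (!all(is.finite(v$data))) stop("volume contains non-finite values")
  ml <- mask_logical(v)
  ref <- if (is.null(ml)) as.vector(v$data) else v$data[ml]
  qs <- stats::quantile(ref, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  p_lo <- qs[1]; p_hi <- qs[2]
  if (p_hi <= p_lo) {
    warning("constant region: ", lo_pct, "th and ", hi_pct,
            "th percentiles coincide; returning all-zero volume")
    out <- array(0, dim(v$data))
  } else {
    out <- (pmin(pmax(v$data, p_lo), p_hi) - p_lo) / (p_hi - p_lo)
  }
  new_volume(out, spacing = v$spacing, mask = v$mask, offset = v$offset)
}

#' Crop the subvolume covering one mask label
#'
#' Returns the tight bounding box of `label_id` (optionally padded, clamped
#' to the volume bounds) with the mask reduced to a binary mask of that
#' label. The crop records its origin in `$offset` (0-based voxel offset
#' into the parent), so `crop index + offset` recovers parent coordinates.
#'
#' @param v a [new_volume()] with a label mask.
#' @param label_id positive integer label present in the mask.
#' @param pad non-negative integer padding in voxels on every side.
#' @return cropped [new_volume()].
#' @export
crop_to_label <- function(v, label_id, pad = 0L) {
  stopifnot(inherits(v, "bovw_volume"))
  if (is.null(v$mask)) stop("volume has no mask")
  hit <- which(v$mask == label_id, arr.ind = TRUE)
  if (nrow(hit) == 0) stop("label ", label_id, " not present in mask")
  d <- dim(v$data)
  lo <- pmax(apply(hit, 2, min) - pad, 1L)
  hi <- pmin(apply(hit, 2, max) + pad, d)
  idx <- lapply(1:3, function(k) lo[k]:hi[k])
  sub <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sub_mask <- array(as.integer(v$mask[idx[[1]], idx[[2]], idx[[3]]] == label_id),
                    dim(sub))
  new_volume(sub, spacing = v$spacing, mask = sub_mask,
             offset = v$offset + as.integer(lo) - 1L)
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with one row per image and columns `image_id`,
#' `image_path`, `mask_path` (may be empty), `label` and `channel`; extra
#' columns are preserved.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "image_path", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
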