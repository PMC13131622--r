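# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to the nearest odd integer
#'
#' Patch edge lengths must be odd so a patch has a well-defined center voxel.
#' Exact even integers round up.
#'
#' @param x numeric vector.
#' @return integer vector of odd values, each >= 1.
#' @keywords internal
round_to_odd <- function(x) {
  o <- 2L * as.integer(round((x - 1) / 2)) + 1L
  pmax(o, 1L)
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Wrap angles to [-pi, pi).
wrap_to_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# 0*log(0) := 0, natural log.
plogp <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

# x*log(y) with the 0*log(0) convention (used for cross-entropies).
xlogy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0 & y > 0
  out[pos] <- x[pos] * log(y[pos])
  out
}

l2_normalize <- function(x) {
  n <- sqrt(sum(x^2))
  if (n > 0) x / n else x
}

#' The 24 orientation-preserving axis-aligned grid rotations
#'
#' Each rotation is represented by an axis permutation and per-axis flips
#' acting on (z, y, x) array coordinates; only signed permutations with
#' determinant +1 (proper rotations) are returned. The first element is the
#' identity.
#'
#' @return list of 24 lists with elements `perm` (integer permutation of
#'   1:3) and `flip` (logical length 3, whether each output axis is reversed).
#' @seealso [apply_grid_rotation()]
#' @export
grid_rotations <- function() {
  perms <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  sign_perm <- function(p) if (sum(vapply(seq_along(p), function(i) sum(p[seq_len(i - 1)] > p[i]), 0L)) %% 2L == 0L) 1 else -1
  out <- list()
  for (p in perms) {
    sp <- sign_perm(p)
    for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) for (f3 in c(FALSE, TRUE)) {
      det <- sp * prod(ifelse(c(f1, f2, f3), -1, 1))
      if (det > 0) out[[length(out) + 1L]] <- list(perm = p, flip = c(f1, f2, f3))
    }
  }
  # put the identity first for convenience
  is_id <- vapply(out, function(r) all(r$perm == 1:3) && !any(r$flip), logical(1))
  c(out[is_id], out[!is_id])
}

#' Apply an axis-aligned grid rotation to a 3D array
#'
#' @param a 3D array.
#' @param rot one element of [grid_rotations()].
#' @return rotated 3D array (dimensions permuted accordingly).
#' @export
apply_grid_rotation <- function(a, rot) {
  stopifnot(length(dim(a)) == 3)
  b <- aperm(a, rot$perm)
  idx <- lapply(seq_len(3), function(k) {
    n <- dim(b)[k]
    if (rot$flip[k]) rev(seq_len(n)) else seq_len(n)
  })
  b[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Rotate a cubic 3D array by a small angle with trilinear resampling
#'
#' Rotates about the array center around one coordinate axis. Used to probe
#' descriptor robustness to non-grid rotations; voxels sampled from outside
#' the source grid take the `fill` value.
#'
#' @param a 3D array (any shape).
#' @param angle rotation angle in radians.
#' @param axis 1, 2 or 3: the (z, y, x) axis held fixed.
#' @param fill value for out-of-bounds samples.
#' @return rotated array, same shape.
#' @export
rotate_resample <- function(a, angle, axis = 1L, fill = 0) {
  d <- dim(a)
  stopifnot(length(d) == 3)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3])))
  rel <- sweep(g, 2, ctr)
  mov <- setdiff(1:3, axis)
  ca <- cos(angle); sa <- sin(angle)
  src <- rel
  # inverse rotation of the two moving axes
  src[, mov[1]] <- ca * rel[, mov[1]] + sa * rel[, mov[2]]
  src[, mov[2]] <- -sa * rel[, mov[1]] + ca * rel[, mov[2]]
  src <- sweep(src, 2, ctr, `+`)
  trilinear_sample(a, src, fill = fill)
}

# Sample a 3D array at fractional (z,y,x) coordinates, trilinear weights.
trilinear_sample <- function(a, pts, fill = 0) {
  d <- dim(a)
  f <- floor(pts)
  w <- pts - f
  out <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    iz <- f[, 1] + dz; iy <- f[, 2] + dy; ix <- f[, 3] + dx
    wt <- (if (dz == 1) w[, 1] else 1 - w[, 1]) *
      (if (dy == 1) w[, 2] else 1 - w[, 2]) *
      (if (dx == 1) w[, 3] else 1 - w[, 3])
    ok <- iz >= 1 & iz <= d[1] & iy >= 1 & iy <= d[2] & ix >= 1 & ix <= d[3]
    v <- rep(fill, nrow(pts))
    if (any(ok)) v[ok] <- a[cbind(iz[ok], iy[ok], ix[ok])]
    out <- out + wt * v
  }
  array(out, d)
}
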