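#' Tract parcellation objects
#'
#' A parcellation divides a tract into `n` parcels along its course, either
#' in streamline space (an integer label per streamline point; schemes
#' `"static"` and `"centerline"`) or in voxel space (an integer label grid
#' over the tract envelope; scheme `"voxel"`). Labels run 1..n, with 0 as
#' background in voxel space.
#'
#' @param labels integer 3-D array (voxel scheme) or list of integer vectors
#'   (streamline schemes).
#' @param n parcel count.
#' @param scheme one of `"static"`, `"centerline"`, `"voxel"`.
#' @param points for streamline schemes, the list of point matrices the
#'   labels refer to.
#' @param centerline the [CenterlineModel][compute_centerline] used, if any.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, n, scheme, points = NULL, centerline = NULL) {
  scheme <- match.arg(scheme, c("static", "centerline", "voxel"))
  structure(list(labels = labels, n = as.integer(n), scheme = scheme,
                 points = points, centerline = centerline),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  where <- if (x$scheme == "voxel") "voxel space" else "streamline space"
  cat(sprintf("<parcellation> scheme=%s, n=%d parcels (%s)\n",
              x$scheme, x$n, where))
  invisible(x)
}

#' Resample a streamline to equidistant arc-length steps
#'
#' @param s n x 3 point matrix (a streamline polyline).
#' @param m number of output points (>= 2); endpoints are preserved exactly.
#' @return m x 3 matrix with points at equal arc-length spacing along the
#'   piecewise-linear curve.
#' @export
resample_streamline <- function(s, m) {
  s <- rbind_points(s)
  if (m < 2L) stop("`m` must be >= 2")
  seg <- sqrt(rowSums(diff(s)^2))
  L <- sum(seg)
  if (L <= 0) stop("cannot resample a zero-length streamline")
  cum <- c(0, cumsum(seg))
  target <- seq(0, L, length.out = m)
  out <- vapply(1:3, function(ax) {
    stats::approx(cum, s[, ax], xout = target, ties = "ordered")$y
  }, numeric(m))
  out <- matrix(out, nrow = m)
  out[1, ] <- s[1, ]; out[m, ] <- s[nrow(s), ]
  out
}

#' Reorient streamlines to a common start-to-end direction
#'
#' If a binary start-region mask is supplied, each streamline is flipped so
#' that its endpoint nearer the mask comes first. Otherwise the longest
#' streamline serves as reference and each streamline is flipped if the
#' flipped orientation has a smaller summed point distance to it (both
#' resampled to equal point counts). Exact ties never flip.
#'
#' @param t a [tractogram()].
#' @param start_mask optional binary [scalar_volume()] marking the tract
#'   start region.
#' @param m point count used for the orientation comparison.
#' @return A [tractogram()] with consistently ordered streamlines.
#' @export
reorient_streamlines <- function(t, start_mask = NULL, m = 20L) {
  sls <- t$streamlines
  if (length(sls) == 0L) stop("empty tractogram")
  if (!is.null(start_mask)) {
    idx <- which(start_mask$data > 0, arr.ind = TRUE) - 1
    if (nrow(idx) == 0L) stop("start mask is empty")
    centers <- voxel_to_world(idx, start_mask$affine)
    d_to_mask <- function(p) {
      min(sqrt(colSums((t(centers) - p)^2)))
    }
    sls <- lapply(sls, function(s) {
      if (d_to_mask(s[nrow(s), ]) < d_to_mask(s[1, ])) s[nrow(s):1, ] else s
    })
  } else {
    lens <- vapply(sls, streamline_length, numeric(1))
    ref <- resample_streamline(sls[[which.max(lens)]], m)
    sls <- lapply(sls, function(s) {
      r <- resample_streamline(s, m)
      d_fwd <- sum(sqrt(rowSums((r - ref)^2)))
      d_rev <- sum(sqrt(rowSums((r[m:1, ] - ref)^2)))
      if (d_rev < d_fwd) s[nrow(s):1, ] else s
    })
  }
  tractogram(sls, t$reference)
}

#' Compute the tract centerline
#'
#' The centerline is the pointwise mean of all streamlines after each is
#' resampled to `n` equidistant points. The input should be consistently
#' oriented first ([reorient_streamlines()]).
#'
#' @param t a [tractogram()].
#' @param n number of centerline points (= parcel count downstream).
#' @return n x 3 matrix of ordered centerline points (class
#'   `centerline_model`).
#' @export
compute_centerline <- function(t, n) {
  if (length(t$streamlines) == 0L) stop("empty tractogram")
  acc <- matrix(0, n, 3L)
  for (s in t$streamlines) {
    acc <- acc + if (n == 1L) {
      resample_streamline(s, 3L)[2, , drop = FALSE]  # arc-length midpoint
    } else {
      resample_streamline(s, n)
    }
  }
  cl <- acc / length(t$streamlines)
  structure(cl, class = c("centerline_model", "matrix"))
}

#' Static along-streamline parcel assignment
#'
#' Each streamline is resampled to `n` points and point i (1-based) gets
#' parcel label i: the parcel is given directly by the point's position
#' along the streamline.
#'
#' @param t a [tractogram()].
#' @param n parcel count (>= 1).
#' @return A streamline-space [parcellation()] carrying the resampled points.
#' @export
assign_static <- function(t, n) {
  if (n < 1L) stop("`n` must be >= 1")
  pts <- lapply(t$streamlines, function(s) {
    resample_streamline(s, max(n, 2L))
  })
  labs <- lapply(pts, function(p) {
    if (n == 1L) rep(1L, nrow(p)) else seq_len(n)
  })
  parcellation(labs, n, "static", points = pts)
}

#' Nearest-centerline-point labels for a point set
#'
#' Assigns each point the 1-based index of its nearest centerline point
#' (Euclidean distance in world mm); exact ties break to the lowest index.
#'
#' @param points N x 3 matrix of world-mm points.
#' @param centerline n x 3 centerline point matrix.
#' @return Integer vector of N labels in 1..n.
#' @export
assign_centerline <- function(points, centerline) {
  points <- rbind_points(points)
  centerline <- rbind_points(centerline)
  if (nrow(points) == 0L) stop("empty point set")
  # squared distances via |p|^2 - 2 p.c + |c|^2; lowest index wins ties
  cross <- points %*% t(centerline)
  d2 <- outer(rowSums(points^2), rep(1, nrow(centerline))) - 2 * cross +
    outer(rep(1, nrow(points)), rowSums(centerline^2))
  max.col(-d2, ties.method = "first")
}

#' Centerline-based streamline-space parcellation
#'
#' Streamlines are densely resampled (so assignment density is independent
#' of the on-disk step size) and every point is labeled by its nearest
#' centerline point.
#'
#' @param t a [tractogram()], consistently oriented.
#' @param n parcel count.
#' @param dense_points resampling density for assignment; default
#'   `max(3 * n, 40)`.
#' @param centerline optional precomputed centerline (n x 3).
#' @return A streamline-space [parcellation()].
#' @export
assign_centerline_scheme <- function(t, n, dense_points = NULL,
                                     centerline = NULL) {
  if (is.null(dense_points)) dense_points <- max(3L * n, 40L)
  if (is.null(centerline)) centerline <- compute_centerline(t, n)
  pts <- lapply(t$streamlines, resample_streamline, m = dense_points)
  labs <- lapply(pts, assign_centerline, centerline = centerline)
  parcellation(labs, n, "centerline", points = pts, centerline = centerline)
}

#' Binary tract envelope
#'
#' Marks every voxel traversed by any streamline with 1, then fills small
#' holes with one pass of morphological closing (3x3x3 26-connected
#' structuring element). Traversal is determined by sampling each segment at
#' quarter-voxel arc steps and mapping to the nearest voxel.
#'
#' @param t a [tractogram()].
#' @param reference a [scalar_volume()] giving the grid.
#' @param closing apply the closing pass (default TRUE).
#' @return Logical 3-D array, TRUE inside the envelope.
#' @export
binary_envelope <- function(t, reference, closing = TRUE) {
  if (length(t$streamlines) == 0L) stop("empty tractogram")
  d <- dim(reference$data)
  env <- array(FALSE, d)
  dropped <- 0L
  for (s in t$streamlines) {
    idx <- traversed_voxels(s, reference)
    ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
          idx[, 2] >= 0 & idx[, 2] < d[2] &
          idx[, 3] >= 0 & idx[, 3] < d[3]
    dropped <- dropped + sum(!ok)
    idx <- idx[ok, , drop = FALSE]
    env[idx + 1L] <- TRUE
  }
  if (dropped > 0L)
    warning(dropped, " out-of-bounds streamline sample(s) dropped")
  if (closing) env <- binary_closing(env)
  env
}

# distinct 0-based voxel indices traversed by one streamline: segment
# sampling at quarter-voxel steps, nearest-voxel mapping
traversed_voxels <- function(s, reference) {
  s <- rbind_points(s)
  step <- 0.25 * min(sqrt(colSums(reference$affine[1:3, 1:3]^2)))
  seg <- sqrt(rowSums(diff(s)^2))
  L <- sum(seg)
  n_samp <- max(2L, ceiling(L / step) + 1L)
  dense <- resample_streamline(s, n_samp)
  idx <- world_to_voxel(dense, reference$affine)
  unique(idx)
}

# one closing pass with the full 3x3x3 element; mask padded by one voxel so
# closing is not clipped at the grid boundary
binary_closing <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  dil <- morph_pass(pad, any_op = TRUE)
  ero <- morph_pass(dil, any_op = FALSE)
  ero[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# dilation (any_op) or erosion (!any_op) by the 27-voxel neighborhood,
# outside treated as FALSE
morph_pass <- function(mask, any_op) {
  d <- dim(mask)
  out <- if (any_op) array(FALSE, d) else array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sh <- shift3d(mask, dx, dy, dz)
    out <- if (any_op) out | sh else out & sh
  }
  out
}

# shift array contents by (dx,dy,dz), filling with FALSE
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  off <- c(dx, dy, dz)
  out <- array(FALSE, d)
  rng <- function(ax) {
    lo <- max(1, 1 + off[ax]); hi <- min(d[ax], d[ax] + off[ax])
    if (lo > hi) integer(0) else lo:hi
  }
  sx <- rng(1); sy <- rng(2); sz <- rng(3)
  if (length(sx) && length(sy) && length(sz))
    out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

#' Voxel-space tract parcellation
#'
#' Assigns each voxel of the binary tract envelope to a parcel by the same
#' nearest-centerline-point rule used in centerline tractometry, giving an
#' integer label map ordered start to end.
#'
#' @param t a [tractogram()], consistently oriented
#'   (see [reorient_streamlines()]).
#' @param reference a [scalar_volume()] giving the grid.
#' @param n parcel count.
#' @param centerline optional precomputed centerline (n x 3).
#' @param envelope optional precomputed envelope mask.
#' @return A voxel-space [parcellation()]; `$labels` is an integer array
#'   with 0 outside the envelope.
#' @export
parcellate_voxels <- function(t, reference, n, centerline = NULL,
                              envelope = NULL) {
  if (n < 1L) stop("`n` must be >= 1")
  if (is.null(envelope)) envelope <- binary_envelope(t, reference)
  if (!any(envelope)) stop("empty tract envelope")
  if (is.null(centerline)) centerline <- compute_centerline(t, n)
  idx <- which(envelope, arr.ind = TRUE) - 1L
  centers <- voxel_to_world(idx, reference$affine)
  labs <- assign_centerline(centers, centerline)
  grid <- array(0L, dim(reference$data))
  grid[idx + 1L] <- labs
  parcellation(grid, n, "voxel", centerline = centerline)
}

#' Adaptive parcel count from desired parcel thickness
#'
#' Chooses the parcel count n so that parcels are roughly `v` voxels thick
#' in tract direction: per subject, `n_voxels` is the mean over streamlines
#' of the number of distinct voxels each traverses and n = n_voxels / v. The
#' returned count is the rounded (half-up) mean over up to ten randomly
#' chosen subjects, clamped to >= 1, and is meant to be fixed for the whole
#' cohort.
#'
#' @param tractograms list of [tractogram()]s, one per subject.
#' @param v desired parcel thickness in voxel units (> 0).
#' @param n_subjects how many random subjects to average over (default 10).
#' @param seed RNG seed for the subject draw.
#' @return Integer parcel count with attribute `subjects` (the sampled
#'   indices) and `seed`.
#' @export
adaptive_parcel_count <- function(tractograms, v, n_subjects = 10L,
                                  seed = 0L) {
  if (v <= 0) stop("`v` must be > 0")
  if (length(tractograms) == 0L) stop("no tractograms given")
  k <- min(n_subjects, length(tractograms))
  pick <- if (k == length(tractograms)) seq_len(k) else {
    with_local_seed(seed, sample.int(length(tractograms), k))
  }
  n_vox <- vapply(tractograms[pick], function(t) {
    counts <- vapply(t$streamlines, function(s) {
      nrow(traversed_voxels(s, t$reference))
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  if (all(n_vox == 0)) stop("all tractograms are empty")
  n <- max(1L, as.integer(floor(mean(n_vox / v) + 0.5)))
  structure(n, subjects = pick, seed = seed)
}

# evaluate `expr` under a local RNG seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
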