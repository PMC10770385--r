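#' Radiomics configuration
#'
#' Controls intensity discretization and which feature classes are
#' extracted. The default is a fixed bin *number* per ROI (G = 32 gray
#' levels over the in-mask min..max), which behaves consistently across
#' parameter maps whose scales differ by orders of magnitude (FA in [0,1],
#' diffusivities around 1e-3 mm^2/s). A fixed bin *width* is available for
#' compatibility with absolute-scale protocols.
#'
#' @param bin_count number of gray levels for fixed-bin-number
#'   discretization (ignored when `bin_width` is set).
#' @param bin_width fixed bin width in map units, or `NULL` (default).
#' @param classes feature classes to compute.
#' @param missing_value value reported for features of empty parcels
#'   (default `NA`).
#' @return List of class `radiomics_config`.
#' @export
radiomics_config <- function(bin_count = 32L, bin_width = NULL,
                             classes = c("firstorder", "shape", "glcm",
                                         "glrlm", "glszm", "ngtdm", "gldm"),
                             missing_value = NA_real_) {
  classes <- match.arg(classes, several.ok = TRUE)
  structure(list(bin_count = as.integer(bin_count), bin_width = bin_width,
                 classes = classes, missing_value = missing_value),
            class = "radiomics_config")
}

#' Read a radiomics configuration from a YAML file
#'
#' Recognized keys: `bin_count`, `bin_width`, `classes`, `missing_value`.
#'
#' @param path YAML file path.
#' @return A [radiomics_config()].
#' @export
read_radiomics_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- radiomics_config()
  for (k in intersect(names(y), c("bin_count", "bin_width", "classes",
                                  "missing_value"))) cfg[[k]] <- y[[k]]
  cfg$bin_count <- as.integer(cfg$bin_count)
  cfg
}

#' Discretize ROI intensities to integer gray levels
#'
#' Fixed-bin-number: G equal-width bins spanning the in-mask min..max
#' (constant ROI collapses to a single level, G = 1). Fixed-bin-width w:
#' level = floor(x / w) - floor(min / w) + 1.
#'
#' @param values numeric vector or array of in-mask intensities (`NA`
#'   outside the mask).
#' @param bin_count number of levels G for fixed-bin-number binning.
#' @param bin_width bin width; overrides `bin_count` when non-`NULL`.
#' @return List with `levels` (same shape as `values`, integer 1..G, `NA`
#'   outside), `G`, and `binning` descriptor.
#' @export
discretize <- function(values, bin_count = 32L, bin_width = NULL) {
  v <- values
  inm <- !is.na(v)
  if (!any(inm)) stop("empty ROI")
  x <- v[inm]
  if (!all(is.finite(x))) stop("ROI values must be finite")
  if (!is.null(bin_width)) {
    lev_in <- floor(x / bin_width) - floor(min(x) / bin_width) + 1
    G <- max(lev_in)
    binning <- sprintf("fixed_bin_width=%g", bin_width)
  } else {
    rng <- max(x) - min(x)
    if (rng <= 0) {
      lev_in <- rep(1, length(x)); G <- 1L
    } else {
      w <- rng / bin_count
      lev_in <- pmin(floor((x - min(x)) / w) + 1, bin_count)
      G <- as.integer(bin_count)
    }
    binning <- sprintf("fixed_bin_count=%d", bin_count)
  }
  lev <- v
  lev[inm] <- lev_in
  list(levels = lev, G = as.integer(G), binning = binning)
}

#' First-order intensity statistics (18 features)
#'
#' Computed on the raw in-mask intensities; Entropy and Uniformity use the
#' discretized histogram. Conventions: population moments; Kurtosis is not
#' excess-corrected; a constant ROI has Skewness = Kurtosis = 0;
#' percentiles use linear interpolation.
#'
#' @param values numeric vector of in-mask intensities.
#' @param spacing per-axis voxel size in mm (for TotalEnergy).
#' @param levels optional discretized levels matching `values` (defaults to
#'   [discretize()] with `bin_count`).
#' @param bin_count gray levels used if `levels` is missing.
#' @return Named numeric vector of the 18 first-order features.
#' @export
firstorder_features <- function(values, spacing = c(1, 1, 1), levels = NULL,
                                bin_count = 32L) {
  x <- values[!is.na(values)]
  if (length(x) == 0L) stop("empty ROI")
  if (is.null(levels)) {
    levels <- discretize(x, bin_count = bin_count)$levels
  } else {
    levels <- levels[!is.na(levels)]
  }
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p <- tabulate(levels) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = prod(spacing) * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

# ---- shape -----------------------------------------------------------------

#' Shape features of a binary mask (14 features)
#'
#' Surface area and mesh volume come from an isosurface triangulation of
#' the padded mask (marching tetrahedra on its lightly smoothed signed
#' Euclidean distance field; see the methods vignette). Axis lengths
#' are 4*sqrt(eigenvalue) of the physical-coordinate covariance of voxel
#' centers. Diameters are largest pairwise distances between the corners of
#' surface voxels (Maximum3DDiameter; the 2-D variants restrict to
#' fixed-z / fixed-x / fixed-y voxel planes).
#'
#' @param mask logical 3-D array.
#' @param spacing per-axis voxel size in mm.
#' @return Named numeric vector of the 14 shape features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- mask > 0
  nv <- sum(mask)
  if (nv == 0L) stop("empty mask")
  mesh <- mask_mesh(mask, spacing)
  A <- mesh$area
  V <- mesh$volume
  idx <- which(mask, arr.ind = TRUE) - 1
  phys <- sweep(idx, 2, spacing, "*")
  if (nv > 1L) {
    cm <- stats::cov(phys) * (nv - 1) / nv
    ev <- sort(pmax(eigen(cm, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  corners <- surface_voxel_corners(mask, spacing)
  d3 <- max_pairwise_distance(corners$pts)
  d2 <- vapply(1:3, function(ax) {
    planes <- split.data.frame(corners$pts, corners$plane[, ax])
    max(vapply(planes, function(p) {
      max_pairwise_distance(p[, -ax, drop = FALSE])
    }, numeric(1)))
  }, numeric(1))
  sphericity <- if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0
  c(MeshVolume = V,
    VoxelVolume = nv * prod(spacing),
    SurfaceArea = A,
    SurfaceVolumeRatio = if (V > 0) A / V else Inf,
    Sphericity = sphericity,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2[3],   # in-plane xy, per z plane
    Maximum2DDiameterColumn = d2[1],  # in-plane yz, per x plane
    Maximum2DDiameterRow = d2[2],     # in-plane xz, per y plane
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

# corners of voxels that touch the background (surface voxels)
surface_voxel_corners <- function(mask, spacing) {
  interior <- morph_pass(mask, any_op = FALSE)
  surf <- which(mask & !interior, arr.ind = TRUE) - 1
  if (nrow(surf) == 0L) surf <- which(mask, arr.ind = TRUE) - 1
  offs <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  pts <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    sweep(sweep(surf, 2, offs[i, ], "+"), 2, spacing, "*")
  }))
  plane <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    surf  # voxel index identifies the plane membership per axis
  }))
  list(pts = pts, plane = plane)
}

# exact largest pairwise Euclidean distance, chunked to bound memory
max_pairwise_distance <- function(p) {
  p <- unique(as.matrix(p))
  n <- nrow(p)
  if (n < 2L) return(0)
  sq <- rowSums(p^2)
  best <- 0
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(sq[s:e], sq, "+") - 2 * p[s:e, , drop = FALSE] %*% t(p)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# 1-D squared Euclidean distance transform (lower envelope of parabolas)
dt1_squared <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# squared distance (in voxels) to the nearest TRUE voxel center
edt_squared <- function(mask) {
  d <- dim(mask)
  f <- array(ifelse(mask, 0, 1e12), d)
  for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    f[, i, j] <- dt1_squared(f[, i, j])
  for (i in seq_len(d[1])) for (j in seq_len(d[3]))
    f[i, , j] <- dt1_squared(f[i, , j])
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    f[i, j, ] <- dt1_squared(f[i, j, ])
  f
}

# isosurface of the mask via marching tetrahedra on the signed Euclidean
# distance field (zero level sits halfway between adjacent inside/outside
# voxel centers). A light Gaussian smoothing of the distance field removes
# the residual voxel staircase so areas/volumes of smooth shapes approach
# their analytic values; masks too small to survive smoothing fall back to
# the raw distance field. Returns surface area and the exact volume
# enclosed by the piecewise-linear surface.
mask_mesh <- function(mask, spacing, smooth_sigma = 0.6) {
  d <- dim(mask)
  m <- max(2L, ceiling(3 * smooth_sigma) + 1L)
  pd <- d + 2L * m
  pad <- array(FALSE, pd)
  pad[(m + 1):(d[1] + m), (m + 1):(d[2] + m), (m + 1):(d[3] + m)] <- mask
  field <- sqrt(edt_squared(!pad)) - sqrt(edt_squared(pad))
  if (smooth_sigma > 0) {
    res <- mesh_from_field(gauss_smooth3(field, smooth_sigma), spacing)
    if (res$area > 0) return(res)
  }
  mesh_from_field(field, spacing)
}

mesh_from_field <- function(field, spacing) {
  pd <- dim(field)
  nc <- pd - 1L
  co <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  # 6-tetrahedra decomposition of each cell along the main diagonal 1-8
  tets <- matrix(c(1, 2, 4, 8,
                   1, 4, 3, 8,
                   1, 3, 7, 8,
                   1, 7, 5, 8,
                   1, 5, 6, 8,
                   1, 6, 2, 8), ncol = 4, byrow = TRUE)
  cx <- seq_len(nc[1]); cy <- seq_len(nc[2]); cz <- seq_len(nc[3])
  fvals <- lapply(seq_len(8), function(k) {
    field[cx + co[k, 1], cy + co[k, 2], cz + co[k, 3]]
  })
  pos <- lapply(fvals, function(f) f > 0)
  s <- Reduce(`+`, pos)
  mixed <- which(s > 0 & s < 8)
  cellvol <- prod(spacing)
  tetvol <- cellvol / 6
  volume <- sum(s == 8) * cellvol
  area <- 0
  if (length(mixed)) {
    ci <- arrayInd(mixed, nc) - 1L
    fm <- vapply(seq_len(8), function(k) fvals[[k]][mixed],
                 numeric(length(mixed)))
    if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1L)
    for (tt in seq_len(6)) {
      vidx <- tets[tt, ]
      ft <- fm[, vidx, drop = FALSE]
      ins <- ft > 0
      cnt <- rowSums(ins)
      volume <- volume + sum(cnt == 4) * tetvol
      act <- which(cnt > 0 & cnt < 4)
      if (!length(act)) next
      vc <- lapply(vidx, function(k) {
        sweep(sweep(ci[act, , drop = FALSE], 2, co[k, ], "+"), 2, spacing,
              "*")
      })
      res <- tet_clip(vc, ft[act, , drop = FALSE], tetvol)
      area <- area + res$area
      volume <- volume + res$volume
    }
  }
  list(area = area, volume = volume)
}

# area and inside-volume contributions of tets crossed by the zero level;
# vc = list of 4 corner-coordinate matrices, fv = corner field values
tet_clip <- function(vc, fv, tetvol) {
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    0.5 * sqrt(rowSums(n^2))
  }
  tet_vol <- function(a, b, c, d) {
    u <- b - a; v <- c - a; w <- d - a
    abs(u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
        u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
        u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
  # crossing point on edge a->b at the zero level
  xp <- function(ia, ib, rows) {
    t <- fv[rows, ia] / (fv[rows, ia] - fv[rows, ib])
    vc[[ia]][rows, , drop = FALSE] * (1 - t) +
      vc[[ib]][rows, , drop = FALSE] * t
  }
  ins <- fv > 0
  pat <- as.integer(ins[, 1] + 2 * ins[, 2] + 4 * ins[, 3] + 8 * ins[, 4])
  area <- 0; volume <- 0
  for (pp in unique(pat)) {
    rows <- which(pat == pp)
    ivs <- which(as.logical(bitwAnd(pp, c(1L, 2L, 4L, 8L))))
    ovs <- setdiff(1:4, ivs)
    if (length(ivs) == 1L) {
      a <- ivs; tfrac <- rep(1, length(rows))
      for (o in ovs) tfrac <- tfrac * fv[rows, a] / (fv[rows, a] - fv[rows, o])
      p1 <- xp(a, ovs[1], rows); p2 <- xp(a, ovs[2], rows)
      p3 <- xp(a, ovs[3], rows)
      area <- area + sum(tri_area(p1, p2, p3))
      volume <- volume + sum(tfrac) * tetvol
    } else if (length(ivs) == 3L) {
      o <- ovs; tfrac <- rep(1, length(rows))
      for (a in ivs) tfrac <- tfrac * fv[rows, o] / (fv[rows, o] - fv[rows, a])
      p1 <- xp(o, ivs[1], rows); p2 <- xp(o, ivs[2], rows)
      p3 <- xp(o, ivs[3], rows)
      area <- area + sum(tri_area(p1, p2, p3))
      volume <- volume + sum(1 - tfrac) * tetvol
    } else if (length(ivs) == 2L) {
      a <- ivs[1]; b <- ivs[2]; c <- ovs[1]; dd <- ovs[2]
      pac <- xp(a, c, rows); pad_ <- xp(a, dd, rows)
      pbc <- xp(b, c, rows); pbd <- xp(b, dd, rows)
      area <- area + sum(tri_area(pac, pad_, pbd)) +
        sum(tri_area(pac, pbd, pbc))
      va <- vc[[a]][rows, , drop = FALSE]
      vb <- vc[[b]][rows, , drop = FALSE]
      # wedge (a, b, pac, pad, pbc, pbd) split into three tets
      volume <- volume + sum(tet_vol(va, pac, pad_, vb)) +
        sum(tet_vol(vb, pac, pad_, pbd)) +
        sum(tet_vol(vb, pac, pbd, pbc))
    }
  }
  list(area = area, volume = volume)
}

# ---- texture matrices ------------------------------------------------------

# the 13 unique 3-D direction offsets (distance-1 neighborhood, up to sign)
texture_directions <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,
           1, 0, 1,  1, 0, -1,
           0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

# all 26 neighbor offsets
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# shift a 3-D array by an offset, filling with NA
shift_na <- function(a, off) {
  d <- dim(a)
  out <- array(NA_real_, d)
  rng <- function(ax) {
    lo <- max(1, 1 + off[ax]); hi <- min(d[ax], d[ax] + off[ax])
    if (lo > hi) integer(0) else lo:hi
  }
  sx <- rng(1); sy <- rng(2); sz <- rng(3)
  if (length(sx) && length(sy) && length(sz))
    out[sx, sy, sz] <- a[sx - off[1], sy - off[2], sz - off[3]]
  out
}

#' Gray-level co-occurrence matrices
#'
#' Symmetric co-occurrence counts at distance 1 for each of the 13 unique
#' 3-D directions, normalized to probabilities.
#'
#' @param lev 3-D array of gray levels (`NA` outside the ROI).
#' @param G number of gray levels.
#' @return List of up to 13 G x G probability matrices (directions without
#'   any valid pair are dropped).
#' @export
glcm_matrices <- function(lev, G) {
  dirs <- texture_directions()
  out <- list()
  for (k in seq_len(nrow(dirs))) {
    b <- shift_na(lev, dirs[k, ])
    ok <- !is.na(lev) & !is.na(b)
    if (!any(ok)) next
    i <- lev[ok]; j <- b[ok]
    cnt <- matrix(tabulate((i - 1) * G + j, nbins = G * G), G, G,
                  byrow = TRUE)
    P <- cnt + t(cnt)
    out[[length(out) + 1L]] <- P / sum(P)
  }
  out
}

# static per-G index structures for GLCM features, memoized
glcm_grid_cache <- new.env(parent = emptyenv())
glcm_grid <- function(G) {
  key <- as.character(G)
  got <- glcm_grid_cache[[key]]
  if (!is.null(got)) return(got)
  i <- matrix(rep(1:G, G), G, G)
  j <- t(i)
  out <- list(i = i, j = j,
              gd = as.vector(abs(i - j)) + 1L,  # groups 1..G
              gs = as.vector(i + j) - 1L)       # groups 1..2G-1
  glcm_grid_cache[[key]] <- out
  out
}

glcm_features_one <- function(p) {
  G <- nrow(p)
  grid <- glcm_grid(G)
  i <- grid$i; j <- grid$j
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  # diagonal / cross-diagonal distributions
  k_diff <- 0:(G - 1)
  pdiff <- as.vector(rowsum(as.vector(p), grid$gd))
  k_sum <- 2:(2 * G)
  psum <- as.vector(rowsum(as.vector(p), grid$gs))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HX <- ent(px)
  HXY <- ent(p)
  lg <- function(q) ifelse(q > 0, log2(q), 0)
  pxi <- px[row(p)]; pyj <- px[col(p)]
  HXY1 <- -sum(p * lg(pxi * pyj))
  HXY2 <- -sum(pxi * pyj * lg(pxi * pyj))
  da <- sum(k_diff * pdiff)
  autoc <- sum(i * j * p)
  corr <- if (sig2 > 0) (autoc - mu^2) / sig2 else 1
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  off <- i != j
  c(Autocorrelation = autoc,
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pdiff),
    DifferenceVariance = sum((k_diff - da)^2 * pdiff),
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / G)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / G)),
    InverseVariance = sum(p[off] / (i[off] - j[off])^2),
    MaximumProbability = max(p),
    SumEntropy = ent(psum),
    SumSquares = sig2)
}

#' GLCM features (22), averaged over the 13 directions
#'
#' @inheritParams glcm_matrices
#' @return Named numeric vector of 22 features; all 0 when no direction has
#'   a valid voxel pair.
#' @export
glcm_features <- function(lev, G) {
  mats <- glcm_matrices(lev, G)
  if (length(mats) == 0L) {
    warning("no valid voxel pairs for GLCM; features default to 0")
    f <- glcm_features_one(matrix(1, 1, 1)) * 0
    return(f)
  }
  rowMeans(vapply(mats, glcm_features_one,
                  numeric(length(glcm_feature_names()))))
}

glcm_feature_names <- function() {
  c("Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
    "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
    "MaximumProbability", "SumEntropy", "SumSquares")
}

#' Gray-level run-length matrices
#'
#' Counts maximal runs of equal gray level along each of the 13 directions.
#'
#' @inheritParams glcm_matrices
#' @return List of matrices (rows = gray level 1..G, cols = run length).
#' @export
glrlm_matrices <- function(lev, G) {
  d <- dim(lev)
  idx <- arrayInd(seq_along(lev), d)
  dirs <- texture_directions()
  out <- list()
  for (k in seq_len(nrow(dirs))) {
    dk <- dirs[k, ]
    ax <- which(dk != 0)[1]
    t_pos <- idx[, ax] * sign(dk[ax])
    line <- idx - outer(t_pos, dk)
    K <- sum(d) + 3  # exceeds any per-axis span of the line intercepts
    line_id <- line[, 1] + K * (line[, 2] + K * line[, 3])
    ord <- order(line_id, t_pos)
    lv <- as.vector(lev)[ord]
    li <- line_id[ord]
    newrun <- c(TRUE, diff(li) != 0 | diff(lv) != 0 | is.na(lv[-1]) |
                  is.na(lv[-length(lv)]))
    newrun[is.na(newrun)] <- TRUE
    grp <- cumsum(newrun)
    keep <- !is.na(lv)
    if (!any(keep)) next
    gk <- grp[keep]  # nondecreasing, so rle gives runs in appearance order
    len_of_run <- rle(gk)$lengths
    lev_of_run <- lv[keep][!duplicated(gk)]
    Lmax <- max(len_of_run)
    R <- matrix(tabulate((lev_of_run - 1L) * Lmax + len_of_run,
                         nbins = G * Lmax), G, Lmax, byrow = TRUE)
    out[[length(out) + 1L]] <- R
  }
  out
}

rl_features_one <- function(R, Np, type = c("run", "zone")) {
  type <- match.arg(type)
  Nr <- sum(R)
  g <- seq_len(nrow(R)); l <- seq_len(ncol(R))
  gm <- matrix(g, nrow(R), ncol(R))
  lm <- matrix(l, nrow(R), ncol(R), byrow = TRUE)
  p <- R / Nr
  mug <- sum(gm * p); mul <- sum(lm * p)
  ent_p <- { q <- p[p > 0]; -sum(q * log2(q)) }
  vals <- c(sum(R / lm^2) / Nr,                 # short emphasis
            sum(R * lm^2) / Nr,                 # long emphasis
            sum(rowSums(R)^2) / Nr,             # gray-level non-uniformity
            sum(rowSums(R)^2) / Nr^2,           # ... normalized
            sum(colSums(R)^2) / Nr,             # length non-uniformity
            sum(colSums(R)^2) / Nr^2,           # ... normalized
            Nr / Np,                            # percentage
            sum((gm - mug)^2 * p),              # gray-level variance
            sum((lm - mul)^2 * p),              # length variance
            ent_p,                              # entropy
            sum(R / gm^2) / Nr,                 # low gray-level emphasis
            sum(R * gm^2) / Nr,                 # high gray-level emphasis
            sum(R / (gm^2 * lm^2)) / Nr,
            sum(R * gm^2 / lm^2) / Nr,
            sum(R * lm^2 / gm^2) / Nr,
            sum(R * gm^2 * lm^2) / Nr)
  names(vals) <- if (type == "run") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  }
  vals
}

#' GLRLM features (16), averaged over the 13 directions
#'
#' @inheritParams glcm_matrices
#' @return Named numeric vector of 16 run-length features.
#' @export
glrlm_features <- function(lev, G) {
  Np <- sum(!is.na(lev))
  mats <- glrlm_matrices(lev, G)
  if (length(mats) == 0L) {
    warning("no valid runs for GLRLM; features default to 0")
    return(rl_features_one(matrix(1, 1, 1), 1, "run") * 0)
  }
  rowMeans(vapply(mats, rl_features_one, numeric(16L), Np = Np,
                  type = "run"))
}

#' Gray-level size-zone matrix
#'
#' Single matrix of 26-connected equal-level zones: entry (g, s) counts the
#' zones of gray level g and size s voxels.
#'
#' @inheritParams glcm_matrices
#' @return Matrix (rows = gray level, cols = zone size).
#' @export
glszm_matrix <- function(lev, G) {
  d <- dim(lev)
  inm <- which(!is.na(lev))
  if (length(inm) == 0L) stop("empty ROI")
  vid <- integer(length(lev)); vid[inm] <- seq_along(inm)
  edges <- NULL
  for (k in seq_len(nrow(texture_directions()))) {
    off <- texture_directions()[k, ]
    b <- shift_na(lev, off)
    same <- !is.na(lev) & !is.na(b) & lev == b
    if (!any(same)) next
    w <- which(same)
    src <- arrayInd(w, d)
    nb <- sweep(src, 2, off, "-")
    wn <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    edges <- rbind(edges, cbind(vid[w], vid[wn]))
  }
  g <- igraph::make_empty_graph(n = length(inm), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  memb <- comp$membership
  zone_level <- lev[inm][match(seq_len(comp$no), memb)]
  zone_size <- comp$csize
  Smax <- max(zone_size)
  matrix(tabulate((zone_level - 1L) * Smax + zone_size, nbins = G * Smax),
         G, Smax, byrow = TRUE)
}

#' GLSZM features (16)
#'
#' @inheritParams glcm_matrices
#' @return Named numeric vector of 16 size-zone features.
#' @export
glszm_features <- function(lev, G) {
  Np <- sum(!is.na(lev))
  S <- glszm_matrix(lev, G)
  rl_features_one(S, Np, "zone")
}

#' Neighbouring gray-tone difference features (5)
#'
#' For each gray level i: n_i voxels of level i that have at least one
#' in-ROI neighbor (26-neighborhood), and s_i the summed absolute
#' difference between the level and the mean level of the valid neighbors.
#'
#' @inheritParams glcm_matrices
#' @return Named numeric vector: Coarseness, Contrast, Busyness,
#'   Complexity, Strength. Coarseness is capped at 1e6 for flat ROIs.
#' @export
ngtdm_features <- function(lev, G) {
  tab <- ngtdm_table(lev, G)
  n_i <- tab$n; s_i <- tab$s
  Nvp <- sum(n_i)
  if (Nvp == 0) {
    warning("no voxel with valid neighbors for NGTDM; features default to 0")
    return(c(Coarseness = 0, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  }
  p_i <- n_i / Nvp
  act <- which(p_i > 0)
  Ngp <- length(act)
  i <- seq_len(G)
  denom_coarse <- sum(p_i * s_i)
  coars <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  coars <- min(coars, 1e6)
  if (Ngp > 1) {
    pij <- outer(p_i[act], p_i[act])
    dij2 <- outer(i[act], i[act], "-")^2
    contrast <- sum(pij * dij2) / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp
  } else contrast <- 0
  ipi <- i[act] * p_i[act]
  denom_busy <- sum(abs(outer(ipi, ipi, "-")))
  busy <- if (denom_busy > 0) denom_coarse / denom_busy else 0
  comp <- 0; strength <- 0
  if (Ngp > 1) {
    for (a in act) for (b in act) {
      if (a == b) next
      comp <- comp + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
      strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
    }
    comp <- comp / Nvp
    strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  }
  c(Coarseness = coars, Contrast = contrast, Busyness = busy,
    Complexity = comp, Strength = strength)
}

ngtdm_table <- function(lev, G) {
  offs <- neighbor_offsets_26()
  nb_sum <- array(0, dim(lev)); nb_cnt <- array(0, dim(lev))
  for (k in seq_len(nrow(offs))) {
    b <- shift_na(lev, offs[k, ])
    valid <- !is.na(b)
    nb_sum[valid] <- nb_sum[valid] + b[valid]
    nb_cnt <- nb_cnt + valid
  }
  ok <- !is.na(lev) & nb_cnt > 0
  abar <- nb_sum[ok] / nb_cnt[ok]
  li <- lev[ok]
  n <- tabulate(li, nbins = G)
  s <- vapply(seq_len(G), function(g) sum(abs(li - abar)[li == g]),
              numeric(1))
  list(n = n, s = s)
}

#' Gray-level dependence matrix features (14)
#'
#' The dependence of a voxel is the number of its 26-neighborhood in-ROI
#' neighbors with the same gray level (similarity tolerance alpha = 0). The
#' matrix counts (gray level, dependence) pairs; dependence-size formulas
#' use j = dependence + 1 so that isolated voxels occupy column 1.
#'
#' @inheritParams glcm_matrices
#' @return Named numeric vector of 14 dependence features.
#' @export
gldm_features <- function(lev, G) {
  P <- gldm_matrix(lev, G)
  Nz <- sum(P)
  g <- seq_len(nrow(P)); j <- seq_len(ncol(P))
  gm <- matrix(g, nrow(P), ncol(P))
  jm <- matrix(j, nrow(P), ncol(P), byrow = TRUE)
  p <- P / Nz
  mug <- sum(gm * p); muj <- sum(jm * p)
  entp <- { q <- p[p > 0]; -sum(q * log2(q)) }
  c(SmallDependenceEmphasis = sum(P / jm^2) / Nz,
    LargeDependenceEmphasis = sum(P * jm^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    GrayLevelVariance = sum((gm - mug)^2 * p),
    DependenceVariance = sum((jm - muj)^2 * p),
    DependenceEntropy = entp,
    LowGrayLevelEmphasis = sum(P / gm^2) / Nz,
    HighGrayLevelEmphasis = sum(P * gm^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (gm^2 * jm^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * gm^2 / jm^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jm^2 / gm^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * gm^2 * jm^2) / Nz)
}

gldm_matrix <- function(lev, G) {
  offs <- neighbor_offsets_26()
  dep <- array(0, dim(lev))
  for (k in seq_len(nrow(offs))) {
    b <- shift_na(lev, offs[k, ])
    same <- !is.na(lev) & !is.na(b) & lev == b
    dep <- dep + same
  }
  inm <- !is.na(lev)
  d_in <- dep[inm]; l_in <- lev[inm]
  Dmax <- max(d_in) + 1L
  matrix(tabulate((l_in - 1L) * Dmax + d_in + 1L, nbins = G * Dmax),
         G, Dmax, byrow = TRUE)
}

# ---- per-parcel extraction -------------------------------------------------

#' All 105 radiomics features for one ROI
#'
#' 18 first-order + 14 shape + 73 texture (GLCM 22, GLRLM 16, GLSZM 16,
#' NGTDM 5, GLDM 14).
#'
#' @param values 3-D array of map intensities with `NA` outside the ROI.
#' @param mask logical 3-D array (the ROI).
#' @param spacing voxel size in mm.
#' @param cfg a [radiomics_config()].
#' @param shape optional precomputed [shape_features()] for this mask
#'   (geometry is map-independent, so callers reuse it across maps).
#' @return Named numeric vector, names `{class}__{feature}`.
#' @export
parcel_features <- function(values, mask, spacing = c(1, 1, 1),
                            cfg = radiomics_config(), shape = NULL) {
  disc <- discretize(values, bin_count = cfg$bin_count,
                     bin_width = cfg$bin_width)
  lev <- disc$levels
  G <- disc$G
  x <- values[mask]
  out <- list()
  if ("firstorder" %in% cfg$classes)
    out$firstorder <- firstorder_features(x, spacing, levels = lev[mask])
  if ("shape" %in% cfg$classes)
    out$shape <- if (is.null(shape)) shape_features(mask, spacing) else shape
  if ("glcm" %in% cfg$classes) out$glcm <- glcm_features(lev, G)
  if ("glrlm" %in% cfg$classes) out$glrlm <- glrlm_features(lev, G)
  if ("glszm" %in% cfg$classes) out$glszm <- glszm_features(lev, G)
  if ("ngtdm" %in% cfg$classes) out$ngtdm <- ngtdm_features(lev, G)
  if ("gldm" %in% cfg$classes) out$gldm <- gldm_features(lev, G)
  unlist(lapply(names(out), function(cl) {
    v <- out[[cl]]
    names(v) <- paste0(cl, "__", names(v))
    v
  }))
}

#' Radiomic tract features for all parcels and parameter maps
#'
#' The radiomic-tractometry feature vector: for every parcel of a
#' voxel-space parcellation and every parameter map, the full 105-feature
#' set, named `{map}__parcel{i:03d}__{class}__{feature}`. Four maps and n
#' parcels give 4 * 105 * n features. Shape features are computed once per
#' parcel and shared across maps. Empty parcels yield the configured
#' missing value (default `NA`) with a warning.
#'
#' @param parc a voxel-space [parcellation()].
#' @param maps named list of [scalar_volume()]s sharing the parcellation
#'   grid.
#' @param cfg a [radiomics_config()].
#' @return Named numeric vector of length `length(maps) * 105 * n` (for the
#'   default full class set).
#' @export
extract_tract_features <- function(parc, maps, cfg = radiomics_config()) {
  if (!inherits(parc, "parcellation") || parc$scheme != "voxel")
    stop("`parc` must be a voxel-space parcellation")
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    stop("`maps` must be a named list")
  labels <- parc$labels
  n <- parc$n
  for (m in maps) {
    if (!all(dim(m$data) == dim(labels)))
      stop("map geometry does not match parcellation")
  }
  spacing <- maps[[1]]$spacing
  # crop each parcel to its bounding box once
  rois <- lapply(seq_len(n), function(i) {
    w <- which(labels == i, arr.ind = TRUE)
    if (nrow(w) == 0L) return(NULL)
    rng <- lapply(1:3, function(ax) range(w[, ax]))
    list(rng = rng,
         mask = labels[rng[[1]][1]:rng[[1]][2],
                       rng[[2]][1]:rng[[2]][2],
                       rng[[3]][1]:rng[[3]][2], drop = FALSE] == i)
  })
  shapes <- lapply(rois, function(r) {
    if (is.null(r)) NULL else shape_features(r$mask, spacing)
  })
  template <- NULL
  out <- list()
  for (mname in names(maps)) {
    mdata <- maps[[mname]]$data
    for (i in seq_len(n)) {
      r <- rois[[i]]
      if (is.null(r)) {
        if (is.null(template))
          stop("cannot size features: first parcel of first map is empty")
        v <- rep(cfg$missing_value, length(template))
        names(v) <- template
        warning("parcel ", i, " is empty; features set to missing value")
      } else {
        vals <- mdata[r$rng[[1]][1]:r$rng[[1]][2],
                      r$rng[[2]][1]:r$rng[[2]][2],
                      r$rng[[3]][1]:r$rng[[3]][2], drop = FALSE]
        vals <- array(vals, dim = dim(r$mask))
        vals[!r$mask] <- NA_real_
        v <- parcel_features(vals, r$mask, spacing, cfg,
                             shape = shapes[[i]])
        if (is.null(template)) template <- names(v)
      }
      names(v) <- sprintf("%s__parcel%03d__%s", mname, i, names(v))
      out[[length(out) + 1L]] <- v
    }
  }
  unlist(out)
}
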