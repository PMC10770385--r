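# Independent brute-force oracles: deliberately naive implementations
# (explicit loops, no shared code with the package internals) used to
# verify matrices, labelings and feature formulas on small inputs.

# all 26 neighbor offsets / the 13 unique directions, re-derived here
oracle_dirs26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
oracle_dirs13 <- function() {
  g <- oracle_dirs26()
  keep <- apply(g, 1, function(d) {
    d[1] > 0 || (d[1] == 0 && d[2] > 0) || (d[1] == 0 && d[2] == 0 && d[3] > 0)
  })
  g[keep, , drop = FALSE]
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# GLCM: symmetric pair tally for one direction, probability-normalized
oracle_glcm <- function(lev, G, dir) {
  d <- dim(lev)
  P <- matrix(0, G, G)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + dir
    if (!in_grid(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# GLRLM: maximal same-level runs along one direction
oracle_glrlm <- function(lev, G, dir) {
  d <- dim(lev)
  counted <- array(FALSE, d)
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a) || counted[x, y, z]) next
    # only start a run if the previous voxel along -dir does not continue it
    p <- c(x, y, z) - dir
    if (in_grid(p, d) && !is.na(lev[p[1], p[2], p[3]]) &&
        lev[p[1], p[2], p[3]] == a) next
    len <- 0L
    q <- c(x, y, z)
    while (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
           lev[q[1], q[2], q[3]] == a) {
      counted[q[1], q[2], q[3]] <- TRUE
      len <- len + 1L
      q <- q + dir
    }
    runs[[length(runs) + 1L]] <- c(a, len)
  }
  if (!length(runs)) return(NULL)
  rn <- do.call(rbind, runs)
  R <- matrix(0, G, max(rn[, 2]))
  for (k in seq_len(nrow(rn))) R[rn[k, 1], rn[k, 2]] <- R[rn[k, 1], rn[k, 2]] + 1
  R
}

# GLSZM: 26-connected equal-level zones via BFS flood fill
oracle_glszm <- function(lev, G) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- oracle_dirs26()
  zones <- list()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    g <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (!in_grid(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- lev[q[1], q[2], q[3]]
        if (!is.na(v) && v == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  zn <- do.call(rbind, zones)
  S <- matrix(0, G, max(zn[, 2]))
  for (k in seq_len(nrow(zn))) S[zn[k, 1], zn[k, 2]] <- S[zn[k, 1], zn[k, 2]] + 1
  S
}

# NGTDM: per-level counts n_i and summed |level - mean(valid neighbors)|
oracle_ngtdm <- function(lev, G) {
  d <- dim(lev)
  offs <- oracle_dirs26()
  n <- numeric(G); s <- numeric(G)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (!in_grid(q, d)) next
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v)) nb <- c(nb, v)
    }
    if (!length(nb)) next
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(n = n, s = s)
}

# GLDM: per-voxel count of equal-level neighbors (alpha = 0)
oracle_gldm <- function(lev, G) {
  d <- dim(lev)
  offs <- oracle_dirs26()
  recs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    dep <- 0L
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (!in_grid(q, d)) next
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v) && v == a) dep <- dep + 1L
    }
    recs[[length(recs) + 1L]] <- c(a, dep)
  }
  rn <- do.call(rbind, recs)
  P <- matrix(0, G, max(rn[, 2]) + 1L)
  for (k in seq_len(nrow(rn))) P[rn[k, 1], rn[k, 2] + 1L] <-
      P[rn[k, 1], rn[k, 2] + 1L] + 1
  P
}

# first-order statistics, direct textbook formulas
oracle_firstorder <- function(x, spacing, levels) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  h <- table(factor(levels, levels = sort(unique(levels))))
  pr <- as.numeric(h) / n
  qs <- stats::quantile(x, c(.1, .25, .75, .9), type = 7, names = FALSE)
  inner <- x[x >= qs[1] & x <= qs[4]]
  c(Energy = sum(x^2),
    TotalEnergy = prod(spacing) * sum(x^2),
    Entropy = -sum(pr * log2(pr)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = qs[3] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(inner - mean(inner))) /
      length(inner),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pr^2))
}

# one binary closing pass with the 3x3x3 element, naive triple loop on a
# zero-padded copy
oracle_closing <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  dil <- array(FALSE, dim(pad))
  for (x in seq_len(dim(pad)[1])) for (y in seq_len(dim(pad)[2]))
    for (z in seq_len(dim(pad)[3])) {
      hit <- FALSE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        q <- c(x + dx, y + dy, z + dz)
        if (in_grid(q, dim(pad)) && pad[q[1], q[2], q[3]]) hit <- TRUE
      }
      dil[x, y, z] <- hit
    }
  ero <- array(FALSE, dim(pad))
  for (x in seq_len(dim(pad)[1])) for (y in seq_len(dim(pad)[2]))
    for (z in seq_len(dim(pad)[3])) {
      all_in <- TRUE
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        q <- c(x + dx, y + dy, z + dz)
        if (!in_grid(q, dim(pad)) || !dil[q[1], q[2], q[3]]) all_in <- FALSE
      }
      ero[x, y, z] <- all_in
    }
  ero[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# nearest-centerline-point labels by exhaustive scan with sqrt distances
oracle_nearest <- function(points, centerline) {
  out <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(nrow(centerline))) {
      dd <- sqrt(sum((points[i, ] - centerline[j, ])^2))
      if (dd < best) { best <- dd; bj <- j }
    }
    out[i] <- bj
  }
  out
}

# random discretized ROI on a small grid (some voxels masked out)
random_lev <- function(dims, G, seed, p_mask = 0.85) {
  set.seed(seed)
  lev <- array(sample.int(G, prod(dims), replace = TRUE), dims)
  lev[stats::runif(prod(dims)) > p_mask] <- NA
  if (all(is.na(lev))) lev[1] <- 1
  lev
}

# straight-bundle fixture: parallel streamlines along x on a small grid
straight_bundle <- function(nx = 12L, ny = 5L, nz = 5L, n_lines = 9L) {
  ref <- scalar_volume(array(0, c(nx, ny, nz)), diag(4))
  offs <- expand.grid(y = seq(1, 3, 1), z = seq(1, 3, 1))
  sls <- lapply(seq_len(min(n_lines, nrow(offs))), function(i) {
    cbind(seq(0.5, nx - 1.5, length.out = 25), offs$y[i] + 0.5,
          offs$z[i] + 0.5)
  })
  list(t = tractogram(sls, ref), ref = ref)
}

# ---- feature-formula oracles: explicit double loops over the matrices ----

oracle_glcm_features <- function(p) {
  G <- nrow(p)
  px <- rowSums(p)
  mu <- 0; for (i in 1:G) for (j in 1:G) mu <- mu + i * p[i, j]
  sig2 <- 0; for (i in 1:G) for (j in 1:G) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  pd <- numeric(G); ps <- numeric(2 * G - 1)
  for (i in 1:G) for (j in 1:G) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  HX <- ent(px); HXY <- ent(p)
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:G) for (j in 1:G) {
    pp <- px[i] * px[j]
    if (pp > 0) {
      HXY1 <- HXY1 - p[i, j] * log2(pp)
      HXY2 <- HXY2 - pp * log2(pp)
    }
  }
  da <- sum((0:(G - 1)) * pd)
  f <- c(Autocorrelation = 0, JointAverage = mu, ClusterProminence = 0,
         ClusterShade = 0, ClusterTendency = 0, Contrast = 0,
         Correlation = 0, DifferenceAverage = da,
         DifferenceEntropy = ent(pd),
         DifferenceVariance = sum(((0:(G - 1)) - da)^2 * pd),
         JointEnergy = 0, JointEntropy = HXY, Imc1 = 0, Imc2 = 0,
         Idm = 0, Idmn = 0, Id = 0, Idn = 0, InverseVariance = 0,
         MaximumProbability = max(p), SumEntropy = ent(ps),
         SumSquares = sig2)
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * v
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - 2 * mu)^4 * v
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - 2 * mu)^3 * v
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - 2 * mu)^2 * v
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * v
    f["JointEnergy"] <- f["JointEnergy"] + v^2
    f["Idm"] <- f["Idm"] + v / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + v / (1 + ((i - j) / G)^2)
    f["Id"] <- f["Id"] + v / (1 + abs(i - j))
    f["Idn"] <- f["Idn"] + v / (1 + abs(i - j) / G)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + v / (i - j)^2
  }
  f["Correlation"] <- if (sig2 > 0) (f[["Autocorrelation"]] - mu^2) / sig2 else 1
  f["Imc1"] <- if (HX > 0) (HXY - HXY1) / HX else 0
  f["Imc2"] <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  f
}

oracle_rl_features <- function(R, Np) {
  G <- nrow(R); L <- ncol(R); Nr <- sum(R)
  p <- R / Nr
  mug <- 0; mul <- 0
  for (g in 1:G) for (l in 1:L) { mug <- mug + g * p[g, l]; mul <- mul + l * p[g, l] }
  acc <- c(sre = 0, lre = 0, gln = 0, rln = 0, glv = 0, rv = 0,
           lgl = 0, hgl = 0, srlgl = 0, srhgl = 0, lrlgl = 0, lrhgl = 0)
  for (g in 1:G) for (l in 1:L) {
    v <- R[g, l]
    acc["sre"] <- acc["sre"] + v / l^2
    acc["lre"] <- acc["lre"] + v * l^2
    acc["glv"] <- acc["glv"] + (g - mug)^2 * p[g, l]
    acc["rv"] <- acc["rv"] + (l - mul)^2 * p[g, l]
    acc["lgl"] <- acc["lgl"] + v / g^2
    acc["hgl"] <- acc["hgl"] + v * g^2
    acc["srlgl"] <- acc["srlgl"] + v / (g^2 * l^2)
    acc["srhgl"] <- acc["srhgl"] + v * g^2 / l^2
    acc["lrlgl"] <- acc["lrlgl"] + v * l^2 / g^2
    acc["lrhgl"] <- acc["lrhgl"] + v * g^2 * l^2
  }
  for (g in 1:G) acc["gln"] <- acc["gln"] + sum(R[g, ])^2
  for (l in 1:L) acc["rln"] <- acc["rln"] + sum(R[, l])^2
  q <- p[p > 0]
  c(acc[["sre"]] / Nr, acc[["lre"]] / Nr, acc[["gln"]] / Nr,
    acc[["gln"]] / Nr^2, acc[["rln"]] / Nr, acc[["rln"]] / Nr^2,
    Nr / Np, acc[["glv"]], acc[["rv"]], -sum(q * log2(q)),
    acc[["lgl"]] / Nr, acc[["hgl"]] / Nr, acc[["srlgl"]] / Nr,
    acc[["srhgl"]] / Nr, acc[["lrlgl"]] / Nr, acc[["lrhgl"]] / Nr)
}

oracle_ngtdm_features <- function(n, s) {
  G <- length(n)
  Nvp <- sum(n)
  p <- n / Nvp
  act <- which(p > 0); Ngp <- length(act)
  denom <- sum(p * s)
  coars <- min(if (denom > 0) 1 / denom else 1e6, 1e6)
  contrast <- 0
  if (Ngp > 1) {
    acc <- 0
    for (i in act) for (j in act) acc <- acc + p[i] * p[j] * (i - j)^2
    contrast <- acc / (Ngp * (Ngp - 1)) * sum(s) / Nvp
  }
  busy_den <- 0
  for (i in act) for (j in act) busy_den <- busy_den + abs(i * p[i] - j * p[j])
  busy <- if (busy_den > 0) denom / busy_den else 0
  comp <- 0; strength <- 0
  if (Ngp > 1) {
    for (i in act) for (j in act) {
      if (i == j) next
      comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    comp <- comp / Nvp
    strength <- if (sum(s) > 0) strength / sum(s) else 0
  }
  c(Coarseness = coars, Contrast = contrast, Busyness = busy,
    Complexity = comp, Strength = strength)
}

oracle_gldm_features <- function(P) {
  G <- nrow(P); D <- ncol(P); Nz <- sum(P)
  p <- P / Nz
  mug <- 0; muj <- 0
  for (g in 1:G) for (j in 1:D) { mug <- mug + g * p[g, j]; muj <- muj + j * p[g, j] }
  acc <- c(sde = 0, lde = 0, gln = 0, dn = 0, glv = 0, dv = 0,
           lgl = 0, hgl = 0, sdlgl = 0, sdhgl = 0, ldlgl = 0, ldhgl = 0)
  for (g in 1:G) for (j in 1:D) {
    v <- P[g, j]
    acc["sde"] <- acc["sde"] + v / j^2
    acc["lde"] <- acc["lde"] + v * j^2
    acc["glv"] <- acc["glv"] + (g - mug)^2 * p[g, j]
    acc["dv"] <- acc["dv"] + (j - muj)^2 * p[g, j]
    acc["lgl"] <- acc["lgl"] + v / g^2
    acc["hgl"] <- acc["hgl"] + v * g^2
    acc["sdlgl"] <- acc["sdlgl"] + v / (g^2 * j^2)
    acc["sdhgl"] <- acc["sdhgl"] + v * g^2 / j^2
    acc["ldlgl"] <- acc["ldlgl"] + v * j^2 / g^2
    acc["ldhgl"] <- acc["ldhgl"] + v * g^2 * j^2
  }
  for (g in 1:G) acc["gln"] <- acc["gln"] + sum(P[g, ])^2
  for (j in 1:D) acc["dn"] <- acc["dn"] + sum(P[, j])^2
  q <- p[p > 0]
  c(SmallDependenceEmphasis = acc[["sde"]] / Nz,
    LargeDependenceEmphasis = acc[["lde"]] / Nz,
    GrayLevelNonUniformity = acc[["gln"]] / Nz,
    DependenceNonUniformity = acc[["dn"]] / Nz,
    DependenceNonUniformityNormalized = acc[["dn"]] / Nz^2,
    GrayLevelVariance = acc[["glv"]],
    DependenceVariance = acc[["dv"]],
    DependenceEntropy = -sum(q * log2(q)),
    LowGrayLevelEmphasis = acc[["lgl"]] / Nz,
    HighGrayLevelEmphasis = acc[["hgl"]] / Nz,
    SmallDependenceLowGrayLevelEmphasis = acc[["sdlgl"]] / Nz,
    SmallDependenceHighGrayLevelEmphasis = acc[["sdhgl"]] / Nz,
    LargeDependenceLowGrayLevelEmphasis = acc[["ldlgl"]] / Nz,
    LargeDependenceHighGrayLevelEmphasis = acc[["ldhgl"]] / Nz)
}
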