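test_that("discretization bins intensities as specified", {
  expect_equal(discretize(rep(2.5, 10))$G, 1L)
  expect_true(all(discretize(rep(2.5, 10))$levels == 1))

  d <- discretize(as.numeric(0:31), bin_count = 32)
  expect_equal(d$G, 32L)
  expect_equal(sort(unique(d$levels)), 1:32)
  expect_equal(d$levels, 1:32)  # identity-like binning

  set.seed(4)
  x <- runif(500)
  d8 <- discretize(x, bin_count = 8)
  # direct quantization oracle
  w <- (max(x) - min(x)) / 8
  want <- pmin(floor((x - min(x)) / w) + 1, 8)
  expect_equal(d8$levels, want)

  dw <- discretize(c(0.1, 0.26, 0.49, 0.51), bin_width = 0.25)
  expect_equal(dw$levels, c(1, 2, 2, 3))
})

test_that("first-order features match direct formula recomputation", {
  f <- firstorder_features(rep(4.2, 20), spacing = c(1, 1, 1))
  expect_equal(f[["Mean"]], 4.2)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Range"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Uniformity"]], 1)
  expect_equal(f[["Skewness"]], 0)

  f2 <- firstorder_features(c(1, 2, 3, 4))
  expect_equal(f2[["Mean"]], 2.5)
  expect_equal(f2[["Median"]], 2.5)
  expect_equal(f2[["Range"]], 3)
  expect_equal(f2[["Variance"]], 1.25)  # population variance
  expect_equal(f2[["Energy"]], 30)

  set.seed(12)
  x <- rnorm(500, 10, 2)
  lev <- discretize(x, bin_count = 32)$levels
  got <- firstorder_features(x, spacing = c(1.25, 1.25, 2.5), levels = lev)
  want <- oracle_firstorder(x, c(1.25, 1.25, 2.5), lev)
  expect_length(got, 18)
  expect_equal(got, want[names(got)], tolerance = 1e-9)

  # shift equivariance: Mean shifts, Variance/Range invariant
  g2 <- firstorder_features(x + 7, levels = lev)
  expect_equal(g2[["Mean"]], got[["Mean"]] + 7, tolerance = 1e-9)
  expect_equal(g2[["Variance"]], got[["Variance"]], tolerance = 1e-9)
  expect_equal(g2[["Range"]], got[["Range"]], tolerance = 1e-9)
})

test_that("shape features respect analytic limits", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  s1 <- shape_features(one, spacing = c(2, 2, 2))
  expect_length(s1, 14)
  expect_equal(s1[["VoxelVolume"]], 8)
  expect_gt(s1[["MeshVolume"]], 0)

  cube <- array(TRUE, c(10, 10, 10))
  sc <- shape_features(cube)
  expect_equal(sc[["Maximum3DDiameter"]], sqrt(300), tolerance = 1e-9)
  expect_equal(sc[["Maximum2DDiameterSlice"]], sqrt(200), tolerance = 1e-9)
  expect_equal(sc[["VoxelVolume"]], 1000)
  expect_equal(sc[["Elongation"]], 1, tolerance = 1e-9)

  # digitized sphere r = 8: near-unit sphericity, volume within 5%
  n <- 21
  g <- expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))
  mask <- array(sqrt((g[, 1] - 10)^2 + (g[, 2] - 10)^2 +
                       (g[, 3] - 10)^2) <= 8, c(n, n, n))
  ss <- shape_features(mask)
  expect_gte(ss[["Sphericity"]], 0.9)
  expect_lte(ss[["Sphericity"]], 1.0)
  expect_lt(abs(ss[["MeshVolume"]] / (4 / 3 * pi * 8^3) - 1), 0.05)
  expect_equal(ss[["MajorAxisLength"]], ss[["LeastAxisLength"]],
               tolerance = 0.05)

  # degenerate planar mask: zero least axis, Flatness 0, no crash
  pl <- array(FALSE, c(5, 5, 3)); pl[, , 2] <- TRUE
  sp <- shape_features(pl)
  expect_equal(sp[["LeastAxisLength"]], 0)
  expect_equal(sp[["Flatness"]], 0)
})

test_that("GLCM construction and features match brute-force enumeration", {
  # constant ROI: single level conventions
  lev <- array(1, c(3, 3, 1))
  f <- glcm_features(lev, 1L)
  expect_length(f, 22)
  expect_equal(f[["JointEnergy"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Correlation"]], 1)

  # hand-enumerable 2x2x1 block
  lev2 <- array(c(1, 1, 2, 2), c(2, 2, 1))
  dirs <- radtract:::texture_directions()
  mats <- glcm_matrices(lev2, 2L)
  om <- list()
  for (k in seq_len(nrow(dirs))) {
    o <- oracle_glcm(lev2, 2L, dirs[k, ])
    if (!is.null(o)) om[[length(om) + 1]] <- o
  }
  expect_equal(length(mats), length(om))
  for (k in seq_along(mats)) expect_equal(mats[[k]], om[[k]])

  # random small ROIs: per-direction matrices equal the pair-tally oracle,
  # are symmetric, and sum to 1; features equal the loop-formula oracle
  for (seed in 1:3) {
    lev3 <- random_lev(c(6, 5, 4), G = 5, seed = seed)
    mats3 <- glcm_matrices(lev3, 5L)
    om3 <- list()
    for (k in seq_len(nrow(dirs))) {
      o <- oracle_glcm(lev3, 5L, dirs[k, ])
      if (!is.null(o)) om3[[length(om3) + 1]] <- o
    }
    for (k in seq_along(mats3)) {
      expect_equal(mats3[[k]], om3[[k]], tolerance = 1e-12)
      expect_equal(mats3[[k]], t(mats3[[k]]))
      expect_equal(sum(mats3[[k]]), 1)
    }
    got <- glcm_features(lev3, 5L)
    want <- rowMeans(vapply(om3, function(P) {
      o <- oracle_glcm_features(P); o[names(got)]
    }, numeric(22)))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("GLRLM runs match exhaustive run scanning", {
  # constant 1x1xL line: one run of length L along the line direction
  L <- 6
  lev <- array(1, c(1, 1, L))
  mats <- glrlm_matrices(lev, 1L)
  along <- vapply(mats, ncol, integer(1)) == L
  expect_true(any(along))
  expect_equal(mats[along][[1]][1, L], 1)

  # alternating levels: every run has length 1
  lev2 <- array(rep(c(1, 2), 5), c(10, 1, 1))
  f2 <- glrlm_features(lev2, 2L)
  expect_equal(f2[["ShortRunEmphasis"]], 1)
  expect_equal(f2[["LongRunEmphasis"]], 1)

  dirs <- radtract:::texture_directions()
  for (seed in 4:6) {
    lev3 <- random_lev(c(6, 6, 6), G = 4, seed = seed)
    mats3 <- glrlm_matrices(lev3, 4L)
    om <- list()
    for (k in seq_len(nrow(dirs))) {
      o <- oracle_glrlm(lev3, 4L, dirs[k, ])
      if (!is.null(o)) om[[length(om) + 1]] <- o
    }
    expect_equal(length(mats3), length(om))
    for (k in seq_along(mats3)) expect_equal(mats3[[k]], om[[k]])
    got <- glrlm_features(lev3, 4L)
    Np <- sum(!is.na(lev3))
    want <- rowMeans(vapply(om, oracle_rl_features, numeric(16), Np = Np))
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
    expect_length(got, 16)
  }
})

test_that("GLSZM zones match independent connected-component labeling", {
  lev <- array(2, c(3, 3, 2))
  S <- glszm_matrix(lev, 2L)
  expect_equal(S[2, 18], 1)  # one zone of 18 voxels
  expect_equal(sum(S), 1)

  # two disjoint same-level blocks of sizes 3 and 5
  lev2 <- array(NA_real_, c(9, 1, 1))
  lev2[1:3, 1, 1] <- 1; lev2[5:9, 1, 1] <- 1
  S2 <- glszm_matrix(lev2, 1L)
  expect_equal(S2[1, 3], 1)
  expect_equal(S2[1, 5], 1)
  expect_equal(sum(S2), 2)

  for (seed in 7:9) {
    lev3 <- random_lev(c(6, 5, 5), G = 3, seed = seed)
    expect_equal(glszm_matrix(lev3, 3L), oracle_glszm(lev3, 3L))
    got <- glszm_features(lev3, 3L)
    want <- oracle_rl_features(oracle_glszm(lev3, 3L),
                               Np = sum(!is.na(lev3)))
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
    expect_length(got, 16)
  }
})

test_that("NGTDM neighbor-difference sums match manual enumeration", {
  lev <- array(3, c(4, 4, 2))
  f <- ngtdm_features(lev, 3L)
  expect_length(f, 5)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Busyness"]], 0)
  expect_equal(f[["Coarseness"]], 1e6)  # capped for flat ROIs

  # hand-computable 3x3x1 pattern
  lev2 <- array(c(1, 2, 1,
                  2, 3, 2,
                  1, 2, 1), c(3, 3, 1))
  tab <- radtract:::ngtdm_table(lev2, 3L)
  otab <- oracle_ngtdm(lev2, 3L)
  expect_equal(tab$n, otab$n)
  expect_equal(tab$s, otab$s, tolerance = 1e-12)

  for (seed in 10:12) {
    lev3 <- random_lev(c(5, 5, 5), G = 4, seed = seed)
    tab3 <- radtract:::ngtdm_table(lev3, 4L)
    otab3 <- oracle_ngtdm(lev3, 4L)
    expect_equal(tab3$n, otab3$n)
    expect_equal(tab3$s, otab3$s, tolerance = 1e-9)
    # counting invariant: sum n_i = in-mask voxels with >= 1 valid neighbor
    expect_equal(sum(tab3$n), sum(!is.na(lev3)))  # 5^3 grid: all have one
    expect_equal(ngtdm_features(lev3, 4L),
                 oracle_ngtdm_features(otab3$n, otab3$s), tolerance = 1e-9)
  }
})

test_that("GLDM dependence counts match exhaustive neighbor counting", {
  lev <- array(1, c(3, 3, 3))
  P <- radtract:::gldm_matrix(lev, 1L)
  expect_equal(P[1, 27], 1)  # center voxel has dependence 26

  lev2 <- array(1, c(3, 3, 3)); lev2[2, 2, 2] <- 2
  P2 <- radtract:::gldm_matrix(lev2, 2L)
  expect_equal(P2[2, 1], 1)  # isolated differing voxel: dependence 0

  for (seed in 13:15) {
    lev3 <- random_lev(c(6, 5, 4), G = 3, seed = seed)
    P3 <- radtract:::gldm_matrix(lev3, 3L)
    O3 <- oracle_gldm(lev3, 3L)
    expect_equal(P3, O3)
    got <- gldm_features(lev3, 3L)
    expect_equal(got, oracle_gldm_features(O3)[names(got)],
                 tolerance = 1e-9)
    expect_length(got, 14)
  }
})

test_that("texture features are invariant to level-preserving monotone transforms", {
  set.seed(30)
  vals <- array(runif(6 * 6 * 4), c(6, 6, 4))
  vals[sample(length(vals), 20)] <- NA
  d1 <- discretize(vals, bin_count = 8)
  d2 <- discretize(2 * vals + 5, bin_count = 8)  # monotone affine
  expect_equal(d1$levels, d2$levels)
  expect_equal(glcm_features(d1$levels, d1$G),
               glcm_features(d2$levels, d2$G))
})

test_that("the per-parcel feature vector has exactly the published structure", {
  sb <- straight_bundle()
  tr <- reorient_streamlines(sb$t)
  parc <- parcellate_voxels(tr, sb$ref, 1)
  mk <- function(seed) {
    set.seed(seed)
    scalar_volume(array(runif(prod(dim(sb$ref$data))), dim(sb$ref$data)))
  }
  fv1 <- extract_tract_features(parc, list(FA = mk(1)))
  expect_length(fv1, 105)
  cls <- vapply(strsplit(names(fv1), "__"), `[[`, character(1), 3)
  cnt <- function(k) sum(cls == k)
  expect_equal(vapply(c("firstorder", "shape", "glcm", "glrlm", "glszm",
                        "ngtdm", "gldm"), cnt, integer(1)),
               c(firstorder = 18L, shape = 14L, glcm = 22L, glrlm = 16L,
                 glszm = 16L, ngtdm = 5L, gldm = 14L))
  expect_equal(sum(cls %in% c("glcm", "glrlm", "glszm", "ngtdm", "gldm")),
               73L)

  maps4 <- list(FA = mk(1), ADC = mk(2), AD = mk(3), RD = mk(4))
  fv4 <- extract_tract_features(parc, maps4)
  expect_length(fv4, 420)

  parc10 <- parcellate_voxels(tr, sb$ref, 10)
  fv10 <- extract_tract_features(parc10, list(FA = mk(1)))
  expect_length(fv10, 1050)

  # determinism: bitwise identical on repeated extraction
  expect_identical(fv4, extract_tract_features(parc, maps4))

  # shape features are identical across maps of the same parcel
  shp <- grep("__shape__", names(fv4), value = TRUE)
  m <- matrix(fv4[shp], nrow = 14)
  expect_true(all(apply(m, 1, function(r) diff(range(r)) == 0)))
})
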