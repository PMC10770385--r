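#' Synthetic fiber-bundle phantom specification
#'
#' Describes a curved bundle of streamlines inside a voxel grid: a
#' centerline family (straight line, planar arc, or helix), the number of
#' streamlines, the perpendicular dispersion of streamlines around the
#' centerline, and the grid geometry.
#'
#' @param family `"line"`, `"arc"` or `"helix"`.
#' @param n_streamlines number of streamlines.
#' @param sigma dispersion of the smooth perpendicular offsets in mm.
#' @param shape grid dimensions in voxels.
#' @param spacing voxel size in mm.
#' @param n_points points per generated streamline.
#' @param seed RNG seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(family = c("arc", "line", "helix"),
                         n_streamlines = 50L, sigma = 0.8,
                         shape = c(28L, 28L, 16L), spacing = c(1, 1, 1),
                         n_points = 40L, seed = 0L) {
  family <- match.arg(family)
  stopifnot(sigma >= 0, n_streamlines >= 1)
  structure(list(family = family, n_streamlines = as.integer(n_streamlines),
                 sigma = sigma, shape = as.integer(shape),
                 spacing = spacing, n_points = as.integer(n_points),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_centerline <- function(spec, m = NULL) {
  if (is.null(m)) m <- spec$n_points
  ext <- (spec$shape - 1) * spec$spacing  # world extent of voxel centers
  t <- seq(0, 1, length.out = m)
  margin <- 0.18
  lo <- ext * margin; hi <- ext * (1 - margin)
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  switch(spec$family,
    line = cbind(lo[1] + t * (hi[1] - lo[1]), mid[2], mid[3]),
    arc = {
      th <- pi * (1 - t)  # half arc in the xy plane
      cbind(mid[1] + half[1] * cos(th),
            lo[2] + 0.8 * (hi[2] - lo[2]) * sin(th),
            mid[3])
    },
    helix = {
      th <- pi * (1 - t)
      cbind(mid[1] + half[1] * cos(th),
            lo[2] + 0.8 * (hi[2] - lo[2]) * sin(th),
            lo[3] + t * (hi[3] - lo[3]) * 0.6)
    })
}

#' Generate a synthetic fiber bundle
#'
#' Streamlines are the specified centerline family plus smooth seeded perpendicular
#' offsets (constant + linear + half-sine components per normal direction,
#' with Gaussian coefficients of standard deviation `sigma`). With
#' `sigma = 0` every streamline equals the centerline. Errors if the bundle
#' leaves the grid.
#'
#' @param spec a [phantom_spec()].
#' @return List: `tractogram` ([tractogram()]), `reference`
#'   ([scalar_volume()] of zeros), `centerline` (the generating curve).
#' @export
generate_bundle <- function(spec) {
  cl <- phantom_centerline(spec)
  m <- nrow(cl)
  tang <- rbind(cl[2, ] - cl[1, ], (cl[-1, , drop = FALSE] -
                  cl[-m, , drop = FALSE]))
  tang <- tang / sqrt(rowSums(tang^2))
  up <- c(0, 0, 1)
  e1 <- cbind(tang[, 2] * up[3] - tang[, 3] * up[2],
              tang[, 3] * up[1] - tang[, 1] * up[3],
              tang[, 1] * up[2] - tang[, 2] * up[1])
  deg <- sqrt(rowSums(e1^2)) < 1e-6
  if (any(deg))
    e1[deg, ] <- matrix(c(0, 1, 0), sum(deg), 3, byrow = TRUE)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  tt <- seq(0, 1, length.out = m)
  basis <- cbind(1, tt - 0.5, sin(pi * tt))
  sls <- with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_streamlines), function(i) {
      a <- stats::rnorm(3, sd = spec$sigma)
      b <- stats::rnorm(3, sd = spec$sigma)
      off1 <- as.vector(basis %*% a)
      off2 <- as.vector(basis %*% b)
      cl + off1 * e1 + off2 * e2
    })
  })
  ext <- (spec$shape - 1) * spec$spacing
  allp <- do.call(rbind, sls)
  if (any(allp < -0.5 * min(spec$spacing)) ||
      any(sweep(allp, 2, ext + 0.5 * min(spec$spacing)) > 0))
    stop("generated bundle exceeds grid bounds; reduce sigma or enlarge grid")
  affine <- diag(c(spec$spacing, 1))
  ref <- scalar_volume(array(0, spec$shape), affine)
  list(tractogram = tractogram(sls, ref), reference = ref, centerline = cl)
}

#' Cohort specification for phantom experiments
#'
#' Defines per-class sample sizes and a localized group effect on the
#' parameter maps: a mean shift (in units of the voxel noise SD), a
#' variance scaling, or a texture change that multiplies the spatial-noise
#' correlation length inside the target parcels while keeping the voxel
#' mean and SD constant (invisible to per-parcel averages, visible to
#' texture features).
#'
#' @param n_per_class named integer vector of subjects per class.
#' @param n_parcels parcel count of the voxel parcellation the effects
#'   refer to.
#' @param effects named list (class -> list(parcels, type, size)); classes
#'   without an entry get no effect. `type` is one of `"mean"`,
#'   `"variance"`, `"texture"`.
#' @param noise_sd voxel noise SD relative to each map's natural scale.
#' @param smooth_sigma base spatial-noise correlation length in voxels.
#' @param seed RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(A = 20L, B = 20L), n_parcels = 8L,
                        effects = list(), noise_sd = 0.07,
                        smooth_sigma = 0.6, seed = 0L) {
  if (is.null(names(n_per_class))) stop("`n_per_class` must be named")
  for (e in effects) {
    stopifnot(all(e$parcels >= 1), all(e$parcels <= n_parcels),
              e$type %in% c("mean", "variance", "texture"), e$size >= 0)
  }
  structure(list(n_per_class = n_per_class, n_parcels = as.integer(n_parcels),
                 effects = effects, noise_sd = noise_sd,
                 smooth_sigma = smooth_sigma, seed = as.integer(seed)),
            class = "cohort_spec")
}

# separable Gaussian smoothing with edge renormalization
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  out <- arr
  ones <- array(1, dim(arr))
  for (ax in 1:3) {
    num <- array(0, dim(arr)); den <- array(0, dim(arr))
    for (j in -r:r) {
      off <- c(0, 0, 0); off[ax] <- j
      w <- k[j + r + 1]
      sh <- shift_na(out, off)
      shw <- shift_na(ones, off)
      valid <- !is.na(sh)
      num[valid] <- num[valid] + w * sh[valid]
      den[valid] <- den[valid] + w * shw[valid]
    }
    out <- num / den
  }
  out
}

# unit-SD smooth noise field
smooth_noise_field <- function(shape, sigma) {
  x <- gauss_smooth3(array(stats::rnorm(prod(shape)), shape), sigma)
  (x - mean(x)) / stats::sd(x)
}

#' Generate a phantom cohort with a known localized group effect
#'
#' For each subject, four parameter maps (FA-, ADC-, AD-, RD-like scales)
#' are built as smooth baseline + seeded smooth subject noise + the class
#' effect restricted to the target parcels of a shared voxel parcellation
#' of the phantom bundle. The FA-like map is clamped to [0, 1]. A ground
#' truth manifest (classes, effect locations, types, sizes) is always
#' returned.
#'
#' @param bundle a [generate_bundle()] result.
#' @param cohort a [cohort_spec()].
#' @return List: `maps` (per subject: named list of four [scalar_volume()]),
#'   `meta` (data frame subject/class), `parcellation` (the shared
#'   voxel-space [parcellation()]), `truth` (manifest list).
#' @export
generate_cohort <- function(bundle, cohort) {
  t_reo <- reorient_streamlines(bundle$tractogram)
  parc <- parcellate_voxels(t_reo, bundle$reference, cohort$n_parcels)
  labels <- parc$labels
  shape <- dim(labels)
  scales <- c(FA = 1, ADC = 1e-3, AD = 1e-3, RD = 1e-3)
  base_level <- c(FA = 0.45, ADC = 0.8, AD = 1.2, RD = 0.6)
  # mild fixed spatial gradient so baselines are smooth, not constant
  gx <- array(rep(seq(-0.5, 0.5, length.out = shape[1]), times =
                    prod(shape[2:3])), shape)
  classes <- rep(names(cohort$n_per_class), cohort$n_per_class)
  n_sub <- length(classes)
  subjects <- sprintf("sub%03d", seq_len(n_sub))
  maps <- vector("list", n_sub)
  for (si in seq_len(n_sub)) {
    cls <- classes[si]
    eff <- cohort$effects[[cls]]
    maps[[si]] <- with_local_seed(cohort$seed * 10000L + si, {
      out <- list()
      for (mn in names(scales)) {
        noise <- smooth_noise_field(shape, cohort$smooth_sigma)
        if (!is.null(eff)) {
          in_eff <- labels %in% eff$parcels
          if (eff$type == "texture") {
            alt <- smooth_noise_field(shape,
                                      cohort$smooth_sigma * eff$size)
            noise[in_eff] <- alt[in_eff]
          } else if (eff$type == "variance") {
            noise[in_eff] <- noise[in_eff] * eff$size
          } else if (eff$type == "mean") {
            noise[in_eff] <- noise[in_eff] + eff$size
          }
        }
        v <- base_level[[mn]] * (1 + 0.1 * gx) + cohort$noise_sd * noise
        if (mn == "FA") v <- pmin(pmax(v, 0), 1)
        out[[mn]] <- scalar_volume(v * scales[[mn]],
                                   bundle$reference$affine)
      }
      out
    })
  }
  truth <- list(classes = classes, effects = cohort$effects,
                n_parcels = cohort$n_parcels, noise_sd = cohort$noise_sd,
                smooth_sigma = cohort$smooth_sigma, seed = cohort$seed)
  list(maps = maps,
       meta = data.frame(subject = subjects, class = classes,
                         stringsAsFactors = FALSE),
       parcellation = parc, truth = truth)
}

#' Full phantom feature tables for the radiomic and profile pipelines
#'
#' Convenience wrapper used by experiments and the command line: extracts,
#' for every subject of a generated cohort, the radiomic tract features
#' (voxel parcellation) and the classic centerline-profile features.
#'
#' @param bundle a [generate_bundle()] result.
#' @param cohort_data a [generate_cohort()] result.
#' @param cfg a [radiomics_config()].
#' @param profile_n parcel count for the classic profile baseline
#'   (default 100).
#' @return List of two matrices (subjects x features): `radiomic`,
#'   `profile`.
#' @export
cohort_feature_tables <- function(bundle, cohort_data,
                                  cfg = radiomics_config(),
                                  profile_n = 100L) {
  t_reo <- reorient_streamlines(bundle$tractogram)
  parc <- cohort_data$parcellation
  sparc <- assign_centerline_scheme(t_reo, profile_n)
  rad <- NULL; prof <- NULL
  for (si in seq_len(nrow(cohort_data$meta))) {
    maps <- cohort_data$maps[[si]]
    fv <- extract_tract_features(parc, maps, cfg)
    profiles <- lapply(maps, function(m) {
      extract_profile(t_reo, m, parc = sparc)
    })
    pv <- profile_feature_vector(profiles)
    if (is.null(rad)) {
      rad <- matrix(NA_real_, nrow(cohort_data$meta), length(fv),
                    dimnames = list(cohort_data$meta$subject, names(fv)))
      prof <- matrix(NA_real_, nrow(cohort_data$meta), length(pv),
                     dimnames = list(cohort_data$meta$subject, names(pv)))
    }
    rad[si, ] <- fv
    prof[si, ] <- pv
  }
  list(radiomic = rad, profile = prof)
}
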