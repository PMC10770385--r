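#' Along-tract profile of a parameter map
#'
#' The classic tractometry feature: the map is sampled at streamline points
#' (trilinear interpolation by default), each value is assigned to a parcel
#' by the chosen scheme, and the values within each parcel are aggregated by
#' averaging. Parcels that receive no points are reported as `NA`, never as
#' a silent zero.
#'
#' @param t a [tractogram()].
#' @param map a [scalar_volume()] sharing the tractogram's geometry.
#' @param n parcel count (default 100, the conventional profile length).
#' @param scheme `"centerline"` or `"static"`.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @param reorient reorient streamlines first (default TRUE); set FALSE if
#'   `t` is already consistently ordered.
#' @param parc optional precomputed streamline-space [parcellation()]
#'   (overrides `n`/`scheme`).
#' @return Object of class `tract_profile`: list with `values` (length-n
#'   numeric, `NA` for empty parcels), `n`, `map`, `scheme`.
#' @export
extract_profile <- function(t, map, n = 100L,
                            scheme = c("centerline", "static"),
                            interpolation = c("trilinear", "nearest"),
                            aggregate = c("mean", "median"),
                            reorient = TRUE, parc = NULL) {
  scheme <- match.arg(scheme)
  interpolation <- match.arg(interpolation)
  aggregate <- match.arg(aggregate)
  if (is.null(parc)) {
    if (reorient) t <- reorient_streamlines(t)
    parc <- switch(scheme,
      static = assign_static(t, n),
      centerline = assign_centerline_scheme(t, n))
  } else {
    if (parc$scheme == "voxel")
      stop("profiles need a streamline-space parcellation")
    scheme <- parc$scheme
    n <- parc$n
  }
  pts <- do.call(rbind, parc$points)
  labs <- unlist(parc$labels)
  vals <- sample_volume(map, pts, method = interpolation)
  agg <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NA_real_)
    if (aggregate == "mean") mean(v) else stats::median(v)
  }
  values <- vapply(seq_len(n), function(i) agg(vals[labs == i]), numeric(1))
  if (anyNA(values))
    warning(sum(is.na(values)), " parcel(s) received no streamline points")
  structure(list(values = values, n = as.integer(n),
                 map = attr(map, "name"), scheme = scheme),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat(sprintf("<tract_profile> scheme=%s, n=%d parcels\n", x$scheme, x$n))
  print(summary(x$values))
  invisible(x)
}

#' Flatten per-map profiles into one named feature vector
#'
#' Concatenates the per-parcel means of several maps into the classic
#' tractometry feature vector of length `n * n_maps`, with names
#' `{map}__parcel{i:03d}__mean`.
#'
#' @param profiles named list of [extract_profile()] results (names = map
#'   names), all with the same `n`.
#' @return Named numeric vector.
#' @export
profile_feature_vector <- function(profiles) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("`profiles` must be a named list (names = map names)")
  ns <- vapply(profiles, function(p) p$n, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all profiles must share the same parcel count")
  n <- ns[[1]]
  out <- unlist(lapply(names(profiles), function(m) {
    v <- profiles[[m]]$values
    names(v) <- sprintf("%s__parcel%03d__mean", m, seq_len(n))
    v
  }))
  out
}
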