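#' Feature-selection configuration
#'
#' @param k number of features to keep in the univariate step.
#' @param r_max correlation-pruning threshold; a feature is dropped when its
#'   absolute Pearson correlation with an already-kept feature *exceeds*
#'   this value (strict inequality). Default 0.95.
#' @param task `"classification"` (ANOVA F against the class label) or
#'   `"regression"` (F from the linear correlation with the target).
#' @param impute_missing median-impute `NA` feature values on training rows
#'   before selection (default TRUE).
#' @return List of class `selection_config`.
#' @export
selection_config <- function(k = 100L, r_max = 0.95,
                             task = c("classification", "regression"),
                             impute_missing = TRUE) {
  task <- match.arg(task)
  if (k < 1L) stop("`k` must be >= 1")
  if (r_max <= 0 || r_max > 1) stop("`r_max` must be in (0, 1]")
  structure(list(k = as.integer(k), r_max = r_max, task = task,
                 impute_missing = impute_missing),
            class = "selection_config")
}

#' Remove constant features
#'
#' @param x numeric matrix (rows = samples, columns = named features).
#' @return List: `x` without zero-variance columns, `dropped` (named reason
#'   vector).
#' @export
drop_constant <- function(x) {
  if (nrow(x) < 1L) stop("need at least one row")
  mins <- suppressWarnings(do.call(pmin, c(asplit(x, 1), na.rm = TRUE)))
  maxs <- suppressWarnings(do.call(pmax, c(asplit(x, 1), na.rm = TRUE)))
  const <- !is.finite(mins) | mins == maxs
  dropped <- stats::setNames(rep("constant", sum(const)),
                             colnames(x)[const])
  list(x = x[, !const, drop = FALSE], dropped = dropped)
}

#' Prune highly correlated features
#'
#' Scans columns in order; a feature is dropped when its absolute Pearson
#' correlation with any already-kept earlier feature exceeds `r_max`
#' (greedy, keeps the earlier member of a violating pair).
#'
#' @param x numeric matrix without constant columns.
#' @param r_max threshold (strict `>`).
#' @return List: pruned `x`, `dropped` (named reason vector
#'   `"correlated-with-<feature>"`).
#' @export
drop_correlated <- function(x, r_max = 0.95) {
  if (nrow(x) < 2L) stop("need at least two rows")
  p <- ncol(x)
  if (p <= 1L) return(list(x = x, dropped = character(0)))
  # Greedy scan in column order: column j is dropped iff |r| with some
  # *kept* earlier column exceeds r_max (strict, with a 1e-12 guard so
  # analytically-exact boundary correlations survive rounding noise).
  # Processed in chunks against the growing kept set, which avoids the
  # full p x p correlation matrix.
  thr <- r_max + 1e-12
  if (anyNA(x)) stop("NA values present; impute before pruning")
  xc <- sweep(x, 2, colMeans(x))
  sx <- sqrt(colSums(xc^2))
  if (any(sx == 0))
    stop("zero-variance or all-NA columns present; run drop_constant first")
  xs <- sweep(xc, 2, sx, "/")
  keep <- rep(TRUE, p)
  culprit <- character(0)
  kept_idx <- integer(0)
  chunk <- 512L
  for (s0 in seq(1L, p, by = chunk)) {
    s1 <- min(p, s0 + chunk - 1L)
    cols <- s0:s1
    # |r| of chunk columns vs all kept-so-far columns, and within chunk
    prev <- if (length(kept_idx)) {
      abs(crossprod(xs[, kept_idx, drop = FALSE], xs[, cols, drop = FALSE]))
    } else matrix(0, 0, length(cols))
    within <- abs(crossprod(xs[, cols, drop = FALSE]))
    for (ci in seq_along(cols)) {
      jj <- cols[ci]
      hit_prev <- if (nrow(prev)) kept_idx[prev[, ci] > thr] else integer(0)
      local_kept <- cols[seq_len(ci - 1L)][keep[cols[seq_len(ci - 1L)]]]
      hit_loc <- local_kept[within[match(local_kept, cols), ci] > thr]
      hit <- c(hit_prev, hit_loc)
      if (length(hit)) {
        keep[jj] <- FALSE
        culprit[colnames(x)[jj]] <-
          paste0("correlated-with-", colnames(x)[min(hit)])
      }
    }
    kept_idx <- which(keep[1:s1])
  }
  list(x = x[, keep, drop = FALSE], dropped = culprit)
}

#' Univariate F-scores of features against a target
#'
#' Classification: one-way ANOVA F between feature and class label, with
#' p from the F distribution (df1 = classes - 1, df2 = n - classes).
#' Regression: F = r^2 / (1 - r^2) * (n - 2) from the Pearson correlation,
#' p with df (1, n - 2).
#'
#' @param x numeric matrix.
#' @param target factor/character (classification) or numeric (regression).
#' @param task `"classification"` or `"regression"`.
#' @return Data frame with `feature`, `F`, `p`.
#' @export
univariate_scores <- function(x, target,
                              task = c("classification", "regression")) {
  task <- match.arg(task)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(target) != n) stop("target length must equal row count")
  if (task == "classification") {
    f <- factor(target)
    g <- nlevels(f)
    if (g < 2L) stop("classification target needs at least 2 classes")
    ng <- tabulate(f)
    Sg <- rowsum(x, f)                     # per-class column sums
    mg <- Sg / ng
    m <- colMeans(x)
    ssb <- colSums(ng * (sweep(mg, 2, m))^2)
    sst <- colSums(sweep(x, 2, m)^2)
    ssw <- pmax(sst - ssb, 0)
    df1 <- g - 1; df2 <- n - g
    Fv <- ifelse(ssw <= 1e-12 * pmax(sst, 1e-300), Inf,
                 (ssb / df1) / (ssw / df2))
    p <- stats::pf(Fv, g - 1, n - g, lower.tail = FALSE)
  } else {
    y <- as.numeric(target)
    if (stats::var(y) == 0) stop("regression target has zero variance")
    r <- as.vector(fast_cor(x, y))
    r2 <- pmin(r^2, 1)
    Fv <- ifelse(r2 >= 1 - 1e-14, Inf, r2 / (1 - r2) * (n - 2))
    p <- stats::pf(Fv, 1, n - 2, lower.tail = FALSE)
  }
  data.frame(feature = colnames(x), F = unname(Fv), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Keep the top-k features by univariate F-value
#'
#' Ties break by column order; when fewer than k features survive upstream
#' filtering, all are kept. Deterministic for identical inputs.
#'
#' @param x numeric matrix.
#' @param target class labels or numeric target.
#' @param cfg a [selection_config()].
#' @return List: reduced `x`, `scores` (data frame), `kept` (names).
#' @export
kbest <- function(x, target, cfg) {
  sc <- univariate_scores(x, target, cfg$task)
  k <- min(cfg$k, ncol(x))
  ord <- order(-sc$F, seq_len(ncol(x)))
  kept_idx <- sort(ord[seq_len(k)])
  list(x = x[, kept_idx, drop = FALSE], scores = sc,
       kept = colnames(x)[kept_idx])
}

#' Full feature pre-selection cascade
#'
#' Constant removal, then correlation pruning (|r| > r_max), then
#' univariate k-best — fitted on training rows only. The returned selector
#' is applied to held-out rows by feature name, so test rows never
#' influence the kept set.
#'
#' @param x numeric feature matrix (training rows).
#' @param target training labels / values.
#' @param cfg a [selection_config()].
#' @return Object of class `feature_selector`: `kept` (feature names in
#'   original column order), `report` (dropped features with reasons,
#'   per-feature F and p), `medians` (training medians used for
#'   imputation).
#' @export
select_features <- function(x, target, cfg = selection_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  if (cfg$impute_missing && anyNA(x)) {
    for (jj in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, jj]), jj] <- stats::median(x[, jj], na.rm = TRUE)
    }
  }
  s1 <- drop_constant(x)
  if (ncol(s1$x) == 0L) stop("all features are constant")
  s2 <- drop_correlated(s1$x, cfg$r_max)
  s3 <- kbest(s2$x, target, cfg)
  low <- setdiff(colnames(s2$x), s3$kept)
  dropped <- c(s1$dropped, s2$dropped,
               stats::setNames(rep("low-score", length(low)), low))
  # training medians of the kept features, for held-out imputation
  medians <- apply(x[, s3$kept, drop = FALSE], 2, stats::median,
                   na.rm = TRUE)
  structure(list(kept = s3$kept,
                 report = list(dropped = dropped, scores = s3$scores),
                 medians = medians, cfg = cfg),
            class = "feature_selector")
}

#' Apply a fitted selector to a feature matrix
#'
#' @param selector a [select_features()] result.
#' @param x matrix with (at least) the training feature columns.
#' @return Matrix restricted to the kept features, with training-median
#'   imputation of `NA`s.
#' @export
apply_selector <- function(selector, x) {
  x <- as.matrix(x)
  missing_cols <- setdiff(selector$kept, colnames(x))
  if (length(missing_cols))
    stop("matrix lacks selected features: ",
         paste(utils::head(missing_cols, 3), collapse = ", "))
  out <- x[, selector$kept, drop = FALSE]
  if (selector$cfg$impute_missing && anyNA(out)) {
    for (jj in seq_len(ncol(out))) {
      nas <- is.na(out[, jj])
      if (any(nas)) out[nas, jj] <- selector$medians[selector$kept[jj]]
    }
  }
  out
}

# Pearson correlation via BLAS crossprod (columns of x vs themselves or y);
# requires complete data (imputation happens upstream)
fast_cor <- function(x, y = NULL) {
  if (anyNA(x) || (!is.null(y) && anyNA(y)))
    return(suppressWarnings(stats::cor(x, y,
                                       use = "pairwise.complete.obs")))
  xc <- sweep(x, 2, colMeans(x))
  sx <- sqrt(colSums(xc^2))
  bad <- sx == 0
  sx[bad] <- 1
  xs <- sweep(xc, 2, sx, "/")  # unit-norm columns: crossprod = correlation
  if (is.null(y)) {
    cm <- crossprod(xs)
    if (any(bad)) { cm[bad, ] <- NA_real_; cm[, bad] <- NA_real_ }
    cm
  } else {
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2))
    r <- crossprod(xs, yc) / sy
    if (any(bad) || sy == 0) r[bad | sy == 0] <- NA_real_
    r
  }
}

#' @export
print.feature_selector <- function(x, ...) {
  cat(sprintf("<feature_selector> kept %d features (%d dropped)\n",
              length(x$kept), length(x$report$dropped)))
  invisible(x)
}
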