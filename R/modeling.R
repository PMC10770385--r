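#' Evaluation-protocol configuration
#'
#' Random forest with 100 trees and maximum depth 4, no further tuning;
#' the experiment is repeated as differently seeded leave-one-out
#' cross-validations (default ten repetitions, seeds 0..9).
#'
#' @param n_trees trees per forest.
#' @param max_depth maximum tree depth.
#' @param seeds integer seed per repetition; its length sets the number of
#'   repetitions.
#' @return List of class `model_config`.
#' @export
model_config <- function(n_trees = 100L, max_depth = 4L, seeds = 0:9) {
  stopifnot(n_trees >= 1, max_depth >= 1, length(seeds) >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 seeds = as.integer(seeds),
                 n_repetitions = length(seeds)),
            class = "model_config")
}

#' Tie-aware AUROC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic with midranks (ties contribute 0.5).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   second level / TRUE / 1 is the positive class).
#' @return AUROC in `[0, 1]`; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("binary labels required")
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("binary labels required")
  labels == u[2]
}

#' One-vs-rest AUROC for multi-class probabilities
#'
#' Per class c: AUROC of the class-c probability against the indicator
#' label == c; macro average is the unweighted mean over classes with both
#' positives and negatives present (absent classes are excluded with a
#' warning).
#'
#' @param probabilities matrix (samples x classes) with class column names.
#' @param labels class labels.
#' @return List: `per_class` (named vector), `macro`.
#' @export
auroc_ovr <- function(probabilities, labels) {
  cls <- colnames(probabilities)
  if (is.null(cls)) stop("probability matrix needs class column names")
  per <- vapply(cls, function(cc) {
    auroc(probabilities[, cc], labels == cc)
  }, numeric(1))
  if (anyNA(per))
    warning("class(es) without positives excluded from macro AUROC: ",
            paste(cls[is.na(per)], collapse = ", "))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Regression metrics: MSE, Pearson r, R-squared
#'
#' @param predictions numeric predictions.
#' @param truth numeric ground truth (same length).
#' @return Named vector `MSE`, `PearsonR`, `R2` (R2 relative to the truth
#'   mean); `PearsonR` is `NA` with a warning for zero-variance inputs.
#' @export
regression_metrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) >= 2)
  mse <- mean((predictions - truth)^2)
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) {
    warning("zero-variance truth; PearsonR/R2 undefined")
    return(c(MSE = mse, PearsonR = NA_real_, R2 = NA_real_))
  }
  r <- if (stats::var(predictions) == 0) {
    warning("zero-variance predictions; PearsonR undefined")
    NA_real_
  } else stats::cor(predictions, truth)
  c(MSE = mse, PearsonR = r, R2 = 1 - sum((truth - predictions)^2) / sst)
}

#' Repeated leave-one-out cross-validated random-forest evaluation
#'
#' The complete evaluation protocol: for each repetition seed, a
#' leave-one-out cross-validation where the feature-selection cascade is
#' refit on the training rows of every fold and a random forest (100
#' trees, depth 4 by default) is trained on the selected features.
#' Classification uses probability forests and pooled out-of-fold
#' probabilities per repetition (one prediction per sample), scored by
#' one-vs-rest AUROC; regression is scored by MSE / Pearson r / R2.
#' Per-feature impurity importances are averaged over folds within each
#' repetition (features not selected in a fold count 0) and normalized to
#' sum 1.
#'
#' @param x feature matrix (samples x named features).
#' @param target class labels (classification) or numeric values
#'   (regression).
#' @param task `"classification"` or `"regression"`.
#' @param model_cfg a [model_config()].
#' @param selection_cfg a [selection_config()]; its `task` is forced to
#'   `task`.
#' @return Object of class `tract_eval` with per-repetition out-of-fold
#'   predictions, metrics, and importance vectors.
#' @export
tract_evaluate <- function(x, target,
                           task = c("classification", "regression"),
                           model_cfg = model_config(),
                           selection_cfg = selection_config()) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples")
  selection_cfg$task <- task
  classification <- task == "classification"
  if (classification) {
    y <- factor(target)
    if (nlevels(y) < 2L) stop("need at least 2 classes")
  } else y <- as.numeric(target)
  reps <- vector("list", length(model_cfg$seeds))
  for (ri in seq_along(model_cfg$seeds)) {
    seed <- model_cfg$seeds[ri]
    pred <- if (classification) {
      matrix(NA_real_, n, nlevels(y), dimnames = list(NULL, levels(y)))
    } else rep(NA_real_, n)
    imp_sum <- stats::setNames(numeric(ncol(x)), colnames(x))
    for (i in seq_len(n)) {
      sel <- select_features(x[-i, , drop = FALSE], y[-i], selection_cfg)
      xtr <- apply_selector(sel, x[-i, , drop = FALSE])
      xte <- apply_selector(sel, x[i, , drop = FALSE])
      fit <- ranger::ranger(
        x = xtr, y = y[-i],
        num.trees = model_cfg$n_trees, max.depth = model_cfg$max_depth,
        probability = classification, importance = "impurity",
        seed = seed * 100003L + i, num.threads = 1L)
      p <- stats::predict(fit, data = xte, num.threads = 1L)$predictions
      if (classification) {
        pred[i, colnames(p)] <- p[1, ]
      } else pred[i] <- p[1]
      imp <- fit$variable.importance
      tot <- sum(imp)
      if (tot > 0) imp_sum[names(imp)] <- imp_sum[names(imp)] + imp / tot
    }
    importance <- imp_sum / n
    if (sum(importance) > 0) importance <- importance / sum(importance)
    metrics <- if (classification) {
      ovr <- auroc_ovr(pred, as.character(y))
      c(stats::setNames(ovr$per_class,
                        paste0("AUROC_", names(ovr$per_class))),
        AUROC_macro = ovr$macro)
    } else regression_metrics(pred, y)
    reps[[ri]] <- list(seed = seed, predictions = pred, metrics = metrics,
                       importance = importance)
  }
  metrics_tab <- do.call(rbind, lapply(reps, function(r) r$metrics))
  structure(list(task = task, labels = y, repetitions = reps,
                 metrics = metrics_tab,
                 importance = vapply(reps, function(r) r$importance,
                                     numeric(ncol(x))),
                 model_cfg = model_cfg, selection_cfg = selection_cfg),
            class = "tract_eval")
}

#' @export
print.tract_eval <- function(x, ...) {
  cat(sprintf("<tract_eval> %s, %d samples, %d repetitions\n", x$task,
              length(x$labels), length(x$repetitions)))
  main <- if (x$task == "classification") "AUROC_macro" else "MSE"
  cat(sprintf("  mean %s over repetitions: %.4f\n", main,
              mean(x$metrics[, main])))
  invisible(x)
}

#' @export
summary.tract_eval <- function(object, ...) {
  out <- data.frame(metric = colnames(object$metrics),
                    mean = colMeans(object$metrics),
                    sd = apply(object$metrics, 2, stats::sd),
                    row.names = NULL)
  out
}

# ---- DeLong ----------------------------------------------------------------

#' Paired DeLong test for two correlated ROC curves
#'
#' Fast midrank implementation of the covariance-based comparison of two
#' AUROCs computed from different scores on the same samples; two-sided
#' normal p-value.
#'
#' @param scores_a,scores_b prediction scores of the two methods on the
#'   identical samples.
#' @param labels binary labels.
#' @return List: `auc_a`, `auc_b`, `delta`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary(labels)
  m <- sum(y); n <- sum(!y)
  if (m == 0L || n == 0L) stop("both classes must be present")
  comp <- function(s) {
    rx <- rank(s[y], ties.method = "average")
    ry <- rank(s[!y], ties.method = "average")
    rall <- rank(s, ties.method = "average")
    v10 <- (rall[y] - rx) / n
    v01 <- 1 - (rall[!y] - ry) / m
    list(auc = (sum(rall[y]) - m * (m + 1) / 2) / (m * n),
         v10 = v10, v01 = v01)
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  p <- if (var_delta <= 0) {
    if (abs(delta) < 1e-12) 1 else 0
  } else 2 * stats::pnorm(-abs(delta) / sqrt(var_delta))
  list(auc_a = a$auc, auc_b = b$auc, delta = delta, p = p)
}

#' DeLong comparison of two evaluation results
#'
#' Per repetition and per class (one-vs-rest), the paired DeLong p-value
#' between the pooled out-of-fold class probabilities of two
#' classification results on identical samples. A comparison is deemed
#' significant when the repetition-mean p of at least one class is below
#' `alpha`.
#'
#' @param result_a,result_b `tract_eval` classification results on the same
#'   samples and labels.
#' @param alpha significance level (default 0.05).
#' @return Object of class `tract_comparison`: matrix `p` (repetitions x
#'   classes), `mean_p` per class, `significant`.
#' @export
delong_compare <- function(result_a, result_b, alpha = 0.05) {
  stopifnot(inherits(result_a, "tract_eval"), inherits(result_b, "tract_eval"))
  if (!identical(as.character(result_a$labels),
                 as.character(result_b$labels)))
    stop("results were not computed on identical samples/labels")
  labs <- as.character(result_a$labels)
  cls <- levels(result_a$labels)
  nr <- min(length(result_a$repetitions), length(result_b$repetitions))
  p <- matrix(NA_real_, nr, length(cls), dimnames = list(NULL, cls))
  for (ri in seq_len(nr)) {
    pa <- result_a$repetitions[[ri]]$predictions
    pb <- result_b$repetitions[[ri]]$predictions
    for (cc in cls) {
      p[ri, cc] <- delong_test(pa[, cc], pb[, cc], labs == cc)$p
    }
  }
  mean_p <- colMeans(p)
  structure(list(p = p, mean_p = mean_p, alpha = alpha,
                 significant = any(mean_p < alpha)),
            class = "tract_comparison")
}

#' @export
print.tract_comparison <- function(x, ...) {
  cat("<tract_comparison> per-class mean DeLong p:\n")
  print(round(x$mean_p, 4))
  cat(sprintf("  significant (any class mean p < %.2f): %s\n", x$alpha,
              x$significant))
  invisible(x)
}

#' Hyperparameter score: min x max x 1/variance
#'
#' Scores a collection of AUROCs (e.g., over tracts and repetitions for one
#' candidate setting) by the product of their minimum, maximum and inverse
#' population variance; the preferred setting maximizes this score.
#' Variances below `eps` are clamped to `eps`.
#'
#' @param aurocs numeric vector (length >= 2).
#' @param eps variance clamp (default 1e-12).
#' @return Scalar score.
#' @export
hyperparam_score <- function(aurocs, eps = 1e-12) {
  if (length(aurocs) < 2L) stop("need at least 2 values")
  v <- mean((aurocs - mean(aurocs))^2)
  min(aurocs) * max(aurocs) / max(v, eps)
}

#' Pick the candidate setting with the best hyperparameter score
#'
#' @param candidates named list of AUROC vectors, one per candidate.
#' @return Name of the argmax candidate, with the full score vector as
#'   attribute `scores`.
#' @export
hyperparam_select <- function(candidates) {
  scores <- vapply(candidates, hyperparam_score, numeric(1))
  structure(names(candidates)[which.max(scores)], scores = scores)
}

#' Aggregate random-forest feature importance by map, class and parcel
#'
#' Mean-decrease-in-impurity importances (averaged over folds and
#' repetitions) are parsed from the feature names
#' `{map}__parcel{i}__{class}__{feature}` and grouped by parameter map,
#' feature class, and parcel; both the group sum and the group mean are
#' reported.
#'
#' @param result a `tract_eval`, or a named importance vector.
#' @return List of data frames `by_map`, `by_class`, `by_parcel`, `by_feature`
#'   each with `group`, `sum`, `mean` columns.
#' @export
aggregate_importance <- function(result) {
  imp <- if (inherits(result, "tract_eval")) {
    rowMeans(result$importance)
  } else result
  parts <- strsplit(names(imp), "__", fixed = TRUE)
  ok <- lengths(parts) == 4L
  if (!all(ok)) stop("malformed feature name(s): ",
                     paste(utils::head(names(imp)[!ok], 3), collapse = ", "))
  f <- function(key) {
    g <- vapply(parts, `[[`, character(1), key)
    data.frame(group = sort(unique(g)),
               sum = as.vector(tapply(imp, g, sum)[sort(unique(g))]),
               mean = as.vector(tapply(imp, g, mean)[sort(unique(g))]),
               row.names = NULL)
  }
  list(by_map = f(1L), by_parcel = f(2L), by_class = f(3L),
       by_feature = f(4L))
}
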