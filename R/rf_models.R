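# Random-forest regression (predict log2 RE) and classification (High vs
# Low) with 5-fold cross-validation, NRMSE/AUROC reporting, and explicit
# permutation feature importance (%IncMSE, MDA).

#' Model specification for the forest analyses
#'
#' Defaults mirror the analysis design: 100 trees, an mtry grid running from
#' 1 to 81 in steps of 10 (clipped to the number of features), and 5-fold
#' cross-validation with the best mtry selected by mean CV metric.
#'
#' @param task `"regression"` or `"classification"`.
#' @param n_trees Number of trees per forest (default 100).
#' @param mtry_grid Candidate numbers of features tried at each split.
#' @param folds Number of cross-validation folds (default 5; stratified for
#'   classification).
#' @param seed Integer seed controlling folds, forests and permutations.
#' @param n_repeats Permutation repeats for importance (default 5).
#' @return An `rt_rf_spec` list.
#' @export
rf_spec <- function(task = c("regression", "classification"),
                    n_trees = 100L, mtry_grid = c(1L, seq(11L, 81L, 10L)),
                    folds = 5L, seed = 1L, n_repeats = 5L) {
  task <- match.arg(task)
  stopifnot(all(mtry_grid >= 1), folds >= 2)
  structure(list(task = task, n_trees = n_trees, mtry_grid = mtry_grid,
                 folds = folds, seed = seed, n_repeats = n_repeats),
            class = "rt_rf_spec")
}

#' Encode a feature matrix for the forest
#'
#' Categorical features become factors (the forest implementation splits on
#' them natively, so no one-hot expansion is needed and each encoded column
#' maps to exactly one original feature in the group map); numerics pass
#' through unchanged.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param schema Feature schema (default taken from the tibble's attribute).
#' @return List with `X` (data.frame), `group_map` (tibble `column`,
#'   `feature`), `ids`.
#' @export
encode_features <- function(features, schema = feature_schema(features)) {
  stopifnot(!is.null(schema))
  keep <- intersect(schema$feature, names(features))
  X <- as.data.frame(features[, keep, drop = FALSE])
  for (f in keep) {
    if (schema$type[schema$feature == f] == "categorical") {
      X[[f]] <- factor(X[[f]])
    } else {
      X[[f]] <- as.numeric(X[[f]])
    }
  }
  list(X = X, group_map = tibble(column = keep, feature = keep),
       ids = features$id)
}

#' Join features and readthrough estimates into model data
#'
#' Applies the missing-value policy: genes with any `NA` core sequence
#' feature are dropped (logged); `NA` external features (`mfe`,
#' `struct_distance`, `helix_fraction`) are median-imputed by default or
#' dropped via `na_external = "drop_genes"`; features that are entirely `NA`
#' are removed. For regression the response is the finite, filtered
#' `log2_re`; for classification only `High`/`Low` genes enter.
#'
#' @param features Feature tibble.
#' @param estimates Readthrough estimates with `passes_filter` and `group`
#'   assigned.
#' @param task `"regression"` or `"classification"`.
#' @param na_external `"impute"` (median, default) or `"drop_genes"`.
#' @return List `X` (data.frame), `y`, `ids`, `group_map`.
#' @export
prepare_rf_data <- function(features, estimates,
                            task = c("regression", "classification"),
                            na_external = c("impute", "drop_genes")) {
  task <- match.arg(task)
  na_external <- match.arg(na_external)
  schema <- feature_schema(features)
  est <- estimates %>% filter(.data$passes_filter %in% TRUE,
                              is.finite(.data$log2_re))
  if (task == "classification") {
    est <- est %>% filter(.data$group %in% c("High", "Low"))
  }
  dat <- features %>% inner_join(est %>% select("id", "log2_re", "group"),
                                 by = "id")
  external <- intersect(c("mfe", "struct_distance", "helix_fraction"),
                        schema$feature)
  core <- setdiff(schema$feature, external)
  all_na <- names(which(purrr::map_lgl(dat[schema$feature],
                                       ~ all(is.na(.x)))))
  if (length(all_na) > 0) {
    inform(paste0("dropping feature(s) with no observed values: ",
                  paste(all_na, collapse = ", ")))
    schema <- schema %>% filter(!.data$feature %in% all_na)
    external <- setdiff(external, all_na)
    core <- setdiff(core, all_na)
  }
  ok_core <- complete.cases(dat[, core, drop = FALSE])
  if (any(!ok_core)) {
    inform(paste0(sum(!ok_core),
                  " gene(s) dropped for missing core features"))
    dat <- dat[ok_core, , drop = FALSE]
  }
  if (length(external) > 0) {
    if (na_external == "impute") {
      for (f in external) {
        na_f <- is.na(dat[[f]])
        if (any(na_f)) dat[[f]][na_f] <- median(dat[[f]], na.rm = TRUE)
      }
    } else {
      ok <- complete.cases(dat[, external, drop = FALSE])
      dat <- dat[ok, , drop = FALSE]
    }
  }
  fm <- dat[, c("id", schema$feature)]
  attr(fm, "schema") <- schema
  enc <- encode_features(fm)
  y <- if (task == "regression") dat$log2_re else
    factor(dat$group, levels = c("Low", "High"))
  list(X = enc$X, y = y, ids = dat$id, group_map = enc$group_map)
}

#' Normalized root-mean-squared error
#'
#' RMSE divided by the range of the observed response (computed per
#' cross-validation fold by [cross_validated_rf()]).
#'
#' @param predicted,actual Numeric vectors.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(predicted, actual) {
  r <- diff(range(actual))
  if (r == 0) abort("actual values have zero range; NRMSE undefined")
  sqrt(mean((predicted - actual)^2)) / r
}

#' Area under the ROC curve
#'
#' Rank-sum formulation: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with ties counting one half.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical vector, or factor/character with `positive` naming
#'   the positive class.
#' @param positive Positive class label for non-logical `labels`
#'   (default `"High"`).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "High") {
  pos <- if (is.logical(labels)) labels else labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute AUROC")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

fold_assignment <- function(y, folds, stratify) {
  n <- length(y)
  if (!stratify) {
    sample(rep_len(seq_len(folds), n))
  } else {
    f <- integer(n)
    for (lv in unique(y)) {
      idx <- which(y == lv)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  }
}

#' Cross-validated random forest with mtry selection
#'
#' Runs k-fold cross-validation (stratified for classification) over the
#' mtry grid, selects the mtry with the best mean CV metric (lowest NRMSE or
#' highest AUROC), computes out-of-fit permutation importance on each held-out
#' fold at the chosen mtry, and refits a final forest on all data. Fully
#' seeded: identical inputs and spec give an identical report.
#'
#' @param X data.frame of encoded features (no `NA`).
#' @param y Numeric response (regression) or two-level factor with positive
#'   level `"High"` (classification).
#' @param spec An [rf_spec()].
#' @param compute_importance Compute per-fold permutation importance
#'   (default `TRUE`).
#' @return An object of class `rt_rf`; see [tidy.rt_rf()] and
#'   [glance.rt_rf()].
#' @export
cross_validated_rf <- function(X, y, spec, compute_importance = TRUE) {
  stopifnot(inherits(spec, "rt_rf_spec"), nrow(X) == length(y))
  if (anyNA(X)) abort("X must not contain NA (see prepare_rf_data)")
  if (nrow(X) < spec$folds * 2) abort("fewer than folds * 2 samples")
  task <- spec$task
  if (task == "classification" && nlevels(factor(y)) != 2) {
    abort("classification requires exactly two classes")
  }
  metric_name <- if (task == "regression") "NRMSE" else "AUROC"
  grid <- sort(unique(pmin(spec$mtry_grid, ncol(X))))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fold <- fold_assignment(y, spec$folds, stratify = task == "classification")
  fit_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(grid) * spec$folds),
                      nrow = length(grid))
  perm_seeds <- sample.int(.Machine$integer.max, spec$folds)

  eval_fold <- function(mtry, k, seed) {
    set.seed(seed)
    tr <- fold != k
    fit <- randomForest::randomForest(
      x = X[tr, , drop = FALSE], y = y[tr],
      ntree = spec$n_trees, mtry = mtry
    )
    if (task == "regression") {
      pred <- predict(fit, X[!tr, , drop = FALSE])
      list(fit = fit, value = nrmse(pred, y[!tr]))
    } else {
      prob <- predict(fit, X[!tr, , drop = FALSE], type = "prob")[, "High"]
      list(fit = fit, value = auroc(prob, y[!tr], positive = "High"))
    }
  }

  report <- tidyr::expand_grid(mtry = grid, fold = seq_len(spec$folds))
  fits <- vector("list", nrow(report))
  vals <- numeric(nrow(report))
  for (i in seq_len(nrow(report))) {
    gi <- match(report$mtry[i], grid)
    r <- eval_fold(report$mtry[i], report$fold[i], fit_seeds[gi, report$fold[i]])
    fits[[i]] <- r$fit
    vals[i] <- r$value
  }
  report$value <- vals
  by_mtry <- report %>% group_by(.data$mtry) %>%
    summarise(mean = mean(.data$value), .groups = "drop")
  best_mtry <- if (task == "regression") {
    by_mtry$mtry[which.min(by_mtry$mean)]
  } else {
    by_mtry$mtry[which.max(by_mtry$mean)]
  }
  chosen <- report %>% filter(.data$mtry == best_mtry)

  importance <- NULL
  if (compute_importance) {
    imp <- purrr::map(seq_len(spec$folds), function(k) {
      i <- which(report$mtry == best_mtry & report$fold == k)
      te <- fold == k
      permutation_importance(
        fits[[i]], X[te, , drop = FALSE], y[te], task = task,
        seed = perm_seeds[k], n_repeats = spec$n_repeats
      ) %>% mutate(fold = k)
    })
    importance <- bind_rows(imp)
  }

  set.seed(spec$seed + 1L)
  final <- randomForest::randomForest(x = X, y = y, ntree = spec$n_trees,
                                      mtry = best_mtry)
  structure(list(
    task = task, metric = metric_name, best_mtry = best_mtry,
    report = chosen %>% select("fold", "value") %>% mutate(metric = metric_name),
    tuning = report, metric_mean = mean(chosen$value),
    metric_sd = stats::sd(chosen$value),
    importance = importance, model = final, spec = spec, n = nrow(X)
  ), class = "rt_rf")
}

#' Out-of-fit permutation feature importance
#'
#' For each feature, permutes its column(s) jointly `n_repeats` times on the
#' supplied evaluation data, recomputes prediction error, and reports the
#' increase over the unpermuted baseline: percent increase in MSE for
#' regression (%IncMSE) and percentage-point increase in misclassification
#' for classification (MDA). Rankings, not absolute magnitudes, are the
#' meaningful output.
#'
#' @param model A fitted `randomForest`.
#' @param X Evaluation features (data.frame).
#' @param y Evaluation response.
#' @param task `"regression"` or `"classification"`.
#' @param seed Integer seed.
#' @param n_repeats Number of permutations per feature (default 5).
#' @param group_map Optional tibble `column`, `feature` mapping encoded
#'   columns to original features (columns of one feature are permuted
#'   jointly).
#' @return Tibble `feature`, `importance`, `metric`.
#' @export
permutation_importance <- function(model, X, y,
                                   task = c("regression", "classification"),
                                   seed = 1L, n_repeats = 5L,
                                   group_map = NULL) {
  task <- match.arg(task)
  if (is.null(group_map)) {
    group_map <- tibble(column = names(X), feature = names(X))
  }
  err <- function(Xe) {
    if (task == "regression") {
      mean((predict(model, Xe) - y)^2)
    } else {
      mean(predict(model, Xe) != y)
    }
  }
  base <- err(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  feats <- unique(group_map$feature)
  imp <- purrr::map_dbl(feats, function(f) {
    cols <- group_map$column[group_map$feature == f]
    deltas <- purrr::map_dbl(seq_len(n_repeats), function(r) {
      Xp <- X
      perm <- sample.int(nrow(X))
      Xp[cols] <- X[perm, cols, drop = FALSE]
      err(Xp)
    })
    mean(deltas)
  })
  value <- if (task == "regression") {
    if (base > 0) 100 * (imp - base) / base else 100 * (imp - base)
  } else {
    100 * (imp - base)
  }
  tibble(feature = feats, importance = value,
         metric = if (task == "regression") "%IncMSE" else "MDA")
}

#' @describeIn cross_validated_rf Per-feature permutation importance,
#'   averaged over folds (broom-style).
#' @param x An `rt_rf` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rt_rf <- function(x, ...) {
  if (is.null(x$importance)) {
    abort("model was fitted with compute_importance = FALSE")
  }
  x$importance %>%
    group_by(.data$feature, .data$metric) %>%
    summarise(sd = stats::sd(.data$importance),
              importance = mean(.data$importance), n_folds = n(),
              .groups = "drop") %>%
    select("feature", "metric", "importance", "sd", "n_folds") %>%
    arrange(dplyr::desc(.data$importance))
}

#' @describeIn cross_validated_rf One-row cross-validation summary
#'   (broom-style).
#' @exportS3Method generics::glance
glance.rt_rf <- function(x, ...) {
  tibble(task = x$task, metric = x$metric, mean = x$metric_mean,
         sd = x$metric_sd, mtry = x$best_mtry,
         n_trees = x$spec$n_trees, folds = x$spec$folds, n = x$n)
}

#' @export
print.rt_rf <- function(x, ...) {
  cat("Cross-validated random forest (", x$task, ")\n", sep = "")
  cat(sprintf("  %s = %.4f +/- %.4f over %d folds (mtry = %d, ntree = %d)\n",
              x$metric, x$metric_mean, x$metric_sd, x$spec$folds,
              x$best_mtry, x$spec$n_trees))
  invisible(x)
}
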