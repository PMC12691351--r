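#' Pipeline configuration for nested leave-one-out model building
#'
#' @param mrmr_k number of features kept by the MRMR filter (50).
#' @param sfs_k features selected by sequential forward selection (4).
#' @param complexity_range feature counts swept in the model-complexity
#'   analysis (3 to 7).
#' @param contamination isolation-forest contamination rate (0.05).
#' @param decision_threshold probability threshold for hard predictions.
#' @param mrmr_eps small constant in the relevance/(redundancy + eps)
#'   quotient.
#' @param smote_k SMOTE neighbor count (capped at minority size - 1).
#' @param n_trees_iforest isolation-forest ensemble size.
#' @param seed base seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mrmr_k = 50, sfs_k = 4, complexity_range = 3:7,
                            contamination = 0.05, decision_threshold = 0.5,
                            mrmr_eps = 1e-6, smote_k = 5,
                            n_trees_iforest = 100, seed = 1L) {
  stopifnot(sfs_k <= mrmr_k, all(complexity_range >= 1),
            contamination >= 0, contamination < 1)
  structure(list(mrmr_k = mrmr_k, sfs_k = sfs_k,
                 complexity_range = complexity_range,
                 contamination = contamination,
                 decision_threshold = decision_threshold,
                 mrmr_eps = mrmr_eps, smote_k = smote_k,
                 n_trees_iforest = n_trees_iforest, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Standardize features on a development set and apply to test rows
#'
#' Means and (population) standard deviations are fitted on the development
#' rows only and applied unchanged to the test rows (no leakage): a
#' development column `{1, 3}` maps to `{-1, 1}`. Zero-variance features get
#' unit divisor and are flagged.
#'
#' @param dev development matrix (rows samples).
#' @param test optional test matrix with the same columns.
#' @return list `dev`, `test`, `mean`, `sd`, `flagged` (zero-variance
#'   column indices).
#' @export
standardize_fit_apply <- function(dev, test = NULL) {
  stopifnot(nrow(dev) >= 2)
  mu <- colMeans(dev)
  sd_ <- sqrt(colMeans(sweep(dev, 2, mu)^2))
  flagged <- which(sd_ == 0 | !is.finite(sd_))
  sd_[flagged] <- 1
  scale_ <- function(m) sweep(sweep(m, 2, mu), 2, sd_, "/")
  list(dev = scale_(dev),
       test = if (!is.null(test)) scale_(test),
       mean = mu, sd = sd_, flagged = flagged)
}

# -- isolation forest ---------------------------------------------------------

.iforest_harmonic <- function(n) log(n) + 0.5772156649015329

.iforest_c <- function(n) {
  if (n <= 1) return(0)
  2 * .iforest_harmonic(n - 1) - 2 * (n - 1) / n
}

.iforest_tree <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1 || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  # random feature with spread among the subsample
  for (try in 1:10) {
    f <- sample.int(ncol(X), 1)
    lo <- min(X[idx, f]); hi <- max(X[idx, f])
    if (hi > lo) break
  }
  if (hi <= lo) return(list(leaf = TRUE, size = n))
  s <- stats::runif(1, lo, hi)
  left <- idx[X[idx, f] < s]
  right <- idx[X[idx, f] >= s]
  if (length(left) == 0 || length(right) == 0) {
    return(list(leaf = TRUE, size = n))
  }
  list(leaf = FALSE, feature = f, split = s,
       left = .iforest_tree(X, left, depth + 1, max_depth),
       right = .iforest_tree(X, right, depth + 1, max_depth))
}

.iforest_path <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + .iforest_c(tree$size))
  if (x[tree$feature] < tree$split) {
    .iforest_path(tree$left, x, depth + 1)
  } else {
    .iforest_path(tree$right, x, depth + 1)
  }
}

#' Isolation-forest outlier removal
#'
#' Random axis-aligned isolation trees; the anomaly score is
#' `2^(-E[path length]/c(psi))`. The `ceiling(contamination * n)` most
#' anomalous development rows are removed, unless removal would empty a
#' class, in which case that class's rows are retained with a warning.
#'
#' @param X development matrix (>= 10 rows).
#' @param y class labels (guards class survival).
#' @param contamination contamination rate.
#' @param seed integer seed; deterministic given the seed.
#' @param n_trees ensemble size.
#' @return list `keep` (retained row indices), `scores` (anomaly scores),
#'   `removed`.
#' @export
isolation_forest_outliers <- function(X, y, contamination = 0.05, seed = 1L,
                                      n_trees = 100L) {
  n <- nrow(X)
  stopifnot(n >= 10)
  m <- ceiling(contamination * n)
  if (m == 0) {
    return(list(keep = seq_len(n), scores = rep(0, n), removed = integer(0)))
  }
  set.seed(as.integer(seed))
  psi <- min(256L, n)
  max_depth <- ceiling(log2(psi))
  paths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    sub <- sample.int(n, psi)
    tree <- .iforest_tree(X, sub, 0, max_depth)
    for (i in seq_len(n)) paths[i, t] <- .iforest_path(tree, X[i, ])
  }
  scores <- 2^(-rowMeans(paths) / .iforest_c(psi))
  removed <- order(scores, decreasing = TRUE)[seq_len(m)]
  for (cl in unique(y)) {
    cls_rows <- which(y == cl)
    if (all(cls_rows %in% removed)) {
      warning("outlier removal would empty class ", cl, "; skipping its rows")
      removed <- setdiff(removed, cls_rows)
    }
  }
  list(keep = setdiff(seq_len(n), removed), scores = scores,
       removed = removed)
}

# -- MRMR ---------------------------------------------------------------------

# one-way ANOVA F statistic of each column against a binary class
.f_statistics <- function(X, y) {
  y <- as.integer(y)
  n <- nrow(X)
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  sst <- colSums(sweep(X, 2, m)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- ifelse(sst == 0, 0,
              ifelse(ssw == 0, Inf, ssb / (ssw / (n - 2))))
  f
}

#' Maximal-relevance minimal-redundancy feature selection
#'
#' Greedy forward selection: relevance is the one-way ANOVA F statistic of a
#' feature against the binary class; redundancy is the mean absolute Pearson
#' correlation with already-selected features; the next feature maximizes
#' `relevance / (redundancy + eps)`. The first feature is the most relevant;
#' ties break toward the lower column index. Constant features have zero
#' relevance and are never chosen before a non-constant feature.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param k number of features to select.
#' @param eps stabilizer in the quotient.
#' @return integer vector of selected column indices (ordered), with the
#'   selected names as names.
#' @export
mrmr_select <- function(X, y, k = 50, eps = 1e-6) {
  p <- ncol(X)
  stopifnot(k <= p)
  f <- .f_statistics(X, y)
  sel <- integer(0)
  red_sum <- rep(0, p)
  sdx <- apply(X, 2, stats::sd)
  for (step in seq_len(k)) {
    if (step == 1) {
      score <- f
    } else {
      last <- sel[length(sel)]
      r <- suppressWarnings(as.vector(stats::cor(X, X[, last])))
      r[!is.finite(r)] <- 0
      red_sum <- red_sum + abs(r)
      score <- f / (red_sum / length(sel) + eps)
    }
    score[sel] <- -Inf
    score[sdx == 0] <- pmin(score[sdx == 0], 0) # constants stay behind
    sel <- c(sel, which.max(score))
  }
  names(sel) <- colnames(X)[sel]
  sel
}

# -- SMOTE --------------------------------------------------------------------

#' SMOTE minority oversampling
#'
#' Synthetic minority samples on segments between a minority sample and one
#' of its k nearest minority neighbors: `x + u (x_nn - x)`, u ~ U(0,1).
#' Output classes have equal counts; already-balanced input is returned
#' unchanged. Deterministic per seed.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param k_neighbors neighbor count, capped at minority size - 1.
#' @param seed integer.
#' @return list `X`, `y`, `synthetic` (logical marker).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1L) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1] == tab[2]) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  minority <- if (tab[1] < tab[2]) 0L else 1L
  min_idx <- which(y == minority)
  if (length(min_idx) < 2) stop("cannot SMOTE a minority class of one sample")
  n_new <- abs(tab[1] - tab[2])
  k <- min(k_neighbors, length(min_idx) - 1)
  Xm <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  if (is.null(dim(nn))) nn <- matrix(nn, nrow = 1)
  set.seed(as.integer(seed))
  base <- sample(seq_along(min_idx), n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  newX <- Xm[base, , drop = FALSE] +
    u * (Xm[nn[cbind(pick, base)], , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, newX),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}

# -- classifiers --------------------------------------------------------------

#' Classifier specifications and hyperparameter grids
#'
#' The five classifiers of the evaluation: LDA, KNN, linear SVM, RBF SVM,
#' Random Forest. SVM variants and RF support class weighting (inverse class
#' frequency); LDA and KNN use SMOTE instead. Grids are modest, sized to a
#' ~30-sample cohort, and ordered so that ties in the inner search resolve
#' toward the simplest model (smallest C / k / trees).
#'
#' @param kind one of "lda", "knn", "svm-linear", "svm-rbf", "rf".
#' @param grid optional data.frame overriding the default grid.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "knn", "svm-linear", "svm-rbf",
                                     "rf"),
                            grid = NULL) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      "lda" = data.frame(dummy = 1),
      "knn" = data.frame(k = c(3, 5, 7)),
      "svm-linear" = data.frame(C = c(0.1, 1, 10, 100)),
      "svm-rbf" = {
        g <- expand.grid(C = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.1))
        g[order(g$C), ] # ascending C so ties pick the smaller C
      },
      "rf" = expand.grid(max_depth = c(2, 3, NA), n_trees = c(100, 300)))
  }
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  supports_cw <- kind %in% c("svm-linear", "svm-rbf", "rf")
  structure(list(kind = kind, grid = grid,
                 supports_class_weight = supports_cw,
                 imbalance = if (supports_cw) "class_weight" else "smote"),
            class = "classifier_spec")
}

.class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- length(y) / (2 * as.numeric(tab))
  names(w) <- c("0", "1")
  w
}

# fit one classifier; returns an object for .predict_score
.fit_classifier <- function(spec, params, X, y, seed = 1L) {
  y <- factor(y, levels = c(0, 1))
  set.seed(as.integer(seed))
  switch(spec$kind,
    "lda" = list(kind = "lda",
                 model = MASS::lda(X, grouping = y)),
    "knn" = list(kind = "knn", train = X, cl = y, k = params$k),
    "svm-linear" = ,
    "svm-rbf" = {
      gamma <- if (spec$kind == "svm-rbf") {
        if (is.na(params$gamma)) 1 / ncol(X) else params$gamma
      } else NULL
      m <- e1071::svm(X, y,
                      kernel = if (spec$kind == "svm-rbf") "radial"
                               else "linear",
                      cost = params$C,
                      gamma = if (is.null(gamma)) 1 / ncol(X) else gamma,
                      class.weights = .class_weights(y),
                      scale = FALSE)
      # orient decision values toward the positive class
      dv <- attr(stats::predict(m, X, decision.values = TRUE),
                 "decision.values")
      pos_is_first <- startsWith(colnames(dv)[1], "1")
      list(kind = "svm", model = m, flip = !pos_is_first)
    },
    "rf" = {
      maxnodes <- if (is.na(params$max_depth)) NULL else 2^params$max_depth
      list(kind = "rf",
           model = randomForest::randomForest(
             X, y, ntree = params$n_trees, maxnodes = maxnodes,
             classwt = .class_weights(y)))
    })
}

# probability-like score of the positive class for each row of X
.predict_score <- function(fit, X) {
  switch(fit$kind,
    "lda" = as.numeric(stats::predict(fit$model, X)$posterior[, "1"]),
    "knn" = {
      pr <- class::knn(fit$train, X, fit$cl, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    "svm" = {
      dv <- attr(stats::predict(fit$model, X, decision.values = TRUE),
                 "decision.values")[, 1]
      stats::plogis(if (fit$flip) -dv else dv)
    },
    "rf" = as.numeric(stats::predict(fit$model, X, type = "prob")[, "1"]))
}

# inner leave-one-out balanced accuracy for a feature subset + params
.inner_loocv_balacc <- function(spec, params, X, y, threshold = 0.5,
                                seed = 1L) {
  n <- nrow(X)
  preds <- integer(n)
  used <- logical(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) next
    fit <- .fit_classifier(spec, params, X[-i, , drop = FALSE], ytr,
                           seed = seed + i)
    preds[i] <- as.integer(.predict_score(fit, X[i, , drop = FALSE]) >=
                             threshold)
    used[i] <- TRUE
  }
  if (!any(used)) return(NA_real_)
  yy <- y[used]; pp <- preds[used]
  tp <- sum(pp == 1 & yy == 1); fn <- sum(pp == 0 & yy == 1)
  tn <- sum(pp == 0 & yy == 0); fp <- sum(pp == 1 & yy == 0)
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA
  spc <- if (tn + fp > 0) tn / (tn + fp) else NA
  mean(c(rec, spc), na.rm = TRUE)
}

#' Sequential forward feature selection by inner leave-one-out
#'
#' Greedily adds the feature whose addition maximizes the inner-LOOCV
#' balanced accuracy; ties break toward the lower column index; stops at `k`
#' features.
#'
#' @param X development matrix (preprocessed).
#' @param y labels.
#' @param spec `classifier_spec`.
#' @param params one row of the hyperparameter grid.
#' @param k subset size.
#' @param threshold decision threshold.
#' @param seed integer.
#' @return list `features` (column indices in selection order), `score`
#'   (inner balanced accuracy of the final subset).
#' @export
sfs_forward <- function(X, y, spec, params = spec$grid[1, , drop = FALSE],
                        k = 4, threshold = 0.5, seed = 1L) {
  p <- ncol(X)
  stopifnot(k <= p)
  sel <- integer(0)
  best <- NA_real_
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    scores <- rep(-Inf, length(cand))
    for (ci in seq_along(cand)) {
      cols <- c(sel, cand[ci])
      scores[ci] <- .inner_loocv_balacc(spec, params,
                                        X[, cols, drop = FALSE], y,
                                        threshold, seed)
    }
    pickat <- which.max(scores) # first max -> lowest index tie-break
    sel <- c(sel, cand[pickat])
    best <- scores[pickat]
  }
  list(features = sel, score = best)
}

#' Inner model search: grid search wrapped around SFS
#'
#' For each hyperparameter grid point, runs sequential forward selection and
#' scores the selected subset by inner-LOOCV balanced accuracy; returns the
#' best grid point (ties resolve to the earlier grid row, i.e. the simpler
#' model) refitted on the full development set.
#'
#' @param X development matrix.
#' @param y labels.
#' @param spec `classifier_spec`.
#' @param sfs_k subset size.
#' @param threshold decision threshold.
#' @param seed integer.
#' @return list `fit`, `params`, `features`, `inner_score`.
#' @export
inner_model_search <- function(X, y, spec, sfs_k = 4, threshold = 0.5,
                               seed = 1L) {
  stopifnot(nrow(X) >= 4)
  best <- NULL
  for (gi in seq_len(nrow(spec$grid))) {
    params <- spec$grid[gi, , drop = FALSE]
    res <- sfs_forward(X, y, spec, params, k = sfs_k, threshold = threshold,
                       seed = seed)
    if (is.null(best) || (!is.na(res$score) && res$score > best$score)) {
      best <- list(params = params, features = res$features,
                   score = res$score)
    }
  }
  fit <- .fit_classifier(spec, best$params,
                         X[, best$features, drop = FALSE], y, seed = seed)
  list(fit = fit, params = best$params, features = best$features,
       inner_score = best$score)
}

#' Nested leave-one-out cross-validation run
#'
#' The full protocol: for each outer fold, the left-out sample is isolated
#' and the development set goes through standardization, isolation-forest
#' outlier removal, MRMR filtering, imbalance handling (SMOTE or class
#' weights according to the classifier), and the inner grid search with
#' sequential forward selection; the refitted model scores the left-out
#' sample. Scores are thresholded and aggregated into a single confusion
#' matrix over all n folds.
#'
#' @param X cohort feature matrix (patients x features).
#' @param y binary labels (both classes present, n >= 4).
#' @param spec `classifier_spec`.
#' @param cfg `pipeline_config`.
#' @return object of class `cv_result`: per-fold selections, parameters and
#'   scores; aggregated counts; metric panel; per-feature selection
#'   frequency.
#' @export
nested_loocv_run <- function(X, y, spec = classifier_spec("svm-rbf"),
                             cfg = pipeline_config()) {
  n <- nrow(X)
  stopifnot(n >= 4, length(unique(y)) == 2)
  y <- as.integer(y)
  scores <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    dev_idx <- setdiff(seq_len(n), i)
    ydev <- y[dev_idx]
    if (length(unique(ydev)) < 2) {
      stop("development set of fold ", i, " lost a class entirely")
    }
    fold_seed <- cfg$seed + 7L * i
    st <- standardize_fit_apply(X[dev_idx, , drop = FALSE],
                                X[i, , drop = FALSE])
    Xd <- st$dev
    if (cfg$contamination > 0 && nrow(Xd) >= 10) {
      iso <- isolation_forest_outliers(Xd, ydev, cfg$contamination,
                                       seed = fold_seed,
                                       n_trees = cfg$n_trees_iforest)
      Xd <- Xd[iso$keep, , drop = FALSE]
      ydev <- ydev[iso$keep]
    }
    k_mrmr <- min(cfg$mrmr_k, ncol(Xd))
    sel <- mrmr_select(Xd, ydev, k = k_mrmr, eps = cfg$mrmr_eps)
    Xd <- Xd[, sel, drop = FALSE]
    if (spec$imbalance == "smote") {
      sm <- smote_oversample(Xd, ydev, k_neighbors = cfg$smote_k,
                             seed = fold_seed)
      Xd <- sm$X; ydev <- sm$y
    }
    ims <- inner_model_search(Xd, ydev, spec,
                              sfs_k = min(cfg$sfs_k, ncol(Xd)),
                              threshold = cfg$decision_threshold,
                              seed = fold_seed)
    test_row <- st$test[, sel[ims$features], drop = FALSE]
    scores[i] <- .predict_score(ims$fit, test_row)
    folds[[i]] <- list(features = names(sel)[ims$features],
                       params = ims$params, inner_score = ims$inner_score,
                       score = scores[i])
  }
  preds <- as.integer(scores >= cfg$decision_threshold)
  counts <- confusion_counts(preds, y)
  freq <- table(unlist(lapply(folds, `[[`, "features")))
  structure(list(folds = folds, scores = scores, predictions = preds,
                 counts = counts,
                 metrics = compute_metrics(counts, scores, y),
                 selection_frequency = sort(freq, decreasing = TRUE),
                 classifier = spec$kind, config = cfg),
            class = "cv_result")
}

#' Aggregate confusion counts from hard predictions
#' @param pred 0/1 predictions.
#' @param y 0/1 truth.
#' @return list TP, FP, TN, FN.
#' @export
confusion_counts <- function(pred, y) {
  list(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
       TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
}

#' AUROC by trapezoidal integration of the ROC curve
#' @param scores prediction scores.
#' @param labels 0/1 truth.
#' @return area in `[0, 1]`.
#' @export
auroc_trapezoid <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) return(NA_real_)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / P,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / N,
                numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step integration)
#' @param scores prediction scores.
#' @param labels 0/1 truth.
#' @return area in `[0, 1]`.
#' @export
auprc_step <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  # evaluate at distinct thresholds only
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Metric panel from confusion counts and prediction scores
#'
#' All seven count-based metrics as percentages, AUROC by trapezoidal ROC
#' integration, AUPRC by precision-recall step integration, 95% Wald
#' confidence intervals on each proportion (clipped to `[0, 100]`), and the
#' Hanley-McNeil standard error for the AUROC interval. Metrics with a zero
#' denominator are reported as NA.
#'
#' @param counts list with TP, FP, TN, FN.
#' @param scores optional scores for the AUC metrics.
#' @param labels optional 0/1 truth matching `scores`.
#' @return object of class `metrics_report` (a list; see fields).
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  prop <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  ci_wald <- function(pct, den) {
    if (is.na(pct) || den == 0) return(c(NA_real_, NA_real_))
    p <- pct / 100
    half <- 1.96 * sqrt(p * (1 - p) / den) * 100
    c(max(0, pct - half), min(100, pct + half))
  }
  recall <- prop(TP, TP + FN)
  specificity <- prop(TN, TN + FP)
  accuracy <- prop(TP + TN, n)
  balacc <- if (!is.na(recall) && !is.na(specificity)) {
    (recall + specificity) / 2
  } else NA_real_
  precision <- prop(TP, TP + FP)
  npv <- prop(TN, TN + FN)
  f1 <- if (!is.na(precision) && !is.na(recall) &&
            (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auroc <- auprc <- NA_real_
  auroc_ci <- c(NA_real_, NA_real_)
  if (!is.null(scores) && !is.null(labels)) {
    auroc <- auroc_trapezoid(scores, labels)
    auprc <- auprc_step(scores, labels)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (!is.na(auroc) && n1 > 0 && n0 > 0) {
      q1 <- auroc / (2 - auroc)
      q2 <- 2 * auroc^2 / (1 + auroc)
      se <- sqrt((auroc * (1 - auroc) + (n1 - 1) * (q1 - auroc^2) +
                    (n0 - 1) * (q2 - auroc^2)) / (n1 * n0))
      auroc_ci <- c(max(0, auroc - 1.96 * se), min(1, auroc + 1.96 * se))
    }
  }
  balacc_ci <- if (!is.na(balacc)) {
    se_r <- sqrt(recall / 100 * (1 - recall / 100) / (TP + FN))
    se_s <- sqrt(specificity / 100 * (1 - specificity / 100) / (TN + FP))
    half <- 1.96 * sqrt(se_r^2 + se_s^2) / 2 * 100
    c(max(0, balacc - half), min(100, balacc + half))
  } else c(NA_real_, NA_real_)
  structure(list(
    recall = recall, specificity = specificity, accuracy = accuracy,
    balanced_accuracy = balacc, precision = precision, npv = npv, f1 = f1,
    auroc = auroc, auprc = auprc,
    ci = list(recall = ci_wald(recall, TP + FN),
              specificity = ci_wald(specificity, TN + FP),
              accuracy = ci_wald(accuracy, n),
              balanced_accuracy = balacc_ci,
              precision = ci_wald(precision, TP + FP),
              npv = ci_wald(npv, TN + FN),
              f1 = ci_wald(f1, n),
              auroc = auroc_ci),
    counts = counts), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.0f%%", v)
  cat("recall ", pct(x$recall), "  specificity ", pct(x$specificity),
      "  accuracy ", pct(x$accuracy), "\nbalanced accuracy ",
      pct(x$balanced_accuracy), "  precision ", pct(x$precision),
      "  NPV ", pct(x$npv), "  F1 ", pct(x$f1), "\n", sep = "")
  if (!is.na(x$auroc)) {
    cat(sprintf("AUROC %.2f  AUPRC %.2f\n", x$auroc, x$auprc))
  }
  invisible(x)
}

#' Model-complexity sweep over the number of selected features
#'
#' One full nested LOOCV per feature count in the configured range, plus the
#' per-feature selection frequency across outer folds.
#'
#' @param X cohort feature matrix.
#' @param y labels.
#' @param spec `classifier_spec`.
#' @param cfg `pipeline_config`.
#' @return list with `table` (data.frame of metrics by feature count) and
#'   `runs` (the `cv_result` objects).
#' @export
complexity_sweep <- function(X, y, spec = classifier_spec("svm-rbf"),
                             cfg = pipeline_config()) {
  runs <- list()
  rows <- list()
  for (k in cfg$complexity_range) {
    cfg_k <- cfg
    cfg_k$sfs_k <- k
    res <- nested_loocv_run(X, y, spec, cfg_k)
    runs[[as.character(k)]] <- res
    m <- res$metrics
    rows[[as.character(k)]] <- data.frame(
      n_features = k, recall = m$recall, specificity = m$specificity,
      accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
      precision = m$precision, npv = m$npv, f1 = m$f1, auroc = m$auroc,
      auprc = m$auprc)
  }
  list(table = do.call(rbind, rows), runs = runs)
}
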