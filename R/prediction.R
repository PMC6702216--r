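# Balanced-ensemble random-forest functional prediction.

#' Sequential regression imputation
#'
#' Single chained imputation of missing feature values: missing cells are
#' initialized with the column median (mode for binary 0/1 features), then
#' features are visited in order of ascending missingness for `n_cycles`
#' cycles, each time re-predicting the missing cells from all other features
#' with a linear model (logistic for binary features, predictions rounded to
#' 0/1).
#'
#' @param features data.frame or matrix of numeric features (rownames =
#'   region ids); `NA` marks missing cells.
#' @param seed integer seed (procedure is deterministic; kept for interface
#'   stability).
#' @param n_cycles number of update cycles (default 10).
#' @return A complete data.frame of the same shape.
#' @export
impute_missing <- function(features, seed = 500L, n_cycles = 10L) {
  X <- as.data.frame(features)
  stopifnot(all(vapply(X, is.numeric, logical(1))))
  miss <- is.na(X)
  fully <- colSums(!miss) == 0
  if (any(fully))
    stop("fully missing column(s): ",
         paste(names(X)[fully], collapse = ", "))
  if (!any(miss)) return(X)
  set.seed(seed)
  is_bin <- vapply(X, function(v) all(stats::na.omit(v) %in% c(0, 1)),
                   logical(1))
  for (j in which(is_bin & colSums(miss) > 0)) {
    tab <- table(X[[j]])
    X[[j]][miss[, j]] <- as.numeric(names(tab)[which.max(tab)])
  }
  for (j in which(!is_bin & colSums(miss) > 0))
    X[[j]][miss[, j]] <- median(X[[j]], na.rm = TRUE)
  visit <- order(colSums(miss))
  visit <- visit[colSums(miss)[visit] > 0]
  for (cycle in seq_len(n_cycles)) {
    for (j in visit) {
      obs <- !miss[, j]
      dat <- X
      names(dat)[j] <- ".y"
      fit <- tryCatch(
        if (is_bin[j])
          suppressWarnings(glm(.y ~ ., data = dat[obs, , drop = FALSE],
                               family = stats::binomial()))
        else stats::lm(.y ~ ., data = dat[obs, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- suppressWarnings(
        predict(fit, newdata = dat[!obs, , drop = FALSE],
                type = "response"))
      if (is_bin[j]) pred <- as.numeric(pred > 0.5)
      pred[is.na(pred)] <- X[[j]][which(obs)[1]]
      X[[j]][!obs] <- pred
    }
  }
  X
}

#' Balanced benchmark datasets
#'
#' Draws `n_sets` balanced datasets, each containing `min(class sizes)`
#' members of every class sampled without replacement within a set; sets are
#' drawn independently. With equal class sizes every set is the full
#' benchmark.
#'
#' @param labels named character/factor vector: benchmark region id ->
#'   class.
#' @param n_sets number of balanced datasets.
#' @param seed integer seed.
#' @return A list of character vectors of region ids.
#' @export
make_balanced_datasets <- function(labels, n_sets, seed = 1L) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  cls <- split(names(labels), as.character(labels))
  if (length(cls) < 2 || any(lengths(cls) == 0))
    stop("need at least two non-empty classes")
  m <- min(lengths(cls))
  set.seed(seed)
  lapply(seq_len(n_sets), function(i)
    unlist(lapply(cls, function(ids) sample(ids, m)), use.names = FALSE))
}

resolve_mtry <- function(feat_prop, p) {
  if (identical(feat_prop, "sqrt")) return(max(1L, floor(sqrt(p))))
  if (identical(feat_prop, "log2")) return(max(1L, floor(log2(p))))
  max(1L, floor(as.numeric(feat_prop) * p))
}

# Fraction of trees voting `positive` for each row of newdata.
tree_vote_fraction <- function(rf, newdata, positive) {
  pr <- predict(rf, data = newdata, predict.all = TRUE, num.threads = 1)
  lev <- rf$forest$levels
  rowMeans(pr$predictions == which(lev == positive))
}

fit_forest <- function(X, y, n_trees, max_depth, feat_prop, seed) {
  dat <- X
  dat$.class <- factor(y)
  ranger::ranger(.class ~ ., data = dat, num.trees = n_trees,
                 mtry = resolve_mtry(feat_prop, ncol(X)),
                 max.depth = max_depth, num.threads = 1, seed = seed)
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (ids in split(seq_along(labels), as.character(labels)))
    fold[ids] <- sample(rep_len(seq_len(k), length(ids)))
  fold
}

#' Two-class balanced random-forest ensemble
#'
#' For each balanced dataset, benchmark members of the set are scored
#' out-of-fold under stratified cross-validation, and every other region is
#' scored by a forest trained on the full balanced set. A region's score in
#' one dataset is the fraction of the forest's trees voting the functional
#' class.
#'
#' @param features complete feature data.frame (rownames = region ids; see
#'   [impute_missing()]).
#' @param labels named vector: benchmark region id -> class; the class named
#'   by `positive` is the functional one.
#' @param balanced_sets list of id vectors from [make_balanced_datasets()].
#' @param cv_folds cross-validation folds (default 10).
#' @param n_trees trees per forest (default 500).
#' @param max_depth maximum tree depth (default 10).
#' @param feat_prop proportion of features tried per split (default 0.25;
#'   `"sqrt"` and `"log2"` also accepted).
#' @param positive functional class label (default `"phenotype_exon"`).
#' @param seed integer seed.
#' @return Numeric matrix of scores: one row per region in `features`, one
#'   column per balanced set.
#' @export
train_two_class <- function(features, labels, balanced_sets, cv_folds = 10L,
                            n_trees = 500L, max_depth = 10L,
                            feat_prop = 0.25, positive = "phenotype_exon",
                            seed = 1L) {
  X <- as.data.frame(features)
  stopifnot(!is.null(rownames(X)), all(names(labels) %in% rownames(X)),
            !anyNA(X))
  scores <- matrix(NA_real_, nrow(X), length(balanced_sets),
                   dimnames = list(rownames(X), NULL))
  for (s in seq_along(balanced_sets)) {
    ids <- balanced_sets[[s]]
    y <- labels[ids]
    if (length(ids) < cv_folds)
      stop("balanced set smaller than the number of folds")
    fold <- stratified_folds(y, cv_folds, derive_seed(seed, paste0("fold", s)))
    for (f in seq_len(cv_folds)) {
      tr <- ids[fold != f]
      te <- ids[fold == f]
      if (length(te) == 0) next
      rf <- fit_forest(X[tr, , drop = FALSE], labels[tr], n_trees, max_depth,
                       feat_prop, derive_seed(seed, sprintf("s%df%d", s, f)))
      scores[te, s] <- tree_vote_fraction(rf, X[te, , drop = FALSE], positive)
    }
    rest <- setdiff(rownames(X), ids)
    if (length(rest)) {
      rf_full <- fit_forest(X[ids, , drop = FALSE], y, n_trees, max_depth,
                            feat_prop, derive_seed(seed, paste0("full", s)))
      scores[rest, s] <- tree_vote_fraction(rf_full, X[rest, , drop = FALSE],
                                            positive)
    }
  }
  scores
}

#' Functional likelihood
#'
#' The median of a region's per-balanced-set prediction scores (even counts:
#' mean of the central pair).
#'
#' @param scores numeric vector of per-set scores for one region, or the
#'   score matrix from [train_two_class()] (rows = regions).
#' @return A single value, or a named vector for a matrix input.
#' @export
functional_likelihood <- function(scores) {
  if (is.matrix(scores)) {
    if (ncol(scores) == 0) stop("no scores")
    return(apply(scores, 1, median, na.rm = TRUE))
  }
  if (length(scores) == 0) stop("no scores")
  median(scores, na.rm = TRUE)
}

#' Calibrate functional-likelihood thresholds
#'
#' T1 is the ascending nearest-rank 95th percentile of the nonfunctional
#' class's likelihoods: calling regions functional only above T1 misclassifies
#' at most 5% of nonfunctional benchmark regions (5% false positive rate).
#' T2 is the nearest-rank 5th percentile of the functional class's
#' likelihoods: calling regions nonfunctional only below T2 misclassifies at
#' most 5% of functional regions (5% false negative rate).
#'
#' @param likelihoods named numeric vector of benchmark functional
#'   likelihoods.
#' @param labels named vector of benchmark classes.
#' @param positive functional class label (default `"phenotype_exon"`).
#' @return A list of class `threshold_pair` with elements `T1` and `T2`.
#' @export
calibrate_thresholds <- function(likelihoods, labels,
                                 positive = "phenotype_exon") {
  lab <- as.character(labels[names(likelihoods)])
  pos <- likelihoods[lab == positive]
  neg <- likelihoods[lab != positive]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both benchmark classes must be present")
  thr <- list(T1 = nearest_rank(neg, 95), T2 = nearest_rank(pos, 5))
  if (thr$T2 > thr$T1)
    warning("T2 exceeds T1: classes overlap strongly; the ambiguous zone is empty",
            call. = FALSE)
  class(thr) <- "threshold_pair"
  thr
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("thresholds: T1 = %.3f (5%% FPR), T2 = %.3f (5%% FNR)\n",
              x$T1, x$T2))
  invisible(x)
}

#' Classify regions by functional likelihood
#'
#' Likelihoods strictly above T1 are `functional`, strictly below T2 are
#' `pseudogene-like`, and everything between (including exact threshold
#' equality) is `ambiguous`.
#'
#' @param likelihood numeric vector of functional likelihoods.
#' @param thresholds a [calibrate_thresholds()] result.
#' @return Character vector of final classes.
#' @export
classify_likelihood <- function(likelihood, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  ifelse(likelihood > thresholds$T1, "functional",
         ifelse(likelihood < thresholds$T2, "pseudogene-like", "ambiguous"))
}

#' Three-class balanced random-forest ensemble
#'
#' Distinguishes phenotype exons, transcribed pseudogenes and transcribed
#' miRNAs. Benchmark regions are scored out-of-fold under stratified
#' cross-validation; within each fold, `sets_per_fold` balanced training sets
#' (equal members of all three classes, limited by the rarest class) are
#' drawn and per-class tree-vote fractions are averaged across the sets.
#' Predicted class is the argmax (exact ties broken toward the pseudogene
#' class); regions predicted phenotype-exon or miRNA are functional.
#'
#' @param features complete feature data.frame (rownames = region ids).
#' @param labels named vector with the three benchmark classes.
#' @param cv_folds folds (default 20).
#' @param sets_per_fold balanced sets per fold (default 250).
#' @param n_trees,max_depth,feat_prop forest parameters as in
#'   [train_two_class()].
#' @param pseudogene_class tie-break class (default
#'   `"transcribed_pseudogene"`).
#' @param seed integer seed.
#' @return A data.frame: `region_id`, one score column per class (summing to
#'   1), `predicted_class`, `functional` (logical).
#' @export
train_three_class <- function(features, labels, cv_folds = 20L,
                              sets_per_fold = 250L, n_trees = 500L,
                              max_depth = 10L, feat_prop = 0.25,
                              pseudogene_class = "transcribed_pseudogene",
                              seed = 1L) {
  X <- as.data.frame(features)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 3) stop("need exactly three benchmark classes")
  if (min(table(labels)) < cv_folds)
    warning("a class is smaller than the fold count; stratified folds leave ",
            "some folds without that class", call. = FALSE)
  ids <- names(labels)
  stopifnot(all(ids %in% rownames(X)))
  fold <- stratified_folds(labels, cv_folds, derive_seed(seed, "folds3"))
  votes <- matrix(0, length(ids), 3, dimnames = list(ids, classes))
  nsets <- matrix(0, length(ids), 1, dimnames = list(ids, NULL))
  for (f in seq_len(cv_folds)) {
    tr_ids <- ids[fold != f]
    te_ids <- ids[fold == f]
    if (length(te_ids) == 0) next
    sets <- make_balanced_datasets(labels[tr_ids], sets_per_fold,
                                   derive_seed(seed, paste0("sets", f)))
    for (s in seq_along(sets)) {
      rf <- fit_forest(X[sets[[s]], , drop = FALSE], labels[sets[[s]]],
                       n_trees, max_depth, feat_prop,
                       derive_seed(seed, sprintf("f%ds%d", f, s)))
      pr <- predict(rf, data = X[te_ids, , drop = FALSE],
                    predict.all = TRUE, num.threads = 1)
      lev <- rf$forest$levels
      for (ci in seq_along(classes))
        votes[te_ids, classes[ci]] <- votes[te_ids, classes[ci]] +
          rowMeans(pr$predictions == which(lev == classes[ci]))
      nsets[te_ids, 1] <- nsets[te_ids, 1] + 1
    }
  }
  sc <- votes / pmax(nsets[, 1], 1)
  pred <- apply(sc, 1, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1 && pseudogene_class %in% classes[top])
      pseudogene_class
    else classes[top[1]]
  })
  data.frame(region_id = ids, sc, predicted_class = pred,
             functional = pred != pseudogene_class,
             row.names = NULL, check.names = FALSE)
}

#' AUC-ROC and precision-recall evaluation
#'
#' AUC-ROC is computed from the rank statistic with midrank tie handling
#' (equivalent to the Mann-Whitney U statistic); the precision-recall curve
#' enumerates every observed score threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or two-level) vector; `TRUE` / the `positive`
#'   level marks the functional class.
#' @param positive positive level when `labels` is not logical.
#' @return A list with `auc` and a data.frame `pr` (`threshold`, `precision`,
#'   `recall`).
#' @export
evaluate_model <- function(scores, labels, positive = "phenotype_exon") {
  if (!is.logical(labels)) labels <- as.character(labels) == positive
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks for ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pr <- do.call(rbind, lapply(thr, function(t) {
    call_pos <- scores >= t
    tp <- sum(call_pos & labels)
    data.frame(threshold = t,
               precision = if (sum(call_pos) == 0) NA_real_
                           else tp / sum(call_pos),
               recall = tp / n1)
  }))
  list(auc = auc, pr = pr)
}

# Quantile normalization: reference = mean of sorted feature columns learned
# on the training table; applied to new data by interpolation.
quantile_normalize_fit <- function(train) {
  train <- as.matrix(train)
  list(reference = rowMeans(apply(train, 2, sort)),
       sorted_cols = apply(train, 2, sort))
}

quantile_normalize_apply <- function(fit, newdata) {
  newdata <- as.matrix(newdata)
  out <- newdata
  for (j in seq_len(ncol(newdata))) {
    xs <- fit$sorted_cols[, j]
    if (length(unique(xs)) < 2) {
      out[, j] <- mean(fit$reference)
    } else {
      out[, j] <- stats::approx(xs, fit$reference, xout = newdata[, j],
                                rule = 2, ties = mean)$y
    }
  }
  out
}

#' Compare random forest with logistic regression and LASSO-selected models
#'
#' Repeated bootstrap comparison: in each repeat a balanced test set
#' (`n_test_per_class` per class) and a disjoint balanced training set
#' (`n_train_per_class` per class) are drawn, features are quantile
#' normalized (reference learned on the training split only), and AUC-ROC on
#' the test split is recorded for a full random forest, a logistic
#' regression, and a random forest restricted to LASSO-selected features at
#' each lambda. A lambda that selects zero features falls back to an
#' uninformative constant score with a warning.
#'
#' @param features complete feature data.frame (rownames = region ids).
#' @param labels named two-class vector.
#' @param n_boot repeats (default 100).
#' @param n_test_per_class,n_train_per_class split sizes (defaults 25 / 225).
#' @param lasso_lambdas LASSO penalties (default `c(1e-2, 5e-2)`).
#' @param n_trees,max_depth,feat_prop forest parameters.
#' @param positive functional class label.
#' @param seed integer seed.
#' @return A list with `aucs` (data.frame: `repeat_id`, `arm`, `auc`,
#'   `n_features`) and `tests` (rank-sum comparisons of each arm against the
#'   full random forest).
#' @export
compare_algorithms <- function(features, labels, n_boot = 100L,
                               n_test_per_class = 25L,
                               n_train_per_class = 225L,
                               lasso_lambdas = c(1e-2, 5e-2),
                               n_trees = 500L, max_depth = 10L,
                               feat_prop = 0.25,
                               positive = "phenotype_exon", seed = 1L) {
  X <- as.data.frame(features)
  cls <- split(names(labels), as.character(labels))
  if (length(cls) != 2) stop("need exactly two classes")
  if (any(lengths(cls) < n_test_per_class + n_train_per_class))
    stop("class sizes insufficient for the requested train/test split")
  rows <- list()
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, paste0("boot", b)))
    test_ids <- unlist(lapply(cls, sample, n_test_per_class))
    train_ids <- unlist(lapply(cls, function(ids)
      sample(setdiff(ids, test_ids), n_train_per_class)))
    qn <- quantile_normalize_fit(X[train_ids, , drop = FALSE])
    Xtr <- as.data.frame(quantile_normalize_apply(
      qn, X[train_ids, , drop = FALSE]))
    Xte <- as.data.frame(quantile_normalize_apply(
      qn, X[test_ids, , drop = FALSE]))
    rownames(Xtr) <- train_ids
    rownames(Xte) <- test_ids
    ytr <- labels[train_ids]
    yte <- as.character(labels[test_ids]) == positive

    rf <- fit_forest(Xtr, ytr, n_trees, max_depth, feat_prop,
                     derive_seed(seed, paste0("rf", b)))
    sc_rf <- tree_vote_fraction(rf, Xte, positive)
    rows[[length(rows) + 1]] <- data.frame(
      repeat_id = b, arm = "random_forest",
      auc = evaluate_model(sc_rf, yte)$auc, n_features = ncol(X))

    lfit <- suppressWarnings(glm(
      I(as.character(ytr) == positive) ~ ., data = Xtr,
      family = stats::binomial()))
    sc_lr <- suppressWarnings(predict(lfit, newdata = Xte, type = "response"))
    rows[[length(rows) + 1]] <- data.frame(
      repeat_id = b, arm = "logistic",
      auc = evaluate_model(sc_lr, yte)$auc, n_features = ncol(X))

    gl <- glmnet::glmnet(as.matrix(Xtr),
                         factor(as.character(ytr) == positive),
                         family = "binomial")
    for (la in lasso_lambdas) {
      co <- as.matrix(coef(gl, s = la))
      sel <- rownames(co)[-1][co[-1, 1] != 0]
      arm <- sprintf("rf_lasso_%g", la)
      if (length(sel) == 0) {
        warning("lambda = ", la, " selected zero features; ",
                "falling back to an uninformative model", call. = FALSE)
        auc <- 0.5
      } else {
        rf_l <- fit_forest(Xtr[, sel, drop = FALSE], ytr, n_trees, max_depth,
                           feat_prop, derive_seed(seed, paste0(arm, b)))
        auc <- evaluate_model(
          tree_vote_fraction(rf_l, Xte[, sel, drop = FALSE], positive),
          yte)$auc
      }
      rows[[length(rows) + 1]] <- data.frame(
        repeat_id = b, arm = arm, auc = auc, n_features = length(sel))
    }
  }
  aucs <- do.call(rbind, rows)
  other <- setdiff(unique(aucs$arm), "random_forest")
  tests <- do.call(rbind, lapply(other, function(a) {
    w <- suppressWarnings(wilcox.test(
      aucs$auc[aucs$arm == "random_forest"], aucs$auc[aucs$arm == a]))
    data.frame(arm = a, p_value = w$p.value,
               median_auc = median(aucs$auc[aucs$arm == a]),
               median_auc_rf = median(aucs$auc[aucs$arm == "random_forest"]))
  }))
  list(aucs = aucs, tests = tests)
}

#' Two-class parameter sweep
#'
#' Cross-validated AUC for every combination of maximum tree depth and
#' feature proportion, using a reduced number of balanced sets.
#'
#' @param features,labels as in [train_two_class()].
#' @param depths depth grid (default `c(3, 5, 10, 50)`).
#' @param feat_props feature-proportion grid (default
#'   `list(0.10, 0.25, 0.50, 0.75, "sqrt", "log2")`).
#' @param n_sets balanced sets per grid cell (default 3).
#' @param cv_folds,n_trees,positive,seed as in [train_two_class()].
#' @return data.frame: `max_depth`, `feat_prop`, `auc`.
#' @export
sweep_two_class <- function(features, labels, depths = c(3, 5, 10, 50),
                            feat_props = list(0.10, 0.25, 0.50, 0.75,
                                              "sqrt", "log2"),
                            n_sets = 3L, cv_folds = 10L, n_trees = 500L,
                            positive = "phenotype_exon", seed = 1L) {
  grid <- expand.grid(d = depths, p = seq_along(feat_props))
  bench <- names(labels)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sets <- make_balanced_datasets(labels, n_sets,
                                   derive_seed(seed, paste0("sw", g)))
    sc <- train_two_class(features[bench, , drop = FALSE], labels, sets,
                          cv_folds = cv_folds, n_trees = n_trees,
                          max_depth = grid$d[g],
                          feat_prop = feat_props[[grid$p[g]]],
                          positive = positive,
                          seed = derive_seed(seed, paste0("swt", g)))
    lik <- functional_likelihood(sc)
    data.frame(max_depth = grid$d[g],
               feat_prop = as.character(feat_props[[grid$p[g]]]),
               auc = evaluate_model(lik[bench],
                                    as.character(labels) == positive)$auc)
  }))
}
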