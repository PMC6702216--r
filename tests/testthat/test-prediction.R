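# small separable feature table for fast ensemble checks
separable_table <- function(n_per_class = 40, p = 6, gap = 3, seed = 51) {
  set.seed(seed)
  lab <- two_class_labels(n_per_class, n_per_class)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  X[seq_len(n_per_class), 1:2] <- X[seq_len(n_per_class), 1:2] + gap
  X <- as.data.frame(X)
  rownames(X) <- names(lab)
  list(X = X, labels = lab)
}

test_that("imputation fills missing cells and respects structure", {
  set.seed(52)
  X <- data.frame(a = rnorm(50), c = round(runif(50)))
  X$b <- 2 * X$a + rnorm(50, sd = 1e-6)   # collinear with a
  X_miss <- X
  X_miss$b[7] <- NA
  got <- impute_missing(X_miss)
  expect_false(anyNA(got))
  # the imputed value matches the direct regression prediction
  direct <- predict(lm(b ~ a + c, data = X_miss[-7, ]),
                    newdata = X_miss[7, ])
  expect_equal(got$b[7], unname(direct), tolerance = 1e-3)
  # a complete table is returned unchanged
  expect_identical(impute_missing(X), X)
  # binary columns stay binary
  Xb <- X
  Xb$c[3] <- NA
  expect_true(impute_missing(Xb)$c[3] %in% c(0, 1))
  X_bad <- X
  X_bad$a <- NA_real_
  expect_error(impute_missing(X_bad), "fully missing")
})

test_that("balanced datasets equalize class sizes without replacement", {
  lab <- two_class_labels(513, 262)
  sets <- make_balanced_datasets(lab, 5, seed = 2)
  expect_equal(length(sets), 5L)
  for (s in sets) {
    expect_equal(length(s), 2 * 262)
    expect_false(anyDuplicated(s) > 0)
    expect_equal(as.integer(table(lab[s])), c(262L, 262L))
  }
  # equal classes: every set is the full benchmark
  lab_eq <- two_class_labels(50, 50)
  s_eq <- make_balanced_datasets(lab_eq, 3, seed = 1)
  expect_true(all(vapply(s_eq, function(s) setequal(s, names(lab_eq)),
                         logical(1))))
  expect_identical(make_balanced_datasets(lab, 4, seed = 9),
                   make_balanced_datasets(lab, 4, seed = 9))
  expect_error(make_balanced_datasets(lab, 0), "n_sets")
})

test_that("functional likelihood is the median of per-set scores", {
  expect_equal(functional_likelihood(c(0.2, 0.5, 0.9)), 0.5)
  expect_equal(functional_likelihood(c(0.4, 0.6)), 0.5)
  expect_equal(functional_likelihood(rep(0.3, 7)), 0.3)
  m <- matrix(c(0.2, 0.5, 0.9, 0.1, 0.1, 0.7), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(functional_likelihood(m), c(a = 0.5, b = 0.1))
  expect_error(functional_likelihood(numeric(0)), "no scores")
  # invariant to permuting the balanced-set order
  set.seed(53)
  v <- runif(25)
  expect_equal(functional_likelihood(v), functional_likelihood(sample(v)))
})

test_that("threshold calibration uses nearest-rank percentiles", {
  lik <- c(seq(0.01, 1, by = 0.01),            # 100 pseudogene scores
           seq(0.5, 1, length.out = 50))       # functional scores
  lab <- stats::setNames(rep(c("transcribed_pseudogene", "phenotype_exon"),
                             c(100, 50)), paste0("r", seq_along(lik)))
  names(lik) <- names(lab)
  thr <- calibrate_thresholds(lik, lab)
  expect_equal(thr$T1, 0.95)
  # perfectly separated small classes: zero realized error rates
  # (with n = 15 the nearest-rank 95th percentile is the class maximum)
  lab2 <- two_class_labels(15, 15)
  lik2 <- stats::setNames(c(runif(15, 0.7, 1), runif(15, 0, 0.3)),
                          names(lab2))
  # fully separated classes leave no ambiguous zone (T2 above T1)
  expect_warning(thr2 <- calibrate_thresholds(lik2, lab2), "T2 exceeds T1")
  pos <- lik2[lab2 == "phenotype_exon"]
  neg <- lik2[lab2 != "phenotype_exon"]
  expect_equal(mean(neg > thr2$T1), 0)
  expect_equal(mean(pos < thr2$T2), 0)
  expect_error(calibrate_thresholds(lik[1:100], lab[1:100]), "classes")
})

test_that("classification brackets the ambiguous zone with strict inequalities", {
  thr <- structure(list(T1 = 0.6, T2 = 0.29), class = "threshold_pair")
  expect_equal(classify_likelihood(c(0.99, 0.10, 0.45, 0.6, 0.29), thr),
               c("functional", "pseudogene-like", "ambiguous",
                 "ambiguous", "ambiguous"))
})

test_that("AUC matches the Mann-Whitney statistic and PR endpoints", {
  expect_equal(evaluate_model(c(0.9, 0.8, 0.2, 0.1),
                              c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(evaluate_model(c(0.1, 0.2, 0.8, 0.9),
                              c(TRUE, TRUE, FALSE, FALSE))$auc, 0)
  set.seed(54)
  for (i in 1:10) {
    sc <- round(runif(30), 2)   # rounded scores force ties
    lb <- runif(30) < 0.4
    if (!any(lb) || all(lb)) next
    u <- unname(suppressWarnings(
      wilcox.test(sc[lb], sc[!lb])$statistic))
    expect_equal(evaluate_model(sc, lb)$auc, u / (sum(lb) * sum(!lb)))
  }
  # random scores hover near 0.5
  set.seed(55)
  aucs <- replicate(50, evaluate_model(runif(60), rep(c(TRUE, FALSE), 30))$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
  expect_error(evaluate_model(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("the two-class ensemble separates planted classes", {
  st <- separable_table()
  sets <- make_balanced_datasets(st$labels, 3, seed = 3)
  sc <- train_two_class(st$X, st$labels, sets, cv_folds = 5, n_trees = 100,
                        seed = 4)
  expect_equal(dim(sc), c(80L, 3L))
  expect_true(all(sc >= 0 & sc <= 1))
  lik <- functional_likelihood(sc)
  auc <- evaluate_model(lik[names(st$labels)],
                        st$labels == "phenotype_exon",
                        positive = TRUE)$auc
  expect_gt(auc, 0.95)
  expect_error(train_two_class(st$X, st$labels, list(names(st$labels)[1:4]),
                               cv_folds = 10), "smaller")
})

test_that("the three-class ensemble recovers separated classes", {
  set.seed(56)
  n <- 30
  lab <- stats::setNames(
    rep(c("phenotype_exon", "transcribed_pseudogene", "transcribed_miRNA"),
        each = n), sprintf("t%03d", seq_len(3 * n)))
  X <- matrix(rnorm(3 * n * 5), 3 * n, 5)
  X[1:n, 1] <- X[1:n, 1] + 4
  X[(n + 1):(2 * n), 2] <- X[(n + 1):(2 * n), 2] + 4
  X[(2 * n + 1):(3 * n), 3] <- X[(2 * n + 1):(3 * n), 3] + 4
  X <- as.data.frame(X)
  rownames(X) <- names(lab)
  out <- train_three_class(X, lab, cv_folds = 5, sets_per_fold = 5,
                           n_trees = 100, seed = 6)
  score_cols <- c("phenotype_exon", "transcribed_pseudogene",
                  "transcribed_miRNA")
  expect_equal(unname(rowSums(out[, score_cols])), rep(1, 3 * n),
               tolerance = 1e-9)
  recall <- vapply(score_cols, function(cl)
    mean(out$predicted_class[lab[out$region_id] == cl] == cl), numeric(1))
  expect_true(all(recall > 1 / 3))
  # exon- and miRNA-predicted regions are functional
  expect_equal(out$functional,
               out$predicted_class != "transcribed_pseudogene")
})

test_that("algorithm comparison runs all arms and handles empty LASSO", {
  st <- separable_table(n_per_class = 40, gap = 4)
  out <- compare_algorithms(st$X, st$labels, n_boot = 2,
                            n_test_per_class = 10, n_train_per_class = 25,
                            lasso_lambdas = c(1e-2), n_trees = 100,
                            seed = 7)
  expect_setequal(unique(out$aucs$arm),
                  c("random_forest", "logistic", "rf_lasso_0.01"))
  expect_true(all(out$aucs$auc > 0.9))
  # a huge lambda selects nothing and falls back with a warning
  expect_warning(
    out2 <- compare_algorithms(st$X, st$labels, n_boot = 1,
                               n_test_per_class = 10,
                               n_train_per_class = 25,
                               lasso_lambdas = c(50), n_trees = 50,
                               seed = 8),
    "zero features")
  expect_equal(out2$aucs$auc[out2$aucs$arm == "rf_lasso_50"], 0.5)
})
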