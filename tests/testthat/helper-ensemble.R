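# Shared benchmark ensemble run used by several acceptance checks.
# Computed once per test session: a 300/300/30 synthetic benchmark
# (generator defaults, fixed seed), imputation, and the reduced two-class
# ensemble (25 balanced sets, 10-fold cross-validation).

.ensemble_cache <- new.env(parent = emptyenv())

benchmark_run <- function() {
  if (!is.null(.ensemble_cache$run)) return(.ensemble_cache$run)
  cfg <- scenario_config()
  labels <- stats::setNames(
    rep(c("phenotype_exon", "transcribed_pseudogene", "transcribed_miRNA"),
        c(300, 300, 30)), sprintf("bench_%04d", 1:630))
  gen <- generate_feature_table(labels, cfg, seed = 11)
  X <- impute_missing(gen$features, seed = 500)
  lab2 <- labels[labels != "transcribed_miRNA"]
  sets <- make_balanced_datasets(lab2, 25, seed = 11)
  scores <- train_two_class(X[names(lab2), ], lab2, sets,
                            cv_folds = 10, seed = 11)
  lik <- functional_likelihood(scores)
  .ensemble_cache$run <- list(config = cfg, labels = labels, lab2 = lab2,
                              features = X, likelihood = lik)
  .ensemble_cache$run
}
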