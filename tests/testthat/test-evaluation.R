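test_that("performance indicators follow their definitions", {
  perfect <- compute_metrics(confusion_counts(rep(c("SCZ", "HC"), each = 5),
                                              rep(c("SCZ", "HC"), each = 5)))
  expect_equal(perfect$balanced_accuracy, 100)
  expect_equal(perfect$error_rate, 0)

  cc <- confusion_counts(rep(c(1, 0), each = 10), rep(c(1, 0, 1, 0), each = 5))
  m <- compute_metrics(cc)
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 50)
  expect_equal(m$balanced_accuracy, 50)
  expect_equal(m$error_rate, 50)

  cc2 <- structure(list(TP = 70, TN = 40, FP = 60, FN = 30),
                   class = "confusion_counts")
  m2 <- compute_metrics(cc2)
  expect_equal(m2$sensitivity, 70)
  expect_equal(m2$specificity, 40)
  expect_equal(m2$balanced_accuracy, 55)
  expect_equal(m2$error_rate, 45)

  # undefined, not zero, when a class is absent
  none <- confusion_counts(rep("HC", 4), rep("HC", 4))
  expect_true(is.na(compute_metrics(none)$sensitivity))
})

test_that("AUC equals the pairwise enumeration oracle and handles ties", {
  expect_equal(auc_roc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1)
  expect_equal(auc_roc(rep(5, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(3)
  for (k in 1:5) {
    y <- rep(c(0, 1), c(5, 3))
    s <- sample(1:4, 8, replace = TRUE)  # forced ties
    pairs <- expand.grid(pos = which(y == 1), neg = which(y == 0))
    oracle <- mean(ifelse(s[pairs$pos] > s[pairs$neg], 1,
                          ifelse(s[pairs$pos] == s[pairs$neg], 0.5, 0)))
    expect_equal(auc_roc(s, y), oracle)
  }
  expect_error(auc_roc(1:4, rep(1, 4)), "both classes")
})

test_that("cross-validation plans partition subjects with disjoint splits", {
  y <- rep(c("HC", "SCZ"), c(10, 14))
  plan <- make_cv_plan(y, n_repeats = 2, n_folds = 3, rng_seed = 5)
  for (r in 1:2) {
    rp <- plan$repeats[[r]]
    expect_setequal(unique(rp$fold_id), 1:3)
    for (f in 1:3) {
      held <- which(rp$fold_id == f)
      expect_setequal(c(rp$val[[f]], rp$test[[f]]), held)
      expect_length(intersect(rp$val[[f]], rp$test[[f]]), 0)
      expect_setequal(c(which(rp$fold_id != f), held), seq_along(y))
    }
  }
  expect_identical(make_cv_plan(y, 2, 3, rng_seed = 5),
                   make_cv_plan(y, 2, 3, rng_seed = 5))
  expect_false(identical(plan$repeats[[1]]$fold_id,
                         make_cv_plan(y, 2, 3, rng_seed = 6)$repeats[[1]]$fold_id))
  # 6 subjects, 3 folds: folds of 2, validation/test of 1 apiece
  plan6 <- make_cv_plan(rep(c("HC", "SCZ"), 3), 1, 3, rng_seed = 2)
  expect_true(all(table(plan6$repeats[[1]]$fold_id) == 2))
  expect_true(all(lengths(plan6$repeats[[1]]$val) == 1))
  expect_true(all(lengths(plan6$repeats[[1]]$test) == 1))
  expect_error(make_cv_plan(rep(c("HC", "SCZ"), c(2, 10)), 1, 3), "per class")
})

test_that("a degenerate mixture reduces the search to uniform draws", {
  sp <- search_space()
  calls <- list()
  obj <- function(cfg) { calls[[length(calls) + 1]] <<- cfg; runif(1) }
  res <- optimize_hyperparameters(obj, sp, n_iter = 40,
                                  mixture = c(tpe = 0, anneal = 0, random = 1),
                                  rng_seed = 3)
  expect_identical(nrow(res$trace), 40L)
  expect_true(all(res$trace$strategy == "random"))
  expect_true(all(res$trace$units >= 10 & res$trace$units <= 200))
  expect_true(all(res$trace$units == round(res$trace$units)))
  expect_true(all(res$trace$pretrain_lr >= 1e-4 & res$trace$pretrain_lr <= 1e-1))
  expect_true(all(res$trace$finetune_lr >= 1e-4 & res$trace$finetune_lr <= 1e-1))
  expect_error(optimize_hyperparameters(obj, sp, 10,
                                        mixture = c(tpe = 0.5, anneal = 0,
                                                    random = 0)),
               "sum to 1")
})

test_that("the mixed search beats random search on a smooth objective", {
  obj <- function(cfg) {
    1 - (((cfg$units - 120) / 190)^2 +
           ((log(cfg$pretrain_lr) - log(0.01)) / log(1e3))^2 +
           ((log(cfg$finetune_lr) - log(0.003)) / log(1e3))^2)
  }
  sp <- search_space()
  wins <- 0; near <- 0
  for (s in 1:10) {
    mixed <- optimize_hyperparameters(obj, sp, n_iter = 200, rng_seed = s)
    rand <- optimize_hyperparameters(obj, sp, n_iter = 200,
                                     mixture = c(tpe = 0, anneal = 0,
                                                 random = 1),
                                     rng_seed = s + 100)
    wins <- wins + (mixed$best_score > rand$best_score)
    near <- near + (mixed$best_score >= 0.9)  # within 10% of the optimum of 1
  }
  expect_gte(wins, 7)
  expect_gte(near, 7)
})

test_that("nested evaluation produces one entry per repeat and fold", {
  co <- balanced_cohort(25, 2, rng_seed = 6)
  z <- preprocess_table(co$table)$table
  plan <- make_cv_plan(z$label, n_repeats = 2, n_folds = 3, rng_seed = 4)
  rep1 <- run_nested_evaluation(z, "dbn", plan,
                                space = search_space(units = c(10, 40)),
                                n_iter = 2, rng_seed = 5)
  expect_identical(nrow(rep1$folds), 6L)
  expect_true(all(rep1$folds$n_train + rep1$folds$n_val + rep1$folds$n_test
                  == 50))
  # metric identities hold on every fold row
  expect_equal(rep1$folds$balanced_accuracy,
               (rep1$folds$sensitivity + rep1$folds$specificity) / 2,
               tolerance = 1e-10)
  expect_true(all(rep1$folds$error_rate >= 0 & rep1$folds$error_rate <= 100))
})

test_that("trained fold models never see test-half features", {
  co <- balanced_cohort(20, 1, rng_seed = 8)
  z <- preprocess_table(co$table)$table
  plan <- make_cv_plan(z$label, n_repeats = 1, n_folds = 3, rng_seed = 2)
  r1 <- run_nested_evaluation(z, "dbn", plan,
                              space = search_space(units = c(10, 20)),
                              n_iter = 2, rng_seed = 7, keep_models = TRUE)
  z2 <- z
  te1 <- plan$repeats[[1]]$test[[1]]
  z2$features[te1, ] <- z2$features[te1, ] + 50   # poison fold-1 test half
  r2 <- suppressWarnings(
    run_nested_evaluation(z2, "dbn", plan,
                          space = search_space(units = c(10, 20)),
                          n_iter = 2, rng_seed = 7, keep_models = TRUE))
  expect_identical(r1$models[[1]], r2$models[[1]])
  expect_false(isTRUE(all.equal(r1$folds$balanced_accuracy[1],
                                r2$folds$balanced_accuracy[1])))
})

test_that("the linear baseline picks C = 1 on ties and solves separable toys", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(c("HC", "SCZ"), each = 20)
  sel <- baseline_linear(X[c(1:12, 21:32), ], y[c(1:12, 21:32)],
                         X[c(13:16, 33:36), ], y[c(13:16, 33:36)])
  expect_identical(sel$C, 1)                  # separable: all C values tie
  expect_equal(max(sel$grid$val_auc), min(sel$grid$val_auc))
  pred <- as.character(predict(sel$model, X[c(17:20, 37:40), ]))
  expect_identical(pred, y[c(17:20, 37:40)])
  expect_error(baseline_linear(X[1:10, ], rep("HC", 10), X, y),
               "single-class")
})

test_that("the deep and linear classifiers land in the same accuracy range", {
  co <- generate_cohort(sim_config(effect_size_d = 1.5, rng_seed = 12))
  z <- preprocess_table(co$table)$table
  hs <- subset_table(z, z$label %in% c("HC", "SCZ"))
  plan <- make_cv_plan(hs$label, n_repeats = 1, n_folds = 3, rng_seed = 3)
  deep <- run_nested_evaluation(hs, "dbn", plan, n_iter = 5, rng_seed = 1)
  lin <- run_nested_evaluation(hs, "baseline", plan, rng_seed = 1)
  ba_deep <- deep$aggregate$mean[deep$aggregate$metric == "balanced_accuracy"]
  ba_lin <- lin$aggregate$mean[lin$aggregate$metric == "balanced_accuracy"]
  expect_lt(abs(ba_deep - ba_lin), 15)
  # near-separable training sets tie the whole C grid, so the conventional
  # default C = 1 is selected in every fold
  expect_true(all(lin$folds$best_C == 1))
})

test_that("external cohorts are scored by the fraction labelled SCZ", {
  co <- balanced_cohort(60, 2, rng_seed = 14, n_fep = 30, fep_scale = 0)
  z <- preprocess_table(co$table)$table
  hs <- subset_table(z, z$label %in% c("HC", "SCZ"))
  net <- train_dbn_classifier(hs$features, hs$label, 40, 0.05, 0.05,
                              rng_seed = 2)
  fep <- subset_table(z, z$label == "FEP")
  out0 <- evaluate_external_cohort(list(net), fep)
  expect_equal(out0$fraction_scz + out0$fraction_hc, 100)
  expect_lt(out0$fraction_scz, 50)    # HC-like cohort leans HC

  co1 <- balanced_cohort(60, 2, rng_seed = 14, n_fep = 30, fep_scale = 1)
  z1 <- preprocess_table(co1$table)$table
  hs1 <- subset_table(z1, z1$label %in% c("HC", "SCZ"))
  net1 <- train_dbn_classifier(hs1$features, hs1$label, 40, 0.05, 0.05,
                               rng_seed = 2)
  out1 <- evaluate_external_cohort(list(net1),
                                   subset_table(z1, z1$label == "FEP"))
  expect_gt(out1$fraction_scz, 50)    # SCZ-like cohort leans SCZ
  expect_error(evaluate_external_cohort(list(), fep), "no models")
})

test_that("the layer sweep compares depths on validation AUC", {
  co <- balanced_cohort(20, 2, rng_seed = 18)
  z <- preprocess_table(co$table)$table
  plan <- make_cv_plan(z$label, n_repeats = 1, n_folds = 3, rng_seed = 6)
  sw <- sweep_layers(z, plan, n_layers = 1:2, n_iter = 2, rng_seed = 4)
  expect_identical(sw$n_hidden_layers, 1:2)
  expect_true(all(sw$mean_val_auc >= 0 & sw$mean_val_auc <= 1))
})
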