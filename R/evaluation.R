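#' Confusion counts with SCZ as the positive class
#'
#' @param truth True labels (`"HC"`/`"SCZ"` or 0/1).
#' @param predicted Predicted labels, same coding.
#' @return Object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion_counts <- function(truth, predicted) {
  yt <- label_to_binary(truth)
  yp <- label_to_binary(predicted)
  if (length(yt) != length(yp)) stop("length mismatch")
  structure(list(TP = sum(yt == 1 & yp == 1), TN = sum(yt == 0 & yp == 0),
                 FP = sum(yt == 0 & yp == 1), FN = sum(yt == 1 & yp == 0)),
            class = "confusion_counts")
}

#' Classification performance indicators
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' (their mean) and error rate `(FP+FN)/total`, all as percentages. A rate
#' whose denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts A `confusion_counts`.
#' @return Named list of percentages.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("no evaluated subjects")
  sens <- if (counts$TP + counts$FN > 0) 100 * counts$TP / (counts$TP + counts$FN) else NA_real_
  spec <- if (counts$TN + counts$FP > 0) 100 * counts$TN / (counts$TN + counts$FP) else NA_real_
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       error_rate = 100 * (counts$FP + counts$FN) / total)
}

#' Area under the ROC curve
#'
#' The normalized Mann-Whitney U statistic: the probability that a random
#' SCZ score exceeds a random HC score, ties counting one half.
#'
#' @param scores Numeric scores, larger = more SCZ-like.
#' @param labels True labels (`"HC"`/`"SCZ"` or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  y <- label_to_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hyperparameter search space
#'
#' The tunable hyperparameters and their ranges: units per hidden layer
#' (quantized uniform on `[10, 200]`), pretraining learning rate and
#' fine-tuning learning rate (both uniform on `[1e-4, 1e-1]`). The number of
#' hidden layers is fixed per sweep, not searched.
#'
#' @param units Length-2 range for the (integer) hidden width.
#' @param pretrain_lr,finetune_lr Length-2 learning-rate ranges.
#' @param n_hidden_layers Fixed hidden-layer count for this sweep.
#' @return Object of class `search_space`.
#' @export
search_space <- function(units = c(10, 200), pretrain_lr = c(1e-4, 1e-1),
                         finetune_lr = c(1e-4, 1e-1), n_hidden_layers = 1) {
  stopifnot(length(units) == 2, units[1] <= units[2],
            pretrain_lr[1] <= pretrain_lr[2],
            finetune_lr[1] <= finetune_lr[2],
            n_hidden_layers %in% 1:5)
  structure(list(
    params = list(
      units = list(type = "quniform", min = units[1], max = units[2], q = 1),
      pretrain_lr = list(type = "uniform", min = pretrain_lr[1], max = pretrain_lr[2]),
      finetune_lr = list(type = "uniform", min = finetune_lr[1], max = finetune_lr[2])
    ),
    n_hidden_layers = as.integer(n_hidden_layers)),
    class = "search_space")
}

space_sample_uniform <- function(space) {
  out <- lapply(space$params, function(p) {
    x <- stats::runif(1, p$min, p$max)
    if (p$type == "quniform") x <- round(x / p$q) * p$q
    x
  })
  out
}

space_clip <- function(space, cand) {
  for (nm in names(space$params)) {
    p <- space$params[[nm]]
    x <- min(max(cand[[nm]], p$min), p$max)
    if (p$type == "quniform") x <- min(max(round(x / p$q) * p$q, p$min), p$max)
    cand[[nm]] <- x
  }
  cand
}

# log kernel density of x under a Gaussian KDE on points (one dimension)
kde_logdens <- function(x, points, range_width) {
  bw <- stats::sd(points) * 1.06 * length(points)^(-1/5)
  if (!is.finite(bw) || bw <= 0) bw <- 0.1 * range_width
  log(mean(stats::dnorm(x, mean = points, sd = bw)) + 1e-300)
}

#' Mixed-strategy hyperparameter optimization
#'
#' Sequential model-based search over a [search_space()], maximizing a
#' user-supplied objective (here: validation AUC). Each iteration draws its
#' proposal strategy from a fixed mixture: a Tree-of-Parzen-Estimators-style
#' proposal (density ratio of the top-quartile vs remaining trials,
#' per-dimension Gaussian kernel densities) with probability 0.7, an
#' annealing-style Gaussian perturbation of the incumbent best with shrinking
#' scale with probability 0.2, and a uniform random draw with probability
#' 0.1. The Parzen proposal falls back to random until enough history exists.
#'
#' @param objective Function taking a named list
#'   `(units, pretrain_lr, finetune_lr)` and returning a scalar score to
#'   maximize.
#' @param space A [search_space()].
#' @param n_iter Number of evaluations.
#' @param mixture Named probabilities for `tpe`, `anneal`, `random`;
#'   must sum to 1.
#' @param rng_seed Integer seed for the proposal stream.
#' @param gamma Top fraction treated as "good" trials by the Parzen proposal.
#' @param n_candidates Candidate draws scored per Parzen iteration.
#' @param min_history Trials required before the Parzen/annealing proposals
#'   activate.
#' @return List with `best` (named list), `best_score`, and `trace`
#'   (data.frame of all trials with the strategy used).
#' @export
optimize_hyperparameters <- function(objective, space, n_iter = 50,
                                     mixture = c(tpe = 0.7, anneal = 0.2,
                                                 random = 0.1),
                                     rng_seed = 1, gamma = 0.25,
                                     n_candidates = 20, min_history = 10) {
  stopifnot(n_iter >= 1)
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (length(space$params) == 0) stop("empty search space")
  pnames <- names(space$params)
  trace <- data.frame()
  with_seed(rng_seed, {
    for (i in seq_len(n_iter)) {
      strategy <- sample(names(mixture), 1, prob = mixture)
      have_hist <- nrow(trace) >= min_history
      cand <- if (strategy == "random" || !have_hist) {
        space_sample_uniform(space)
      } else if (strategy == "anneal") {
        best <- trace[which.max(trace$score), pnames]
        shrink <- 0.2 * exp(-2 * i / n_iter)
        cand <- lapply(pnames, function(nm) {
          p <- space$params[[nm]]
          best[[nm]] + stats::rnorm(1, 0, shrink * (p$max - p$min))
        })
        names(cand) <- pnames
        space_clip(space, cand)
      } else {
        n_good <- max(2L, ceiling(gamma * nrow(trace)))
        ord <- order(trace$score, decreasing = TRUE)
        good <- trace[ord[seq_len(n_good)], pnames, drop = FALSE]
        bad <- trace[ord[-seq_len(n_good)], pnames, drop = FALSE]
        if (nrow(bad) < 2) {
          space_sample_uniform(space)
        } else {
          cands <- vector("list", n_candidates)
          ratio <- numeric(n_candidates)
          for (k in seq_len(n_candidates)) {
            base <- good[sample.int(nrow(good), 1), ]
            cand <- lapply(pnames, function(nm) {
              p <- space$params[[nm]]
              bw <- stats::sd(good[[nm]]) * 1.06 * nrow(good)^(-1/5)
              if (!is.finite(bw) || bw <= 0) bw <- 0.1 * (p$max - p$min)
              base[[nm]] + stats::rnorm(1, 0, bw)
            })
            names(cand) <- pnames
            cand <- space_clip(space, cand)
            ratio[k] <- sum(vapply(pnames, function(nm) {
              p <- space$params[[nm]]
              kde_logdens(cand[[nm]], good[[nm]], p$max - p$min) -
                kde_logdens(cand[[nm]], bad[[nm]], p$max - p$min)
            }, numeric(1)))
            cands[[k]] <- cand
          }
          cands[[which.max(ratio)]]
        }
      }
      score <- objective(cand)
      row <- as.data.frame(cand)
      row$score <- score
      row$strategy <- strategy
      row$iter <- i
      trace <- rbind(trace, row)
    }
  })
  best_i <- which.max(trace$score)
  list(best = as.list(trace[best_i, pnames]),
       best_score = trace$score[best_i], trace = trace)
}

#' Repeated stratified cross-validation plan
#'
#' Per repeat: subjects are shuffled and split into `n_folds` folds
#' (stratified by class so every partition sees both classes); each held-out
#' fold is further split at random into two halves differing by at most one
#' subject and class-balanced where counts allow: a validation half (drives
#' hyperparameter search) and a test half (touched only by the final model).
#'
#' @param labels Diagnosis labels (`"HC"`/`"SCZ"`) of the subjects to plan
#'   over.
#' @param n_repeats Number of independent repetitions (default 5).
#' @param n_folds Folds per repetition (default 3).
#' @param rng_seed Integer seed.
#' @param stratified Set `FALSE` for plain shuffling without class balance.
#' @return Object of class `cv_plan`.
#' @export
make_cv_plan <- function(labels, n_repeats = 5, n_folds = 3, rng_seed = 1,
                         stratified = TRUE) {
  y <- label_to_binary(labels)
  n <- length(y)
  if (min(table(y)) < n_folds) stop("need at least n_folds subjects per class")
  reps <- with_seed(rng_seed, {
    lapply(seq_len(n_repeats), function(r) {
      fold_id <- integer(n)
      if (stratified) {
        for (cls in unique(y)) {
          idx <- sample(which(y == cls))
          fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
        }
      } else {
        fold_id[sample.int(n)] <- rep_len(seq_len(n_folds), n)
      }
      val <- test <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        held <- which(fold_id == f)
        # 50/50 split, alternating within class with the parity carried
        # across classes: halves differ by at most one subject overall and
        # are class-balanced whenever the per-class counts allow it
        v <- integer(0)
        parity <- 0L
        for (cls in unique(y[held])) {
          members <- held[y[held] == cls]
          hc <- members[sample.int(length(members))]
          take <- (parity + seq_along(hc)) %% 2L == 1L
          v <- c(v, hc[take])
          parity <- (parity + length(hc)) %% 2L
        }
        val[[f]] <- sort(v)
        test[[f]] <- sort(setdiff(held, v))
      }
      list(fold_id = fold_id, val = val, test = test)
    })
  })
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 rng_seed = as.integer(rng_seed), labels = as.character(labels),
                 stratified = stratified, repeats = reps),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$n_repeats, " x ", x$n_folds, "-fold, ",
      length(x$labels), " subjects\n", sep = "")
  invisible(x)
}

#' Fit a DBN-initialized classifier with given hyperparameters
#'
#' Pretrains a DBN (`n_hidden_layers` equal-width Gaussian/Bernoulli RBM
#' layers), converts it to a feedforward softmax classifier and fine-tunes
#' it. The workhorse called for every candidate during hyperparameter
#' search.
#'
#' @param X Standardized feature matrix (training subjects x features).
#' @param y Labels (`"HC"`/`"SCZ"` or 0/1).
#' @param units Hidden width.
#' @param pretrain_lr,finetune_lr Learning rates for the two phases.
#' @param n_hidden_layers Number of hidden layers.
#' @param rng_seed Integer seed.
#' @param pretrain Set `FALSE` to skip generative pretraining (random init).
#' @param engine `"C"` or `"R"`.
#' @return A trained `dbn_network`.
#' @export
train_dbn_classifier <- function(X, y, units, pretrain_lr, finetune_lr,
                                 n_hidden_layers = 1, rng_seed = 1,
                                 pretrain = TRUE, engine = "C") {
  sizes <- rep(as.integer(round(units)), n_hidden_layers)
  net <- if (pretrain) {
    dbn <- pretrain_dbn(X, sizes,
                        cd_config(learning_rate = pretrain_lr,
                                  rng_seed = child_seed(rng_seed, 1)),
                        engine = engine)
    initialize_network(dbn)
  } else {
    random_network(ncol(X), sizes, rng_seed = child_seed(rng_seed, 1))
  }
  fine_tune(net, X, y,
            finetune_config(learning_rate = finetune_lr,
                            rng_seed = child_seed(rng_seed, 2)),
            engine = engine)
}

#' Nested cross-validated evaluation
#'
#' For every repeat and fold of the plan: run the hyperparameter search on
#' the training folds scored by validation-half AUC, retrain the best
#' configuration on the training folds, and evaluate once on the untouched
#' test half. Aggregates balanced accuracy, sensitivity, specificity, error
#' rate and AUC over all `n_repeats * n_folds` fold evaluations.
#'
#' @param table A preprocessed (`zscored`) `morph_table`; FEP rows are
#'   excluded automatically and must never enter training.
#' @param model_family `"dbn"` or `"baseline"` (linear SVM).
#' @param plan A [make_cv_plan()] built on this table's HC/SCZ labels.
#' @param space A [search_space()] (DBN family only).
#' @param n_iter Search iterations per fold (DBN family only).
#' @param C_grid Soft-margin grid (baseline family only).
#' @param rng_seed Integer seed for searches and training.
#' @param keep_models Keep the per-fold final models (needed for
#'   [evaluate_external_cohort()] and probing).
#' @param engine `"C"` or `"R"`.
#' @return Object of class `performance_report`: `$folds` (one row per fold
#'   evaluation), `$aggregate` (mean and sd per metric), and optionally
#'   `$models`.
#' @export
run_nested_evaluation <- function(table, model_family = c("dbn", "baseline"),
                                  plan, space = search_space(), n_iter = 50,
                                  C_grid = c(0.001, 0.1, 1, 10, 100, 1000),
                                  rng_seed = 1, keep_models = FALSE,
                                  engine = "C") {
  model_family <- match.arg(model_family)
  stopifnot(inherits(table, "morph_table"), inherits(plan, "cv_plan"))
  keep <- table$label %in% c("HC", "SCZ")
  tab <- subset_table(table, keep)
  if (!identical(plan$labels, tab$label)) {
    stop("plan labels do not match the table's HC/SCZ rows; ",
         "build the plan from this table")
  }
  X <- tab$features
  y <- tab$label
  folds <- list()
  models <- list()
  k <- 0
  for (r in seq_len(plan$n_repeats)) {
    rep_plan <- plan$repeats[[r]]
    for (f in seq_len(plan$n_folds)) {
      k <- k + 1
      tr <- which(rep_plan$fold_id != f)
      va <- rep_plan$val[[f]]
      te <- rep_plan$test[[f]]
      fold_seed <- child_seed(rng_seed, r * 100 + f)
      if (model_family == "dbn") {
        train_seed <- child_seed(fold_seed, 1)
        objective <- function(cfg) {
          net <- train_dbn_classifier(X[tr, , drop = FALSE], y[tr],
                                      cfg$units, cfg$pretrain_lr,
                                      cfg$finetune_lr, space$n_hidden_layers,
                                      rng_seed = train_seed, engine = engine)
          auc_roc(predict_proba(net, X[va, , drop = FALSE])[, "SCZ"], y[va])
        }
        found <- optimize_hyperparameters(objective, space, n_iter,
                                          rng_seed = child_seed(fold_seed, 2))
        model <- train_dbn_classifier(X[tr, , drop = FALSE], y[tr],
                                      found$best$units,
                                      found$best$pretrain_lr,
                                      found$best$finetune_lr,
                                      space$n_hidden_layers,
                                      rng_seed = train_seed, engine = engine)
        score_te <- predict_proba(model, X[te, , drop = FALSE])[, "SCZ"]
        pred_te <- predict_label(model, X[te, , drop = FALSE])
        best_desc <- found$best
        best_val <- found$best_score
      } else {
        sel <- baseline_linear(X[tr, , drop = FALSE], y[tr],
                               X[va, , drop = FALSE], y[va], C_grid)
        model <- sel$model
        score_te <- -attr(stats::predict(model, X[te, , drop = FALSE],
                                         decision.values = TRUE),
                          "decision.values")[, 1]
        pred_te <- as.character(stats::predict(model, X[te, , drop = FALSE]))
        best_desc <- list(C = sel$C)
        best_val <- sel$val_auc
      }
      m <- compute_metrics(confusion_counts(y[te], pred_te))
      folds[[k]] <- data.frame(
        repeat_id = r, fold = f,
        balanced_accuracy = m$balanced_accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, error_rate = m$error_rate,
        auc = auc_roc(score_te, y[te]), best_val_auc = best_val,
        n_train = length(tr), n_val = length(va), n_test = length(te))
      folds[[k]] <- cbind(folds[[k]],
                          stats::setNames(as.data.frame(best_desc),
                                          paste0("best_", names(best_desc))))
      if (keep_models) models[[k]] <- model
    }
  }
  folds <- do.call(rbind, folds)
  metrics <- c("balanced_accuracy", "sensitivity", "specificity",
               "error_rate", "auc")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(folds = folds, aggregate = aggregate,
                 model_family = model_family,
                 models = if (keep_models) models),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> ", x$model_family, ", ", nrow(x$folds),
      " fold evaluations (mean +/- sd):\n", sep = "")
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-18s %6.2f +/- %.2f\n", a$metric[i], a$mean[i], a$sd[i]))
  }
  invisible(x)
}

#' Linear SVM baseline with soft-margin selection
#'
#' Trains a linear soft-margin SVM for every value of the C grid on the
#' training set, scores each by validation AUC, and selects the winner; when
#' the maximum is tied (as happens when the training set is separated at
#' every C), the conventional default C = 1 is chosen.
#'
#' @param X_train,y_train Training features/labels.
#' @param X_val,y_val Validation features/labels for the grid search.
#' @param C_grid Candidate soft-margin constants.
#' @return List with the fitted `model` (on the training set at the chosen
#'   `C`), `C`, `val_auc` and the per-C grid AUCs.
#' @export
baseline_linear <- function(X_train, y_train, X_val, y_val,
                            C_grid = c(0.001, 0.1, 1, 10, 100, 1000)) {
  yf <- factor(as.character(y_train), levels = c("HC", "SCZ"))
  if (any(is.na(yf))) {
    yf <- factor(ifelse(label_to_binary(y_train) == 1, "SCZ", "HC"),
                 levels = c("HC", "SCZ"))
  }
  if (nlevels(droplevels(yf)) < 2) stop("single-class training labels")
  fits <- lapply(C_grid, function(C) {
    e1071::svm(X_train, yf, kernel = "linear", cost = C, scale = FALSE)
  })
  aucs <- vapply(fits, function(fit) {
    dv <- attr(stats::predict(fit, X_val, decision.values = TRUE),
               "decision.values")[, 1]
    auc_roc(-dv, y_val)  # decision values are oriented toward the first level
  }, numeric(1))
  best_auc <- max(aucs)
  tied <- which(aucs >= best_auc - 1e-12)
  pick <- if (any(C_grid[tied] == 1)) which(C_grid == 1) else tied[1]
  list(model = fits[[pick]], C = C_grid[pick], val_auc = aucs[pick],
       grid = data.frame(C = C_grid, val_auc = aucs))
}

#' Classify an external cohort with the per-fold final models
#'
#' Applies each trained model to a cohort that took no part in training or
#' search (here: first-episode psychosis) and reports the fraction labelled
#' SCZ and the complementary fraction labelled HC, with mean and sd over
#' models.
#'
#' @param models List of trained `dbn_network` models (e.g.
#'   `report$models` from [run_nested_evaluation()] with
#'   `keep_models = TRUE`).
#' @param cohort A `morph_table` of external subjects (any labels; they are
#'   not used).
#' @return List with `fraction_scz`, `fraction_hc` (means in percent), their
#'   `sd`, and the per-model fractions.
#' @export
evaluate_external_cohort <- function(models, cohort) {
  stopifnot(inherits(cohort, "morph_table"))
  if (n_subjects(cohort) == 0) stop("empty cohort")
  if (length(models) == 0) stop("no models supplied")
  fr <- vapply(models, function(m) {
    100 * mean(predict_label(m, cohort$features) == "SCZ")
  }, numeric(1))
  list(fraction_scz = mean(fr), fraction_hc = 100 - mean(fr),
       sd = stats::sd(fr), per_model = fr)
}

#' Layer-count sweep
#'
#' Reproduces the layer-selection design: for each candidate hidden-layer
#' count, run the full nested evaluation and record the mean best-validation
#' AUC, the criterion used to pick the depth.
#'
#' @param table Preprocessed `morph_table`.
#' @param plan A [make_cv_plan()].
#' @param n_layers Candidate depths.
#' @param n_iter Search iterations per fold.
#' @param rng_seed Integer seed.
#' @param ... Passed to [run_nested_evaluation()].
#' @return Data frame with one row per depth: mean/sd validation AUC and
#'   mean test balanced accuracy.
#' @export
sweep_layers <- function(table, plan, n_layers = 1:5, n_iter = 50,
                         rng_seed = 1, ...) {
  rows <- lapply(n_layers, function(L) {
    rep_ <- run_nested_evaluation(table, "dbn", plan,
                                  space = search_space(n_hidden_layers = L),
                                  n_iter = n_iter, rng_seed = rng_seed, ...)
    data.frame(n_hidden_layers = L,
               mean_val_auc = mean(rep_$folds$best_val_auc),
               sd_val_auc = stats::sd(rep_$folds$best_val_auc),
               mean_balanced_accuracy = mean(rep_$folds$balanced_accuracy))
  })
  do.call(rbind, rows)
}
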