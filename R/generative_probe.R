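#' Train the associative top-level RBM
#'
#' Attaches a top-level Bernoulli RBM whose visible layer concatenates the
#' DBN's top hidden activation probabilities with a one-hot diagnosis code
#' `(HC, SCZ)`. Clamping the two label units during Gibbs sampling then
#' draws from the model's class-conditional distribution.
#'
#' @param dbn A pretrained `dbn_model`.
#' @param data Standardized feature matrix the DBN was pretrained on.
#' @param labels `"HC"`/`"SCZ"` (or 0/1) labels, one per row of `data`.
#' @param n_hidden Hidden width of the top RBM; defaults to the width of the
#'   DBN's top layer.
#' @param config A [cd_config()].
#' @param engine Training engine, see [train_rbm()].
#' @return The `dbn_model` with `associative_top` set.
#' @export
train_associative_top <- function(dbn, data, labels,
                                  n_hidden = dbn$hidden_sizes[length(dbn$hidden_sizes)],
                                  config = cd_config(), engine = c("C", "R")) {
  stopifnot(inherits(dbn, "dbn_model"))
  if (missing(labels) || is.null(labels)) stop("labels are required")
  y <- label_to_binary(labels)
  pen <- dbn_propagate(dbn, data)
  onehot <- cbind(HC = 1 - y, SCZ = y)
  vis <- cbind(pen, onehot)
  cfg <- config
  cfg$rng_seed <- child_seed(config$rng_seed, 1000L)
  dbn$associative_top <- train_rbm(vis, n_hidden, cfg,
                                   visible_family = "bernoulli",
                                   engine = match.arg(engine))
  dbn$label_index <- ncol(pen) + 1:2
  dbn
}

onehot_for_class <- function(class_label) {
  if (!class_label %in% c("HC", "SCZ")) {
    stop("unknown class '", class_label, "' (use HC or SCZ)")
  }
  if (class_label == "SCZ") c(0, 1) else c(1, 0)
}

#' Class-conditional Gibbs sampling in the top-level RBM
#'
#' Runs `n_gibbs` alternating Gibbs updates in the associative top RBM with
#' the two label units clamped to the one-hot code of `class_label`. Chains
#' start from the clamped conditional of a random (Bernoulli(0.5)) free
#' visible state.
#'
#' @param dbn A `dbn_model` with a trained associative top.
#' @param class_label `"HC"` or `"SCZ"`.
#' @param n_gibbs Number of alternating Gibbs iterations (default 1000).
#' @param n_chains Number of independent chains run in parallel.
#' @param rng_seed Integer seed.
#' @return List with final `h_prob`, `h_sample` (n_chains x hidden) and the
#'   free-visible `v_prob`, `v_sample` (n_chains x top width).
#' @export
sample_class <- function(dbn, class_label, n_gibbs = 1000, n_chains = 1,
                         rng_seed = 1) {
  top <- dbn$associative_top
  if (is.null(top)) stop("no associative top: call train_associative_top() first")
  if (n_chains < 1) stop("n_chains must be >= 1")
  lab_idx <- dbn$label_index
  free_idx <- setdiff(seq_len(ncol(top$W)), lab_idx)
  code <- onehot_for_class(class_label)
  with_seed(rng_seed, {
    v <- matrix(0, n_chains, ncol(top$W))
    v[, free_idx] <- (matrix(stats::runif(n_chains * length(free_idx)),
                             n_chains) < 0.5) * 1
    v[, lab_idx] <- matrix(code, n_chains, 2, byrow = TRUE)
    h_prob <- hidden_conditional(top, v)
    h_sample <- (matrix(stats::runif(length(h_prob)), n_chains) < h_prob) * 1
    v_prob <- visible_conditional(top, h_sample)
    for (g in seq_len(n_gibbs)) {
      v <- (matrix(stats::runif(length(v_prob)), n_chains) < v_prob) * 1
      v[, lab_idx] <- matrix(code, n_chains, 2, byrow = TRUE)
      h_prob <- hidden_conditional(top, v)
      h_sample <- (matrix(stats::runif(length(h_prob)), n_chains) < h_prob) * 1
      v_prob <- visible_conditional(top, h_sample)
    }
    list(h_prob = h_prob, h_sample = h_sample,
         v_prob = v_prob[, free_idx, drop = FALSE],
         v_sample = (v_prob[, free_idx, drop = FALSE] > 0.5) * 1)
  })
}

#' Single deterministic down-pass to morphometry space
#'
#' Propagates a top-level hidden state down through the generative
#' connections: visible conditional of the associative top (label units
#' dropped), then activation probabilities at each Bernoulli layer, ending
#' with the Gaussian means of the bottom layer, i.e. an input-space vector
#' in z-score units.
#'
#' @param dbn A `dbn_model` with associative top.
#' @param top_state Hidden state(s) of the top RBM, rowwise.
#' @return Matrix (rows x 113 features for the canonical schema).
#' @export
down_pass <- function(dbn, top_state) {
  top <- dbn$associative_top
  if (is.null(top)) stop("no associative top: call train_associative_top() first")
  v_top <- visible_conditional(top, top_state)
  cur <- v_top[, -dbn$label_index, drop = FALSE]
  for (l in rev(seq_along(dbn$layers))) {
    cur <- visible_conditional(dbn$layers[[l]], cur)
  }
  cur
}

#' Rank brain regions by class-conditional generated difference
#'
#' For each diagnosis class, draws `n_chains` clamped Gibbs chains in the
#' top-level RBM, down-passes the final hidden probabilities to input space,
#' and averages them into a class prototype. Features are ranked by the
#' absolute difference between the SCZ and HC prototypes: the regions the
#' generative model considers most class-discriminative.
#'
#' @param dbn A `dbn_model` with trained associative top.
#' @param n_chains Chains per class (default 100; `1` reproduces a single
#'   literal sample per class).
#' @param n_gibbs Gibbs iterations per chain (default 1000).
#' @param rng_seed Integer seed.
#' @param feature_names Optional feature names for the report.
#' @return Object of class `region_difference_report`: prototypes, absolute
#'   differences, descending ranking and the sampling settings.
#' @export
class_difference <- function(dbn, n_chains = 100, n_gibbs = 1000,
                             rng_seed = 1, feature_names = NULL) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  protos <- lapply(c(HC = "HC", SCZ = "SCZ"), function(cl) {
    s <- sample_class(dbn, cl, n_gibbs = n_gibbs, n_chains = n_chains,
                      rng_seed = child_seed(rng_seed, match(cl, c("HC", "SCZ"))))
    colMeans(down_pass(dbn, s$h_prob))
  })
  if (is.null(feature_names)) {
    feature_names <- if (dbn$n_input == 113) feature_schema()$feature_names
    else paste0("feature_", seq_len(dbn$n_input))
  }
  diff <- abs(protos$SCZ - protos$HC)
  names(diff) <- names(protos$HC) <- names(protos$SCZ) <- feature_names
  ord <- order(diff, decreasing = TRUE)
  structure(
    list(prototype_hc = protos$HC, prototype_scz = protos$SCZ,
         difference = diff, ranking = feature_names[ord],
         settings = list(n_chains = n_chains, n_gibbs = n_gibbs,
                         rng_seed = rng_seed)),
    class = "region_difference_report"
  )
}

#' @export
print.region_difference_report <- function(x, n = 10, ...) {
  cat("<region_difference_report> top", n, "of", length(x$difference),
      "features (|SCZ - HC| prototype difference, z-score units)\n")
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  print(data.frame(rank = seq_along(top), region = top,
                   difference = round(unname(x$difference[top]), 4)),
        row.names = FALSE)
  invisible(x)
}

#' Back-transform a difference report to native units
#'
#' Converts the z-score-unit prototype differences to mm (thickness) or mm^3
#' (volume) using the residual standard deviations stored in a preprocessing
#' model.
#'
#' @param report A `region_difference_report`.
#' @param model A `preprocess_model` with z-score statistics.
#' @return Named vector of differences in native units.
#' @export
report_native_units <- function(report, model) {
  if (is.null(model$zscore)) stop("preprocess model carries no z-score stats")
  report$difference * model$zscore$sd[names(report$difference)]
}

#' Exact clamped conditional hidden means of a small associative RBM
#'
#' Enumerates all free-visible configurations of a (small) Bernoulli RBM
#' with the label units held at the given code and returns the exact
#' stationary expectation of each hidden unit. Ground-truth oracle for
#' [sample_class()].
#'
#' @param top A bernoulli `rbm_parameters`.
#' @param label_index Columns of the visible layer that are clamped.
#' @param code Values the clamped units are held at.
#' @return List with `h_mean` (exact E\[h\]) and `v_mean` (exact E\[v_free\]).
#' @export
exact_clamped_means <- function(top, label_index, code) {
  V <- ncol(top$W)
  free_idx <- setdiff(seq_len(V), label_index)
  if (length(free_idx) > 16) stop("too many free visible units to enumerate")
  states <- all_binary_states(length(free_idx))
  full <- matrix(0, nrow(states), V)
  full[, free_idx] <- states
  full[, label_index] <- matrix(code, nrow(states), length(code), byrow = TRUE)
  logp <- -free_energy(top, full)
  p <- exp(logp - logsumexp(logp))
  hp <- hidden_conditional(top, full)
  list(h_mean = as.numeric(p %*% hp), v_mean = as.numeric(p %*% states))
}
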