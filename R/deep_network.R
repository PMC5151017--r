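#' Fine-tuning configuration
#'
#' Defaults encode the supervised training recipe: 200 epochs of minibatch
#' (size 10) stochastic gradient descent on the softmax cross-entropy with an
#' L2 penalty of 5e-5 on the weights, Nesterov momentum ramped linearly from
#' 0.5 to a maximum of 0.9 over the first 10% of epochs, and per-parameter
#' RMSProp rescaling (decay 0.9, epsilon 1e-6).
#'
#' @param learning_rate Positive step size.
#' @param epochs Training epochs.
#' @param minibatch_size Samples per gradient step.
#' @param momentum_max Maximum Nesterov momentum coefficient.
#' @param rmsprop_decay Running-average decay of the squared gradient.
#' @param rmsprop_epsilon Stabilizer added to the RMS denominator.
#' @param weight_decay L2 coefficient (applied to weights, not biases).
#' @param rng_seed Integer seed for shuffling.
#' @return Object of class `finetune_config`.
#' @export
finetune_config <- function(learning_rate = 0.05, epochs = 200,
                            minibatch_size = 10, momentum_max = 0.9,
                            rmsprop_decay = 0.9, rmsprop_epsilon = 1e-6,
                            weight_decay = 5e-5, rng_seed = 1) {
  stopifnot(learning_rate >= 0, epochs >= 0, minibatch_size >= 1,
            momentum_max >= 0, momentum_max < 1,
            rmsprop_decay > 0, rmsprop_decay < 1, rmsprop_epsilon > 0,
            weight_decay >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 momentum_max = momentum_max, rmsprop_decay = rmsprop_decay,
                 rmsprop_epsilon = rmsprop_epsilon,
                 weight_decay = weight_decay, rng_seed = as.integer(rng_seed)),
            class = "finetune_config")
}

momentum_schedule <- function(config) {
  e <- config$epochs
  if (e == 0) return(numeric(0))
  ramp <- max(1L, ceiling(0.1 * e))
  mu <- rep(config$momentum_max, e)
  mu[seq_len(ramp)] <- 0.5 + (config$momentum_max - 0.5) *
    (seq_len(ramp) - 1) / max(1L, ramp - 1L)
  if (ramp == 1) mu[1] <- config$momentum_max
  mu
}

#' Greedy layer-wise pretraining of a deep belief network
#'
#' Trains a stack of RBMs bottom-up: the first layer is a Gaussian-visible
#' RBM on the (z-scored) input features; each subsequent layer is a
#' Bernoulli RBM trained on the deterministic hidden activation
#' probabilities of the frozen layer below.
#'
#' @param data Numeric matrix of standardized features (subjects x features).
#' @param hidden_sizes Integer vector of hidden-layer widths, bottom to top.
#' @param config A [cd_config()]; each layer trains with a layer-specific
#'   seed derived from `config$rng_seed`.
#' @param engine Training engine, see [train_rbm()].
#' @return Object of class `dbn_model`: list of `rbm_parameters` plus an
#'   (initially absent) associative top.
#' @export
pretrain_dbn <- function(data, hidden_sizes, config = cd_config(),
                         engine = c("C", "R")) {
  engine <- match.arg(engine)
  data <- as.matrix(data)
  if (length(hidden_sizes) < 1) stop("need at least one hidden layer")
  if (any(hidden_sizes < 1)) stop("invalid hidden layer sizes")
  frac_off <- mean(abs(colMeans(data)) > 0.5)
  if (frac_off >= 0.10) {
    warning("input does not look standardized (", round(100 * frac_off),
            "% of features have |mean| > 0.5); the first layer assumes ",
            "unit-variance z-scored data")
  }
  layers <- vector("list", length(hidden_sizes))
  cur <- data
  for (l in seq_along(hidden_sizes)) {
    cfg <- config
    cfg$rng_seed <- child_seed(config$rng_seed, l)
    fam <- if (l == 1) "gaussian_unit_variance" else "bernoulli"
    layers[[l]] <- train_rbm(cur, hidden_sizes[l], cfg, visible_family = fam,
                             engine = engine)
    cur <- hidden_conditional(layers[[l]], cur)
  }
  structure(list(layers = layers, hidden_sizes = as.integer(hidden_sizes),
                 n_input = ncol(data), associative_top = NULL),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat("<dbn_model> ", x$n_input, " -> ",
      paste(x$hidden_sizes, collapse = " -> "),
      if (!is.null(x$associative_top)) " (+ associative top)", "\n", sep = "")
  invisible(x)
}

#' Deterministic upward propagation through a DBN
#'
#' @param dbn A `dbn_model`.
#' @param data Input matrix (subjects x features).
#' @param upto Propagate through this many layers (default: all).
#' @return Hidden activation probabilities at the requested layer.
#' @export
dbn_propagate <- function(dbn, data, upto = length(dbn$layers)) {
  cur <- as.matrix(data)
  for (l in seq_len(upto)) cur <- hidden_conditional(dbn$layers[[l]], cur)
  cur
}

#' Initialize a feedforward classifier from a pretrained DBN
#'
#' Hidden-layer weights and biases are copied verbatim from the recognition
#' direction of each RBM; a 2-unit softmax output layer (HC vs SCZ) is
#' appended with all-zero parameters, so the untrained network outputs
#' (0.5, 0.5) for every input.
#'
#' @param dbn A `dbn_model`.
#' @return Object of class `dbn_network`.
#' @export
initialize_network <- function(dbn) {
  stopifnot(inherits(dbn, "dbn_model"))
  layers <- lapply(dbn$layers, function(r) {
    list(W = t(r$W), b = r$b_hid)
  })
  k <- dbn$hidden_sizes[length(dbn$hidden_sizes)]
  structure(list(layers = layers, W_out = matrix(0, k, 2),
                 b_out = numeric(2), n_input = dbn$n_input,
                 classes = c("HC", "SCZ")),
            class = "dbn_network")
}

#' Randomly initialized classifier of the same architecture
#'
#' Baseline for measuring the benefit of generative pretraining: identical
#' architecture, weights from `Normal(0, sd^2)` instead of pretrained values.
#'
#' @param n_input Input width.
#' @param hidden_sizes Hidden-layer widths.
#' @param sd Weight init standard deviation.
#' @param rng_seed Integer seed.
#' @return A `dbn_network`.
#' @export
random_network <- function(n_input, hidden_sizes, sd = 0.01, rng_seed = 1) {
  with_seed(rng_seed, {
    sizes <- c(n_input, hidden_sizes)
    layers <- lapply(seq_along(hidden_sizes), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd),
                      sizes[l], sizes[l + 1]),
           b = numeric(sizes[l + 1]))
    })
    k <- hidden_sizes[length(hidden_sizes)]
    structure(list(layers = layers, W_out = matrix(0, k, 2),
                   b_out = numeric(2), n_input = n_input,
                   classes = c("HC", "SCZ")),
              class = "dbn_network")
  })
}

#' @export
print.dbn_network <- function(x, ...) {
  cat("<dbn_network> ", x$n_input, " -> ",
      paste(vapply(x$layers, function(l) ncol(l$W), integer(1)),
            collapse = " -> "), " -> 2 softmax\n", sep = "")
  invisible(x)
}

network_forward <- function(net, X) {
  X <- as_rowmat(as.matrix(X), net$n_input, "input")
  A <- vector("list", length(net$layers) + 1)
  A[[1]] <- X
  for (l in seq_along(net$layers)) {
    A[[l + 1]] <- logistic(sweep(A[[l]] %*% net$layers[[l]]$W, 2,
                                 net$layers[[l]]$b, "+"))
  }
  logits <- sweep(A[[length(A)]] %*% net$W_out, 2, net$b_out, "+")
  m <- logits - apply(logits, 1, max)
  P <- exp(m) / rowSums(exp(m))
  list(activations = A, logits = logits, prob = P)
}

# cross-entropy + 0.5 * wd * sum of squared weights (weights only)
network_loss <- function(net, X, y, weight_decay = 0) {
  fw <- network_forward(net, X)
  ce <- -mean(log(pmax(fw$prob[cbind(seq_along(y), y + 1)], 1e-300)))
  pen <- sum(vapply(net$layers, function(l) sum(l$W^2), numeric(1))) +
    sum(net$W_out^2)
  ce + 0.5 * weight_decay * pen
}

# analytic gradient of network_loss by backpropagation
network_gradient <- function(net, X, y, weight_decay = 0) {
  fw <- network_forward(net, X)
  A <- fw$activations
  m <- nrow(fw$prob)
  Tm <- matrix(0, m, 2)
  Tm[cbind(seq_len(m), y + 1)] <- 1
  dlog <- (fw$prob - Tm) / m
  L <- length(net$layers)
  gW_out <- t(A[[L + 1]]) %*% dlog + weight_decay * net$W_out
  gb_out <- colSums(dlog)
  grads <- vector("list", L)
  delta <- dlog %*% t(net$W_out)
  for (l in L:1) {
    delta <- delta * A[[l + 1]] * (1 - A[[l + 1]])
    grads[[l]] <- list(W = t(A[[l]]) %*% delta + weight_decay * net$layers[[l]]$W,
                       b = colSums(delta))
    if (l > 1) delta <- delta %*% t(net$layers[[l]]$W)
  }
  list(layers = grads, W_out = gW_out, b_out = gb_out)
}

label_to_binary <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("HC", "SCZ"))) {
    stop("labels must be HC/SCZ (or 0/1); got: ",
         paste(utils::head(setdiff(labels, c("HC", "SCZ")), 3), collapse = ", "))
  }
  as.integer(labels == "SCZ")
}

#' Supervised fine-tuning of a classifier network
#'
#' Minimizes softmax cross-entropy plus L2 weight penalty by minibatch
#' backpropagation with Nesterov momentum (gradient taken at the lookahead
#' point, momentum ramped to `momentum_max`) combined with RMSProp
#' per-parameter step rescaling.
#'
#' @param net A `dbn_network` (from [initialize_network()] or
#'   [random_network()]).
#' @param data Input matrix (subjects x features).
#' @param labels `"HC"`/`"SCZ"` labels or 0/1 (1 = SCZ).
#' @param config A [finetune_config()].
#' @param engine `"C"` (compiled, default) or `"R"` (reference loop); both
#'   consume identical R-generated shuffles and return identical parameters.
#' @return The trained `dbn_network` with a `training_log` attribute
#'   (per-epoch mean minibatch cross-entropy).
#' @export
fine_tune <- function(net, data, labels, config = finetune_config(),
                      engine = c("C", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(net, "dbn_network"))
  X <- as_rowmat(as.matrix(data), net$n_input, "input")
  y <- label_to_binary(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (length(y) != nrow(X)) stop("label/data length mismatch")
  if (config$epochs == 0) return(net)
  n <- nrow(X)
  mu <- momentum_schedule(config)
  with_seed(config$rng_seed, {
    perms <- vapply(seq_len(config$epochs), function(e) sample.int(n),
                    integer(n))
    if (engine == "C") {
      res <- cpp_fine_tune(lapply(net$layers, `[[`, "W"),
                           lapply(net$layers, `[[`, "b"),
                           net$W_out, net$b_out, X, y,
                           config$learning_rate, config$epochs,
                           config$minibatch_size, mu, config$rmsprop_decay,
                           config$rmsprop_epsilon, config$weight_decay, perms)
      for (l in seq_along(net$layers)) {
        net$layers[[l]]$W <- res$W[[l]]
        net$layers[[l]]$b <- as.numeric(res$b[[l]])
      }
      net$W_out <- res$W_out
      net$b_out <- as.numeric(res$b_out)
      attr(net, "training_log") <- as.numeric(res$loss)
      return(net)
    }
    fine_tune_r(net, X, y, config, mu, perms)
  })
}

# plain-R reference engine, step-for-step identical to the compiled path
fine_tune_r <- function(net, X, y, config, mu, perms) {
  n <- nrow(X)
  L <- length(net$layers)
  vel <- list(layers = lapply(net$layers, function(l)
    list(W = l$W * 0, b = l$b * 0)),
    W_out = net$W_out * 0, b_out = net$b_out * 0)
  cache <- vel
  loss <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    idx <- perms[, e]
    Xs <- X[idx, , drop = FALSE]
    ys <- y[idx]
    ce_sum <- 0; nb <- 0
    i0 <- 1
    while (i0 <= n) {
      i1 <- min(n, i0 + config$minibatch_size - 1)
      mub <- mu[e]
      look <- net
      for (l in seq_len(L)) {
        look$layers[[l]]$W <- net$layers[[l]]$W + mub * vel$layers[[l]]$W
        look$layers[[l]]$b <- net$layers[[l]]$b + mub * vel$layers[[l]]$b
      }
      look$W_out <- net$W_out + mub * vel$W_out
      look$b_out <- net$b_out + mub * vel$b_out
      Xb <- Xs[i0:i1, , drop = FALSE]
      yb <- ys[i0:i1]
      g <- network_gradient(look, Xb, yb, config$weight_decay)
      fw <- network_forward(look, Xb)
      ce_sum <- ce_sum - mean(log(pmax(
        fw$prob[cbind(seq_along(yb), yb + 1)], 1e-300)))
      nb <- nb + 1
      for (l in seq_len(L)) {
        cache$layers[[l]]$W <- config$rmsprop_decay * cache$layers[[l]]$W +
          (1 - config$rmsprop_decay) * g$layers[[l]]$W^2
        vel$layers[[l]]$W <- mub * vel$layers[[l]]$W -
          config$learning_rate * g$layers[[l]]$W /
          (sqrt(cache$layers[[l]]$W) + config$rmsprop_epsilon)
        net$layers[[l]]$W <- net$layers[[l]]$W + vel$layers[[l]]$W
        cache$layers[[l]]$b <- config$rmsprop_decay * cache$layers[[l]]$b +
          (1 - config$rmsprop_decay) * g$layers[[l]]$b^2
        vel$layers[[l]]$b <- mub * vel$layers[[l]]$b -
          config$learning_rate * g$layers[[l]]$b /
          (sqrt(cache$layers[[l]]$b) + config$rmsprop_epsilon)
        net$layers[[l]]$b <- net$layers[[l]]$b + vel$layers[[l]]$b
      }
      cache$W_out <- config$rmsprop_decay * cache$W_out +
        (1 - config$rmsprop_decay) * g$W_out^2
      vel$W_out <- mub * vel$W_out - config$learning_rate * g$W_out /
        (sqrt(cache$W_out) + config$rmsprop_epsilon)
      net$W_out <- net$W_out + vel$W_out
      cache$b_out <- config$rmsprop_decay * cache$b_out +
        (1 - config$rmsprop_decay) * g$b_out^2
      vel$b_out <- mub * vel$b_out - config$learning_rate * g$b_out /
        (sqrt(cache$b_out) + config$rmsprop_epsilon)
      net$b_out <- net$b_out + vel$b_out
      i0 <- i1 + 1
    }
    loss[e] <- ce_sum / nb
  }
  attr(net, "training_log") <- loss
  net
}

#' Class probabilities and predicted labels
#'
#' @param net A `dbn_network`.
#' @param rows Input matrix (subjects x features).
#' @return `predict_proba()`: matrix with columns `HC` and `SCZ` summing to
#'   one per row. `predict_label()`: character vector; ties go to `HC`.
#' @export
predict_proba <- function(net, rows) {
  P <- network_forward(net, rows)$prob
  colnames(P) <- net$classes
  P
}

#' @rdname predict_proba
#' @export
predict_label <- function(net, rows) {
  P <- predict_proba(net, rows)
  ifelse(P[, "SCZ"] > P[, "HC"], "SCZ", "HC")
}

#' Total trainable parameter count of a network
#' @param net A `dbn_network`.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1))) +
    length(net$W_out) + length(net$b_out)
}
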