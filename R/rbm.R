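#' Restricted Boltzmann machine parameters
#'
#' A two-layer undirected model with `H` binary hidden units and `V` visible
#' units that are either binary (`"bernoulli"`) or real-valued with fixed
#' unit conditional variance (`"gaussian_unit_variance"`, appropriate for
#' z-scored inputs).
#'
#' @param W Hidden-by-visible weight matrix (`H x V`).
#' @param b_vis Visible bias vector (length `V`).
#' @param b_hid Hidden bias vector (length `H`).
#' @param visible_family `"bernoulli"` or `"gaussian_unit_variance"`.
#' @return Object of class `rbm_parameters`.
#' @export
rbm_parameters <- function(W, b_vis, b_hid,
                           visible_family = c("bernoulli", "gaussian_unit_variance")) {
  visible_family <- match.arg(visible_family)
  W <- as.matrix(W)
  if (length(b_vis) != ncol(W) || length(b_hid) != nrow(W)) {
    stop("bias lengths inconsistent with the weight matrix")
  }
  if (!all(is.finite(W)) || !all(is.finite(b_vis)) || !all(is.finite(b_hid))) {
    stop("RBM parameters must be finite")
  }
  structure(list(W = W, b_vis = as.numeric(b_vis), b_hid = as.numeric(b_hid),
                 visible_family = visible_family),
            class = "rbm_parameters")
}

#' @export
print.rbm_parameters <- function(x, ...) {
  cat("<rbm_parameters> ", ncol(x$W), " visible (", x$visible_family, ") x ",
      nrow(x$W), " hidden\n", sep = "")
  invisible(x)
}

#' Contrastive-divergence training configuration
#'
#' Defaults encode the pretraining recipe used throughout the package:
#' one-step contrastive divergence, weights initialized from
#' `Normal(0, 0.01^2)`, zero initial biases, minibatches of 10 samples,
#' 10 epochs, no momentum or weight decay during pretraining.
#'
#' @param learning_rate Positive step size.
#' @param epochs Number of passes over the data.
#' @param minibatch_size Samples per gradient estimate.
#' @param cd_steps Alternating Gibbs steps in the negative phase.
#' @param init_weight_sd Standard deviation of the Gaussian weight init.
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param weight_decay Non-negative L2 coefficient (weights only).
#' @param rng_seed Integer seed; every stochastic choice derives from it.
#' @return Object of class `cd_config`.
#' @export
cd_config <- function(learning_rate = 0.05, epochs = 10, minibatch_size = 10,
                      cd_steps = 1, init_weight_sd = 0.01, momentum = 0,
                      weight_decay = 0, rng_seed = 1) {
  stopifnot(learning_rate >= 0, epochs >= 0, minibatch_size >= 1,
            cd_steps >= 1, init_weight_sd > 0,
            momentum >= 0, momentum < 1, weight_decay >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 cd_steps = as.integer(cd_steps),
                 init_weight_sd = init_weight_sd, momentum = momentum,
                 weight_decay = weight_decay,
                 rng_seed = as.integer(rng_seed)),
            class = "cd_config")
}

#' Hidden-unit activation probabilities
#'
#' `P(h_j = 1 | v) = logistic(W v + b_hid)_j`, rowwise when `v` is a matrix.
#'
#' @param params An `rbm_parameters`.
#' @param v Visible vector, or matrix with one configuration per row.
#' @return Probabilities with the same row structure as `v`.
#' @export
hidden_conditional <- function(params, v) {
  v <- as_rowmat(v, ncol(params$W), "visible")
  logistic(sweep(v %*% t(params$W), 2, params$b_hid, "+"))
}

#' Visible-unit conditional parameters
#'
#' Bernoulli family: activation probabilities `logistic(W'h + b_vis)`.
#' Gaussian family: conditional means `W'h + b_vis` (unit variance).
#'
#' @param params An `rbm_parameters`.
#' @param h Hidden vector, or matrix with one configuration per row.
#' @return Probabilities (bernoulli) or means (gaussian), rowwise.
#' @export
visible_conditional <- function(params, h) {
  h <- as_rowmat(h, nrow(params$W), "hidden")
  mean_act <- sweep(h %*% params$W, 2, params$b_vis, "+")
  if (params$visible_family == "bernoulli") logistic(mean_act) else mean_act
}

as_rowmat <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != width) {
    stop(what, " dimension mismatch: expected ", width, ", got ", ncol(x))
  }
  x
}

#' One alternating Gibbs step
#'
#' Samples `h ~ P(h | v)` then `v' ~ P(v | h)` (coin flips for bernoulli
#' visibles; mean plus unit-variance Gaussian noise for gaussian visibles).
#' Uses R's RNG stream: seed with `set.seed()` for reproducible chains.
#'
#' @param params An `rbm_parameters`.
#' @param v Visible configuration(s), rowwise.
#' @return List with `h_prob`, `h_sample`, `v_prob` (probabilities or means)
#'   and `v_sample`.
#' @export
gibbs_step <- function(params, v) {
  v <- as_rowmat(v, ncol(params$W), "visible")
  h_prob <- hidden_conditional(params, v)
  h_sample <- (matrix(stats::runif(length(h_prob)), nrow(h_prob)) < h_prob) * 1
  v_prob <- visible_conditional(params, h_sample)
  if (params$visible_family == "bernoulli") {
    v_sample <- (matrix(stats::runif(length(v_prob)), nrow(v_prob)) < v_prob) * 1
  } else {
    v_sample <- v_prob + matrix(stats::rnorm(length(v_prob)), nrow(v_prob))
  }
  list(h_prob = h_prob, h_sample = h_sample, v_prob = v_prob, v_sample = v_sample)
}

#' Single CD-1 parameter update
#'
#' One contrastive-divergence step on one minibatch: positive statistics use
#' the data and the hidden activation probabilities; the reconstruction is
#' the visible conditional (probabilities/means, not samples) of a sampled
#' hidden state; negative statistics use the reconstruction and its hidden
#' probabilities. Gradients are averaged over the actual minibatch size and
#' applied with learning rate, classical momentum, and L2 weight decay on
#' the weights.
#'
#' @param params An `rbm_parameters`.
#' @param minibatch Matrix of visible rows.
#' @param config A [cd_config()].
#' @param state Optional momentum state (as returned in `$state`).
#' @param u Optional uniform variates (`nrow(minibatch) x H`) for the hidden
#'   sampling step; drawn from R's RNG when omitted.
#' @return List with updated `params`, momentum `state`, and the minibatch
#'   mean squared reconstruction error `recon_error`.
#' @export
cd1_update <- function(params, minibatch, config, state = NULL, u = NULL) {
  minibatch <- as_rowmat(minibatch, ncol(params$W), "visible")
  m <- nrow(minibatch)
  if (m == 0) stop("empty minibatch")
  H <- nrow(params$W)
  if (is.null(u)) u <- matrix(stats::runif(m * H), m, H)
  if (is.null(state)) {
    state <- list(W = params$W * 0, b_vis = params$b_vis * 0,
                  b_hid = params$b_hid * 0)
  }
  h_pos <- hidden_conditional(params, minibatch)
  cur_v <- minibatch
  for (k in seq_len(config$cd_steps)) {
    h_prob <- if (k == 1) h_pos else hidden_conditional(params, cur_v)
    uk <- if (k == 1) u else matrix(stats::runif(m * H), m, H)
    h_state <- (uk < h_prob) * 1
    cur_v <- visible_conditional(params, h_state)
  }
  v_recon <- cur_v
  h_neg <- hidden_conditional(params, v_recon)
  gW <- (t(h_pos) %*% minibatch - t(h_neg) %*% v_recon) / m -
    config$weight_decay * params$W
  gbv <- colMeans(minibatch - v_recon)
  gbh <- colMeans(h_pos - h_neg)
  state$W <- config$momentum * state$W + config$learning_rate * gW
  state$b_vis <- config$momentum * state$b_vis + config$learning_rate * gbv
  state$b_hid <- config$momentum * state$b_hid + config$learning_rate * gbh
  params$W <- params$W + state$W
  params$b_vis <- params$b_vis + state$b_vis
  params$b_hid <- params$b_hid + state$b_hid
  list(params = params, state = state,
       recon_error = mean((minibatch - v_recon)^2))
}

#' Train an RBM by one-step contrastive divergence
#'
#' Initializes weights from `Normal(0, init_weight_sd^2)` and biases at zero,
#' then runs `epochs` passes of minibatch CD-1 over the data, reshuffled each
#' epoch. All random draws come from R's RNG seeded with `config$rng_seed`,
#' so runs are reproducible; the compiled fast path and the plain-R path
#' consume the same draws and return bit-identical parameters.
#'
#' @param data Numeric matrix, samples x visible units. Bernoulli training
#'   data must lie in `[0, 1]`.
#' @param n_hidden Number of hidden units.
#' @param config A [cd_config()].
#' @param visible_family Passed to [rbm_parameters()].
#' @param engine `"C"` (compiled, default) or `"R"` (reference loop). CD
#'   steps greater than 1 always use the R path.
#' @return An `rbm_parameters` with an attached `training_log` attribute
#'   (per-epoch mean squared reconstruction error).
#' @export
train_rbm <- function(data, n_hidden, config = cd_config(),
                      visible_family = c("bernoulli", "gaussian_unit_variance"),
                      engine = c("C", "R")) {
  visible_family <- match.arg(visible_family)
  engine <- match.arg(engine)
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("need at least one training sample")
  if (!all(is.finite(data))) stop("non-finite training data")
  if (visible_family == "bernoulli" && (min(data) < 0 || max(data) > 1)) {
    stop("bernoulli training data must lie in [0, 1]")
  }
  n <- nrow(data); V <- ncol(data); H <- as.integer(n_hidden)
  with_seed(config$rng_seed, {
    W <- matrix(stats::rnorm(H * V, 0, config$init_weight_sd), H, V)
    params <- rbm_parameters(W, numeric(V), numeric(H), visible_family)
    if (config$epochs == 0) return(params)
    perms <- vapply(seq_len(config$epochs), function(e) sample.int(n),
                    integer(n))
    U <- matrix(stats::runif(as.double(config$epochs) * n * H),
                config$epochs * n, H)
    if (engine == "C" && config$cd_steps == 1) {
      res <- cpp_train_rbm(data, params$W, params$b_vis, params$b_hid,
                           visible_family == "gaussian_unit_variance",
                           config$learning_rate, config$epochs,
                           config$minibatch_size, config$momentum,
                           config$weight_decay, perms, U)
      out <- rbm_parameters(res$W, res$b_vis, res$b_hid, visible_family)
      attr(out, "training_log") <- as.numeric(res$recon)
      return(out)
    }
    state <- NULL
    recon <- numeric(config$epochs)
    for (e in seq_len(config$epochs)) {
      xs <- data[perms[, e], , drop = FALSE]
      sse <- 0
      i0 <- 1
      while (i0 <= n) {
        i1 <- min(n, i0 + config$minibatch_size - 1)
        u <- U[(e - 1) * n + (i0:i1), , drop = FALSE]
        upd <- cd1_update(params, xs[i0:i1, , drop = FALSE], config,
                          state = state, u = u)
        params <- upd$params
        state <- upd$state
        sse <- sse + upd$recon_error * (i1 - i0 + 1)
        i0 <- i1 + 1
      }
      recon[e] <- sse / n
    }
    attr(params, "training_log") <- recon
    params
  })
}

#' Free energy of a visible configuration
#'
#' Bernoulli family: `-b_vis . v - sum_j softplus(W v + b_hid)_j`.
#' Gaussian family: `||v - b_vis||^2 / 2 - sum_j softplus(W v + b_hid)_j`.
#'
#' @param params An `rbm_parameters`.
#' @param v Visible configuration(s), rowwise.
#' @return Numeric vector of free energies, one per row.
#' @export
free_energy <- function(params, v) {
  v <- as_rowmat(v, ncol(params$W), "visible")
  act <- sweep(v %*% t(params$W), 2, params$b_hid, "+")
  sp <- rowSums(softplus(act))
  if (params$visible_family == "bernoulli") {
    -as.numeric(v %*% params$b_vis) - sp
  } else {
    0.5 * rowSums(sweep(v, 2, params$b_vis)^2) - sp
  }
}

all_binary_states <- function(k) {
  if (k == 0) return(matrix(numeric(0), 1, 0))
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  dimnames(g) <- NULL
  g
}

#' Exact average log-likelihood of a small bernoulli RBM
#'
#' Computes the partition function by brute-force enumeration of all visible
#' configurations via the free energy, feasible only for small models; used
#' as a ground-truth oracle for the stochastic training procedures.
#'
#' @param params A bernoulli-visible `rbm_parameters` with at most 20 units
#'   in total.
#' @param data Matrix of binary visible rows.
#' @return Average log-likelihood per data row.
#' @export
exact_log_likelihood <- function(params, data) {
  if (params$visible_family != "bernoulli") {
    stop("exact enumeration is implemented for bernoulli-visible models only")
  }
  V <- ncol(params$W); H <- nrow(params$W)
  if (V + H > 20) {
    stop("model too large for exact enumeration (", V + H,
         " units > 20); use reconstruction-error diagnostics instead")
  }
  states <- all_binary_states(V)
  logZ <- logsumexp(-free_energy(params, states))
  mean(-free_energy(params, as_rowmat(data, V, "visible"))) - logZ
}

#' Exact gradient of the average log-likelihood (small bernoulli RBM)
#'
#' The expected-statistics form: data-expectation of `(h v', v, h)` minus the
#' model expectation computed by full enumeration of the visible states.
#'
#' @inheritParams exact_log_likelihood
#' @return List `dW`, `db_vis`, `db_hid`.
#' @export
rbm_exact_gradient <- function(params, data) {
  if (params$visible_family != "bernoulli") stop("bernoulli models only")
  V <- ncol(params$W); H <- nrow(params$W)
  if (V + H > 20) stop("model too large for exact enumeration")
  data <- as_rowmat(data, V, "visible")
  n <- nrow(data)
  hp_data <- hidden_conditional(params, data)
  dW_data <- t(hp_data) %*% data / n
  states <- all_binary_states(V)
  logp <- -free_energy(params, states)
  p <- exp(logp - logsumexp(logp))
  hp_model <- hidden_conditional(params, states)
  dW_model <- t(hp_model * p) %*% states
  list(dW = dW_data - dW_model,
       db_vis = colMeans(data) - as.numeric(p %*% states),
       db_hid = colMeans(hp_data) - as.numeric(p %*% hp_model))
}
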