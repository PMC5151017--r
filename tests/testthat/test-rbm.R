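random_rbm <- function(V, H, family = "bernoulli", sd = 0.6, rng_seed = 1) {
  set.seed(rng_seed)
  rbm_parameters(matrix(rnorm(H * V, 0, sd), H, V), rnorm(V, 0, 0.3),
                 rnorm(H, 0, 0.3), family)
}

test_that("conditionals match an elementwise logistic oracle", {
  p <- random_rbm(4, 3)
  expect_equal(unname(hidden_conditional(p, rep(0, 4))[1, ]),
               plogis(p$b_hid))
  expect_true(all(hidden_conditional(rbm_parameters(matrix(0, 3, 4),
                                                    rep(0, 4), rep(0, 3)),
                                     runif(4)) == 0.5))
  v <- c(1, 0, 1, 1)
  byhand <- vapply(1:3, function(j)
    1 / (1 + exp(-(sum(p$W[j, ] * v) + p$b_hid[j]))), numeric(1))
  expect_equal(unname(hidden_conditional(p, v)[1, ]), byhand, tolerance = 1e-14)
  # saturation
  psat <- rbm_parameters(matrix(0, 1, 1), 0, 30)
  expect_gt(hidden_conditional(psat, 0)[1, 1], 0.999999)
})

test_that("visible conditionals respect the unit family", {
  g <- rbm_parameters(matrix(0, 3, 4), c(1, -1, 0.5, 2), rep(0, 3),
                      "gaussian_unit_variance")
  expect_equal(unname(visible_conditional(g, rep(1, 3))[1, ]),
               c(1, -1, 0.5, 2))
  b <- rbm_parameters(matrix(0, 3, 4), rep(0, 4), rep(0, 3))
  expect_true(all(visible_conditional(b, rep(1, 3)) == 0.5))
  # transpose duality: P(v|h) of the swapped model equals P(h|v)
  p <- random_rbm(4, 3, rng_seed = 7)
  swapped <- rbm_parameters(t(p$W), p$b_hid, p$b_vis)
  h <- c(1, 0, 1)
  expect_equal(visible_conditional(swapped, c(1, 0, 1, 1)),
               hidden_conditional(p, c(1, 0, 1, 1)), tolerance = 1e-14)
})

test_that("gibbs sampling is seed-reproducible, saturates, and is calibrated", {
  p <- random_rbm(4, 3, rng_seed = 2)
  s1 <- with_seed(5, gibbs_step(p, c(1, 0, 1, 0)))
  s2 <- with_seed(5, gibbs_step(p, c(1, 0, 1, 0)))
  expect_identical(s1, s2)
  # saturated biases force a deterministic fixed point
  psat <- rbm_parameters(matrix(0, 2, 2), c(30, -30), c(30, -30))
  s <- with_seed(1, gibbs_step(psat, c(0, 1)))
  expect_equal(unname(s$h_sample[1, ]), c(1, 0))
  expect_equal(unname(s$v_sample[1, ]), c(1, 0))
  # Monte Carlo calibration of the visible conditional at fixed h
  h <- c(1, 0, 1)
  mu <- visible_conditional(p, h)[1, ]
  draws <- with_seed(11, {
    hs <- matrix(h, 10000, 3, byrow = TRUE)
    vp <- visible_conditional(p, hs)
    (matrix(runif(length(vp)), nrow(vp)) < vp) * 1
  })
  se <- sqrt(mu * (1 - mu) / 10000)
  expect_lt(max(abs(colMeans(draws) - mu) / se), 4)
})

test_that("a single CD-1 update equals hand-computed statistics", {
  p <- random_rbm(2, 2, rng_seed = 3)
  batch <- rbind(c(1, 0), c(0, 1), c(1, 1))
  u <- matrix(c(0.2, 0.9, 0.5, 0.1, 0.7, 0.4), 3, 2)
  cfg <- cd_config(learning_rate = 0.3, weight_decay = 0.01)
  upd <- cd1_update(p, batch, cfg, u = u)
  # independent hand computation
  hp <- 1 / (1 + exp(-(batch %*% t(p$W) + rep(1, 3) %o% p$b_hid)))
  hs <- (u < hp) * 1
  vr <- 1 / (1 + exp(-(hs %*% p$W + rep(1, 3) %o% p$b_vis)))
  hn <- 1 / (1 + exp(-(vr %*% t(p$W) + rep(1, 3) %o% p$b_hid)))
  gW <- (t(hp) %*% batch - t(hn) %*% vr) / 3 - 0.01 * p$W
  expect_equal(upd$params$W, p$W + 0.3 * gW, tolerance = 1e-13)
  expect_equal(upd$params$b_vis, p$b_vis + 0.3 * colMeans(batch - vr),
               tolerance = 1e-13)
  expect_equal(upd$params$b_hid, p$b_hid + 0.3 * colMeans(hp - hn),
               tolerance = 1e-13)
  # zero learning rate leaves parameters unchanged
  upd0 <- cd1_update(p, batch, cd_config(learning_rate = 0), u = u)
  expect_identical(upd0$params$W, p$W)
  expect_error(cd1_update(p, batch[0, , drop = FALSE], cfg), "empty")
})

test_that("weight decay pulls weights toward zero", {
  # identical data, uniforms and steps; the only difference is the decay term,
  # whose per-step effect is -lr * wd * W
  p <- random_rbm(3, 2, sd = 1.5, rng_seed = 5)
  batch <- rbind(c(1, 0, 1), c(0, 1, 0))
  u <- matrix(c(0.3, 0.8, 0.6, 0.2), 2, 2)
  p_free <- p_decay <- p
  for (i in 1:20) {
    p_free <- cd1_update(p_free, batch,
                         cd_config(learning_rate = 0.1), u = u)$params
    p_decay <- cd1_update(p_decay, batch,
                          cd_config(learning_rate = 0.1, weight_decay = 0.3),
                          u = u)$params
  }
  expect_lt(sum(p_decay$W^2), sum(p_free$W^2))
})

test_that("train_rbm honors the configured recipe and is deterministic", {
  set.seed(1)
  X <- (matrix(runif(80), 20, 4) > 0.5) * 1
  cfg <- cd_config(epochs = 0, rng_seed = 6)
  init <- train_rbm(X, 3, cfg)
  # epochs 0 returns the Gaussian(0, 0.01) initialization with zero biases
  expect_true(all(init$b_vis == 0) && all(init$b_hid == 0))
  expect_lt(max(abs(init$W)), 0.1)
  a <- train_rbm(X, 3, cd_config(epochs = 5, rng_seed = 6))
  b <- train_rbm(X, 3, cd_config(epochs = 5, rng_seed = 6))
  expect_identical(a, b)
  c2 <- train_rbm(X, 3, cd_config(epochs = 5, rng_seed = 7))
  expect_false(identical(a$W, c2$W))
  expect_error(train_rbm(X * 2, 3, cd_config()), "\\[0, 1\\]")
  expect_error(train_rbm(X * NA, 3, cd_config()), "finite")
})

test_that("compiled and reference training engines agree bit-for-bit", {
  set.seed(2)
  X <- (matrix(runif(120), 30, 4) > 0.4) * 1
  cfg <- cd_config(epochs = 4, minibatch_size = 7, momentum = 0.5,
                   weight_decay = 1e-3, rng_seed = 9)
  a <- train_rbm(X, 5, cfg, engine = "C")
  b <- train_rbm(X, 5, cfg, engine = "R")
  expect_equal(a$W, b$W, tolerance = 1e-12)
  expect_equal(attr(a, "training_log"), attr(b, "training_log"),
               tolerance = 1e-12)
  Z <- matrix(rnorm(150), 30, 5)
  g1 <- train_rbm(Z, 4, cfg, "gaussian_unit_variance", engine = "C")
  g2 <- train_rbm(Z, 4, cfg, "gaussian_unit_variance", engine = "R")
  expect_equal(g1$W, g2$W, tolerance = 1e-12)
})

test_that("free energy matches its closed forms in degenerate cases", {
  zero <- rbm_parameters(matrix(0, 5, 4), rep(0, 4), rep(0, 5))
  expect_equal(free_energy(zero, c(1, 0, 1, 0)), -5 * log(2))
  g <- rbm_parameters(matrix(0, 3, 4), c(1, 2, 3, 4), rep(0, 3),
                      "gaussian_unit_variance")
  expect_equal(free_energy(g, c(1, 2, 3, 4)), -3 * log(2))
  expect_gt(free_energy(g, c(0, 2, 3, 4)), free_energy(g, c(1, 2, 3, 4)))
})

test_that("exact likelihood agrees with a second enumeration over the joint", {
  p <- random_rbm(3, 3, rng_seed = 4)
  data <- (matrix(runif(15), 5, 3) > 0.5) * 1
  # independent oracle: enumerate all (v, h) jointly from the energy
  energy <- function(v, h) {
    -as.numeric(t(h) %*% p$W %*% v) - sum(p$b_vis * v) - sum(p$b_hid * h)
  }
  vs <- as.matrix(expand.grid(rep(list(0:1), 3)))
  hs <- vs
  Z <- 0
  pv <- numeric(nrow(vs))
  for (i in seq_len(nrow(vs))) {
    for (j in seq_len(nrow(hs))) {
      e <- exp(-energy(vs[i, ], hs[j, ]))
      Z <- Z + e
      pv[i] <- pv[i] + e
    }
  }
  oracle_ll <- mean(log(pv[apply(data, 1, function(r)
    which(colSums(abs(t(vs) - r)) == 0))])) - log(Z)
  expect_equal(exact_log_likelihood(p, data), oracle_ll, tolerance = 1e-10)
  # uniform model baseline and hidden-permutation invariance
  zero <- rbm_parameters(matrix(0, 3, 4), rep(0, 4), rep(0, 3))
  expect_equal(exact_log_likelihood(zero, (matrix(runif(12), 3) > 0.5) * 1),
               -4 * log(2))
  perm <- rbm_parameters(p$W[c(2, 3, 1), ], p$b_vis, p$b_hid[c(2, 3, 1)])
  expect_equal(exact_log_likelihood(perm, data), exact_log_likelihood(p, data),
               tolerance = 1e-12)
  big <- rbm_parameters(matrix(0, 15, 15), rep(0, 15), rep(0, 15))
  expect_error(exact_log_likelihood(big, diag(15)), "too large")
})

test_that("analytic expected-statistics gradient matches finite differences", {
  fix <- tiny_fixture("rbm", rng_seed = 2)
  p <- rbm_parameters(fix$params$W[1:3, 1:3], fix$params$b_vis[1:3],
                      fix$params$b_hid, "bernoulli")
  d <- fix$data[, 1:3]
  g <- rbm_exact_gradient(p, d)
  h <- 1e-5
  for (idx in list(c(1, 1), c(2, 3), c(3, 2))) {
    pp <- p; pp$W[idx[1], idx[2]] <- pp$W[idx[1], idx[2]] + h
    pm <- p; pm$W[idx[1], idx[2]] <- pm$W[idx[1], idx[2]] - h
    num <- (exact_log_likelihood(pp, d) - exact_log_likelihood(pm, d)) / (2 * h)
    expect_equal(num, g$dW[idx[1], idx[2]], tolerance = 1e-5)
  }
  for (j in 1:3) {
    pp <- p; pp$b_vis[j] <- pp$b_vis[j] + h
    pm <- p; pm$b_vis[j] <- pm$b_vis[j] - h
    num <- (exact_log_likelihood(pp, d) - exact_log_likelihood(pm, d)) / (2 * h)
    expect_equal(num, g$db_vis[j], tolerance = 1e-5)
  }
})

test_that("CD-1 training raises the exact likelihood of enumerable models", {
  wins <- 0
  for (s in 1:10) {
    fix <- tiny_fixture("rbm", rng_seed = s)
    init <- train_rbm(fix$data, 3, cd_config(learning_rate = 0.1, epochs = 0,
                                             rng_seed = s))
    tr <- train_rbm(fix$data, 3, cd_config(learning_rate = 0.1, epochs = 20,
                                           rng_seed = s))
    wins <- wins + (exact_log_likelihood(tr, fix$data) >
                      exact_log_likelihood(init, fix$data))
  }
  expect_gte(wins, 8)
})

test_that("gaussian RBM reconstruction error improves during training", {
  co <- generate_cohort(sim_config(rng_seed = 3))
  z <- preprocess_table(co$table)$table
  g <- train_rbm(z$features, 50, cd_config(learning_rate = 0.05, rng_seed = 2),
                 "gaussian_unit_variance")
  log <- attr(g, "training_log")
  expect_gte(sum(diff(log) <= 0), 8)
})
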