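#' Default planted effect regions
#'
#' The ten brain measures used as default planted-effect regions by the
#' cohort simulator: a mix of subcortical volumes and cortical thickness
#' regions spanning frontal, temporal, parietal and insular cortex.
#'
#' @return Character vector of ten canonical feature names.
#' @export
default_effect_regions <- function() {
  c("Right-Cerebellum-White-Matter", "Right-Lateral-Ventricle",
    "rh_entorhinal", "rh_rostralanteriorcingulate", "lh_inferiorparietal",
    "rh_insula", "lh_transversetemporal", "rh_inferiortemporal",
    "lh_lateralorbitofrontal", "Left-Putamen")
}

#' Cohort simulation configuration
#'
#' Defaults emulate the demographics of a chronic-schizophrenia case-control
#' study with an intermediate first-episode cohort: group sizes 83 (HC), 143
#' (SCZ), 32 (FEP); ages 35.49 +/- 11.08, 37.12 +/- 10.99 and 27.09 +/- 7.97
#' years; male fractions 56/83, 95/143 and 15/32. Each feature j is
#' generated as
#' `mu_j + beta_age_j (age - mean age) + beta_sex_j sex + delta_j g + eps`,
#' where `g` is 0 for HC, 1 for SCZ and `fep_scale` for FEP, `delta_j` equals
#' `effect_size_d` residual standard deviations on the effect regions and 0
#' elsewhere, and `eps` is Gaussian with an optional equicorrelation across
#' features (shared per-subject variance).
#'
#' @param n_hc,n_scz,n_fep Group sizes.
#' @param effect_regions Canonical feature names carrying the planted group
#'   effect.
#' @param effect_size_d Standardized mean difference (SCZ vs HC) on the
#'   effect regions.
#' @param fep_scale Lambda in `[0, 1]`: FEP effect is `lambda * d`
#'   (0 = HC-like, 1 = SCZ-like, 0.5 = midway).
#' @param age_mean,age_sd Length-3 vectors (HC, SCZ, FEP).
#' @param male_frac Length-3 male probability (HC, SCZ, FEP).
#' @param residual_sd Multiplier on the per-feature residual scale.
#' @param equicorrelation Shared-variance fraction across features in
#'   `[0, 1)`.
#' @param rng_seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_hc = 83, n_scz = 143, n_fep = 32,
                       effect_regions = default_effect_regions(),
                       effect_size_d = 1.0, fep_scale = 0.5,
                       age_mean = c(hc = 35.49, scz = 37.12, fep = 27.09),
                       age_sd = c(hc = 11.08, scz = 10.99, fep = 7.97),
                       male_frac = c(hc = 56 / 83, scz = 95 / 143,
                                     fep = 15 / 32),
                       residual_sd = 1, equicorrelation = 0.2,
                       rng_seed = 1) {
  stopifnot(n_hc >= 0, n_scz >= 0, n_fep >= 0, effect_size_d >= 0,
            fep_scale >= 0, fep_scale <= 1, residual_sd > 0,
            equicorrelation >= 0, equicorrelation < 1)
  structure(list(n_hc = n_hc, n_scz = n_scz, n_fep = n_fep,
                 effect_regions = effect_regions,
                 effect_size_d = effect_size_d, fep_scale = fep_scale,
                 age_mean = age_mean, age_sd = age_sd,
                 male_frac = male_frac, residual_sd = residual_sd,
                 equicorrelation = equicorrelation,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# deterministic structure-typical baselines: thickness ~2.2-2.8 mm with
# residual sd 0.15 mm; volumes log-spaced 300 mm^3 - 60 cm^3 with 10%
# residual sd
feature_baselines <- function(schema = feature_schema()) {
  nt <- length(schema$thickness_names)
  nv <- length(schema$volume_names)
  mu <- c(seq(2.2, 2.8, length.out = nt),
          exp(seq(log(300), log(60000), length.out = nv)))
  sdv <- c(rep(0.15, nt), 0.10 * mu[-seq_len(nt)])
  names(mu) <- names(sdv) <- schema$feature_names
  list(mean = mu, sd = sdv)
}

#' Generate a synthetic morphometry cohort with known ground truth
#'
#' @param config A [sim_config()].
#' @param schema A [feature_schema()].
#' @return List with `table` (a `morph_table`, provenance `"synthetic"`) and
#'   `truth` (planted effect vector, confound coefficients, and the config).
#' @export
generate_cohort <- function(config = sim_config(), schema = feature_schema()) {
  stopifnot(inherits(config, "sim_config"))
  bad <- setdiff(config$effect_regions, schema$feature_names)
  if (length(bad)) {
    stop("unknown region name(s) in effect_regions: ",
         paste(bad, collapse = ", "))
  }
  base <- feature_baselines(schema)
  sigma <- base$sd * config$residual_sd
  p <- length(schema$feature_names)
  delta <- stats::setNames(numeric(p), schema$feature_names)
  delta[config$effect_regions] <- config$effect_size_d * sigma[config$effect_regions]
  beta_age <- -0.02 * sigma          # gentle atrophy with age, per year
  beta_sex <- 0.3 * sigma            # males slightly larger / thicker
  ns <- c(config$n_hc, config$n_scz, config$n_fep)
  labels <- rep(c("HC", "SCZ", "FEP"), ns)
  g <- rep(c(0, 1, config$fep_scale), ns)
  n <- sum(ns)
  with_seed(config$rng_seed, {
    age <- stats::rnorm(n, rep(config$age_mean, ns), rep(config$age_sd, ns))
    sex <- stats::rbinom(n, 1, rep(config$male_frac, ns))
    rho <- config$equicorrelation
    shared <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * p), n, p)
    eps <- (sqrt(rho) * shared + sqrt(1 - rho) * noise) %*% diag(sigma)
    feats <- matrix(base$mean, n, p, byrow = TRUE) +
      outer(age - mean(age), beta_age) + outer(sex, beta_sex) +
      outer(g, delta) + eps
    colnames(feats) <- schema$feature_names
    table <- morph_table(sprintf("S%04d", seq_len(n)), labels, age, sex,
                         feats, provenance = "synthetic", schema = schema)
    list(table = table,
         truth = list(effect_regions = config$effect_regions,
                      effect = delta, beta_age = beta_age,
                      beta_sex = beta_sex, sigma = sigma,
                      baseline_mean = base$mean, config = config))
  })
}

#' Tiny enumerable fixtures for oracle tests
#'
#' Small models (at most 20 binary units, so exact enumeration is feasible)
#' together with datasets sampled exactly from them.
#'
#' * `"rbm"`: a 4-visible / 3-hidden Bernoulli RBM and 60 visible rows drawn
#'   from its exact marginal.
#' * `"associative"`: a Bernoulli RBM over 6 free visible units + 2 one-hot
#'   label units with 6 hidden units (14 total), plus 80 visible rows drawn
#'   from its exact joint restricted to valid one-hot label codes.
#' * `"network"`: a 2-input / 4-hidden softmax network and a separable 2-D
#'   two-class dataset.
#'
#' @param kind `"rbm"`, `"associative"` or `"network"`.
#' @param rng_seed Integer seed.
#' @return A list; components depend on `kind` (see Details).
#' @export
tiny_fixture <- function(kind = c("rbm", "associative", "network"),
                         rng_seed = 1) {
  kind <- match.arg(kind)
  with_seed(rng_seed, {
    if (kind == "rbm") {
      V <- 4; H <- 3
      params <- rbm_parameters(matrix(stats::rnorm(H * V, 0, 0.8), H, V),
                               stats::rnorm(V, 0, 0.3),
                               stats::rnorm(H, 0, 0.3), "bernoulli")
      states <- all_binary_states(V)
      logp <- -free_energy(params, states)
      prob <- exp(logp - logsumexp(logp))
      rows <- sample.int(nrow(states), 60, replace = TRUE, prob = prob)
      list(params = params, data = states[rows, , drop = FALSE])
    } else if (kind == "associative") {
      nf <- 6; H <- 6
      V <- nf + 2
      params <- rbm_parameters(matrix(stats::rnorm(H * V, 0, 0.5), H, V),
                               stats::rnorm(V, 0, 0.2),
                               stats::rnorm(H, 0, 0.2), "bernoulli")
      states <- all_binary_states(V)
      valid <- states[, nf + 1] + states[, nf + 2] == 1
      states <- states[valid, , drop = FALSE]
      logp <- -free_energy(params, states)
      prob <- exp(logp - logsumexp(logp))
      rows <- sample.int(nrow(states), 80, replace = TRUE, prob = prob)
      list(params = params, data = states[rows, , drop = FALSE],
           label_index = nf + 1:2)
    } else {
      n <- 40
      y <- rep(0:1, each = n / 2)
      X <- cbind(stats::rnorm(n, ifelse(y == 1, 1.5, -1.5), 1),
                 stats::rnorm(n, ifelse(y == 1, 1, -1), 1))
      net <- random_network(2, 4, sd = 0.1, rng_seed = rng_seed)
      list(net = net, X = X, y = y)
    }
  })
}
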