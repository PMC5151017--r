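# shared fixtures built in code; all seeded for reproducibility

# five planted regions used by the probe recovery tests
probe_regions <- c("Right-Cerebellum-White-Matter", "rh_entorhinal",
                   "lh_inferiorparietal", "rh_insula", "Left-Putamen")

# small two-group cohort with identical demographics across groups, so raw
# group contrasts are confound-free
balanced_cohort <- function(n_per_group, d, regions = probe_regions,
                            rng_seed = 1, n_fep = 0, fep_scale = 0.5) {
  generate_cohort(sim_config(
    n_hc = n_per_group, n_scz = n_per_group, n_fep = n_fep,
    effect_regions = regions, effect_size_d = d, fep_scale = fep_scale,
    age_mean = c(hc = 35, scz = 35, fep = 35),
    age_sd = c(hc = 10, scz = 10, fep = 10),
    male_frac = c(hc = 0.6, scz = 0.6, fep = 0.6),
    rng_seed = rng_seed))
}

# complete synthetic per-subject stats maps matching the canonical schema
synthetic_stats_maps <- function(rng_seed = 1) {
  sch <- feature_schema()
  set.seed(rng_seed)
  lh <- stats::setNames(round(stats::runif(34, 1.5, 3.5), 4), dk_region_names())
  rh <- stats::setNames(round(stats::runif(34, 1.5, 3.5), 4), dk_region_names())
  vol <- stats::setNames(round(stats::runif(45, 100, 60000), 4),
                         sch$volume_names)
  list(lh = lh, rh = rh, vol = vol)
}

dk_region_names <- function() {
  sub("^lh_", "", feature_schema()$thickness_names[1:34])
}
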