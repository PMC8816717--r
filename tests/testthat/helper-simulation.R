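# quiet the stage logging during tests
options(proteoflux.quiet = TRUE)

default_schedule <- function() labeling_schedule(label_days = 6)

noise_free <- function() noise_model(intensity_cv = 0, missing_rate = 0)

# equal mix over all seven mechanism archetypes
archetype_mix <- function() {
  setNames(rep(1 / length(mechanism_levels), length(mechanism_levels)),
           mechanism_levels)
}

# small end-to-end simulation used by several test files
sim_small <- function(n_proteins = 120, seed = 7, noise = noise_model(),
                      schedule = default_schedule(), ...) {
  truth <- simulate_ground_truth(n_proteins, seed = seed,
                                 schedule = schedule, ...)
  sim <- simulate_cohorts(truth, schedule, noise, seed = seed + 1)
  list(truth = truth, evidence = sim$evidence, abundance = sim$abundance)
}

# run the turnover arm of the pipeline on an evidence table
turnover_arm <- function(evidence, ...) {
  merge_fractions(aggregate_to_protein(compute_incorporation(evidence), ...))
}

# hand-coded Welch p-value, independent of stats::t.test
welch_p_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(y) - mean(x)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}
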