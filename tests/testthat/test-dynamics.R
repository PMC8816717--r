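make_incorporation <- function(protein_id, control, disease,
                               fraction_id = "F01") {
  tibble::tibble(
    protein_id = protein_id,
    fraction_id = fraction_id,
    mouse_id = c(paste0("C", seq_along(control)),
                 paste0("D", seq_along(disease))),
    cohort = rep(c("control", "disease"), c(length(control), length(disease))),
    incorporation = c(control, disease),
    n_peptides = 1L)
}

test_that("per-protein tests handle identical and degenerate cohorts", {
  same <- make_incorporation("P1", c(0.30, 0.31, 0.29), c(0.30, 0.31, 0.29))
  out <- protein_turnover_test(same)
  expect_equal(out$delta, 0)
  expect_equal(out$p_value, 1)
  const <- make_incorporation("P2", c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4))
  out2 <- protein_turnover_test(const)
  expect_equal(out2$delta, 0.2)
  expect_true(out2$degenerate)
  expect_lt(out2$p_value, 1e-300)
  expect_gt(out2$p_value, 0)
})

test_that("p-values match an independently coded Welch evaluation", {
  withr::local_seed(55)
  for (i in 1:100) {
    ctrl <- runif(sample(2:5, 1), 0.1, 0.6)
    dis <- runif(sample(2:5, 1), 0.1, 0.6)
    tbl <- make_incorporation(sprintf("P%03d", i), ctrl, dis)
    got <- protein_turnover_test(tbl)
    expect_equal(got$p_value, welch_p_oracle(ctrl, dis), tolerance = 1e-10)
    expect_equal(got$delta, mean(dis) - mean(ctrl))
  }
  # pooled flag reproduces the classical Student statistic
  ctrl <- c(0.25, 0.30, 0.35); dis <- c(0.40, 0.45, 0.50)
  pooled <- protein_turnover_test(make_incorporation("P1", ctrl, dis),
                                  pooled = TRUE)
  expect_equal(pooled$p_value,
               t.test(dis, ctrl, var.equal = TRUE)$p.value)
})

test_that("GAPT summarizes cohort means and recovers injected scalings", {
  k <- log(2) / exp(seq(log(2), log(60), length.out = 300))
  i_c <- expected_incorporation(k, default_schedule())
  as_comparisons <- function(ic, id) {
    tibble::tibble(protein_id = sprintf("P%03d", seq_along(ic)),
                   mean_incorporation_control = ic,
                   mean_incorporation_disease = id)
  }
  # identical cohorts
  null <- compute_gapt(as_comparisons(i_c, i_c))
  expect_equal(null$percent_change, 0)
  expect_equal(null$p_value, 1)
  # uniform -6.1% scaling is recovered exactly
  slow <- compute_gapt(as_comparisons(i_c, 0.939 * i_c))
  expect_equal(slow$percent_change, -6.1, tolerance = 1e-10)
  # an 18% rate speedup maps to ~+18% at low incorporation ...
  k_lo <- rep(0.005, 200)
  lo <- compute_gapt(as_comparisons(
    expected_incorporation(k_lo, default_schedule()),
    expected_incorporation(1.18 * k_lo, default_schedule())))
  expect_gt(lo$percent_change, 16.5)
  expect_lt(lo$percent_change, 18)
  # ... and is compressed near saturation
  k_hi <- rep(0.5, 200)
  hi <- compute_gapt(as_comparisons(
    expected_incorporation(k_hi, default_schedule()),
    expected_incorporation(1.18 * k_hi, default_schedule())))
  expect_lt(hi$percent_change, 5)
})

test_that("an all-decreasing aging series gives fraction 1 and a vanishing p", {
  k <- withr::with_seed(66, rlnorm(360, log(0.022), 0.7))
  tbl_at <- function(scale) tibble::tibble(
    protein_id = sprintf("P%03d", seq_along(k)),
    incorporation = expected_incorporation(scale * k, default_schedule()))
  res <- aging_trend(list(tbl_at(1), tbl_at(0.8), tbl_at(0.64)),
                     ages = c(113, 285, 503))
  expect_equal(res$fraction_decreasing, 1)
  expect_equal(res$n_proteins, 360)
  expect_lt(res$p_value, 1e-15)
  expect_true(all(res$slopes$slope < 0))
})

test_that("a trend-free aging series stays near the null", {
  withr::local_seed(68)
  base <- runif(200, 0.05, 0.6)
  jitter_tbl <- function() tibble::tibble(
    protein_id = sprintf("P%03d", seq_along(base)),
    incorporation = pmin(pmax(base + rnorm(200, 0, 0.02), 0.01), 0.9))
  res <- aging_trend(list(jitter_tbl(), jitter_tbl(), jitter_tbl()),
                     ages = c(113, 285, 503))
  expect_gt(res$fraction_decreasing, 0.35)
  expect_lt(res$fraction_decreasing, 0.65)
  expect_gt(res$p_value, 0.05)
})

test_that("a simulated age series with slowing turnover is detected", {
  # wild-type cohorts at three ages, degradation slowed 0.8-fold per step
  sched <- default_schedule()
  tables <- lapply(0:2, function(step) {
    truth <- simulate_ground_truth(360, seed = 71,
                                   k_meanlog = log(0.022) + step * log(0.8))
    sim <- simulate_cohorts(truth, sched, noise_model(), seed = 72 + step)
    ctrl <- sim$evidence[sim$evidence$cohort == "control", ]
    merge_fractions(aggregate_to_protein(compute_incorporation(ctrl)))
  })
  res <- aging_trend(tables, ages = c(113, 285, 503))
  expect_gt(res$n_proteins, 300)
  expect_gte(res$fraction_decreasing, 0.95)
  expect_lt(res$p_value, 1e-15)
  expect_lt(median(res$slopes$slope), 0)
})

test_that("aging restricts to proteins present at every age", {
  t1 <- tibble::tibble(protein_id = c("P1", "P2", "P3"),
                       incorporation = c(0.3, 0.4, 0.5))
  t2 <- tibble::tibble(protein_id = c("P1", "P2"),
                       incorporation = c(0.2, 0.3))
  res <- aging_trend(list(t1, t2), ages = c(100, 200))
  expect_equal(res$n_proteins, 2)
  expect_error(aging_trend(list(t1, t2), ages = c(200, 100)), "increasing")
})

test_that("the dynaplot table mirrors the classification", {
  sim <- sim_small(n_proteins = 150, seed = 501,
                   mechanism_mix = archetype_mix())
  merged <- turnover_arm(sim$evidence)
  prof <- integrate_abundance(fraction_completeness_filter(sim$abundance))
  res <- compare_dynamics(merged, prof)
  tab <- dynaplot_table(res)
  # colors agree with classify_mechanism output for every row
  reclass <- classify_mechanism(res$turnover_delta, res$turnover_p,
                                res$abundance_delta, res$abundance_p)
  expect_equal(tab$mechanism_class[match(res$protein_id, tab$protein_id)],
               reclass$mechanism_class)
  expect_equal(tab$color,
               unname(mechanism_palette[tab$mechanism_class]))
  expect_equal(tab$turnover_delta_pp,
               100 * res$turnover_delta[match(tab$protein_id,
                                              res$protein_id)])
  p <- dynaplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("noise-free archetypes classify perfectly through the pipeline", {
  truth <- simulate_ground_truth(210, seed = 503,
                                 mechanism_mix = archetype_mix())
  sim <- simulate_cohorts(truth, default_schedule(), noise_free(),
                          seed = 504)
  merged <- turnover_arm(sim$evidence)
  prof <- integrate_abundance(fraction_completeness_filter(sim$abundance))
  res <- compare_dynamics(merged, prof)
  m <- dplyr::inner_join(res, truth, by = "protein_id")
  expect_gt(nrow(m), 180)
  expect_equal(m$mechanism_class, m$mechanism_label)
})
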