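#' Noise model for simulated evidence and abundance tables
#'
#' @param intensity_cv Multiplicative log-normal coefficient of variation
#'   applied independently to each isotopologue species intensity and to each
#'   abundance cell (>= 0; 0 = noise-free).
#' @param missing_rate Per-observation dropout probability in `[0, 1]`,
#'   applied to evidence rows and abundance cells independently.
#' @param obs_lambda Poisson rate of repeat scans beyond the first: the number
#'   of scans supporting a peptide pair is `1 + Poisson(obs_lambda)`.
#' @param decoy_pair_rate Probability that a peptide in an unlabeled sample
#'   yields a spurious single-scan heavy match; repeat spurious matches on the
#'   same peptide are independent, so double matches occur at the squared
#'   rate.
#' @return An object of class `"noise_model"`.
#' @examples
#' noise_model()                      # study-condition defaults
#' noise_model(0, 0)                  # noise-free limit
#' @export
noise_model <- function(intensity_cv = 0.10, missing_rate = 0.05,
                        obs_lambda = 2, decoy_pair_rate = 0.02) {
  stopifnot(is.numeric(intensity_cv), length(intensity_cv) == 1L,
            is.finite(intensity_cv), intensity_cv >= 0)
  for (p in list(missing_rate = missing_rate, decoy_pair_rate = decoy_pair_rate)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      abort("Probabilities in the noise model must lie in [0, 1].")
    }
  }
  if (!is.numeric(obs_lambda) || length(obs_lambda) != 1L || obs_lambda < 0) {
    abort("`obs_lambda` must be a nonnegative rate.")
  }
  structure(
    list(intensity_cv = intensity_cv, missing_rate = missing_rate,
         obs_lambda = obs_lambda, decoy_pair_rate = decoy_pair_rate),
    class = "noise_model"
  )
}

check_noise <- function(noise) {
  if (!inherits(noise, "noise_model")) {
    abort("`noise` must be created with `noise_model()`.")
  }
  noise
}

# mean-1 multiplicative log-normal noise; cv = 0 returns exact 1s
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# as above but with a per-draw cv (scan-summed intensities)
lnorm_noise_cv <- function(cv) {
  if (all(cv == 0)) return(rep(1, length(cv)))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(length(cv), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-protein ground-truth kinetics for two cohorts
#'
#' Draws control-cohort degradation rate constants from a log-normal
#' distribution calibrated so that a 6-day label yields incorporations
#' spanning roughly 1.4--71% over ~1400 proteins (the dynamic range observed
#' in brain tissue), with steady-state abundances log-normal over ~2 orders of
#' magnitude. Disease-cohort rates are derived from the control rates in one
#' of two ways:
#'
#' * `turnover_scale`: the disease incorporation of every protein is exactly
#'   `turnover_scale` times its control incorporation (the degradation rate is
#'   inverted through the labeling model), with the synthesis rate co-adjusted
#'   so steady-state abundance is unchanged. This reproduces a uniform global
#'   turnover slowdown/speedup.
#' * `mechanism_mix`: named probabilities over [mechanism_levels]; each
#'   protein is assigned an archetype and its rates scaled by `effect_size`
#'   accordingly (e.g. `repair_up` scales both `s` and `k` up so abundance is
#'   unchanged).
#'
#' The disease perturbation is treated as a step change applied long before
#' labeling, so the disease cohort is at its new steady state during the
#' feeding window.
#'
#' @param n_proteins Number of proteins.
#' @param seed Integer seed; all randomness is local to this call.
#' @param k_meanlog,k_sdlog Log-normal parameters of the control degradation
#'   rate constant (1/day). Defaults: `log(0.022)`, `0.70` (median half-life
#'   ~31 days).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of control
#'   steady-state abundance (arbitrary intensity units).
#' @param turnover_scale Uniform disease/control incorporation ratio
#'   (default 1 = no global effect). Ignored when `mechanism_mix` is given.
#' @param mechanism_mix Optional named numeric vector of archetype
#'   probabilities (names from [mechanism_levels]).
#' @param effect_size Fold-change applied to the perturbed rate(s) of each
#'   archetype (default 2, a clearly separated exemplar of each regime at
#'   the reference design's cohort size).
#' @param schedule [labeling_schedule()] used to invert `turnover_scale` into
#'   degradation rates.
#' @param dead_band Relative dead-band passed to [assign_mechanism_label()].
#' @return A tibble with columns `protein_id`, `s_control`, `k_control`,
#'   `s_disease`, `k_disease`, `mechanism_label`.
#' @export
simulate_ground_truth <- function(n_proteins, seed,
                                  k_meanlog = log(0.022), k_sdlog = 0.70,
                                  abundance_meanlog = log(5e6),
                                  abundance_sdlog = 1,
                                  turnover_scale = 1,
                                  mechanism_mix = NULL,
                                  effect_size = 2,
                                  schedule = labeling_schedule(),
                                  dead_band = 0.05) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    abort("`n_proteins` must be a positive count.")
  }
  check_schedule(schedule)
  withr::local_seed(seed)
  k_c <- rlnorm(n_proteins, k_meanlog, k_sdlog)
  a_c <- rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
  s_c <- a_c * k_c

  if (!is.null(mechanism_mix)) {
    bad <- setdiff(names(mechanism_mix), mechanism_levels)
    if (length(bad) || is.null(names(mechanism_mix))) {
      abort("`mechanism_mix` must be named with mechanism levels.")
    }
    archetype <- sample(names(mechanism_mix), n_proteins, replace = TRUE,
                        prob = mechanism_mix)
    e <- effect_size
    k_ratio <- dplyr::case_match(archetype,
      c("synthesis_up", "degradation_up", "repair_up") ~ e,
      c("synthesis_down", "degradation_down", "repair_down") ~ 1 / e,
      "unchanged" ~ 1
    )
    a_ratio <- dplyr::case_match(archetype,
      c("synthesis_up", "degradation_down") ~ e,
      c("synthesis_down", "degradation_up") ~ 1 / e,
      .default = 1
    )
    k_d <- k_c * k_ratio
    s_d <- s_c * k_ratio * a_ratio
  } else if (turnover_scale != 1) {
    if (turnover_scale <= 0) abort("`turnover_scale` must be positive.")
    target <- turnover_scale * expected_incorporation(k_c, schedule)
    if (any(target >= schedule$precursor_plateau)) {
      abort("`turnover_scale` drives some proteins past the precursor plateau; lower it or the rate spread.")
    }
    k_d <- k_for_incorporation(target, schedule)
    s_d <- s_c * k_d / k_c   # abundance preserved: pure turnover perturbation
  } else {
    k_d <- k_c
    s_d <- s_c
  }

  tibble::tibble(
    protein_id = sprintf("P%05d", seq_len(n_proteins)),
    s_control = s_c, k_control = k_c,
    s_disease = s_d, k_disease = k_d,
    mechanism_label = assign_mechanism_label(s_d / s_c, k_d / k_c, dead_band)
  )
}

# random tryptic peptide sequences with an exact lysine count
# (body drawn from the 18 residues that are neither K nor R, C-terminal K,
# 2-K peptides carry one internal missed-cleavage K)
random_tryptic_peptides <- function(n, lysine_count) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  len <- sample(6:18, n, replace = TRUE)
  body <- vapply(len, function(l) paste(sample(aa, l, replace = TRUE),
                                        collapse = ""), character(1))
  cut <- pmax(2L, len %/% 2L)
  ifelse(lysine_count == 2L,
         paste0(substr(body, 1L, cut), "K",
                substr(body, cut + 1L, len), "K"),
         paste0(body, "K"))
}

#' Forward-simulate a two-cohort labeling experiment
#'
#' Generates a peptide-level evidence table and a per-fraction protein
#' abundance table from known kinetics. Fractionation happens at the protein
#' level, as in the wet protocol (tissue is fractionated before digestion):
#' each protein partitions into one to three detergent fractions with
#' log-normal loadings, and all of its peptides appear in every fraction
#' where the protein is present. Each protein yields a Poisson number of
#' tryptic peptides (at least one, and the first always single-lysine), 80%
#' with one lysine and 20% with two by default. Per mouse, the heavy
#' fraction of every peptide follows [expected_incorporation()] for the
#' mouse's cohort; species intensities are the exact isotopologue shares of
#' the peptide's total intensity perturbed by mean-one log-normal noise, so
#' the noise-free limit reproduces the expected incorporation exactly.
#' Because incorporation is quantified from intensities summed over the
#' scans supporting a pair, the relative noise of a pair observed in `n`
#' scans is reduced by `sqrt(n)`. Two-lysine peptides carry fully light
#' (`LL`), mixed (`HL`) and fully heavy (`HH`) species, with the per-site
#' heavy probability among newly synthesized molecules chosen so that the
#' per-site incorporation matches the kinetic expectation; these peptides
#' drive the precursor-pool estimator. Abundance rows follow
#' [steady_state_abundance()] times the protein-by-fraction loading (shared
#' across mice, so cohort contrasts are unaffected), times noise.
#'
#' @param truth Ground-truth tibble from [simulate_ground_truth()] (or any
#'   tibble with its rate columns).
#' @param schedule A [labeling_schedule()].
#' @param noise A [noise_model()].
#' @param n_mice Mice per cohort (>= 2; reference design: 3).
#' @param n_fractions Number of detergent fractions (>= 1).
#' @param peptides_per_protein Mean peptides per protein (>= 1); default 10,
#'   the ratio of quantified peptides to quantified proteins in the
#'   reference brain dataset.
#' @param prop_two_lysine Proportion of peptides carrying two lysines
#'   (missed cleavage), default 0.2.
#' @param seed Integer seed.
#' @return A list with tibbles `evidence` (native evidence schema, see
#'   [read_evidence()]) and `abundance` (native protein-group schema).
#' @export
simulate_cohorts <- function(truth, schedule, noise, n_mice = 3,
                             n_fractions = 3, peptides_per_protein = 10,
                             prop_two_lysine = 0.2, seed) {
  if (!is.data.frame(truth) || nrow(truth) == 0L) {
    abort("`truth` must be a nonempty ground-truth table.")
  }
  check_schedule(schedule)
  check_noise(noise)
  if (n_mice < 2) abort("`n_mice` must be at least 2 per cohort.")
  if (n_fractions < 1) abort("`n_fractions` must be at least 1.")
  if (peptides_per_protein < 1) abort("`peptides_per_protein` must be >= 1.")
  withr::local_seed(seed)

  n_prot <- nrow(truth)
  fraction_ids <- sprintf("F%02d", seq_len(n_fractions))

  # protein-level fractionation: most proteins concentrate in one fraction
  n_present <- sample(seq_len(min(3L, n_fractions)), n_prot, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)[seq_len(min(3L, n_fractions))])
  loading <- dplyr::bind_rows(lapply(seq_len(n_prot), function(i) {
    tibble::tibble(protein_id = truth$protein_id[i],
                   fraction_id = sample(fraction_ids, n_present[i]))
  }))
  loading$loading <- rlnorm(nrow(loading), 0, 0.5)

  n_pep <- 1L + rpois(n_prot, peptides_per_protein - 1)
  pep <- tibble::tibble(protein_id = rep(truth$protein_id, n_pep))
  m <- nrow(pep)
  first <- !duplicated(pep$protein_id)
  pep$lysine_count <- ifelse(!first & runif(m) < prop_two_lysine, 2L, 1L)
  pep$peptide_sequence <- random_tryptic_peptides(m, pep$lysine_count)
  pep$charge <- sample(2:3, m, replace = TRUE)
  pep$ionization <- rlnorm(m, 0, 0.5)

  mice <- tibble::tibble(
    cohort = rep(c("control", "disease"), each = n_mice),
    mouse_id = c(sprintf("C%d", seq_len(n_mice)),
                 sprintf("D%d", seq_len(n_mice)))
  )

  obs <- dplyr::inner_join(pep, loading, by = "protein_id",
                           relationship = "many-to-many")
  obs <- tidyr::expand_grid(obs, mice)
  idx <- match(obs$protein_id, truth$protein_id)
  k <- ifelse(obs$cohort == "control", truth$k_control[idx],
              truth$k_disease[idx])
  s <- ifelse(obs$cohort == "control", truth$s_control[idx],
              truth$s_disease[idx])
  t <- schedule$label_days
  incorporation <- expected_incorporation(k, schedule)
  f_new <- -expm1(-k * t)               # fraction of molecules synthesized
  q_site <- incorporation / f_new       # per-site heavy prob among new ones
  base <- (s / k) * obs$ionization * obs$loading
  n <- nrow(obs)

  one_k <- obs$lysine_count == 1L
  share_l <- ifelse(one_k, 1 - incorporation,
                    (1 - f_new) + f_new * (1 - q_site)^2)
  share_m <- ifelse(one_k, 0, f_new * 2 * q_site * (1 - q_site))
  share_h <- ifelse(one_k, incorporation, f_new * q_site^2)

  n_obs <- 1L + rpois(n, noise$obs_lambda)
  cv_row <- noise$intensity_cv / sqrt(n_obs)   # scan-summed intensities
  evidence <- tibble::tibble(
    protein_id = obs$protein_id,
    peptide_sequence = obs$peptide_sequence,
    lysine_count = obs$lysine_count,
    charge = obs$charge,
    fraction_id = obs$fraction_id,
    mouse_id = obs$mouse_id,
    cohort = obs$cohort,
    intensity_light = base * share_l * lnorm_noise_cv(cv_row),
    intensity_mixed = base * share_m * lnorm_noise_cv(cv_row),
    intensity_heavy = base * share_h * lnorm_noise_cv(cv_row),
    n_observations = n_obs
  )
  evidence <- evidence[runif(n) >= noise$missing_rate, , drop = FALSE]

  ab <- tidyr::expand_grid(loading, mice)
  aidx <- match(ab$protein_id, truth$protein_id)
  a_ss <- ifelse(ab$cohort == "control",
                 truth$s_control[aidx] / truth$k_control[aidx],
                 truth$s_disease[aidx] / truth$k_disease[aidx])
  abundance <- tibble::tibble(
    protein_id = ab$protein_id,
    fraction_id = ab$fraction_id,
    mouse_id = ab$mouse_id,
    cohort = ab$cohort,
    abundance = a_ss * ab$loading * lnorm_noise(nrow(ab), noise$intensity_cv)
  )
  abundance <- abundance[runif(nrow(abundance)) >= noise$missing_rate, ,
                         drop = FALSE]

  list(evidence = evidence, abundance = abundance)
}

#' Simulate an unlabeled decoy sample
#'
#' All proteins are fully light; spurious heavy matches arise as single-scan
#' events with probability `decoy_pair_rate` per peptide, and a repeat
#' spurious match on the same peptide occurs independently with the same
#' probability (so double-scan spurious pairs occur at the squared rate).
#' Used to benchmark the false pair-detection rate of single- versus
#' double-count quantification.
#'
#' @param n_proteins Number of proteins (one representative peptide each).
#' @param noise A [noise_model()]; `decoy_pair_rate` and `intensity_cv` are
#'   used.
#' @param seed Integer seed.
#' @return An evidence tibble in the native schema; `intensity_heavy > 0`
#'   marks a spurious pair and `n_observations` counts its spurious scans.
#' @export
simulate_decoy_unlabeled <- function(n_proteins, noise, seed) {
  check_noise(noise)
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    abort("`n_proteins` must be a positive count.")
  }
  withr::local_seed(seed)
  n <- as.integer(n_proteins)
  p <- noise$decoy_pair_rate
  first <- runif(n) < p
  second <- first & (runif(n) < p)
  n_spurious <- as.integer(first) + as.integer(second)
  light <- rlnorm(n, log(5e6), 1)
  tibble::tibble(
    protein_id = sprintf("P%05d", seq_len(n)),
    peptide_sequence = random_tryptic_peptides(n, rep(1L, n)),
    lysine_count = 1L,
    charge = sample(2:3, n, replace = TRUE),
    fraction_id = "F01",
    mouse_id = "U1",
    cohort = "control",
    intensity_light = light * lnorm_noise(n, noise$intensity_cv),
    intensity_mixed = 0,
    intensity_heavy = ifelse(first, light * runif(n, 0.005, 0.05), 0),
    n_observations = ifelse(first, n_spurious,
                            1L + rpois(n, noise$obs_lambda))
  )
}
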