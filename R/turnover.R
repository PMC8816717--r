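#' Peptide-level heavy-lysine incorporation
#'
#' Computes the relative incorporation `H / (H + L)` of each peptide-pair
#' observation and applies the double-count rule: a pair must be supported by
#' at least `min_observations` scans (default 2) to be quantified, which
#' suppresses spurious single-scan pairs. Two-lysine peptides carrying a
#' mixed (`HL`) species are excluded here -- their isotopologue pattern feeds
#' the precursor-pool estimator ([estimate_precursor_pool()]) instead -- but
#' are retained when fully light or fully heavy. Peptides without lysine
#' cannot form a pair and are dropped.
#'
#' @param records Evidence tibble in the native schema (see
#'   [read_evidence()]).
#' @param min_observations Minimum supporting scans per pair (default 2).
#' @return A tibble with one row per surviving observation: `protein_id`,
#'   `peptide_sequence`, `lysine_count`, `fraction_id`, `mouse_id`, `cohort`,
#'   `incorporation`, `n_observations`. Exclusion counts are reported.
#' @export
compute_incorporation <- function(records, min_observations = 2) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  if (!is.numeric(min_observations) || min_observations < 1) {
    abort("`min_observations` must be >= 1.")
  }
  n0 <- nrow(records)
  no_lysine <- records$lysine_count < 1L
  under_counted <- records$n_observations < min_observations
  mixed_2k <- records$lysine_count >= 2L & records$intensity_mixed > 0
  keep <- !no_lysine & !under_counted & !mixed_2k
  if (n0 > 0) {
    pf_inform(sprintf(
      "compute_incorporation: %d of %d record(s) kept (%d below the %d-scan count rule, %d mixed-species multi-K routed to the pool estimator, %d without lysine).",
      sum(keep), n0, sum(under_counted), as.integer(min_observations),
      sum(mixed_2k & !under_counted), sum(no_lysine)))
  }
  out <- records[keep, , drop = FALSE]
  denom <- out$intensity_heavy + out$intensity_light
  tibble::tibble(
    protein_id = out$protein_id,
    peptide_sequence = out$peptide_sequence,
    lysine_count = out$lysine_count,
    fraction_id = out$fraction_id,
    mouse_id = out$mouse_id,
    cohort = out$cohort,
    incorporation = ifelse(denom > 0, out$intensity_heavy / denom, NA_real_),
    n_observations = out$n_observations
  ) |> dplyr::filter(!is.na(.data$incorporation))
}

#' Aggregate peptide incorporations to proteins and apply the replicate rule
#'
#' Summarizes peptide incorporations per (protein, fraction, mouse) with the
#' median (or mean), then keeps only (protein, fraction) cells supported in
#' at least `min_replicates` mice in *every* cohort present -- the
#' 2-of-3-in-both-cohorts rule of the reference design, parameterized so
#' other cohort sizes remain usable.
#'
#' @param peptides Output of [compute_incorporation()].
#' @param summary `"median"` (default, robust to single-peptide outliers) or
#'   `"mean"`.
#' @param min_replicates Minimum mice per cohort (default 2).
#' @return A tibble with one row per (protein, fraction, mouse):
#'   `protein_id`, `fraction_id`, `mouse_id`, `cohort`, `incorporation`,
#'   `n_peptides`.
#' @export
aggregate_to_protein <- function(peptides, summary = c("median", "mean"),
                                 min_replicates = 2) {
  summary <- match.arg(summary)
  fun <- if (summary == "median") median else mean
  if (!is.data.frame(peptides)) abort("`peptides` must be a data frame.")

  per_mouse <- peptides |>
    dplyr::group_by(.data$protein_id, .data$fraction_id, .data$mouse_id,
                    .data$cohort) |>
    dplyr::summarise(incorporation = fun(.data$incorporation),
                     n_peptides = dplyr::n(), .groups = "drop")

  cohorts <- unique(per_mouse$cohort)
  support <- per_mouse |>
    dplyr::group_by(.data$protein_id, .data$fraction_id, .data$cohort) |>
    dplyr::summarise(n_mice = dplyr::n_distinct(.data$mouse_id),
                     .groups = "drop") |>
    dplyr::group_by(.data$protein_id, .data$fraction_id) |>
    dplyr::summarise(
      ok = dplyr::n() == length(cohorts) & all(.data$n_mice >= min_replicates),
      .groups = "drop") |>
    dplyr::filter(.data$ok)

  n_cells <- dplyr::n_distinct(per_mouse[c("protein_id", "fraction_id")])
  pf_inform(sprintf(
    "aggregate_to_protein: %d of %d (protein, fraction) cell(s) pass the >=%d-of-%d-mice-per-cohort rule.",
    nrow(support), n_cells, as.integer(min_replicates),
    dplyr::n_distinct(per_mouse$mouse_id) / length(cohorts)))

  dplyr::semi_join(per_mouse, support,
                   by = c("protein_id", "fraction_id")) |>
    dplyr::arrange(.data$protein_id, .data$fraction_id, .data$cohort,
                   .data$mouse_id)
}

#' Merge detergent fractions to one measurement per protein
#'
#' A protein quantified in several detergent fractions keeps exactly the
#' fraction with the greatest absolute difference in mean incorporation
#' between the cohorts, producing a nonredundant per-protein dataset. Ties
#' are broken by the larger total peptide support, then by lexicographic
#' fraction identifier. When only one cohort is present (e.g. an aging
#' series of wild-type mice) no between-cohort difference exists and the
#' fraction with the larger peptide support is kept.
#'
#' @param protein_incorporation Output of [aggregate_to_protein()].
#' @return The input restricted to one fraction per protein.
#' @export
merge_fractions <- function(protein_incorporation) {
  if (!is.data.frame(protein_incorporation) ||
      nrow(protein_incorporation) == 0L) {
    abort("`protein_incorporation` must be a nonempty data frame.")
  }
  x <- protein_incorporation
  two_cohorts <- all(c("control", "disease") %in% x$cohort)

  stats_tbl <- x |>
    dplyr::group_by(.data$protein_id, .data$fraction_id) |>
    dplyr::summarise(
      delta = if (two_cohorts) {
        mean(.data$incorporation[.data$cohort == "disease"]) -
          mean(.data$incorporation[.data$cohort == "control"])
      } else 0,
      total_peptides = sum(.data$n_peptides),
      .groups = "drop")

  best <- stats_tbl |>
    dplyr::arrange(.data$protein_id, dplyr::desc(abs(.data$delta)),
                   dplyr::desc(.data$total_peptides), .data$fraction_id) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE)

  dplyr::semi_join(x, best, by = c("protein_id", "fraction_id")) |>
    dplyr::arrange(.data$protein_id, .data$cohort, .data$mouse_id)
}

#' Estimate the heavy fraction of the precursor pool
#'
#' Control for amino-acid recycling: among newly synthesized molecules of a
#' two-lysine peptide, each lysine is heavy independently with the precursor
#' pool's heavy fraction `q`, so the fully heavy and mixed isotopologues obey
#' `HH : HL = q^2 : 2q(1-q)`, giving the per-record estimator
#' `q_hat = 2 HH / (2 HH + HL)` -- independent of the (unknown) fraction of
#' old molecules. Estimates are aggregated by the median over qualifying
#' peptide records, per cohort. A cohort difference in `q_hat` would mean
#' incorporation differences partly reflect precursor availability rather
#' than protein turnover.
#'
#' @param records Evidence tibble (native schema); only records with
#'   `lysine_count >= 2`, a detectable heavy or mixed species, and passing
#'   the double-count rule are used.
#' @param min_observations Minimum supporting scans (default 2).
#' @return A tibble with one row per cohort: `cohort`, `q_hat`,
#'   `n_peptides_used`, plus an attribute `cohort_difference`
#'   (disease minus control, `NA` when one cohort is absent). With no usable
#'   two-lysine peptides a zero-row tibble is returned with a warning.
#' @export
estimate_precursor_pool <- function(records, min_observations = 2) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  use <- records$lysine_count >= 2L &
    records$n_observations >= min_observations &
    (records$intensity_heavy + records$intensity_mixed) > 0
  x <- records[use, , drop = FALSE]
  if (nrow(x) == 0L) {
    warn("No usable multi-lysine peptides: precursor pool not estimable.")
    out <- tibble::tibble(cohort = character(), q_hat = double(),
                          n_peptides_used = integer())
    attr(out, "cohort_difference") <- NA_real_
    return(out)
  }
  out <- tibble::tibble(
    cohort = x$cohort,
    q = 2 * x$intensity_heavy / (2 * x$intensity_heavy + x$intensity_mixed)
  ) |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(q_hat = median(.data$q),
                     n_peptides_used = dplyr::n(), .groups = "drop")
  diff <- if (all(c("control", "disease") %in% out$cohort)) {
    out$q_hat[out$cohort == "disease"] - out$q_hat[out$cohort == "control"]
  } else {
    NA_real_
  }
  attr(out, "cohort_difference") <- diff
  out
}
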