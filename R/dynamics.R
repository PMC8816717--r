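# two-sample two-tailed t-test with explicit handling of the degenerate
# (essentially) zero-variance case that exact noise-free simulations
# produce: equal means -> p = 1, unequal means -> p at the smallest
# representable positive value, flagged. "Essentially zero" follows the
# same relative cutoff stats::t.test uses to refuse constant data.
welch_test <- function(x, y, pooled = FALSE) {
  vx <- if (length(x) > 1) var(x) else 0
  vy <- if (length(y) > 1) var(y) else 0
  mx <- mean(x)
  my <- mean(y)
  delta <- my - mx
  scale2 <- max(abs(mx), abs(my), .Machine$double.eps)^2
  degenerate <- (is.na(vx) || vx <= 1e-20 * scale2) &&
    (is.na(vy) || vy <= 1e-20 * scale2)
  if (degenerate) {
    p <- if (isTRUE(all.equal(mx, my, tolerance = 1e-10))) 1
         else .Machine$double.xmin
    return(list(delta = delta, p_value = p, degenerate = TRUE))
  }
  p <- tryCatch(t.test(y, x, var.equal = pooled)$p.value,
                error = function(e) NA_real_)
  if (is.na(p)) {  # t.test refused (near-constant data): fall back
    p <- if (isTRUE(all.equal(mx, my, tolerance = 1e-10))) 1
         else .Machine$double.xmin
    return(list(delta = delta, p_value = p, degenerate = TRUE))
  }
  list(delta = delta, p_value = p, degenerate = FALSE)
}

#' Per-protein cohort comparison of incorporation
#'
#' Two-sample two-tailed t-test (Welch by default; pooled-variance Student
#' behind the `pooled` flag) on the per-mouse incorporations of each protein,
#' disease versus control. Proteins with fewer than two mice in either cohort
#' are skipped. Zero variance in both cohorts (an exact simulation) is
#' flagged `degenerate`: equal means give p = 1, unequal means a p-value at
#' the smallest positive double.
#'
#' @param protein_incorporation Output of [merge_fractions()] (or
#'   [aggregate_to_protein()], for per-fraction tests).
#' @param pooled Use the pooled-variance Student statistic instead of Welch.
#' @return A tibble with one row per protein: `protein_id`,
#'   `mean_incorporation_control`, `mean_incorporation_disease`, `delta`
#'   (disease minus control), `p_value`, `degenerate`, `n_control`,
#'   `n_disease`.
#' @export
protein_turnover_test <- function(protein_incorporation, pooled = FALSE) {
  if (!is.data.frame(protein_incorporation) ||
      nrow(protein_incorporation) == 0L) {
    abort("`protein_incorporation` must be a nonempty data frame.")
  }
  x <- protein_incorporation
  split_idx <- split(seq_len(nrow(x)), x$protein_id)
  rows <- lapply(split_idx, function(i) {
    ctrl <- x$incorporation[i][x$cohort[i] == "control"]
    dis <- x$incorporation[i][x$cohort[i] == "disease"]
    if (length(ctrl) < 2 || length(dis) < 2) return(NULL)
    w <- welch_test(ctrl, dis, pooled = pooled)
    tibble::tibble(
      protein_id = x$protein_id[i][1],
      mean_incorporation_control = mean(ctrl),
      mean_incorporation_disease = mean(dis),
      delta = w$delta, p_value = w$p_value, degenerate = w$degenerate,
      n_control = length(ctrl), n_disease = length(dis))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("No protein had >= 2 mice in both cohorts.")
  dplyr::arrange(out, .data$protein_id)
}

# same contract for abundance profiles; the test runs on log2 intensities
# because intensity noise is multiplicative (on the raw scale the cohort
# variances scale with the squared means, which starves the t-test of
# degrees of freedom at n = 3); the reported delta and log2 ratio are on
# the natural scales
abundance_cohort_test <- function(profiles, pooled = FALSE) {
  x <- profiles
  split_idx <- split(seq_len(nrow(x)), x$protein_id)
  rows <- lapply(split_idx, function(i) {
    ctrl <- x$abundance[i][x$cohort[i] == "control"]
    dis <- x$abundance[i][x$cohort[i] == "disease"]
    if (length(ctrl) < 2 || length(dis) < 2) return(NULL)
    w <- welch_test(log2(ctrl), log2(dis), pooled = pooled)
    tibble::tibble(
      protein_id = x$protein_id[i][1],
      mean_abundance_control = mean(ctrl),
      mean_abundance_disease = mean(dis),
      abundance_delta = mean(dis) - mean(ctrl),
      abundance_log2_ratio = log2(mean(dis) / mean(ctrl)),
      abundance_p = w$p_value, abundance_degenerate = w$degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Global average protein turnover (GAPT) summary
#'
#' The GAPT of a cohort is the mean, over the shared protein set, of the
#' per-protein cohort-mean incorporations. The cohort contrast is reported as
#' a percent change and tested with a two-sided unpaired t-test across the
#' per-protein cohort means (a paired test over the matched proteins is
#' available behind the `paired` flag).
#'
#' @param comparisons Output of [protein_turnover_test()].
#' @param paired Pair the per-protein means across cohorts (default
#'   `FALSE`, i.e. unpaired).
#' @return A one-row tibble: `gapt_control`, `gapt_disease`,
#'   `percent_change`, `p_value`, `n_proteins`.
#' @export
compute_gapt <- function(comparisons, paired = FALSE) {
  if (!is.data.frame(comparisons) || nrow(comparisons) == 0L) {
    abort("`comparisons` must be a nonempty table of per-protein cohort means.")
  }
  ctrl <- comparisons$mean_incorporation_control
  dis <- comparisons$mean_incorporation_disease
  gapt_c <- mean(ctrl)
  gapt_d <- mean(dis)
  p <- if (isTRUE(all.equal(ctrl, dis, tolerance = 1e-12))) {
    1
  } else if (paired) {
    d <- dis - ctrl
    if (var(d) <= 1e-20 * max(mean(d)^2, .Machine$double.eps)) {
      .Machine$double.xmin   # constant nonzero shift across all proteins
    } else {
      t.test(dis, ctrl, paired = TRUE)$p.value
    }
  } else {
    welch_test(ctrl, dis)$p_value
  }
  tibble::tibble(
    gapt_control = gapt_c,
    gapt_disease = gapt_d,
    percent_change = 100 * (gapt_d - gapt_c) / gapt_c,
    p_value = p,
    n_proteins = nrow(comparisons)
  )
}

#' Joint turnover + abundance comparison with mechanism classification
#'
#' Joins the per-protein turnover comparison and the per-protein abundance
#' comparison on their shared protein set and classifies every protein into
#' a mechanistic regime with [classify_mechanism()]. Turnover is tested on
#' the incorporation fractions; abundance is tested on log2 intensities
#' (intensity noise is multiplicative, so the t-test's assumptions hold on
#' the log scale) while deltas and ratios are reported on the natural
#' scales. Two thresholds are carried: `alpha_table` (default 0.05) flags
#' per-axis significance for result tables, `alpha_dynaplot` (default 0.01)
#' governs the mechanism classification and the dynaplot highlighting.
#'
#' @param protein_incorporation Output of [merge_fractions()].
#' @param profiles Output of [integrate_abundance()].
#' @param alpha_table Per-axis significance threshold for reporting.
#' @param alpha_dynaplot Threshold used by the mechanism classification.
#' @param pooled Use pooled-variance t-tests.
#' @return A tibble with one row per shared protein: the turnover columns of
#'   [protein_turnover_test()] (`delta` renamed `turnover_delta`, `p_value`
#'   renamed `turnover_p`), the abundance columns, significance flags at both
#'   thresholds, `mechanism_class` and `uncoupled`.
#' @export
compare_dynamics <- function(protein_incorporation, profiles,
                             alpha_table = 0.05, alpha_dynaplot = 0.01,
                             pooled = FALSE) {
  turn <- protein_turnover_test(protein_incorporation, pooled = pooled) |>
    dplyr::rename(turnover_delta = "delta", turnover_p = "p_value",
                  turnover_degenerate = "degenerate")
  ab <- abundance_cohort_test(profiles, pooled = pooled)
  if (is.null(ab) || nrow(ab) == 0L) {
    abort("No protein had complete abundance profiles in both cohorts.")
  }
  joined <- dplyr::inner_join(turn, ab, by = "protein_id")
  pf_inform(sprintf(
    "compare_dynamics: %d protein(s) shared between turnover (%d) and abundance (%d).",
    nrow(joined), nrow(turn), nrow(ab)))
  if (nrow(joined) == 0L) abort("Turnover and abundance protein sets are disjoint.")
  cls <- classify_mechanism(joined$turnover_delta, joined$turnover_p,
                            joined$abundance_delta, joined$abundance_p,
                            alpha = alpha_dynaplot)
  dplyr::bind_cols(joined, cls) |>
    dplyr::mutate(
      turnover_significant_table = .data$turnover_p < alpha_table,
      abundance_significant_table = .data$abundance_p < alpha_table) |>
    dplyr::arrange(.data$protein_id)
}

#' Aging trend across an ordered series of cohorts
#'
#' Given per-protein incorporation tables at increasing ages, restricts to
#' proteins measured at every age, computes the share of proteins whose
#' incorporation at the oldest age is below that at the youngest (the
#' endpoint contrast), tests that share against the no-trend null with a
#' two-sided sign (binomial) test, and reports per-protein least-squares
#' slopes of incorporation over age from the per-mouse values.
#'
#' @param tables List of per-protein incorporation tibbles (as returned by
#'   [merge_fractions()]), one per age, in the same order as `ages`. Tables
#'   may contain a single cohort.
#' @param ages Numeric vector of ages (days), strictly increasing, length
#'   >= 2.
#' @return A list: `fraction_decreasing`, `p_value`, `n_proteins`, and a
#'   `slopes` tibble (`protein_id`, `slope` in incorporation fraction per
#'   day).
#' @export
aging_trend <- function(tables, ages) {
  if (!is.list(tables) || length(tables) < 2L) {
    abort("`tables` must be a list of >= 2 incorporation tables.")
  }
  if (length(ages) != length(tables) || is.unsorted(ages, strictly = TRUE)) {
    abort("`ages` must be strictly increasing and match `tables`.")
  }
  per_age <- lapply(seq_along(tables), function(i) {
    tables[[i]] |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::summarise(incorporation = mean(.data$incorporation),
                       .groups = "drop") |>
      dplyr::mutate(age = ages[i])
  })
  shared <- Reduce(intersect, lapply(per_age, function(d) d$protein_id))
  n_all <- length(unique(unlist(lapply(per_age, function(d) d$protein_id))))
  pf_inform(sprintf(
    "aging_trend: %d protein(s) measured at all %d ages (of %d seen at any age).",
    length(shared), length(ages), n_all))
  if (length(shared) == 0L) abort("No protein is measured at every age.")
  long <- dplyr::bind_rows(per_age) |>
    dplyr::filter(.data$protein_id %in% shared)

  youngest <- long[long$age == ages[1], c("protein_id", "incorporation")]
  oldest <- long[long$age == ages[length(ages)],
                 c("protein_id", "incorporation")]
  m <- dplyr::inner_join(youngest, oldest, by = "protein_id",
                         suffix = c("_young", "_old"))
  decreasing <- m$incorporation_old < m$incorporation_young
  n <- nrow(m)
  p <- binom.test(sum(decreasing), n, p = 0.5,
                  alternative = "two.sided")$p.value

  mice_long <- dplyr::bind_rows(lapply(seq_along(tables), function(i) {
    d <- tables[[i]]
    d[d$protein_id %in% shared, c("protein_id", "incorporation")] |>
      dplyr::mutate(age = ages[i])
  }))
  slopes <- mice_long |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      slope = coef(lm(incorporation ~ age,
                      data = dplyr::pick(dplyr::everything())))[["age"]],
      .groups = "drop")

  list(fraction_decreasing = mean(decreasing), p_value = p,
       n_proteins = n, slopes = slopes)
}

#' Plot-ready dynaplot table
#'
#' One row per protein with the dynaplot coordinates (x = change in
#' incorporation, disease minus control, in percentage points; y = log2
#' abundance ratio), the mechanism class and its display color. Rows are
#' ordered by protein for stable output.
#'
#' @param results Output of [compare_dynamics()].
#' @return A tibble: `protein_id`, `turnover_delta_pp`,
#'   `abundance_log2_ratio`, `mechanism_class`, `color`.
#' @export
dynaplot_table <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort("`results` must be a nonempty comparison table.")
  }
  tibble::tibble(
    protein_id = results$protein_id,
    turnover_delta_pp = 100 * results$turnover_delta,
    abundance_log2_ratio = results$abundance_log2_ratio,
    mechanism_class = results$mechanism_class,
    color = unname(mechanism_palette[results$mechanism_class])
  ) |> dplyr::arrange(.data$protein_id)
}

#' Dynaplot of turnover change versus abundance change
#'
#' Scatter of each protein's incorporation change (percentage points,
#' x-axis) against its log2 abundance ratio (y-axis), colored by mechanistic
#' regime: red/blue net synthesis up/down, magenta/yellow net degradation
#' up/down, green/brown repair flux up/down, grey unchanged.
#'
#' @param results Output of [compare_dynamics()].
#' @return A ggplot object.
#' @export
dynaplot <- function(results) {
  tab <- dynaplot_table(results)
  tab$mechanism_class <- factor(tab$mechanism_class,
                                levels = mechanism_levels)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$turnover_delta_pp,
                                    y = .data$abundance_log2_ratio,
                                    color = .data$mechanism_class)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, color = "grey80") +
    ggplot2::geom_point(alpha = 0.8, size = 1.4) +
    ggplot2::scale_color_manual(values = mechanism_palette, drop = FALSE,
                                name = "mechanism") +
    ggplot2::labs(
      x = "Change in K6 incorporation (percentage points, disease - control)",
      y = "log2 abundance ratio (disease / control)") +
    ggplot2::theme_minimal()
}
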