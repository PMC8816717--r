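#' Keep only (protein, fraction) cells quantified in every mouse
#'
#' Label-free abundances of a protein in a given detergent fraction are
#' forwarded only when the protein was quantified in every mouse of that
#' fraction -- the six-of-six rule of the reference 3 + 3 design. With a
#' different roster size the rule generalizes to "all mice", which is
#' reported.
#'
#' @param groups Protein-group abundance tibble (native schema, see
#'   [read_abundance()]); absence and non-positive abundance are treated
#'   identically.
#' @param roster Character vector of all mouse identifiers in the experiment.
#'   Defaults to the mice present anywhere in `groups`; pass the sample
#'   roster explicitly if a mouse could be missing from the table entirely.
#' @return The filtered tibble.
#' @export
fraction_completeness_filter <- function(groups, roster = NULL) {
  if (!is.data.frame(groups)) abort("`groups` must be a data frame.")
  roster <- roster %||% sort(unique(groups$mouse_id))
  if (length(roster) != 6L) {
    pf_inform(sprintf(
      "fraction_completeness_filter: roster has %d mice; applying the all-mice generalization of the six-of-six rule.",
      length(roster)))
  }
  x <- groups[!is.na(groups$abundance) & groups$abundance > 0, , drop = FALSE]
  complete <- x |>
    dplyr::group_by(.data$protein_id, .data$fraction_id) |>
    dplyr::summarise(
      ok = dplyr::n_distinct(.data$mouse_id) == length(roster),
      .groups = "drop") |>
    dplyr::filter(.data$ok)
  n_cells <- dplyr::n_distinct(x[c("protein_id", "fraction_id")])
  pf_inform(sprintf(
    "fraction_completeness_filter: %d of %d (protein, fraction) cell(s) complete in all %d mice.",
    nrow(complete), n_cells, length(roster)))
  dplyr::semi_join(x, complete, by = c("protein_id", "fraction_id"))
}

#' Integrate abundance across detergent fractions
#'
#' Averages, mouse by mouse, the label-free quantities of each protein over
#' the fractions that survived [fraction_completeness_filter()]. Averaging is
#' arithmetic on the intensity scale by default; the `log_scale` flag instead
#' averages `log` intensities (geometric mean), for workflows that prefer
#' ratio-compressed integration.
#'
#' @param filtered Output of [fraction_completeness_filter()].
#' @param log_scale Average on the log scale (default `FALSE`).
#' @return A tibble with one row per (protein, mouse): `protein_id`,
#'   `mouse_id`, `cohort`, `abundance`, `n_fractions_integrated`.
#' @export
integrate_abundance <- function(filtered, log_scale = FALSE) {
  if (!is.data.frame(filtered)) abort("`filtered` must be a data frame.")
  filtered |>
    dplyr::group_by(.data$protein_id, .data$mouse_id, .data$cohort) |>
    dplyr::summarise(
      abundance = if (log_scale) exp(mean(log(.data$abundance)))
                  else mean(.data$abundance),
      n_fractions_integrated = dplyr::n_distinct(.data$fraction_id),
      .groups = "drop") |>
    dplyr::arrange(.data$protein_id, .data$cohort, .data$mouse_id)
}
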