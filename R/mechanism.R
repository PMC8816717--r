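#' Mechanistic regimes of a proteome-dynamics change
#'
#' The six regimes of the dynaplot coordinate space, plus `unchanged`.
#' A protein's turnover (readout: heavy-lysine incorporation, driven by the
#' degradation rate constant `k`) and steady-state abundance (`A = s/k`)
#' together imply the mechanism of its change between cohorts:
#'
#' * turnover up, abundance up: net synthesis increased (`synthesis_up`)
#' * turnover down, abundance down: net synthesis decreased (`synthesis_down`)
#' * turnover up, abundance down: net degradation increased (`degradation_up`)
#' * turnover down, abundance up: net degradation decreased (`degradation_down`)
#' * turnover up, abundance unchanged: repair flux increased (`repair_up`)
#' * turnover down, abundance unchanged: repair flux decreased (`repair_down`)
#'
#' @format Character vector of the seven class names.
#' @export
mechanism_levels <- c(
  "synthesis_up", "synthesis_down",
  "degradation_up", "degradation_down",
  "repair_up", "repair_down",
  "unchanged"
)

#' Dynaplot color palette
#'
#' Named colors for the mechanistic regimes: red/blue for net synthesis
#' up/down, magenta/yellow for net degradation up/down, green/brown for
#' increasing/decreasing repair flux, grey for unchanged.
#'
#' @format Named character vector of hex colors, names = [mechanism_levels].
#' @export
mechanism_palette <- c(
  synthesis_up = "#D7191C",
  synthesis_down = "#2C7BB6",
  degradation_up = "#C51B8A",
  degradation_down = "#FDC514",
  repair_up = "#1A9850",
  repair_down = "#8C510A",
  unchanged = "grey65"
)

ratio_direction <- function(ratio, tolerance) {
  up <- ratio > 1 + tolerance
  down <- ratio < 1 / (1 + tolerance)
  ifelse(up, 1L, ifelse(down, -1L, 0L))
}

#' Mechanism label from ground-truth rate ratios
#'
#' Deterministic mapping from the disease/control ratios of the synthesis
#' rate `s` and degradation rate constant `k` to a mechanistic regime. The
#' abundance ratio is `s_ratio / k_ratio` (steady state `A = s/k`). Ratios
#' within a multiplicative dead-band of 1 (i.e. in
#' `[1/(1+tolerance), 1+tolerance]`) are treated as unity so that numerical
#' noise is not labeled as mechanism. A changed abundance with unchanged
#' degradation is a pure net-synthesis change and maps to
#' `synthesis_up`/`synthesis_down`.
#'
#' @param s_ratio Disease/control synthesis-rate ratio(s); positive.
#' @param k_ratio Disease/control degradation-rate ratio(s); positive.
#' @param tolerance Relative dead-band around 1 (default 0.05).
#' @return Character vector of [mechanism_levels] labels.
#' @examples
#' assign_mechanism_label(2, 1.5)    # abundance and turnover up: synthesis_up
#' assign_mechanism_label(1.5, 1.5)  # turnover up, abundance flat: repair_up
#' @export
assign_mechanism_label <- function(s_ratio, k_ratio, tolerance = 0.05) {
  if (any(!is.finite(s_ratio)) || any(s_ratio <= 0) ||
      any(!is.finite(k_ratio)) || any(k_ratio <= 0)) {
    abort("Rate ratios must be strictly positive and finite.")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    abort("`tolerance` must be a single nonnegative number.")
  }
  a_ratio <- s_ratio / k_ratio
  kd <- ratio_direction(k_ratio, tolerance)
  ad <- ratio_direction(a_ratio, tolerance)
  label_from_directions(kd, ad)
}

label_from_directions <- function(turnover_dir, abundance_dir) {
  dplyr::case_when(
    turnover_dir == 1L & abundance_dir == 1L ~ "synthesis_up",
    turnover_dir == -1L & abundance_dir == -1L ~ "synthesis_down",
    turnover_dir == 1L & abundance_dir == -1L ~ "degradation_up",
    turnover_dir == -1L & abundance_dir == 1L ~ "degradation_down",
    turnover_dir == 1L & abundance_dir == 0L ~ "repair_up",
    turnover_dir == -1L & abundance_dir == 0L ~ "repair_down",
    turnover_dir == 0L & abundance_dir == 1L ~ "synthesis_up",
    turnover_dir == 0L & abundance_dir == -1L ~ "synthesis_down",
    TRUE ~ "unchanged"
  )
}

#' Classify measured per-protein changes into mechanistic regimes
#'
#' Applies the dynaplot mapping to measured turnover and abundance changes,
#' using two-tailed p-values to decide which axes moved. An axis counts as
#' changed only when its p-value is below `alpha` (default 0.01, the dynaplot
#' highlighting threshold). A significant abundance change without a
#' significant turnover change is a net-synthesis change inferred from one
#' axis only and is flagged `uncoupled`.
#'
#' @param turnover_delta Disease minus control incorporation (fraction or
#'   percentage points; only the sign is used).
#' @param turnover_p Two-tailed p-value(s) of the turnover comparison.
#' @param abundance_delta Disease minus control abundance (sign used).
#' @param abundance_p Two-tailed p-value(s) of the abundance comparison.
#' @param alpha Significance threshold in (0, 1); default 0.01.
#' @return A tibble with columns `mechanism_class`,
#'   `turnover_significant`, `abundance_significant`, `uncoupled`.
#' @examples
#' classify_mechanism(0.05, 0.001, 0.4, 0.001)  # synthesis_up
#' classify_mechanism(0.05, 0.001, 0.0, 0.8)    # repair_up
#' @export
classify_mechanism <- function(turnover_delta, turnover_p,
                               abundance_delta, abundance_p,
                               alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  t_sig <- !is.na(turnover_p) & turnover_p < alpha
  a_sig <- !is.na(abundance_p) & abundance_p < alpha
  t_dir <- ifelse(t_sig, sign(turnover_delta), 0L)
  a_dir <- ifelse(a_sig, sign(abundance_delta), 0L)
  tibble::tibble(
    mechanism_class = label_from_directions(t_dir, a_dir),
    turnover_significant = t_sig,
    abundance_significant = a_sig,
    uncoupled = a_sig & !t_sig
  )
}
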