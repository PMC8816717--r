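#' Mass shift of a K6-labeled peptide ion pair
#'
#' Each \eqn{^{13}C_6}-lysine replaces six \eqn{^{12}C} atoms, adding
#' `6 * (13.0033548378 - 12) = 6.0201290` Da per labeled lysine; the observed
#' m/z shift is that mass divided by the charge state. At one lysine and
#' charge 1 this is the canonical 6.02 Da pair spacing.
#'
#' @param n_labeled_lysines Number of labeled lysines in the peptide (>= 1).
#' @param charge Charge state (>= 1).
#' @return m/z shift in Da (Th).
#' @examples
#' round(k6_mass_shift(1, 1), 2)  # 6.02
#' round(k6_mass_shift(1, 2), 2)  # 3.01
#' @export
k6_mass_shift <- function(n_labeled_lysines, charge) {
  if (!is.numeric(n_labeled_lysines) || any(n_labeled_lysines < 1) ||
      any(n_labeled_lysines != round(n_labeled_lysines))) {
    abort("`n_labeled_lysines` must be a positive integer.")
  }
  if (!is.numeric(charge) || any(charge < 1) || any(charge != round(charge))) {
    abort("`charge` must be a positive integer.")
  }
  delta_c13 <- 13.0033548378 - 12
  n_labeled_lysines * 6 * delta_c13 / charge
}

# native column schemas ------------------------------------------------------

evidence_columns <- c(
  protein_id = "character", peptide_sequence = "character",
  lysine_count = "integer", charge = "integer",
  fraction_id = "character", mouse_id = "character", cohort = "character",
  intensity_light = "double", intensity_mixed = "double",
  intensity_heavy = "double", n_observations = "integer"
)

abundance_columns <- c(
  protein_id = "character", fraction_id = "character",
  mouse_id = "character", cohort = "character", abundance = "double"
)

# MaxQuant-dialect column mapping (normalized: lower case, alphanumerics only).
# "Intensity M" exists only in triple-label searches; it is optional and
# defaults to 0. Sample identity (mouse, cohort, fraction) is not carried by
# MaxQuant evidence columns and comes from the companion sample map, keyed by
# the "Experiment" (or "Raw file") column.
maxquant_evidence_map <- c(
  protein_id = "leadingrazorprotein",
  peptide_sequence = "sequence",
  lysine_count = "kcount",
  charge = "charge",
  intensity_light = "intensityl",
  intensity_mixed = "intensitym",
  intensity_heavy = "intensityh",
  n_observations = "ratiohlcount",
  experiment = "experiment"
)

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

coerce_columns <- function(df, schema) {
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
      character = as.character(df[[nm]]),
      integer = as.integer(df[[nm]]),
      double = as.numeric(df[[nm]])
    )
  }
  df[names(schema)]
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) abort(sprintf("Input table is empty: %s", path))
  df
}

#' Read a peptide evidence table
#'
#' Reads a tab-separated evidence table in either the native schema (one row
#' per peptide-pair observation with columns `protein_id, peptide_sequence,
#' lysine_count, charge, fraction_id, mouse_id, cohort, intensity_light,
#' intensity_mixed, intensity_heavy, n_observations`) or the MaxQuant
#' evidence.txt dialect, whose columns are renamed through a fixed mapping
#' (`Leading razor protein`, `Sequence`, `K Count`, `Charge`, `Intensity L`,
#' `Intensity M` (optional), `Intensity H`, `Ratio H/L count`, `Experiment`).
#' For the MaxQuant dialect a `sample_map` table with columns
#' `experiment, mouse_id, cohort, fraction_id` must be supplied. Rows whose
#' three species intensities are all zero or unparseable are dropped and the
#' count reported.
#'
#' @param path Path to the TSV file.
#' @param dialect `"native"` or `"maxquant"`.
#' @param sample_map Data frame mapping `experiment` to `mouse_id`, `cohort`
#'   and `fraction_id` (MaxQuant dialect only).
#' @return A tibble of validated evidence records.
#' @export
read_evidence <- function(path, dialect = c("native", "maxquant"),
                          sample_map = NULL) {
  dialect <- match.arg(dialect)
  df <- read_tsv_checked(path)

  if (dialect == "maxquant") {
    norm <- normalize_header(names(df))
    wanted <- maxquant_evidence_map
    pos <- match(wanted, norm)
    optional <- c("intensity_mixed")
    missing_cols <- names(wanted)[is.na(pos) & !names(wanted) %in% optional]
    if (length(missing_cols)) {
      abort(paste0("MaxQuant evidence table is missing required column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    out <- tibble::as_tibble(
      setNames(lapply(seq_along(wanted), function(i) {
        if (is.na(pos[i])) rep(0, nrow(df)) else df[[pos[i]]]
      }), names(wanted))
    )
    if (is.null(sample_map)) {
      abort("The maxquant dialect needs a `sample_map` (experiment -> mouse_id, cohort, fraction_id).")
    }
    need <- c("experiment", "mouse_id", "cohort", "fraction_id")
    if (!all(need %in% names(sample_map))) {
      abort(paste0("`sample_map` must have columns: ",
                   paste(need, collapse = ", ")))
    }
    out <- dplyr::inner_join(out, tibble::as_tibble(sample_map),
                             by = "experiment")
    out$experiment <- NULL
    df <- out
  }

  missing_cols <- setdiff(names(evidence_columns), names(df))
  if (length(missing_cols)) {
    abort(paste0("Evidence table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- coerce_columns(df, evidence_columns)

  n0 <- nrow(df)
  complete <- !is.na(df$protein_id) & !is.na(df$mouse_id) &
    !is.na(df$cohort) & !is.na(df$intensity_light) &
    !is.na(df$intensity_heavy) & !is.na(df$intensity_mixed) &
    !is.na(df$n_observations)
  usable <- complete &
    (df$intensity_light + df$intensity_mixed + df$intensity_heavy) > 0
  df <- df[usable, , drop = FALSE]
  dropped <- n0 - nrow(df)
  if (dropped > 0) {
    pf_inform(sprintf("read_evidence: dropped %d of %d row(s) with zero total intensity or unparseable fields.",
                      dropped, n0))
  }
  if (nrow(df) == 0L) abort("No usable evidence rows after validation.")
  bad_cohort <- setdiff(unique(df$cohort), c("control", "disease"))
  if (length(bad_cohort)) {
    abort(paste0("Unknown cohort label(s): ", paste(bad_cohort, collapse = ", "),
                 " (expected 'control'/'disease')."))
  }
  tibble::as_tibble(df)
}

#' Read a per-fraction protein abundance table
#'
#' Native schema: one row per (protein, fraction, mouse) with columns
#' `protein_id, fraction_id, mouse_id, cohort, abundance`. The MaxQuant
#' proteinGroups.txt dialect carries one wide row per protein group with
#' `LFQ intensity <experiment>` columns; these are pivoted to the native long
#' form through the `sample_map` (`experiment, mouse_id, cohort,
#' fraction_id`).
#'
#' @inheritParams read_evidence
#' @return A tibble of protein-group abundance records; rows with missing or
#'   zero abundance are dropped (the completeness filter treats absence and
#'   zero identically).
#' @export
read_abundance <- function(path, dialect = c("native", "maxquant"),
                           sample_map = NULL) {
  dialect <- match.arg(dialect)
  df <- read_tsv_checked(path)

  if (dialect == "maxquant") {
    if (is.null(sample_map)) {
      abort("The maxquant dialect needs a `sample_map` (experiment -> mouse_id, cohort, fraction_id).")
    }
    norm <- normalize_header(names(df))
    id_pos <- match("majorityproteinids", norm)
    if (is.na(id_pos)) id_pos <- match("proteinids", norm)
    lfq <- grep("^lfqintensity.+", norm)
    if (is.na(id_pos) || !length(lfq)) {
      abort("MaxQuant proteinGroups table needs 'Majority protein IDs' and 'LFQ intensity <experiment>' columns.")
    }
    long <- tibble::tibble(
      protein_id = rep(as.character(df[[id_pos]]), times = length(lfq)),
      experiment = rep(sub("^lfqintensity", "", norm[lfq]),
                       each = nrow(df)),
      abundance = as.numeric(unlist(df[lfq], use.names = FALSE))
    )
    map <- tibble::as_tibble(sample_map)
    map$experiment <- normalize_header(map$experiment)
    long <- dplyr::inner_join(long, map, by = "experiment")
    long$experiment <- NULL
    df <- long
  }

  missing_cols <- setdiff(names(abundance_columns), names(df))
  if (length(missing_cols)) {
    abort(paste0("Abundance table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- coerce_columns(df, abundance_columns)
  n0 <- nrow(df)
  df <- df[!is.na(df$abundance) & df$abundance > 0 & !is.na(df$protein_id), ,
           drop = FALSE]
  if (n0 - nrow(df) > 0) {
    pf_inform(sprintf("read_abundance: dropped %d of %d row(s) without a positive abundance.",
                      n0 - nrow(df), n0))
  }
  tibble::as_tibble(df)
}

#' Write a result table deterministically
#'
#' Writes a TSV with fixed column order, rows sorted by the identifier
#' columns present (`protein_id`, `fraction_id`, `mouse_id`, `cohort`), and
#' floating-point values serialized at a fixed precision, so repeated runs on
#' identical inputs produce byte-identical files.
#'
#' @param records Data frame to write.
#' @param path Output path.
#' @param allow_empty Permit writing a header-only file (default `FALSE`).
#' @param digits Significant digits for floating-point columns (default 8).
#' @return The input, invisibly.
#' @export
write_results <- function(records, path, allow_empty = FALSE, digits = 8) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  if (nrow(records) == 0L && !allow_empty) {
    abort("Refusing to write an empty table (set `allow_empty = TRUE` to override).")
  }
  # total order over identifier columns first, then every remaining atomic
  # column, so tied keys still sort deterministically
  keys <- intersect(c("protein_id", "fraction_id", "mouse_id", "cohort"),
                    names(records))
  sortable <- names(records)[vapply(records, is.atomic, logical(1))]
  keys <- c(keys, setdiff(sortable, keys))
  if (length(keys) && nrow(records) > 1L) {
    records <- records[do.call(order, records[keys]), , drop = FALSE]
  }
  out <- records
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], digits = digits, format = "g")
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(records)
}

#' Validate a table against its native schema
#'
#' @param df Data frame to check.
#' @param type `"evidence"` or `"abundance"`.
#' @return A list with `ok` (logical) and `problems` (character vector);
#'   usable from the command-line `validate` subcommand.
#' @export
validate_table <- function(df, type = c("evidence", "abundance")) {
  type <- match.arg(type)
  schema <- if (type == "evidence") evidence_columns else abundance_columns
  problems <- character(0)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing_cols, collapse = ", ")))
  } else {
    if (type == "evidence") {
      tot <- df$intensity_light + df$intensity_mixed + df$intensity_heavy
      if (any(tot <= 0, na.rm = TRUE)) {
        problems <- c(problems, sprintf("%d row(s) with zero total intensity",
                                        sum(tot <= 0, na.rm = TRUE)))
      }
      if (any(df$n_observations < 1, na.rm = TRUE)) {
        problems <- c(problems, "n_observations below 1")
      }
      with_seq <- !is.na(df$peptide_sequence) & nzchar(df$peptide_sequence)
      kcount <- vapply(strsplit(df$peptide_sequence[with_seq], ""),
                       function(x) sum(x == "K"), integer(1))
      if (any(kcount != df$lysine_count[with_seq])) {
        problems <- c(problems, sprintf(
          "%d row(s) where lysine_count disagrees with the K residues in the sequence",
          sum(kcount != df$lysine_count[with_seq])))
      }
    } else {
      if (any(df$abundance < 0, na.rm = TRUE)) {
        problems <- c(problems, "negative abundances")
      }
      dup <- duplicated(df[c("protein_id", "fraction_id", "mouse_id")])
      if (any(dup)) {
        problems <- c(problems, sprintf(
          "%d duplicate (protein, fraction, mouse) record(s)", sum(dup)))
      }
    }
  }
  list(ok = length(problems) == 0L, problems = problems)
}
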