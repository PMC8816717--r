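test_that("K6 pair mass shifts match the printed spacing", {
  expect_equal(round(k6_mass_shift(1, 1), 2), 6.02)
  expect_equal(round(k6_mass_shift(1, 2), 2), 3.01)
  expect_equal(round(k6_mass_shift(2, 1), 2), 12.04)
  expect_equal(k6_mass_shift(1, 1), 6 * (13.0033548378 - 12))
  expect_error(k6_mass_shift(0, 1))
  expect_error(k6_mass_shift(1, 0))
})

test_that("native evidence round-trips through write and read", {
  sim <- sim_small(n_proteins = 30, seed = 101)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(sim$evidence, path)
  back <- read_evidence(path)
  orig <- dplyr::arrange(sim$evidence, protein_id, fraction_id, mouse_id,
                         peptide_sequence, lysine_count)
  back <- dplyr::arrange(back, protein_id, fraction_id, mouse_id,
                         peptide_sequence, lysine_count)
  expect_equal(back$protein_id, orig$protein_id)
  expect_equal(back$intensity_light, orig$intensity_light,
               tolerance = 1e-6)
  expect_equal(back$intensity_heavy, orig$intensity_heavy,
               tolerance = 1e-6)
  expect_equal(back$n_observations, orig$n_observations)
})

test_that("repeated writes of the same table are byte-identical", {
  sim <- sim_small(n_proteins = 15, seed = 103)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(sim$evidence, p1)
  write_results(sim$evidence[sample(nrow(sim$evidence)), ], p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the MaxQuant dialect maps onto the native schema", {
  sim <- sim_small(n_proteins = 20, seed = 105)
  ev <- sim$evidence
  # disguise the table in MaxQuant clothes, with sample identity in the
  # Experiment column resolved through a sample map
  mq <- tibble::tibble(
    `Leading razor protein` = ev$protein_id,
    Sequence = ev$peptide_sequence,
    `K Count` = ev$lysine_count,
    Charge = ev$charge,
    `Intensity L` = ev$intensity_light,
    `Intensity M` = ev$intensity_mixed,
    `Intensity H` = ev$intensity_heavy,
    `Ratio H/L count` = ev$n_observations,
    Experiment = paste(ev$mouse_id, ev$fraction_id, sep = "_")
  )
  map <- dplyr::distinct(ev, mouse_id, cohort, fraction_id) |>
    dplyr::mutate(experiment = paste(mouse_id, fraction_id, sep = "_"))
  p_mq <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(mq, p_mq, progress = FALSE)
  p_native <- withr::local_tempfile(fileext = ".tsv")
  write_results(ev, p_native)

  from_mq <- read_evidence(p_mq, dialect = "maxquant", sample_map = map)
  from_native <- read_evidence(p_native)
  key <- function(d) dplyr::arrange(d, protein_id, peptide_sequence,
                                    fraction_id, mouse_id)
  expect_equal(key(from_mq)[names(from_native)] |> as.data.frame(),
               key(from_native) |> as.data.frame(), tolerance = 1e-6)
})

test_that("MaxQuant proteinGroups wide LFQ columns pivot to long form", {
  ab <- sim_small(n_proteins = 10, seed = 107)$abundance
  ab$experiment <- paste(ab$mouse_id, ab$fraction_id, sep = "_")
  wide <- tidyr::pivot_wider(ab, id_cols = "protein_id",
                             names_from = "experiment",
                             names_prefix = "LFQ intensity ",
                             values_from = "abundance")
  names(wide)[1] <- "Majority protein IDs"
  map <- dplyr::distinct(ab, experiment, mouse_id, cohort, fraction_id)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, path, progress = FALSE)
  long <- read_abundance(path, dialect = "maxquant", sample_map = map)
  key <- function(d) dplyr::arrange(d, protein_id, fraction_id, mouse_id)
  expect_equal(key(long) |> as.data.frame(),
               key(ab[names(long)]) |> as.data.frame(), tolerance = 1e-6)
})

test_that("schema violations fail loudly and bad rows are dropped", {
  sim <- sim_small(n_proteins = 10, seed = 109)
  ev <- sim$evidence
  # zero-intensity row is dropped with a report
  ev$intensity_light[1] <- 0
  ev$intensity_mixed[1] <- 0
  ev$intensity_heavy[1] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(ev, path)
  withr::local_options(proteoflux.quiet = FALSE)
  expect_message(back <- read_evidence(path), "dropped 1 of")
  expect_equal(nrow(back), nrow(ev) - 1)

  # missing mandatory column is named in the error
  broken <- ev[setdiff(names(ev), "charge")]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(broken, p2, progress = FALSE)
  expect_error(read_evidence(p2), "charge")

  # empty file is an explicit error
  p3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ev[0, ], p3, progress = FALSE)
  expect_error(read_evidence(p3), "empty")
})

test_that("empty tables are refused unless explicitly allowed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- tibble::tibble(protein_id = character(), x = double())
  expect_error(write_results(empty, path), "empty")
  expect_silent(write_results(empty, path, allow_empty = TRUE))
  expect_true(file.exists(path))
})

test_that("validate_table reports schema problems", {
  sim <- sim_small(n_proteins = 10, seed = 111)
  good <- validate_table(sim$evidence, "evidence")
  expect_true(good$ok)
  bad <- sim$evidence
  bad$lysine_count[1] <- bad$lysine_count[1] + 1L
  res <- validate_table(bad, "evidence")
  expect_false(res$ok)
  expect_match(res$problems, "lysine_count", all = FALSE)
  ab <- sim$abundance
  dup <- validate_table(rbind(ab, ab[1, ]), "abundance")
  expect_false(dup$ok)
})
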