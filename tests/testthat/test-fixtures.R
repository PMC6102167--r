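test_that("fixture generation is deterministic: same spec and seed give identical files", {
  spec <- fixture_spec(seed = 21)
  d1 <- tempfile("fxa"); d2 <- tempfile("fxb")
  fx1 <- make_source_tables(spec, d1)
  fx2 <- make_source_tables(spec, d2)
  expect_identical(readLines(fx1$quantitative),
                   readLines(fx2$quantitative))
  expect_identical(readLines(fx1$qualitative), readLines(fx2$qualitative))
  expect_identical(fx1$truth, fx2$truth)
  # metadata sidecar records the RNG
  meta <- jsonlite::read_json(fx1$metadata)
  expect_equal(meta$seed, 21)
  expect_true(nzchar(meta$rng_kind))
})

test_that("fixture outputs parse with zero validation failures", {
  spec <- fixture_spec(n_molecules = 7, seed = 5)
  fx <- make_source_tables(spec, tempfile("fxv"))
  q <- read_quantitative_table(fx$quantitative,
                               fx$sources[["quantitative"]])
  l <- read_qualitative_table(fx$qualitative, fx$sources[["qualitative"]])
  expect_equal(nrow(ingest_report(q)), 0)
  expect_equal(nrow(ingest_report(l)), 0)
  v <- validate_records(rbind(q, l))
  expect_equal(nrow(v$records), spec$n_quant_records + spec$n_qual_records)
  expect_true(all(v$report[names(v$report) != "censored_relation"] == 0))
})

test_that("duplicate_rate 0 gives registry size equal to n_molecules", {
  spec <- fixture_spec(n_molecules = 5, n_qual_records = 10,
                       duplicate_rate = 0, seed = 2)
  fx <- make_source_tables(spec, tempfile("fxd"))
  recs <- rbind(
    read_quantitative_table(fx$quantitative, "sq"),
    read_qualitative_table(fx$qualitative, "sl"))
  reg <- register_molecules(validate_records(recs)$records)
  expect_equal(nrow(reg$entries), 5)
})

test_that("pipeline summary table equals the independent ground-truth pass exactly", {
  spec <- fixture_spec(n_molecules = 5, n_targets = 4,
                       n_quant_records = 20, n_qual_records = 8, seed = 7)
  fx <- make_source_tables(spec, tempfile("fxg"))
  recs <- rbind(
    read_quantitative_table(fx$quantitative,
                            fx$sources[["quantitative"]]),
    read_qualitative_table(fx$qualitative, fx$sources[["qualitative"]]))
  db <- build_drug_target_db(recs)
  got <- db$summaries[, c("internal_id", "gene_symbol", "mean_pchembl",
                          "n_quantitative", "n_qualitative", "ksi",
                          "confidence")]
  want <- fx$truth[, c("internal_id", "gene_symbol", "mean_pchembl",
                       "n_quantitative", "n_qualitative", "ksi",
                       "confidence")]
  got <- got[order(got$internal_id, got$gene_symbol), ]
  want <- want[order(want$internal_id, want$gene_symbol), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got$internal_id, want$internal_id)
  expect_identical(got$gene_symbol, want$gene_symbol)
  expect_identical(got$n_quantitative, want$n_quantitative)
  expect_identical(got$n_qualitative, want$n_qualitative)
  expect_equal(got$mean_pchembl, want$mean_pchembl, tolerance = 0)
  expect_equal(got$ksi, want$ksi, tolerance = 0)
  expect_equal(got$confidence, want$confidence, tolerance = 0)
})

test_that("response fixtures honour their construction parameters", {
  spec <- fixture_spec(n_molecules = 6, seed = 31)
  # zero missing rate: every pair shares all cell lines
  fx <- make_response_matrix(spec, n_cell_lines = 8, missing_rate = 0,
                             dir = tempfile("rm0"))
  m <- read_response_matrix(fx$auc, fx$structures)
  rows <- correlate_responses(m, fx$expected$reference)
  expect_true(all(rows$n_shared == 8))
  # same seed: identical files
  fx2 <- make_response_matrix(spec, n_cell_lines = 8, missing_rate = 0,
                              dir = tempfile("rm1"))
  expect_identical(readLines(fx$auc), readLines(fx2$auc))
  # missing values reduce overlap but never invent correlations
  fx3 <- make_response_matrix(spec, n_cell_lines = 8,
                              missing_rate = 0.3, dir = tempfile("rm2"))
  m3 <- read_response_matrix(fx3$auc, fx3$structures)
  rows3 <- correlate_responses(m3, fx3$expected$reference)
  expect_true(all(rows3$n_shared <= 8))
  merged <- merge(rows3, fx3$expected$rho_table, by = "drug")
  expect_equal(merged$spearman_rho, merged$rho, tolerance = 1e-12)
  expect_equal(merged$n_shared.x, merged$n_shared.y)
})

test_that("database writing round-trips registry, summaries and fingerprints", {
  spec <- fixture_spec(n_molecules = 5, seed = 17)
  fx <- make_source_tables(spec, tempfile("dbrt"))
  recs <- rbind(read_quantitative_table(fx$quantitative, "sq"),
                read_qualitative_table(fx$qualitative, "sl"))
  db <- build_drug_target_db(recs)
  dir <- tempfile("dbout")
  write_database(db, dir)
  db2 <- read_database(dir)
  expect_equal(db2$registry$entries$internal_id,
               db$registry$entries$internal_id)
  expect_equal(db2$registry$structure_index, db$registry$structure_index)
  expect_equal(db2$summaries$mean_pchembl, db$summaries$mean_pchembl)
  expect_equal(db2$summaries$ksi, db$summaries$ksi)
  expect_equal(db2$summaries$confidence, db$summaries$confidence)
  expect_equal(db2$params$mu_all, db$params$mu_all)
  q <- db$registry$entries$canonical_smiles[1]
  expect_equal(similarity_search(db2, q, 0.9),
               similarity_search(db, q, 0.9))
})
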