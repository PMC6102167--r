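make_response_files <- function(auc_df, st_df) {
  ap <- tempfile(fileext = ".csv")
  utils::write.csv(auc_df, ap, row.names = FALSE, na = "")
  sp <- tempfile(fileext = ".tsv")
  utils::write.table(st_df, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(auc = ap, structures = sp)
}

test_that("response matrix reader aligns labels and flags missing structures", {
  auc <- data.frame(drug = c("d1", "d2", "d3"),
                    CL1 = c(0.1, 0.2, NA), CL2 = c(0.3, 0.4, 0.5),
                    CL3 = c(0.5, 0.6, 0.7), CL4 = c(0.7, 0.8, 0.9))
  st <- data.frame(drug = c("d1", "d2"),
                   smiles = c("CCO", "c1ccccc1"))
  f <- make_response_files(auc, st)
  m <- read_response_matrix(f$auc, f$structures)
  expect_equal(dim(m$auc), c(3L, 4L))
  expect_true(is.na(m$auc["d3", "CL1"]))  # missing, not zero
  expect_equal(m$missing_structure, "d3")

  st_bad <- rbind(st, data.frame(drug = "ghost", smiles = "CCO"))
  f2 <- make_response_files(auc, st_bad)
  expect_error(read_response_matrix(f2$auc, f2$structures), "ghost")
})

test_that("reference selection is the brute-force Tanimoto argmax", {
  auc <- data.frame(drug = sprintf("d%d", 1:5),
                    CL1 = runif(5), CL2 = runif(5), CL3 = runif(5))
  st <- data.frame(drug = sprintf("d%d", 1:5),
                   smiles = c("CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1",
                              "CCO", "Cc1ccccc1", "C1CCCCC1"))
  f <- make_response_files(auc, st)
  m <- read_response_matrix(f$auc, f$structures)
  query <- "CC(=O)Oc1ccccc1C(=O)N"  # close to aspirin, not in the set
  ref <- select_reference(m, query)
  sims <- vapply(st$smiles, function(s)
    tanimoto(compute_fingerprint(query, "extended"),
             compute_fingerprint(s, "extended")), numeric(1))
  expect_equal(ref$drug, st$drug[which.max(sims)])
  expect_equal(ref$similarity, max(sims))
  # query identical to one drug: that drug at similarity 1
  ref2 <- select_reference(m, "c1ccccc1")
  expect_equal(ref2, list(drug = "d2", similarity = 1.0))
  # single-drug matrix: that drug regardless of similarity
  m1 <- read_response_matrix(
    make_response_files(auc[1, ], st[1, ])$auc,
    make_response_files(auc[1, ], st[1, ])$structures)
  expect_equal(select_reference(m1, "CCO")$drug, "d1")
})

test_that("spearman correlation matches the closed-form rank formula", {
  auc <- data.frame(drug = c("ref", "same", "rev", "perm"),
                    rbind(c(1, 2, 3, 4, 5),
                          c(10, 20, 30, 40, 50),   # monotone transform
                          c(5, 4, 3, 2, 1),
                          c(2, 1, 4, 3, 5)))
  st <- data.frame(drug = auc$drug, smiles = "CCO")
  f <- make_response_files(auc, st)
  m <- read_response_matrix(f$auc, f$structures)
  rows <- correlate_responses(m, "ref")
  expect_equal(rows$drug, c("same", "rev", "perm"))
  expect_equal(rows$spearman_rho[rows$drug == "same"], 1)
  expect_equal(rows$spearman_rho[rows$drug == "rev"], -1)
  # hand computation: d^2 = (1,1,1,1,0) -> rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(rows$spearman_rho[rows$drug == "perm"], 0.8)
  expect_equal(rows$n_shared, rep(5L, 3))
})

test_that("pairwise-complete handling and the minimum-overlap rule", {
  auc <- data.frame(drug = c("ref", "full", "sparse"),
                    CL1 = c(0.1, 0.2, 0.15), CL2 = c(0.2, 0.4, NA),
                    CL3 = c(0.3, 0.5, NA), CL4 = c(0.4, 0.9, NA),
                    CL5 = c(0.5, 0.95, NA))
  st <- data.frame(drug = auc$drug, smiles = "CCO")
  f <- make_response_files(auc, st)
  m <- read_response_matrix(f$auc, f$structures)
  rows <- correlate_responses(m, "ref")
  expect_equal(rows$n_shared[rows$drug == "sparse"], 1L)
  expect_true(is.na(rows$spearman_rho[rows$drug == "sparse"]))
  expect_false(is.na(rows$spearman_rho[rows$drug == "full"]))
  # inserting a missing value only changes rows sharing that cell line
  auc2 <- auc; auc2$CL5[2] <- NA
  f2 <- make_response_files(auc2, st)
  rows2 <- correlate_responses(read_response_matrix(f2$auc,
                                                    f2$structures), "ref")
  expect_equal(rows2$n_shared[rows2$drug == "full"], 4L)
  expect_equal(rows2[rows2$drug == "sparse", ],
               rows[rows$drug == "sparse", ], ignore_attr = TRUE)
})

test_that("similarity annotation targets the original query, reference excluded", {
  spec <- fixture_spec(n_molecules = 6, seed = 13)
  fx <- make_response_matrix(spec, n_cell_lines = 10, noise_sd = 0,
                             dir = tempfile("resp"))
  m <- read_response_matrix(fx$auc, fx$structures)
  res <- response_correlation(m, fx$query_smiles)
  expect_equal(res$reference$drug, fx$expected$reference)
  expect_equal(res$reference$similarity, 1.0)
  expect_false(fx$expected$reference %in% res$table$drug)
  # embedded analog with zero noise: rho exactly 1, high similarity
  analog <- res$table[res$table$drug == "SCR002", ]
  expect_equal(analog$spearman_rho, 1)
  expect_gt(analog$tanimoto_to_query, 0.8)
  # rho column matches the generator's independent rank computation
  merged <- merge(res$table, fx$expected$rho_table, by = "drug")
  expect_equal(merged$spearman_rho, merged$rho, tolerance = 1e-12)
  # monotone-transform invariance of spearman
  expect_equal(res$table$spearman_rho,
               {
        m2 <- m; m2$auc <- log(m2$auc - min(m2$auc, na.rm = TRUE) + 0.5)
        correlate_responses(m2, res$reference$drug)$spearman_rho
               })
})

test_that("structureless drugs keep correlations but get no similarity", {
  auc <- data.frame(drug = c("ref", "nostruct"),
                    CL1 = c(0.1, 0.3), CL2 = c(0.2, 0.1),
                    CL3 = c(0.3, 0.6), CL4 = c(0.4, 0.5))
  st <- data.frame(drug = "ref", smiles = "CCO")
  f <- make_response_files(auc, st)
  m <- read_response_matrix(f$auc, f$structures)
  out <- annotate_similarity(correlate_responses(m, "ref"), m, "CCO")
  expect_true(is.na(out$tanimoto_to_query))
  expect_false(is.na(out$spearman_rho))
})
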