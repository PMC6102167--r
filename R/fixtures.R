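# Deterministic synthetic source tables, GMT collections and response
# matrices with independently computed ground truth.
#
# The ground-truth pass is intentionally naive -- plain loops over the
# generated rows, its own unit handling and its own rank-correlation
# code -- and never calls the pipeline modules, so it can serve as an
# oracle for them.

# vetted, standardizable structures; extended programmatically with
# n-alkanols when a fixture needs more molecules than the list holds
.FIXTURE_SMILES <- c(
  "CC(=O)Oc1ccccc1C(=O)O",          # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",     # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",     # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",             # paracetamol
  "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "c1ccncc1",
  "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1c[nH]cn1",
  "C1COCCN1", "C1CCNCC1", "C1CCCCC1", "C1CCOC1",
  "C[C@H](N)C(=O)O",                # L-alanine (one stereocentre)
  "OC(=O)c1ccccc1", "COc1ccccc1", "CC(=O)c1ccccc1",
  "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1",
  "CCOCC", "CC(C)O", "CCN(CC)CC", "CC(=O)OCC", "CCC(=O)O",
  "N#Cc1ccccc1", "O=Cc1ccccc1")

#' Pool of valid fixture structures
#'
#' @param n Number of structures required.
#' @return Character vector of `n` distinct, parseable SMILES.
#' @export
fixture_smiles_pool <- function(n) {
  pool <- .FIXTURE_SMILES
  k <- 2
  while (length(pool) < n) {
    pool <- c(pool, paste0(strrep("C", k), "O"))  # n-alkanols
    k <- k + 1
  }
  pool[seq_len(n)]
}

#' Fixture specification
#'
#' Describes one synthetic evidence dataset: how many molecules and
#' targets, how many quantitative and qualitative rows, the potency range
#' for log-uniform draws (nM), the fraction of molecules registered under
#' a second alias and source, and the RNG seed. Identical spec + seed
#' produce byte-identical files.
#'
#' @param n_molecules,n_targets,n_quant_records,n_qual_records Positive
#'   counts.
#' @param potency_range Length-2 numeric, min/max potency in nM for
#'   log-uniform draws.
#' @param duplicate_rate Fraction in `[0, 1]` of molecules that also
#'   appear under an alternate alias in the qualitative source.
#' @param seed Integer RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 8, n_targets = 6,
                         n_quant_records = 40, n_qual_records = 15,
                         potency_range = c(1, 10000),
                         duplicate_rate = 0.25, seed = 1) {
  stopifnot(n_molecules >= 1, n_targets >= 1, n_quant_records >= 1,
            n_qual_records >= 0, length(potency_range) == 2,
            potency_range[1] > 0, potency_range[2] >= potency_range[1],
            duplicate_rate >= 0, duplicate_rate <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_targets = as.integer(n_targets),
                 n_quant_records = as.integer(n_quant_records),
                 n_qual_records = as.integer(n_qual_records),
                 potency_range = as.numeric(potency_range),
                 duplicate_rate = duplicate_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.fixture_metadata <- function(spec, path) {
  jsonlite::write_json(
    c(unclass(spec),
      list(rng_kind = RNGkind()[1], r_version = as.character(getRversion()))),
    path, auto_unbox = TRUE, digits = NA)
}

#' Generate synthetic source tables with ground truth
#'
#' Writes a quantitative table (ChEMBL-style potency rows: alias, SMILES,
#' gene, value type, value, unit, relation) and a qualitative table
#' (curated-association style: alias, SMILES, gene). A `duplicate_rate`
#' fraction of molecules appear in the qualitative table under an
#' alternate alias, so structural consolidation is exercised. The exact
#' expected association summary (means, counts, KSI, confidence) is
#' computed by an independent straightforward pass over the generated
#' rows and returned as `truth`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return List with `quantitative`, `qualitative`, `metadata` (paths),
#'   `sources` (labels to pass to the readers), and `truth` (data frame:
#'   `internal_id`, `canonical_smiles`, `gene_symbol`, `mean_pchembl`,
#'   `n_quantitative`, `n_qualitative`, `ksi`, `confidence`).
#' @export
make_source_tables <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smiles <- fixture_smiles_pool(spec$n_molecules)
  alias <- sprintf("drug%03d", seq_len(spec$n_molecules))
  alt <- sprintf("drug%03d-alt", seq_len(spec$n_molecules))
  n_dup <- floor(spec$duplicate_rate * spec$n_molecules)
  genes <- sprintf("GENE%02d", seq_len(spec$n_targets))
  lo <- log(spec$potency_range[1]); hi <- log(spec$potency_range[2])

  out <- .with_seed(spec$seed, {
    m <- sample.int(spec$n_molecules, spec$n_quant_records, replace = TRUE)
    g <- sample(genes, spec$n_quant_records, replace = TRUE)
    vt <- sample(c("IC50", "EC50", "AC50", "Ki", "Kd", "potency",
                   "pChEMBL"),
                 spec$n_quant_records, replace = TRUE)
    nm_val <- exp(stats::runif(spec$n_quant_records, lo, hi))
    unit <- ifelse(vt == "pChEMBL", "pchembl_unitless",
                   sample(c("nM", "uM"), spec$n_quant_records,
                          replace = TRUE))
    value <- ifelse(unit == "pchembl_unitless", -log10(nm_val * 1e-9),
                    ifelse(unit == "uM", nm_val / 1e3, nm_val))
    quant <- data.frame(molecule_alias = alias[m], smiles = smiles[m],
                        gene_symbol = g, value_type = vt,
                        value = sprintf("%.10g", value), unit = unit,
                        relation = "=", stringsAsFactors = FALSE)

    if (spec$n_qual_records > 0) {
      qm <- sample.int(spec$n_molecules, spec$n_qual_records,
                       replace = TRUE)
      qg <- sample(genes, spec$n_qual_records, replace = TRUE)
      qual <- data.frame(
        molecule_alias = ifelse(qm <= n_dup, alt[qm], alias[qm]),
        smiles = smiles[qm], gene_symbol = qg, stringsAsFactors = FALSE)
    } else {
      qual <- data.frame(molecule_alias = character(),
                         smiles = character(),
                         gene_symbol = character(),
                         stringsAsFactors = FALSE)
    }
    list(quant = quant, qual = qual)
  })

  qpath <- file.path(dir, "quantitative.tsv")
  lpath <- file.path(dir, "qualitative.tsv")
  mpath <- file.path(dir, "metadata.json")
  utils::write.table(out$quant, qpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(out$qual, lpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .fixture_metadata(spec, mpath)

  truth <- .naive_truth(out$quant, out$qual)
  list(quantitative = qpath, qualitative = lpath, metadata = mpath,
       sources = c(quantitative = "synthetic_potency_db",
                   qualitative = "synthetic_curated_db"),
       truth = truth)
}

# Independent straightforward summary pass over the written rows: plain
# loops, its own unit handling; shares nothing with the pipeline beyond
# the canonical-SMILES call needed to define molecule identity.
.naive_truth <- function(quant, qual) {
  all_smiles <- unique(c(quant$smiles, qual$smiles))
  canon <- vapply(all_smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", s)
    trimws(sub("[\t\n].*$", "", out))
  }, character(1))
  ids <- stats::setNames(sprintf("MOL%05d",
                                 seq_along(sort(unique(canon),
                                                method = "radix"))),
                         sort(unique(canon), method = "radix"))
  qc <- ids[canon[match(quant$smiles, all_smiles)]]
  lc <- ids[canon[match(qual$smiles, all_smiles)]]

  pch <- numeric(nrow(quant))
  for (i in seq_len(nrow(quant))) {
    v <- as.numeric(quant$value[i])
    pch[i] <- switch(quant$unit[i],
                     pchembl_unitless = v,
                     nM = -log10(v * 1e-9),
                     uM = -log10((v * 1e3) * 1e-9),
                     M = -log10((v * 1e9) * 1e-9))
  }

  keys <- sort(unique(c(paste(qc, quant$gene_symbol),
                        paste(lc, qual$gene_symbol))), method = "radix")
  rows <- NULL
  for (k in keys) {
    id <- sub(" .*", "", k); gene <- sub(".* ", "", k)
    qi <- which(qc == id & quant$gene_symbol == gene)
    li <- which(lc == id & qual$gene_symbol == gene)
    mp <- if (length(qi)) mean(pch[qi]) else NA_real_
    rows <- rbind(rows, data.frame(
      internal_id = id,
      canonical_smiles = names(ids)[match(id, ids)],
      gene_symbol = gene, mean_pchembl = mp,
      n_quantitative = length(qi), n_qualitative = length(li),
      stringsAsFactors = FALSE))
  }
  rows$ksi <- NA_real_
  for (id in unique(rows$internal_id)) {
    sel <- rows$internal_id == id
    tot <- sum(rows$mean_pchembl[sel], na.rm = TRUE)
    rows$ksi[sel] <- rows$mean_pchembl[sel] / tot
  }
  counts <- rows$n_quantitative + rows$n_qualitative
  mu <- sum(counts) / length(counts)
  sigma <- sqrt(sum((counts - mu)^2) / length(counts))
  rows$confidence <- if (sigma > 0) (counts - mu) / sigma else
    rep(0, length(counts))
  rownames(rows) <- NULL
  rows
}

# independent rank correlation: average ranks, Pearson on ranks
.naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Generate a synthetic drug-response matrix with ground truth
#'
#' Emulates a screening export: an AUC matrix (drugs x cell lines) plus a
#' companion structure table. With `embedded_analog = TRUE` the set
#' contains a drug with the designated query's exact structure (the
#' expected reference) and a close structural analog whose response
#' vector is the reference's signal plus Gaussian noise, so a
#' high-similarity / high-correlation row is present by construction.
#'
#' @param spec A [fixture_spec()] (supplies the molecule count and seed).
#' @param n_cell_lines Number of cell-line columns.
#' @param embedded_analog Embed the reference/analog pair (default TRUE).
#' @param noise_sd SD of the analog's response noise (0 gives rho 1).
#' @param missing_rate Fraction of AUC cells blanked at random.
#' @param dir Output directory.
#' @return List with `auc`, `structures`, `metadata` (paths),
#'   `query_smiles`, and `expected`: `reference` (drug label),
#'   `similarity`, and `rho_table` (drug, rho, n_shared by the
#'   independent rank-correlation pass).
#' @export
make_response_matrix <- function(spec, n_cell_lines = 12,
                                 embedded_analog = TRUE, noise_sd = 0.05,
                                 missing_rate = 0, dir) {
  stopifnot(inherits(spec, "fixture_spec"), n_cell_lines >= 3)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- max(spec$n_molecules, if (embedded_analog) 4 else 2)
  # a family of n-alkanols keeps the analog pair structurally close and
  # the aromatic pool distant
  query_smiles <- "CCCCCCCO"
  drugs <- sprintf("SCR%03d", seq_len(n))
  smiles <- fixture_smiles_pool(n)
  if (embedded_analog) {
    smiles[1] <- query_smiles       # exact-match reference
    smiles[2] <- "CCCCCCCCO"        # close analog, correlated response
  }
  stopifnot(!anyDuplicated(smiles))

  gen <- .with_seed(spec$seed + 1L, {
    auc <- matrix(stats::runif(n * n_cell_lines, 0, 1), nrow = n)
    if (embedded_analog)
      auc[2, ] <- auc[1, ] + stats::rnorm(n_cell_lines, 0, noise_sd)
    if (missing_rate > 0) {
      drop <- stats::runif(length(auc)) < missing_rate
      auc[drop] <- NA
    }
    auc
  })
  auc <- round(gen, 6)
  rownames(auc) <- drugs
  colnames(auc) <- sprintf("CL%02d", seq_len(n_cell_lines))

  apath <- file.path(dir, "auc.csv")
  spath <- file.path(dir, "structures.tsv")
  mpath <- file.path(dir, "response_metadata.json")
  utils::write.csv(data.frame(drug = drugs, auc, check.names = FALSE),
                   apath, row.names = FALSE, na = "")
  utils::write.table(data.frame(drug = drugs, smiles = smiles),
                     spath, sep = "\t", quote = FALSE, row.names = FALSE)
  .fixture_metadata(spec, mpath)

  ref_row <- if (embedded_analog) 1L else 1L
  rho_table <- NULL
  for (i in seq_len(n)[-ref_row]) {
    ok <- !is.na(auc[i, ]) & !is.na(auc[ref_row, ])
    rho <- if (sum(ok) >= 3) .naive_spearman(auc[i, ok], auc[ref_row, ok])
      else NA_real_
    rho_table <- rbind(rho_table, data.frame(
      drug = drugs[i], rho = rho, n_shared = sum(ok),
      stringsAsFactors = FALSE))
  }
  list(auc = apath, structures = spath, metadata = mpath,
       query_smiles = query_smiles,
       expected = list(reference = drugs[ref_row],
                       similarity = if (embedded_analog) 1.0 else NA_real_,
                       rho_table = rho_table))
}

#' Generate a synthetic GMT collection
#'
#' @param path Output GMT path.
#' @param n_sets Number of gene sets.
#' @param universe Character vector of genes to draw from.
#' @param set_size_range Min/max set size.
#' @param seed RNG seed.
#' @return The path, with the written set list as attribute `"sets"`.
#' @export
make_gmt <- function(path, n_sets = 6,
                     universe = sprintf("GENE%02d", 1:40),
                     set_size_range = c(5, 15), seed = 1) {
  sets <- .with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      sort(sample(universe, size))
    })
  })
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  attr(path, "sets") <- sets
  path
}
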