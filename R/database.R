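# The assembled drug-target database: registry + scored summaries +
# fingerprints + indexes.

#' Build a drug-target database from evidence records
#'
#' Runs the full harmonization pipeline: record validation, structure
#' standardization and molecule consolidation, per-pair evidence
#' summarization, KSI and confidence scoring, and fingerprint generation
#' for every structured molecule.
#'
#' @param records Evidence records (rbind of the table readers' outputs).
#' @param fingerprint_methods Fingerprint methods to precompute; default
#'   `"extended"`, the method used by similarity queries unless
#'   overridden.
#' @param validate Run [validate_records()] first (default `TRUE`).
#' @return A `drug_target_db`: list with `registry`, `summaries`,
#'   `params`, `fingerprints` (keyed `<internal_id>.<method>`),
#'   `gene_index` (gene symbol -> internal ids) and
#'   `validation_report`.
#' @export
build_drug_target_db <- function(records,
                                 fingerprint_methods = "extended",
                                 validate = TRUE) {
  stopifnot(all(fingerprint_methods %in% FP_METHODS))
  vreport <- NULL
  if (validate) {
    v <- validate_records(records)
    records <- v$records
    vreport <- v$report
  }
  registry <- register_molecules(records)
  summaries <- summarize_associations(records, registry)
  summaries <- known_selectivity_index(summaries)
  conf <- confidence_scores(summaries)

  structured <- registry$entries[!is.na(registry$entries$canonical_smiles), ]
  fps <- list()
  for (m in fingerprint_methods) {
    for (i in seq_len(nrow(structured))) {
      fps[[paste(structured$internal_id[i], m, sep = ".")]] <-
        compute_fingerprint(structured$canonical_smiles[i], m)
    }
  }

  gene_index <- lapply(
    split(conf$summaries$internal_id, conf$summaries$gene_symbol),
    function(x) .radix_sort(unique(x)))

  structure(list(registry = registry,
                 summaries = conf$summaries,
                 params = conf$params,
                 fingerprints = fps,
                 gene_index = gene_index,
                 fingerprint_methods = fingerprint_methods,
                 validation_report = vreport),
            class = "drug_target_db")
}

#' @export
print.drug_target_db <- function(x, ...) {
  cat(sprintf(paste0("<drug_target_db: %d molecules, %d targets, ",
                     "%d associations>\n"),
              nrow(x$registry$entries), length(x$gene_index),
              nrow(x$summaries)))
  invisible(x)
}

#' Write a database to a directory
#'
#' Emits plain-text artifacts: `registry.tsv` (+ alias index JSON),
#' `summaries.tsv` (rounded report table), `summaries_full.tsv` (full
#' precision, for lossless reload), `params.json` and
#' `fingerprints.json`.
#'
#' @param db A `drug_target_db`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_registry(db$registry, file.path(dir, "registry.tsv"))
  write_summaries(db$summaries, file.path(dir, "summaries.tsv"))
  full <- db$summaries[, setdiff(names(db$summaries), "mean_by_type")]
  num <- vapply(full, is.numeric, logical(1))
  for (j in which(num)) full[[j]] <- sprintf("%.17g", full[[j]])
  utils::write.table(full, file.path(dir, "summaries_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  jsonlite::write_json(list(mu_all = db$params$mu_all,
                            sigma_all = db$params$sigma_all,
                            fingerprint_methods = db$fingerprint_methods),
                       file.path(dir, "params.json"), digits = NA,
                       auto_unbox = TRUE)
  jsonlite::write_json(
    lapply(db$fingerprints, function(fp)
      list(method = fp$method, length = fp$length, bits = fp$bits)),
    file.path(dir, "fingerprints.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a database written by [write_database()]
#'
#' @param dir Directory produced by [write_database()].
#' @return A `drug_target_db`.
#' @export
read_database <- function(dir) {
  reg_df <- .read_table(file.path(dir, "registry.tsv"), "\t")
  entries <- data.frame(internal_id = reg_df$internal_id,
                        canonical_smiles = reg_df$canonical_smiles,
                        stringsAsFactors = FALSE)
  entries$aliases <- strsplit(reg_df$aliases, "|", fixed = TRUE)
  entries$sources <- strsplit(reg_df$sources, "|", fixed = TRUE)
  alias_index <- list()
  for (i in seq_len(nrow(entries)))
    for (a in tolower(entries$aliases[[i]]))
      alias_index[[a]] <- .radix_sort(unique(c(alias_index[[a]],
                                               entries$internal_id[i])))
  ok <- !is.na(entries$canonical_smiles)
  registry <- structure(
    list(entries = entries, alias_index = alias_index,
         structure_index = stats::setNames(entries$internal_id[ok],
                                           entries$canonical_smiles[ok])),
    class = "mol_registry")

  summ <- .read_table(file.path(dir, "summaries_full.tsv"), "\t")
  for (nm in c("mean_pchembl", "ksi", "confidence"))
    summ[[nm]] <- as.numeric(summ[[nm]])
  for (nm in c("n_quantitative", "n_qualitative"))
    summ[[nm]] <- as.integer(as.numeric(summ[[nm]]))
  summ$mean_by_type <- I(rep(list(stats::setNames(numeric(0),
                                                  character(0))),
                             nrow(summ)))
  summ <- summ[, c("internal_id", "molecule_name", "gene_symbol",
                   "mean_pchembl", "mean_by_type", "n_quantitative",
                   "n_qualitative", "ksi", "confidence")]

  pj <- jsonlite::read_json(file.path(dir, "params.json"),
                            simplifyVector = TRUE)
  fpj <- jsonlite::read_json(file.path(dir, "fingerprints.json"),
                             simplifyVector = TRUE)
  fps <- lapply(fpj, function(fp)
    structure(list(method = fp$method,
                   bits = as.integer(fp$bits),
                   length = as.integer(fp$length)),
              class = "dt_fingerprint"))

  gene_index <- lapply(split(summ$internal_id, summ$gene_symbol),
                       function(x) .radix_sort(unique(x)))
  structure(list(registry = registry, summaries = summ,
                 params = structure(list(mu_all = pj$mu_all,
                                         sigma_all = pj$sigma_all),
                                    class = "confidence_params"),
                 fingerprints = fps, gene_index = gene_index,
                 fingerprint_methods = pj$fingerprint_methods,
                 validation_report = NULL),
            class = "drug_target_db")
}
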