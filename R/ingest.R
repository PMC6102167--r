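# Reading heterogeneous source tables into a uniform evidence-record stream.
#
# Every source row becomes one record with the same columns regardless of
# origin; quantitative potencies are normalized to nM at read time so that
# downstream aggregation never sees mixed units.

#' @keywords internal
VALUE_TYPES <- c("IC50", "XC50", "EC50", "AC50", "C50", "Ki", "Kd",
                 "potency", "pChEMBL")

#' @keywords internal
RELATIONS <- c("=", ">", "<", ">=", "<=", "~")

RECORD_COLS <- c("molecule_alias", "smiles", "gene_symbol", "kind",
                 "value_type", "value", "unit", "relation", "source")

.empty_records <- function() {
  data.frame(molecule_alias = character(), smiles = character(),
             gene_symbol = character(), kind = character(),
             value_type = character(), value = numeric(),
             unit = character(), relation = character(),
             source = character(), stringsAsFactors = FALSE)
}

.resolve_columns <- function(df, required, col_map, path) {
  map <- stats::setNames(as.list(required), required)
  for (nm in names(col_map)) map[[nm]] <- col_map[[nm]]
  for (nm in required) {
    if (!map[[nm]] %in% names(df))
      .stopf("missing required column '%s' in %s", map[[nm]], path)
  }
  map
}

#' Read a quantitative potency table
#'
#' Reads a delimited table of numeric drug-target potency measurements
#' (IC50/XC50/EC50/AC50/C50/Ki/Kd/potency in nM, uM or M, or unitless
#' pChEMBL values) into evidence records. Concentrations are converted to
#' nM (uM x 1000, M x 1e9); pChEMBL rows pass through unitless. Rows whose
#' value does not parse as a number, or whose unit is unknown, are skipped
#' and collected in the report attached as attribute \code{"report"}
#' (see [ingest_report()]).
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param source Label identifying the source database.
#' @param sep Field delimiter; default inferred from the file extension
#'   (`.csv` is comma, anything else tab).
#' @param col_map Named list remapping the expected column names
#'   (`molecule_alias`, `smiles`, `gene_symbol`, `value_type`, `value`,
#'   `unit`, and optionally `relation`) to the names used in the file.
#' @return A data frame of evidence records, one per surviving input row,
#'   in input order, with `kind = "quantitative"` throughout.
#' @examples
#' \dontrun{
#' recs <- read_quantitative_table("chembl_export.tsv", source = "chembl")
#' ingest_report(recs)
#' }
#' @export
read_quantitative_table <- function(path, source, sep = NULL,
                                    col_map = list()) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- .read_table(path, .detect_sep(path, sep))
  required <- c("molecule_alias", "smiles", "gene_symbol", "value_type",
                "value", "unit")
  map <- .resolve_columns(df, required, col_map, path)
  rel_col <- col_map[["relation"]] %||% "relation"

  report <- data.frame(row = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    out <- .empty_records()
    attr(out, "report") <- report
    return(out)
  }

  value <- suppressWarnings(as.numeric(df[[map$value]]))
  unit <- trimws(df[[map$unit]])
  bad_value <- is.na(value)
  bad_unit <- !bad_value & !unit %in% c("nM", "uM", "M", "pchembl_unitless")

  # normalize concentrations to nM; pChEMBL stays unitless
  value_nm <- value
  value_nm[unit == "uM"] <- value[unit == "uM"] * 1e3
  value_nm[unit == "M"] <- value[unit == "M"] * 1e9
  unit_out <- ifelse(unit == "pchembl_unitless", "pchembl_unitless", "nM")

  relation <- if (rel_col %in% names(df)) df[[rel_col]] else
    rep("=", nrow(df))
  relation[is.na(relation) | !nzchar(trimws(relation))] <- "="

  keep <- !(bad_value | bad_unit)
  if (any(bad_value))
    report <- rbind(report, data.frame(row = which(bad_value),
                                       reason = "non_numeric_value"))
  if (any(bad_unit))
    report <- rbind(report, data.frame(row = which(bad_unit),
                                       reason = "unknown_unit"))

  out <- data.frame(
    molecule_alias = trimws(df[[map$molecule_alias]]),
    smiles = trimws(df[[map$smiles]]),
    gene_symbol = toupper(trimws(df[[map$gene_symbol]])),
    kind = "quantitative",
    value_type = trimws(df[[map$value_type]]),
    value = value_nm,
    unit = unit_out,
    relation = trimws(relation),
    source = source,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report[order(report$row), , drop = FALSE]
  out
}

#' Read a qualitative association table
#'
#' Reads a delimited table of curated drug-target links that carry no
#' numeric potency (DrugBank/DGIdb/ChemicalProbes-style exports). Rows with
#' an empty gene symbol are skipped and reported. Duplicate (alias, gene)
#' rows are emitted as-is; consolidation happens in
#' [summarize_associations()].
#'
#' @inheritParams read_quantitative_table
#' @param col_map Named list remapping `molecule_alias`, `smiles`,
#'   `gene_symbol` to the file's column names.
#' @return A data frame of evidence records with `kind = "qualitative"` and
#'   no value fields, in input order, with a `"report"` attribute.
#' @export
read_qualitative_table <- function(path, source, sep = NULL,
                                   col_map = list()) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- .read_table(path, .detect_sep(path, sep))
  map <- .resolve_columns(df, c("molecule_alias", "smiles", "gene_symbol"),
                          col_map, path)
  report <- data.frame(row = integer(), reason = character(),
                       stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    out <- .empty_records()
    attr(out, "report") <- report
    return(out)
  }
  gene <- toupper(trimws(df[[map$gene_symbol]]))
  keep <- !is.na(gene) & nzchar(gene)
  if (any(!keep))
    report <- data.frame(row = which(!keep), reason = "empty_gene")
  out <- data.frame(
    molecule_alias = trimws(df[[map$molecule_alias]]),
    smiles = trimws(df[[map$smiles]]),
    gene_symbol = gene,
    kind = "qualitative",
    value_type = NA_character_,
    value = NA_real_,
    unit = NA_character_,
    relation = "=",
    source = source,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Row-skip report of a table reader
#'
#' @param records A record stream returned by [read_quantitative_table()]
#'   or [read_qualitative_table()].
#' @return Data frame with columns `row` (1-based input row index) and
#'   `reason`.
#' @export
ingest_report <- function(records) {
  attr(records, "report") %||%
    data.frame(row = integer(), reason = character())
}

#' Write a record stream back to a delimited table
#'
#' Inverse of the readers: writing a normalized stream and re-reading it
#' with [read_quantitative_table()] / [read_qualitative_table()] yields an
#' identical stream (values are already in nM, so unit conversion is a
#' no-op on the second pass).
#'
#' @param records Evidence records.
#' @param path Output path; delimiter inferred from extension.
#' @return `path`, invisibly.
#' @export
write_records_table <- function(records, path) {
  out <- records[, setdiff(RECORD_COLS, c("kind", "source")), drop = FALSE]
  out$value <- ifelse(is.na(records$value), NA,
                      sprintf("%.17g", records$value))
  utils::write.table(out, path, sep = .detect_sep(path), quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate evidence records
#'
#' Removes records violating the record invariants and tallies each failure
#' class. Quantitative records must carry a recognized value type, a
#' non-negative value and a unit; qualitative records must carry no value;
#' all records need a non-empty gene symbol. Censored quantitative records
#' (relation other than `"="`) are kept -- they count as evidence -- but
#' are tallied under `censored_relation` because they are excluded from
#' potency means downstream. Validation is idempotent: re-validating the
#' clean stream removes nothing.
#'
#' @param records Evidence records from the table readers (or rbind of
#'   several).
#' @return List with elements `records` (clean stream, input order
#'   preserved) and `report` (named integer vector of per-class counts,
#'   zeros included).
#' @export
validate_records <- function(records) {
  classes <- c("empty_gene", "bad_kind", "missing_value_type",
               "invalid_value_type", "missing_value", "negative_value",
               "missing_unit", "invalid_relation", "qualitative_with_value",
               "censored_relation")
  report <- stats::setNames(integer(length(classes)), classes)
  if (nrow(records) == 0) return(list(records = records, report = report))

  quant <- records$kind == "quantitative"
  qual <- records$kind == "qualitative"
  bad <- rep(FALSE, nrow(records))

  flag <- function(cond, class) {
    cond[is.na(cond)] <- FALSE
    report[[class]] <<- report[[class]] + sum(cond & !bad)
    bad <<- bad | cond
  }
  flag(is.na(records$gene_symbol) | !nzchar(records$gene_symbol),
       "empty_gene")
  flag(!(quant | qual), "bad_kind")
  flag(quant & is.na(records$value_type), "missing_value_type")
  flag(quant & !is.na(records$value_type) &
         !records$value_type %in% VALUE_TYPES, "invalid_value_type")
  flag(quant & is.na(records$value), "missing_value")
  flag(quant & !is.na(records$value) & records$value < 0, "negative_value")
  flag(quant & is.na(records$unit), "missing_unit")
  flag(!records$relation %in% RELATIONS, "invalid_relation")
  flag(qual & !is.na(records$value), "qualitative_with_value")

  # counted but retained
  censored <- quant & !bad & records$relation != "="
  report[["censored_relation"]] <- sum(censored)

  clean <- records[!bad, , drop = FALSE]
  rownames(clean) <- NULL
  attr(clean, "report") <- NULL
  list(records = clean, report = report)
}
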