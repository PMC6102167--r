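# Aggregating evidence per molecule-target pair and scoring it.
#
# Potency harmonization: every quantitative "=" measurement is converted
# to pChEMBL (-log10 molar), the semi-comparable scale that lets IC50, Ki,
# Kd etc. be pooled into one mean per pair. Per-pair scores:
#   mean_pchembl  pooled mean over all per-record pChEMBLs of the pair
#   KSI           pair's mean pChEMBL / sum over all targets of the drug
#   confidence    z-score of the pair's evidence count over all pairs

#' Convert a potency to pChEMBL
#'
#' pChEMBL is the negative log10 of a molar potency (IC50, XC50, EC50,
#' AC50, C50, Ki, Kd or potency): 100 nM corresponds to 7, 1 nM to 9.
#' Values already on the pChEMBL scale (`unit = "pchembl_unitless"`) pass
#' through unchanged.
#'
#' @param value Positive potency value(s).
#' @param unit `"nM"`, `"uM"`, `"M"`, or `"pchembl_unitless"`; recycled.
#' @return pChEMBL value(s).
#' @examples
#' to_pchembl(100, "nM")  # 7
#' @export
to_pchembl <- function(value, unit = "nM") {
  unit <- rep_len(unit, length(value))
  bad_unit <- !unit %in% c("nM", "uM", "M", "pchembl_unitless")
  if (any(bad_unit)) .stopf("unknown unit '%s'", unit[bad_unit][1])
  pass <- unit == "pchembl_unitless"
  if (any(value[!pass] <= 0, na.rm = TRUE))
    .stopf("potency must be positive for pChEMBL conversion")
  molar <- c(nM = 1e-9, uM = 1e-6, M = 1)
  out <- value
  out[!pass] <- -log10(value[!pass] * molar[unit[!pass]])
  out
}

# map each record to its registry internal id (structure first, alias
# fallback); NA when unmapped
.record_ids <- function(records, registry) {
  canon <- .canonicalize(records$smiles)
  ids <- unname(registry$structure_index[canon])
  need <- is.na(ids)
  if (any(need)) {
    key <- tolower(trimws(records$molecule_alias[need]))
    ids[need] <- vapply(key, function(a) {
      hit <- registry$alias_index[[a]]
      if (is.null(hit)) NA_character_ else hit[1]
    }, character(1), USE.NAMES = FALSE)
  }
  ids
}

#' Summarize evidence per molecule-target pair
#'
#' Produces one row per (internal id, gene symbol) with exact evidence
#' counts and harmonized potency means. `mean_pchembl` is the arithmetic
#' mean of per-record pChEMBL values pooled across value types, using only
#' uncensored (`relation == "="`) quantitative records; censored records
#' still count in `n_quantitative`. `mean_by_type` holds per value type
#' the mean potency in nM (pChEMBL-typed records, having no concentration,
#' contribute only to `mean_pchembl`).
#'
#' @param records Validated evidence records.
#' @param registry Registry from [register_molecules()] built from the
#'   same records.
#' @return Data frame of association summaries ordered by internal id,
#'   then gene symbol, with columns `internal_id`, `molecule_name` (first
#'   alias), `gene_symbol`, `mean_pchembl`, `mean_by_type` (list-column of
#'   named numeric vectors), `n_quantitative`, `n_qualitative`. KSI and
#'   confidence are filled in by [known_selectivity_index()] and
#'   [confidence_scores()].
#' @export
summarize_associations <- function(records, registry) {
  ids <- .record_ids(records, registry)
  mapped <- !is.na(ids)
  rec <- records[mapped, , drop = FALSE]
  ids <- ids[mapped]

  key <- paste(ids, rec$gene_symbol, sep = "\r")
  ord <- .radix_sort(unique(key))
  rows <- lapply(ord, function(k) {
    sel <- key == k
    r <- rec[sel, , drop = FALSE]
    id <- ids[sel][1]
    quant <- r$kind == "quantitative"
    usable <- quant & r$relation == "="
    pchembl <- if (any(usable))
      mean(to_pchembl(r$value[usable], r$unit[usable])) else NA_real_
    conc <- usable & r$value_type != "pChEMBL"
    mbt <- if (any(conc))
      vapply(split(r$value[conc], r$value_type[conc]), mean, numeric(1))
    else stats::setNames(numeric(0), character(0))
    entry <- match(id, registry$entries$internal_id)
    data.frame(internal_id = id,
               molecule_name = registry$entries$aliases[[entry]][1],
               gene_symbol = r$gene_symbol[1],
               mean_pchembl = pchembl,
               mean_by_type = I(list(mbt)),
               n_quantitative = sum(quant),
               n_qualitative = sum(!quant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(stringsAsFactors = FALSE)))
  if (is.null(out)) out <- data.frame(
    internal_id = character(), molecule_name = character(),
    gene_symbol = character(), mean_pchembl = numeric(),
    mean_by_type = I(list()), n_quantitative = integer(),
    n_qualitative = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Known selectivity index
#'
#' For each molecule-target pair with a defined mean pChEMBL, the KSI is
#' that mean divided by the sum of mean pChEMBLs over all targets of the
#' same molecule. Values near 1 indicate a known-single-target drug; per
#' molecule the defined KSIs sum to 1. Qualitative-only pairs (no mean
#' pChEMBL) get no KSI.
#'
#' @param summaries Association summaries from [summarize_associations()].
#' @return `summaries` with a `ksi` column added.
#' @export
known_selectivity_index <- function(summaries) {
  tot <- stats::ave(summaries$mean_pchembl, summaries$internal_id,
                    FUN = function(x) sum(x, na.rm = TRUE))
  ksi <- summaries$mean_pchembl / tot
  ksi[!is.na(ksi) & tot <= 0] <- NA_real_
  summaries$ksi <- ksi
  summaries
}

#' Evidence-count confidence scores
#'
#' The confidence of a pair is the z-score of its total evidence count
#' (quantitative + qualitative records) standardized over all pairs in the
#' table: \eqn{c_{ab} = ((n_{ab} + l_{ab}) - \mu_{all}) / \sigma_{all}},
#' with the population standard deviation, so the scores have mean 0 and
#' SD 1 by construction. A larger score indicates more accumulated
#' evidence for the pair. If every pair has the same count the scores are
#' all 0 (with a warning).
#'
#' @param summaries Association summaries.
#' @return List with `summaries` (a `confidence` column added) and
#'   `params` (`mu_all`, `sigma_all` -- recomputable from the table).
#' @export
confidence_scores <- function(summaries) {
  counts <- summaries$n_quantitative + summaries$n_qualitative
  mu <- mean(counts)
  sigma <- sqrt(mean((counts - mu)^2))
  if (nrow(summaries) && sigma == 0) {
    .warnf("all association counts equal; confidence scores set to 0")
    summaries$confidence <- rep(0, nrow(summaries))
  } else {
    summaries$confidence <- (counts - mu) / sigma
  }
  params <- structure(list(mu_all = mu, sigma_all = sigma),
                      class = "confidence_params")
  list(summaries = summaries, params = params)
}

#' @export
print.confidence_params <- function(x, ...) {
  cat(sprintf("<confidence_params: mu_all=%.4g, sigma_all=%.4g>\n",
              x$mu_all, x$sigma_all))
  invisible(x)
}

#' Write an association summary table
#'
#' Emits the per-pair summary as TSV with `mean_pchembl`, `ksi` and
#' `confidence` rounded to 3 decimals for reporting (full precision is
#' kept in the in-memory table).
#'
#' @param summaries Scored association summaries.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  df <- summaries[, c("internal_id", "molecule_name", "gene_symbol",
                      "mean_pchembl", "n_quantitative", "n_qualitative")]
  df$mean_pchembl <- round(df$mean_pchembl, 3)
  if (!is.null(summaries$ksi)) df$ksi <- round(summaries$ksi, 3)
  if (!is.null(summaries$confidence))
    df$confidence <- round(summaries$confidence, 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
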