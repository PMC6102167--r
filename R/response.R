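# Structure-similarity vs drug-response analysis against a screening
# dataset: pick the screening drug most similar to the query, correlate
# its response profile (AUC across cell lines) with every other drug,
# and pair each correlation with that drug's similarity to the original
# query.

#' Read a drug-response matrix with companion structures
#'
#' @param path_auc CSV of AUC values: first column drug labels, remaining
#'   columns cell lines; empty cells are missing (not zero).
#' @param path_structures TSV/CSV with columns `drug`, `smiles`.
#' @return A `response_matrix`: list with `auc` (numeric matrix, drugs x
#'   cell lines), `structures` (named SMILES vector) and
#'   `missing_structure` (drugs present in the matrix but lacking a
#'   structure -- retained, but invisible to similarity operations).
#' @export
read_response_matrix <- function(path_auc, path_structures) {
  df <- utils::read.csv(path_auc, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("response matrix needs >= 1 cell-line column")
  drugs <- as.character(df[[1]])
  if (anyDuplicated(drugs)) .stopf("duplicated drug labels in %s", path_auc)
  auc <- as.matrix(df[, -1, drop = FALSE])
  mode(auc) <- "numeric"
  rownames(auc) <- drugs

  st <- .read_table(path_structures, .detect_sep(path_structures))
  for (nm in c("drug", "smiles"))
    if (!nm %in% names(st))
      .stopf("missing required column '%s' in %s", nm, path_structures)
  extra <- setdiff(st$drug, drugs)
  if (length(extra))
    .stopf("structure table names drugs absent from the matrix: %s",
           paste(extra, collapse = ", "))
  structures <- stats::setNames(st$smiles, st$drug)
  structures <- structures[!is.na(structures) & nzchar(structures)]
  structure(list(auc = auc, structures = structures,
                 missing_structure = setdiff(drugs, names(structures))),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix: %d drugs x %d cell lines, %d without structures>\n",
              nrow(x$auc), ncol(x$auc), length(x$missing_structure)))
  invisible(x)
}

#' Most structurally similar screening drug
#'
#' Finds the screening-set drug whose structure has the highest Tanimoto
#' similarity to the query -- the reference for response correlation. The
#' query need not be in the screening set. Ties break by drug label.
#'
#' @param matrix A `response_matrix`.
#' @param query_smiles Query structure.
#' @param method Fingerprint method (default `"extended"`).
#' @return List with `drug` and `similarity`.
#' @export
select_reference <- function(matrix, query_smiles, method = "extended") {
  stopifnot(inherits(matrix, "response_matrix"))
  if (length(matrix$structures) == 0)
    .stopf("no screening drug has a structure")
  sims <- drug_similarities(matrix, query_smiles, method)
  sims <- sims[!is.na(sims)]
  if (length(sims) == 0) .stopf("no screening structure could be parsed")
  ord <- .radix_sort(names(sims))
  sims <- sims[ord]
  best <- ord[which.max(sims)]
  list(drug = best, similarity = unname(sims[best]))
}

#' Tanimoto similarity of each structured screening drug to a query
#'
#' @inheritParams select_reference
#' @return Named numeric vector (NA where a structure fails to parse).
#' @export
drug_similarities <- function(matrix, query_smiles, method = "extended") {
  qfp <- compute_fingerprint(query_smiles, method)
  vapply(matrix$structures, function(s) {
    fp <- tryCatch(compute_fingerprint(s, method), error = function(e) NULL)
    if (is.null(fp)) NA_real_ else tanimoto(qfp, fp)
  }, numeric(1))
}

#' Spearman correlation of response profiles against a reference drug
#'
#' For every non-reference drug, the Spearman rank correlation between its
#' AUC profile and the reference's, over pairwise-complete cell lines
#' (average ranks for ties; two-sided p via the t approximation). Rows
#' with fewer than `min_shared` complete pairs are marked undefined
#' (NA rho and p).
#'
#' @param matrix A `response_matrix`.
#' @param reference Reference drug label (must be in the matrix).
#' @param min_shared Minimum pairwise-complete overlap (default 3).
#' @return Data frame `drug`, `spearman_rho`, `p_value`, `n_shared`, in
#'   matrix row order, reference excluded.
#' @export
correlate_responses <- function(matrix, reference, min_shared = 3) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (!reference %in% rownames(matrix$auc))
    .stopf("reference drug '%s' not in matrix", reference)
  ref <- matrix$auc[reference, ]
  others <- setdiff(rownames(matrix$auc), reference)
  rows <- lapply(others, function(d) {
    x <- matrix$auc[d, ]
    ok <- !is.na(x) & !is.na(ref)
    n <- sum(ok)
    if (n < min_shared)
      return(data.frame(drug = d, spearman_rho = NA_real_,
                        p_value = NA_real_, n_shared = n,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], ref[ok], method = "spearman", exact = FALSE))
    data.frame(drug = d, spearman_rho = unname(ct$estimate),
               p_value = ct$p.value, n_shared = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate correlation rows with similarity to the original query
#'
#' Similarity is computed against the original query structure, not the
#' reference drug, so the output pairs "how chemically close to my
#' molecule" with "how correlated to its best screening proxy" for every
#' screening drug (the point set of a similarity-vs-correlation plot).
#' Drugs without structures keep their correlation but get NA similarity.
#'
#' @param rows Output of [correlate_responses()].
#' @param matrix The `response_matrix` the rows came from.
#' @param query_smiles The original query structure.
#' @param method Fingerprint method.
#' @return `rows` with a `tanimoto_to_query` column inserted after `drug`.
#' @export
annotate_similarity <- function(rows, matrix, query_smiles,
                                method = "extended") {
  sims <- drug_similarities(matrix, query_smiles, method)
  rows$tanimoto_to_query <- unname(sims[rows$drug])
  rows[, c("drug", "tanimoto_to_query", "spearman_rho", "p_value",
           "n_shared")]
}

#' Full similarity-vs-response analysis for a query structure
#'
#' Convenience wrapper chaining [select_reference()],
#' [correlate_responses()] and [annotate_similarity()].
#'
#' @inheritParams select_reference
#' @param min_shared Minimum pairwise-complete overlap.
#' @return List with `reference` (drug, similarity) and `table` (the
#'   annotated correlation rows).
#' @export
response_correlation <- function(matrix, query_smiles,
                                 method = "extended", min_shared = 3) {
  ref <- select_reference(matrix, query_smiles, method)
  rows <- correlate_responses(matrix, ref$drug, min_shared)
  list(reference = ref,
       table = annotate_similarity(rows, matrix, query_smiles, method))
}
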