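# Local over-representation analysis of target lists against GMT
# gene-set collections (hypergeometric upper tail, BH adjustment).

#' Read a GMT gene-set collection
#'
#' Standard GMT: one tab-separated line per set -- name, description,
#' then member genes. Gene symbols are uppercased; duplicate genes within
#' a line are stored once.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `universe` (union of all member genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      .stopf("GMT parse error at line %d: fewer than 3 fields", i)
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      .stopf("GMT parse error at line %d: empty gene set", i)
    sets[[fields[1]]] <- genes
  }
  structure(list(sets = sets,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d sets, %d genes in universe>\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Target-list enrichment against a gene-set collection
#'
#' One-sided over-representation test per set: the p-value is the
#' hypergeometric upper tail of drawing at least the observed overlap when
#' sampling `list_size` genes from the background without replacement.
#' Benjamini-Hochberg q-values are computed across all sets of the
#' collection. The background defaults to the collection universe;
#' supplying an explicit background restricts sets, targets, and the test
#' to it.
#'
#' @param targets Non-empty character vector of gene symbols (a
#'   molecule's target list).
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param background Optional character vector of background genes.
#' @return Data frame sorted by p-value (ties by set name):
#'   `set_name`, `overlap_count`, `set_size`, `list_size`,
#'   `background_size`, `p_value`, `q_value`, `overlap_genes`
#'   (joined by `|`).
#' @export
enrich_targets <- function(targets, collection, background = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  bg <- if (is.null(background)) collection$universe else
    unique(toupper(trimws(background)))
  targets <- unique(toupper(trimws(targets)))
  targets <- intersect(targets, bg)
  if (length(targets) == 0)
    .stopf("no target genes remain after intersecting with the background")
  n_bg <- length(bg)
  n_list <- length(targets)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], bg)
    ov <- intersect(targets, set)
    k <- length(ov)
    # P(X >= k), X ~ Hypergeom(n_bg, |set|, n_list)
    p <- stats::phyper(k - 1, length(set), n_bg - length(set), n_list,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = length(set),
               list_size = n_list, background_size = n_bg, p_value = p,
               overlap_genes = paste(.radix_sort(ov), collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name, method = "radix"),
             c("set_name", "overlap_count", "set_size", "list_size",
               "background_size", "p_value", "q_value", "overlap_genes")]
  rownames(out) <- NULL
  out
}
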