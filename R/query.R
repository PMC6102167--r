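# Query engine: alias/structure resolution, thresholded similarity
# search, target-based queries and bipartite network construction.

#' Resolve a molecule alias
#'
#' Case-insensitive exact match against all registered aliases.
#'
#' @param db A `drug_target_db`.
#' @param name Free-text alias.
#' @return Character vector of internal ids (empty if unknown).
#' @export
resolve_alias <- function(db, name) {
  hit <- db$registry$alias_index[[tolower(trimws(name))]]
  if (is.null(hit)) character(0) else hit
}

#' Structure-similarity search
#'
#' Standardizes the query structure, fingerprints it, and returns every
#' database molecule whose Tanimoto similarity reaches the threshold --
#' the query molecule itself need not be in the database. A query
#' identical to a registered structure always returns that molecule at
#' similarity 1. Molecules without structures are not searchable.
#'
#' @param db A `drug_target_db` built with fingerprints for `method`.
#' @param query_smiles Query structure (SMILES).
#' @param threshold Minimum Tanimoto similarity in `[0, 1]`; default 0.8.
#'   Lowering it widens the chemical space of the results.
#' @param method Fingerprint method (default `"extended"`).
#' @return Data frame (`internal_id`, `similarity`, `canonical_smiles`)
#'   sorted by similarity descending, ties broken by internal id.
#' @export
similarity_search <- function(db, query_smiles, threshold = 0.8,
                              method = "extended") {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!method %in% db$fingerprint_methods)
    .stopf("database has no '%s' fingerprints; rebuild with fingerprint_methods=c(..., \"%s\")",
           method, method)
  qfp <- compute_fingerprint(query_smiles, method)
  entries <- db$registry$entries
  entries <- entries[!is.na(entries$canonical_smiles), , drop = FALSE]
  sims <- vapply(entries$internal_id, function(id) {
    fp <- db$fingerprints[[paste(id, method, sep = ".")]]
    if (is.null(fp)) return(NA_real_)
    tanimoto(qfp, fp)
  }, numeric(1))
  keep <- !is.na(sims) & sims >= threshold
  out <- data.frame(internal_id = entries$internal_id[keep],
                    similarity = unname(sims[keep]),
                    canonical_smiles = entries$canonical_smiles[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$internal_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Association summaries for a set of molecules
#'
#' @param db A `drug_target_db`.
#' @param internal_ids Internal molecule ids (must exist).
#' @return Summary rows for those molecules sorted by mean pChEMBL
#'   descending, qualitative-only rows (no mean pChEMBL) last.
#' @export
targets_of <- function(db, internal_ids) {
  unknown <- setdiff(internal_ids, db$registry$entries$internal_id)
  if (length(unknown))
    .stopf("unknown internal id(s): %s", paste(unknown, collapse = ", "))
  out <- db$summaries[db$summaries$internal_id %in% internal_ids, ,
                      drop = FALSE]
  out <- out[order(is.na(out$mean_pchembl), -ifelse(is.na(out$mean_pchembl),
                                                    0, out$mean_pchembl),
                   out$internal_id, out$gene_symbol, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Molecules hitting a set of targets
#'
#' `mode = "all"` (the default) returns molecules with evidence against
#' every query gene -- the multi-target intersection query; `mode = "any"`
#' returns the union. Unknown genes contribute an empty set with a
#' warning.
#'
#' @param db A `drug_target_db`.
#' @param genes Non-empty character vector of gene symbols.
#' @param mode `"all"` or `"any"`.
#' @return Sorted character vector of internal ids.
#' @export
molecules_for_targets <- function(db, genes, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (length(genes) == 0) .stopf("empty gene list")
  genes <- toupper(trimws(genes))
  sets <- lapply(genes, function(g) {
    hit <- db$gene_index[[g]]
    if (is.null(hit)) {
      .warnf("gene '%s' not in database", g)
      character(0)
    } else hit
  })
  out <- if (mode == "all") Reduce(intersect, sets) else
    unique(unlist(sets))
  .radix_sort(out)
}

#' Build a bipartite drug-target network
#'
#' Molecule nodes are the given internal ids; target nodes are the union
#' of their targets; one edge per association summary row, annotated with
#' the row's mean pChEMBL and evidence counts. Node ordering is
#' deterministic (molecules then targets, each sorted).
#'
#' @param db A `drug_target_db`.
#' @param internal_ids Internal molecule ids.
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attributes `kind` (`"molecule"`/`"target"`) and `type` (logical,
#'   `TRUE` for targets) and edge attributes `mean_pchembl`,
#'   `n_qualitative`, `n_quantitative`.
#' @export
build_network <- function(db, internal_ids) {
  rows <- targets_of(db, internal_ids)
  mols <- .radix_sort(unique(internal_ids))
  targets <- .radix_sort(unique(rows$gene_symbol))
  vertices <- data.frame(
    name = c(mols, targets),
    kind = c(rep("molecule", length(mols)), rep("target", length(targets))),
    type = c(rep(FALSE, length(mols)), rep(TRUE, length(targets))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = rows$internal_id, to = rows$gene_symbol,
                      mean_pchembl = rows$mean_pchembl,
                      n_qualitative = rows$n_qualitative,
                      n_quantitative = rows$n_quantitative,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a drug-target network
#'
#' @param network Graph from [build_network()].
#' @param format `"graphml"` or `"json"` (node-link).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, format = c("graphml", "json"), path) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    vname <- igraph::V(network)$name
    nodes <- data.frame(id = vname,
                        kind = igraph::V(network)$kind,
                        stringsAsFactors = FALSE)
    ed <- igraph::as_data_frame(network, what = "edges")
    jsonlite::write_json(list(nodes = nodes, links = ed), path,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"json"`.
#' @return An igraph graph with `kind` vertex attributes.
#' @export
read_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(obj$nodes) == 0 || nrow(obj$nodes) == 0) {
      g <- igraph::make_empty_graph(0, directed = FALSE)
    } else {
      g <- igraph::graph_from_data_frame(
        obj$links, directed = FALSE,
        vertices = data.frame(name = obj$nodes$id, kind = obj$nodes$kind,
                              stringsAsFactors = FALSE))
      igraph::V(g)$type <- igraph::V(g)$kind == "target"
    }
  }
  g
}
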