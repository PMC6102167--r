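# one small database shared by the query tests
local_query_db <- function() {
  recs <- rbind(
    rec_quant("imatinib", "Cc1ccc(cc1)C(=O)O", "ABL1", 25),
    rec_quant("imatinib", "Cc1ccc(cc1)C(=O)O", "ABL1", 40,
              value_type = "Kd", source = "srcC"),
    rec_quant("imatinib", "Cc1ccc(cc1)C(=O)O", "KIT", 80),
    rec_qual("imatinib", "Cc1ccc(cc1)C(=O)O", "PDGFRA"),
    rec_quant("tolacid", "OC(=O)c1ccc(C)cc1", "LIMK1", 50),  # same mol
    rec_quant("benzo", "c1ccccc1", "LIMK1", 200),
    rec_quant("benzo", "c1ccccc1", "LIMK2", 400),
    rec_quant("pyrid", "c1ccncc1", "LIMK2", 10),
    rec_quant("etha", "CCO", "ADH1B", 1e6))
  build_drug_target_db(recs)
}

test_that("alias resolution is case-insensitive exact match", {
  db <- local_query_db()
  id <- resolve_alias(db, "imatinib")
  expect_length(id, 1)
  expect_equal(resolve_alias(db, "IMATINIB"), id)
  expect_equal(resolve_alias(db, "tolacid"), id)  # merged by structure
  expect_length(resolve_alias(db, "no-such-drug"), 0)
})

test_that("similarity search equals a brute-force scan and respects the threshold", {
  db <- local_query_db()
  query <- "Cc1ccc(cc1)C(=O)O"
  for (thr in c(0, 0.4, 0.8, 1)) {
    hits <- similarity_search(db, query, threshold = thr)
    # brute force: canonicalize + fingerprint every structured entry
    entries <- db$registry$entries
    entries <- entries[!is.na(entries$canonical_smiles), ]
    qfp <- compute_fingerprint(query, "extended")
    sims <- vapply(entries$canonical_smiles, function(s)
      tanimoto(qfp, compute_fingerprint(s, "extended")), numeric(1))
    want <- entries$internal_id[sims >= thr]
    expect_setequal(hits$internal_id, want)
    expect_true(all(diff(hits$similarity) <= 0))
  }
  exact <- similarity_search(db, query, threshold = 1)
  expect_equal(exact$similarity, 1)
  expect_equal(exact$internal_id, resolve_alias(db, "imatinib"))
  all_hits <- similarity_search(db, query, threshold = 0)
  expect_equal(nrow(all_hits),
               sum(!is.na(db$registry$entries$canonical_smiles)))
  expect_error(similarity_search(db, query, method = "maccs"), "maccs")
})

test_that("targets_of orders by potency with qualitative-only rows last", {
  db <- local_query_db()
  id <- resolve_alias(db, "imatinib")
  rows <- targets_of(db, id)
  expect_equal(rows$gene_symbol, c("ABL1", "LIMK1", "KIT", "PDGFRA"))
  expect_true(is.na(rows$mean_pchembl[4]))
  expect_error(targets_of(db, "MOL99999"), "unknown")
  expect_equal(nrow(targets_of(db, character(0))), 0)
})

test_that("multi-target queries intersect or union per-gene molecule sets", {
  db <- local_query_db()
  both <- molecules_for_targets(db, c("LIMK1", "LIMK2"), mode = "all")
  expect_equal(both, resolve_alias(db, "benzo"))
  either <- molecules_for_targets(db, c("LIMK1", "LIMK2"), mode = "any")
  expect_setequal(either, c(resolve_alias(db, "benzo"),
                            resolve_alias(db, "pyrid"),
                            resolve_alias(db, "imatinib")))
  expect_true(all(both %in% either))
  # single gene == its index; intersection across singles == mode "all"
  expect_equal(molecules_for_targets(db, "LIMK1"),
               db$gene_index[["LIMK1"]])
  expect_equal(both,
               sort(Reduce(intersect,
                           lapply(c("LIMK1", "LIMK2"), function(g)
                             molecules_for_targets(db, g)))))
  expect_warning(none <- molecules_for_targets(db, c("LIMK1", "NOPE")),
                 "NOPE")
  expect_length(none, 0)
  expect_error(molecules_for_targets(db, character(0)), "empty")
})

test_that("networks are bipartite with one edge per summary row", {
  db <- local_query_db()
  ids <- c(resolve_alias(db, "imatinib"), resolve_alias(db, "benzo"))
  g <- build_network(db, ids)
  expect_true(igraph::is_bipartite(g))
  rows <- targets_of(db, ids)
  expect_equal(igraph::ecount(g), nrow(rows))
  expect_equal(igraph::vcount(g),
               length(ids) + length(unique(rows$gene_symbol)))
  kinds <- igraph::V(g)$kind
  ends <- igraph::ends(g, igraph::E(g))
  for (i in seq_len(nrow(ends))) {
    k <- kinds[match(ends[i, ], igraph::V(g)$name)]
    expect_setequal(k, c("molecule", "target"))
  }
  # two molecules sharing a target: that target has degree 2
  one <- build_network(db, resolve_alias(db, "imatinib"))
  expect_equal(igraph::ecount(one), 4)
})

test_that("network export round-trips through graphml and json", {
  db <- local_query_db()
  g <- build_network(db, resolve_alias(db, "imatinib"))
  for (fmt in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_network(g, fmt, path)
    g2 <- read_network(path, fmt)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(sort(igraph::V(g2)$kind), sort(igraph::V(g)$kind))
    expect_true(igraph::isomorphic(g, g2))
  }
  # empty network still serializes
  g0 <- build_network(db, character(0))
  p0 <- tempfile(fileext = ".json")
  export_network(g0, "json", p0)
  expect_equal(igraph::vcount(read_network(p0, "json")), 0)
})

test_that("graphml output is schema-valid xml with node-type attributes", {
  db <- local_query_db()
  g <- build_network(db, resolve_alias(db, "benzo"))
  path <- tempfile(fileext = ".graphml")
  export_network(g, "graphml", path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  expect_length(nodes, igraph::vcount(g))
})
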