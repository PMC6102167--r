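# in-code builders for small evidence-record fixtures

rec_quant <- function(alias, smiles, gene, value, unit = "nM",
                      value_type = "IC50", relation = "=",
                      source = "srcA") {
  data.frame(molecule_alias = alias, smiles = smiles, gene_symbol = gene,
             kind = "quantitative", value_type = value_type,
             value = value, unit = unit, relation = relation,
             source = source, stringsAsFactors = FALSE)
}

rec_qual <- function(alias, smiles, gene, source = "srcB") {
  data.frame(molecule_alias = alias, smiles = smiles, gene_symbol = gene,
             kind = "qualitative", value_type = NA_character_,
             value = NA_real_, unit = NA_character_, relation = "=",
             source = source, stringsAsFactors = FALSE)
}

# write a delimited table and return its path
write_fixture_table <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

# exhaustive hypergeometric upper-tail oracle: P(overlap >= k) by
# enumerating all overlap counts
enum_hyper_tail <- function(k, set_size, bg_size, list_size) {
  js <- k:min(set_size, list_size)
  sum(vapply(js, function(j)
    choose(set_size, j) * choose(bg_size - set_size, list_size - j),
    numeric(1))) / choose(bg_size, list_size)
}

# brute-force z-scores with population SD
brute_z <- function(counts) {
  mu <- sum(counts) / length(counts)
  sd <- sqrt(sum((counts - mu)^2) / length(counts))
  (counts - mu) / sd
}
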