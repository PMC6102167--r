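# Structure standardization, molecule consolidation and fingerprints.
#
# All structure handling goes through OpenBabel (ChemmineOB). Canonical
# SMILES generation sanitizes the input (aromaticity perception, normalized
# atom ordering) and preserves stereochemistry, so identical structures
# written in any atom order -- including different Kekule spellings --
# collapse to one string. Salt counterions are kept: stripping them would
# merge distinctly registered entities.

FP_METHODS <- c("extended", "circular", "maccs")

.canonical_one <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) "")
  # CAN output is "smiles[\t title]\n"
  out <- sub("[\t\n].*$", "", out)
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

#' Standardize a structure string
#'
#' Converts SMILES to a canonical standardized form: the molecule is
#' parsed, aromaticity is perceived, and atoms are renumbered canonically,
#' so any two spellings of the same structure yield the same output.
#' Stereochemistry is preserved (enantiomers remain distinct). The
#' function is idempotent on its own output.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length.
#' @examples
#' standardize_structure("OCC") == standardize_structure("CCO")
#' @export
standardize_structure <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vapply(smiles, .canonical_one, character(1), USE.NAMES = FALSE)
  if (anyNA(out))
    .stopf("cannot parse structure: '%s'", smiles[which(is.na(out))[1]])
  out
}

# vectorized canonicalizer that returns NA for unparseable inputs,
# caching duplicates (used by registry construction and fixtures)
.canonicalize <- function(smiles) {
  smiles <- trimws(smiles)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  uniq <- unique(smiles[ok])
  if (length(uniq))
    canon <- vapply(uniq, .canonical_one, character(1))
  out[ok] <- canon[match(smiles[ok], uniq)]
  out
}

#' Compute a molecular fingerprint
#'
#' Three methods are supported: `"extended"` -- path-based fingerprint
#' with ring features, folded to 1024 bits (the default method for all
#' similarity operations in this package); `"circular"` -- radius-3
#' circular environment fingerprint (FCFP6-analog) folded to 1024 bits and
#' made chirality-aware by hashing stereo descriptors of the canonical
#' SMILES into the same bit space, so enantiomers get distinct
#' fingerprints; `"maccs"` -- the 166 MACCS structural keys.
#'
#' @param smiles A single SMILES string (canonical or not; it is
#'   standardized internally so equal structures always get equal
#'   fingerprints).
#' @param method One of `"extended"`, `"circular"`, `"maccs"`.
#' @return A `dt_fingerprint`: list with `method`, `bits` (sorted set-bit
#'   positions, 1-based) and `length` (bit-vector length).
#' @export
compute_fingerprint <- function(smiles, method = c("extended", "circular",
                                                   "maccs")) {
  method <- match.arg(method)
  stopifnot(is.character(smiles), length(smiles) == 1)
  canon <- standardize_structure(smiles)
  mol <- ChemmineOB::forEachMol("SMILES", canon, identity)
  fp <- switch(method,
    extended = {
      v <- ChemmineOB::fingerprint_OB(mol, "FP2")
      list(bits = which(v != 0), length = length(v))
    },
    circular = {
      v <- ChemmineOB::fingerprint_OB(mol, "ECFP6")
      folded <- unique(((which(v != 0) - 1L) %% 1024L) + 1L)
      list(bits = c(folded, .stereo_bits(canon, 1024L)), length = 1024L)
    },
    maccs = {
      v <- ChemmineOB::fingerprint_OB(mol, "MACCS")
      list(bits = which(v[seq_len(166)] != 0), length = 166L)
    })
  structure(list(method = method,
                 bits = sort(unique(as.integer(fp$bits))),
                 length = as.integer(fp$length)),
            class = "dt_fingerprint")
}

# one extra bit per stereo token (@, @@, /, \) of the canonical SMILES,
# keyed by token and occurrence index so enantiomers and cis/trans
# isomers differ
.stereo_bits <- function(canon, nbits) {
  toks <- regmatches(canon, gregexpr("@@|@|/|\\\\", canon))[[1]]
  if (!length(toks)) return(integer())
  vapply(seq_along(toks),
         function(k) .hash_bit(paste0("stereo:", k, ":", toks[k]), nbits),
         integer(1))
}

#' @export
print.dt_fingerprint <- function(x, ...) {
  cat(sprintf("<%s fingerprint: %d/%d bits set>\n",
              x$method, length(x$bits), x$length))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over set-bit positions. Symmetric, 1 for
#' identical non-empty bit sets, and defined as 0 (with a warning) when
#' both fingerprints are empty.
#'
#' @param fp_a,fp_b `dt_fingerprint` objects of the same method.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (!inherits(fp_a, "dt_fingerprint") || !inherits(fp_b, "dt_fingerprint"))
    .stopf("tanimoto() expects dt_fingerprint objects")
  if (fp_a$method != fp_b$method)
    .stopf("fingerprint method mismatch: '%s' vs '%s'",
           fp_a$method, fp_b$method)
  n_union <- length(union(fp_a$bits, fp_b$bits))
  if (n_union == 0) {
    .warnf("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(fp_a$bits, fp_b$bits)) / n_union
}

#' Consolidate records into a molecule registry
#'
#' Standardizes every distinct structure in the record stream and assigns
#' one internal identifier per distinct canonical structure, so the same
#' molecule reported under different aliases or by different sources gets
#' a single entry with the union of its aliases and sources. Identifiers
#' are deterministic: entries are ordered by canonical SMILES (C locale)
#' and numbered `MOL00001`, `MOL00002`, ... so the registry is a pure
#' function of the multiset of input records.
#'
#' Records without a structure are retained for alias-based lookup: when
#' their alias already belongs to a structured entry they are merged into
#' it, otherwise they get their own structureless entry (numbered after
#' the structured ones, ordered by alias). Records whose structure fails
#' to parse are skipped and reported in attribute `"skipped"`.
#'
#' @param records Validated evidence records.
#' @return A `mol_registry`: list with `entries` (data frame of
#'   `internal_id`, `canonical_smiles`, list-columns `aliases`, `sources`),
#'   `alias_index` (lowercased alias -> internal ids) and
#'   `structure_index` (canonical SMILES -> internal id).
#' @export
register_molecules <- function(records) {
  canon <- .canonicalize(records$smiles)
  has_struct_input <- !is.na(records$smiles) & nzchar(trimws(records$smiles))
  unparseable <- has_struct_input & is.na(canon)

  structured <- !is.na(canon)
  uniq_canon <- .radix_sort(unique(canon[structured]))
  ids <- sprintf("MOL%05d", seq_along(uniq_canon))
  names(ids) <- uniq_canon

  aliases <- lapply(uniq_canon, function(cs)
    .radix_sort(unique(records$molecule_alias[structured & canon == cs])))
  sources <- lapply(uniq_canon, function(cs)
    .radix_sort(unique(records$source[structured & canon == cs])))

  entries <- data.frame(internal_id = unname(ids),
                        canonical_smiles = uniq_canon,
                        stringsAsFactors = FALSE)
  entries$aliases <- aliases
  entries$sources <- sources
  rownames(entries) <- NULL

  # alias -> ids over structured entries, for merging structureless records
  alias_of <- function(entr) {
    idx <- list()
    for (i in seq_len(nrow(entr))) {
      for (a in tolower(entr$aliases[[i]])) {
        idx[[a]] <- .radix_sort(unique(c(idx[[a]], entr$internal_id[i])))
      }
    }
    idx
  }
  alias_index <- alias_of(entries)

  # structureless (but parse-clean) records: merge by alias or add entries
  free <- records[!structured & !unparseable, , drop = FALSE]
  if (nrow(free)) {
    key <- tolower(free$molecule_alias)
    for (a in .radix_sort(unique(key))) {
      rows <- free[key == a, , drop = FALSE]
      hit <- alias_index[[a]]
      if (!is.null(hit)) {
        i <- match(hit[1], entries$internal_id)
        entries$aliases[[i]] <- .radix_sort(unique(c(
          entries$aliases[[i]], rows$molecule_alias)))
        entries$sources[[i]] <- .radix_sort(unique(c(
          entries$sources[[i]], rows$source)))
      } else {
        entries <- rbind(entries, data.frame(
          internal_id = NA_character_, canonical_smiles = NA_character_,
          aliases = I(list(.radix_sort(unique(rows$molecule_alias)))),
          sources = I(list(.radix_sort(unique(rows$source)))),
          stringsAsFactors = FALSE))
      }
    }
    fresh <- is.na(entries$internal_id)
    entries$internal_id[fresh] <-
      sprintf("MOL%05d", length(uniq_canon) + seq_len(sum(fresh)))
  }

  structure_index <- stats::setNames(
    entries$internal_id[!is.na(entries$canonical_smiles)],
    entries$canonical_smiles[!is.na(entries$canonical_smiles)])

  reg <- structure(list(entries = entries,
                        alias_index = alias_of(entries),
                        structure_index = structure_index),
                   class = "mol_registry")
  skipped <- unique(trimws(records$smiles[unparseable]))
  attr(reg, "skipped") <- data.frame(
    smiles = skipped,
    reason = rep("unparseable_structure", length(skipped)),
    stringsAsFactors = FALSE)
  reg
}

#' @export
print.mol_registry <- function(x, ...) {
  n_struct <- sum(!is.na(x$entries$canonical_smiles))
  cat(sprintf("<mol_registry: %d molecules (%d with structures), %d aliases>\n",
              nrow(x$entries), n_struct, length(x$alias_index)))
  invisible(x)
}

#' Serialize a molecule registry
#'
#' Writes `entries` as TSV (aliases and sources joined by `|`) and the
#' alias index as JSON next to it.
#'
#' @param registry A `mol_registry`.
#' @param path Output TSV path; the alias index goes to
#'   `<path>.aliases.json`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  df <- data.frame(
    internal_id = registry$entries$internal_id,
    canonical_smiles = registry$entries$canonical_smiles,
    aliases = vapply(registry$entries$aliases, paste, "", collapse = "|"),
    sources = vapply(registry$entries$sources, paste, "", collapse = "|"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  jsonlite::write_json(registry$alias_index,
                       paste0(path, ".aliases.json"))
  invisible(path)
}
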