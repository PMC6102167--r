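# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# locale-independent character sort (C collation) so ids are reproducible
.radix_sort <- function(x) sort(x, method = "radix")

.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# small deterministic string hash onto 1..nbits (for stereo-descriptor bits)
.hash_bit <- function(s, nbits) {
  h <- 0L
  for (i in utf8ToInt(s)) h <- (h * 31L + i) %% 1048573L
  (h %% as.integer(nbits)) + 1L
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.read_table <- function(path, sep) {
  utils::read.table(path, sep = sep, header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
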