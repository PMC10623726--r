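# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# Atomic write: data lands in a sibling temp file, then a rename.
#' @keywords internal
#' @noRd
write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  if (!file.rename(tmp, path)) {
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

# Gene matching is case-insensitive; keys are upper-cased internally and
# rendered species-aware on output (all-caps human, capitalised mouse).
#' @keywords internal
#' @noRd
gene_key <- function(x) toupper(trimws(x))

#' @keywords internal
#' @noRd
gene_display <- function(keys, species = "human") {
  if (identical(species, "mouse")) {
    paste0(substr(keys, 1, 1), tolower(substring(keys, 2)))
  } else {
    keys
  }
}

#' @keywords internal
#' @noRd
split_genes <- function(x) {
  g <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  g <- g[nzchar(g)]
  g[!duplicated(gene_key(g))]
}

# Restore RNG state on exit so seeded internals don't disturb the caller.
#' @keywords internal
#' @noRd
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
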