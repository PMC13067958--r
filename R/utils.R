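# Shared helpers: TSV conventions, seed derivation, small checks.

#' Read a tab-separated table with the package's conventions
#'
#' UTF-8, single header row, no quoting, no comment character. Used for
#' panels, metadata and all intermediate tables so regex patterns and
#' free-text annotation fields survive round-trips verbatim.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with character columns left as-is.
#' @export
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", quote = "", comment.char = "",
             stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Write a tab-separated table with the package's conventions
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_strict <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive per-stage seeds from one top-level seed
#'
#' One user-facing seed deterministically fans out to named per-stage seeds
#' so stages can be re-run or skipped without perturbing each other's
#' random streams.
#'
#' @param seed Integer scalar.
#' @param stages Character vector of stage names.
#' @return Named integer vector of seeds, all in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

# stopifnot with a friendlier message
.assert <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)

# %||% : first non-NULL
`%||%` <- function(a, b) if (is.null(a)) b else a

# case-insensitive perl regex match over a character vector; NA -> FALSE
.regex_hit <- function(pattern, x) {
  out <- grepl(pattern, x, ignore.case = TRUE, perl = TRUE)
  out & !is.na(x)
}

# path to a packaged extdata file
.pkg_file <- function(...) {
  system.file("extdata", ..., package = "probioscreen", mustWork = TRUE)
}
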