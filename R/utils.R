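#' @keywords internal
#' @importFrom igraph graph_from_data_frame components
#' @importFrom jsonlite write_json
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges seqnames strand start end
#' @importFrom stats median qt sd phyper p.adjust runif rnbinom rlnorm setNames ave
#' @importFrom utils read.delim write.table modifyList head combn packageVersion
"_PACKAGE"

## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_format(...)
  invisible(TRUE)
}

## required columns check for tabular readers; names the first missing column
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_format("%s: missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

## lower median: for even n returns the lower of the two central values
lower_median <- function(x) {
  n <- length(x)
  assert_that(n >= 1L, "lower_median: empty input")
  sort(x)[floor((n + 1L) / 2L)]
}

## deterministic TSV writer (no quoting, no row names); doubles are
## serialized with 17 significant digits so numeric columns round-trip
## bit-identically through the readers
write_tsv <- function(df, path) {
  for (col in names(df)) {
    x <- df[[col]]
    if (is.double(x)) {
      df[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
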