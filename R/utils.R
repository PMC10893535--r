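#' @keywords internal
"_PACKAGE"

# shared internal helpers: logging, alphabet checks, TSV writing

.cm_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

RNA_BASES <- c("A", "C", "G", "U")

.check_rna <- function(x, allow_n = TRUE, what = "sequence") {
  allowed <- if (allow_n) c(RNA_BASES, "N") else RNA_BASES
  bad <- setdiff(unique(strsplit(x, "")[[1]]), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains characters outside {%s}: %s",
                 what, paste(allowed, collapse = ","),
                 paste(bad, collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

# T<->U normalisation; mapping and scanning treat the two as equivalent
.to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
.to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Write a data frame as tab-separated values with a header line
#'
#' All tabular pipeline outputs go through this helper so that every TSV
#' has the same conventions (header, no quoting, no row names).
#'
#' @param df a data.frame
#' @param path output file path
#' @return the path, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# derive a child RNG seed from a user seed and a stream index, staying
# within 32-bit integer range
.child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483629)
}
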