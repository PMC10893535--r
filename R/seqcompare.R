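# seqcompare: pairwise global protein alignment with EMBOSS-style percent
# identity and similarity.
#
# Conventions follow the community defaults for pairwise protein alignment:
# Needleman-Wunsch with affine gaps (BLOSUM62, gap open 10, extend 0.5);
# identity = identical columns / alignment length (gap columns included in
# the denominator); similarity = columns whose substitution score is
# positive, identities included, again over the full alignment length.

AA_ALPHABET20 <- "ACDEFGHIKLMNPQRSTVWY"

.get_submat <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Global pairwise protein alignment
#'
#' @param seq_a,seq_b protein sequences over the 20 standard amino acids
#' @param matrix substitution matrix name shipped with Biostrings (default
#'   "BLOSUM62") or a numeric matrix
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5)
#' @return list of class `pairwise_alignment` with aligned_a, aligned_b,
#'   score, identity_pct, similarity_pct, alignment_length
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  for (s in c(seq_a, seq_b)) {
    if (grepl(sprintf("[^%s]", AA_ALPHABET20), s)) {
      stop("sequence contains non-amino-acid characters", call. = FALSE)
    }
  }
  mat <- .get_submat(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  alen <- length(ca)
  ident <- sum(ca == cb & ca != "-")
  nongap <- ca != "-" & cb != "-"
  pos <- sum(mat[cbind(ca[nongap], cb[nongap])] > 0)
  structure(list(aligned_a = a, aligned_b = b,
                 score = Biostrings::score(pa),
                 identity_pct = 100 * ident / alen,
                 similarity_pct = 100 * pos / alen,
                 alignment_length = alen),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("# Length: %d\n# Identity: %.1f%%\n# Similarity: %.1f%%\n# Score: %.1f\n",
              x$alignment_length, x$identity_pct, x$similarity_pct,
              x$score))
  for (i in seq(1L, x$alignment_length, by = width)) {
    j <- min(i + width - 1L, x$alignment_length)
    ca <- substr(x$aligned_a, i, j)
    cb <- substr(x$aligned_b, i, j)
    mid <- paste(ifelse(strsplit(ca, "")[[1L]] == strsplit(cb, "")[[1L]],
                        "|", " "), collapse = "")
    cat(ca, "\n", mid, "\n", cb, "\n\n", sep = "")
  }
  invisible(x)
}

#' One-line alignment summary
#'
#' @param x a `pairwise_alignment`
#' @param name_a,name_b sequence labels
#' @return a one-row data.frame (seq_a, seq_b, alignment_length, score,
#'   identity_pct, similarity_pct)
#' @export
alignment_summary <- function(x, name_a = "a", name_b = "b") {
  data.frame(seq_a = name_a, seq_b = name_b,
             alignment_length = x$alignment_length, score = x$score,
             identity_pct = x$identity_pct,
             similarity_pct = x$similarity_pct,
             stringsAsFactors = FALSE)
}
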