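# genome_scan: motif prevalence over coding sequences with a
# base-composition null.
#
# The expectation model is a zeroth-order composition null declared by this
# package (the underlying statistical treatment is not standardised in the
# field): under the CDS's own base frequencies f, a motif of length m
# matches a given window with probability p = prod_j f(motif_j), the
# expected count over L - m + 1 windows is E = (L - m + 1) p, and the
# enrichment p-value is the Poisson upper tail P(X >= observed | lambda = E).

.parse_locus_tag <- function(header) {
  m <- regmatches(header, regexec("\\[locus_tag=([^]]+)\\]", header))[[1L]]
  if (length(m) == 2L) m[2L] else strsplit(trimws(header), "\\s+")[[1L]][1L]
}

#' Count motif occurrences in coding sequences
#'
#' Scans the sense strand only; overlapping matches are counted.  T and U
#' are treated as equivalent.  Records shorter than the motif simply count
#' zero.
#'
#' @param cds named character vector of CDS sequences (DNA or RNA), e.g.
#'   from [read_fasta()]; locus tags are parsed from NCBI-style
#'   `[locus_tag=...]` header fields when present, else the first header
#'   token
#' @param motif motif string (RNA or DNA)
#' @return data.frame (locus_tag, cds_length, occurrence_count, product)
#' @export
scan_cds <- function(cds, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  motif_dna <- .to_dna(motif)
  if (length(cds) == 0L) {
    return(data.frame(locus_tag = character(0), cds_length = integer(0),
                      occurrence_count = integer(0), product = character(0),
                      stringsAsFactors = FALSE))
  }
  headers <- names(cds)
  if (is.null(headers)) headers <- sprintf("cds_%d", seq_along(cds))
  seqs <- Biostrings::DNAStringSet(.to_dna(cds))
  counts <- Biostrings::vcountPattern(motif_dna, seqs)
  prod <- vapply(headers, function(h) {
    m <- regmatches(h, regexec("\\[product=([^]]+)\\]", h))[[1L]]
    if (length(m) == 2L) m[2L] else ""
  }, character(1), USE.NAMES = FALSE)
  data.frame(locus_tag = vapply(headers, .parse_locus_tag, character(1),
                                USE.NAMES = FALSE),
             cds_length = nchar(cds), occurrence_count = counts,
             product = prod, stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected motif count and Poisson enrichment p-value for one CDS
#'
#' @param sequence the CDS sequence (DNA or RNA)
#' @param motif motif string
#' @param observed observed occurrence count; computed by scanning when
#'   omitted
#' @param base_freqs optional length-4 named (A,C,G,U) frequency vector to
#'   use instead of the CDS's own composition (e.g. genome-wide
#'   frequencies)
#' @return list with elements expected_count and p_value
#' @export
expected_counts <- function(sequence, motif, observed = NULL,
                            base_freqs = NULL) {
  L <- nchar(sequence)
  if (L == 0L) stop("zero-length CDS", call. = FALSE)
  motif <- .to_rna(motif)
  m <- nchar(motif)
  rna <- .to_rna(sequence)
  if (is.null(base_freqs)) {
    chars <- strsplit(rna, "")[[1L]]
    tot <- sum(chars %in% RNA_BASES)
    base_freqs <- vapply(RNA_BASES, function(b) sum(chars == b) / tot,
                         numeric(1))
  }
  names(base_freqs) <- RNA_BASES
  p_match <- prod(base_freqs[strsplit(motif, "")[[1L]]])
  expected <- max(L - m + 1L, 0L) * p_match
  if (is.null(observed)) {
    observed <- scan_cds(stats::setNames(rna, "x"), motif)$occurrence_count
  }
  p <- if (observed == 0L) 1 else
    stats::ppois(observed - 1L, lambda = expected, lower.tail = FALSE)
  list(expected_count = unname(expected), p_value = unname(p))
}

#' Scan CDSs and attach the composition-null statistics
#'
#' @param cds named character vector of CDS sequences
#' @param motif motif string
#' @param genome_wide use pooled base frequencies across all CDSs for the
#'   null instead of each CDS's own composition
#' @param adjust apply Benjamini-Hochberg adjustment to the Poisson
#'   p-values (off by default; the headline output is the counts)
#' @return data.frame (locus_tag, cds_length, occurrence_count,
#'   expected_count, p_value[, p_adj], product)
#' @export
gene_hits <- function(cds, motif, genome_wide = FALSE, adjust = FALSE) {
  hits <- scan_cds(cds, motif)
  if (nrow(hits) == 0L) return(hits)
  bf <- NULL
  if (genome_wide) {
    pool <- paste(.to_rna(cds), collapse = "")
    chars <- strsplit(pool, "")[[1L]]
    tot <- sum(chars %in% RNA_BASES)
    bf <- vapply(RNA_BASES, function(b) sum(chars == b) / tot, numeric(1))
  }
  stat <- mapply(function(s, obs) {
    e <- expected_counts(s, motif, observed = obs, base_freqs = bf)
    c(e$expected_count, e$p_value)
  }, cds, hits$occurrence_count)
  hits$expected_count <- stat[1L, ]
  hits$p_value <- stat[2L, ]
  if (adjust) hits$p_adj <- stats::p.adjust(hits$p_value, method = "BH")
  hits[c(setdiff(names(hits), "product"), "product")]
}

#' Group gene hits by occurrence count
#'
#' @param hits data.frame from [scan_cds()] or [gene_hits()]
#' @return list with `genes` (hits sorted by occurrence count descending,
#'   then locus tag) and `summary` (data.frame occurrence_count, n_genes,
#'   descending)
#' @export
tabulate_hits <- function(hits) {
  genes <- hits[order(-hits$occurrence_count, hits$locus_tag), ,
                drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(hits) == 0L) {
    return(list(genes = genes,
                summary = data.frame(occurrence_count = integer(0),
                                     n_genes = integer(0))))
  }
  tab <- table(hits$occurrence_count)
  summary <- data.frame(occurrence_count = as.integer(names(tab)),
                        n_genes = as.integer(tab))
  summary <- summary[order(-summary$occurrence_count), , drop = FALSE]
  rownames(summary) <- NULL
  list(genes = genes, summary = summary)
}
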