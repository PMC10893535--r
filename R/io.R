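# core_io: FASTA/FASTQ/config reading and writing, shared sequence types.
#
# Sequence containers are deliberately plain: substrates are named character
# vectors (names = ids, values = RNA strings), reads are data.frames with
# columns id/sequence/quality.  Coordinates are 1-based and fully closed
# throughout the package, on the sense strand only.

#' Default 45-nt barcode sequence
#'
#' A fixed 45-mer RNA used as the 5' ligation barcode in simulations and as
#' the default for barcode extraction.  It contains no occurrence of the
#' UACAUA motif (nor of the shorter UACAU), no repeated 8-mer and no
#' homopolymer of length four, so a read prefix matching it is very unlikely
#' to arise from substrate sequence.
#'
#' @format a length-1 character vector of 45 RNA bases
#' @export
DEFAULT_BARCODE <- "GUGACUGAUUGAUACAGGUCAUCGGUCCAUCGGCUGCUUAAUGGC"

#' Construct a substrate object
#'
#' A substrate is an identified single-stranded RNA reference sequence,
#' optionally annotated with the 1-based start positions of planted motif
#' occurrences (used only by test oracles, never by the calling pipeline).
#'
#' @param id substrate identifier
#' @param sequence RNA string over A,C,G,U (N allowed)
#' @param planted_sites optional integer vector of 1-based motif start
#'   positions
#' @param motif_length motif length used to validate `planted_sites`
#' @return an object of class `substrate`
#' @export
substrate <- function(id, sequence, planted_sites = integer(0),
                      motif_length = 6L) {
  stopifnot(is.character(id), length(id) == 1L, nchar(sequence) >= 1L)
  sequence <- .to_rna(sequence)
  .check_rna(sequence, allow_n = TRUE, what = paste0("substrate ", id))
  planted_sites <- as.integer(planted_sites)
  if (length(planted_sites) > 0L) {
    if (any(planted_sites < 1L) ||
        any(planted_sites > nchar(sequence) - motif_length + 1L)) {
      stop("planted_sites out of range for substrate ", id, call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence,
                 planted_sites = planted_sites),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("<substrate %s: %d nt, %d planted site(s)>\n",
              x$id, nchar(x$sequence), length(x$planted_sites)))
  invisible(x)
}

# extract the plain named-character view used by mapping and windowing
.substrate_seqs <- function(substrates) {
  if (is.character(substrates)) {
    if (is.null(names(substrates))) stop("substrates must be named")
    return(substrates)
  }
  if (inherits(substrates, "substrate")) substrates <- list(substrates)
  stats::setNames(vapply(substrates, function(s) s$sequence, character(1)),
                  vapply(substrates, function(s) s$id, character(1)))
}

#' Read a FASTA file
#'
#' @param path FASTA file path
#' @param alphabet one of "RNA", "DNA", "protein".  Sequences are
#'   uppercased; for RNA, T is transliterated to U (and the reverse for
#'   DNA).  RNA/DNA sequences may contain N; other ambiguity codes are
#'   rejected.  Protein sequences must use the 20 standard amino acids.
#' @return a named character vector of sequences, in file order
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    stop(sprintf("FASTA format error at line 1 of %s: file is empty", path),
         call. = FALSE)
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop(sprintf("FASTA format error at line %d of %s: expected '>' header",
                 nonempty[1], path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(set))
  ids <- names(set)
  seqs <- switch(alphabet,
                 RNA = chartr("T", "U", seqs),
                 DNA = chartr("U", "T", seqs),
                 protein = seqs)
  allowed <- switch(alphabet,
                    RNA = "ACGUN", DNA = "ACGTN",
                    protein = "ACDEFGHIKLMNPQRSTVWY")
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    stop(sprintf("record '%s' contains characters outside the %s alphabet",
                 ids[which(bad)[1]], alphabet), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (names become headers)
#' @param path output path
#' @param width line-wrap width (default 60 columns)
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ (Sanger/Phred+33) file path
#' @return a data.frame with columns id, sequence, quality
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n_lines <- length(lines)
  if (n_lines %% 4L != 0L) {
    stop(sprintf("FASTQ format error in %s: %d lines is not a multiple of 4 (truncated record?)",
                 path, n_lines), call. = FALSE)
  }
  # validate seq/qual lengths on the raw lines: the C-level parser reads
  # past a short quality string, returning nondeterministic bytes
  if (n_lines > 0L) {
    seq_len_b <- nchar(lines[seq(2L, n_lines, by = 4L)], type = "bytes")
    qual_len_b <- nchar(lines[seq(4L, n_lines, by = 4L)], type = "bytes")
    bad <- which(seq_len_b != qual_len_b)
    if (length(bad) > 0L) {
      stop("FASTQ format error in ", path,
           ": sequence/quality length mismatch in record ", bad[1L],
           call. = FALSE)
    }
  }
  parsed <- tryCatch({
    set <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(ids = names(set), seqs = toupper(as.character(set)),
         quals = as.character(S4Vectors::mcols(set)$qualities))
  }, error = function(e) stop("FASTQ format error in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  data.frame(id = parsed$ids, sequence = parsed$seqs,
             quality = parsed$quals, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with columns id, sequence and (optionally)
#'   quality; missing qualities are written as maximal Phred 'I'
#' @param path output path
#' @return the path, invisibly
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  qual <- reads$quality
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  if (any(nchar(qual) != nchar(reads$sequence))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  set <- Biostrings::BStringSet(stats::setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable the pipeline exposes, with the study defaults:
#' the ten highest-RCI sites are analysed inside 11-base windows, fragments
#' shorter than 200 nt are excluded, and cleavage 5' ends carry a 45-nt
#' barcode.
#'
#' @param K number of top-RCI sites to call (default 10)
#' @param window_w odd window width centred on each site (default 11)
#' @param barcode 5' ligation barcode (default [DEFAULT_BARCODE])
#' @param min_fragment_len size-selection threshold in nt (default 200)
#' @param rng_seed integer seed for stochastic stages
#' @param max_barcode_mismatches substitutions tolerated when matching the
#'   barcode prefix (default 1)
#' @param max_mismatches substitutions tolerated over a full mapped read
#'   (default 3)
#' @param min_match_len reads shorter than this after barcode removal are
#'   discarded (default 30)
#' @param min_depth minimum coverage at a position before it is eligible
#'   for top-site ranking; the raw depth ratio is unstable at depth 0/1
#'   (default 5)
#' @param core_threshold information content (bits) a window offset needs
#'   to join the consensus core (default 1.0; with only ten windows the
#'   information content of a nonconserved column has substantial sampling
#'   mass above 0.5 bits, while motif columns sit near 2 bits)
#' @param low_consistency_threshold majority-base frequency below which a
#'   consensus position is flagged low-consistency (default 0.9)
#' @param fold_threshold endpoint fold-change over the no-enzyme control
#'   calling a FRET probe cleaved (default 2)
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(K = 10L, window_w = 11L,
                            barcode = DEFAULT_BARCODE,
                            min_fragment_len = 200L, rng_seed = 1L,
                            max_barcode_mismatches = 1L,
                            max_mismatches = 3L, min_match_len = 30L,
                            min_depth = 5L, core_threshold = 1.0,
                            low_consistency_threshold = 0.9,
                            fold_threshold = 2) {
  K <- as.integer(K); window_w <- as.integer(window_w)
  min_fragment_len <- as.integer(min_fragment_len)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (window_w < 3L || window_w %% 2L == 0L) {
    stop("window_w must be odd and >= 3", call. = FALSE)
  }
  if (min_fragment_len < 0L) stop("min_fragment_len must be >= 0",
                                  call. = FALSE)
  barcode <- .to_rna(barcode)
  .check_rna(barcode, allow_n = TRUE, what = "barcode")
  structure(list(K = K, window_w = window_w, barcode = barcode,
                 min_fragment_len = min_fragment_len,
                 rng_seed = as.integer(rng_seed),
                 max_barcode_mismatches = as.integer(max_barcode_mismatches),
                 max_mismatches = as.integer(max_mismatches),
                 min_match_len = as.integer(min_match_len),
                 min_depth = as.integer(min_depth),
                 core_threshold = core_threshold,
                 low_consistency_threshold = low_consistency_threshold,
                 fold_threshold = fold_threshold),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Missing keys take the package defaults; unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML key/value file; an empty file yields all defaults
#' @return a `pipeline_config`
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}
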