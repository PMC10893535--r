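# motifcall: windows around called sites -> position frequency matrix ->
# information content -> consensus core and low-consistency flags.
#
# Window offsets run -(w-1)/2 ... +(w-1)/2 with the called site at offset 0;
# the cleavage position lies between offsets -1 and 0.

#' Extract sequence windows centred on called sites
#'
#' @param sites data.frame from [top_sites()] (substrate_id, position)
#' @param substrates list of [substrate] objects or named character vector
#' @param w odd window width
#' @return data.frame with columns substrate_id, position, sequence; bases
#'   falling outside the substrate are N
#' @export
windows <- function(sites, substrates, w = 11L) {
  if (w < 3L || w %% 2L == 0L) stop("w must be odd and >= 3", call. = FALSE)
  seqs <- .substrate_seqs(substrates)
  unknown <- setdiff(unique(sites$substrate_id), names(seqs))
  if (length(unknown) > 0L) {
    stop("sites reference unknown substrate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  half <- (w - 1L) %/% 2L
  win <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$substrate_id[i]]]
    L <- nchar(s)
    lo <- sites$position[i] - half
    hi <- sites$position[i] + half
    core <- substr(s, max(lo, 1L), min(hi, L))
    win[i] <- paste0(strrep("N", max(0L, 1L - lo)), core,
                     strrep("N", max(0L, hi - L)))
  }
  data.frame(substrate_id = sites$substrate_id, position = sites$position,
             sequence = win, stringsAsFactors = FALSE)
}

#' Position frequency matrix over aligned windows
#'
#' Counts exclude N.  Columns whose every base is N carry zero counts and
#' are flagged unusable.
#'
#' @param wins data.frame from [windows()] (or character vector of
#'   equal-length window sequences)
#' @return list of class `pfm` with counts (4 x w, rows A,C,G,U), freqs,
#'   n_windows, offsets and a logical `usable` per column
#' @export
pfm <- function(wins) {
  seqs <- if (is.data.frame(wins)) wins$sequence else wins
  if (length(seqs) == 0L) stop("no windows", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("windows have unequal lengths", call. = FALSE)
  half <- (w - 1L) %/% 2L
  mat <- do.call(rbind, strsplit(.to_rna(seqs), ""))
  counts <- vapply(seq_len(w), function(j) {
    col <- mat[, j]
    vapply(RNA_BASES, function(b) sum(col == b), integer(1))
  }, integer(4))
  rownames(counts) <- RNA_BASES
  offsets <- seq_len(w) - half - 1L
  colnames(counts) <- offsets
  tot <- colSums(counts)
  usable <- tot > 0L
  if (!any(usable)) stop("zero usable windows", call. = FALSE)
  freqs <- sweep(counts, 2L, pmax(tot, 1L), "/")
  freqs[, !usable] <- 0
  structure(list(counts = counts, freqs = freqs,
                 n_windows = length(seqs), offsets = offsets,
                 usable = usable),
            class = "pfm")
}

#' Per-offset information content in bits
#'
#' bits(j) = 2 + sum_b f_bj log2 f_bj with 0 log 0 = 0; uniform columns
#' score 0, invariant columns 2.  No small-sample correction is applied.
#' Unusable (all-N) columns return NA.
#'
#' @param x a `pfm`
#' @return numeric vector of bits named by offset
#' @export
info_content <- function(x) {
  stopifnot(inherits(x, "pfm"))
  bits <- apply(x$freqs, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  bits[!x$usable] <- NA_real_
  bits
}

#' Motif object
#'
#' Constructor for a called (or externally specified) motif: a consensus
#' core with its cleavage annotation and low-consistency position flags.
#'
#' @param consensus consensus RNA string over the core span
#' @param low_consistency_positions 1-based indices within the consensus
#'   whose majority-base frequency fell below threshold
#' @param cut_after cleavage falls between consensus positions `cut_after`
#'   and `cut_after + 1` (0 = before the consensus)
#' @param core_span offset interval (length-2 integer) of the core within
#'   the window
#' @param info_content per-offset bits of the underlying PFM
#' @return list of class `motif`
#' @export
motif <- function(consensus, low_consistency_positions = integer(0),
                  cut_after = 1L, core_span = NULL, info_content = NULL) {
  consensus <- .to_rna(consensus)
  .check_rna(consensus, allow_n = FALSE, what = "consensus")
  lc <- as.integer(low_consistency_positions)
  if (any(lc < 1L | lc > nchar(consensus))) {
    stop("low-consistency positions outside consensus", call. = FALSE)
  }
  structure(list(consensus = consensus,
                 low_consistency_positions = lc,
                 cut_after = as.integer(cut_after),
                 core_span = core_span, info_content = info_content),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  ann <- paste0(substr(x$consensus, 1L, x$cut_after), "^",
                substr(x$consensus, x$cut_after + 1L, nchar(x$consensus)))
  cat(sprintf("<motif %s; low-consistency positions: %s>\n", ann,
              if (length(x$low_consistency_positions) == 0L) "none"
              else paste(x$low_consistency_positions, collapse = ",")))
  invisible(x)
}

#' Call the consensus motif from a PFM
#'
#' The core is the maximal contiguous run of offsets with information
#' content at least `core_threshold` bits (default 1.0: at the ten-window
#' scale the pipeline operates on, nonconserved columns regularly exceed
#' 0.5 bits by sampling noise alone, e.g. a 7/10 majority scores 0.64 bits,
#' while motif columns sit near 2) that contains offset 0; the
#' consensus is the column-majority base over that span (ties broken in
#' A < C < G < U order and logged).  Positions whose majority frequency is
#' below `low_consistency_threshold` are flagged low-consistency.  The
#' cleavage annotation is fixed by the window convention: the cut lies
#' between offsets -1 and 0, i.e. after consensus position
#' `-(core start offset)`.
#'
#' @param x a `pfm`
#' @param core_threshold bits required for an offset to join the core
#' @param low_consistency_threshold majority-frequency flag threshold
#' @return a [motif]
#' @export
consensus <- function(x, core_threshold = 1.0,
                      low_consistency_threshold = 0.9) {
  stopifnot(inherits(x, "pfm"))
  bits <- info_content(x)
  ok <- !is.na(bits) & bits >= core_threshold
  zero <- which(x$offsets == 0L)
  if (length(zero) != 1L || !ok[zero]) {
    stop("no motif at called sites: offset 0 is below the core threshold",
         call. = FALSE)
  }
  lo <- zero
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- zero
  while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  span <- lo:hi
  cons <- character(length(span))
  lowpos <- integer(0)
  for (k in seq_along(span)) {
    f <- x$freqs[, span[k]]
    top <- which(f == max(f))
    if (length(top) > 1L) {
      .cm_log(sprintf("consensus tie at offset %d resolved as %s",
                      x$offsets[span[k]], RNA_BASES[top[1L]]),
              level = "WARN")
    }
    cons[k] <- RNA_BASES[top[1L]]
    if (max(f) < low_consistency_threshold) lowpos <- c(lowpos, k)
  }
  motif(consensus = paste(cons, collapse = ""),
        low_consistency_positions = lowpos,
        cut_after = -x$offsets[lo],
        core_span = c(x$offsets[lo], x$offsets[hi]),
        info_content = bits)
}

#' Run the motif-calling stage
#'
#' @param sites called sites data.frame
#' @param substrates list of [substrate] objects
#' @param config a [pipeline_config]
#' @return list with `windows`, `pfm` and `motif`
#' @export
call_motif <- function(sites, substrates, config = pipeline_config()) {
  wins <- windows(sites, substrates, w = config$window_w)
  mat <- pfm(wins)
  list(windows = wins, pfm = mat,
       motif = consensus(mat, config$core_threshold,
                         config$low_consistency_threshold))
}

#' PFM export table
#'
#' @param x a `pfm`
#' @return data.frame (offset, count_A..count_U, freq_A..freq_U, bits)
#'   consumable by standard logo plotters
#' @export
pfm_table <- function(x) {
  stopifnot(inherits(x, "pfm"))
  bits <- info_content(x)
  df <- data.frame(offset = x$offsets, t(x$counts), t(x$freqs), bits)
  names(df) <- c("offset", paste0("count_", RNA_BASES),
                 paste0("freq_", RNA_BASES), "bits")
  df
}
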