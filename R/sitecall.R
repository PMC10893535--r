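# sitecall: from reads to called cleavage sites.
#
# The statistic of interest is the relative coverage increase (RCI):
# depth at position n divided by depth at position n-1, with the zero rule
# RCI(n) = depth(n) when depth(n-1) = 0.  A cleavage-generated 5' end shows
# up as a step in coverage, hence a high RCI one base downstream of the cut.

# Hamming distance between two equal-length strings (no indels)
.hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Extract barcode-ligated reads
#'
#' Keeps only reads whose prefix matches the barcode with at most
#' `max_mismatches` substitutions (no indels) and strips that prefix.
#' Reads shorter than the barcode are discarded.  T and U are treated as
#' equivalent.
#'
#' @param reads data.frame with id/sequence/quality columns
#' @param barcode barcode sequence
#' @param max_mismatches substitutions tolerated in the barcode prefix
#' @return the surviving reads, barcode removed
#' @export
extract_barcoded <- function(reads, barcode = DEFAULT_BARCODE,
                             max_mismatches = 1L) {
  if (!nzchar(barcode)) stop("barcode must be non-empty", call. = FALSE)
  bc <- .to_rna(barcode)
  bl <- nchar(bc)
  seqs <- .to_rna(reads$sequence)
  long_enough <- nchar(seqs) >= bl
  prefix <- substr(seqs, 1L, bl)
  hit <- long_enough & prefix == bc
  if (max_mismatches > 0L) {
    cand <- which(long_enough & !hit)
    if (length(cand) > 0L) {
      bci <- utf8ToInt(bc)
      mm <- vapply(prefix[cand],
                   function(p) sum(utf8ToInt(p) != bci), integer(1),
                   USE.NAMES = FALSE)
      hit[cand] <- mm <= max_mismatches
    }
  }
  .cm_log(sprintf("barcode extraction: kept %d / %d reads",
                  sum(hit), nrow(reads)))
  out <- reads[hit, , drop = FALSE]
  out$sequence <- substr(out$sequence, bl + 1L, nchar(out$sequence))
  if (!is.null(out$quality)) {
    out$quality <- substr(out$quality, bl + 1L, nchar(out$quality))
  }
  rownames(out) <- NULL
  out
}

# seed index: position of every k-mer of every substrate
.build_seed_index <- function(seqs, k) {
  tabs <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < k) return(NULL)
    data.frame(kmer = substring(s, 1:(L - k + 1L), k:L),
               substrate_id = id, pos = seq_len(L - k + 1L),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  # environment as a hash map: kmer -> data.frame(substrate_id, pos)
  list2env(split(tab[c("substrate_id", "pos")], tab$kmer),
           envir = new.env(hash = TRUE, size = 2L * nrow(tab)))
}

#' Map reads to known substrate sequences
#'
#' A bespoke assigner for short, known, synthetic references: the first
#' `seed_len` bases of a read are looked up exactly in a k-mer index of all
#' substrates, and each candidate location is then scored over the full
#' read allowing up to `max_mismatches` substitutions (no indels).  Reads
#' with no acceptable location, or with two equally good distinct
#' locations, are discarded.  T and U are treated as equivalent.
#'
#' @param reads data.frame with id/sequence columns (barcode already
#'   removed)
#' @param substrates list of [substrate] objects or named character vector
#' @param max_mismatches substitutions tolerated over the full read
#' @param min_match_len reads shorter than this are discarded
#' @param seed_len exact-match seed length (default 20, capped at the read
#'   length)
#' @return data.frame with columns read_id, substrate_id, start,
#'   matched_len, mismatches
#' @export
map_reads <- function(reads, substrates, max_mismatches = 3L,
                      min_match_len = 30L, seed_len = 20L) {
  seqs <- .to_rna(.substrate_seqs(substrates))
  if (length(seqs) == 0L) stop("substrates must be non-empty", call. = FALSE)
  idx <- .build_seed_index(seqs, seed_len)
  rseq <- .to_rna(reads$sequence)
  rlen <- nchar(rseq)
  keep <- rlen >= max(min_match_len, seed_len)
  out <- vector("list", nrow(reads))
  sublen <- nchar(seqs)
  for (i in which(keep)) {
    r <- rseq[i]
    cand <- get0(substr(r, 1L, seed_len), envir = idx, inherits = FALSE)
    if (is.null(cand)) next
    best_mm <- Inf; best <- NULL; tie <- FALSE
    for (j in seq_len(nrow(cand))) {
      sid <- cand$substrate_id[j]; pos <- cand$pos[j]
      end <- pos + rlen[i] - 1L
      if (end > sublen[[sid]]) next
      ref <- substr(seqs[[sid]], pos, end)
      mm <- if (ref == r) 0L else .hamming(ref, r)
      if (mm < best_mm) {
        best_mm <- mm; best <- c(sid, pos); tie <- FALSE
      } else if (mm == best_mm &&
                 !(sid == best[1L] && pos == as.integer(best[2L]))) {
        tie <- TRUE
      }
    }
    if (is.null(best) || tie || best_mm > max_mismatches) next
    out[[i]] <- c(i, best[1L], best[2L], best_mm)
  }
  hits <- out[!vapply(out, is.null, logical(1))]
  .cm_log(sprintf("mapping: placed %d / %d reads", length(hits),
                  nrow(reads)))
  if (length(hits) == 0L) {
    return(data.frame(read_id = character(0), substrate_id = character(0),
                      start = integer(0), matched_len = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, hits)
  ri <- as.integer(m[, 1L])
  data.frame(read_id = reads$id[ri], substrate_id = m[, 2L],
             start = as.integer(m[, 3L]), matched_len = rlen[ri],
             mismatches = as.integer(m[, 4L]), stringsAsFactors = FALSE)
}

#' Per-position read coverage of one substrate
#'
#' depth(n) = number of mapped reads whose interval
#' `[start, start + matched_len - 1]` contains n.
#'
#' @param mappings mapping data.frame (rows for other substrates are
#'   ignored)
#' @param sub a [substrate]
#' @return list of class `coverage_profile` with fields substrate_id and
#'   integer vector depth of length nchar(substrate)
#' @export
coverage <- function(mappings, sub) {
  L <- nchar(sub$sequence)
  m <- mappings[mappings$substrate_id == sub$id, , drop = FALSE]
  delta <- integer(L + 1L)
  if (nrow(m) > 0L) {
    add <- tabulate(m$start, nbins = L + 1L)
    ends <- pmin(m$start + m$matched_len - 1L, L)
    sub_ <- tabulate(ends + 1L, nbins = L + 1L)
    delta <- add - sub_
  }
  structure(list(substrate_id = sub$id,
                 depth = cumsum(delta)[seq_len(L)]),
            class = "coverage_profile")
}

#' Relative coverage increase (RCI) track
#'
#' RCI(n) = depth(n) / depth(n-1); when depth(n-1) is zero, RCI(n) is
#' defined equal to depth(n).  Position 1 takes depth(0) = 0, so
#' RCI(1) = depth(1).
#'
#' @param profile a `coverage_profile`
#' @return list of class `rci_profile` with fields substrate_id, rci and
#'   the depth vector it was derived from
#' @export
rci <- function(profile) {
  d <- as.numeric(profile$depth)
  prev <- c(0, d[-length(d)])
  r <- ifelse(prev > 0, d / prev, d)
  structure(list(substrate_id = profile$substrate_id, rci = r,
                 depth = profile$depth),
            class = "rci_profile")
}

#' Select the top-K RCI sites pooled across substrates
#'
#' Positions are ranked by RCI across all profiles jointly.  Ties are
#' broken by higher depth, then substrate id (lexicographic), then smaller
#' position.  Positions whose `window_w`-wide window would run off either
#' substrate end are skipped, as are positions below the minimum-depth
#' floor (the raw depth ratio is unstable at depths 0 and 1).
#'
#' @param rci_profiles list of `rci_profile` objects
#' @param K number of sites to return
#' @param window_w window width used downstream (controls the edge skip)
#' @param min_depth minimum depth(n) for eligibility
#' @return data.frame with columns rank, substrate_id, position, rci,
#'   depth
#' @export
top_sites <- function(rci_profiles, K = 10L, window_w = 11L,
                      min_depth = 5L) {
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (inherits(rci_profiles, "rci_profile")) {
    rci_profiles <- list(rci_profiles)
  }
  half <- (window_w - 1L) %/% 2L
  pooled <- do.call(rbind, lapply(rci_profiles, function(p) {
    L <- length(p$rci)
    data.frame(substrate_id = p$substrate_id, position = seq_len(L),
               rci = p$rci, depth = as.integer(p$depth),
               edge = seq_len(L) <= half | seq_len(L) > L - half,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || all(pooled$depth == 0L)) {
    stop("no coverage in any profile; cannot call sites", call. = FALSE)
  }
  n_edge <- sum(pooled$edge & pooled$depth >= min_depth & pooled$rci > 0)
  if (n_edge > 0L) {
    .cm_log(sprintf("top_sites: %d covered position(s) skipped at substrate edges",
                    n_edge), level = "WARN")
  }
  elig <- pooled[!pooled$edge & pooled$depth >= min_depth, , drop = FALSE]
  if (nrow(elig) == 0L) {
    stop("no position passes the depth floor; cannot call sites",
         call. = FALSE)
  }
  ord <- order(-elig$rci, -elig$depth, elig$substrate_id, elig$position)
  if (K > nrow(elig)) {
    .cm_log(sprintf("top_sites: only %d eligible positions for K=%d",
                    nrow(elig), K), level = "WARN")
    K <- nrow(elig)
  }
  sel <- elig[ord[seq_len(K)], c("substrate_id", "position", "rci",
                                 "depth")]
  sel <- cbind(rank = seq_len(K), sel)
  rownames(sel) <- NULL
  sel
}

#' Run the full site-calling stage
#'
#' Barcode extraction, mapping, per-substrate coverage and RCI, and pooled
#' top-K selection, using the thresholds in `config`.
#'
#' @param reads FASTQ-style reads data.frame
#' @param substrates list of [substrate] objects
#' @param config a [pipeline_config]
#' @return list with elements `sites` (data.frame), `coverage` and `rci`
#'   (lists keyed by substrate id), and `n_mapped`
#' @export
call_sites <- function(reads, substrates, config = pipeline_config()) {
  if (nrow(reads) == 0L) stop("no reads supplied", call. = FALSE)
  bar <- extract_barcoded(reads, config$barcode,
                          config$max_barcode_mismatches)
  if (nrow(bar) == 0L) stop("zero barcoded reads", call. = FALSE)
  maps <- map_reads(bar, substrates, config$max_mismatches,
                    config$min_match_len)
  covs <- lapply(substrates, function(s) coverage(maps, s))
  names(covs) <- vapply(substrates, function(s) s$id, character(1))
  rcis <- lapply(covs, rci)
  sites <- top_sites(rcis, K = config$K, window_w = config$window_w,
                     min_depth = config$min_depth)
  list(sites = sites, coverage = covs, rci = rcis, n_mapped = nrow(maps))
}

#' Flatten coverage/RCI tracks to a plot-ready table
#'
#' @param covs list of `coverage_profile`
#' @param rcis list of `rci_profile`
#' @return data.frame (substrate_id, position, depth, rci)
#' @export
tracks_table <- function(covs, rcis) {
  do.call(rbind, lapply(seq_along(covs), function(i) {
    data.frame(substrate_id = covs[[i]]$substrate_id,
               position = seq_along(covs[[i]]$depth),
               depth = covs[[i]]$depth, rci = rcis[[i]]$rci,
               stringsAsFactors = FALSE)
  }))
}
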