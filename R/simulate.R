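# simulate: seeded generator emulating partial endoribonuclease digestion of
# known RNA substrates followed by library preparation.  Ground truth
# (planted sites, fragment origins) is carried in substrate objects and read
# ids only; the calling pipeline never consults it.

#' Digestion and library model
#'
#' Parameters of the simulated digestion/sequencing experiment.  The
#' defaults are the study conditions the package is calibrated against:
#' cleavage at UACAUA between the U and the first A, partial digestion at
#' 70\% per site per molecule, a low uniform nonspecific breakage rate, and
#' MiSeq-like 150-nt single-end reads with a 0.1\% substitution error rate.
#'
#' @param motif recognition motif (RNA string)
#' @param cut_offset backbone cut position: the cut falls between motif
#'   positions `cut_offset` and `cut_offset + 1` counted from the motif
#'   start, so the default 1 cuts between U and the first A (U^ACAUA)
#' @param site_cleavage_prob probability each motif occurrence in each
#'   molecule is cut
#' @param background_break_rate per-position probability of nonspecific
#'   breakage
#' @param n_molecules molecules simulated per substrate
#' @param read_length single-end read length in nt
#' @param read_error_rate per-base substitution probability
#' @param ligation_prob probability a fragment 5' end receives the barcode
#' @return a list of class `digestion_model`
#' @export
digestion_model <- function(motif = "UACAUA", cut_offset = 1L,
                            site_cleavage_prob = 0.7,
                            background_break_rate = 1e-4,
                            n_molecules = 1000L, read_length = 150L,
                            read_error_rate = 0.001,
                            ligation_prob = 0.8) {
  motif <- .to_rna(motif)
  .check_rna(motif, allow_n = FALSE, what = "motif")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 1L || cut_offset > nchar(motif)) {
    stop("cut_offset must lie within the motif", call. = FALSE)
  }
  for (p in c(site_cleavage_prob, background_break_rate,
              read_error_rate, ligation_prob)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0,1]", call. = FALSE)
  }
  structure(list(motif = motif, cut_offset = cut_offset,
                 site_cleavage_prob = site_cleavage_prob,
                 background_break_rate = background_break_rate,
                 n_molecules = as.integer(n_molecules),
                 read_length = as.integer(read_length),
                 read_error_rate = read_error_rate,
                 ligation_prob = ligation_prob),
            class = "digestion_model")
}

.find_occurrences <- function(seq, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Generate a substrate with planted motif sites
#'
#' Produces a random-composition RNA of the requested length carrying
#' exactly `n_sites` non-overlapping planted occurrences of the motif and no
#' spurious occurrence anywhere else (flanking sequence is re-randomised
#' until this holds).  Sites are kept away from the substrate ends and from
#' each other so that size selection does not silently remove their
#' cleavage fragments.
#'
#' @param length substrate length in nt
#' @param n_sites number of planted motif occurrences
#' @param motif RNA motif to plant
#' @param seed integer RNG seed
#' @param min_separation minimum distance between planted site starts
#'   (default 250 nt, comfortably above the 200-nt size-selection
#'   threshold)
#' @param end_margin minimum distance of a site start from either substrate
#'   end (default 220 nt)
#' @return a [substrate] with `planted_sites` recorded
#' @export
make_substrate <- function(length, n_sites, motif = "UACAUA", seed = 1L,
                           min_separation = 250L, end_margin = 220L) {
  motif <- .to_rna(motif)
  m <- nchar(motif)
  length <- as.integer(length); n_sites <- as.integer(n_sites)
  if (length < n_sites * (m + 20L)) {
    stop("impossible packing: substrate too short for ", n_sites, " sites",
         call. = FALSE)
  }
  lo <- max(1L, end_margin)
  hi <- length - max(end_margin, m) - m + 1L
  if (n_sites > 0L &&
      (hi < lo || (hi - lo) < (n_sites - 1L) * min_separation)) {
    stop("impossible packing: cannot place ", n_sites, " sites ",
         min_separation, " nt apart within [", lo, ",", hi, "]",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sites <- integer(0)
  if (n_sites > 0L) {
    # place sites by sampling in a gap-contracted range, then re-expanding
    span <- hi - lo - (n_sites - 1L) * (min_separation - 1L)
    raw <- sort(sample.int(span + 1L, n_sites)) - 1L
    sites <- lo + raw + (seq_len(n_sites) - 1L) * (min_separation - 1L)
  }
  bases <- sample(RNA_BASES, length, replace = TRUE)
  for (s in sites) bases[s:(s + m - 1L)] <- strsplit(motif, "")[[1L]]
  planted_mask <- logical(length)
  for (s in sites) planted_mask[s:(s + m - 1L)] <- TRUE
  repeat {
    seq <- paste(bases, collapse = "")
    occ <- .find_occurrences(seq, motif)
    spurious <- setdiff(occ, sites)
    if (length(spurious) == 0L) break
    for (s in spurious) {
      span <- s:(s + m - 1L)
      redo <- span[!planted_mask[span]]
      bases[redo] <- sample(RNA_BASES, length(redo), replace = TRUE)
    }
  }
  substrate(id = sprintf("sub_%d_%d", length, seed), sequence = seq,
            planted_sites = sites, motif_length = m)
}

#' Digest substrate molecules into fragments
#'
#' Simulates partial digestion of `n_molecules` copies of a substrate.
#' Each planted motif occurrence is cut, with probability
#' `site_cleavage_prob`, between positions `site + cut_offset - 1` and
#' `site + cut_offset`; nonspecific breaks occur independently after each
#' position at `background_break_rate`.  Fragments partition every
#' molecule.
#'
#' @param sub a [substrate]
#' @param model a [digestion_model]
#' @param seed integer RNG seed
#' @return data.frame with columns substrate_id, molecule, start, end,
#'   barcoded (initialised FALSE)
#' @export
digest <- function(sub, model, seed = 1L) {
  stopifnot(inherits(sub, "substrate"), inherits(model, "digestion_model"))
  L <- nchar(sub$sequence)
  n <- model$n_molecules
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sites <- sub$planted_sites
  cutpos <- sites + model$cut_offset - 1L  # cut after this position
  cutpos <- cutpos[cutpos >= 1L & cutpos < L]
  ns <- length(cutpos)
  site_cut <- if (ns > 0L) {
    matrix(stats::runif(ns * n) < model$site_cleavage_prob, nrow = ns)
  } else matrix(logical(0), nrow = 0L, ncol = n)
  # background break count per molecule, then positions
  nbg <- stats::rbinom(n, L - 1L, model$background_break_rate)
  frag_list <- vector("list", n)
  for (i in seq_len(n)) {
    cuts <- cutpos[site_cut[, i]]
    if (nbg[i] > 0L) cuts <- c(cuts, sample.int(L - 1L, nbg[i]))
    cuts <- sort(unique(cuts))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    frag_list[[i]] <- cbind(i, starts, ends)
  }
  all <- do.call(rbind, frag_list)
  data.frame(substrate_id = sub$id, molecule = all[, 1L],
             start = all[, 2L], end = all[, 3L], barcoded = FALSE,
             stringsAsFactors = FALSE)
}

#' Size-select fragments
#'
#' Removes fragments shorter than `min_fragment_len`, emulating the
#' purification step that excludes short digestion products; order is
#' preserved.
#'
#' @param fragments fragment data.frame from [digest()]
#' @param min_fragment_len minimum retained length in nt (default 200)
#' @return the filtered fragment data.frame
#' @export
size_select <- function(fragments, min_fragment_len = 200L) {
  keep <- (fragments$end - fragments$start + 1L) >= min_fragment_len
  fragments[keep, , drop = FALSE]
}

#' Mark fragments as barcode-ligated
#'
#' Each fragment independently receives the 5' barcode with probability
#' `ligation_prob`; the barcode is conceptually prepended at the fragment's
#' 5' end, the end generated by cleavage.
#'
#' @param fragments fragment data.frame
#' @param barcode barcode sequence (RNA alphabet, N allowed)
#' @param ligation_prob per-fragment ligation probability
#' @param seed integer RNG seed
#' @return the fragment data.frame with `barcoded` set
#' @export
ligate_barcode <- function(fragments, barcode = DEFAULT_BARCODE,
                           ligation_prob = 0.8, seed = 1L) {
  .check_rna(.to_rna(barcode), allow_n = TRUE, what = "barcode")
  if (ligation_prob < 0 || ligation_prob > 1) {
    stop("ligation_prob must be in [0,1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fragments$barcoded <- stats::runif(nrow(fragments)) < ligation_prob
  fragments
}

#' Sample sequencing reads from fragments
#'
#' Each read is the 5' prefix of (barcode + fragment sequence) for barcoded
#' fragments, or of the fragment alone otherwise, truncated to the model's
#' read length; substitution errors are applied i.i.d. per base.  Read ids
#' encode the originating substrate, fragment start and barcode status so
#' that test oracles can score recovery without the pipeline ever parsing
#' them.
#'
#' @param substrates list of [substrate] objects (or named character vector)
#' @param fragments fragment data.frame (after size selection/ligation)
#' @param model a [digestion_model]
#' @param seed integer RNG seed
#' @param barcode barcode sequence prepended to barcoded fragments
#' @param n_reads if non-NULL, sample this many reads from the fragment
#'   pool with replacement; otherwise one read per fragment
#' @return data.frame with columns id, sequence, quality (constant Phred
#'   'I'; quality modelling is out of scope)
#' @export
fragments_to_reads <- function(substrates, fragments, model, seed = 1L,
                               barcode = DEFAULT_BARCODE, n_reads = NULL) {
  seqs <- .substrate_seqs(substrates)
  if (!all(fragments$substrate_id %in% names(seqs))) {
    stop("fragments reference unknown substrates", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  if (!is.null(n_reads)) {
    if (nrow(fragments) == 0L) stop("no fragments to sample", call. = FALSE)
    fragments <- fragments[sample.int(nrow(fragments), n_reads,
                                      replace = TRUE), , drop = FALSE]
  }
  nfrag <- nrow(fragments)
  if (nfrag == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  bc_len <- ifelse(fragments$barcoded, nchar(barcode), 0L)
  body_len <- pmin(fragments$end - fragments$start + 1L,
                   pmax(model$read_length - bc_len, 0L))
  body <- substr(seqs[fragments$substrate_id], fragments$start,
                 fragments$start + body_len - 1L)
  reads <- ifelse(fragments$barcoded, paste0(barcode, body), body)
  reads <- substr(reads, 1L, model$read_length)
  # i.i.d. substitution errors across the whole base pool
  lens <- nchar(reads)
  total <- sum(lens)
  nerr <- stats::rbinom(1L, total, model$read_error_rate)
  if (nerr > 0L) {
    flat <- sample.int(total, nerr)
    cum <- cumsum(lens)
    ridx <- findInterval(flat - 1L, cum) + 1L
    pos <- flat - c(0L, cum)[ridx]
    for (j in seq_len(nerr)) {
      b <- substr(reads[ridx[j]], pos[j], pos[j])
      repl <- sample(setdiff(RNA_BASES, b), 1L)
      substr(reads[ridx[j]], pos[j], pos[j]) <- repl
    }
  }
  ids <- sprintf("r%07d|%s|%d|%d", seq_len(nfrag), fragments$substrate_id,
                 fragments$start, as.integer(fragments$barcoded))
  data.frame(id = ids, sequence = reads, quality = strrep("I", lens),
             stringsAsFactors = FALSE)
}

#' Simulate a full digestion sequencing library
#'
#' End-to-end generator reproducing the study design: eight substrates of
#' 1000, 1500 and 2000 nt carrying two to four planted motif sites each,
#' partial digestion, 200-nt size selection, 45-nt barcode ligation and
#' sampling of 50,000 single-end reads.
#'
#' @param seed integer seed controlling every stochastic step
#' @param model a [digestion_model]
#' @param config a [pipeline_config] (supplies barcode and size threshold)
#' @param lengths substrate lengths
#' @param n_sites planted sites per substrate (recycled against `lengths`)
#' @param n_reads total reads sampled
#' @return list with elements `substrates` (list of [substrate]), `reads`
#'   (FASTQ-ready data.frame), `truth` (data.frame substrate_id, position
#'   of each planted site), `fragments`
#' @export
simulate_library <- function(seed = 1L, model = digestion_model(),
                             config = pipeline_config(),
                             lengths = c(1000L, 1000L, 1500L, 1500L, 1500L,
                                         2000L, 2000L, 2000L),
                             n_sites = c(2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
                             n_reads = 50000L) {
  n_sites <- rep_len(n_sites, length(lengths))
  subs <- vector("list", length(lengths))
  frags <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    s <- make_substrate(lengths[i], n_sites[i], motif = model$motif,
                        seed = .child_seed(seed, i))
    s$id <- sprintf("RNA%02d_%d", i, lengths[i])
    f <- digest(s, model, seed = .child_seed(seed, 100L + i))
    subs[[i]] <- s
    frags[[i]] <- f
  }
  fragments <- do.call(rbind, frags)
  fragments <- size_select(fragments, config$min_fragment_len)
  fragments <- ligate_barcode(fragments, config$barcode,
                              model$ligation_prob,
                              seed = .child_seed(seed, 1000L))
  reads <- fragments_to_reads(subs, fragments, model,
                              seed = .child_seed(seed, 2000L),
                              barcode = config$barcode, n_reads = n_reads)
  truth <- do.call(rbind, lapply(subs, function(s) {
    if (length(s$planted_sites) == 0L) return(NULL)
    data.frame(substrate_id = s$id, position = s$planted_sites,
               stringsAsFactors = FALSE)
  }))
  list(substrates = subs, reads = reads, truth = truth,
       fragments = fragments)
}
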