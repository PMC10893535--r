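# independent oracles and small fixture builders used across the suite

# brute-force RCI per the ratio-with-zero-rule definition
rci_oracle <- function(depth) {
  out <- numeric(length(depth))
  for (n in seq_along(depth)) {
    prev <- if (n == 1L) 0 else depth[n - 1L]
    out[n] <- if (prev > 0) depth[n] / prev else depth[n]
  }
  out
}

# naive sliding-window overlapping motif count (T/U equivalent)
scan_oracle <- function(seq, motif) {
  seq <- chartr("T", "U", toupper(seq))
  motif <- chartr("T", "U", toupper(motif))
  L <- nchar(seq); m <- nchar(motif)
  if (L < m) return(0L)
  sum(vapply(seq_len(L - m + 1L),
             function(i) substr(seq, i, i + m - 1L) == motif, logical(1)))
}

# exhaustive global affine-gap alignment score: enumerates every alignment
# of a and b recursively; gap of length g costs open + ext * g.  Only
# usable for very short sequences.
nw_score_oracle <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1L, j + 1L, score + mat[av[i], bv[j]], "M")
    }
    if (i <= length(av)) {
      pen <- if (state == "A") ext else open + ext
      rec(i + 1L, j, score - pen, "A")
    }
    if (j <= length(bv)) {
      pen <- if (state == "B") ext else open + ext
      rec(i, j + 1L, score - pen, "B")
    }
  }
  rec(1L, 1L, 0, "M")
  best
}

# deterministic random coverage profile
random_profile <- function(len, seed, max_depth = 50L) {
  set.seed(seed)
  structure(list(substrate_id = paste0("p", seed),
                 depth = sample(0:max_depth, len, replace = TRUE)),
            class = "coverage_profile")
}

# a small substrate with one planted UACAUA site at a known position
toy_substrate <- function(site = 40L, length = 100L, id = "toy") {
  set.seed(99L)
  repeat {
    bases <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
    bases[site:(site + 5L)] <- c("U", "A", "C", "A", "U", "A")
    seq <- paste(bases, collapse = "")
    occ <- gregexpr("(?=UACAUA)", seq, perl = TRUE)[[1L]]
    if (identical(as.integer(occ), as.integer(site))) break
  }
  substrate(id, seq, planted_sites = site)
}

# toy 6-letter substitution matrix for hand-checkable protein alignments
toy_submat <- function() {
  letters6 <- c("H", "E", "A", "G", "P", "W")
  m <- matrix(-1, 6, 6, dimnames = list(letters6, letters6))
  diag(m) <- 3
  m["H", "E"] <- m["E", "H"] <- 1
  m["A", "G"] <- m["G", "A"] <- 1
  m
}
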