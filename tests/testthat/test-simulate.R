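test_that("make_substrate plants exactly the requested motif occurrences", {
  s <- make_substrate(1500, 3, "UACAUA", seed = 7)
  occ <- gregexpr("(?=UACAUA)", s$sequence, perl = TRUE)[[1L]]
  expect_identical(sort(as.integer(occ)), sort(s$planted_sites))
  expect_length(s$planted_sites, 3L)

  s0 <- make_substrate(800, 0, "UACAUA", seed = 5)
  expect_equal(scan_oracle(s0$sequence, "UACAUA"), 0L)

  expect_identical(make_substrate(1500, 3, seed = 7)$sequence, s$sequence)
  expect_error(make_substrate(60, 3, "UACAUA", seed = 1),
               "impossible packing")
})

test_that("digest splits molecules at planted sites and partitions them", {
  s <- toy_substrate(site = 40L, length = 300L)
  m1 <- digestion_model(site_cleavage_prob = 1, background_break_rate = 0,
                        n_molecules = 1L)
  fr <- digest(s, m1, seed = 2)
  expect_equal(nrow(fr), 2L)
  # cut between positions site + cut_offset - 1 and site + cut_offset
  expect_equal(fr$start, c(1L, 41L))
  expect_equal(fr$end, c(40L, 300L))

  m0 <- digestion_model(site_cleavage_prob = 0, background_break_rate = 0,
                        n_molecules = 5L)
  fr0 <- digest(s, m0, seed = 2)
  expect_equal(nrow(fr0), 5L)
  expect_true(all(fr0$start == 1L & fr0$end == 300L))

  mm <- digestion_model(site_cleavage_prob = 0.5,
                        background_break_rate = 0.01, n_molecules = 40L)
  fr2 <- digest(s, mm, seed = 9)
  lens <- tapply(fr2$end - fr2$start + 1L, fr2$molecule, sum)
  expect_true(all(lens == 300L))
  expect_identical(digest(s, mm, seed = 9), fr2)
})

test_that("every forced fragment boundary lies cut_offset bases into a planted site", {
  s <- make_substrate(1200, 3, seed = 21)
  mod <- digestion_model(site_cleavage_prob = 1, background_break_rate = 0,
                         n_molecules = 20L, cut_offset = 1L)
  fr <- digest(s, mod, seed = 4)
  internal_starts <- unique(fr$start[fr$start > 1L])
  expect_setequal(internal_starts, s$planted_sites + mod$cut_offset)
})

test_that("size_select drops short fragments and preserves order", {
  fr <- data.frame(substrate_id = "s", molecule = 1L,
                   start = c(1L, 200L, 400L), end = c(150L, 399L, 1932L),
                   barcoded = FALSE)
  kept <- size_select(fr, 200L)
  expect_equal(kept$end - kept$start + 1L, c(200L, 1533L))
  expect_identical(size_select(fr, 0L), fr)
  expect_equal(nrow(size_select(fr, 5000L)), 0L)
})

test_that("ligate_barcode marks fragments at the requested probability", {
  fr <- data.frame(substrate_id = "s", molecule = 1:100, start = 1L,
                   end = 300L, barcoded = FALSE)
  expect_true(all(ligate_barcode(fr, ligation_prob = 1, seed = 1)$barcoded))
  expect_false(any(ligate_barcode(fr, ligation_prob = 0, seed = 1)$barcoded))
  expect_identical(ligate_barcode(fr, ligation_prob = 0.5, seed = 3),
                   ligate_barcode(fr, ligation_prob = 0.5, seed = 3))
  expect_error(ligate_barcode(fr, barcode = "ACXGU", ligation_prob = 1),
               "outside")
})

test_that("reads are 5' prefixes of barcode + fragment", {
  s <- toy_substrate(site = 40L, length = 300L)
  mod <- digestion_model(site_cleavage_prob = 1, background_break_rate = 0,
                         n_molecules = 1L, read_length = 80L,
                         read_error_rate = 0)
  fr <- digest(s, mod, seed = 1)
  fr$barcoded <- TRUE
  reads <- fragments_to_reads(list(s), fr, mod, seed = 1)
  expect_equal(nrow(reads), 2L)
  expect_true(all(startsWith(reads$sequence, DEFAULT_BARCODE)))
  body <- substr(reads$sequence[2], 46L, 80L)
  expect_identical(body, substr(s$sequence, 41L, 41L + 34L))
  expect_true(all(nchar(reads$sequence) == 80L))
  # unbarcoded fragment reads start directly in substrate sequence
  fr$barcoded <- FALSE
  reads2 <- fragments_to_reads(list(s), fr, mod, seed = 1)
  expect_identical(substr(reads2$sequence[2], 1L, 35L), body)
  # reproducibility
  expect_identical(fragments_to_reads(list(s), fr, mod, seed = 8),
                   fragments_to_reads(list(s), fr, mod, seed = 8))
})

test_that("read ids carry ground truth and errors hit the requested rate", {
  sim <- simulate_library(seed = 5, n_reads = 2000,
                          lengths = c(1000L, 1000L), n_sites = c(2L, 2L),
                          model = digestion_model(n_molecules = 200L,
                                                  read_error_rate = 0.01))
  parts <- strsplit(sim$reads$id, "|", fixed = TRUE)
  expect_true(all(vapply(parts, length, integer(1)) == 4L))
  subs <- vapply(parts, `[`, character(1), 2L)
  expect_true(all(subs %in% vapply(sim$substrates, function(s) s$id,
                                   character(1))))
  # substitution rate lands near 1% over the read pool
  seqs <- setNames(vapply(sim$substrates, function(s) s$sequence,
                          character(1)),
                   vapply(sim$substrates, function(s) s$id, character(1)))
  bar <- vapply(parts, function(p) p[4L] == "1", logical(1))
  start <- as.integer(vapply(parts, `[`, character(1), 3L))
  mism <- 0L; tot <- 0L
  for (i in head(which(!bar), 200L)) {
    r <- sim$reads$sequence[i]
    ref <- substr(seqs[subs[i]], start[i], start[i] + nchar(r) - 1L)
    mism <- mism + sum(utf8ToInt(r) != utf8ToInt(ref))
    tot <- tot + nchar(r)
  }
  expect_gt(mism / tot, 0.004)
  expect_lt(mism / tot, 0.02)
})
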