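test_that("extract_barcoded keeps matching prefixes and strips them", {
  bc <- DEFAULT_BARCODE
  mk <- function(seqs) data.frame(id = paste0("r", seq_along(seqs)),
                                  sequence = seqs,
                                  quality = strrep("I", nchar(seqs)))
  exact <- paste0(bc, "ACGUACGU")
  onemm <- exact
  substr(onemm, 10L, 10L) <- if (substr(onemm, 10, 10) == "A") "C" else "A"
  short <- substr(bc, 1L, 20L)
  reads <- mk(c(exact, onemm, short, "ACGUACGUACGU"))

  strict <- suppressMessages(extract_barcoded(reads, bc, max_mismatches = 0))
  expect_identical(strict$id, "r1")
  expect_identical(strict$sequence, "ACGUACGU")
  expect_identical(nchar(strict$quality), 8L)

  loose <- suppressMessages(extract_barcoded(reads, bc, max_mismatches = 1))
  expect_identical(loose$id, c("r1", "r2"))
})

test_that("all reads from a fully ligated, error-free library survive extraction", {
  mod <- digestion_model(read_error_rate = 0, n_molecules = 100L,
                         ligation_prob = 1)
  sim <- simulate_library(seed = 11, model = mod, n_reads = 1500,
                          lengths = c(1000L, 1000L), n_sites = c(2L, 2L))
  kept <- suppressMessages(
    extract_barcoded(sim$reads, DEFAULT_BARCODE, max_mismatches = 0))
  longer <- sum(nchar(sim$reads$sequence) >= nchar(DEFAULT_BARCODE) + 1L)
  expect_equal(nrow(kept), longer)
})

test_that("map_reads places error-free reads exactly and applies discard rules", {
  s1 <- toy_substrate(site = 40L, length = 300L, id = "s1")
  r101 <- substr(s1$sequence, 101L, 160L)
  # a read present identically in two substrates is ambiguous
  s2 <- substrate("s2", paste0(substr(s1$sequence, 101L, 160L),
                               substr(toy_substrate(40L, 260L,
                                                    "other")$sequence,
                                      1L, 240L)))
  reads <- data.frame(id = c("a", "b", "c"),
                      sequence = c(r101, chartr("U", "T", r101), "ACGU"),
                      quality = "")
  reads$quality <- strrep("I", nchar(reads$sequence))
  m1 <- suppressMessages(map_reads(reads, list(s1), max_mismatches = 3))
  expect_equal(m1$start, c(101L, 101L))      # T/U equivalence
  expect_equal(m1$mismatches, c(0L, 0L))
  expect_equal(m1$matched_len, c(60L, 60L))  # read "c" too short, dropped

  amb <- suppressMessages(map_reads(reads[1, ], list(s1, s2)))
  expect_equal(nrow(amb), 0L)

  # more substitutions than allowed -> discarded
  noisy <- r101
  for (p in c(30L, 35L, 40L, 45L)) {
    substr(noisy, p, p) <- setdiff(c("A", "C", "G", "U"),
                                   substr(noisy, p, p))[1L]
  }
  m2 <- suppressMessages(map_reads(data.frame(id = "n", sequence = noisy,
                                              quality = strrep("I", 60)),
                                   list(s1), max_mismatches = 3))
  expect_equal(nrow(m2), 0L)
  m3 <- suppressMessages(map_reads(data.frame(id = "n", sequence = noisy,
                                              quality = strrep("I", 60)),
                                   list(s1), max_mismatches = 4))
  expect_equal(m3$mismatches, 4L)
})

test_that("coverage counts interval membership and conserves mapped bases", {
  s <- substrate("s", strrep("ACGU", 10L))
  maps <- data.frame(read_id = c("a", "b"), substrate_id = "s",
                     start = c(3L, 5L), matched_len = c(5L, 10L),
                     mismatches = 0L)
  cov <- coverage(maps, s)
  expect_length(cov$depth, 40L)
  expect_equal(cov$depth[5L], 2L)
  expect_equal(cov$depth[2L], 0L)
  expect_equal(sum(cov$depth), sum(maps$matched_len))
  empty <- coverage(maps[0, ], s)
  expect_true(all(empty$depth == 0L))
})

test_that("rci matches the §-definition examples and the brute-force oracle", {
  p <- structure(list(substrate_id = "s",
                      depth = c(10L, 50L, 0L, 7L, 5L, 0L)),
                 class = "coverage_profile")
  r <- rci(p)
  expect_equal(r$rci[2L], 5)    # 50 / 10
  expect_equal(r$rci[4L], 7)    # previous depth 0 -> equals own depth
  expect_equal(r$rci[6L], 0)    # 0 / 5
  expect_equal(r$rci[1L], 10)   # depth(0) taken as 0

  for (seed in 1:200) {
    prof <- random_profile(len = 50L, seed = seed)
    expect_identical(rci(prof)$rci, rci_oracle(prof$depth))
  }
})

test_that("top_sites ranks by RCI with the deterministic tie rule", {
  set.seed(42)
  mk_prof <- function(id, depth) {
    rci(structure(list(substrate_id = id, depth = depth),
                  class = "coverage_profile"))
  }
  # brute-force oracle on a pair of 30-position toy profiles with ties
  d1 <- sample(5:30, 30L, replace = TRUE)
  d2 <- d1[c(2:30, 1L)]
  profs <- list(mk_prof("b", d1), mk_prof("a", d2))
  got <- suppressMessages(top_sites(profs, K = 8L, window_w = 11L,
                                    min_depth = 5L))
  pool <- do.call(rbind, lapply(profs, function(p) {
    data.frame(substrate_id = p$substrate_id,
               position = seq_along(p$rci), rci = p$rci,
               depth = as.integer(p$depth))
  }))
  pool <- pool[pool$position >= 6L & pool$position <= 25L &
                 pool$depth >= 5L, ]
  pool <- pool[order(-pool$rci, -pool$depth, pool$substrate_id,
                     pool$position), ]
  expect_equal(got$substrate_id, pool$substrate_id[1:8])
  expect_equal(got$position, pool$position[1:8])
  expect_equal(got$rci, pool$rci[1:8])

  # K beyond the eligible positions returns everything, logged
  all_sites <- suppressMessages(top_sites(profs, K = 500L))
  expect_lt(nrow(all_sites), 500L)
  expect_equal(all_sites$rank, seq_len(nrow(all_sites)))

  empty <- mk_prof("e", rep(0L, 30L))
  expect_error(suppressMessages(top_sites(list(empty), K = 3L)),
               "no coverage")
})

test_that("noise-free pipeline recovers every planted site exactly", {
  mod <- digestion_model(site_cleavage_prob = 1, background_break_rate = 0,
                         read_error_rate = 0, ligation_prob = 1,
                         n_molecules = 60L)
  sim <- simulate_library(seed = 13, model = mod, n_reads = 4000,
                          lengths = c(1000L, 1200L), n_sites = c(2L, 3L))
  cfg <- pipeline_config(K = 5L)
  res <- suppressMessages(call_sites(sim$reads, sim$substrates, cfg))
  truth_pos <- paste(sim$truth$substrate_id, sim$truth$position + 1L)
  called <- paste(res$sites$substrate_id, res$sites$position)
  expect_setequal(called, truth_pos)
})
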