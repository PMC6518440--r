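test_that("pairing rules implement the Hoogsteen table", {
  # A.A only in antiparallel (GA motif)
  expect_true(pairing_valid("A", "A", "antiparallel", "GA"))
  expect_false(pairing_valid("A", "A", "parallel", "TC"))
  expect_false(pairing_valid("A", "A", "parallel", "GA"))
  expect_false(pairing_valid("A", "A", "parallel", "GT"))
  # G.G in both orientations
  expect_true(pairing_valid("G", "G", "parallel", "GT"))
  expect_true(pairing_valid("G", "G", "antiparallel", "GA"))
  expect_true(pairing_valid("G", "G", "antiparallel", "GT"))
  # U.A in both orientations
  expect_true(pairing_valid("U", "A", "parallel", "TC"))
  expect_true(pairing_valid("U", "A", "parallel", "GT"))
  expect_true(pairing_valid("U", "A", "antiparallel", "GT"))
  # C.G parallel only
  expect_true(pairing_valid("C", "G", "parallel", "TC"))
  expect_false(pairing_valid("C", "G", "antiparallel", "GA"))
  # U.G never valid
  for (o in c("parallel", "antiparallel"))
    for (mo in c("TC", "GA", "GT"))
      expect_false(pairing_valid("U", "G", o, mo))
})

test_that("a long perfect triplex yields all overlap-allowed sub-windows", {
  w <- enumerate_triplexes("GAGAGAGAGAG", "GAGAGAGAGAG")
  expect_equal(nrow(w), 3L)
  expect_true(all(w$orientation == "antiparallel"))
  expect_true(all(w$motifs == "GA"))
  expect_true(all(w$dna_strand == "+"))
  expect_true(all(w$n_errors == 0L))
  # the length-11 alignment plus its two length-10 sub-windows
  expect_equal(w[, c("rna_start", "rna_end", "dna_start", "dna_end")],
               data.frame(rna_start = c(0L, 0L, 1L),
                          rna_end = c(10L, 11L, 11L),
                          dna_start = c(1L, 0L, 0L),
                          dna_end = c(11L, 11L, 10L)))
  expect_equal(count_triplexes("GAGAGAGAGAG", "GAGAGAGAGAG"), 3)
})

test_that("homopolymer pairs resolve motifs and orientations correctly", {
  # C10 x G10: single parallel TC window
  w <- enumerate_triplexes(strrep("C", 10), strrep("G", 10))
  expect_equal(nrow(w), 1L)
  expect_equal(w$orientation, "parallel")
  expect_equal(w$motifs, "TC")
  expect_equal(w$n_errors, 0L)
  # U10 x A10: one parallel window validated by TC and GT (deduplicated),
  # one antiparallel GT window
  w2 <- enumerate_triplexes(strrep("U", 10), strrep("A", 10))
  expect_equal(nrow(w2), 2L)
  expect_setequal(w2$orientation, c("parallel", "antiparallel"))
  expect_equal(w2$motifs[w2$orientation == "parallel"], "TC,GT")
  expect_equal(w2$motifs[w2$orientation == "antiparallel"], "GT")
  expect_equal(oracle_enumerate(strrep("U", 10), strrep("A", 10))$motifs,
               w2$motifs)
  # U.G is never a valid triple
  expect_equal(count_triplexes(strrep("U", 10), strrep("G", 10)), 0)
})

test_that("pairs shorter than the minimum window length yield no windows", {
  expect_equal(count_triplexes(strrep("U", 9), strrep("A", 50)), 0)
  expect_equal(count_triplexes(strrep("U", 50), strrep("A", 9)), 0)
})

test_that("engine equals the brute-force oracle across parameter settings", {
  set.seed(20240901)
  settings <- list(
    engine_params(),
    engine_params(min_length = 8L, max_error_rate = 20),
    engine_params(max_error_rate = 0),
    engine_params(require_terminal_match = FALSE),
    engine_params(motifs = "GT", orientations = "parallel",
                  scan_both_dna_strands = FALSE)
  )
  for (p in settings) {
    for (k in 1:60) {
      r <- random_rna(sample(p$min_length:25, 1))
      d <- random_dna(sample(p$min_length:25, 1))
      a <- enumerate_triplexes(r, d, p)
      b <- oracle_enumerate(r, d, min_length = p$min_length,
                            rate = p$max_error_rate,
                            terminal = p$require_terminal_match,
                            motifs = p$motifs,
                            orientations = p$orientations,
                            both_strands = p$scan_both_dna_strands)
      expect_identical(nrow(a), nrow(b))
      expect_equal(a, b, ignore_attr = TRUE)
    }
  }
})

test_that("masked positions are unconditional mismatches", {
  rna <- "GAGAGNGAGAG"
  dna <- "GAGAGAGAGAG"
  a <- enumerate_triplexes(rna, dna)
  b <- oracle_enumerate(rna, dna)
  expect_equal(a, b, ignore_attr = TRUE)
  expect_true(all(a$n_errors[a$rna_start <= 5 & a$rna_end > 5] >= 1))
})

test_that("counts are symmetric under DNA reverse complement", {
  set.seed(77)
  for (k in 1:25) {
    r <- random_rna(sample(10:40, 1))
    d <- random_dna(sample(10:40, 1))
    expect_equal(count_triplexes(r, d), count_triplexes(r, revcomp(d)))
  }
  # also for a sequence guaranteed to produce windows
  d <- paste0(random_dna(10), strrep("A", 14), random_dna(10))
  r <- paste0(random_rna(5), strrep("U", 12), random_rna(5))
  expect_gt(count_triplexes(r, d), 0)
  expect_equal(count_triplexes(r, d), count_triplexes(r, revcomp(d)))
})

test_that("appending residues never decreases the count", {
  set.seed(88)
  for (k in 1:20) {
    r <- paste0(random_rna(8), strrep("U", 11))
    d <- paste0(strrep("A", 12), random_dna(8))
    n0 <- count_triplexes(r, d)
    expect_gte(count_triplexes(paste0(r, random_rna(4)), d), n0)
    expect_gte(count_triplexes(r, paste0(d, random_dna(4))), n0)
  }
})

test_that("poly-U vs poly-A counts match the offset/length closed form", {
  for (dims in list(c(10, 10), c(12, 15), c(20, 11))) {
    k <- dims[1]; m <- dims[2]
    # per orientation every (rna offset, dna offset, length) qualifies;
    # parallel TC and GT windows coincide and deduplicate
    closed <- 0
    for (L in 10:min(k, m)) closed <- closed + (k - L + 1) * (m - L + 1)
    closed <- 2 * closed
    expect_equal(count_triplexes(strrep("U", k), strrep("A", m)), closed)
    expect_equal(oracle_count(strrep("U", k), strrep("A", m)), closed)
  }
})

test_that("enumeration is deterministic and input validation works", {
  r <- random_rna(30); d <- random_dna(30)
  expect_identical(enumerate_triplexes(r, d), enumerate_triplexes(r, d))
  expect_error(count_triplexes("", "ACGT"), "empty")
  expect_error(count_triplexes("ACGU", ""), "empty")
  expect_error(count_triplexes("ACGT", "ACGT"), "RNA passed as DNA")
  expect_error(count_triplexes("ACGU", "ACGU"), "DNA passed as RNA")
  expect_error(engine_params(min_length = 1), "min_length")
  expect_error(engine_params(max_error_rate = 100), "max_error_rate")
})

test_that("optional consecutive-error and guanine-rate filters restrict", {
  # window with 2 scattered errors at 20% rate
  rna <- paste0(strrep("U", 3), "G", strrep("U", 3), "G", strrep("U", 3))
  dna <- strrep("A", 11)
  base_n <- count_triplexes(rna, dna,
                            engine_params(max_error_rate = 20))
  expect_gt(base_n, 0)
  # adjacent errors blocked by the consecutive-error cap
  rna2 <- paste0(strrep("U", 4), "GG", strrep("U", 5))
  n_free <- count_triplexes(rna2, dna, engine_params(max_error_rate = 20))
  n_cap <- count_triplexes(rna2, dna,
                           engine_params(max_error_rate = 20,
                                         max_consecutive_errors = 1))
  expect_gt(n_free, n_cap)
  # guanine-rate filter removes A-only targets
  expect_equal(count_triplexes(strrep("U", 10), strrep("A", 10),
                               engine_params(min_guanine_rate = 10)), 0)
  expect_gt(count_triplexes(strrep("C", 10), strrep("G", 10),
                            engine_params(min_guanine_rate = 10)), 0)
})
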